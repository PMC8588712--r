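# Sub-seeds for the replicate streams: one independent stream per
# replicate, derived deterministically from the master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Bootstrap replicates of the learned structure
#'
#' Resamples the prepared dataset with replacement `N` times and re-learns
#' the structure on every resample with [hill_climb()]. The replicate
#' structures are the raw material for credibility assessment and for
#' comparison with an expert-specified structure.
#'
#' @param data Complete prepared data frame of factors (n >= 2 rows).
#' @param N Number of bootstrap replicates (the method's reference setting
#'   is 10,000; smaller values are fine for exploration).
#' @param config A [score_config()].
#' @param seed Integer master seed; each replicate uses an independent
#'   stream derived from it, so results are reproducible and invariant to
#'   chunking.
#' @param keep_indices Keep each replicate's resampled row indices as an
#'   attribute (`attr(, "indices")`), mainly for verification.
#' @return A list of `N` [bn_dag()] objects (class
#'   `"bnmmi_replicates"`).
#' @export
bootstrap_replicates <- function(data, N, config = score_config(),
                                 seed = 1L, keep_indices = FALSE) {
  stopifnot(N >= 1)
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 rows to resample")
  enc <- encode_discrete(data)
  seeds <- derive_seeds(seed, N)
  reps <- vector("list", N)
  for (b in seq_len(N)) {
    set.seed(seeds[[b]])
    idx <- sample.int(n, n, replace = TRUE)
    enc_b <- list(X = enc$X[idx, , drop = FALSE], nlev = enc$nlev,
                  vars = enc$vars, levels = enc$levels)
    dag <- hill_climb_int(enc_b, config)
    if (keep_indices) attr(dag, "indices") <- idx
    reps[[b]] <- dag
  }
  structure(reps, class = c("bnmmi_replicates", "list"), seed = seed)
}

#' Skeleton relation frequencies across replicates
#'
#' For every unordered variable pair, the fraction of replicate structures
#' whose skeleton contains the pair. Orientation is ignored because it is
#' not identifiable within a Markov-equivalence class.
#'
#' @param replicates A non-empty list of [bn_dag()] objects over a common
#'   node set (e.g. from [bootstrap_replicates()]).
#' @return A named numeric vector over all unordered pairs, names
#'   `"a|b"` with `a < b` alphabetically; values in `[0, 1]`.
#' @export
relation_frequencies <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  nodes <- replicates[[1L]]$nodes
  for (r in replicates) {
    if (!setequal(r$nodes, nodes)) stop("replicates have differing node sets")
  }
  ns <- sort(nodes)
  pairs <- t(utils::combn(ns, 2L))
  keys <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (r in replicates) {
    k <- skeleton_keys(r)
    counts[k] <- counts[k] + 1
  }
  counts / length(replicates)
}

#' Credibility assessment of a learned structure
#'
#' A learned missing data structure is judged credible when every one of
#' its skeleton relations reappears in at least `threshold` of the
#' bootstrap replicates. Only the original structure's relations are
#' checked; extra relations appearing in some replicates do not count
#' against credibility.
#'
#' @param original The structure learned from the original dataset
#'   ([bn_dag()]).
#' @param freqs Relation frequencies from [relation_frequencies()].
#' @param threshold Credibility threshold in `(0, 1]` (default 0.90).
#' @param n_replicates Number of replicates behind `freqs` (for reporting).
#' @return An object of class `"bnmmi_credibility"`: list with
#'   `credible` (logical), `threshold`, `n_replicates`, `relations`
#'   (data frame of the original relations with their frequencies and
#'   pass/fail), and `frequencies` (the full vector).
#' @export
assess_credibility <- function(original, freqs, threshold = 0.90,
                               n_replicates = NA_integer_) {
  stopifnot(inherits(original, "bn_dag"),
            threshold > 0, threshold <= 1)
  keys <- skeleton_keys(original)
  f <- if (length(keys)) {
    missing_keys <- setdiff(keys, names(freqs))
    if (length(missing_keys)) stop("frequency missing for relation(s): ",
                                   paste(missing_keys, collapse = ", "))
    unname(freqs[keys])
  } else {
    numeric(0)
  }
  relations <- data.frame(relation = keys, frequency = f,
                          passed = f >= threshold,
                          stringsAsFactors = FALSE)
  structure(list(credible = all(relations$passed),
                 threshold = threshold,
                 n_replicates = n_replicates,
                 relations = relations,
                 frequencies = freqs),
            class = "bnmmi_credibility")
}

#' @export
print.bnmmi_credibility <- function(x, ...) {
  cat("Bootstrap credibility assessment (threshold ",
      format(100 * x$threshold), "%, N = ", x$n_replicates, ")\n", sep = "")
  if (nrow(x$relations)) {
    for (i in seq_len(nrow(x$relations))) {
      cat(sprintf("  %-30s %6.2f%%  %s\n", x$relations$relation[i],
                  100 * x$relations$frequency[i],
                  if (x$relations$passed[i]) "ok" else "BELOW THRESHOLD"))
    }
  } else {
    cat("  (empty structure: vacuously credible)\n")
  }
  cat(if (x$credible) "=> credible\n" else "=> NOT credible\n")
  invisible(x)
}

#' Compare replicate structures with an expert structure
#'
#' For every unordered variable pair, the percentage of replicates that
#' agree with the expert-specified structure on the presence or absence of
#' the relation (real-study consistency), and its complement (real-study
#' inconsistency).
#'
#' @param replicates A list of [bn_dag()] objects.
#' @param expert The expert-specified structure ([bn_dag()] over the same
#'   node set, e.g. from [read_edge_list()]).
#' @return An object of class `"bnmmi_expert_comparison"`: data frame with
#'   columns `relation`, `in_expert`, `consistency` and `inconsistency`
#'   (percentages summing to 100 per row).
#' @export
compare_with_expert <- function(replicates, expert) {
  stopifnot(inherits(expert, "bn_dag"))
  if (!setequal(replicates[[1L]]$nodes, expert$nodes)) {
    stop("expert structure is over a different node set")
  }
  freqs <- relation_frequencies(replicates)
  in_expert <- names(freqs) %in% skeleton_keys(expert)
  consistency <- 100 * ifelse(in_expert, freqs, 1 - freqs)
  out <- data.frame(relation = names(freqs),
                    in_expert = in_expert,
                    consistency = unname(consistency),
                    inconsistency = 100 - unname(consistency),
                    stringsAsFactors = FALSE)
  class(out) <- c("bnmmi_expert_comparison", "data.frame")
  out
}

#' @export
print.bnmmi_expert_comparison <- function(x, ...) {
  cat("Agreement with the expert structure (per unordered pair):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-30s %s  consistency %6.2f%%\n", x$relation[i],
                if (x$in_expert[i]) "expert: present" else "expert: absent ",
                x$consistency[i]))
  }
  invisible(x)
}

#' Identify the missing mechanism from the learned structure
#'
#' The decision rule of the method's final step. If the credibility
#' assessment failed, identification is deferred (`"INCONCLUSIVE"`).
#' Otherwise the verdict is `"MCAR"` when no skeleton relation touches the
#' missing indicator, and `"NOT_MCAR_MAR_OR_MNAR"` when at least one does
#' (MAR and MNAR cannot be distinguished, since the missing values
#' themselves are unobserved). The rule depends only on the skeleton
#' incident to the indicator and the credibility flag — never on arc
#' orientation.
#'
#' @param original The learned structure ([bn_dag()]).
#' @param indicator Name of the missing-indicator node.
#' @param credibility A [assess_credibility()] result.
#' @return An object of class `"bnmmi_verdict"`: list with `verdict` (one
#'   of `"MCAR"`, `"NOT_MCAR_MAR_OR_MNAR"`, `"INCONCLUSIVE"`),
#'   `indicator`, `incident_relations` (character), and `credible`.
#' @export
identify_mechanism <- function(original, indicator, credibility) {
  stopifnot(inherits(original, "bn_dag"),
            inherits(credibility, "bnmmi_credibility"))
  if (!indicator %in% original$nodes) {
    stop("indicator '", indicator, "' is not a node of the structure")
  }
  sk <- skeleton(original)
  incident <- sk[sk[, 1L] == indicator | sk[, 2L] == indicator, ,
                 drop = FALSE]
  incident_keys <- skeleton_keys(incident)
  verdict <- if (!credibility$credible) {
    "INCONCLUSIVE"
  } else if (length(incident_keys) == 0L) {
    "MCAR"
  } else {
    "NOT_MCAR_MAR_OR_MNAR"
  }
  structure(list(verdict = verdict,
                 indicator = indicator,
                 incident_relations = incident_keys,
                 credible = credibility$credible),
            class = "bnmmi_verdict")
}

#' @export
print.bnmmi_verdict <- function(x, ...) {
  lab <- switch(x$verdict,
    MCAR = "MCAR (no relation between the missing indicator and any variable)",
    NOT_MCAR_MAR_OR_MNAR =
      "not MCAR; MAR or MNAR (indistinguishable without the missing values)",
    INCONCLUSIVE =
      "inconclusive (structure failed the credibility assessment)")
  cat("Missing mechanism verdict for '", x$indicator, "': ", lab, "\n",
      sep = "")
  if (length(x$incident_relations)) {
    cat("  evidence:", paste(x$incident_relations, collapse = ", "), "\n")
  }
  invisible(x)
}
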