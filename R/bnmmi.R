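#' Identify the missing mechanism of a dataset
#'
#' The main fitting function. Given a categorical dataset in which exactly
#' one variable is incompletely observed, it (1) replaces that variable by
#' its missing indicator and learns the missing data structure by
#' score-based hill climbing, (2) assesses the structure's credibility by
#' nonparametric bootstrap (every learned relation must reappear in at
#' least `threshold` of the replicates) and, optionally, compares the
#' replicates with an expert-specified structure, and (3) classifies the
#' missing mechanism as MCAR, not-MCAR (MAR or MNAR), or inconclusive.
#'
#' If no variable has missing cells the indicator must be named explicitly
#' via `indicator` (a column already coding 0/1 missingness) — this is how
#' simulated datasets, where only the indicator is generated, are analysed.
#'
#' @param data Data frame of factors; either one variable contains `NA`
#'   cells, or `indicator` names an existing 0/1 indicator column.
#' @param var Name of the incompletely observed variable; by default the
#'   single variable containing `NA`s.
#' @param indicator Name of an existing missing-indicator column, for data
#'   that are already prepared.
#' @param n_boot Number of bootstrap replicates (default 10,000, the
#'   method's reference setting; reduce for quick exploration).
#' @param threshold Credibility threshold in `(0, 1]` (default 0.90).
#' @param config A [score_config()].
#' @param seed Integer master seed for the bootstrap.
#' @param expert Optional expert structure: a [bn_dag()] or the path of an
#'   edge-list file ([read_edge_list()]).
#' @param prior_weight Dirichlet equivalent sample size for parameter
#'   learning on the selected structure.
#' @return An object of class `"bnmmi"`: list with elements `structure`
#'   (learned [bn_dag()]), `fit` (CPTs via [fit_parameters()]),
#'   `credibility`, `verdict`, `expert_comparison` (or `NULL`),
#'   `indicator`, `prepared` (the analysed complete data frame), `n`,
#'   `n_boot`, `seed` and `config`.
#' @examples
#' set.seed(7)
#' d <- generate_complete(500)
#' d <- impose_mar(d, rate = 0.15)
#' f <- bnmmi(d, indicator = "fee_missing", n_boot = 50, seed = 7)
#' f
#' @export
bnmmi <- function(data, var = NULL, indicator = NULL, n_boot = 10000L,
                  threshold = 0.90, config = score_config(), seed = 1L,
                  expert = NULL, prior_weight = 1) {
  stopifnot(is.data.frame(data))
  if (is.null(indicator)) {
    if (is.null(var)) {
      mv <- missing_variables(data)
      if (length(mv) == 0L) {
        stop("no variable contains missing cells; pass `indicator` for ",
             "already-prepared data")
      }
      if (length(mv) > 1L) {
        stop("multivariate missingness is not supported (missing in: ",
             paste(mv, collapse = ", "), ")")
      }
      var <- mv
    }
    prep <- make_missing_indicator(data, var)
    prepared <- prep$data
    indicator <- prep$indicator_variable
  } else {
    if (!indicator %in% names(data)) {
      stop("indicator column not found: ", indicator)
    }
    if (anyNA(data)) stop("data with an explicit indicator must be complete")
    prepared <- data
  }
  learned <- hill_climb(prepared, config)
  reps <- bootstrap_replicates(prepared, n_boot, config, seed)
  freqs <- relation_frequencies(reps)
  credibility <- assess_credibility(learned, freqs, threshold, n_boot)
  verdict <- identify_mechanism(learned, indicator, credibility)
  expert_cmp <- NULL
  if (!is.null(expert)) {
    if (is.character(expert)) {
      expert <- read_edge_list(expert, nodes = learned$nodes)
    }
    expert_cmp <- compare_with_expert(reps, expert)
  }
  structure(list(structure = learned,
                 fit = fit_parameters(prepared, learned, prior_weight),
                 credibility = credibility,
                 verdict = verdict,
                 expert_comparison = expert_cmp,
                 indicator = indicator,
                 prepared = prepared,
                 n = nrow(prepared),
                 n_boot = n_boot,
                 seed = seed,
                 config = config),
            class = "bnmmi")
}

#' @export
print.bnmmi <- function(x, ...) {
  cat("Missing mechanism identification (", x$n, " records, ",
      length(x$structure$nodes), " variables, indicator '", x$indicator,
      "')\n", sep = "")
  if (nrow(x$structure$arcs)) {
    cat("Learned structure:",
        paste(x$structure$arcs[, 1L], "->", x$structure$arcs[, 2L],
              collapse = "; "), "\n")
  } else {
    cat("Learned structure: empty graph\n")
  }
  cat("Credibility      :",
      if (x$credibility$credible) "credible" else "NOT credible",
      sprintf("(threshold %.0f%%, N = %d)\n", 100 * x$credibility$threshold,
              x$n_boot))
  print(x$verdict)
  invisible(x)
}

#' @export
summary.bnmmi <- function(object, ...) {
  structure(list(object = object), class = "summary.bnmmi")
}

#' @export
print.summary.bnmmi <- function(x, ...) {
  print(x$object)
  cat("\n")
  print(x$object$credibility)
  if (!is.null(x$object$expert_comparison)) {
    cat("\n")
    print(x$object$expert_comparison)
  }
  cat("\nBootstrap relation frequencies:\n")
  f <- x$object$credibility$frequencies
  for (k in names(f)) cat(sprintf("  %-30s %6.2f%%\n", k, 100 * f[[k]]))
  invisible(x)
}

#' @export
coef.bnmmi <- function(object, ...) object$fit$cpts

#' @export
simulate.bnmmi <- function(object, nsim = 1, seed = NULL, ...) {
  simulate.bn_fit(object$fit, nsim = nsim, seed = seed, ...)
}

#' Plot a learned missing data structure
#'
#' Draws the learned DAG with the missing indicator highlighted, using
#' igraph when available (otherwise a simple circular layout in base
#' graphics).
#'
#' @param x A [bnmmi()] result.
#' @param ... Passed to `plot.igraph()` when igraph is installed.
#' @export
plot.bnmmi <- function(x, ...) {
  dag <- x$structure
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(dag$arcs), directed = TRUE,
      vertices = data.frame(name = dag$nodes))
    cols <- ifelse(dag$nodes == x$indicator, "tomato", "lightsteelblue")
    igraph::plot.igraph(g, vertex.color = cols, ...)
  } else {
    p <- length(dag$nodes)
    theta <- 2 * pi * seq_len(p) / p
    xs <- cos(theta); ys <- sin(theta)
    graphics::plot(xs, ys, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                   axes = FALSE, xlab = "", ylab = "", pch = 19,
                   col = ifelse(dag$nodes == x$indicator, "tomato",
                                "lightsteelblue"), cex = 3)
    graphics::text(xs * 1.25, ys * 1.25, dag$nodes)
    for (i in seq_len(nrow(dag$arcs))) {
      a <- match(dag$arcs[i, 1L], dag$nodes)
      b <- match(dag$arcs[i, 2L], dag$nodes)
      graphics::arrows(xs[a], ys[a], xs[b], ys[b], length = 0.12)
    }
  }
  invisible(x)
}

#' Serialize an identification result as JSON
#'
#' Writes the learned structure, bootstrap credibility report, verdict and
#' (if present) expert comparison in a versioned JSON schema.
#'
#' @param x A [bnmmi()] result.
#' @param path Output file path.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "bnmmi"))
  obj <- list(
    schema = "bnmmi-report/1",
    n = x$n,
    indicator = x$indicator,
    seed = x$seed,
    n_boot = x$n_boot,
    structure = list(
      nodes = as.list(x$structure$nodes),
      arcs = apply(x$structure$arcs, 1L, function(a) {
        list(from = a[[1L]], to = a[[2L]])
      })),
    credibility = list(
      credible = x$credibility$credible,
      threshold = x$credibility$threshold,
      relations = x$credibility$relations,
      frequencies = as.list(x$credibility$frequencies)),
    verdict = list(
      verdict = x$verdict$verdict,
      incident_relations = as.list(x$verdict$incident_relations)))
  if (!is.null(x$expert_comparison)) {
    obj$expert_comparison <- as.data.frame(x$expert_comparison)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
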