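#' Scoring configuration for structure learning
#'
#' Bundles the network score and search settings used by [hill_climb()],
#' [family_score()] and [network_score()]. The default score is the BIC for
#' discrete data (multinomial log-likelihood minus `log(n)/2` per free
#' parameter); the BDeu score (Bayesian Dirichlet equivalent uniform) is
#' available as an alternative. Both are decomposable and score equivalent,
#' so Markov-equivalent DAGs always receive equal scores.
#'
#' @param score `"bic"` (default) or `"bdeu"`.
#' @param ess Equivalent sample size of the BDeu prior (ignored for BIC).
#' @param epsilon Minimal score improvement for a hill-climbing move;
#'   must be positive.
#' @return An object of class `"bn_score_config"`.
#' @export
score_config <- function(score = c("bic", "bdeu"), ess = 1, epsilon = 1e-9) {
  score <- match.arg(score)
  stopifnot(is.numeric(ess), ess > 0, is.numeric(epsilon), epsilon > 0)
  structure(list(score = score, ess = ess, epsilon = epsilon),
            class = "bn_score_config")
}

# Local score of one family from the integer encoding.
# enc: encode_discrete() output; ci: child column index; pa: parent indices.
family_score_int <- function(enc, ci, pa, config) {
  n <- nrow(enc$X)
  rc <- enc$nlev[[ci]]
  q <- if (length(pa)) prod(enc$nlev[pa]) else 1L
  if (n == 0L) stop("empty dataset")
  idx <- enc$X[, ci]
  mult <- rc
  for (k in pa) {
    idx <- idx + (enc$X[, k] - 1L) * mult
    mult <- mult * enc$nlev[[k]]
  }
  counts <- tabulate(idx, nbins = rc * q)
  tab <- matrix(counts, nrow = rc)
  nj <- colSums(tab)
  if (config$score == "bic") {
    pos <- counts > 0L
    ll <- sum(counts[pos] * log(counts[pos])) -
      sum(nj[nj > 0L] * log(nj[nj > 0L]))
    ll - 0.5 * log(n) * (rc - 1L) * q
  } else {
    a_j <- config$ess / q
    a_jk <- config$ess / (rc * q)
    sum(lgamma(a_j) - lgamma(a_j + nj)) +
      sum(lgamma(a_jk + counts) - lgamma(a_jk))
  }
}

#' Local score of one node given a parent set
#'
#' Decomposable score of the family `child | parents` used by the
#' hill-climbing search. With the default BIC score this is the multinomial
#' log-likelihood of the child given each joint parent configuration minus
#' `log(n)/2` times the number of free parameters.
#'
#' @param data Complete data frame of factors.
#' @param child Child variable name.
#' @param parents Character vector of parent names (default none).
#' @param config A [score_config()].
#' @return A single numeric score (deterministic in the data).
#' @examples
#' d <- data.frame(x = factor(rep(c("0", "1"), each = 5)))
#' family_score(d, "x")   # 10*log(0.5) - log(10)/2
#' @export
family_score <- function(data, child, parents = character(0),
                         config = score_config()) {
  enc <- encode_discrete(data)
  ci <- match(child, enc$vars)
  if (is.na(ci)) stop("unknown child: ", child)
  pa <- match(parents, enc$vars)
  if (anyNA(pa)) stop("unknown parent(s): ",
                      paste(parents[is.na(pa)], collapse = ", "))
  if (ci %in% pa) stop("child cannot be its own parent")
  if (enc$nlev[[ci]] == 1L) {
    warning("child '", child, "' has a single observed level; ",
            "family has zero free parameters")
  }
  family_score_int(enc, ci, pa, config)
}

#' Score of a whole network
#'
#' Sum of [family_score()] over all nodes of the DAG. Decomposability means
#' a single-arc change only touches one or two families; score equivalence
#' means all members of a Markov-equivalence class score identically.
#'
#' @param data Complete data frame of factors over exactly the DAG's nodes.
#' @param dag A [bn_dag()] object.
#' @param config A [score_config()].
#' @return A single numeric score.
#' @export
network_score <- function(data, dag, config = score_config()) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(data), dag$nodes)) {
    stop("DAG nodes and dataset variables differ")
  }
  enc <- encode_discrete(data)
  parents <- dag_parents(dag)
  total <- 0
  for (v in dag$nodes) {
    ci <- match(v, enc$vars)
    pa <- match(parents[[v]], enc$vars)
    total <- total + family_score_int(enc, ci, pa, config)
  }
  total
}
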