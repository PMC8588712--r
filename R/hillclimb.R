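# Greedy hill-climbing structure search on the integer encoding.
#
# Starts from the empty graph and repeatedly applies the single arc
# addition, deletion or reversal with the largest score improvement, under
# acyclicity, until no operation improves the score by more than epsilon.
# Candidate order (add < delete < reverse, then parent, then child, both in
# node order) breaks exact ties, making the search fully deterministic.
hill_climb_int <- function(enc, config) {
  p <- length(enc$vars)
  n <- nrow(enc$X)
  if (n == 0L) stop("empty dataset")
  if (p < 2L) {
    return(bn_dag(enc$vars))
  }
  if (any(enc$nlev == 1L)) {
    warning("variable(s) with a single observed level: ",
            paste(enc$vars[enc$nlev == 1L], collapse = ", "))
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fam <- function(ci, pa) {
    key <- paste(ci, paste(sort(pa), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score_int(enc, ci, pa, config)
      cache[[key]] <- val
    }
    val
  }
  adj <- matrix(FALSE, p, p)
  node_score <- vapply(seq_len(p), function(ci) fam(ci, integer(0)),
                       numeric(1L))
  # does a directed path a ~> b exist in adj?
  has_path <- function(adj, a, b) {
    seen <- logical(p)
    stack <- a
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (v == b) return(TRUE)
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, which(adj[v, ]))
      }
    }
    FALSE
  }
  repeat {
    best <- list(delta = config$epsilon, op = NULL)
    consider <- function(delta, op, i, j) {
      if (delta > best$delta) best <<- list(delta = delta, op = op,
                                            i = i, j = j)
    }
    # additions
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || adj[i, j] || adj[j, i]) next
      if (has_path(adj, j, i)) next          # i -> j would close a cycle
      pa <- which(adj[, j])
      consider(fam(j, c(pa, i)) - fam(j, pa), "add", i, j)
    }
    # deletions
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!adj[i, j]) next
      pa <- which(adj[, j])
      consider(fam(j, setdiff(pa, i)) - fam(j, pa), "delete", i, j)
    }
    # reversals
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!adj[i, j]) next
      adj2 <- adj; adj2[i, j] <- FALSE
      if (has_path(adj2, i, j)) next         # j -> i would close a cycle
      pa_j <- which(adj[, j]); pa_i <- which(adj[, i])
      delta <- (fam(j, setdiff(pa_j, i)) - fam(j, pa_j)) +
        (fam(i, c(pa_i, j)) - fam(i, pa_i))
      consider(delta, "reverse", i, j)
    }
    if (is.null(best$op)) break
    if (best$op == "add") {
      adj[best$i, best$j] <- TRUE
    } else if (best$op == "delete") {
      adj[best$i, best$j] <- FALSE
    } else {
      adj[best$i, best$j] <- FALSE
      adj[best$j, best$i] <- TRUE
    }
  }
  adjacency_to_dag(adj, enc$vars)
}

#' Learn a Bayesian-network structure by hill climbing
#'
#' Score-based greedy search for the missing data structure: starting from
#' the empty graph, the single arc addition, deletion or reversal with the
#' largest score improvement is applied at each step, maintaining
#' acyclicity, until no single-arc operation improves the score by more
#' than `config$epsilon`. The result is locally optimal and the search is
#' deterministic: exact score ties are broken by a fixed candidate order
#' (add before delete before reverse, then parent, then child).
#'
#' @param data Complete data frame of factors (at least two variables; run
#'   [make_missing_indicator()] first if the data contain missing cells).
#' @param config A [score_config()].
#' @return A [bn_dag()] object.
#' @examples
#' set.seed(1)
#' x <- rbinom(500, 1, 0.5)
#' y <- rbinom(500, 1, ifelse(x == 1, 0.9, 0.1))
#' d <- data.frame(x = factor(x), y = factor(y))
#' hill_climb(d)
#' @export
hill_climb <- function(data, config = score_config()) {
  stopifnot(inherits(config, "bn_score_config"))
  hill_climb_int(encode_discrete(data), config)
}
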