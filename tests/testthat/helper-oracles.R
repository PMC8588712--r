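# Independent oracles and fixture builders used across the suite.

# All acyclic digraphs on a node set: every unordered pair is absent,
# forward or backward; cyclic combinations are filtered out.
enumerate_dags <- function(nodes) {
  pairs <- t(combn(nodes, 2L))
  k <- nrow(pairs)
  out <- list()
  for (code in seq_len(3L^k) - 1L) {
    digits <- (code %/% 3L^(seq_len(k) - 1L)) %% 3L
    arcs <- NULL
    for (i in seq_len(k)) {
      if (digits[i] == 1L) arcs <- rbind(arcs, pairs[i, ])
      if (digits[i] == 2L) arcs <- rbind(arcs, rev(pairs[i, ]))
    }
    dag <- tryCatch(bn_dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <- dag
  }
  out
}

# Brute-force multinomial log-likelihood of child | parents via table().
oracle_family_loglik <- function(data, child, parents) {
  if (length(parents) == 0L) {
    counts <- table(data[[child]])
    n <- sum(counts)
    return(sum(counts[counts > 0] * log(counts[counts > 0] / n)))
  }
  cfg <- interaction(data[parents], drop = FALSE)
  ll <- 0
  for (g in levels(cfg)) {
    sub <- data[[child]][cfg == g]
    counts <- table(sub)
    nj <- sum(counts)
    if (nj > 0) ll <- ll + sum(counts[counts > 0] *
                                 log(counts[counts > 0] / nj))
  }
  ll
}

oracle_bic <- function(data, child, parents) {
  r <- nlevels(data[[child]])
  q <- if (length(parents)) prod(vapply(data[parents], nlevels, 1L)) else 1L
  oracle_family_loglik(data, child, parents) -
    0.5 * log(nrow(data)) * (r - 1) * q
}

oracle_network_bic <- function(data, dag) {
  sum(vapply(dag$nodes, function(v) {
    pa <- dag$arcs[dag$arcs[, 2L] == v, 1L]
    oracle_bic(data, v, pa)
  }, numeric(1L)))
}

# Random complete factor dataset over binary/ternary variables.
random_discrete <- function(n, nlev = c(2L, 2L, 2L), seed = 1L) {
  set.seed(seed)
  cols <- lapply(seq_along(nlev), function(j) {
    factor(sample(as.character(seq_len(nlev[j]) - 1L), n, replace = TRUE),
           levels = as.character(seq_len(nlev[j]) - 1L))
  })
  names(cols) <- paste0("v", seq_along(nlev))
  as.data.frame(cols)
}

# Single add/delete/reverse neighbors of a DAG (validity-checked).
dag_neighbors <- function(dag) {
  out <- list()
  nodes <- dag$nodes
  arcs <- dag$arcs
  has <- function(a, b) any(arcs[, 1L] == a & arcs[, 2L] == b)
  for (a in nodes) for (b in nodes) {
    if (a == b) next
    if (!has(a, b) && !has(b, a)) {
      g <- tryCatch(bn_dag(nodes, rbind(arcs, c(a, b))),
                    error = function(e) NULL)
      if (!is.null(g)) out[[length(out) + 1L]] <- g
    } else if (has(a, b)) {
      keep <- !(arcs[, 1L] == a & arcs[, 2L] == b)
      out[[length(out) + 1L]] <- bn_dag(nodes, arcs[keep, , drop = FALSE])
      g <- tryCatch(bn_dag(nodes, rbind(arcs[keep, , drop = FALSE],
                                        c(b, a))),
                    error = function(e) NULL)
      if (!is.null(g)) out[[length(out) + 1L]] <- g
    }
  }
  out
}

# Strongly dependent binary pair: P(y=1|x=1)=.9, P(y=1|x=0)=.1.
strong_pair <- function(n = 1000L, seed = 1L) {
  set.seed(seed)
  x <- rbinom(n, 1L, 0.5)
  y <- rbinom(n, 1L, ifelse(x == 1L, 0.9, 0.1))
  data.frame(x = factor(x, levels = 0:1), y = factor(y, levels = 0:1))
}
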