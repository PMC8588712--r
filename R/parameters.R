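#' Bayesian parameter learning for a discrete network
#'
#' Estimates one conditional probability table (CPT) per node by the
#' posterior mean under a symmetric Dirichlet prior: each CPT entry is
#' `(count + a) / (row total + r * a)` where `a` is the per-cell prior
#' weight, `prior_weight` distributed uniformly over the family's cells.
#' Rows for unobserved parent configurations are therefore well defined
#' (uniform).
#'
#' @param data Complete data frame of factors over the DAG's nodes.
#' @param dag A [bn_dag()] object.
#' @param prior_weight Total equivalent sample size of the Dirichlet prior
#'   per family (default 1), split uniformly over the family's cells.
#' @return An object of class `"bn_fit"`: list with `dag` and `cpts`, where
#'   `cpts[[v]]` is a matrix with one row per joint parent configuration
#'   (in row-major order of the parents as listed) and one column per child
#'   level; attribute `"parents"` records the parent order.
#' @examples
#' d <- data.frame(x = factor(c("0", "0", "0", "1")))
#' fit_parameters(d, bn_dag("x"), prior_weight = 1)$cpts$x  # (0.7, 0.3)
#' @export
fit_parameters <- function(data, dag, prior_weight = 1) {
  stopifnot(inherits(dag, "bn_dag"), prior_weight > 0)
  if (!setequal(names(data), dag$nodes)) {
    stop("DAG nodes and dataset variables differ")
  }
  enc <- encode_discrete(data)
  parents <- dag_parents(dag)
  cpts <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) {
    ci <- match(v, enc$vars)
    pa <- match(parents[[v]], enc$vars)
    rc <- enc$nlev[[ci]]
    q <- if (length(pa)) prod(enc$nlev[pa]) else 1L
    idx <- enc$X[, ci]
    mult <- rc
    for (k in pa) {
      idx <- idx + (enc$X[, k] - 1L) * mult
      mult <- mult * enc$nlev[[k]]
    }
    counts <- matrix(tabulate(idx, nbins = rc * q), nrow = rc)
    a <- prior_weight / (rc * q)
    post <- t(counts) + a
    tab <- post / rowSums(post)
    colnames(tab) <- enc$levels[[ci]]
    rownames(tab) <- if (length(pa)) {
      cfg <- expand.grid(lapply(pa, function(k) enc$levels[[k]]),
                         stringsAsFactors = FALSE)
      apply(cfg, 1L, paste, collapse = ",")
    } else {
      ""
    }
    attr(tab, "parents") <- parents[[v]]
    cpts[[v]] <- tab
  }
  structure(list(dag = dag, cpts = cpts,
                 levels = stats::setNames(enc$levels, enc$vars)),
            class = "bn_fit")
}

# Row index of a parent configuration in a CPT, given level assignments.
cpt_row <- function(fit, v, assignment) {
  pa <- attr(fit$cpts[[v]], "parents")
  if (!length(pa)) return(1L)
  idx <- 1L
  mult <- 1L
  for (k in pa) {
    li <- match(assignment[[k]], fit$levels[[k]])
    if (is.na(li)) stop("invalid level '", assignment[[k]], "' for ", k)
    idx <- idx + (li - 1L) * mult
    mult <- mult * length(fit$levels[[k]])
  }
  idx
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorized joint distribution of the network — the product
#' over nodes of the conditional probability of the node's level given its
#' parents' levels — at one complete assignment. Marginalization over
#' partial assignments is deliberately out of scope.
#'
#' @param fit A [fit_parameters()] result.
#' @param assignment Named character vector or list mapping every node to
#'   one of its levels.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(fit, assignment) {
  stopifnot(inherits(fit, "bn_fit"))
  assignment <- as.list(assignment)
  missing_nodes <- setdiff(fit$dag$nodes, names(assignment))
  if (length(missing_nodes)) {
    stop("assignment must cover every node; missing: ",
         paste(missing_nodes, collapse = ", "))
  }
  prob <- 1
  for (v in fit$dag$nodes) {
    li <- match(assignment[[v]], fit$levels[[v]])
    if (is.na(li)) stop("invalid level '", assignment[[v]], "' for ", v)
    prob <- prob * fit$cpts[[v]][cpt_row(fit, v, assignment), li]
  }
  unname(prob)
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("Fitted discrete Bayesian network:", length(x$dag$nodes),
      "nodes,", nrow(x$dag$arcs), "arcs\n")
  for (v in x$dag$nodes) {
    pa <- attr(x$cpts[[v]], "parents")
    cat("  P(", v, if (length(pa)) paste0(" | ", paste(pa, collapse = ", ")),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Simulate records from a fitted network
#'
#' Ancestral sampling: nodes are drawn in topological order, each from its
#' CPT row selected by its parents' sampled levels.
#'
#' @param object A [fit_parameters()] result.
#' @param nsim Number of records to draw.
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @param ... Unused.
#' @return A data frame of factors with `nsim` rows.
#' @export
simulate.bn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- object$dag$nodes
  adj <- dag_adjacency(object$dag)
  order <- character(0)
  left <- nodes
  while (length(left)) {
    ready <- left[vapply(left, function(v) {
      all(rownames(adj)[adj[, v]] %in% order)
    }, logical(1L))]
    order <- c(order, ready)
    left <- setdiff(left, ready)
  }
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  codes <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in order) {
    cpt <- object$cpts[[v]]
    pa <- attr(cpt, "parents")
    rc <- ncol(cpt)
    if (!length(pa)) {
      row <- rep(1L, nsim)
    } else {
      row <- rep(1L, nsim)
      mult <- 1L
      for (k in pa) {
        row <- row + (codes[[k]] - 1L) * mult
        mult <- mult * length(object$levels[[k]])
      }
    }
    u <- stats::runif(nsim)
    cum <- t(apply(cpt, 1L, cumsum))
    drawn <- rowSums(u > cum[row, , drop = FALSE]) + 1L
    codes[[v]] <- drawn
    out[[v]] <- factor(object$levels[[v]][drawn],
                       levels = object$levels[[v]])
  }
  as.data.frame(out[nodes], stringsAsFactors = FALSE)
}

#' Export fitted CPTs as JSON
#'
#' @param fit A [fit_parameters()] result.
#' @param path Output file path.
#' @export
write_cpts_json <- function(fit, path) {
  stopifnot(inherits(fit, "bn_fit"))
  obj <- lapply(fit$dag$nodes, function(v) {
    cpt <- fit$cpts[[v]]
    list(node = v,
         parents = as.list(attr(cpt, "parents")),
         levels = as.list(colnames(cpt)),
         rows = lapply(seq_len(nrow(cpt)), function(i) {
           list(parent_config = rownames(cpt)[i],
                probabilities = unname(cpt[i, ]))
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
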