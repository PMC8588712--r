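#' Directed acyclic graph over named variables
#'
#' Constructor for the structure object used throughout the package: a node
#' set plus a set of directed arcs, checked for self-loops and cycles.
#'
#' @param nodes Character vector of variable names.
#' @param arcs Two-column character matrix (or data frame) of directed arcs,
#'   first column parent, second column child. May have zero rows.
#' @return An object of class `"bn_dag"`: a list with elements `nodes` and
#'   `arcs` (a two-column character matrix with columns `from`, `to`).
#' @examples
#' bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' @export
bn_dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(character(0), 0L, 2L)
  } else {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2L) stop("arcs must have two columns (from, to)")
    storage.mode(arcs) <- "character"
  }
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  bad <- setdiff(c(arcs), nodes)
  if (length(bad)) stop("arc endpoint not in nodes: ",
                        paste(unique(bad), collapse = ", "))
  if (any(arcs[, 1L] == arcs[, 2L])) stop("self-loop arc")
  if (anyDuplicated(paste(arcs[, 1L], arcs[, 2L]))) stop("duplicate arc")
  dag <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (!is_acyclic(dag)) stop("arc set contains a directed cycle")
  dag
}

# Adjacency matrix (logical, parent x child) of a bn_dag.
dag_adjacency <- function(dag) {
  p <- length(dag$nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs)) adj[dag$arcs] <- TRUE
  adj
}

adjacency_to_dag <- function(adj, nodes) {
  idx <- which(adj, arr.ind = TRUE)
  arcs <- cbind(nodes[idx[, 1L]], nodes[idx[, 2L]])
  structure(list(nodes = nodes,
                 arcs = matrix(as.character(arcs), ncol = 2L,
                               dimnames = list(NULL, c("from", "to")))),
            class = "bn_dag")
}

# Kahn's algorithm on a logical adjacency matrix.
acyclic_adj <- function(adj) {
  repeat {
    if (!nrow(adj)) return(TRUE)
    sinks <- colSums(adj) == 0L
    if (!any(sinks)) return(FALSE)
    adj <- adj[!sinks, !sinks, drop = FALSE]
  }
}

is_acyclic <- function(dag) acyclic_adj(dag_adjacency(dag))

# Parents of each node as a named list of character vectors.
dag_parents <- function(dag) {
  out <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) out[[v]] <- dag$arcs[dag$arcs[, 2L] == v, 1L]
  out
}

#' Undirected skeleton of a DAG
#'
#' Drops arc orientation: the skeleton is the set of unordered variable
#' pairs joined by an arc in either direction. Credibility assessment and
#' mechanism identification operate at this level, since orientation within
#' a Markov-equivalence class is not statistically identifiable.
#'
#' @param dag A [bn_dag()] object.
#' @return A two-column character matrix of unordered pairs, each row sorted
#'   alphabetically, rows sorted; zero rows for an empty graph.
#' @export
skeleton <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!nrow(dag$arcs)) {
    return(matrix(character(0), 0L, 2L, dimnames = list(NULL, c("a", "b"))))
  }
  pairs <- t(apply(dag$arcs, 1L, sort))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("a", "b"))
  pairs
}

# "a|b" keys (a < b) for a skeleton matrix or a bn_dag.
skeleton_keys <- function(x) {
  sk <- if (inherits(x, "bn_dag")) skeleton(x) else x
  if (!nrow(sk)) return(character(0))
  paste(sk[, 1L], sk[, 2L], sep = "|")
}

#' Completed partially directed acyclic graph (CPDAG)
#'
#' Canonical representative of a DAG's Markov-equivalence class: the
#' skeleton with exactly the compelled arcs directed. V-structure arcs are
#' directed first and the orientation is closed under the Meek rules; two
#' DAGs are Markov equivalent if and only if their CPDAGs are equal.
#'
#' @param dag A [bn_dag()] object.
#' @return An object of class `"bn_cpdag"`: list with `nodes`, `directed`
#'   (two-column matrix of compelled arcs) and `undirected` (two-column
#'   matrix of reversible pairs, rows sorted).
#' @examples
#' cpdag(bn_dag(c("t", "o", "w"), rbind(c("t", "o"), c("o", "w"))))
#' @export
cpdag <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  nodes <- dag$nodes
  p <- length(nodes)
  adj <- dag_adjacency(dag)
  und <- adj | t(adj)              # skeleton adjacency
  dir <- matrix(FALSE, p, p, dimnames = dimnames(adj))
  # v-structures: x -> z <- y with x, y non-adjacent are compelled
  for (z in seq_len(p)) {
    pa <- which(adj[, z])
    if (length(pa) >= 2L) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i != j && !und[pa[i], pa[j]]) dir[pa[i], z] <- TRUE
      }
    }
  }
  rev <- und & !(dir | t(dir))     # currently undirected pairs
  # Meek rules 1-3 (starting from a DAG's v-structures, rule 4 never fires)
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) for (c in seq_len(p)) {
      if (b == c || !rev[b, c]) next
      oriented <- FALSE
      # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
      for (a in which(dir[, b])) {
        if (a != c && !und[a, c]) { oriented <- TRUE; break }
      }
      # R2: b -> a -> c and b - c  =>  b -> c
      if (!oriented && any(dir[b, ] & dir[, c])) oriented <- TRUE
      # R3: b - a, b - d, a -> c, d -> c, a and d non-adjacent  =>  b -> c
      if (!oriented) {
        cand <- which(dir[, c] & rev[b, ])
        if (length(cand) >= 2L) {
          for (i in seq_along(cand)) for (j in seq_along(cand)) {
            if (i != j && !und[cand[i], cand[j]]) { oriented <- TRUE; break }
          }
        }
      }
      if (oriented) {
        dir[b, c] <- TRUE
        rev[b, c] <- rev[c, b] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dpairs <- which(dir, arr.ind = TRUE)
  directed <- cbind(nodes[dpairs[, 1L]], nodes[dpairs[, 2L]])
  upairs <- which(rev & upper.tri(rev), arr.ind = TRUE)
  undirected <- cbind(nodes[pmin(upairs[, 1L], upairs[, 2L])],
                      nodes[pmax(upairs[, 1L], upairs[, 2L])])
  canon <- function(m) {
    m <- matrix(as.character(m), ncol = 2L)
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  # rows of `undirected` use node order, not alphabetical; fix both to sorted
  if (nrow(undirected)) {
    undirected <- t(apply(undirected, 1L, sort))
  } else {
    undirected <- matrix(character(0), 0L, 2L)
  }
  structure(list(nodes = nodes,
                 directed = canon(directed),
                 undirected = canon(undirected)),
            class = "bn_cpdag")
}

# Canonical string key of a CPDAG, for fast equality tests.
cpdag_key <- function(cp) {
  if (inherits(cp, "bn_dag")) cp <- cpdag(cp)
  paste(c(paste0(cp$directed[, 1L], ">", cp$directed[, 2L]),
          paste0(cp$undirected[, 1L], "-", cp$undirected[, 2L])),
        collapse = ";")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$arcs), "arcs\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$arcs)) {
    cat("  arcs :", paste(x$arcs[, 1L], "->", x$arcs[, 2L],
                          collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.bn_cpdag <- function(x, ...) {
  cat("CPDAG with", length(x$nodes), "nodes\n")
  if (nrow(x$directed)) {
    cat("  compelled :", paste(x$directed[, 1L], "->", x$directed[, 2L],
                               collapse = "; "), "\n")
  }
  if (nrow(x$undirected)) {
    cat("  reversible:", paste(x$undirected[, 1L], "-", x$undirected[, 2L],
                               collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read or write a structure as an edge list
#'
#' Plain-text exchange format for structures (for example an
#' expert-specified missing data structure): one `parent<TAB>child` line per
#' arc. Isolated nodes can be supplied via `nodes`.
#'
#' @param path File path.
#' @param nodes Optional character vector of all nodes (for isolated ones);
#'   defaults to the arc endpoints.
#' @return `read_edge_list()` returns a [bn_dag()].
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("each line must be 'parent<TAB>child'")
    }
    arcs <- do.call(rbind, parts)
  } else {
    arcs <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(arcs)))
  bn_dag(nodes, arcs)
}

#' @rdname read_edge_list
#' @param dag A [bn_dag()] object.
#' @export
write_edge_list <- function(dag, path) {
  stopifnot(inherits(dag, "bn_dag"))
  writeLines(paste(dag$arcs[, 1L], dag$arcs[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export a structure in DOT format
#'
#' Writes a Graphviz `digraph` description of the DAG, for rendering with
#' any DOT viewer. No renderer is required or invoked.
#'
#' @param dag A [bn_dag()] object.
#' @param path Output file path.
#' @export
write_dot <- function(dag, path) {
  stopifnot(inherits(dag, "bn_dag"))
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph structure {",
             paste0("  ", q(dag$nodes), ";"),
             if (nrow(dag$arcs)) {
               paste0("  ", q(dag$arcs[, 1L]), " -> ", q(dag$arcs[, 2L]), ";")
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}
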