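#' Directed acyclic graphs over named variables
#'
#' A `cmx_dag` stores an ordered node vector and a binary adjacency matrix
#' with `amat[i, j] == 1` meaning an arc from node `i` to node `j`.  DAGs are
#' the hypothesis space of the Bayesian reliability score: every causal
#' statement is evaluated by averaging over all DAGs on a small subset of
#' variables.
#'
#' @param nodes character vector of variable names (unique, non-empty).
#' @param edges arcs, either a two-column matrix/data.frame of
#'   `(parent, child)` names or `NULL` for the empty graph.
#' @return an object of class `cmx_dag`.
#' @examples
#' dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  k <- length(nodes)
  amat <- matrix(0L, k, k, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
    bad <- !(edges %in% nodes)
    if (any(bad)) stop("unknown node name(s): ", paste(unique(edges[bad]), collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    amat[edges] <- 1L
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "cmx_dag")
  if (has_cycle(amat)) stop("edge set contains a directed cycle")
  g
}

has_cycle <- function(amat) {
  # Kahn's algorithm: repeatedly delete sources
  k <- nrow(amat)
  alive <- rep(TRUE, k)
  repeat {
    indeg <- colSums(amat[alive, , drop = FALSE])
    src <- alive & indeg == 0
    if (!any(src)) break
    alive[src] <- FALSE
  }
  any(alive)
}

#' @export
print.cmx_dag <- function(x, ...) {
  e <- which(x$amat == 1L, arr.ind = TRUE)
  cat("DAG with", length(x$nodes), "nodes and", nrow(e), "arcs\n")
  if (nrow(e)) {
    cat(paste0("  ", x$nodes[e[, 1]], " --> ", x$nodes[e[, 2]]), sep = "\n")
  }
  invisible(x)
}

dag_edges <- function(g) {
  e <- which(g$amat == 1L, arr.ind = TRUE)
  cbind(parent = g$nodes[e[, 1]], child = g$nodes[e[, 2]])
}

#' Enumerate all labeled DAGs on a small node set
#'
#' Exhaustive enumeration by recursive arc-wise construction with
#' reachability pruning.  The count grows super-exponentially (1, 3, 25, 543,
#' 29,281 for one to five nodes), which is why the reliability score caps
#' subsets at five variables; larger node sets are refused unless `force`
#' is set.
#'
#' @param nodes character vector of node names.
#' @param force allow more than five nodes (complexity guard override).
#' @return list of [dag()] objects, each labeled DAG exactly once.
#' @examples
#' length(enumerate_dags(c("X", "Y")))  # 3
#' @export
enumerate_dags <- function(nodes, force = FALSE) {
  nodes <- as.character(nodes)
  k <- length(nodes)
  if (k < 1) stop("need at least one node")
  if (k > 5 && !force) {
    stop("enumeration over ", k, " nodes is refused (29,281 DAGs already at 5); ",
         "set force = TRUE to override")
  }
  tab <- dag_tables(k)
  lapply(seq_len(tab$n_dags), function(d) {
    amat <- matrix(0L, k, k, dimnames = list(nodes, nodes))
    for (j in seq_len(k)) {
      pm <- tab$parent_mask[d, j]
      if (pm > 0) amat[bitwAnd(pm, bitwShiftL(1L, seq_len(k) - 1L)) > 0, j] <- 1L
    }
    structure(list(nodes = nodes, amat = amat), class = "cmx_dag")
  })
}

# Session cache of the C++ DAG tables, one entry per subset size.
the <- new.env(parent = emptyenv())

dag_tables <- function(k) {
  key <- paste0("dag_tables_", k)
  if (is.null(the[[key]])) the[[key]] <- cmx_dag_tables(k)
  the[[key]]
}

#' Number of labeled DAGs on n nodes
#'
#' @param n number of nodes (1 to 5 without `force`).
#' @param force allow larger n.
#' @return integer count.
#' @export
count_dags <- function(n, force = FALSE) {
  if (n > 5 && !force) stop("n > 5 refused; set force = TRUE")
  dag_tables(n)$n_dags
}

#' Test d-separation in a DAG
#'
#' Standard d-separation: `x` and `y` are d-separated given `z` when every
#' path between them is blocked.  Implemented by the moralized-ancestral-graph
#' criterion: restrict to ancestors of `{x, y} U z`, moralize, delete `z`,
#' and test connectivity.
#'
#' @param g a [dag()].
#' @param x,y single variable names, distinct, not in `z`.
#' @param z character vector of conditioning variables (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
#' d_separated(g, "A", "C", character())  # TRUE: unconditioned collider
#' d_separated(g, "A", "C", "B")          # FALSE: conditioning opens it
#' @export
d_separated <- function(g, x, y, z = character()) {
  z <- as.character(z)
  for (v in c(x, y, z)) {
    if (!v %in% g$nodes) stop("unknown variable name: ", v)
  }
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("x and y must not be in the conditioning set")
  k <- length(g$nodes)
  ix <- match(x, g$nodes); iy <- match(y, g$nodes); iz <- match(z, g$nodes)
  # ancestral set of {x, y} U z
  anc <- ancestor_matrix(g$amat)
  keep <- union(c(ix, iy, iz), which(apply(anc[, c(ix, iy, iz), drop = FALSE], 1, any)))
  a <- g$amat[keep, keep, drop = FALSE]
  # moralize: undirected parent-child links plus links between co-parents
  m <- (a + t(a) + (a %*% t(a))) > 0
  diag(m) <- FALSE
  # delete conditioning nodes, test connectivity x -- y
  pos <- match(c(ix, iy, iz), keep)
  m[pos[-(1:2)], ] <- FALSE
  m[, pos[-(1:2)]] <- FALSE
  !undirected_connected(m, pos[1], pos[2])
}

ancestor_matrix <- function(amat) {
  # anc[i, j] TRUE iff i is a (proper) ancestor of j
  k <- nrow(amat)
  r <- amat > 0
  repeat {
    r2 <- r | ((r %*% r) > 0)
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

undirected_connected <- function(m, i, j) {
  seen <- logical(nrow(m))
  frontier <- i
  seen[i] <- TRUE
  while (length(frontier)) {
    nxt <- which(apply(m[frontier, , drop = FALSE], 2, any) & !seen)
    if (j %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[j]
}

#' Ancestor set of a node
#' @param g a [dag()].
#' @param x a node name.
#' @return character vector of proper ancestors of `x`.
#' @export
dag_ancestors <- function(g, x) {
  if (!x %in% g$nodes) stop("unknown variable name: ", x)
  g$nodes[ancestor_matrix(g$amat)[, match(x, g$nodes)]]
}
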