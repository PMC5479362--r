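#' Partial ancestral graphs
#'
#' A `cmx_pag` records, for every edge, one mark per endpoint: `tail` (the
#' variable is an ancestor of the other in every member of the equivalence
#' class), `arrow` (it is a non-ancestor in every member), or `circle`
#' (undecided).  Marks are stored in an integer matrix with the pcalg
#' convention `amat[i, j]` = mark at the `j` end of edge `i -- j`
#' (0 none, 1 circle, 2 arrowhead, 3 tail).
#'
#' @param nodes character vector of variable names.
#' @param amat optional integer mark matrix (defaults to the empty graph).
#' @return an object of class `cmx_pag`.
#' @export
pag <- function(nodes, amat = NULL) {
  nodes <- as.character(nodes)
  k <- length(nodes)
  if (is.null(amat)) amat <- matrix(0L, k, k)
  amat <- matrix(as.integer(amat), k, k, dimnames = list(nodes, nodes))
  if (!all(amat %in% 0:3)) stop("marks must be 0 (none), 1 (circle), 2 (arrow) or 3 (tail)")
  if (any((amat == 0L) != (t(amat) == 0L))) stop("edge set must be symmetric: both endpoints marked or neither")
  if (any(diag(amat) != 0L)) stop("self-edges are not allowed")
  structure(list(nodes = nodes, amat = amat), class = "cmx_pag")
}

MARK_NONE <- 0L; MARK_CIRCLE <- 1L; MARK_ARROW <- 2L; MARK_TAIL <- 3L

#' Add or replace an edge in a PAG
#'
#' @param p a [pag()].
#' @param x,y endpoint variable names.
#' @param mark_x,mark_y marks at the `x` and `y` ends, each one of
#'   `"circle"`, `"arrow"`, `"tail"`.
#' @return the modified PAG.
#' @export
pag_set_edge <- function(p, x, y, mark_x = "circle", mark_y = "circle") {
  mk <- c(circle = MARK_CIRCLE, arrow = MARK_ARROW, tail = MARK_TAIL)
  p$amat[y, x] <- mk[[mark_x]]
  p$amat[x, y] <- mk[[mark_y]]
  p
}

pag_edge_df <- function(p) {
  # one row per unordered edge, with endpoint marks
  idx <- which(p$amat != 0L & upper.tri(p$amat), arr.ind = TRUE)
  data.frame(
    x = p$nodes[idx[, 1]], y = p$nodes[idx[, 2]],
    mark_x = p$amat[cbind(idx[, 2], idx[, 1])],
    mark_y = p$amat[cbind(idx[, 1], idx[, 2])],
    stringsAsFactors = FALSE
  )
}

edge_token <- function(mark_x, mark_y) {
  left <- c("?", "o", "<", "-")[mark_x + 1L]
  right <- c("?", "o", ">", "-")[mark_y + 1L]
  paste0(left, "-", right)
}

#' @export
print.cmx_pag <- function(x, ...) {
  e <- pag_edge_df(x)
  cat("PAG with", length(x$nodes), "nodes and", nrow(e), "edges\n")
  if (nrow(e)) {
    rel <- attr(x, "reliability")
    lab <- paste0("  ", e$x, " ", edge_token(e$mark_x, e$mark_y), " ", e$y)
    if (!is.null(rel)) {
      key <- paste(pmin(e$x, e$y), pmax(e$x, e$y))
      r <- rel[key]
      lab <- ifelse(is.na(r), lab, paste0(lab, "  ", round(100 * r), "%"))
    }
    cat(lab, sep = "\n")
  }
  invisible(x)
}

#' Endpoint-mark accuracy between two PAGs
#'
#' The fraction of edge endpoints reproduced correctly, over all endpoints of
#' the union of the two edge sets: an edge present in both graphs contributes
#' its two marks (compared one by one), while an edge present in only one
#' graph contributes two incorrect endpoints.  This rewards partially correct
#' orientation of a recovered edge.  Two empty graphs have accuracy 1.
#'
#' @param estimated,truth two [pag()]s over the same node set.
#' @return a fraction in `[0, 1]`; 1 exactly when the PAGs are identical.
#' @export
pag_accuracy <- function(estimated, truth) {
  check_same_nodes(estimated, truth)
  a <- estimated$amat[truth$nodes, truth$nodes]
  b <- truth$amat
  both <- a != 0L & b != 0L
  either <- a != 0L | b != 0L
  n_union <- sum(either & upper.tri(either))
  if (n_union == 0) return(1)
  sum(a == b & both) / (2 * n_union)
}

#' Skeleton precision and recall
#'
#' Compares edge sets only, ignoring marks.  Precision is the fraction of
#' inferred edges that are in the truth (1 when nothing is inferred, by the
#' vacuous-truth convention so the metric is total); recall is the fraction
#' of true edges recovered.
#'
#' @param estimated,truth two [pag()]s over the same node set.
#' @return named numeric vector `c(precision = , recall = )`.
#' @export
skeleton_precision_recall <- function(estimated, truth) {
  check_same_nodes(estimated, truth)
  a <- estimated$amat[truth$nodes, truth$nodes] != 0L & upper.tri(truth$amat)
  b <- truth$amat != 0L & upper.tri(truth$amat)
  n_est <- sum(a); n_true <- sum(b); n_both <- sum(a & b)
  c(precision = if (n_est == 0) 1 else n_both / n_est,
    recall = if (n_true == 0) 1 else n_both / n_true)
}

check_same_nodes <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) stop("PAGs are over different node sets")
  invisible(TRUE)
}

#' Skeleton of a DAG as an all-circle PAG
#' @param g a [dag()].
#' @return a [pag()] with a circle-circle edge wherever `g` has an arc.
#' @export
dag_skeleton_pag <- function(g) {
  sk <- (g$amat + t(g$amat)) > 0
  pag(g$nodes, ifelse(sk, MARK_CIRCLE, MARK_NONE))
}

#' DAG as a fully oriented PAG
#'
#' Each arc `i -> j` becomes an edge with a tail at `i` and an arrowhead at
#' `j`; used to express ground-truth graphs in the common mark vocabulary.
#' @param g a [dag()].
#' @return a [pag()].
#' @export
dag_as_pag <- function(g) {
  amat <- matrix(0L, length(g$nodes), length(g$nodes))
  amat[g$amat == 1L] <- MARK_ARROW          # mark at child end
  amat[t(g$amat) == 1L] <- MARK_TAIL        # mark at parent end
  pag(g$nodes, amat)
}
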