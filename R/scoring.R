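#' Gaussian mutual information between a variable and its parents
#'
#' For a correlation matrix with unit diagonal,
#' `I(X_i, X_Pa) = -1/2 * log( det(Sigma_{i,Pa}) / det(Sigma_Pa) )`,
#' the mutual information between node `i` and its parent set under the
#' Gaussian model.  An empty parent set gives 0.
#'
#' @param corr a [correlation_matrix()] or plain matrix with named rows.
#' @param i a variable name.
#' @param parents character vector of parent names (may be empty).
#' @return mutual information in nats (non-negative up to rounding).
#' @export
mutual_information <- function(corr, i, parents = character()) {
  cm <- corr_of(corr)
  vars <- rownames(cm)
  if (!i %in% vars) stop("unknown variable: ", i)
  if (i %in% parents) stop("a variable cannot be its own parent")
  if (!all(parents %in% vars)) stop("unknown parent name(s)")
  if (length(parents) == 0) return(0)
  dp <- det(cm[parents, parents, drop = FALSE])
  dip <- det(cm[c(i, parents), c(i, parents), drop = FALSE])
  if (dp <= 0 || dip <= 0) {
    stop("singular correlation submatrix; project to positive definite first ",
         "(see nearest_positive_definite)")
  }
  -0.5 * log(dip / dp)
}

#' BIC score of a DAG from a correlation matrix
#'
#' `M * sum_i I(X_i, Pa_i) - (log M / 2) * Dim[G]`, where the model dimension
#' `Dim[G]` counts the arcs: per-node variances are common to every DAG on a
#' fixed node set and cancel when scores are normalized into posteriors, so
#' they are left out of the penalty (set `dim_fun` to change this).  The
#' empty DAG scores 0, and Markov-equivalent DAGs score identically.
#'
#' @param corr a [correlation_matrix()] or named matrix.
#' @param g a [dag()] whose nodes appear in `corr`.
#' @param M sample size.
#' @param dim_fun function mapping a DAG to its parameter count
#'   (default: number of arcs).
#' @return the BIC score (log scale).
#' @export
bic_score <- function(corr, g, M, dim_fun = function(g) sum(g$amat)) {
  total <- 0
  for (j in seq_along(g$nodes)) {
    pa <- g$nodes[g$amat[, j] == 1L]
    total <- total + mutual_information(corr, g$nodes[j], pa)
  }
  M * total - (log(M) / 2) * dim_fun(g)
}

#' Score every DAG on a small variable subset
#'
#' Enumerates all DAGs on the subset (at most five variables), computes each
#' BIC score from the correlation matrix, and converts the scores to
#' normalized posterior probabilities under a uniform structure prior via
#' log-sum-exp.
#'
#' @param corr a [correlation_matrix()] or named matrix.
#' @param subset character vector of 1 to 5 variable names.
#' @param M sample size.
#' @return an object of class `cmx_scored`: `subset`, `log_scores`,
#'   `posterior` (sums to 1), plus cached per-DAG statement indicators.
#' @export
score_subset <- function(corr, subset, M) {
  cm <- corr_of(corr)
  subset <- as.character(subset)
  if (!all(subset %in% rownames(cm))) stop("subset names must index the correlation matrix")
  k <- length(subset)
  if (k > 5) stop("subsets are capped at five variables")
  tab <- dag_tables(k)
  ls <- cmx_dag_bic(cm[subset, subset, drop = FALSE], M, tab$parent_mask, tab$n_edges)
  post <- exp(ls - logsumexp(ls))
  post <- post / sum(post)
  structure(list(subset = subset, log_scores = ls, posterior = post, tables = tab, M = M),
            class = "cmx_scored")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Column index of the unordered pair (i < j) among k-choose-2 pairs, and of
# the ordered pair (i, j), matching the layout emitted by cmx_dag_tables.
pair_index <- function(k, i, j) {
  stopifnot(i < j)
  (i - 1) * k - i * (i + 1) / 2 + j
}
ordered_pair_index <- function(k, i, j) {
  stopifnot(i != j)
  (i - 1) * (k - 1) + j - (j > i)
}

#' Causal statement
#'
#' @param kind `"independence"`, `"dependence"` (of `x` and `y` given
#'   `cond`), or `"cause"` (`x` is an ancestor of `y`).
#' @param x,y distinct variable names.
#' @param cond conditioning set (independence/dependence only).
#' @return an object of class `cmx_statement`.
#' @export
statement <- function(kind = c("independence", "dependence", "cause"), x, y,
                      cond = character()) {
  kind <- match.arg(kind)
  cond <- as.character(cond)
  if (x == y) stop("x and y must differ")
  if (x %in% cond || y %in% cond) stop("conditioning set must exclude x and y")
  structure(list(kind = kind, x = x, y = y, cond = cond), class = "cmx_statement")
}

#' @export
print.cmx_statement <- function(x, ...) {
  cat(switch(x$kind,
    independence = paste0(x$x, " _||_ ", x$y,
                          if (length(x$cond)) paste0(" | {", paste(x$cond, collapse = ", "), "}") else ""),
    dependence = paste0(x$x, " ~ ", x$y,
                        if (length(x$cond)) paste0(" | {", paste(x$cond, collapse = ", "), "}") else ""),
    cause = paste0(x$x, " => ", x$y)), "\n")
  invisible(x)
}

#' Posterior reliability of a causal statement
#'
#' The summed posterior probability of the DAGs that entail the statement:
#' a conditional (in)dependence is entailed through d-separation, and
#' `x` causes `y` when a directed path runs from `x` to `y`.
#'
#' @param scored a [score_subset()] result covering the statement's variables.
#' @param stmt a [statement()].
#' @return a probability in `[0, 1]`.
#' @export
statement_reliability <- function(scored, stmt) {
  vars <- scored$subset
  k <- length(vars)
  if (!all(c(stmt$x, stmt$y, stmt$cond) %in% vars)) {
    stop("statement variables must lie inside the scored subset")
  }
  ix <- match(stmt$x, vars); iy <- match(stmt$y, vars)
  if (stmt$kind == "cause") {
    mask <- scored$tables$ancestor[, ordered_pair_index(k, ix, iy)]
    return(sum(scored$posterior[mask]))
  }
  rest <- setdiff(seq_len(k), c(ix, iy))
  if (setequal(match(stmt$cond, vars), rest)) {
    # cached fast path: independence given all other subset members
    mask <- scored$tables$dsep_rest[, pair_index(k, min(ix, iy), max(ix, iy))]
  } else {
    mask <- dsep_mask(scored$tables, vars, stmt$x, stmt$y, stmt$cond)
  }
  p <- sum(scored$posterior[mask])
  if (stmt$kind == "dependence") 1 - p else p
}

# Per-DAG d-separation indicator for an arbitrary conditioning set (general
# path, used for statements that do not condition on the whole rest).
dsep_mask <- function(tab, vars, x, y, cond) {
  k <- tab$k
  vapply(seq_len(tab$n_dags), function(d) {
    amat <- matrix(0L, k, k, dimnames = list(vars, vars))
    for (j in seq_len(k)) {
      pm <- tab$parent_mask[d, j]
      if (pm > 0) amat[bitwAnd(pm, bitwShiftL(1L, seq_len(k) - 1L)) > 0, j] <- 1L
    }
    d_separated(structure(list(nodes = vars, amat = amat), class = "cmx_dag"),
                x, y, cond)
  }, logical(1))
}
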