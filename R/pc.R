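#' Fisher-z test of conditional independence from a correlation matrix
#'
#' The partial correlation of `i` and `j` given `cond` is read off the
#' inverse of the correlation submatrix over `{i, j} U cond`; the Fisher
#' transform `atanh(r) * sqrt(n - |cond| - 3)` is referred to a standard
#' normal for a two-sided p-value.
#'
#' @param corr a [correlation_matrix()] or named matrix.
#' @param n sample size (must exceed `|cond| + 3`).
#' @param i,j variable names.
#' @param cond character vector of conditioning variables.
#' @return a list with `p_value`, `partial_correlation`, `statistic`.
#' @export
fisher_z_test <- function(corr, n, i, j, cond = character()) {
  cm <- corr_of(corr)
  vars <- c(i, j, as.character(cond))
  if (!all(vars %in% rownames(cm))) stop("unknown variable name(s)")
  if (length(cond) > n - 3) stop("conditioning set too large for the sample size")
  sub <- cm[vars, vars, drop = FALSE]
  prec <- tryCatch(solve(sub), error = function(e)
    stop("singular correlation submatrix in the independence test"))
  r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(n - length(cond) - 3)
  list(p_value = 2 * stats::pnorm(-abs(z)), partial_correlation = r, statistic = z)
}

#' PC algorithm from a correlation matrix
#'
#' The standard PC pipeline run from a correlation matrix: order-independent
#' ("stable") level-wise skeleton pruning with the Fisher-z test, collider
#' orientation from the recorded separating sets, and Meek's rules to the
#' completed partially directed acyclic graph.  The CPDAG is expressed in
#' PAG mark vocabulary -- tails and arrowheads for compelled arcs, circles at
#' both ends of reversible edges -- so the same evaluation metrics apply to
#' PC and to the Bayesian search.
#'
#' @param corr a [correlation_matrix()] or named matrix.
#' @param n sample size; defaults to the matrix's recorded effective size.
#' @param alpha test level for edge removal.
#' @param max_cond cap on conditioning-set size (default: unlimited).
#' @return a [pag()].
#' @export
run_pc <- function(corr, n = NULL, alpha = 0.05, max_cond = Inf) {
  cm <- corr_of(corr)
  if (is.null(n)) {
    if (!inherits(corr, "cmx_corr")) stop("n is required when corr is a plain matrix")
    n <- corr$sample_size
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vars <- rownames(cm)
  k <- length(vars)
  adj <- matrix(TRUE, k, k, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  sepset <- vector("list", k * k); dim(sepset) <- c(k, k)

  level <- 0
  repeat {
    adj_frozen <- adj
    any_candidate <- FALSE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!adj[i, j]) next
      cand <- setdiff(vars[adj_frozen[i, ] | adj_frozen[j, ]], vars[c(i, j)])
      if (length(cand) >= level) any_candidate <- TRUE
      for (z in subsets_of_size(cand, level)) {
        if (fisher_z_test(cm, n, vars[i], vars[j], z)$p_value > alpha) {
          adj[i, j] <- adj[j, i] <- FALSE
          sepset[[i, j]] <- sepset[[j, i]] <- z
          break
        }
      }
    }
    level <- level + 1
    if (!any_candidate || level > max_cond) break
  }

  # v-structures: i -> z <- j for unshielded triples with z outside sepset(i, j)
  dir <- matrix(0L, k, k)  # 1 = directed arc
  und <- adj
  for (z in seq_len(k)) {
    nb <- which(adj[, z])
    for (i in nb) for (j in nb) {
      if (i < j && !adj[i, j] && !(vars[z] %in% sepset[[i, j]])) {
        dir[i, z] <- dir[j, z] <- 1L
        und[i, z] <- und[z, i] <- und[j, z] <- und[z, j] <- FALSE
      }
    }
  }
  dir <- meek_rules(dir, und)

  amat <- matrix(0L, k, k, dimnames = list(vars, vars))
  und <- adj & !(dir == 1L | t(dir) == 1L)
  amat[und] <- MARK_CIRCLE
  amat[dir == 1L] <- MARK_ARROW       # mark at head
  amat[t(dir) == 1L] <- MARK_TAIL     # mark at tail
  pag(vars, amat)
}

# Meek's completion rules on a partially directed graph.
# dir[i, j] = 1 for a compelled arc i -> j, und = remaining undirected edges.
meek_rules <- function(dir, und) {
  k <- nrow(dir)
  adj <- function(i, j) und[i, j] || dir[i, j] == 1L || dir[j, i] == 1L
  repeat {
    changed <- FALSE
    orient <- function(i, j) {
      dir[i, j] <<- 1L
      und[i, j] <<- und[j, i] <<- FALSE
      changed <<- TRUE
    }
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (!und[a, b]) next
      # R1: c -> a, c not adjacent to b  =>  a -> b
      if (any(dir[, a] == 1L & !vapply(seq_len(k), adj, logical(1), j = b) &
              seq_len(k) != b)) { orient(a, b); next }
      # R2: a -> c -> b  =>  a -> b
      if (any(dir[a, ] == 1L & dir[, b] == 1L)) { orient(a, b); next }
      # R3: a - c1 -> b, a - c2 -> b, c1 and c2 non-adjacent  =>  a -> b
      cs <- which(und[a, ] & dir[, b] == 1L)
      if (length(cs) >= 2) {
        pairs <- utils::combn(cs, 2)
        if (any(!mapply(adj, pairs[1, ], pairs[2, ]))) { orient(a, b); next }
      }
      # R4: a - d, d -> c, c -> b, a - c  =>  a -> b (needed with background
      # knowledge; harmless otherwise)
      ds <- which(und[a, ])
      if (any(vapply(ds, function(d) any(dir[d, ] == 1L & dir[, b] == 1L & und[a, ]),
                     logical(1)))) { orient(a, b); next }
    }
    if (!changed) break
  }
  dir
}
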