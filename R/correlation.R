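#' Correlation-matrix container
#'
#' A symmetric unit-diagonal matrix together with the effective sample size
#' used to estimate it (the number of rows retained after dropping rows with
#' every entry missing — one convention for all estimators, so that scores
#' computed from different estimators are comparable) and a provenance tag.
#'
#' @param matrix symmetric numeric matrix with unit diagonal.
#' @param sample_size effective number of rows behind the estimate.
#' @param estimator provenance label, e.g. `"em"` or `"spearman-pairwise"`.
#' @return an object of class `cmx_corr`.
#' @export
correlation_matrix <- function(matrix, sample_size, estimator = "unknown") {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("correlation matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8) stop("correlation matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  if (max(abs(diag(matrix) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal")
  diag(matrix) <- 1
  structure(list(matrix = matrix, sample_size = as.numeric(sample_size),
                 estimator = estimator),
            class = "cmx_corr")
}

#' @export
print.cmx_corr <- function(x, ...) {
  cat(sprintf("%d x %d correlation matrix (estimator: %s, effective n = %g)\n",
              nrow(x$matrix), ncol(x$matrix), x$estimator, x$sample_size))
  print(round(x$matrix, 3))
  invisible(x)
}

corr_of <- function(x) if (inherits(x, "cmx_corr")) x$matrix else as.matrix(x)

# Drop rows with every entry missing; returns list(values, n, dropped).
retained_rows <- function(vals) {
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " row(s) with all entries missing dropped")
    vals <- vals[!all_missing, , drop = FALSE]
  }
  list(values = vals, n = nrow(vals))
}

#' Gaussian maximum-likelihood correlation under MAR, by EM
#'
#' Treats the (transformed) data as multivariate normal with values missing
#' at random and finds the maximum-likelihood covariance by expectation
#' maximization: the E-step fills in, per missing pattern, the conditional
#' means of the missing block given the observed block and accumulates the
#' conditional covariance; the M-step re-estimates the mean and covariance
#' from the pooled sufficient statistics.  The mean is estimated jointly but
#' discarded; the covariance is normalized to unit diagonal.  The
#' observed-data log-likelihood is tracked and is non-decreasing across
#' iterations (the classic EM guarantee, asserted on every run).
#'
#' @param data a `cmx_transformed` / [mixed_data()] object or numeric matrix
#'   with `NA` for missing entries.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param delta eigenvalue floor applied to the final matrix as a numerical
#'   safety net.
#' @return a list of class `cmx_em` with elements `correlation`
#'   (a [correlation_matrix()]), `iterations`, `loglik_trace`, `converged`.
#' @export
em_correlation <- function(data, tol = 1e-6, max_iter = 500, delta = 1e-8) {
  vals <- as_values_matrix(data)
  r <- retained_rows(vals)
  y <- r$values
  n <- r$n
  d <- ncol(y)
  if (any(colSums(!is.na(y)) < 2)) stop("every variable must be observed at least twice")

  # group rows by missing pattern
  pat_key <- apply(is.na(y), 1, function(m) paste(as.integer(m), collapse = ""))
  groups <- split(seq_len(n), pat_key)

  # initialize from mean-imputed moments (always well-defined)
  mu <- colMeans(y, na.rm = TRUE)
  y0 <- y
  for (j in seq_len(d)) y0[is.na(y0[, j]), j] <- mu[j]
  sigma <- crossprod(sweep(y0, 2, mu)) / n
  diag(sigma) <- diag(sigma) + 1e-10

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    t1 <- numeric(d)
    t2 <- matrix(0, d, d)
    ll <- 0
    for (rows in groups) {
      miss <- is.na(y[rows[1], ])
      o <- which(!miss); m <- which(miss)
      xo <- y[rows, o, drop = FALSE]
      soo <- sigma[o, o, drop = FALSE]
      ch <- chol(soo)
      centered <- sweep(xo, 2, mu[o])
      w <- backsolve(ch, t(centered), transpose = TRUE)  # ch' w = centered'
      ll <- ll - 0.5 * (length(rows) * (length(o) * log(2 * pi) +
                                          2 * sum(log(diag(ch)))) + sum(w * w))
      if (length(m) == 0) {
        t1 <- t1 + colSums(y[rows, , drop = FALSE])
        t2 <- t2 + crossprod(y[rows, , drop = FALSE])
        next
      }
      beta <- backsolve(ch, backsolve(ch, sigma[o, m, drop = FALSE], transpose = TRUE))
      xm <- matrix(mu[m], length(rows), length(m), byrow = TRUE) + centered %*% beta
      cc <- sigma[m, m, drop = FALSE] - crossprod(sigma[o, m, drop = FALSE], beta)
      xfull <- matrix(0, length(rows), d)
      xfull[, o] <- xo
      xfull[, m] <- xm
      t1 <- t1 + colSums(xfull)
      t2 <- t2 + crossprod(xfull)
      t2[m, m] <- t2[m, m] + length(rows) * cc
    }
    mu <- t1 / n
    sigma <- t2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    loglik <- c(loglik, ll)
    if (iter >= 2) {
      if (abs(ll - loglik[iter - 1]) <= tol * (abs(loglik[iter - 1]) + 1e-12)) {
        converged <- TRUE
        break
      }
    } else if (length(groups) == 1 && !anyNA(y)) {
      converged <- TRUE  # complete data: the M-step is the MLE outright
      break
    }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  corr <- stats::cov2cor(sigma)
  corr <- pd_floor(corr, delta)
  structure(list(correlation = correlation_matrix(corr, n, "em"),
                 iterations = iter, loglik_trace = loglik,
                 converged = converged),
            class = "cmx_em")
}

#' @export
print.cmx_em <- function(x, ...) {
  cat(sprintf("EM correlation estimate: %d iteration(s), %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$correlation)
  invisible(x)
}

# Eigenvalue floor preserving the unit diagonal.
pd_floor <- function(m, delta = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= delta) return(m)
  v <- pmax(e$values, delta)
  out <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(out)
}

#' Pairwise Spearman correlation, optionally Gaussian-adjusted
#'
#' Entry (i, j) is the Spearman rank correlation over the rows where both
#' variables are observed.  With `adjusted = TRUE` every off-diagonal entry
#' is mapped through `2 sin(pi rho / 6)`, which makes the matrix approach the
#' Pearson correlation when the data are truly Gaussian.  Pairwise deletion
#' gives no positive-definiteness guarantee; project with
#' [nearest_positive_definite()] before determinant-based scoring.
#'
#' @param data dataset or matrix with `NA` for missing entries.
#' @param adjusted apply the Gaussian adjustment of the rank correlation.
#' @return a [correlation_matrix()].
#' @export
spearman_pairwise <- function(data, adjusted = FALSE) {
  vals <- as_values_matrix(data)
  r <- retained_rows(vals)
  y <- r$values
  n_pair <- crossprod(!is.na(y))
  suppressWarnings(
    rho <- stats::cor(y, method = "spearman", use = "pairwise.complete.obs")
  )
  thin <- n_pair < 3 & row(n_pair) != col(n_pair)
  if (any(thin) || anyNA(rho)) {
    warning("pair(s) with fewer than 3 complete cases: correlation set to 0")
    rho[thin | is.na(rho)] <- 0
  }
  if (adjusted) {
    off <- row(rho) != col(rho)
    rho[off] <- 2 * sin(pi * rho[off] / 6)
  }
  diag(rho) <- 1
  correlation_matrix(rho, r$n, if (adjusted) "spearman-adjusted" else "spearman-pairwise")
}

#' Spearman correlation with listwise deletion
#'
#' Uses only the rows with no missing entry at all.
#'
#' @param data dataset or matrix with `NA` for missing entries.
#' @return a [correlation_matrix()].
#' @export
listwise_correlation <- function(data) {
  vals <- as_values_matrix(data)
  r <- retained_rows(vals)
  complete <- stats::complete.cases(r$values)
  if (sum(complete) < 3) stop("fewer than 3 complete rows; listwise deletion impossible")
  rho <- stats::cor(r$values[complete, , drop = FALSE], method = "spearman")
  correlation_matrix(rho, r$n, "listwise")
}

#' Spearman correlation after mean imputation
#'
#' Replaces every missing entry by the observed mean of its column, then
#' computes the full-sample Spearman correlation.  Imputing at the mean
#' shrinks variances, which attenuates correlations when much data are
#' missing.
#'
#' @param data dataset or matrix with `NA` for missing entries.
#' @return a [correlation_matrix()].
#' @export
mean_impute_correlation <- function(data) {
  vals <- as_values_matrix(data)
  r <- retained_rows(vals)
  y <- r$values
  if (any(colSums(!is.na(y)) == 0)) stop("column(s) entirely missing cannot be mean-imputed")
  for (j in seq_len(ncol(y))) y[is.na(y[, j]), j] <- mean(y[, j], na.rm = TRUE)
  rho <- stats::cor(y, method = "spearman")
  correlation_matrix(rho, r$n, "mean-impute")
}

#' Nearest positive-definite correlation matrix
#'
#' Projects a symmetric matrix to the closest correlation matrix in
#' Frobenius norm with unit diagonal and all eigenvalues at least `delta`
#' (Higham's alternating-projections method).  Inputs already satisfying the
#' constraints are returned unchanged.
#'
#' @param m symmetric numeric matrix (or a [correlation_matrix()]).
#' @param delta eigenvalue floor.
#' @return a matrix of the same dimension, or a [correlation_matrix()] if one
#'   was supplied (tag suffixed with `"+pd"`).
#' @export
nearest_positive_definite <- function(m, delta = 1e-8) {
  x <- if (inherits(m, "cmx_corr")) m$matrix else as.matrix(m)
  if (max(abs(x - t(x))) > 1e-8) stop("input must be symmetric")
  ev <- eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= delta && max(abs(diag(x) - 1)) < 1e-12) {
    out <- x
  } else {
    out <- as.matrix(Matrix::nearPD(x, corr = TRUE, eig.tol = 1e-10,
                                    posd.tol = delta, maxit = 200)$mat)
    out <- pd_floor(out, delta)
    dimnames(out) <- dimnames(x)
  }
  if (inherits(m, "cmx_corr")) {
    correlation_matrix(out, m$sample_size, paste0(m$estimator, "+pd"))
  } else {
    out
  }
}

#' Estimate a correlation matrix by a named method
#'
#' Dispatcher used by the discovery front ends: `"em"` runs the copula
#' transform followed by [em_correlation()]; the Spearman variants work on
#' the raw values (ranks are what they use either way).  Any estimate that
#' is not positive definite is projected with [nearest_positive_definite()].
#'
#' @param data a [mixed_data()] object or matrix with `NA`s.
#' @param estimator one of `"em"`, `"spearman-pairwise"`,
#'   `"spearman-adjusted"`, `"listwise"`, `"mean-impute"`.
#' @param ... passed on to the chosen estimator.
#' @return a [correlation_matrix()].
#' @export
estimate_correlation <- function(data,
                                 estimator = c("em", "spearman-pairwise",
                                               "spearman-adjusted", "listwise",
                                               "mean-impute"),
                                 ...) {
  estimator <- match.arg(estimator)
  out <- switch(estimator,
    "em" = em_correlation(transform_dataset(data), ...)$correlation,
    "spearman-pairwise" = spearman_pairwise(data, adjusted = FALSE),
    "spearman-adjusted" = spearman_pairwise(data, adjusted = TRUE),
    "listwise" = listwise_correlation(data),
    "mean-impute" = mean_impute_correlation(data)
  )
  ev <- eigen(out$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) out <- nearest_positive_definite(out)
  out
}
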