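simulate_gaussian <- function(n, corr, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * nrow(corr)), n)
  x <- z %*% chol(corr)
  colnames(x) <- rownames(corr)
  x
}

toy_corr <- function(rho = c(0.6, 0.3, 0.5)) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- rho[1]
  m[1, 3] <- m[3, 1] <- rho[2]
  m[2, 3] <- m[3, 2] <- rho[3]
  dimnames(m) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  m
}

test_that("EM on complete data reproduces the Pearson correlation in one iteration", {
  x <- simulate_gaussian(80, toy_corr())
  em <- em_correlation(x)
  expect_equal(em$correlation$matrix, cor(x), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(em$iterations, 1)
  expect_true(em$converged)
  expect_equal(em$correlation$sample_size, 80)
})

test_that("EM log-likelihood is monotonically non-decreasing", {
  for (seed in 1:5) {
    x <- simulate_gaussian(150, toy_corr(), seed = seed)
    x[sample(length(x), 120)] <- NA
    em <- em_correlation(x)
    expect_true(all(diff(em$loglik_trace) >= -1e-8 * abs(em$loglik_trace[-1])))
    ev <- eigen(em$correlation$matrix, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("bivariate MAR estimate matches direct likelihood maximization", {
  set.seed(42)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + 0.6 * rnorm(n)
  # MAR: x2 goes missing with probability depending on the observed x1
  miss <- runif(n) < plogis(-0.5 + 1.5 * x1)
  x2[miss] <- NA
  em <- em_correlation(cbind(a = x1, b = x2), tol = 1e-10)

  # oracle: generic optimizer on the explicit observed-data log-likelihood
  negll <- function(par) {
    mu <- par[1:2]; s1 <- exp(par[3]); s2 <- exp(par[4]); rho <- tanh(par[5])
    ll <- sum(dnorm(x1[miss], mu[1], s1, log = TRUE))
    cm <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2)
    z <- cbind(x1[!miss] - mu[1], x2[!miss] - mu[2])
    -(ll + sum(mvn_logpdf(z, cm)))
  }
  mvn_logpdf <- function(z, cm) {
    ch <- tryCatch(chol(cm), error = function(e) NULL)
    if (is.null(ch)) return(rep(-1e8, nrow(z)))
    w <- backsolve(ch, t(z), transpose = TRUE)
    -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(w^2)
  }
  fit <- optim(c(0, 0, 0, 0, atanh(0.5)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  rho_oracle <- tanh(fit$par[5])
  expect_equal(em$correlation$matrix[1, 2], rho_oracle, tolerance = 1e-4)
})

test_that("EM beats pairwise deletion in RMSE on MCAR Gaussian data", {
  truth <- toy_corr()
  err <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    x <- simulate_gaussian(600, truth, seed = 100 + r)
    x[sample(length(x), round(0.3 * length(x)))] <- NA
    em <- em_correlation(x)$correlation$matrix
    pw <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
    up <- upper.tri(truth)
    err[r, ] <- c(sqrt(mean((em[up] - truth[up])^2)),
                  sqrt(mean((pw[up] - truth[up])^2)))
  }
  expect_lt(mean(err[, 1]), mean(err[, 2]))
})

test_that("Spearman adjustment follows 2 sin(pi rho / 6)", {
  # fixed points and the 0.5 case of the adjustment map
  expect_equal(2 * sin(pi * 0 / 6), 0)
  x <- cbind(a = 1:20, b = 1:20)  # perfect rank correlation
  expect_equal(spearman_pairwise(x, adjusted = TRUE)$matrix[1, 2], 1)
  set.seed(5)
  y <- simulate_gaussian(500, toy_corr())
  raw <- spearman_pairwise(y)$matrix
  adj <- spearman_pairwise(y, adjusted = TRUE)$matrix
  expect_equal(adj[1, 2], 2 * sin(pi * raw[1, 2] / 6))
  # rho = 0.5 maps to ~0.5176
  expect_equal(2 * sin(pi * 0.5 / 6), 0.5176381, tolerance = 1e-6)
})

test_that("adjusted Spearman approaches Pearson on truly Gaussian data", {
  x <- simulate_gaussian(4000, toy_corr(), seed = 11)
  adj <- spearman_pairwise(x, adjusted = TRUE)$matrix
  raw <- spearman_pairwise(x)$matrix
  pe <- cor(x)
  expect_lt(max(abs(adj - pe)), max(abs(raw - pe)))
  expect_lt(max(abs(adj - pe)), 0.03)
})

test_that("pairwise, listwise and mean imputation coincide on complete data", {
  x <- simulate_gaussian(200, toy_corr(), seed = 3)
  pw <- spearman_pairwise(x)
  expect_equal(listwise_correlation(x)$matrix, pw$matrix)
  expect_equal(mean_impute_correlation(x)$matrix, pw$matrix)
})

test_that("deletion estimators enforce their sample-size preconditions", {
  x <- simulate_gaussian(10, toy_corr(), seed = 4)
  x[1:8, 1] <- NA  # only 2 complete rows
  expect_error(listwise_correlation(x), "complete rows")
  thin <- cbind(a = c(1, 2, NA, NA, 5), b = c(NA, NA, 3, 4, NA), c = 1:5)
  expect_warning(r <- spearman_pairwise(thin), "fewer than 3")
  expect_equal(r$matrix["a", "b"], 0)
  allna <- cbind(a = rep(NA_real_, 5), b = 1:5)
  expect_error(mean_impute_correlation(allna), "missing")
})

test_that("mean imputation attenuates correlations on average", {
  set.seed(6)
  deltas <- replicate(20, {
    x <- simulate_gaussian(300, toy_corr(), seed = sample.int(1e6, 1))
    full <- abs(cor(x, method = "spearman")[1, 2])
    x[sample(300, 120), 2] <- NA
    abs(mean_impute_correlation(x)$matrix[1, 2]) - full
  })
  expect_lt(mean(deltas), 0)
})

test_that("nearest-PD projection satisfies its constraints and is idempotent", {
  ok <- toy_corr()
  expect_equal(nearest_positive_definite(ok), ok, tolerance = 1e-12)

  bad <- matrix(0.9, 3, 3); diag(bad) <- 1
  bad[1, 3] <- bad[3, 1] <- -0.9  # indefinite
  proj <- nearest_positive_definite(bad)
  expect_equal(diag(proj), rep(1, 3), ignore_attr = TRUE)
  expect_gt(min(eigen(proj, only.values = TRUE)$values), 0)
  expect_equal(proj, t(proj))
  expect_error(nearest_positive_definite(matrix(1:9, 3)), "symmetric")

  # Frobenius optimality against a brute-force 1-parameter search for the
  # 2x2 case with off-diagonal 1.2
  two <- matrix(c(1, 1.2, 1.2, 1), 2)
  p2 <- nearest_positive_definite(two)
  expect_lt(abs(p2[1, 2]), 1)
  grid_best <- optimize(function(r) (r - 1.2)^2, c(-0.9999999, 0.9999999))$minimum
  expect_equal(p2[1, 2], grid_best, tolerance = 1e-4)
})

test_that("nearest-PD projection is Frobenius-optimal against a generic optimizer", {
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1
  bad[1, 3] <- bad[3, 1] <- -0.9
  proj <- nearest_positive_definite(bad)
  # optimize over the 3 off-diagonals with a PD penalty barrier
  obj <- function(par) {
    m <- diag(3)
    m[lower.tri(m)] <- par; m <- m + t(m) - diag(3) * 0  # symmetric fill
    diag(m) <- 1
    ev <- min(eigen(m, only.values = TRUE)$values)
    sum((m - bad)^2) + if (ev < 1e-8) 1e4 * (1e-8 - ev) else 0
  }
  fit <- optim(proj[lower.tri(proj)], obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(sum((proj - bad)^2), fit$value + 1e-6)
})

test_that("all estimators agree with the truth on lightly-masked Gaussian data", {
  truth <- toy_corr()
  x <- simulate_gaussian(5000, truth, seed = 9)
  x[sample(length(x), round(0.05 * length(x)))] <- NA
  d <- mixed_data(x)
  for (est in c("em", "spearman-pairwise", "spearman-adjusted",
                "listwise", "mean-impute")) {
    cm <- estimate_correlation(d, est)
    # the unadjusted rank estimators converge to the (slightly smaller)
    # Spearman correlation of the Gaussian, and mean imputation attenuates
    # further; allow them the corresponding extra margin
    tol <- if (est %in% c("em", "spearman-adjusted")) 0.05 else 0.07
    expect_lt(max(abs(cm$matrix - truth)), tol)
    expect_s3_class(cm, "cmx_corr")
    ev <- eigen(cm$matrix, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})
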