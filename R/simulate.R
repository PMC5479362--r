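#' Monotone distortion of the continuous variables
#'
#' Applies the cubic map `x^3` entrywise to the continuous columns (the
#' benchmark's nonnormality-inducing transformation); discrete columns and
#' the missingness pattern are untouched.  Ranks are preserved exactly, so
#' the copula transform of a distorted dataset equals that of the original.
#'
#' @param data a [mixed_data()].
#' @param which columns to distort; defaults to all continuous columns.
#' @param f the strictly increasing map (default: cube).
#' @return a [mixed_data()].
#' @export
distort <- function(data, which = NULL, f = function(x) x^3) {
  stopifnot(inherits(data, "cmx_data"))
  if (is.null(which)) which <- names(data$types)[data$types == "continuous"]
  out <- data
  for (j in which) out$values[, j] <- f(out$values[, j])
  out
}

#' Inject missing values
#'
#' MCAR: every cell is masked independently with probability `rate`.
#' MAR: the masking probability of each target column follows a logistic
#' function of an always-observed driver column (by default the discrete
#' root variables, mimicking complete baseline covariates with incomplete
#' downstream measurements), with the intercept calibrated on the realized
#' driver values so the marginal rate matches `rate` exactly.  Neither
#' mechanism is allowed to empty a row or a column: a lone surviving cell is
#' restored at random where needed.
#'
#' @param data a [mixed_data()].
#' @param rate target missing fraction in `[0, 0.9]`.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param seed optional integer seed.
#' @param drivers always-observed driver columns for MAR (default: the
#'   discrete columns, or the first column if none).
#' @param slope logistic slope on the standardized driver under MAR.
#' @return a [mixed_data()] with `NA`s injected.
#' @export
inject_missing <- function(data, rate, mechanism = c("mcar", "mar"), seed = NULL,
                           drivers = NULL, slope = 1.5) {
  stopifnot(inherits(data, "cmx_data"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate > 0.9) stop("rate must be in [0, 0.9]")
  if (rate == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  vals <- data$values
  n <- nrow(vals); vars <- colnames(vals)

  if (mechanism == "mcar") {
    mask <- matrix(stats::runif(length(vals)) < rate, n, ncol(vals))
  } else {
    if (is.null(drivers)) {
      drivers <- names(data$types)[data$types == "discrete"]
      if (length(drivers) == 0) drivers <- vars[1]
    }
    if (!all(drivers %in% vars)) stop("unknown driver column(s)")
    targets <- setdiff(vars, drivers)
    if (length(targets) == 0) stop("no target columns left for MAR masking")
    # marginal rate over the whole table, drivers never missing
    target_rate <- rate * length(vars) / length(targets)
    if (target_rate > 0.95) stop("rate too high to keep the driver columns complete")
    mask <- matrix(FALSE, n, ncol(vals), dimnames = list(NULL, vars))
    for (idx in seq_along(targets)) {
      j <- targets[idx]
      d <- drivers[(idx - 1) %% length(drivers) + 1]
      x <- scale(vals[, d])[, 1]
      a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * x)) - target_rate,
                          c(-30, 30))$root
      mask[, j] <- stats::runif(n) < stats::plogis(a + slope * x)
    }
  }

  # never empty a full row or column
  for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(ncol(mask), 1)] <- FALSE
  for (j in which(colSums(!mask) == 0)) mask[sample.int(n, 1), j] <- FALSE
  vals[mask] <- NA_real_
  mixed_data(vals, data$types)
}

#' Simulation-study configuration
#'
#' The default grid mirrors the benchmark protocol: both correlation
#' regimes, missingness levels 0, 5 and 30 percent, sample sizes 100, 250,
#' 500 and 1000, fifty repetitions, all five correlation estimators, and
#' both discovery algorithms.
#'
#' @param regimes,missing_rates,sample_sizes,estimators,algorithms grid axes.
#' @param repetitions seeded repetitions per cell.
#' @param base_seed base of the per-cell seed stream.
#' @param mechanism missingness mechanism passed to [inject_missing()].
#' @param threshold,alpha decision parameters for BCCD and PC.
#' @return a list of class `cmx_config`.
#' @export
experiment_config <- function(regimes = c("medium", "high"),
                              missing_rates = c(0, 0.05, 0.30),
                              sample_sizes = c(100, 250, 500, 1000),
                              repetitions = 50,
                              estimators = c("em", "spearman-pairwise",
                                             "spearman-adjusted", "listwise",
                                             "mean-impute"),
                              algorithms = c("bccd", "pc"),
                              base_seed = 1,
                              mechanism = "mcar",
                              threshold = 0.6, alpha = 0.05) {
  stopifnot(all(missing_rates >= 0 & missing_rates < 1), repetitions >= 1)
  structure(list(regimes = regimes, missing_rates = missing_rates,
                 sample_sizes = sample_sizes, repetitions = repetitions,
                 estimators = estimators, algorithms = algorithms,
                 base_seed = base_seed, mechanism = mechanism,
                 threshold = threshold, alpha = alpha),
            class = "cmx_config")
}

cell_seed <- function(base_seed, cell, rep) {
  (base_seed + 104729 * cell + 7919 * rep) %% 2147483563L
}

#' Run the benchmark simulation grid
#'
#' For every cell of regime x missing rate x sample size x estimator x
#' algorithm, draws `repetitions` seeded datasets from the Waste Incinerator
#' network, applies the cubic distortion and missingness injection, runs the
#' chosen estimator and discovery algorithm, and scores the output PAG
#' against the ground truth (endpoint accuracy, skeleton precision and
#' recall).  At zero missingness the mean-imputed, listwise and pairwise
#' Spearman estimators coincide, so only the pairwise representative is run
#' there.  Individual run failures are recorded as `NA` rows, not raised.
#'
#' @param config an [experiment_config()].
#' @param verbose print one line per cell.
#' @return a tidy data.frame, one row per run.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  grid <- expand.grid(regime = config$regimes, rate = config$missing_rates,
                      n = config$sample_sizes, estimator = config$estimators,
                      algorithm = config$algorithms,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # deletion/imputation strategies coincide at 0% missing: keep one of them
  dup0 <- grid$rate == 0 & grid$estimator %in% c("listwise", "mean-impute")
  grid <- grid[!dup0, , drop = FALSE]
  nets <- lapply(stats::setNames(nm = unique(grid$regime)), waste_incinerator)
  truths <- lapply(nets, function(net) ground_truth_pag(net$dag))

  rows <- vector("list", nrow(grid) * config$repetitions)
  out_i <- 0
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    if (verbose) {
      message(sprintf("cell %d/%d: %s, %.0f%% missing, n=%d, %s, %s",
                      cell, nrow(grid), g$regime, 100 * g$rate, g$n,
                      g$estimator, g$algorithm))
    }
    for (rep in seq_len(config$repetitions)) {
      seed <- cell_seed(config$base_seed, cell, rep)
      res <- tryCatch(
        one_run(nets[[g$regime]], truths[[g$regime]], g, config, seed),
        error = function(e) {
          message("run failed (", conditionMessage(e), ")")
          c(pag_accuracy = NA_real_, precision = NA_real_, recall = NA_real_)
        })
      out_i <- out_i + 1
      rows[[out_i]] <- data.frame(g, rep = rep, seed = seed,
                                  pag_accuracy = res[["pag_accuracy"]],
                                  precision = res[["precision"]],
                                  recall = res[["recall"]],
                                  stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

one_run <- function(net, truth, g, config, seed) {
  set.seed(seed)
  data <- sample_network(net, g$n)
  data <- distort(data)
  if (g$rate > 0) data <- inject_missing(data, g$rate, config$mechanism)
  corr <- estimate_correlation(data, g$estimator)
  est <- if (g$algorithm == "bccd") {
    bccd_from_correlation(corr, threshold = config$threshold)$pag
  } else {
    run_pc(corr, alpha = config$alpha)
  }
  pr <- skeleton_precision_recall(est, truth)
  c(pag_accuracy = pag_accuracy(est, truth),
    precision = pr[["precision"]], recall = pr[["recall"]])
}

#' Summarize a simulation result table
#'
#' Mean and standard error of each metric per grid cell.
#'
#' @param results output of [run_experiment()].
#' @return a data.frame, one row per cell.
#' @export
summarize_experiment <- function(results) {
  keys <- c("regime", "rate", "n", "estimator", "algorithm")
  keys <- keys[keys %in% names(results)]
  split_idx <- interaction(results[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(results, split_idx)
  do.call(rbind, lapply(parts, function(p) {
    out <- p[1, keys, drop = FALSE]
    for (m in c("pag_accuracy", "precision", "recall")) {
      v <- p[[m]]
      out[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(m, "_se")]] <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
      out[[paste0(m, "_n")]] <- sum(!is.na(v))
    }
    out
  }))
}

#' Plot a summarized simulation grid
#'
#' Accuracy/precision/recall against sample size, one line per estimator,
#' faceted by regime and missing rate.  Requires ggplot2.
#'
#' @param summary output of [summarize_experiment()].
#' @param metric which metric to plot.
#' @return a ggplot object.
#' @export
plot_experiment <- function(summary, metric = c("pag_accuracy", "precision", "recall")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  metric <- match.arg(metric)
  d <- summary
  d$mean_val <- d[[paste0(metric, "_mean")]]
  d$se_val <- d[[paste0(metric, "_se")]]
  ggplot2::ggplot(d, ggplot2::aes(x = n, y = mean_val, colour = estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_val - se_val,
                                          ymax = mean_val + se_val)) +
    ggplot2::facet_grid(regime ~ rate) +
    ggplot2::labs(x = "sample size", y = metric) +
    ggplot2::theme_minimal()
}
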