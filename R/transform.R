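#' Mixed discrete/continuous dataset with missing values
#'
#' Container for a subjects-by-variables table in which each variable is
#' flagged discrete or continuous and missing cells are `NA`.  Discrete
#' values are stored as numeric category codes; the copula transform treats
#' both kinds identically (both are ranked), so codes only need to respect
#' the category order.
#'
#' @param values numeric matrix or data.frame, one row per subject, one
#'   column per named variable; `NA` marks a missing cell.
#' @param types character vector, one of `"discrete"` / `"continuous"` per
#'   column (recycled if length one).
#' @return an object of class `cmx_data` with elements `values` (numeric
#'   matrix), `mask` (logical matrix, `TRUE` = missing) and `types`.
#' @export
mixed_data <- function(values, types = "continuous") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  types <- rep_len(match.arg(types, c("discrete", "continuous"), several.ok = TRUE),
                   ncol(values))
  names(types) <- colnames(values)
  structure(list(values = values, mask = is.na(values), types = types),
            class = "cmx_data")
}

#' @export
print.cmx_data <- function(x, ...) {
  cat(sprintf("Mixed dataset: %d subjects x %d variables (%d discrete, %d continuous), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$types == "discrete"), sum(x$types == "continuous"),
              100 * mean(x$mask)))
  invisible(x)
}

as_values_matrix <- function(data) {
  if (inherits(data, "cmx_data")) data$values
  else if (inherits(data, "cmx_transformed")) data$values
  else as.matrix(data)
}

#' Rescaled empirical distribution of one variable
#'
#' Maps every non-missing entry to mid-rank / (n + 1), where n counts the
#' non-missing entries of the column and tied observations share their
#' average rank, so all probabilities fall strictly inside (0, 1).  The
#' strict-indicator variant (the count of strictly smaller values over
#' n + 1, which assigns the column minimum probability 0) is available with
#' `ties = "strict"` and is clamped to `[1/(n+1), n/(n+1)]` to keep the
#' normal scores finite.
#'
#' @param column numeric vector, `NA` for missing.
#' @param ties `"midrank"` (default) or `"strict"`.
#' @param name variable name used in error messages.
#' @return numeric vector of the same length; missing entries stay `NA`.
#' @examples
#' empirical_cdf(c(3, 1, 2))        # 0.75 0.25 0.50
#' empirical_cdf(c(1, 1, 2, 2))     # 0.3 0.3 0.7 0.7
#' @export
empirical_cdf <- function(column, ties = c("midrank", "strict"), name = "column") {
  ties <- match.arg(ties)
  obs <- !is.na(column)
  n <- sum(obs)
  if (length(unique(column[obs])) < 2) {
    stop("variable '", name, "' is constant (or has fewer than two distinct ",
         "observed values); its normal scores are undefined")
  }
  out <- rep(NA_real_, length(column))
  if (ties == "midrank") {
    out[obs] <- rank(column[obs], ties.method = "average") / (n + 1)
  } else {
    x <- column[obs]
    out[obs] <- pmax(vapply(x, function(v) sum(x < v), numeric(1)), 1) / (n + 1)
  }
  out
}

#' Gaussian normal scores of one variable
#'
#' The standard-normal quantile of the rescaled empirical distribution; a
#' strictly monotone map of the observed values, so any strictly increasing
#' marginal distortion of the data leaves the scores unchanged.
#'
#' @inheritParams empirical_cdf
#' @return numeric vector of normal scores; missing entries stay `NA`.
#' @export
normal_scores <- function(column, ties = c("midrank", "strict"), name = "column") {
  stats::qnorm(empirical_cdf(column, ties = ties, name = name))
}

#' Copula transform of a mixed dataset
#'
#' Applies [normal_scores()] column by column, ignoring missing values
#' (each column's ranks are computed over its observed entries only).
#' Discrete and continuous variables are treated identically: both are
#' ranked, which models both through a Gaussian copula at the cost of a
#' slight underestimation of some correlations involving coarse discrete
#' variables.
#'
#' @param data a [mixed_data()] object (or plain matrix).
#' @param ties passed to [empirical_cdf()].
#' @return an object of class `cmx_transformed` with the transformed
#'   `values` matrix and the unchanged missingness `mask`.
#' @export
transform_dataset <- function(data, ties = c("midrank", "strict")) {
  ties <- match.arg(ties)
  vals <- as_values_matrix(data)
  failed <- character()
  out <- vals
  for (j in seq_len(ncol(vals))) {
    res <- tryCatch(normal_scores(vals[, j], ties = ties, name = colnames(vals)[j]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, conditionMessage(res))
      next
    }
    out[, j] <- res
  }
  if (length(failed)) stop(paste(failed, collapse = "\n"))
  structure(list(values = out, mask = is.na(out)), class = "cmx_transformed")
}

#' @export
print.cmx_transformed <- function(x, ...) {
  cat(sprintf("Normal-score dataset: %d x %d, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}
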