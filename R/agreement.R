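#' Residual set of log-transformed predictions and known values
#'
#' Container for agreement analysis: `e` holds the log-transformed
#' predicted values, `a` the log-transformed known values, and
#' `residuals = e - a` element-wise. All agreement statistics
#' ([bias()], [precision()], [accuracy_mae()], [bland_altman()],
#' [pearson_r()]) operate on this object.
#'
#' @param e,a numeric vectors of equal length (>= 1), already
#'   log-transformed.
#' @return an object of class `residual_set` with elements `e`, `a`,
#'   `residuals`, `n`.
#' @export
residual_set <- function(e, a) {
  if (!is.numeric(e) || !is.numeric(a) || length(e) != length(a)) {
    stop("e and a must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(e) < 1L) {
    stop("a residual set needs at least one observation", call. = FALSE)
  }
  if (anyNA(e) || anyNA(a) || any(!is.finite(e)) || any(!is.finite(a))) {
    stop("e and a must be finite and non-missing", call. = FALSE)
  }
  structure(list(e = e, a = a, residuals = e - a, n = length(e)),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat("Residual set: n =", x$n, "\n")
  cat(sprintf("  mean residual %.4g, range [%.4g, %.4g]\n",
              mean(x$residuals), min(x$residuals), max(x$residuals)))
  invisible(x)
}

#' Bias of a prediction set
#'
#' Arithmetic mean of the residuals (log predicted minus log known).
#' Positive bias means predictions sit above the known values on the log
#' scale, i.e. toxicity is understated on average.
#'
#' @param rs a [residual_set()].
#' @return single numeric value.
#' @export
bias <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  mean(rs$residuals)
}

#' Relative bias (percent)
#'
#' Back-transforms a bias on the log scale to a percentage:
#' `(exp(bias) - 1) * 100`, using the natural exponential.
#'
#' @param bias_value bias on the log scale.
#' @return percentage (0 at zero bias; `relative_bias(log(2))` is exactly
#'   100).
#' @export
relative_bias <- function(bias_value) {
  (exp(bias_value) - 1) * 100
}

#' Precision of a prediction set
#'
#' Sample standard deviation of the residuals about the bias:
#' `sqrt(sum((r - bias)^2) / (n - 1))`. Reported on the same (log) scale as
#' the bias.
#'
#' @param rs a [residual_set()] with at least two observations.
#' @return nonnegative numeric value.
#' @export
precision <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  if (rs$n < 2L) {
    stop("precision requires at least two residuals", call. = FALSE)
  }
  stats::sd(rs$residuals)
}

#' Accuracy as mean absolute error
#'
#' Mean of the absolute residuals. By the triangle inequality this is
#' always at least the absolute bias.
#'
#' @param rs a [residual_set()].
#' @return nonnegative numeric value.
#' @export
accuracy_mae <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  mean(abs(rs$residuals))
}

#' Absolute offset of means
#'
#' `|mean(e) - mean(a)|`: the distance between the mean log-predicted and
#' mean log-known values. Reported alongside [accuracy_mae()] as a
#' secondary, mean-level summary of accuracy; it equals `|bias|` and is a
#' lower bound on the MAE.
#'
#' @param rs a [residual_set()].
#' @return nonnegative numeric value.
#' @export
mean_offset <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  abs(mean(rs$e) - mean(rs$a))
}

#' Bland-Altman limits of agreement
#'
#' Differences are oriented predicted minus known (the residuals); the
#' limits of agreement are the mean difference plus or minus 1.96 sample
#' standard deviations. Per-point coordinates for the standard plot
#' (x = pairwise mean, y = difference) are returned as well.
#'
#' @param rs a [residual_set()] with at least two observations.
#' @return a list `ba_mean`, `ba_upper`, `ba_lower`, and `points` (data
#'   frame with columns `mean` and `difference`). Class `bland_altman`.
#' @export
bland_altman <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  if (rs$n < 2L) {
    stop("Bland-Altman limits require at least two observations",
         call. = FALSE)
  }
  d <- rs$residuals
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(
    ba_mean = m,
    ba_upper = m + 1.96 * s,
    ba_lower = m - 1.96 * s,
    points = data.frame(mean = (rs$e + rs$a) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean %.4g, limits [%.4g, %.4g], n = %d\n",
              x$ba_mean, x$ba_lower, x$ba_upper, nrow(x$points)))
  invisible(x)
}

#' Pearson correlation of log predictions and log known values
#'
#' @param rs a [residual_set()] with at least three observations and
#'   nonzero variance in both sequences.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  if (rs$n < 3L) {
    stop("Pearson correlation requires at least three observations",
         call. = FALSE)
  }
  if (stats::sd(rs$e) == 0 || stats::sd(rs$a) == 0) {
    stop("Pearson correlation undefined for zero-variance input",
         call. = FALSE)
  }
  stats::cor(rs$e, rs$a)
}

#' Anderson-Darling normality gate
#'
#' Screens a sample for normality before log-scale agreement statistics are
#' reported. The gate only annotates reports - it never blocks any
#' computation. Samples smaller than 8 are reported as inconclusive.
#'
#' @param values numeric vector.
#' @param alpha significance level (default 0.05).
#' @return a list `statistic` (the A-squared statistic), `p_value`, `pass`
#'   (`TRUE` when p >= alpha), and `conclusive` (`FALSE` for small n, in
#'   which case the other elements are `NA`).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) {
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                conclusive = FALSE))
  }
  ad <- nortest::ad.test(values)
  list(statistic = unname(ad$statistic), p_value = unname(ad$p.value),
       pass = unname(ad$p.value) >= alpha, conclusive = TRUE)
}

#' Grouped agreement summary for a prediction set
#'
#' Computes the full lack-of-agreement panel on log-transformed predicted
#' and known values, overall or per functional group: n, bias, relative
#' bias (%), precision, accuracy (MAE), the mean-offset secondary accuracy,
#' Bland-Altman mean and limits, and the Pearson correlation. Predictions
#' without a known value are dropped first.
#'
#' @param predictions data frame from [predict_target()] (rows may span
#'   pairs and taxa) with columns `predicted_lc50_ug_L` and
#'   `known_lc50_ug_L`; for `grouping = "functional_group"` it must also
#'   carry a `functional_group` column (as written by [run_pipeline()]).
#' @param grouping `"overall"` or `"functional_group"`.
#' @param log_base base of the log transform applied to predicted and known
#'   values before any statistic (default 10, the toxicology convention).
#'   The relative bias always uses the natural exponential of the bias,
#'   independent of `log_base`.
#' @return a data frame with one row per group. Statistics whose minimum n
#'   is not met (`precision` and Bland-Altman need 2, `pearson_r` needs 3
#'   and nonzero variance) are `NA` rather than errors.
#' @export
summarize_agreement <- function(predictions,
                                grouping = c("overall", "functional_group"),
                                log_base = 10) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(predictions))
  known <- predictions[!is.na(predictions$known_lc50_ug_L), , drop = FALSE]
  if (nrow(known) == 0L) {
    stop("no predictions with known values to summarize", call. = FALSE)
  }
  if (grouping == "functional_group" &&
      is.null(known$functional_group)) {
    stop("grouping by functional_group requires a functional_group column",
         call. = FALSE)
  }
  groups <- if (grouping == "overall") {
    list(overall = known)
  } else {
    split(known, known$functional_group)
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    rs <- residual_set(log(d$predicted_lc50_ug_L, base = log_base),
                       log(d$known_lc50_ug_L, base = log_base))
    b <- bias(rs)
    prec <- if (rs$n >= 2L) precision(rs) else NA_real_
    ba <- if (rs$n >= 2L) bland_altman(rs) else NULL
    r <- if (rs$n >= 3L && stats::sd(rs$e) > 0 && stats::sd(rs$a) > 0) {
      pearson_r(rs)
    } else NA_real_
    data.frame(group = g, n = rs$n, bias = b,
               relative_bias_pct = relative_bias(b),
               precision = prec, accuracy_mae = accuracy_mae(rs),
               mean_offset = mean_offset(rs),
               ba_mean = if (is.null(ba)) NA_real_ else ba$ba_mean,
               ba_upper = if (is.null(ba)) NA_real_ else ba$ba_upper,
               ba_lower = if (is.null(ba)) NA_real_ else ba$ba_lower,
               pearson_r = r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
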