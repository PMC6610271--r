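# Method-agreement machinery: Dice overlap, Bland-Altman bias and limits of
# agreement (raw and percentage), test-retest coefficient of variation, the
# limits-of-agreement sample-size planner, and the per-method volume-error
# summary table.

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined to overlap
#' completely (DSC 1).
#'
#' @param a,b [kidney_mask()] objects (or plain binary arrays) on congruent
#'   grids.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  va <- if (is_kidney_mask(a)) a$voxels else a
  vb <- if (is_kidney_mask(b)) b$voxels else b
  if (!identical(dim(va), dim(vb)))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(va), collapse = "x"), paste(dim(vb), collapse = "x")))
  sa <- sum(va); sb <- sum(vb)
  if (sa + sb == 0) return(1)
  2 * sum(va * vb) / (sa + sb)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `test - reference`; in percent mode they are
#' `100 * (test - reference) / denominator`, the denominator being the
#' reference value by default (so negative values mean the test method
#' underestimates) or the pair mean in classical form. Limits of agreement
#' are `bias +/- 1.96 SD`.
#'
#' @param reference,test paired measurements, equal length >= 2.
#' @param mode `"raw"` or `"percent"`.
#' @param denominator `"reference"` (default) or `"mean"`, percent mode only.
#' @return An object of class `agreement_stats`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `mode`, and the per-pair `differences`.
#' @export
bland_altman <- function(reference, test, mode = c("raw", "percent"),
                         denominator = c("reference", "mean")) {
  mode <- match.arg(mode); denominator <- match.arg(denominator)
  if (length(reference) != length(test)) stop("unequal pair lengths")
  if (length(reference) < 2) stop("need at least 2 measurement pairs")
  d <- test - reference
  if (mode == "percent") {
    den <- if (denominator == "reference") reference else (reference + test) / 2
    if (any(den <= 0)) stop("percent mode needs strictly positive values")
    d <- 100 * d / den
  }
  bias <- mean(d); sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d), mode = mode, differences = d,
                 means = (reference + test) / 2),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("<agreement_stats> n = %d, bias %.3g%s, SD %.3g%s, LoA [%.3g, %.3g]%s\n",
              x$n, x$bias, unit, x$sd_diff, unit, x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' Test-retest coefficient of variation
#'
#' Per subject, CoV = SD of the two repeats / their mean; the reported value
#' is the root mean square of the per-subject CoVs, times 100.
#'
#' @param first,second paired repeat measurements (> 0).
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(first, second) {
  if (length(first) != length(second)) stop("unequal repeat lengths")
  if (any(first <= 0) || any(second <= 0))
    stop("CoV needs strictly positive measurements")
  m <- (first + second) / 2
  s <- abs(first - second) / sqrt(2)  # SD of two values
  100 * sqrt(mean((s / m)^2))
}

#' Minimum pairs for a Bland-Altman agreement study
#'
#' Plans the number of measurement pairs needed to show both 95% limits of
#' agreement inside the clinically acceptable band `+/- max_allowed_diff`,
#' with the stated power at the stated type-I error, given the expected bias
#' and SD of differences. The limit estimate's sampling SD is approximated by
#' `sqrt(3 sigma^2 / n)`, and the requirement is
#' `|bias| + 1.96 sigma + (t_{1-alpha/2, n-1} + z_power) * sigma * sqrt(3/n)
#' <= max_allowed_diff`, solved for the smallest integer `n >= 2`. The result
#' is monotone non-decreasing in the expected SD and non-increasing in the
#' allowed difference. All five inputs share one unit (typically percent).
#'
#' @param expected_mean expected bias of differences.
#' @param expected_sd expected SD of differences (> 0).
#' @param max_allowed_diff maximum clinically acceptable difference; must
#'   exceed `|expected_mean| + 1.96 * expected_sd`, otherwise the agreement
#'   claim is unattainable at any n and an error is raised.
#' @param alpha type-I error (two-sided).
#' @param power target power.
#' @param n_max search cap.
#' @return minimum number of pairs (integer).
#' @export
ba_sample_size <- function(expected_mean = 2, expected_sd = 5,
                           max_allowed_diff = 15, alpha = 0.05, power = 0.80,
                           n_max = 100000L) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, expected_sd > 0)
  if (max_allowed_diff <= abs(expected_mean) + 1.96 * expected_sd)
    stop(paste("infeasible: the expected limits of agreement already reach the",
               "maximum allowed difference; no sample size attains the power"))
  zb <- stats::qnorm(power)
  for (n in 2:n_max) {
    margin <- (stats::qt(1 - alpha / 2, n - 1) + zb) * expected_sd * sqrt(3 / n)
    if (abs(expected_mean) + 1.96 * expected_sd + margin <= max_allowed_diff)
      return(n)
  }
  stop("no n <= n_max achieves the requested power")
}

#' Per-method volume-error summary table
#'
#' Mean and SD of raw (ml) and percentage differences of each method against
#' the reference, per side and for TKV, mirroring the usual accuracy/
#' precision comparison layout. Negative values mean the method
#' underestimates the reference.
#'
#' @param reference data frame with columns `subject_id`, `right_kv_ml`,
#'   `left_kv_ml`.
#' @param tests named list of data frames with the same columns, one per
#'   method.
#' @return data frame with one row per (region, method).
#' @export
volume_error_table <- function(reference, tests) {
  stopifnot(is.list(tests), length(tests) >= 1, !is.null(names(tests)))
  need <- c("subject_id", "right_kv_ml", "left_kv_ml")
  stopifnot(all(need %in% names(reference)))
  rows <- list()
  for (method in names(tests)) {
    tst <- tests[[method]]
    stopifnot(all(need %in% names(tst)))
    m <- match(reference$subject_id, tst$subject_id)
    if (anyNA(m)) stop(sprintf("method '%s': unmatched subject ids", method))
    tst <- tst[m, ]
    for (region in c("right_kv_ml", "left_kv_ml", "tkv")) {
      ref_v <- if (region == "tkv") reference$right_kv_ml + reference$left_kv_ml
               else reference[[region]]
      tst_v <- if (region == "tkv") tst$right_kv_ml + tst$left_kv_ml
               else tst[[region]]
      d <- tst_v - ref_v
      p <- 100 * d / ref_v
      rows[[length(rows) + 1L]] <- data.frame(
        region = c(right_kv_ml = "right_kv", left_kv_ml = "left_kv",
                   tkv = "tkv")[region],
        method = method, n = length(d),
        mean_volume_ml = mean(tst_v), sd_volume_ml = stats::sd(tst_v),
        pct_diff_mean = mean(p), pct_diff_sd = stats::sd(p),
        raw_diff_mean_ml = mean(d), raw_diff_sd_ml = stats::sd(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias as a bold line and the 95%
#' limits of agreement dashed.
#'
#' @param stats an `agreement_stats` object from [bland_altman()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(stats, title = NULL) {
  stopifnot(inherits(stats, "agreement_stats"))
  df <- data.frame(mean = stats$means, diff = stats$differences)
  ylab <- if (stats$mode == "percent") "difference (%)" else "difference"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = stats$bias, linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(stats$loa_low, stats$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair", y = ylab, title = title) +
    ggplot2::theme_minimal()
}
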