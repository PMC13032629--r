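#' Bland-Altman limits of agreement
#'
#' Bias is the mean of the paired differences (rater 1 minus rater 2); the
#' 95\% limits of agreement are \code{bias +/- 1.96} times the sample
#' standard deviation of the differences.
#'
#' @param values_rater1,values_rater2 equal-length numeric vectors of paired
#'   measurements (n >= 2).
#' @param loa_mult multiplier for the limits (default 1.96).
#' @return object of class \code{octmhri_bland_altman}: \code{bias},
#'   \code{loa_low}, \code{loa_high}, \code{sd_diff}, \code{n} and
#'   \code{points}, a data frame of per-pair \code{(mean, difference)}.
#' @export
bland_altman <- function(values_rater1, values_rater2, loa_mult = 1.96) {
  check_that(length(values_rater1) == length(values_rater2),
             "values_rater2", "must match `values_rater1` in length")
  check_that(is.numeric(values_rater1) && is.numeric(values_rater2) &&
               length(values_rater1) >= 2L,
             "values_rater1", "need at least 2 numeric pairs")
  d <- values_rater1 - values_rater2
  bias <- mean(d)
  s <- sd(d)                       # sample SD (n - 1 denominator)
  structure(list(bias = bias,
                 loa_low = bias - loa_mult * s,
                 loa_high = bias + loa_mult * s,
                 sd_diff = s, n = length(d),
                 points = data.frame(mean = (values_rater1 + values_rater2) / 2,
                                     difference = d)),
            class = "octmhri_bland_altman")
}

#' @export
print.octmhri_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, 95%% LOA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Single-measurement ICCs from the two-way ANOVA mean squares of an
#' n-subjects by k-raters rating matrix. The default \code{"ICC2_1"} is the
#' two-way random-effects, absolute-agreement, single-measurement
#' coefficient — the standard choice for inter-rater reproducibility:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' \code{"ICC3_1"} (two-way mixed, consistency) and \code{"ICC1_1"}
#' (one-way random) are also available.
#'
#' @param ratings numeric matrix, rows = subjects (n >= 3), columns =
#'   raters (k >= 2), no missing cells.
#' @param model \code{"ICC2_1"} (default), \code{"ICC3_1"} or
#'   \code{"ICC1_1"}.
#' @return object of class \code{octmhri_icc}: \code{icc_value},
#'   \code{icc_model_label}, the mean squares and dimensions.
#' @export
icc <- function(ratings, model = c("ICC2_1", "ICC3_1", "ICC1_1")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  check_that(n >= 3L, "ratings", "need at least 3 subjects (rows)")
  check_that(k >= 2L, "ratings", "need at least 2 raters (columns)")
  check_that(all(is.finite(ratings)), "ratings", "must have no missing cells")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  value <- switch(model,
    ICC2_1 = {
      den <- msr + (k - 1) * mse + k * (msc - mse) / n
      if (den == 0) NA_real_ else (msr - mse) / den
    },
    ICC3_1 = {
      den <- msr + (k - 1) * mse
      if (den == 0) NA_real_ else (msr - mse) / den
    },
    ICC1_1 = {
      msw <- (ss_cols + ss_err) / (n * (k - 1))
      den <- msr + (k - 1) * msw
      if (den == 0) NA_real_ else (msr - msw) / den
    })
  label <- switch(model,
    ICC2_1 = "ICC(2,1) two-way random, absolute agreement, single measurement",
    ICC3_1 = "ICC(3,1) two-way mixed, consistency, single measurement",
    ICC1_1 = "ICC(1,1) one-way random, single measurement")
  structure(list(icc_value = value, icc_model_label = label,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "octmhri_icc")
}

#' @export
print.octmhri_icc <- function(x, ...) {
  cat(sprintf("%s: %.4f (n = %d subjects, k = %d raters)\n",
              x$icc_model_label, x$icc_value, x$n, x$k))
  invisible(x)
}

#' Inter-rater agreement summary
#'
#' Combines [icc()] and [bland_altman()] for a pair of raters.
#'
#' @inheritParams bland_altman
#' @param model ICC variant, see [icc()].
#' @return object of class \code{octmhri_agreement}: \code{icc_value},
#'   \code{icc_model_label}, \code{bias}, \code{loa_low}, \code{loa_high}
#'   and the component objects.
#' @export
agreement_analysis <- function(values_rater1, values_rater2,
                               model = "ICC2_1") {
  ic <- icc(cbind(values_rater1, values_rater2), model = model)
  ba <- bland_altman(values_rater1, values_rater2)
  structure(list(icc_value = ic$icc_value,
                 icc_model_label = ic$icc_model_label,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 icc = ic, bland_altman = ba),
            class = "octmhri_agreement")
}

#' @export
print.octmhri_agreement <- function(x, ...) {
  cat(sprintf("inter-rater agreement: ICC %.3f [%s]\n", x$icc_value,
              x$icc_model_label))
  cat(sprintf("  Bland-Altman bias %.4g, 95%% LOA [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
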