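# AUC as the normalized Mann-Whitney statistic (ties count 0.5), with
# "higher score = positive" orientation
auc_mw <- function(scores, is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  r <- rank(scores)          # midranks handle ties
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong variance of the AUC via placement values
delong_ci <- function(scores, is_pos, auc, conf) {
  x <- scores[is_pos]; y <- scores[!is_pos]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yi) mean(psi(x, yi)), numeric(1))
  s <- var(v10) / m + var(v01) / n
  z <- qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * sqrt(s)), min(1, auc + z * sqrt(s)))
}

#' ROC analysis with a Youden-index cutoff
#'
#' Computes the area under the ROC curve as the normalized Mann-Whitney
#' statistic (ties counted 0.5) and chooses the operating cutoff maximizing
#' Youden's \eqn{J = sensitivity + specificity - 1}. Cutoff candidates are
#' the midpoints between consecutive distinct score values; ties in J are
#' broken toward higher specificity, then the lower cutoff. With
#' \code{direction = "auto"} the score orientation is flipped whenever the
#' raw higher-is-positive AUC falls below 0.5, and the flip is recorded:
#' \code{direction = "lower"} means the positive class is predicted by
#' \code{score < cutoff}.
#'
#' The AUC confidence interval is a stratified bootstrap percentile interval
#' by default (cases and controls resampled separately); the DeLong
#' asymptotic interval is available via \code{ci = "delong"}. The p-value is
#' the two-sided Mann-Whitney test of the score-class association.
#'
#' A score vector with fewer than two distinct values cannot discriminate;
#' it yields a degenerate result (AUC 0.5, no cutoff) with a warning.
#'
#' @param scores numeric predictor values, finite.
#' @param labels two-class labels (logical, factor or character).
#' @param positive the label counted as the positive class (default:
#'   \code{TRUE} for logical labels, otherwise the last sorted level).
#' @param direction \code{"auto"} (default), \code{"higher"} or
#'   \code{"lower"}: which score orientation predicts the positive class.
#' @param ci \code{"bootstrap"}, \code{"delong"} or \code{"none"}.
#' @param boot_n bootstrap replicates (default 2000).
#' @param conf confidence level (default 0.95).
#' @return object of class \code{octmhri_roc}: \code{auc},
#'   \code{auc_ci_low}, \code{auc_ci_high}, \code{cutoff},
#'   \code{youden_j}, \code{sensitivity}, \code{specificity},
#'   \code{direction}, \code{rule}, \code{p_value}, \code{n_pos},
#'   \code{n_neg}, \code{degenerate}.
#' @export
roc_analysis <- function(scores, labels, positive = NULL,
                         direction = c("auto", "higher", "lower"),
                         ci = c("bootstrap", "delong", "none"),
                         boot_n = 2000L, conf = 0.95) {
  direction <- match.arg(direction)
  ci <- match.arg(ci)
  if (ci == "bootstrap" && boot_n < 1L) ci <- "none"
  check_that(is.numeric(scores) && all(is.finite(scores)), "scores",
             "must be finite numeric values")
  check_that(length(scores) == length(labels), "labels",
             "must match `scores` in length")
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE else sort(unique(as.character(labels)))[
      length(unique(as.character(labels)))]
  }
  is_pos <- if (is.logical(labels)) labels == positive else
    as.character(labels) == as.character(positive)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in `labels`", call. = FALSE)
  }

  if (length(unique(scores)) < 2L) {
    warning("all scores are equal: ROC is degenerate (AUC 0.5, no cutoff)")
    out <- list(auc = 0.5, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                cutoff = NA_real_, youden_j = 0, sensitivity = NA_real_,
                specificity = NA_real_, direction = "higher",
                rule = NA_character_, p_value = 1, n_pos = n_pos,
                n_neg = n_neg, degenerate = TRUE, ci_method = "none")
    return(structure(out, class = "octmhri_roc"))
  }

  raw_auc <- auc_mw(scores, is_pos)
  flip <- switch(direction,
                 auto = raw_auc < 0.5,
                 higher = FALSE,
                 lower = TRUE)
  s <- if (flip) -scores else scores
  auc <- auc_mw(s, is_pos)

  ds <- sort(unique(s))
  thr <- (ds[-length(ds)] + ds[-1]) / 2      # midpoints between distinct values
  sens <- vapply(thr, function(t) mean(s[is_pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!is_pos] <= t), numeric(1))
  j <- sens + spec - 1
  cut_rep <- if (flip) -thr else thr         # cutoffs on the original scale
  ord <- order(-j, -spec, cut_rep)
  best <- ord[1]

  p_value <- suppressWarnings(
    wilcox.test(scores[is_pos], scores[!is_pos])$p.value)

  ci_lim <- c(NA_real_, NA_real_)
  if (ci == "bootstrap") {
    pos_scores <- s[is_pos]; neg_scores <- s[!is_pos]
    boots <- vapply(seq_len(boot_n), function(i) {
      bp <- sample(pos_scores, n_pos, replace = TRUE)
      bn <- sample(neg_scores, n_neg, replace = TRUE)
      auc_mw(c(bp, bn), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }, numeric(1))
    ci_lim <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  } else if (ci == "delong") {
    ci_lim <- delong_ci(s, is_pos, auc, conf)
  }

  out <- list(auc = auc, auc_ci_low = ci_lim[1], auc_ci_high = ci_lim[2],
              cutoff = cut_rep[best], youden_j = j[best],
              sensitivity = sens[best], specificity = spec[best],
              direction = if (flip) "lower" else "higher",
              rule = if (flip) "positive if score < cutoff" else
                "positive if score > cutoff",
              p_value = p_value, n_pos = n_pos, n_neg = n_neg,
              degenerate = FALSE, ci_method = ci)
  structure(out, class = "octmhri_roc")
}

#' @export
print.octmhri_roc <- function(x, ...) {
  if (x$degenerate) {
    cat("ROC (degenerate): AUC 0.50, no discriminative cutoff\n")
    return(invisible(x))
  }
  cat(sprintf("ROC: AUC %.3f", x$auc))
  if (!is.na(x$auc_ci_low)) {
    cat(sprintf(" (95%% CI %.3f-%.3f, %s)", x$auc_ci_low, x$auc_ci_high,
                x$ci_method))
  }
  cat(sprintf("\n  cutoff %.4g (%s), J = %.2f, sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, x$rule, x$youden_j, 100 * x$sensitivity,
              100 * x$specificity))
  cat(sprintf("  p = %.4g (Mann-Whitney), %d positives / %d negatives\n",
              x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden's J from sensitivity and specificity
#'
#' \eqn{J = sensitivity + specificity - 1}, the quantity maximized to choose
#' a diagnostic cutoff.
#'
#' @param sensitivity,specificity rates in \[0, 1\] (proportions, not
#'   percentages).
#' @return J in \[-1, 1\].
#' @export
youden_from_rates <- function(sensitivity, specificity) {
  check_that(all(is_prob_vec(sensitivity)), "sensitivity",
             "must be rates in [0, 1]")
  check_that(all(is_prob_vec(specificity)), "specificity",
             "must be rates in [0, 1]")
  sensitivity + specificity - 1
}

is_prob_vec <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & x <= 1
}
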