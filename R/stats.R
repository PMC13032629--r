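#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation (via \code{stats::cor.test} with
#' \code{exact = FALSE}).
#'
#' @param x,y equal-length numeric vectors, n >= 3; neither may be constant.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman <- function(x, y) {
  check_that(length(x) == length(y), "y", "must match `x` in length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= 3L, "x", "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rank correlation is undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Label anatomical and visual outcomes
#'
#' Adds \code{closure_success} (logical) and \code{visual_success}:
#' postoperative acuity of 0.3 logMAR or better (boundary inclusive),
#' defined only among eyes with successful anatomical closure — closure
#' failures get \code{NA} and are excluded from every visual-success
#' denominator.
#'
#' @param records a cohort data frame with \code{closure} and
#'   \code{post_va_logmar} columns.
#' @param va_threshold visual-success threshold in logMAR (default 0.3).
#' @return the data frame with the two outcome columns appended.
#' @export
classify_outcomes <- function(records, va_threshold = 0.3) {
  stopifnot(is.data.frame(records))
  for (col in c("closure", "post_va_logmar")) {
    if (!col %in% names(records)) {
      stop(sprintf("missing required column: %s", col), call. = FALSE)
    }
  }
  records$closure_success <- records$closure == "success"
  records$visual_success <- ifelse(records$closure_success,
                                   records$post_va_logmar <= va_threshold,
                                   NA)
  records
}

# Shapiro-Wilk normality gate for one group (constant or tiny samples are
# treated as non-normal so the dispatch falls back to the rank test)
shapiro_ok <- function(x, alpha = 0.05) {
  if (length(x) < 3L || length(x) > 5000L || sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value > alpha
}

# two-sample dispatch for one continuous variable
compare_continuous <- function(x1, x2, alpha = 0.05) {
  if (shapiro_ok(x1, alpha) && shapiro_ok(x2, alpha)) {
    tt <- t.test(x1, x2, var.equal = TRUE)
    return(list(test = "t-test", p_value = tt$p.value))
  }
  ties <- anyDuplicated(c(x1, x2)) > 0L
  exact <- min(length(x1), length(x2)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x1, x2, exact = exact, correct = !exact))
  list(test = if (exact) "Mann-Whitney (exact)" else
    "Mann-Whitney (normal approximation)", p_value = wt$p.value)
}

#' Per-variable two-group comparisons
#'
#' Dispatches the comparison for each variable between the two levels of
#' \code{grouping}: continuous variables are tested with Student's t-test
#' when both groups pass Shapiro-Wilk normality (alpha 0.05), otherwise with
#' the Mann-Whitney U test (exact when the smaller group has at most 8
#' observations and there are no ties, normal approximation with continuity
#' and tie correction otherwise); two-level categorical variables use
#' Fisher's exact test (two-sided). The test used is reported alongside
#' each p-value.
#'
#' @param records cohort data frame.
#' @param grouping name of a two-level grouping column (e.g.
#'   \code{"closure"}).
#' @param variables character vector of columns to compare.
#' @param alpha normality-gate level for the Shapiro-Wilk screen.
#' @return data frame with one row per variable: group summaries
#'   (mean and sd, or counts for categorical), the test name and p-value.
#' @export
group_tests <- function(records, grouping, variables, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  g <- records[[grouping]]
  if (is.null(g)) stop(sprintf("missing grouping column: %s", grouping), call. = FALSE)
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2L) {
    stop("grouping must have exactly two levels", call. = FALSE)
  }
  if (!all(table(g) > 0L)) stop("empty group", call. = FALSE)
  rows <- lapply(variables, function(v) {
    x <- records[[v]]
    if (is.null(x)) stop(sprintf("missing column: %s", v), call. = FALSE)
    x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
    if (length(x1) == 0L || length(x2) == 0L) stop("empty group", call. = FALSE)
    if (is.numeric(x)) {
      res <- compare_continuous(x1, x2, alpha)
      data.frame(variable = v,
                 group1 = lev[1], mean1 = mean(x1), sd1 = sd(x1),
                 group2 = lev[2], mean2 = mean(x2), sd2 = sd(x2),
                 test = res$test, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(as.character(x)), factor(as.character(g), levels = lev))
      if (nrow(tab) < 2L) {
        # single observed category: no association to test
        data.frame(variable = v, group1 = lev[1], mean1 = NA, sd1 = NA,
                   group2 = lev[2], mean2 = NA, sd2 = NA,
                   test = "Fisher exact", p_value = 1,
                   stringsAsFactors = FALSE)
      } else {
        ft <- fisher.test(tab)
        data.frame(variable = v, group1 = lev[1], mean1 = NA, sd1 = NA,
                   group2 = lev[2], mean2 = NA, sd2 = NA,
                   test = "Fisher exact", p_value = ft$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

#' Paired pre/post visual-acuity comparison
#'
#' Paired-sample t-test of preoperative versus postoperative logMAR acuity.
#'
#' @param records cohort data frame with \code{pre_va_logmar} and
#'   \code{post_va_logmar}.
#' @return list with means, mean difference and the paired-t p-value.
#' @export
paired_va_test <- function(records) {
  tt <- t.test(records$pre_va_logmar, records$post_va_logmar, paired = TRUE)
  list(pre_mean = mean(records$pre_va_logmar),
       post_mean = mean(records$post_va_logmar),
       mean_difference = unname(tt$estimate),
       p_value = tt$p.value, n = nrow(records))
}

#' Multiple linear regression for postoperative acuity
#'
#' Ordinary least squares of postoperative logMAR acuity on MHRI, MLD, age,
#' preoperative acuity and surgery type (combined phaco-vitrectomy coded 1),
#' fitted on eyes with successful anatomical closure only (visual analyses
#' exclude closure failures). Reports per-coefficient 95\% confidence
#' intervals from the t distribution and, for each predictor, the variance
#' inflation factor (via \pkg{car}) with tolerance = 1/VIF.
#'
#' @param records cohort data frame.
#' @param predictors predictor columns (default \code{mhri}, \code{mld_um},
#'   \code{age_years}, \code{pre_va_logmar}, \code{surgery}).
#' @param response response column (default \code{post_va_logmar}).
#' @param closed_only restrict to \code{closure == "success"} rows
#'   (default TRUE).
#' @return object of class \code{octmhri_regression}: \code{coefficients}
#'   data frame (term, estimate, ci_low, ci_high, p_value, vif, tolerance),
#'   \code{r_squared}, \code{n} and the underlying \code{lm} fit.
#' @export
fit_postva_regression <- function(records,
                                  predictors = c("mhri", "mld_um",
                                                 "age_years",
                                                 "pre_va_logmar", "surgery"),
                                  response = "post_va_logmar",
                                  closed_only = TRUE) {
  stopifnot(is.data.frame(records))
  if (closed_only && "closure" %in% names(records)) {
    records <- records[records$closure == "success", , drop = FALSE]
  }
  missing <- setdiff(c(predictors, response), names(records))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df <- records[, c(response, predictors), drop = FALSE]
  if ("surgery" %in% predictors) {
    df$surgery <- as.numeric(df$surgery == "vitx_pe")
  }
  for (p in predictors) {
    if (!is.numeric(df[[p]])) df[[p]] <- as.numeric(factor(df[[p]])) - 1
  }
  if (nrow(df) <= length(predictors) + 1L) {
    stop("too few rows to fit the regression", call. = FALSE)
  }
  X <- as.matrix(cbind(1, df[, predictors, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = df)
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  vifs <- if (length(predictors) >= 2L) car::vif(fit) else
    setNames(1, predictors)
  terms <- predictors
  coefs <- data.frame(
    term = terms,
    estimate = unname(coef(fit)[terms]),
    ci_low = unname(ci[terms, 1]),
    ci_high = unname(ci[terms, 2]),
    p_value = unname(sm$coefficients[terms, 4]),
    vif = unname(vifs[terms]),
    stringsAsFactors = FALSE
  )
  coefs$tolerance <- 1 / coefs$vif
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 n = nrow(df), fit = fit),
            class = "octmhri_regression")
}

#' @export
print.octmhri_regression <- function(x, ...) {
  cat(sprintf("postoperative-VA regression (n = %d, R^2 = %.3f):\n",
              x$n, x$r_squared))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}
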