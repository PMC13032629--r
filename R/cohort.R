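#' Configuration for a synthetic macular-hole cohort
#'
#' Defaults reproduce the statistical structure of a 48-eye full-thickness
#' macular hole case series: 3/48 closure failures; group-conditional
#' Gaussian MHRI (success 1.42 +/- 0.16, failure 2.24 +/- 0.69) and MLD
#' (success 300.4 +/- 71.8 um, failure 433.3 +/- 21.3 um) with an MHRI-MLD
#' correlation of 0.45; postoperative logMAR acuity generated linearly from
#' MHRI, MLD and preoperative acuity. The visual-acuity coefficients are
#' calibration choices (chosen so that group mean postoperative acuities and
#' correlation signs land near the observed cohort), not observed quantities.
#'
#' @param n_eyes number of eyes.
#' @param closure_failure_prob probability of anatomical closure failure.
#' @param mhri_success,mhri_failure,mld_success,mld_failure length-2
#'   \code{c(mean, sd)} vectors of the group-conditional Gaussians.
#' @param mhri_mld_corr within-group MHRI-MLD correlation.
#' @param cri_max_success,cri_max_failure \code{c(mean, sd)} for CRI-Max;
#'   the remaining indices are derived (PCRI-Min = CRI-Max / MHRI exactly,
#'   preserving the index identity; CRI-Mean slightly below CRI-Max,
#'   PCRI-Mean slightly above PCRI-Min).
#' @param va_intercept,beta_mhri,beta_mld,beta_preva,va_residual_sd linear
#'   model for postoperative logMAR acuity (floored at 0).
#' @param preva_mean,preva_sd preoperative logMAR acuity distribution
#'   (floored at 0).
#' @param age_mean,age_sd age distribution, years.
#' @param female_prob,pseudophakia_prob,vitx_pe_prob Bernoulli probabilities
#'   for sex, lens status and combined phaco-vitrectomy.
#' @param rater_noise_sd between-rater measurement noise on MHRI.
#' @param seed integer RNG seed (NULL = use the current RNG state).
#' @return object of class \code{octmhri_cohort_config}.
#' @export
cohort_config <- function(n_eyes = 48L, closure_failure_prob = 3 / 48,
                          mhri_success = c(1.42, 0.16),
                          mhri_failure = c(2.24, 0.69),
                          mld_success = c(300.4, 71.8),
                          mld_failure = c(433.3, 21.3),
                          mhri_mld_corr = 0.45,
                          cri_max_success = c(1.06, 0.10),
                          cri_max_failure = c(1.14, 0.18),
                          va_intercept = -1.61, beta_mhri = 0.581,
                          beta_mld = 0.003, beta_preva = 0.2,
                          va_residual_sd = 0.15,
                          preva_mean = 0.9, preva_sd = 0.3,
                          age_mean = 67.8, age_sd = 7.7,
                          female_prob = 29 / 48,
                          pseudophakia_prob = 10 / 48,
                          vitx_pe_prob = 28 / 48,
                          rater_noise_sd = 0.04, seed = NULL) {
  check_that(is.numeric(n_eyes) && n_eyes >= 0 && n_eyes == round(n_eyes),
             "n_eyes", "must be a non-negative integer")
  check_that(is_prob(closure_failure_prob), "closure_failure_prob",
             "must be a probability in [0, 1]")
  for (f in c("mhri_success", "mhri_failure", "mld_success", "mld_failure",
              "cri_max_success", "cri_max_failure")) {
    v <- get(f)
    check_that(is.numeric(v) && length(v) == 2 && v[1] > 0 && v[2] >= 0,
               f, "must be c(mean > 0, sd >= 0)")
  }
  check_that(is.numeric(mhri_mld_corr) && abs(mhri_mld_corr) < 1,
             "mhri_mld_corr", "must be in (-1, 1)")
  check_that(is.numeric(va_residual_sd) && va_residual_sd >= 0,
             "va_residual_sd", "must be >= 0")
  check_that(is.numeric(rater_noise_sd) && rater_noise_sd >= 0,
             "rater_noise_sd", "must be >= 0")
  for (f in c("female_prob", "pseudophakia_prob", "vitx_pe_prob")) {
    check_that(is_prob(get(f)), f, "must be a probability in [0, 1]")
  }
  fields <- names(formals(cohort_config))
  structure(mget(fields, envir = environment()),
            class = "octmhri_cohort_config")
}

# draw n correlated positive (mhri, mld) pairs for one closure group,
# resampling the rare non-positive draws (truncation to > 0)
draw_group_indices <- function(n, mhri_ms, mld_ms, rho) {
  if (n == 0L) {
    return(data.frame(mhri = numeric(0), mld_um = numeric(0)))
  }
  mhri <- numeric(n); mld <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    z1 <- rnorm(length(todo))
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(length(todo))
    m1 <- mhri_ms[1] + mhri_ms[2] * z1
    m2 <- mld_ms[1] + mld_ms[2] * z2
    ok <- m1 > 0 & m2 > 0
    mhri[todo[ok]] <- m1[ok]
    mld[todo[ok]] <- m2[ok]
    todo <- todo[!ok]
  }
  data.frame(mhri = mhri, mld_um = mld)
}

#' Simulate a macular-hole surgical cohort
#'
#' Draws one eye per row: anatomical closure (Bernoulli), group-conditional
#' correlated (MHRI, MLD) truncated to positive values, the remaining
#' reflectivity indices consistent with the MHRI identity
#' (PCRI-Min = CRI-Max / MHRI), demographics, pre- and postoperative logMAR
#' acuity from the configured linear model (floored at 0), and two
#' per-rater MHRI readings (true value plus independent Gaussian rater
#' noise, kept positive).
#'
#' @param config a [cohort_config()].
#' @return a \code{data.frame} of class \code{octmhri_cohort} with one
#'   \code{EyeRecord} per row: \code{eye_id}, \code{age_years}, \code{sex},
#'   \code{pre_va_logmar}, \code{post_va_logmar}, \code{mld_um},
#'   \code{surgery}, \code{pseudophakic}, \code{closure}, the five index
#'   columns and \code{rater1_mhri}, \code{rater2_mhri}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "octmhri_cohort_config")) {
    stop("`config` must come from cohort_config()", call. = FALSE)
  }
  n <- as.integer(config$n_eyes)
  with_seed(config$seed, {
    closure <- ifelse(rbinom(n, 1L, config$closure_failure_prob) == 1L,
                      "failure", "success")
    idx <- data.frame(mhri = numeric(n), mld_um = numeric(n))
    for (grp in c("success", "failure")) {
      sel <- closure == grp
      g <- draw_group_indices(sum(sel),
                              if (grp == "success") config$mhri_success else config$mhri_failure,
                              if (grp == "success") config$mld_success else config$mld_failure,
                              config$mhri_mld_corr)
      idx[sel, ] <- g
    }
    cri_ms <- ifelse(closure == "success", config$cri_max_success[1],
                     config$cri_max_failure[1])
    cri_sd <- ifelse(closure == "success", config$cri_max_success[2],
                     config$cri_max_failure[2])
    cri_max <- pmax(0.2, rnorm(n, cri_ms, cri_sd))
    pcri_min <- cri_max / idx$mhri                 # index identity, exact
    cri_mean <- pmax(0.1, cri_max - abs(rnorm(n, 0.08, 0.03)))
    pcri_mean <- pcri_min + abs(rnorm(n, 0.06, 0.02))

    age <- rnorm(n, config$age_mean, config$age_sd)
    sex <- ifelse(runif(n) < config$female_prob, "female", "male")
    pseudophakic <- runif(n) < config$pseudophakia_prob
    surgery <- ifelse(runif(n) < config$vitx_pe_prob, "vitx_pe", "vitx")
    pre_va <- pmax(0, rnorm(n, config$preva_mean, config$preva_sd))
    post_va <- pmax(0, config$va_intercept +
                      config$beta_mhri * idx$mhri +
                      config$beta_mld * idx$mld_um +
                      config$beta_preva * pre_va +
                      rnorm(n, 0, config$va_residual_sd))
    rater1 <- pmax(1e-6, idx$mhri + rnorm(n, 0, config$rater_noise_sd))
    rater2 <- pmax(1e-6, idx$mhri + rnorm(n, 0, config$rater_noise_sd))

    out <- data.frame(
      eye_id = sprintf("eye%03d", seq_len(n)),
      age_years = age, sex = sex,
      pre_va_logmar = pre_va, post_va_logmar = post_va,
      mld_um = idx$mld_um, surgery = surgery, pseudophakic = pseudophakic,
      closure = closure,
      cri_max = cri_max, cri_mean = cri_mean,
      pcri_min = pcri_min, pcri_mean = pcri_mean, mhri = idx$mhri,
      rater1_mhri = rater1, rater2_mhri = rater2,
      stringsAsFactors = FALSE
    )
    class(out) <- c("octmhri_cohort", "data.frame")
    out
  })
}

#' Convert Snellen acuity to logMAR
#'
#' \code{logMAR = log10(denominator / numerator)} for the standard 20-foot
#' notation, so 20/20 maps to 0.0 and 20/200 to 1.0.
#'
#' @param snellen either a character vector like \code{"20/40"} or a numeric
#'   numerator (with \code{denominator} supplied).
#' @param denominator Snellen denominator when \code{snellen} is numeric.
#' @return numeric logMAR values.
#' @export
snellen_to_logmar <- function(snellen, denominator = NULL) {
  if (is.character(snellen)) {
    parts <- strsplit(snellen, "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("Snellen strings must look like \"20/40\"", call. = FALSE)
    num <- as.numeric(vapply(parts, `[`, "", 1L))
    den <- as.numeric(vapply(parts, `[`, "", 2L))
  } else {
    num <- as.numeric(snellen)
    den <- as.numeric(denominator)
    if (length(den) == 0L) stop("`denominator` required for numeric input", call. = FALSE)
  }
  if (any(!is.finite(num)) || any(!is.finite(den)) || any(num <= 0) || any(den <= 0)) {
    stop("Snellen numerator and denominator must be positive", call. = FALSE)
  }
  log10(den / num)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort an \code{octmhri_cohort} data frame.
#' @param path CSV path.
#' @return \code{read_cohort} returns the cohort with columns checked.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

cohort_columns <- c("eye_id", "age_years", "sex", "pre_va_logmar",
                    "post_va_logmar", "mld_um", "surgery", "pseudophakic",
                    "closure", "cri_max", "cri_mean", "pcri_min",
                    "pcri_mean", "mhri", "rater1_mhri", "rater2_mhri")

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("cohort CSV is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("octmhri_cohort", "data.frame")
  df
}
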