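#' Full prognostic analysis of a cohort
#'
#' Runs the complete study analogue on one cohort table: outcome labelling,
#' group comparison table, paired pre/post acuity test, Spearman
#' correlations of the indices with postoperative acuity (closure failures
#' excluded from all visual analyses), the adjusted postoperative-VA
#' regression with collinearity diagnostics, ROC analyses for anatomical
#' closure (all eyes) and for visual success (closed eyes only) with
#' Youden-index cutoffs, and the inter-rater agreement summary (ICC(2,1)
#' plus Bland-Altman).
#'
#' Anatomical ROCs use every eye; when a cohort has a single closure class
#' the anatomical ROC is skipped with an explicit notice rather than an
#' error. The visual-success denominator never includes closure failures.
#'
#' @param cohort an \code{octmhri_cohort} data frame (see
#'   [generate_cohort()] / [read_cohort()]).
#' @param seed integer seed for the bootstrap confidence intervals.
#' @param boot_n bootstrap replicates for ROC confidence intervals.
#' @param va_threshold visual-success threshold, logMAR (default 0.3).
#' @return object of class \code{octmhri_analysis}: a list with
#'   \code{counts}, \code{group_table}, \code{paired_va},
#'   \code{correlations}, \code{regression}, \code{roc_anatomical},
#'   \code{roc_visual}, \code{agreement}, \code{notices} and \code{seed}.
#' @export
analyze_cohort <- function(cohort, seed = NULL, boot_n = 2000L,
                           va_threshold = 0.3) {
  stopifnot(is.data.frame(cohort))
  required <- c("age_years", "sex", "pre_va_logmar", "post_va_logmar",
                "mld_um", "surgery", "pseudophakic", "closure",
                "cri_max", "cri_mean", "pcri_min", "pcri_mean", "mhri",
                "rater1_mhri", "rater2_mhri")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    notices <- character(0)
    rec <- classify_outcomes(cohort, va_threshold = va_threshold)
    closed <- rec[rec$closure_success, , drop = FALSE]
    counts <- list(
      n = nrow(rec),
      n_success = sum(rec$closure_success),
      n_failure = sum(!rec$closure_success),
      closure_rate = mean(rec$closure_success),
      n_visual_eligible = nrow(closed),
      n_visual_success = sum(closed$visual_success),
      visual_success_rate = if (nrow(closed) > 0)
        mean(closed$visual_success) else NA_real_,
      n_female = sum(rec$sex == "female"),
      female_rate = mean(rec$sex == "female")
    )

    both_closure_classes <- counts$n_success > 0 && counts$n_failure > 0
    group_table <- NULL
    if (both_closure_classes) {
      rec$sex_f <- factor(rec$sex)
      rec$pseudophakic_f <- factor(rec$pseudophakic)
      rec$surgery_f <- factor(rec$surgery)
      group_table <- group_tests(
        rec, "closure",
        variables = c("age_years", "sex_f", "pre_va_logmar",
                      "pseudophakic_f", "mld_um", "surgery_f",
                      "cri_max", "cri_mean", "pcri_min", "pcri_mean",
                      "mhri", "post_va_logmar"))
    } else {
      notices <- c(notices,
                   "group comparisons skipped: only one closure class present")
    }

    paired_va <- paired_va_test(rec)

    corr_vars <- c("cri_max", "cri_mean", "pcri_min", "pcri_mean", "mhri",
                   "mld_um")
    correlations <- do.call(rbind, lapply(corr_vars, function(v) {
      sp <- spearman(closed[[v]], closed$post_va_logmar)
      data.frame(variable = v, rho = sp$rho, p_value = sp$p_value, n = sp$n,
                 stringsAsFactors = FALSE)
    }))

    regression <- fit_postva_regression(rec)

    roc_pair <- function(data, labels) {
      list(mhri = roc_analysis(data$mhri, labels, positive = TRUE,
                               boot_n = boot_n),
           mld = roc_analysis(data$mld_um, labels, positive = TRUE,
                              boot_n = boot_n))
    }
    roc_anatomical <- NULL
    if (both_closure_classes) {
      roc_anatomical <- roc_pair(rec, rec$closure_success)
    } else {
      notices <- c(notices,
                   "anatomical ROC skipped: only one closure class present")
    }
    roc_visual <- NULL
    if (nrow(closed) > 0 && length(unique(closed$visual_success)) == 2L) {
      roc_visual <- roc_pair(closed, closed$visual_success)
    } else {
      notices <- c(notices,
                   "visual ROC skipped: visual-success labels are single-class")
    }

    agreement <- agreement_analysis(rec$rater1_mhri, rec$rater2_mhri)

    structure(list(counts = counts, group_table = group_table,
                   paired_va = paired_va, correlations = correlations,
                   regression = regression,
                   roc_anatomical = roc_anatomical, roc_visual = roc_visual,
                   agreement = agreement, notices = notices,
                   seed = seed, va_threshold = va_threshold),
              class = "octmhri_analysis")
  })
}

#' @export
print.octmhri_analysis <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("cohort analysis: %d eyes, %d closed (%.1f%%)\n",
              ct$n, ct$n_success, 100 * ct$closure_rate))
  if (!is.na(ct$visual_success_rate)) {
    cat(sprintf("  visual success (<= %.1f logMAR): %d of %d closed (%.1f%%)\n",
                x$va_threshold, ct$n_visual_success, ct$n_visual_eligible,
                100 * ct$visual_success_rate))
  }
  if (!is.null(x$roc_anatomical)) {
    cat(sprintf("  anatomical ROC, MHRI: AUC %.3f, cutoff %.2f (J = %.2f)\n",
                x$roc_anatomical$mhri$auc, x$roc_anatomical$mhri$cutoff,
                x$roc_anatomical$mhri$youden_j))
  }
  if (!is.null(x$roc_visual)) {
    cat(sprintf("  visual ROC, MHRI: AUC %.3f, cutoff %.2f (J = %.2f)\n",
                x$roc_visual$mhri$auc, x$roc_visual$mhri$cutoff,
                x$roc_visual$mhri$youden_j))
  }
  cat(sprintf("  inter-rater MHRI: ICC %.3f, Bland-Altman bias %.4g\n",
              x$agreement$icc_value, x$agreement$bias))
  for (msg in x$notices) cat("  note:", msg, "\n")
  invisible(x)
}

roc_row <- function(name, r) {
  data.frame(parameter = name, auc = r$auc, ci_low = r$auc_ci_low,
             ci_high = r$auc_ci_high, cutoff = r$cutoff,
             youden_j = r$youden_j, sensitivity = r$sensitivity,
             specificity = r$specificity, direction = r$direction,
             p_value = r$p_value, stringsAsFactors = FALSE)
}

#' Simulate phantom B-scan images to disk
#'
#' Writes \code{n} phantoms (PNG plus JSON ground-truth sidecar) and a
#' manifest CSV listing ids and per-image seeds. Phantom MLDs are drawn
#' uniformly over \code{mld_range_um}; per-image seeds are
#' \code{seed, seed + 1, ...} so reruns are byte-identical.
#'
#' @param n number of phantoms (0 gives an empty manifest).
#' @param outdir writable output directory (created if needed).
#' @param config base [phantom_config()]; mld and seed are overridden
#'   per image.
#' @param seed base seed.
#' @param mld_range_um range of simulated hole diameters, micrometres.
#' @return invisibly, the manifest data frame.
#' @export
cmd_simulate_images <- function(n, outdir, config = phantom_config(),
                                seed = 1L, mld_range_um = c(200, 450)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("output directory is not writable", call. = FALSE)
  n <- as.integer(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer(seed + i - 1L)
    mld_i <- with_seed(seed_i,
                       round(runif(1, mld_range_um[1], mld_range_um[2])))
    cfg <- config
    cfg$mld_um <- mld_i
    cfg$seed <- seed_i
    cfg <- do.call(phantom_config, unclass(cfg))
    ph <- generate_bscan(cfg)
    id <- sprintf("phantom%03d", i)
    write_phantom(ph, file.path(outdir, paste0(id, ".png")))
    rows[[i]] <- data.frame(id = id, seed = seed_i, mld_um = ph$truth$mld_um,
                            mhri_true = ph$truth$true_index_set$mhri,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(id = character(0), seed = integer(0), mld_um = numeric(0),
               mhri_true = numeric(0))
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Simulate a cohort table to disk
#'
#' @param path output CSV path.
#' @param config a [cohort_config()].
#' @param seed RNG seed (overrides the config seed when given).
#' @return invisibly, the cohort data frame.
#' @export
cmd_simulate_cohort <- function(path, config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  write_cohort(cohort, path)
  invisible(cohort)
}

# parse one image's annotation rows into the four named segments
segments_from_annotations <- function(ann) {
  need <- c("central", "paracentral_left", "paracentral_right", "normal_rpe")
  segs <- lapply(need, function(rg) {
    row <- ann[ann$region == rg, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop(sprintf("annotation for region `%s` missing or duplicated", rg),
           call. = FALSE)
    }
    line_segment(c(row$row0, row$col0), c(row$row1, row$col1))
  })
  names(segs) <- need
  segs
}

#' Measure reflectivity indices for a set of images
#'
#' Measures each image either automatically ([auto_measure()]) or from
#' manual segment annotations (CSV with columns \code{image_id},
#' \code{region}, \code{row0}, \code{col0}, \code{row1}, \code{col1};
#' regions \code{central}, \code{paracentral_left},
#' \code{paracentral_right}, \code{normal_rpe}). Per-image failures are
#' logged as warnings and the run continues; if every image fails, the
#' call errors.
#'
#' @param image_paths character vector of PNG paths (phantom sidecars are
#'   used for the pixel scale when present).
#' @param out_csv output CSV path (one index row per image).
#' @param annotations optional annotation data frame or CSV path; when
#'   NULL, regions are located automatically.
#' @param lateral_scale_um fallback lateral scale when no sidecar exists.
#' @return invisibly, the indices data frame.
#' @export
cmd_measure <- function(image_paths, out_csv, annotations = NULL,
                        lateral_scale_um = 10) {
  if (is.character(annotations)) annotations <- read.csv(annotations)
  rows <- list()
  n_fail <- 0L
  for (path in image_paths) {
    id <- sub("\\.png$", "", basename(path))
    res <- tryCatch({
      json <- sub("\\.png$", ".json", path)
      if (file.exists(json)) {
        ph <- read_phantom(path, json)
        img <- ph$pixels
        scale <- ph$lateral_scale_um
      } else {
        img <- read_bscan(path)
        scale <- lateral_scale_um
      }
      if (is.null(annotations)) {
        am <- auto_measure(img, scale)
        idx <- am$indices
        mld <- am$mld_um
      } else {
        ann <- annotations[annotations$image_id == id, , drop = FALSE]
        if (nrow(ann) == 0L) stop("no annotation rows for this image")
        segs <- segments_from_annotations(ann)
        m <- measure_reflectivity(img, segs$central, segs$paracentral_left,
                                  segs$paracentral_right, segs$normal_rpe)
        idx <- compute_indices(m)
        mld <- measure_mld(img, scale)
      }
      cbind(data.frame(image_id = id, stringsAsFactors = FALSE),
            as.data.frame(idx), data.frame(mld_um = mld))
    }, error = function(e) {
      warning(sprintf("image %s skipped: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L && length(image_paths) > 0L) {
    stop("all images failed to measure", call. = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(image_id = character(0), cri_max = numeric(0),
               cri_mean = numeric(0), pcri_min = numeric(0),
               pcri_mean = numeric(0), mhri = numeric(0),
               mld_um = numeric(0))
  write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Analyze a cohort CSV and write the report bundle
#'
#' Reads the cohort, runs [analyze_cohort()] and writes the report tables
#' (group comparisons, correlations, regression, anatomical and visual ROC,
#' agreement) as CSVs plus a JSON summary. Every file records the seed; the
#' JSON also carries the counts and notices.
#'
#' @param cohort_csv input cohort CSV path.
#' @param outdir output directory.
#' @param seed RNG seed for the bootstrap CIs.
#' @param boot_n bootstrap replicates.
#' @return invisibly, the \code{octmhri_analysis} object.
#' @export
cmd_analyze <- function(cohort_csv, outdir, seed = 1L, boot_n = 2000L) {
  cohort <- read_cohort(cohort_csv)
  res <- analyze_cohort(cohort, seed = seed, boot_n = boot_n)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  wr(res$group_table, "group_comparisons.csv")
  wr(res$correlations, "correlations.csv")
  wr(res$regression$coefficients, "regression.csv")
  if (!is.null(res$roc_anatomical)) {
    wr(rbind(roc_row("mhri", res$roc_anatomical$mhri),
             roc_row("mld", res$roc_anatomical$mld)), "roc_anatomical.csv")
  }
  if (!is.null(res$roc_visual)) {
    wr(rbind(roc_row("mhri", res$roc_visual$mhri),
             roc_row("mld", res$roc_visual$mld)), "roc_visual.csv")
  }
  wr(data.frame(icc = res$agreement$icc_value,
                icc_model = res$agreement$icc_model_label,
                bias = res$agreement$bias,
                loa_low = res$agreement$loa_low,
                loa_high = res$agreement$loa_high), "agreement.csv")
  summary_json <- list(seed = seed, boot_n = boot_n,
                       va_threshold = res$va_threshold,
                       counts = res$counts, notices = res$notices)
  writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(outdir, "summary.json"))
  invisible(res)
}
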