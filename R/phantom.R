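#' Configuration for a macular-hole B-scan phantom
#'
#' Collects the geometry, target intensities and noise level of a synthetic
#' B-scan. Defaults emulate a typical SD-OCT scan (10 um/px lateral,
#' 4 um/px axial) of a medium-sized full-thickness macular hole whose
#' noise-free indices sit near the centre of the surgical-success group
#' (central 210 / paracentral 150 / RPE 200, i.e. MHRI = 1.40,
#' CRI-Max = 1.05, PCRI-Min = 0.75).
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param mld_um true minimum linear diameter of the hole, micrometres.
#' @param lateral_scale_um,axial_scale_um micrometres per pixel.
#' @param rpe_intensity brightness of the unaffected RPE band (0-255).
#' @param central_intensity brightness of the central hyperreflective region
#'   at the hole base (0-255).
#' @param paracentral_intensity brightness of the two flanking paracentral
#'   hyporeflective regions (0-255).
#' @param background_intensity vitreous/choroid background brightness (0-255).
#' @param inner_retina_intensity brightness of the neurosensory retina (0-255).
#' @param edge_elevation_px how far the hole edges lift off the RPE, pixels.
#' @param speckle_level multiplicative speckle scale: the per-pixel intensity
#'   is multiplied by a unit-mean Gamma variate with coefficient of variation
#'   \code{speckle_level}. 0 disables noise.
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   bit-identical phantoms.
#' @return an object of class \code{octmhri_phantom_config}.
#' @seealso [generate_bscan()]
#' @export
phantom_config <- function(image_height_px = 160L, image_width_px = 512L,
                           mld_um = 300, lateral_scale_um = 10,
                           axial_scale_um = 4,
                           rpe_intensity = 200, central_intensity = 210,
                           paracentral_intensity = 150,
                           background_intensity = 20,
                           inner_retina_intensity = 110,
                           edge_elevation_px = 12, speckle_level = 0,
                           seed = 1L) {
  check_that(is_count(image_height_px), "image_height_px", "must be a positive integer")
  check_that(is_count(image_width_px), "image_width_px", "must be a positive integer")
  check_that(is.numeric(mld_um) && length(mld_um) == 1 && mld_um > 0,
             "mld_um", "must be a positive number")
  check_that(is.numeric(lateral_scale_um) && lateral_scale_um > 0,
             "lateral_scale_um", "must be > 0")
  check_that(is.numeric(axial_scale_um) && axial_scale_um > 0,
             "axial_scale_um", "must be > 0")
  for (f in c("rpe_intensity", "central_intensity", "paracentral_intensity",
              "background_intensity", "inner_retina_intensity")) {
    check_that(is_intensity(get(f)), f, "must be an intensity in [0, 255]")
  }
  check_that(is.numeric(edge_elevation_px) && edge_elevation_px >= 0,
             "edge_elevation_px", "must be >= 0")
  check_that(is.numeric(speckle_level) && length(speckle_level) == 1 &&
               speckle_level >= 0, "speckle_level", "must be >= 0")
  check_that(mld_um < image_width_px * lateral_scale_um, "mld_um",
             "hole must be narrower than the image")
  check_that(is.numeric(seed) && length(seed) == 1 && seed == round(seed),
             "seed", "must be a single integer")
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    mld_um = mld_um, lateral_scale_um = lateral_scale_um,
    axial_scale_um = axial_scale_um,
    rpe_intensity = rpe_intensity, central_intensity = central_intensity,
    paracentral_intensity = paracentral_intensity,
    background_intensity = background_intensity,
    inner_retina_intensity = inner_retina_intensity,
    edge_elevation_px = edge_elevation_px, speckle_level = speckle_level,
    seed = as.integer(seed)
  ), class = "octmhri_phantom_config")
}

# programmed, noise-free index set implied by the configured intensities;
# regions are constant so the mean/min/max collapse to the programmed values
truth_index_set <- function(central, paracentral, rpe) {
  index_set(cri_max = central / rpe, cri_mean = central / rpe,
            pcri_min = paracentral / rpe, pcri_mean = paracentral / rpe,
            mhri = central / paracentral)
}

#' Generate a macular-hole B-scan phantom
#'
#' Renders a synthetic greyscale B-scan (rows = axial depth increasing
#' downward, columns = lateral position): a bright RPE band, a neurosensory
#' retina layer interrupted by the hole aperture, elevated slightly cystic
#' hole edges, and at the hole base a central hyperreflective region flanked
#' on either side by paracentral hyporeflective regions. An unaffected
#' ("normal RPE") reference stretch is annotated at least 1500 um from the
#' hole centre. Optional multiplicative Gamma speckle (unit mean, coefficient
#' of variation \code{speckle_level}) perturbs the noise-free intensities,
#' which are then rounded and clamped to 0-255. The ground truth (geometry,
#' programmed intensities, implied index set) is exact regardless of noise.
#'
#' All coordinates are 1-based \code{(row, col)}; column intervals are closed
#' \code{c(start, end)}.
#'
#' @param config a [phantom_config()].
#' @return an object of class \code{octmhri_phantom}: list with \code{pixels}
#'   (integer matrix), \code{lateral_scale_um}, \code{axial_scale_um},
#'   \code{truth} (see Details) and the generating \code{config}.
#' @details \code{truth} carries: \code{mld_um} (pixel-quantized true
#'   diameter), \code{inner_edge_cols} (first hole column, first tissue
#'   column right of the hole), \code{rpe_row_profile} (band centre row per
#'   column), the three disjoint region column intervals, the
#'   \code{normal_rpe_cols} reference interval, the programmed intensities
#'   and the implied \code{true_index_set}.
#' @export
generate_bscan <- function(config) {
  if (!inherits(config, "octmhri_phantom_config")) {
    config <- do.call(phantom_config, as.list(config))
  }
  H <- config$image_height_px
  W <- config$image_width_px
  mld_px <- max(4L, as.integer(round(config$mld_um / config$lateral_scale_um)))
  check_that(mld_px < W - 2L, "mld_um", "hole must be narrower than the image")

  rpe_row <- as.integer(round(0.65 * H))
  band_hw <- 2L                      # RPE band half-thickness (5 rows total)
  ir_thick <- max(8L, as.integer(round(0.2 * H)))  # neurosensory retina
  centre <- as.integer(W %/% 2L)

  cl <- centre - mld_px %/% 2L       # first column of the hole aperture
  cr <- cl + mld_px                  # first tissue column right of the hole
  check_that(cl > 2L && cr <= W - 1L, "mld_um", "hole does not fit laterally")

  # hole-base split: central hyperreflective region in the middle (~40% of
  # the base), paracentral hyporeflective regions filling the flanks
  base_cols <- cl:(cr - 1L)
  cw <- max(2L, as.integer(round(0.4 * mld_px)))
  ccs <- centre - cw %/% 2L
  cce <- ccs + cw - 1L
  check_that(ccs - cl >= 2L && (cr - 1L) - cce >= 2L, "mld_um",
             "hole too narrow to carve central and paracentral regions")
  central_cols <- c(ccs, cce)
  para_left <- c(cl, ccs - 1L)
  para_right <- c(cce + 1L, cr - 1L)

  # normal-RPE reference: >= 1500 um from the hole centre, 200 um long,
  # on whichever side has more room (ties -> temporal/right)
  offset_px <- as.integer(ceiling(1500 / config$lateral_scale_um))
  ref_len <- max(2L, as.integer(round(200 / config$lateral_scale_um)))
  room_right <- W - (centre + offset_px)
  room_left <- centre - offset_px
  if (room_right >= ref_len) {
    normal_cols <- c(centre + offset_px, centre + offset_px + ref_len - 1L)
  } else if (room_left >= ref_len) {
    normal_cols <- c(centre - offset_px - ref_len + 1L, centre - offset_px)
  } else {
    stop("image too narrow to place the normal-RPE reference >= 1500 um from the hole centre",
         call. = FALSE)
  }

  img <- matrix(config$background_intensity, nrow = H, ncol = W)

  # neurosensory retina above the band, interrupted by the hole aperture,
  # lifted (and rendered slightly darker, as cystic tissue) near the edges
  ir_bottom <- rpe_row - band_hw - 1L
  ir_top <- ir_bottom - ir_thick + 1L
  edge_w <- max(2L, as.integer(round(0.25 * mld_px)))
  for (col in seq_len(W)) {
    if (col >= cl && col < cr) next  # hole aperture: no inner retina
    lift <- 0L
    cystic <- FALSE
    if (col < cl && col >= cl - edge_w) {
      lift <- as.integer(round(config$edge_elevation_px * (1 - (cl - 1L - col) / edge_w)))
      cystic <- TRUE
    } else if (col >= cr && col < cr + edge_w) {
      lift <- as.integer(round(config$edge_elevation_px * (1 - (col - cr) / edge_w)))
      cystic <- TRUE
    }
    rows <- (ir_top - lift):(ir_bottom - lift)
    rows <- rows[rows >= 1L & rows <= H]
    val <- if (cystic) 0.7 * config$inner_retina_intensity else config$inner_retina_intensity
    img[rows, col] <- val
  }

  # RPE/Bruch band: programmed region intensities across the full band
  # thickness so that interior band pixels are pure region values
  band_rows <- (rpe_row - band_hw):(rpe_row + band_hw)
  img[band_rows, ] <- config$rpe_intensity
  img[band_rows, para_left[1]:para_left[2]] <- config$paracentral_intensity
  img[band_rows, para_right[1]:para_right[2]] <- config$paracentral_intensity
  img[band_rows, central_cols[1]:central_cols[2]] <- config$central_intensity

  if (config$speckle_level > 0) {
    s2 <- config$speckle_level^2
    img <- with_seed(config$seed,
                     img * matrix(rgamma(H * W, shape = 1 / s2, rate = 1 / s2),
                                  nrow = H))
  }
  pixels <- matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow = H)

  truth <- structure(list(
    mld_um = mld_px * config$lateral_scale_um,
    inner_edge_cols = c(cl, cr),
    rpe_row_profile = rep(rpe_row, W),
    central_region_cols = central_cols,
    paracentral_region_cols_left = para_left,
    paracentral_region_cols_right = para_right,
    normal_rpe_cols = normal_cols,
    true_max_central = config$central_intensity,
    true_min_paracentral = config$paracentral_intensity,
    true_normal_rpe = config$rpe_intensity,
    true_index_set = truth_index_set(config$central_intensity,
                                     config$paracentral_intensity,
                                     config$rpe_intensity)
  ), class = "octmhri_truth")

  structure(list(pixels = pixels,
                 lateral_scale_um = config$lateral_scale_um,
                 axial_scale_um = config$axial_scale_um,
                 truth = truth, config = config),
            class = "octmhri_phantom")
}

#' Measurement line segments from phantom ground truth
#'
#' Converts the annotated region intervals of a phantom's ground truth into
#' the four straight-line measurement segments of the reflectometry protocol
#' (central, paracentral left/right, normal RPE), each lying along the RPE
#' band within its region interval.
#'
#' @param truth the \code{truth} element of an [generate_bscan()] phantom.
#' @return named list of [line_segment()]s: \code{central},
#'   \code{paracentral_left}, \code{paracentral_right}, \code{normal_rpe}.
#' @export
annotate_segments <- function(truth) {
  if (!inherits(truth, "octmhri_truth")) {
    stop("`truth` must be the truth element of an octmhri phantom", call. = FALSE)
  }
  seg_from_interval <- function(iv, name) {
    if (length(iv) != 2L || iv[2] < iv[1] + 1L) {
      stop(sprintf("region `%s` is empty or too short for a line profile", name),
           call. = FALSE)
    }
    rows <- truth$rpe_row_profile
    line_segment(start = c(rows[iv[1]], iv[1]), stop = c(rows[iv[2]], iv[2]))
  }
  list(central = seg_from_interval(truth$central_region_cols, "central"),
       paracentral_left = seg_from_interval(truth$paracentral_region_cols_left,
                                            "paracentral_left"),
       paracentral_right = seg_from_interval(truth$paracentral_region_cols_right,
                                             "paracentral_right"),
       normal_rpe = seg_from_interval(truth$normal_rpe_cols, "normal_rpe"))
}

#' Write / read a phantom as PNG plus JSON sidecar
#'
#' The image is stored as an 8-bit single-channel PNG; the ground truth,
#' pixel scales and generating configuration go to a JSON sidecar so that
#' reading reverses writing exactly.
#'
#' @param phantom an [generate_bscan()] phantom.
#' @param png_path output PNG path; the sidecar replaces the extension with
#'   \code{.json} unless \code{json_path} is given.
#' @param json_path optional explicit sidecar path.
#' @return \code{write_phantom}: invisibly, the two paths;
#'   \code{read_phantom}: the reconstructed \code{octmhri_phantom}.
#' @export
write_phantom <- function(phantom, png_path, json_path = NULL) {
  stopifnot(inherits(phantom, "octmhri_phantom"))
  if (is.null(json_path)) json_path <- sub("\\.png$", ".json", png_path)
  png::writePNG(phantom$pixels / 255, target = png_path)
  side <- list(lateral_scale_um = phantom$lateral_scale_um,
               axial_scale_um = phantom$axial_scale_um,
               truth = unclass(phantom$truth),
               config = unclass(phantom$config))
  side$truth$true_index_set <- unclass(side$truth$true_index_set)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA), json_path)
  invisible(c(png = png_path, json = json_path))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(png_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.png$", ".json", png_path)
  raw <- png::readPNG(png_path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  pixels <- matrix(as.integer(round(raw * 255)), nrow = nrow(raw))
  side <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  truth <- side$truth
  truth$true_index_set <- do.call(index_set, as.list(truth$true_index_set))
  class(truth) <- "octmhri_truth"
  config <- do.call(phantom_config, side$config)
  structure(list(pixels = pixels,
                 lateral_scale_um = side$lateral_scale_um,
                 axial_scale_um = side$axial_scale_um,
                 truth = truth, config = config),
            class = "octmhri_phantom")
}

#' @export
print.octmhri_phantom <- function(x, ...) {
  cat(sprintf("B-scan phantom: %d x %d px (%.1f um/px lateral, %.1f um/px axial)\n",
              nrow(x$pixels), ncol(x$pixels), x$lateral_scale_um, x$axial_scale_um))
  cat(sprintf("  true MLD %.0f um; speckle level %.3g; seed %d\n",
              x$truth$mld_um, x$config$speckle_level, x$config$seed))
  cat(sprintf("  true MHRI %.3f (central %d / paracentral %d / RPE %d)\n",
              x$truth$true_index_set$mhri, x$truth$true_max_central,
              x$truth$true_min_paracentral, x$truth$true_normal_rpe))
  invisible(x)
}
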