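#' Straight-line measurement segment
#'
#' A straight line between two pixel coordinates, the unit of the brightness
#' profiling protocol. Coordinates are 1-based \code{(row, col)} with rows
#' increasing downward (deeper axially).
#'
#' @param start,stop numeric length-2 \code{(row, col)} endpoints; must differ.
#' @param width_px sampling width perpendicular to the line (default 1);
#'   for \code{width_px > 1} intensities are averaged across perpendicular
#'   offsets before the min/mean/max are taken.
#' @return an object of class \code{octmhri_segment}.
#' @export
line_segment <- function(start, stop, width_px = 1L) {
  check_that(is.numeric(start) && length(start) == 2 && all(is.finite(start)),
             "start", "must be a finite (row, col) pair")
  check_that(is.numeric(stop) && length(stop) == 2 && all(is.finite(stop)),
             "stop", "must be a finite (row, col) pair")
  start <- round(start); stop <- round(stop)
  check_that(any(start != stop), "stop", "segment must have nonzero length")
  check_that(is_count(width_px), "width_px", "must be a positive integer")
  structure(list(start = as.integer(start), stop = as.integer(stop),
                 width_px = as.integer(width_px)),
            class = "octmhri_segment")
}

#' Convert a raster image to 8-bit greyscale
#'
#' Single-channel input is rounded and clamped to 0-255 (already-integer
#' 8-bit matrices pass through unchanged). Three-channel input is reduced by
#' a weighted channel sum (default ITU-R BT.601 luma weights, the standard
#' RGB-to-8-bit conversion of image-analysis software), rounded half-to-even
#' and clamped.
#'
#' @param image a numeric matrix (single channel, intensities 0-255) or an
#'   H x W x 3 array.
#' @param channel_weights length-3 RGB weights; need not sum to 1.
#' @return integer matrix with values in 0-255.
#' @export
to_greyscale8 <- function(image, channel_weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) {
    out <- round(image)
    out[out < 0] <- 0
    out[out > 255] <- 255
    storage.mode(out) <- "integer"
    return(out)
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    nch <- dim(image)[3]
    if (nch == 1L) return(to_greyscale8(matrix(image[, , 1L], dim(image)[1])))
    if (nch != 3L) {
      stop(sprintf("unsupported channel count: %d (expected 1 or 3)", nch),
           call. = FALSE)
    }
    check_that(is.numeric(channel_weights) && length(channel_weights) == 3,
               "channel_weights", "must be a length-3 numeric vector")
    grey <- image[, , 1L] * channel_weights[1] +
      image[, , 2L] * channel_weights[2] +
      image[, , 3L] * channel_weights[3]
    return(to_greyscale8(matrix(grey, dim(image)[1])))
  }
  stop("`image` must be a matrix or an H x W x 3 array", call. = FALSE)
}

#' Read a B-scan raster from PNG or TIFF
#'
#' Reads the file, rescales to 0-255 and converts to 8-bit greyscale with
#' [to_greyscale8()]. TIFF support requires the \pkg{tiff} package.
#'
#' @param path image path ending in .png, .tif or .tiff.
#' @inheritParams to_greyscale8
#' @return integer matrix with values in 0-255.
#' @export
read_bscan <- function(path, channel_weights = c(0.299, 0.587, 0.114)) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the `tiff` package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) raw <- raw[, , 1:3]  # drop alpha
  to_greyscale8(raw * 255, channel_weights = channel_weights)
}

# integer line rasterization (Bresenham); returns an n x 2 matrix of (row, col)
bresenham_points <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  pts <- matrix(0L, nrow = n, ncol = 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    pts[i, ] <- c(r, c)
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pts
}

#' Brightness statistics along a straight line
#'
#' Rasterizes the segment (Bresenham, width 1 by default) and returns the
#' minimum, mean and maximum of the sampled intensities — the three numbers
#' the straight-line profiling protocol records per region. For
#' \code{width_px > 1}, intensities are first averaged across integer
#' perpendicular offsets at each sample.
#'
#' @param image integer/numeric matrix of intensities.
#' @param segment a [line_segment()]; endpoints must lie inside the image
#'   (including all perpendicular offsets when \code{width_px > 1}).
#' @return object of class \code{octmhri_profile}: list with
#'   \code{min_brightness}, \code{mean_brightness}, \code{max_brightness},
#'   \code{n_samples}.
#' @export
profile_stats <- function(image, segment) {
  stopifnot(is.matrix(image))
  if (!inherits(segment, "octmhri_segment")) {
    stop("`segment` must be a line_segment()", call. = FALSE)
  }
  st <- segment$start; sp <- segment$stop
  H <- nrow(image); W <- ncol(image)
  inside <- function(p) p[1] >= 1 && p[1] <= H && p[2] >= 1 && p[2] <= W
  if (!inside(st) || !inside(sp)) {
    stop("segment endpoints lie outside the image", call. = FALSE)
  }
  pts <- bresenham_points(st[1], st[2], sp[1], sp[2])
  w <- segment$width_px
  if (w > 1L) {
    d <- c(sp[1] - st[1], sp[2] - st[2])
    perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
    offsets <- seq_len(w) - 1 - (w - 1) / 2
    vals <- vapply(seq_len(nrow(pts)), function(i) {
      sub <- vapply(offsets, function(k) {
        p <- round(pts[i, ] + k * perp)
        if (!inside(p)) {
          stop("segment width extends outside the image", call. = FALSE)
        }
        image[p[1], p[2]]
      }, numeric(1))
      mean(sub)
    }, numeric(1))
  } else {
    vals <- image[cbind(pts[, 1], pts[, 2])]
  }
  if (length(vals) < 2L) {
    stop("segment samples fewer than 2 pixels", call. = FALSE)
  }
  structure(list(min_brightness = min(vals),
                 mean_brightness = mean(vals),
                 max_brightness = max(vals),
                 n_samples = length(vals)),
            class = "octmhri_profile")
}

#' Measure the four region profiles of one B-scan
#'
#' Applies [profile_stats()] to the central hyperreflective segment, the two
#' paracentral hyporeflective segments and the normal-RPE reference segment.
#' No aggregation across the two sides is done at this stage.
#'
#' @param image intensity matrix.
#' @param central_seg,left_seg,right_seg,rpe_seg [line_segment()]s.
#' @return object of class \code{octmhri_measurement}: named list of four
#'   \code{octmhri_profile}s (\code{central}, \code{paracentral_left},
#'   \code{paracentral_right}, \code{normal_rpe}).
#' @export
measure_reflectivity <- function(image, central_seg, left_seg, right_seg,
                                 rpe_seg) {
  out <- list(central = profile_stats(image, central_seg),
              paracentral_left = profile_stats(image, left_seg),
              paracentral_right = profile_stats(image, right_seg),
              normal_rpe = profile_stats(image, rpe_seg))
  if (out$normal_rpe$mean_brightness <= 0) {
    stop("normal-RPE reference has non-positive mean brightness", call. = FALSE)
  }
  structure(out, class = "octmhri_measurement")
}

#' Construct a reflectivity index set
#'
#' The five dimensionless indices derived from one measurement: CRI-Max,
#' CRI-Mean (central max/mean over normal-RPE mean), PCRI-Min, PCRI-Mean
#' (paracentral min/mean over normal-RPE mean) and MHRI, the macular hole
#' reflectivity index (maximum central brightness / minimum paracentral
#' brightness).
#'
#' @param cri_max,cri_mean,pcri_min,pcri_mean,mhri positive finite ratios.
#' @return object of class \code{octmhri_indices}.
#' @export
index_set <- function(cri_max, cri_mean, pcri_min, pcri_mean, mhri) {
  vals <- c(cri_max = cri_max, cri_mean = cri_mean, pcri_min = pcri_min,
            pcri_mean = pcri_mean, mhri = mhri)
  check_that(all(is.finite(vals)) && all(vals > 0), "index_set",
             "all five indices must be finite and positive")
  structure(as.list(vals), class = "octmhri_indices")
}

#' Compute the five reflectivity indices from a measurement
#'
#' Aggregation across the two paracentral sides follows the conservative
#' convention: the minimum over both sides for the min statistic and the
#' arithmetic mean of the two side means for the mean statistic; a single
#' side can be selected instead via \code{side}.
#'
#' \deqn{CRI_{max} = \frac{\max central}{\overline{RPE}},\quad
#'       PCRI_{min} = \frac{\min paracentral}{\overline{RPE}},\quad
#'       MHRI = \frac{\max central}{\min paracentral}}
#'
#' @param m an \code{octmhri_measurement} from [measure_reflectivity()].
#' @param side paracentral aggregation: \code{"both"} (default),
#'   \code{"left"} or \code{"right"}.
#' @return an [index_set()].
#' @export
compute_indices <- function(m, side = c("both", "left", "right")) {
  if (!inherits(m, "octmhri_measurement")) {
    stop("`m` must come from measure_reflectivity()", call. = FALSE)
  }
  side <- match.arg(side)
  rpe <- m$normal_rpe$mean_brightness
  if (rpe <= 0) stop("normal-RPE mean brightness must be > 0", call. = FALSE)
  para_min <- switch(side,
    both = min(m$paracentral_left$min_brightness,
               m$paracentral_right$min_brightness),
    left = m$paracentral_left$min_brightness,
    right = m$paracentral_right$min_brightness)
  para_mean <- switch(side,
    both = mean(c(m$paracentral_left$mean_brightness,
                  m$paracentral_right$mean_brightness)),
    left = m$paracentral_left$mean_brightness,
    right = m$paracentral_right$mean_brightness)
  if (para_min <= 0) {
    stop("paracentral minimum brightness is zero: MHRI undefined", call. = FALSE)
  }
  index_set(cri_max = m$central$max_brightness / rpe,
            cri_mean = m$central$mean_brightness / rpe,
            pcri_min = para_min / rpe,
            pcri_mean = para_mean / rpe,
            mhri = m$central$max_brightness / para_min)
}

#' @export
print.octmhri_indices <- function(x, ...) {
  cat(sprintf("reflectivity indices: CRI-Max %.3f, CRI-Mean %.3f, PCRI-Min %.3f, PCRI-Mean %.3f, MHRI %.3f\n",
              x$cri_max, x$cri_mean, x$pcri_min, x$pcri_mean, x$mhri))
  invisible(x)
}

#' @export
as.data.frame.octmhri_indices <- function(x, ...) {
  data.frame(cri_max = x$cri_max, cri_mean = x$cri_mean,
             pcri_min = x$pcri_min, pcri_mean = x$pcri_mean, mhri = x$mhri)
}
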