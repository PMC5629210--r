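# Junctional fluorescence quantification from calibrated images:
# apical max-projection, perpendicular line scans, Gaussian peak fitting,
# two-band AUC with the 10-px background rule, co-localized readout at a
# reference peak, and the junction/cytoplasm enrichment ratio.

#' Construct a calibrated image
#'
#' @param data numeric matrix (2D, row = y, col = x) or 3D array
#'   (y, x, plane) of non-negative intensities (a.u.).
#' @param pixel_size_um pixel size in um/px (> 0).
#' @param z_spacing_um plane spacing for stacks (um).
#' @param apical_end which end of the plane axis is apical (`"last"` or
#'   `"first"`); explicit metadata, never inferred from the data.
#' @return a `calibrated_image`.
#' @export
calibrated_image <- function(data, pixel_size_um, z_spacing_um = NULL,
                             apical_end = "last") {
  assert_that(is.numeric(data) && length(dim(data)) %in% c(2, 3),
              "data must be a 2D matrix or 3D array")
  assert_that(all(is.finite(data)) && all(data >= 0),
              "intensities must be finite and >= 0")
  assert_that(pixel_size_um > 0, "pixel size must be > 0")
  assert_that(apical_end %in% c("first", "last"), "bad apical_end")
  structure(data, pixel_size_um = pixel_size_um,
            z_spacing_um = z_spacing_um, apical_end = apical_end,
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x)
  cat("Calibrated image:", paste(d, collapse = " x "),
      sprintf("(%g um/px", attr(x, "pixel_size_um")),
      if (length(d) == 3)
        sprintf(", %g um z-spacing, apical = %s)",
                attr(x, "z_spacing_um") %||% NA, attr(x, "apical_end"))
      else ")", "\n")
  invisible(x)
}

#' Maximum projection of the most-apical sections
#'
#' Pixelwise maximum over the `n_sections` most-apical planes of a stack
#' (which end is apical comes from the image's metadata).
#'
#' @param stack a 3D `calibrated_image`.
#' @param n_sections number of apical planes to project (default 3).
#' @return a 2D `calibrated_image`.
#' @export
max_project_apical <- function(stack, n_sections = 3) {
  assert_that(inherits(stack, "calibrated_image") &&
                length(dim(stack)) == 3, "need a 3D calibrated_image")
  np <- dim(stack)[3]
  if (np < n_sections)
    stopf("stack has %d plane(s), need %d", np, n_sections)
  idx <- if (attr(stack, "apical_end") == "last")
    seq(np - n_sections + 1, np) else seq_len(n_sections)
  proj <- apply(unclass(stack)[, , idx, drop = FALSE], c(1, 2), max)
  calibrated_image(proj, attr(stack, "pixel_size_um"))
}

# distance from point (px,py) to segment (x1,y1)-(x2,y2)
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Extract a perpendicular line-scan profile across a junction
#'
#' Samples the image by bilinear interpolation along a line perpendicular to
#' the junction, centered on the ROI midpoint, in 1-px steps, and averages
#' over `width_px` parallel lines spaced 1 px along the junction direction.
#' Defaults mirror the standard design: 20-um scans averaged over 30 px.
#'
#' @param image a 2D `calibrated_image`.
#' @param roi junction ROI: numeric matrix of >= 2 vertices with columns
#'   x, y in pixel coordinates (1-based, pixel-center convention;
#'   sub-pixel allowed).
#' @param length_um scan length in um.
#' @param width_px number of parallel lines averaged.
#' @return a `junction_profile` (data.frame `pos_um`, `intensity`) with the
#'   scan geometry in attributes; positions are centered on the junction.
#' @export
extract_line_scan <- function(image, roi, length_um = 20, width_px = 30) {
  assert_that(inherits(image, "calibrated_image") &&
                length(dim(image)) == 2, "need a 2D calibrated_image")
  roi <- as.matrix(roi)
  assert_that(nrow(roi) >= 2 && ncol(roi) >= 2, "ROI needs >= 2 vertices")
  px <- attr(image, "pixel_size_um")
  # junction direction from the ROI chord; center at mid-arclength vertex pair
  seglen <- sqrt(rowSums((roi[-1, , drop = FALSE] -
                            roi[-nrow(roi), , drop = FALSE])^2))
  if (sum(seglen) == 0) stopf("zero-length ROI")
  cum <- c(0, cumsum(seglen))
  half <- cum[length(cum)] / 2
  i <- max(which(cum <= half))
  i <- min(i, nrow(roi) - 1L)
  f <- (half - cum[i]) / seglen[i]
  center <- roi[i, 1:2] + f * (roi[i + 1, 1:2] - roi[i, 1:2])
  dvec <- roi[nrow(roi), 1:2] - roi[1, 1:2]
  dvec <- dvec / sqrt(sum(dvec^2))
  perp <- c(-dvec[2], dvec[1])

  n_half <- ceiling(length_um / px / 2)
  steps <- seq(-n_half, n_half)                    # 1-px steps across
  offs <- seq_len(width_px) - (width_px + 1) / 2   # 1-px steps along
  xs <- outer(steps * perp[1], offs * dvec[1], "+") + center[1]
  ys <- outer(steps * perp[2], offs * dvec[2], "+") + center[2]
  nr <- nrow(image); nc <- ncol(image)
  if (any(xs < 1 | xs > nc | ys < 1 | ys > nr))
    stopf("line scan exits image bounds")
  vals <- matrix(bilinear(unclass(image), as.vector(xs), as.vector(ys)),
                 nrow = length(steps))
  structure(data.frame(pos_um = steps * px, intensity = rowMeans(vals)),
            pixel_size_um = px, width_px = width_px, center = center,
            direction = dvec,
            class = c("junction_profile", "data.frame"))
}

# Background per the 10-px rule: mean of the samples in windows starting
# `offset_px` beyond the outer centers, `width_px` samples long, both sides.
profile_background <- function(profile, centers_idx, offset_px = 10,
                               width_px = 5) {
  n <- nrow(profile)
  lo <- min(centers_idx); hi <- max(centers_idx)
  left <- seq(lo - offset_px - width_px, lo - offset_px - 1)
  right <- seq(hi + offset_px + 1, hi + offset_px + width_px)
  idx <- c(left, right)
  idx <- idx[idx >= 1 & idx <= n]
  if (!length(idx)) return(NA_real_)
  mean(profile$intensity[idx])
}

new_measurement <- function(kind, value, background, fit = NULL,
                            flag = NA_character_, extra = list()) {
  structure(c(list(kind = kind, value = value, background = background,
                   fit = fit, flag = flag), extra),
            class = "junction_measurement")
}

#' @export
print.junction_measurement <- function(x, ...) {
  cat(sprintf("Junction measurement [%s]: value = %.6g (background %.6g)\n",
              x$kind, x$value, x$background))
  if (!is.null(x$fit))
    cat("  fit:", paste(sprintf("%s=%.4g", names(x$fit), x$fit),
                        collapse = ", "), "\n")
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Gaussian peak measurement of a junction profile
#'
#' Fits `amp * exp(-(x - mu)^2 / (2 sigma^2)) + baseline` to the profile and
#' reports the peak amplitude over baseline as the junctional intensity.
#' The windowed background (samples lying 10 px beyond the maximum on either
#' side) is reported alongside; the value itself is the fitted amplitude so
#' the offset is not subtracted twice.
#'
#' @param profile a `junction_profile`.
#' @param bg_offset_px,bg_width_px background window geometry (px).
#' @return a `junction_measurement` of kind `"gaussian_peak"` with fit
#'   parameters `amp`, `mu`, `sigma`, `baseline`.
#' @export
gaussian_peak <- function(profile, bg_offset_px = 10, bg_width_px = 5) {
  x <- profile$pos_um; y <- profile$intensity
  n <- length(y)
  imax <- which.max(y)
  if (max(y) - min(y) < 1e-12 * max(abs(y) + 1))
    return(new_measurement("gaussian_peak", 0,
                           background = mean(y),
                           flag = "no-peak"))
  flag <- if (imax <= 2 || imax >= n - 1) "peak-at-edge" else NA_character_
  base0 <- min(y); amp0 <- max(y) - base0
  mu0 <- x[imax]
  px <- attr(profile, "pixel_size_um") %||% mean(diff(x))
  above <- which(y - base0 > amp0 / 2)
  sig0 <- max(diff(range(x[above])) / 2.355, px)
  # raw Levenberg-Marquardt: a symmetric profile converges to mu = 0
  # exactly, which the nls model-object machinery cannot represent
  resid_fn <- function(p) y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(amp0, mu0, sig0, base0), fn = resid_fn,
                       lower = c(0, min(x), 1e-6, 0),
                       upper = c(Inf, max(x), diff(range(x)), Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  bg <- profile_background(profile, imax, bg_offset_px, bg_width_px)
  if (inherits(fit, "error") || fit$info %in% c(0, 5, 9))
    return(new_measurement("gaussian_peak", NA_real_, bg,
                           flag = paste("non-convergence:",
                                        if (inherits(fit, "error"))
                                          conditionMessage(fit)
                                        else fit$message)))
  cf <- fit$par
  new_measurement("gaussian_peak", cf[1], bg,
                  fit = c(amp = cf[1], mu = cf[2], sigma = cf[3],
                          baseline = cf[4]),
                  flag = flag)
}

# local maxima of a numeric vector (strictly greater than both neighbours,
# plateaus take their first index), with a simple prominence score
local_maxima <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx)) return(data.frame(idx = integer(0), prom = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- min(y[1:i]); right <- min(y[i:n])
    y[i] - max(left, right)
  }, numeric(1))
  data.frame(idx = idx, prom = prom)
}

#' Band AUC measurement (two-parallel-band channels)
#'
#' For channels that form two parallel perijunctional bundles (F-actin,
#' NMIIA), sums background-subtracted intensities over +/- `half_width_px`
#' around each band center. Band centers default to the two
#' highest-prominence local maxima within `center_window_um` of the scan
#' center (single center if only one band is present); background follows
#' the 10-px-beyond rule. Overlapping band windows are counted once.
#'
#' @param profile a `junction_profile`.
#' @param half_width_px half-width of each band window (px).
#' @param centers_um optional explicit band center position(s) (um).
#' @param center_window_um search window for band centers around the scan
#'   center.
#' @param bg_offset_px,bg_width_px background window geometry.
#' @return a `junction_measurement` of kind `"band_auc"`, with the band
#'   center positions in `$centers_um`.
#' @export
band_auc <- function(profile, half_width_px = 10, centers_um = NULL,
                     center_window_um = 3, bg_offset_px = 10,
                     bg_width_px = 5) {
  x <- profile$pos_um; y <- profile$intensity
  n <- length(y)
  if (is.null(centers_um)) {
    lm_ <- local_maxima(y)
    lm_ <- lm_[abs(x[lm_$idx]) <= center_window_um, , drop = FALSE]
    if (nrow(lm_) == 0)
      return(new_measurement("band_auc", 0,
                             background = mean(y), flag = "no-band"))
    lm_ <- lm_[order(-lm_$prom), , drop = FALSE]
    centers_idx <- sort(lm_$idx[seq_len(min(2, nrow(lm_)))])
  } else {
    centers_idx <- vapply(centers_um, function(c0) which.min(abs(x - c0)),
                          integer(1))
  }
  flag <- NA_character_
  if (min(centers_idx) - half_width_px < 1 ||
      max(centers_idx) + half_width_px > n)
    flag <- "band-at-edge"
  bg <- profile_background(profile, centers_idx, bg_offset_px, bg_width_px)
  win <- sort(unique(unlist(lapply(centers_idx, function(i)
    seq(max(1, i - half_width_px), min(n, i + half_width_px))))))
  auc <- sum(y[win] - bg)
  new_measurement("band_auc", auc, bg, flag = flag,
                  extra = list(centers_um = x[centers_idx]))
}

#' Target intensity at the reference channel's peak
#'
#' Locates the Gaussian peak of a reference profile (e.g. total cortactin)
#' and reports the background-subtracted target intensity (e.g. pY421
#' cortactin) at that position, plus the target/reference ratio.
#'
#' @param target_profile,reference_profile `junction_profile`s sharing the
#'   same scan geometry.
#' @param bg_offset_px,bg_width_px background window geometry.
#' @return a `junction_measurement` of kind `"coloc_at_reference_peak"`;
#'   `$ratio` holds target/reference, `$mu_ref` the reference peak position.
#' @export
coloc_at_reference_peak <- function(target_profile, reference_profile,
                                    bg_offset_px = 10, bg_width_px = 5) {
  assert_that(nrow(target_profile) == nrow(reference_profile),
              "profiles must share the same scan geometry")
  ref <- gaussian_peak(reference_profile, bg_offset_px, bg_width_px)
  if (is.null(ref$fit) || !is.finite(ref$value) || ref$value <= 0)
    stopf("reference profile has no usable peak")
  mu <- ref$fit[["mu"]]
  x <- target_profile$pos_um
  ti <- stats::approx(x, target_profile$intensity, xout = mu)$y
  imu <- which.min(abs(x - mu))
  bg <- profile_background(target_profile, imu, bg_offset_px, bg_width_px)
  val <- ti - bg
  new_measurement("coloc_at_reference_peak", val, bg,
                  extra = list(ratio = val / ref$value, mu_ref = mu,
                               reference_value = ref$value))
}

#' Junction/cytoplasm mean-intensity ratio
#'
#' Ratio of the mean intensity within a `band_width_px`-wide band covering
#' the whole junction to the mean intensity within a cytoplasm mask; the
#' enrichment readout used for the GFP-AHPH location biosensor of active
#' RhoA.
#'
#' @param image a 2D `calibrated_image`.
#' @param junction_polyline matrix of junction vertices (x, y in px).
#' @param cytoplasm_mask logical matrix of the image size selecting
#'   cytoplasmic pixels; must not overlap the junction band.
#' @param band_width_px full width of the junction band (px).
#' @return a `junction_measurement` of kind `"junction_cytoplasm_ratio"`,
#'   with the two means in `$junction_mean` / `$cytoplasm_mean`.
#' @export
junction_cytoplasm_ratio <- function(image, junction_polyline,
                                     cytoplasm_mask, band_width_px = 20) {
  assert_that(inherits(image, "calibrated_image") &&
                length(dim(image)) == 2, "need a 2D calibrated_image")
  poly <- as.matrix(junction_polyline)
  assert_that(nrow(poly) >= 2, "junction polyline needs >= 2 vertices")
  assert_that(is.logical(cytoplasm_mask) &&
                all(dim(cytoplasm_mask) == dim(image)),
              "cytoplasm_mask must be a logical matrix of the image size")
  if (!any(cytoplasm_mask)) stopf("empty cytoplasm mask")
  nr <- nrow(image); nc <- ncol(image)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  dmin <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(poly) - 1)) {
    d <- dist_to_segment(xs, ys, poly[i, 1], poly[i, 2],
                         poly[i + 1, 1], poly[i + 1, 2])
    dmin <- pmin(dmin, d)
  }
  band <- dmin <= band_width_px / 2
  if (!any(band)) stopf("junction band selects no pixels")
  if (any(band & cytoplasm_mask))
    stopf("cytoplasm mask overlaps the junction band")
  jm <- mean(image[band]); cm <- mean(image[cytoplasm_mask])
  if (cm == 0) stopf("zero cytoplasm mean")
  new_measurement("junction_cytoplasm_ratio", jm / cm, background = cm,
                  extra = list(junction_mean = jm, cytoplasm_mean = cm,
                               n_band_px = sum(band)))
}

#' Summarize junction measurements per condition
#'
#' Computes per-condition/experiment mean values, refusing to summarize
#' undersampled batches: the minimum is 25 junctions per condition for
#' immunofluorescence readouts and 60 for the GFP-AHPH ratio, unless
#' `force = TRUE`.
#'
#' @param df data.frame with `experiment`, `condition`, `value` and
#'   optionally `junction_id`.
#' @param assay `"IF"` or `"AHPH"` (sets the minimum junction count).
#' @param force bypass the minimum-count guard.
#' @return data.frame of per-experiment/condition means and counts.
#' @export
junction_summary <- function(df, assay = c("IF", "AHPH"), force = FALSE) {
  assay <- match.arg(assay)
  min_n <- if (assay == "IF") 25L else 60L
  counts <- stats::aggregate(value ~ experiment + condition, df, length)
  if (!force && any(counts$value < min_n))
    stopf("fewer than %d junctions for %s in: %s (use force = TRUE)",
          min_n, assay,
          paste(counts$condition[counts$value < min_n], collapse = ", "))
  means <- stats::aggregate(value ~ experiment + condition, df, mean)
  names(means)[3] <- "mean_value"
  means$n <- counts$value[match(paste(means$experiment, means$condition),
                                paste(counts$experiment, counts$condition))]
  means
}
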