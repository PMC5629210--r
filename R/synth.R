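# Synthetic-data generators. Every input the analysis modules consume can
# be generated here with known ground truth, on acquisition designs that
# mirror the reference protocols: recoil movies with a 12 s gap to the
# first post-ablation frame then 8 s intervals; FRAP with 3 pre-bleach and
# 57 post-bleach frames at 5 s; junction images with Gaussian cross-section
# bands over background with Poisson + Gaussian read noise; nuclear tracks
# as a persistent random walk over 6 h.

# default post-ablation frame schedule: ablation at t = 0 within the 12 s
# gap, 5 post-ablation frames
recoil_frame_times <- function(n_frames = 5, first_delay_s = 12,
                               interval_s = 8) {
  first_delay_s + interval_s * (seq_len(n_frames) - 1)
}

#' Generate synthetic recoil series
#'
#' Samples `L(t) = L0 + A (1 - exp(-k t)) + eps`, `eps ~ N(0, sigma^2)`,
#' on the standard frame schedule (first post-ablation frame 12 s after
#' ablation, then 8 s intervals).
#'
#' @param n_junctions number of junctions (default 12, the per-condition
#'   minimum of the reference design).
#' @param L0 pre-ablation vertex distance (um).
#' @param A recoil amplitude (um).
#' @param k relaxation rate constant (1/s).
#' @param sigma additive Gaussian noise SD (um).
#' @param times post-ablation frame times (s).
#' @param condition,experiment labels.
#' @param seed random seed (recorded in the output).
#' @return list with `series` (list of `recoil_series`) and `truth`
#'   (data.frame of the generating parameters per junction, including
#'   `v0 = A*k` and the seed).
#' @export
gen_recoil <- function(n_junctions = 12, L0 = 10, A = 1.2, k = 0.05,
                       sigma = 0.05, times = recoil_frame_times(),
                       condition = "control", experiment = "exp1",
                       seed = 1) {
  set.seed(seed)
  series <- vector("list", n_junctions)
  for (j in seq_len(n_junctions)) {
    L <- L0 + A * (1 - exp(-k * times)) + stats::rnorm(length(times), 0, sigma)
    series[[j]] <- recoil_series(times, pmax(L, 1e-6), L0 = L0,
                                 condition = condition,
                                 experiment = experiment,
                                 junction_id = sprintf("j%02d", j))
  }
  truth <- data.frame(junction_id = sprintf("j%02d", seq_len(n_junctions)),
                      L0 = L0, A = A, k = k, v0 = A * k, sigma = sigma,
                      condition = condition, experiment = experiment,
                      seed = seed, stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Generate synthetic FRAP series
#'
#' Pre-bleach plateau at `F_i`, bleach step to depth `bleach_depth`
#' (default 0.75, matching the > 70% protocol), then one-phase recovery
#' with mobile fraction `Mf` and half-time `t_half`, plus additive Gaussian
#' noise (SD `sigma` on the normalized scale).
#'
#' @param n_junctions number of junctions (reference design: 6-10).
#' @param Mf mobile fraction.
#' @param t_half half-time of recovery (s).
#' @param bleach_depth fractional bleach depth `1 - F(0)/F(i)`.
#' @param F_i pre-bleach intensity (a.u.).
#' @param n_pre,n_post pre-/post-bleach frame counts (default 3 and 57).
#' @param dt_s frame interval (s, default 5).
#' @param sigma noise SD on the normalized recovery scale.
#' @param condition,experiment labels.
#' @param seed random seed.
#' @return list with `series` (list of `frap_series`) and `truth`.
#' @export
gen_frap <- function(n_junctions = 6, Mf = 0.7, t_half = 20,
                     bleach_depth = 0.75, F_i = 100, n_pre = 3,
                     n_post = 57, dt_s = 5, sigma = 0,
                     condition = "control", experiment = "exp1", seed = 1) {
  set.seed(seed)
  F_0 <- F_i * (1 - bleach_depth)
  t_all <- dt_s * (seq_len(n_pre + n_post) - 1)
  t_post <- dt_s * (seq_len(n_post) - 1)  # t = 0 at first post-bleach frame
  series <- vector("list", n_junctions)
  for (j in seq_len(n_junctions)) {
    recovery <- Mf * (1 - exp(-log(2) * t_post / t_half))
    noise <- stats::rnorm(n_post, 0, sigma)
    # the first post-bleach frame defines F(0): keep it exact
    noise[1] <- 0
    post <- F_0 + (F_i - F_0) * (recovery + noise)
    pre <- rep(F_i, n_pre)
    series[[j]] <- frap_series(t_all, c(pre, post), n_prebleach = n_pre,
                               junction_id = sprintf("j%02d", j),
                               condition = condition, experiment = experiment)
  }
  truth <- data.frame(junction_id = sprintf("j%02d", seq_len(n_junctions)),
                      Mf = Mf, t_half = t_half, bleach_depth = bleach_depth,
                      F_i = F_i, F_0 = F_0, sigma = sigma,
                      condition = condition, experiment = experiment,
                      seed = seed, stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Generate a synthetic junction image
#'
#' Renders a straight junction with Gaussian cross-section band(s) over a
#' uniform background: a single band for adhesion-receptor-like channels or
#' two parallel bands offset by `band_offset_um` for perijunctional-bundle
#' channels (F-actin/NMIIA-like). Optionally adds a co-localized second
#' channel at a set amplitude ratio, renders a 3-plane apical stack with
#' per-plane amplitude weights, and applies Poisson (photon) then Gaussian
#' (read) noise.
#'
#' @param size_px image side (square image).
#' @param pixel_size_um pixel size (um/px).
#' @param amplitude band peak amplitude above background (a.u.).
#' @param sigma_um band cross-section SD (um); must resolve to >= 1 px.
#' @param background uniform background level (a.u.).
#' @param two_band render two parallel bands instead of one.
#' @param band_offset_um band offset from the junction line (each side).
#' @param angle_deg junction orientation (0 = vertical junction).
#' @param coloc_ratio if non-`NULL`, also return a second channel whose
#'   amplitude is `coloc_ratio * amplitude` at the same position.
#' @param n_planes 1 for a 2D image, else a stack with `plane_weights`.
#' @param plane_weights per-plane amplitude weights (apical last).
#' @param poisson_noise apply Poisson noise.
#' @param read_noise_sd Gaussian read noise SD (0 = off).
#' @param seed random seed.
#' @return list with `image` (a `calibrated_image`), `roi` (junction
#'   polyline, px coordinates), `coloc_image` (or `NULL`) and `truth`.
#' @export
gen_junction_image <- function(size_px = 128, pixel_size_um = 0.2,
                               amplitude = 500, sigma_um = 0.5,
                               background = 100, two_band = FALSE,
                               band_offset_um = 1, angle_deg = 0,
                               coloc_ratio = NULL, n_planes = 1,
                               plane_weights = c(0.6, 1, 0.8),
                               poisson_noise = FALSE, read_noise_sd = 0,
                               seed = 1) {
  assert_that(sigma_um / pixel_size_um >= 1,
              "band sigma below 1 px is unresolvable")
  set.seed(seed)
  ctr <- floor((size_px + 1) / 2)  # a pixel center, so on-axis scans sample exactly
  xs <- matrix(rep(seq_len(size_px), each = size_px), size_px, size_px)
  ys <- matrix(rep(seq_len(size_px), size_px), size_px, size_px)
  th <- angle_deg * pi / 180
  # signed distance (um) from the junction line through the image center
  dist_um <- ((xs - ctr) * cos(th) + (ys - ctr) * sin(th)) * pixel_size_um
  band <- function(amp) {
    if (two_band)
      amp * (exp(-(dist_um - band_offset_um)^2 / (2 * sigma_um^2)) +
               exp(-(dist_um + band_offset_um)^2 / (2 * sigma_um^2)))
    else amp * exp(-dist_um^2 / (2 * sigma_um^2))
  }
  render <- function(amp) {
    clean <- if (n_planes == 1) background + band(amp)
    else {
      w <- plane_weights[seq_len(n_planes)]
      array(vapply(w, function(wi) background + band(amp * wi),
                   matrix(0, size_px, size_px)),
            dim = c(size_px, size_px, n_planes))
    }
    img <- clean
    if (poisson_noise) img <- array(stats::rpois(length(img), img), dim = dim(clean))
    if (read_noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, read_noise_sd),
                         dim = dim(clean))
    calibrated_image(pmax(img, 0), pixel_size_um,
                     z_spacing_um = if (n_planes > 1) 0.19 else NULL)
  }
  image <- render(amplitude)
  coloc <- if (!is.null(coloc_ratio)) render(coloc_ratio * amplitude) else NULL
  # junction polyline along the line dist = 0
  u <- c(-sin(th), cos(th))
  half <- size_px / 2 - 2
  roi <- rbind(c(ctr - half * u[1], ctr - half * u[2]),
               c(ctr + half * u[1], ctr + half * u[2]))
  colnames(roi) <- c("x", "y")
  band_mass_per_scan <- if (two_band)
    2 * amplitude * sigma_um / pixel_size_um * sqrt(2 * pi)
  else amplitude * sigma_um / pixel_size_um * sqrt(2 * pi)
  truth <- list(amplitude = amplitude, sigma_um = sigma_um,
                background = background, two_band = two_band,
                band_offset_um = band_offset_um, angle_deg = angle_deg,
                coloc_ratio = coloc_ratio, pixel_size_um = pixel_size_um,
                band_mass_per_scan = band_mass_per_scan,
                plane_weights = if (n_planes > 1) plane_weights[seq_len(n_planes)] else 1,
                seed = seed)
  list(image = image, roi = roi, coloc_image = coloc, truth = truth)
}

#' Generate synthetic nuclear tracks
#'
#' Persistent random walk sampled at the movie frame interval: increments
#' combine a drift velocity, an optional exponentially correlated
#' (persistent) velocity component with correlation time `persistence_min`,
#' and isotropic diffusion with coefficient `D`. Defaults mirror the
#' reference scale: 35 nuclei tracked over 6 h.
#'
#' @param n_tracks number of nuclei (reference: 30-40 per movie).
#' @param duration_min track duration (default 360 min = 6 h).
#' @param dt_min frame interval (min).
#' @param D diffusion coefficient (um^2/min); MSD of the pure random walk
#'   is `4 D tau`.
#' @param drift drift velocity c(vx, vy) (um/min).
#' @param persistence_min correlation time of the persistent component
#'   (0 = uncorrelated walk).
#' @param speed_persistent RMS speed of the persistent component (um/min).
#' @param condition,experiment labels.
#' @param seed random seed.
#' @return list with `tracks` (a `track_set`) and `truth`.
#' @export
gen_tracks <- function(n_tracks = 35, duration_min = 360, dt_min = 5,
                       D = 0.5, drift = c(0, 0), persistence_min = 0,
                       speed_persistent = 0, condition = "control",
                       experiment = "exp1", seed = 1) {
  set.seed(seed)
  n_steps <- round(duration_min / dt_min)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    vx <- vy <- rep(0, n_steps)
    if (persistence_min > 0 && speed_persistent > 0) {
      a <- exp(-dt_min / persistence_min)
      s <- speed_persistent * sqrt(1 - a^2) / sqrt(2)
      v0 <- stats::rnorm(2, 0, speed_persistent / sqrt(2))
      vx[1] <- v0[1]; vy[1] <- v0[2]
      for (kk in 2:n_steps) {
        vx[kk] <- a * vx[kk - 1] + stats::rnorm(1, 0, s)
        vy[kk] <- a * vy[kk - 1] + stats::rnorm(1, 0, s)
      }
    }
    dx <- drift[1] * dt_min + vx * dt_min +
      stats::rnorm(n_steps, 0, sqrt(2 * D * dt_min))
    dy <- drift[2] * dt_min + vy * dt_min +
      stats::rnorm(n_steps, 0, sqrt(2 * D * dt_min))
    rows[[i]] <- data.frame(track_id = sprintf("t%03d", i),
                            time_min = dt_min * (0:n_steps),
                            x_um = c(0, cumsum(dx)), y_um = c(0, cumsum(dy)),
                            condition = condition, experiment = experiment,
                            stringsAsFactors = FALSE)
  }
  truth <- data.frame(D = D, drift_x = drift[1], drift_y = drift[2],
                      persistence_min = persistence_min,
                      speed_persistent = speed_persistent,
                      n_tracks = n_tracks, duration_min = duration_min,
                      dt_min = dt_min, condition = condition,
                      experiment = experiment, seed = seed)
  list(tracks = track_set(do.call(rbind, rows)), truth = truth)
}

#' Generate synthetic wound margins
#'
#' Two margin polylines separated by a known mean advance along the wound
#' axis, with independent sinusoidal-plus-noise roughness.
#'
#' @param advance_um mean margin advance between the two time points.
#' @param length_um margin length along the wound edge.
#' @param n_points vertices per margin.
#' @param rough_amp_um,rough_period_um sinusoidal roughness amplitude/period.
#' @param noise_sd additional Gaussian roughness SD (um).
#' @param seed random seed.
#' @return list with `margin_t0`, `margin_t1`, `truth`.
#' @export
gen_margins <- function(advance_um = 30, length_um = 400, n_points = 201,
                        rough_amp_um = 5, rough_period_um = 50,
                        noise_sd = 1, seed = 1) {
  set.seed(seed)
  yy <- seq(0, length_um, length.out = n_points)
  rough <- function(phase) {
    rough_amp_um * sin(2 * pi * yy / rough_period_um + phase) +
      stats::rnorm(n_points, 0, noise_sd)
  }
  m0 <- data.frame(x_um = rough(stats::runif(1, 0, 2 * pi)), y_um = yy)
  m1 <- data.frame(x_um = advance_um + rough(stats::runif(1, 0, 2 * pi)),
                   y_um = yy)
  list(margin_t0 = m0, margin_t1 = m1,
       truth = data.frame(advance_um = advance_um, seed = seed))
}
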