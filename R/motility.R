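# Intraepithelial motility metrics: ensemble MSD of nuclear tracks with a
# fitted displacement summary at a horizon (default 6 h), and mean
# wound-margin displacement.

#' Construct a track set
#'
#' @param df data.frame with columns `track_id`, `time_min`, `x_um`, `y_um`
#'   and optionally `condition`, `experiment`.
#' @return a `track_set` data.frame.
#' @export
track_set <- function(df) {
  req <- c("track_id", "time_min", "x_um", "y_um")
  assert_that(all(req %in% names(df)),
              paste("tracks need columns:", paste(req, collapse = ", ")))
  df <- df[order(df$track_id, df$time_min), , drop = FALSE]
  for (id in unique(df$track_id)) {
    tt <- df$time_min[df$track_id == id]
    if (length(tt) < 2) stopf("track '%s' has fewer than 2 points", id)
    if (any(diff(tt) <= 0)) stopf("track '%s' times not strictly increasing", id)
  }
  structure(df, class = c("track_set", "data.frame"))
}

#' Ensemble mean squared displacement
#'
#' Time-averaged MSD per track over overlapping windows, then averaged over
#' the ensemble of tracks. Lags are restricted to at most
#' `max_lag_fraction` of each track's duration, so every reported lag is
#' estimated from many displacement pairs.
#'
#' @param tracks a `track_set` (or data.frame with the same columns);
#'   a common frame interval is assumed (tracks are resampled onto the
#'   modal interval if theirs differs).
#' @param max_lag_fraction largest lag as a fraction of track duration.
#' @return an `msd_result`: data.frame `tau_min`, `msd_um2`, `n_tracks`.
#' @examples
#' tr <- gen_tracks(n_tracks = 5, seed = 1)
#' head(compute_msd(tr))
#' @export
compute_msd <- function(tracks, max_lag_fraction = 0.25) {
  if (!inherits(tracks, "track_set")) tracks <- track_set(tracks)
  ids <- unique(tracks$track_id)
  dts <- unlist(lapply(ids, function(id)
    diff(tracks$time_min[tracks$track_id == id])))
  dt <- as.numeric(names(sort(table(signif(dts, 10)), decreasing = TRUE))[1])

  per_track <- lapply(ids, function(id) {
    d <- tracks[tracks$track_id == id, ]
    tt <- d$time_min
    if (any(abs(diff(tt) - dt) > 1e-9 * dt)) {  # resample to common grid
      grid <- seq(min(tt), max(tt), by = dt)
      d <- data.frame(time_min = grid,
                      x_um = stats::approx(tt, d$x_um, grid)$y,
                      y_um = stats::approx(tt, d$y_um, grid)$y)
    }
    n <- nrow(d)
    max_lag <- max(1L, floor((n - 1) * max_lag_fraction))
    vapply(seq_len(max_lag), function(lag) {
      dx <- d$x_um[(lag + 1):n] - d$x_um[1:(n - lag)]
      dy <- d$y_um[(lag + 1):n] - d$y_um[1:(n - lag)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  })
  max_lag <- max(lengths(per_track))
  if (max_lag < 1) stopf("no track long enough for any lag")
  msd <- vapply(seq_len(max_lag), function(lag) {
    vals <- unlist(lapply(per_track, function(m)
      if (length(m) >= lag) m[lag] else NULL))
    c(mean(vals), length(vals))
  }, numeric(2))
  structure(data.frame(tau_min = dt * seq_len(max_lag),
                       msd_um2 = msd[1, ], n_tracks = as.integer(msd[2, ])),
            dt_min = dt, class = c("msd_result", "data.frame"))
}

#' Fit a power law to an MSD curve and project to a horizon
#'
#' Least-squares fit of `MSD(tau) = Gamma * tau^alpha` on log-log axes
#' (non-positive MSD values are excluded from the log fit), evaluated at the
#' projection horizon (default 6 h = 360 min). `alpha` near 1 indicates
#' diffusive motion (`Gamma = 4D`), near 2 ballistic. A linear `4 D tau`
#' alternative is available via `form = "linear"`.
#'
#' @param msd an `msd_result` (or data.frame `tau_min`, `msd_um2`).
#' @param horizon_min projection horizon in minutes.
#' @param form `"power"` (default) or `"linear"`.
#' @return an `msd_fit` with `Gamma`, `alpha`, `msd_at_horizon`; methods
#'   `print`, `coef`, `predict`, `plot`.
#' @export
fit_msd <- function(msd, horizon_min = 360, form = c("power", "linear")) {
  form <- match.arg(form)
  ok <- msd$msd_um2 > 0 & msd$tau_min > 0
  if (sum(ok) < 5) stopf("fewer than 5 usable lag points")
  tau <- msd$tau_min[ok]; y <- msd$msd_um2[ok]
  if (form == "power") {
    fit <- stats::lm(log(y) ~ log(tau))
    Gamma <- exp(unname(stats::coef(fit)[1]))
    alpha <- unname(stats::coef(fit)[2])
  } else {
    Gamma <- unname(stats::coef(stats::lm(y ~ tau - 1))[1])
    alpha <- 1
  }
  out <- list(Gamma = Gamma, alpha = alpha, form = form,
              horizon_min = horizon_min,
              msd_at_horizon = Gamma * horizon_min^alpha,
              data = msd)
  class(out) <- "msd_fit"
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD %s-law fit: Gamma = %.4g, alpha = %.4g\n",
              x$form, x$Gamma, x$alpha))
  cat(sprintf("  MSD(%g min) = %.4g um^2\n", x$horizon_min, x$msd_at_horizon))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(Gamma = object$Gamma, alpha = object$alpha)
}

#' @export
predict.msd_fit <- function(object, tau_min = object$data$tau_min, ...) {
  object$Gamma * tau_min^object$alpha
}

#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(x$data$tau_min, x$data$msd_um2, log = "xy",
                 xlab = "lag (min)", ylab = "MSD (um^2)", ...)
  graphics::lines(x$data$tau_min, predict(x), col = 2)
  invisible(x)
}

#' Relative MSD at the horizon
#'
#' Fitted-curve MSD of a condition at the horizon divided by the control's,
#' the per-experiment normalization convention used for the 6-h summary.
#'
#' @param fit_condition,fit_control `msd_fit` objects.
#' @param horizon_min horizon (defaults to the condition fit's).
#' @return numeric ratio.
#' @export
relative_msd <- function(fit_condition, fit_control,
                         horizon_min = fit_condition$horizon_min) {
  (fit_condition$Gamma * horizon_min^fit_condition$alpha) /
    (fit_control$Gamma * horizon_min^fit_control$alpha)
}

#' Mean wound-margin displacement
#'
#' Mean perpendicular advance of an epithelial margin toward the wound
#' between two time points (default readout: 15 h). Margins are polylines
#' sampled along the wound edge; both are interpolated onto a common
#' along-margin grid and the mean signed advance along the wound axis is
#' returned (negative if the margin retreated).
#'
#' @param margin_t0,margin_t1 data.frames with columns `x_um` (position
#'   along the wound axis, i.e. the advance direction) and `y_um`
#'   (position along the margin).
#' @param direction +1 if the wound lies toward increasing x, -1 otherwise.
#' @return mean displacement (um).
#' @export
margin_displacement <- function(margin_t0, margin_t1, direction = 1) {
  req <- c("x_um", "y_um")
  assert_that(all(req %in% names(margin_t0)) && all(req %in% names(margin_t1)),
              "margins need columns x_um, y_um")
  assert_that(direction %in% c(-1, 1), "direction must be +1 or -1")
  lo <- max(min(margin_t0$y_um), min(margin_t1$y_um))
  hi <- min(max(margin_t0$y_um), max(margin_t1$y_um))
  if (hi <= lo) stopf("margins do not overlap along the wound edge (mismatched axes?)")
  grid <- seq(lo, hi, length.out = 200)
  x0 <- stats::approx(margin_t0$y_um, margin_t0$x_um, grid)$y
  x1 <- stats::approx(margin_t1$y_um, margin_t1$x_um, grid)$y
  direction * mean(x1 - x0)
}
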