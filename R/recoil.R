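# Kelvin-Voigt analysis of post-ablation junction recoil.
#
# After laser ablation of a junction the distance L(t) between the released
# vertices relaxes as a Kelvin-Voigt element (spring and dashpot in
# parallel):
#
#   L(t) = L0 + A * (1 - exp(-k t))
#
# A is the asymptotic retraction amplitude (um), k the relaxation rate
# constant (s^-1, the elasticity/viscosity ratio), and the initial recoil
# velocity v0 = A * k (um/s) is the tension index.

#' Construct a recoil time series
#'
#' @param time_s post-ablation frame times in seconds, strictly increasing,
#'   with t = 0 at the moment of ablation.
#' @param distance_um vertex-vertex distance at each frame (um, > 0).
#' @param L0 pre-ablation vertex distance (um).
#' @param condition,experiment,junction_id labels.
#' @return a `recoil_series` (data.frame `time_s`, `distance_um` with
#'   metadata attributes).
#' @export
recoil_series <- function(time_s, distance_um, L0,
                          condition = "control", experiment = "exp1",
                          junction_id = "j1") {
  assert_that(length(time_s) == length(distance_um),
              "time and distance lengths differ")
  assert_that(length(time_s) >= 3, "need >= 3 post-ablation points")
  assert_that(all(diff(time_s) > 0), "times must be strictly increasing")
  assert_that(all(distance_um > 0) && L0 > 0, "distances must be > 0")
  structure(data.frame(time_s = time_s, distance_um = distance_um),
            L0 = L0, condition = condition, experiment = experiment,
            junction_id = junction_id,
            class = c("recoil_series", "data.frame"))
}

#' Pointwise mean recoil curve
#'
#' Averages several recoil series (typically >= 12 ablated junctions per
#' condition) into one mean curve used for fitting. Series on different
#' frame grids are linearly interpolated onto the grid of the first series.
#'
#' @param series_list list of `recoil_series`.
#' @return a `recoil_series` whose distances are pointwise means; the number
#'   of series contributing to each time point is stored in attribute
#'   `"n_per_point"`, and `L0` is the mean of the input `L0` values.
#' @export
mean_recoil_curve <- function(series_list) {
  assert_that(is.list(series_list) && length(series_list) >= 1,
              "need at least one recoil series")
  grid <- series_list[[1]]$time_s
  mat <- vapply(series_list, function(s) {
    if (isTRUE(all.equal(s$time_s, grid))) s$distance_um
    else stats::approx(s$time_s, s$distance_um, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  L0s <- vapply(series_list, function(s) attr(s, "L0"), numeric(1))
  out <- recoil_series(grid, rowMeans(mat), L0 = mean(L0s),
                       condition = attr(series_list[[1]], "condition"),
                       experiment = attr(series_list[[1]], "experiment"),
                       junction_id = "mean")
  attr(out, "n_per_point") <- rep(length(series_list), length(grid))
  out
}

#' Fit a Kelvin-Voigt element to a recoil curve
#'
#' Nonlinear least squares for `L(t) = L0 + A (1 - exp(-k t))` with `L0`
#' fixed from the pre-ablation frame (not fitted; reduces parameter
#' correlation on short 5-point curves) and bounds `A >= 0`, `k > 0`.
#' Starting values come from the log-linearized residual
#' `log(1 - (L - L0)/A_hat)`. When the curve shows no recoil (amplitude
#' indistinguishable from zero) the fit reports `A = 0`, `v0 = 0` and flags
#' `k` as unidentifiable instead of failing.
#'
#' @param series a `recoil_series` (usually from [mean_recoil_curve()]).
#' @return a `recoil_fit` with elements `A`, `k`, `v0 = A*k`, `rss`,
#'   `converged`, `flag` plus the data; methods: `print`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @examples
#' t <- c(12, 20, 28, 36, 44)
#' s <- recoil_series(t, 10 + 1.2 * (1 - exp(-0.05 * t)), L0 = 10)
#' coef(fit_kelvin_voigt(s))
#' @export
fit_kelvin_voigt <- function(series) {
  assert_that(inherits(series, "recoil_series"), "need a recoil_series")
  t <- series$time_s
  y <- series$distance_um - attr(series, "L0")
  assert_that(length(t) >= 3, "need >= 3 post-ablation points")

  out <- list(L0 = attr(series, "L0"), data = series,
              condition = attr(series, "condition"),
              experiment = attr(series, "experiment"),
              junction_id = attr(series, "junction_id"))
  # no-recoil guard: amplitude indistinguishable from zero
  if (max(abs(y)) < 1e-12 || stats::sd(y) < 1e-12 && abs(mean(y)) < 1e-9) {
    out <- c(out, list(A = 0, k = NA_real_, v0 = 0, rss = sum(y^2),
                       converged = TRUE, flag = "k-unidentifiable"))
    class(out) <- "recoil_fit"
    return(out)
  }
  A0 <- max(y) * 1.05
  frac <- pmax(1 - y / A0, 1e-8)
  k0 <- max(-stats::coef(stats::lm(log(frac) ~ t))[["t"]], 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)),
                      start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- c(out, list(A = NA_real_, k = NA_real_, v0 = NA_real_,
                       rss = NA_real_, converged = FALSE,
                       flag = paste("non-convergence:",
                                    conditionMessage(fit))))
    class(out) <- "recoil_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out <- c(out, list(A = unname(cf["A"]), k = unname(cf["k"]),
                     v0 = unname(cf["A"] * cf["k"]),
                     rss = sum(stats::residuals(fit)^2),
                     converged = TRUE, flag = NA_character_))
  class(out) <- "recoil_fit"
  out
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat("Kelvin-Voigt recoil fit\n")
  cat(sprintf("  A  = %.4g um   k = %.4g 1/s   v0 = A*k = %.4g um/s\n",
              x$A, x$k, x$v0))
  cat(sprintf("  L0 = %.4g um   rss = %.4g   converged: %s\n",
              x$L0, x$rss, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.recoil_fit <- function(object, ...) {
  c(A = object$A, k = object$k, v0 = object$v0)
}

#' @export
predict.recoil_fit <- function(object, time_s = object$data$time_s, ...) {
  if (is.na(object$k)) return(rep(object$L0 + object$A, length(time_s)))
  object$L0 + object$A * (1 - exp(-object$k * time_s))
}

#' @export
residuals.recoil_fit <- function(object, ...) {
  object$data$distance_um - predict(object)
}

#' @export
plot.recoil_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$distance_um,
                 xlab = "time after ablation (s)",
                 ylab = "vertex distance (um)", ...)
  tt <- seq(0, max(x$data$time_s), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

#' Normalize initial recoil to same-experiment controls
#'
#' Divides each fit's initial recoil velocity by the mean control `v0` of
#' the same experiment, so control conditions average to 1 per experiment
#' and between-experiment scale offsets cancel.
#'
#' @param fits either a list of `recoil_fit` objects or a data.frame with
#'   columns `experiment`, `condition`, `v0`.
#' @param control_label condition label identifying controls.
#' @return data.frame with an added `v0_norm` column.
#' @export
normalize_initial_recoil <- function(fits, control_label = "control") {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(experiment = f$experiment, condition = f$condition,
                 junction_id = f$junction_id, v0 = f$v0,
                 stringsAsFactors = FALSE)))
  }
  normalize_to_control(fits, value_col = "v0",
                       control_label = control_label)
}
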