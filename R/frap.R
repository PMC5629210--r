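# FRAP analysis: normalization and one-phase association fitting.
#
# Acquisition design: a few pre-bleach frames (default 3), a bleach event,
# then the recovery (the reference design is 3 pre + 57 post frames at 5 s).
# F(i) is the mean of the pre-bleach frames, F(0) the first post-bleach
# value. The normalized recovery
#
#   FRAP(t) = (F(t) - F(0)) / (F(i) - F(0))
#
# is fitted to the one-phase association model with Y0 fixed at zero,
#
#   FRAP(t) = Mf * (1 - exp(-log(2) * t / t_half)),
#
# where Mf is the mobile fraction (the plateau) and t_half the half-time of
# recovery; the immobile fraction is 1 - Mf.

#' Construct a FRAP intensity series
#'
#' @param time_s frame times in seconds, strictly increasing.
#' @param intensity mean bleach-ROI intensity per frame (a.u.).
#' @param n_prebleach number of pre-bleach frames (default 3); the bleach
#'   falls between frame `n_prebleach` and `n_prebleach + 1`.
#' @param junction_id,condition,experiment labels.
#' @return a `frap_series` with attributes `F_i` (pre-bleach reference,
#'   mean of the pre-bleach frames), `F_0` (first post-bleach value) and
#'   `bleach_index`.
#' @export
frap_series <- function(time_s, intensity, n_prebleach = 3,
                        junction_id = "j1", condition = "control",
                        experiment = "exp1") {
  assert_that(length(time_s) == length(intensity),
              "time and intensity lengths differ")
  assert_that(all(diff(time_s) > 0), "times must be strictly increasing")
  assert_that(n_prebleach >= 1 && n_prebleach < length(time_s),
              "n_prebleach out of range")
  bleach_index <- n_prebleach + 1L
  structure(data.frame(time_s = time_s, intensity = intensity),
            n_prebleach = n_prebleach,
            bleach_index = bleach_index,
            F_i = mean(intensity[seq_len(n_prebleach)]),
            F_0 = intensity[bleach_index],
            junction_id = junction_id, condition = condition,
            experiment = experiment,
            class = c("frap_series", "data.frame"))
}

#' Bleach-depth quality control
#'
#' Reports the fractional bleach depth `1 - F(0)/F(i)`; the reference
#' protocol achieves over 70%, so depths below 0.7 are flagged `"warn"`.
#'
#' @param series a `frap_series`.
#' @return list(depth =, status = "pass"/"warn").
#' @export
qc_bleach_depth <- function(series) {
  assert_that(inherits(series, "frap_series"), "need a frap_series")
  depth <- 1 - attr(series, "F_0") / attr(series, "F_i")
  list(depth = depth, status = if (depth >= 0.7) "pass" else "warn")
}

#' Normalize a FRAP series
#'
#' Applies `FRAP(t) = (F(t) - F(0)) / (F(i) - F(0))` to the post-bleach
#' frames and rebases time so t = 0 at the first post-bleach frame (where
#' FRAP = 0 exactly). Full recovery to the pre-bleach level maps to 1.
#'
#' @param series a `frap_series`.
#' @param warn_depth warn when the bleach depth falls below this fraction.
#' @return a `frap_norm` data.frame (`time_s`, `frap`) with the series
#'   metadata carried along.
#' @export
normalize_frap <- function(series, warn_depth = 0.5) {
  assert_that(inherits(series, "frap_series"), "need a frap_series")
  F_i <- attr(series, "F_i"); F_0 <- attr(series, "F_0")
  if (F_i <= F_0) stopf("no bleach detected: F(i) = %g <= F(0) = %g", F_i, F_0)
  depth <- 1 - F_0 / F_i
  if (depth < warn_depth)
    warning(sprintf("bleach depth %.2f below %.2f", depth, warn_depth),
            call. = FALSE)
  idx <- seq(attr(series, "bleach_index"), nrow(series))
  t <- series$time_s[idx] - series$time_s[idx[1]]
  frap <- (series$intensity[idx] - F_0) / (F_i - F_0)
  structure(data.frame(time_s = t, frap = frap),
            F_i = F_i, F_0 = F_0, depth = depth,
            junction_id = attr(series, "junction_id"),
            condition = attr(series, "condition"),
            experiment = attr(series, "experiment"),
            class = c("frap_norm", "data.frame"))
}

#' Fit the one-phase association model to a normalized FRAP curve
#'
#' Nonlinear least squares for `FRAP(t) = Mf (1 - exp(-log(2) t / t_half))`
#' with Y0 fixed at 0, the mobile fraction Mf being the plateau. Fitted
#' values of Mf above 1.05 are flagged; a flat curve (no recovery) returns
#' `Mf = 0` with `t_half` flagged unidentifiable.
#'
#' @param norm a `frap_norm` (from [normalize_frap()]), or any data.frame
#'   with `time_s` and `frap` columns.
#' @return a `frap_fit` with `Mf`, `t_half` (s), `immobile = 1 - Mf`,
#'   `rss`, `converged`, `flag`; methods: `print`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @examples
#' t <- seq(0, by = 5, length.out = 57)
#' d <- data.frame(time_s = t, frap = 0.7 * (1 - exp(-log(2) * t / 20)))
#' coef(fit_one_phase_association(d))
#' @export
fit_one_phase_association <- function(norm) {
  t <- norm$time_s; y <- norm$frap
  assert_that(length(t) >= 10, "need >= 10 post-bleach points")
  out <- list(data = norm,
              junction_id = attr(norm, "junction_id") %||% "j1",
              condition = attr(norm, "condition") %||% "control",
              experiment = attr(norm, "experiment") %||% "exp1")
  tail_mean <- mean(y[t >= stats::quantile(t, 0.75)])
  if (max(abs(y)) < 1e-12 || tail_mean < 1e-9) {
    out <- c(out, list(Mf = 0, t_half = NA_real_, immobile = 1,
                       rss = sum(y^2), converged = TRUE,
                       flag = "t_half-unidentifiable"))
    class(out) <- "frap_fit"
    return(out)
  }
  th0 <- {
    cross <- which(y >= tail_mean / 2)[1]
    if (is.na(cross) || t[cross] <= 0) max(t) / 10 else t[cross]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Mf * (1 - exp(-log(2) * t / th)),
                      start = list(Mf = tail_mean, th = th0),
                      lower = c(Mf = 0, th = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- c(out, list(Mf = NA_real_, t_half = NA_real_, immobile = NA_real_,
                       rss = NA_real_, converged = FALSE,
                       flag = paste("non-convergence:",
                                    conditionMessage(fit))))
    class(out) <- "frap_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  flag <- if (cf["Mf"] > 1.05) "Mf-above-1" else NA_character_
  out <- c(out, list(Mf = unname(cf["Mf"]), t_half = unname(cf["th"]),
                     immobile = 1 - unname(cf["Mf"]),
                     rss = sum(stats::residuals(fit)^2),
                     converged = TRUE, flag = flag))
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP one-phase association fit\n")
  cat(sprintf("  Mf = %.4g   t1/2 = %.4g s   immobile = %.4g\n",
              x$Mf, x$t_half, x$immobile))
  cat(sprintf("  rss = %.4g   converged: %s\n", x$rss, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(Mf = object$Mf, t_half = object$t_half, immobile = object$immobile)
}

#' @export
predict.frap_fit <- function(object, time_s = object$data$time_s, ...) {
  if (is.na(object$t_half)) return(rep(object$Mf, length(time_s)))
  object$Mf * (1 - exp(-log(2) * time_s / object$t_half))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$frap - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$frap,
                 xlab = "time after bleach (s)", ylab = "FRAP", ...)
  tt <- seq(0, max(x$data$time_s), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2)
  graphics::abline(h = x$Mf, lty = 2)
  invisible(x)
}
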