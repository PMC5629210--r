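test_that("apical max-projection takes the pixelwise maximum", {
  plane <- matrix(runif(64), 8, 8)
  st <- calibrated_image(array(rep(plane, 4), dim = c(8, 8, 4)), 0.2,
                         z_spacing_um = 0.19)
  expect_equal(unclass(max_project_apical(st)), plane,
               ignore_attr = TRUE)
  st2 <- calibrated_image(array(c(1, 5, 3), dim = c(1, 1, 3)), 0.2)
  expect_equal(as.numeric(unclass(max_project_apical(st2))), 5)
  expect_error(max_project_apical(
    calibrated_image(array(0, dim = c(4, 4, 2)), 0.2)), "2 plane")
})

test_that("projection of a stack keeps the brightest plane's band", {
  g <- gen_junction_image(n_planes = 3, plane_weights = c(0.6, 1, 0.8),
                          amplitude = 400, background = 50, seed = 2)
  proj <- max_project_apical(g$image)
  m <- gaussian_peak(extract_line_scan(proj, g$roi))
  expect_equal(m$value, 400, tolerance = 1e-6)
})

test_that("line scans are flat on uniform images and centered on bands", {
  img <- calibrated_image(matrix(7, 128, 128), 0.2)
  roi <- cbind(x = 64, y = c(20, 108))
  pr <- extract_line_scan(img, roi)
  expect_true(all(pr$intensity == 7))
  expect_equal(nrow(pr), 101)  # 20 um at 0.2 um/px, centered
  g <- gen_junction_image(seed = 5)
  pk <- gaussian_peak(extract_line_scan(g$image, g$roi))
  expect_lt(abs(pk$fit[["mu"]]), 0.2)  # within 1 px of the junction
  expect_error(extract_line_scan(img, cbind(x = 2, y = c(20, 108))),
               "bounds")
  expect_error(extract_line_scan(img, cbind(x = c(64, 64), y = c(50, 50))),
               "zero-length")
})

test_that("line scans are rotation-equivariant within 2%", {
  g0 <- gen_junction_image(amplitude = 500, seed = 6)
  g37 <- gen_junction_image(amplitude = 500, angle_deg = 37, seed = 6)
  a0 <- gaussian_peak(extract_line_scan(g0$image, g0$roi))$value
  a37 <- gaussian_peak(extract_line_scan(g37$image, g37$roi))$value
  expect_lt(abs(a37 - a0) / a0, 0.02)
})

test_that("gaussian peak fits amplitude over baseline", {
  gauss <- function(x) 500 * exp(-x^2 / (2 * 0.8^2)) + 100
  pr <- make_profile(gauss)
  m <- gaussian_peak(pr)
  expect_equal(m$value, 500, tolerance = 1e-6)
  expect_equal(m$fit[["baseline"]], 100, tolerance = 1e-6)
  expect_equal(m$fit[["sigma"]], 0.8, tolerance = 1e-6)
  # windowed background: mean over the 5-px windows past 10 px either side
  bg_x <- c(-(15:11), 11:15) * 0.2
  expect_equal(m$background, mean(gauss(bg_x)), tolerance = 1e-9)
  flat <- make_profile(function(x) rep(100, length(x)))
  mf <- gaussian_peak(flat)
  expect_equal(mf$value, 0)
  expect_identical(mf$flag, "no-peak")
})

test_that("gaussian peak recovers amplitude under Poisson noise", {
  for (amp in c(200, 500, 1000)) {
    errs <- sapply(1:15, function(i) {
      g <- gen_junction_image(amplitude = amp, background = 100,
                              poisson_noise = TRUE, seed = 100 * amp + i)
      m <- gaussian_peak(extract_line_scan(g$image, g$roi))
      abs(m$value - amp) / amp
    })
    expect_lt(median(errs), 0.05)
  }
})

test_that("band AUC sums background-subtracted band mass", {
  # rectangular band of height h over 21 px, zero background
  h <- 40
  pr <- make_profile(function(x) ifelse(abs(x) <= 10 * 0.2 + 1e-9, h, 0))
  m <- band_auc(pr, centers_um = 0)
  expect_equal(m$value, 21 * h, tolerance = 1e-9)
  flat <- make_profile(function(x) rep(55, length(x)))
  expect_equal(band_auc(flat)$value, 0, tolerance = 1e-9)
  g <- gen_junction_image(two_band = TRUE, amplitude = 300,
                          background = 80, seed = 9)
  pr2 <- extract_line_scan(g$image, g$roi)
  a <- band_auc(pr2)
  expect_equal(a$value, g$truth$band_mass_per_scan, tolerance = 0.05)
  expect_length(a$centers_um, 2)
})

test_that("coloc reads the target at the reference peak", {
  pr <- make_profile(function(x) 400 * exp(-x^2 / (2 * 0.6^2)) + 50)
  same <- coloc_at_reference_peak(pr, pr)
  # windowed background picks up a trace of Gaussian tail (~1e-4 relative)
  expect_equal(same$ratio, 1, tolerance = 1e-3)
  zero <- make_profile(function(x) rep(0, length(x)))
  z <- coloc_at_reference_peak(zero, pr)
  expect_equal(z$value, 0, tolerance = 1e-9)
  expect_equal(z$ratio, 0, tolerance = 1e-9)
  g <- gen_junction_image(coloc_ratio = 0.4, poisson_noise = TRUE, seed = 12)
  cc <- coloc_at_reference_peak(extract_line_scan(g$coloc_image, g$roi),
                                extract_line_scan(g$image, g$roi))
  expect_equal(cc$ratio, 0.4, tolerance = 0.05)
  expect_error(coloc_at_reference_peak(pr, zero), "no usable peak")
})

test_that("junction/cytoplasm ratio matches exact masks", {
  img <- calibrated_image(matrix(100, 64, 64), 0.2)
  mask <- matrix(FALSE, 64, 64); mask[, 50:60] <- TRUE
  poly <- cbind(x = 20, y = c(5, 60))
  expect_equal(junction_cytoplasm_ratio(img, poly, mask)$value, 1)
  dat <- matrix(100, 64, 64); dat[, 10:30] <- 300
  img2 <- calibrated_image(dat, 0.2)
  r <- junction_cytoplasm_ratio(img2, poly, mask)
  expect_equal(r$value, 3)
  expect_error(junction_cytoplasm_ratio(img, poly, matrix(FALSE, 64, 64)),
               "empty")
  overlap <- matrix(FALSE, 64, 64); overlap[, 15:25] <- TRUE
  expect_error(junction_cytoplasm_ratio(img, poly, overlap), "overlap")
})

test_that("generator-set enrichment is recovered within 5%", {
  E <- 2.6
  g <- gen_junction_image(size_px = 96, amplitude = 0, background = 100,
                          seed = 4)
  dat <- unclass(g$image)
  # flat junction band at E * background, 20 px wide around the junction
  ctr <- 48
  dat[, (ctr - 10):(ctr + 10)] <- E * 100
  img <- calibrated_image(dat, 0.2)
  mask <- matrix(FALSE, 96, 96); mask[, 75:92] <- TRUE
  poly <- cbind(x = ctr, y = c(3, 93))
  r <- junction_cytoplasm_ratio(img, poly, mask, band_width_px = 20)
  expect_equal(r$value, E, tolerance = 0.05)
})

test_that("profile measures are linear in intensity, the ratio scale-free", {
  g <- gen_junction_image(two_band = FALSE, amplitude = 350,
                          background = 90, seed = 15)
  pr <- extract_line_scan(g$image, g$roi)
  scaled <- pr; scaled$intensity <- 3 * pr$intensity
  expect_equal(gaussian_peak(scaled)$value, 3 * gaussian_peak(pr)$value,
               tolerance = 1e-6)
  g2 <- gen_junction_image(two_band = TRUE, seed = 16)
  pr2 <- extract_line_scan(g2$image, g2$roi)
  s2 <- pr2; s2$intensity <- 3 * pr2$intensity
  expect_equal(band_auc(s2)$value, 3 * band_auc(pr2)$value,
               tolerance = 1e-9)
  dat <- matrix(100, 64, 64); dat[, 10:30] <- 300
  mask <- matrix(FALSE, 64, 64); mask[, 50:60] <- TRUE
  poly <- cbind(x = 20, y = c(5, 60))
  r1 <- junction_cytoplasm_ratio(calibrated_image(dat, 0.2), poly, mask)
  r3 <- junction_cytoplasm_ratio(calibrated_image(3 * dat, 0.2), poly, mask)
  expect_equal(r1$value, r3$value)
})

test_that("a constant offset is fully removed by the background rule", {
  pr <- make_profile(function(x) 500 * exp(-x^2 / (2 * 0.8^2)))
  off <- pr; off$intensity <- pr$intensity + 77
  expect_equal(gaussian_peak(off)$value, gaussian_peak(pr)$value,
               tolerance = 1e-5)
  two <- make_profile(function(x)
    300 * (exp(-(x - 1)^2 / 0.5) + exp(-(x + 1)^2 / 0.5)))
  two_off <- two; two_off$intensity <- two$intensity + 77
  expect_equal(band_auc(two_off)$value, band_auc(two)$value,
               tolerance = 1e-6)
})

test_that("summaries refuse undersampled batches unless forced", {
  df <- data.frame(experiment = "e1", condition = "control",
                   value = rnorm(24, 100))
  expect_error(junction_summary(df, "IF"), "25")
  expect_silent(junction_summary(df, "IF", force = TRUE))
  df59 <- data.frame(experiment = "e1", condition = "control",
                     value = rnorm(59, 2))
  expect_error(junction_summary(df59, "AHPH"), "60")
  df60 <- data.frame(experiment = "e1", condition = "control",
                     value = rnorm(60, 2))
  out <- junction_summary(df60, "AHPH")
  expect_equal(out$n, 60L)
})

test_that("condition means normalize to same-experiment controls", {
  df <- data.frame(experiment = rep(c("e1", "e2", "e3"), each = 2),
                   condition = rep(c("control", "kd"), 3),
                   value = c(10, 5, 40, 20, 2, 1))
  out <- normalize_to_control(df, "value")
  expect_equal(out$value_norm, rep(c(1, 0.5), 3))
})
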