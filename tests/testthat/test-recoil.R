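frame_t <- c(12, 20, 28, 36, 44)

test_that("mean recoil curve averages pointwise", {
  s <- recoil_series(frame_t, rep(1, 5), L0 = 1)
  m <- mean_recoil_curve(list(s, s))
  expect_equal(m$distance_um, s$distance_um)
  s1 <- recoil_series(frame_t, rep(1, 5), L0 = 1)
  s3 <- recoil_series(frame_t, rep(3, 5), L0 = 3)
  expect_equal(mean_recoil_curve(list(s1, s3))$distance_um, rep(2, 5))
  expect_error(mean_recoil_curve(list()), "at least one")
})

test_that("averaging 12 junctions shrinks pointwise noise ~ 1/sqrt(12)", {
  single_sd <- sapply(1:200, function(i)
    gen_recoil(n_junctions = 1, sigma = 0.05,
               seed = i)$series[[1]]$distance_um[3])
  mean_sd <- sapply(1:200, function(i) {
    g <- gen_recoil(n_junctions = 12, sigma = 0.05, seed = 1000 + i)
    mean_recoil_curve(g$series)$distance_um[3]
  })
  ratio <- sd(mean_sd) / sd(single_sd)
  expect_equal(ratio, 1 / sqrt(12), tolerance = 0.25)
})

test_that("noiseless Kelvin-Voigt curves are recovered exactly", {
  for (A in c(0.1, 0.5, 1.2, 5)) {
    for (k in c(0.01, 0.05, 0.2, 0.5)) {
      L <- 10 + A * (1 - exp(-k * frame_t))
      f <- fit_kelvin_voigt(recoil_series(frame_t, L, L0 = 10))
      expect_lt(abs(f$A - A) / A, 1e-6)
      expect_lt(abs(f$k - k) / k, 1e-6)
      expect_lt(abs(f$v0 - A * k) / (A * k), 1e-6)
    }
  }
})

test_that("v0 equals A * k for every fit", {
  for (seed in 1:20) {
    g <- gen_recoil(n_junctions = 1, sigma = 0.08, seed = seed)
    f <- fit_kelvin_voigt(g$series[[1]])
    expect_identical(f$v0, f$A * f$k)
  }
})

test_that("a flat curve reports no recoil with k flagged", {
  f <- fit_kelvin_voigt(recoil_series(frame_t, rep(10, 5), L0 = 10))
  expect_equal(f$A, 0)
  expect_equal(f$v0, 0)
  expect_true(is.na(f$k))
  expect_identical(f$flag, "k-unidentifiable")
})

test_that("fit is invariant to translating all distances", {
  g <- gen_recoil(n_junctions = 1, sigma = 0.03, seed = 11)
  s <- g$series[[1]]
  f1 <- fit_kelvin_voigt(s)
  s2 <- recoil_series(s$time_s, s$distance_um + 5, L0 = attr(s, "L0") + 5)
  f2 <- fit_kelvin_voigt(s2)
  expect_equal(f1$A, f2$A, tolerance = 1e-9)
  expect_equal(f1$k, f2$k, tolerance = 1e-9)
})

test_that("median v0 error of 12-junction mean-curve fits is below 10%", {
  errs <- sapply(1:200, function(i) {
    g <- gen_recoil(n_junctions = 12, sigma = 0.05, seed = i)
    f <- fit_kelvin_voigt(mean_recoil_curve(g$series))
    abs(f$v0 - 0.06) / 0.06
  })
  expect_lt(median(errs), 0.10)
})

test_that("k is separable from amplitude changes", {
  # only A differs between conditions: fitted k statistically unchanged,
  # v0 tracks A
  fits_ctrl <- sapply(1:40, function(i)
    coef(fit_kelvin_voigt(mean_recoil_curve(
      gen_recoil(A = 1.2, k = 0.05, sigma = 0.03, seed = i)$series))))
  fits_low <- sapply(1:40, function(i)
    coef(fit_kelvin_voigt(mean_recoil_curve(
      gen_recoil(A = 0.6, k = 0.05, sigma = 0.03, seed = 500 + i)$series))))
  expect_gt(t.test(fits_ctrl["k", ], fits_low["k", ])$p.value, 0.01)
  expect_equal(median(fits_low["v0", ]) / median(fits_ctrl["v0", ]), 0.5,
               tolerance = 0.1)
})

test_that("control normalization is per experiment and removes offsets", {
  tab <- data.frame(experiment = "e1",
                    condition = c("control", "kd"),
                    v0 = c(0.06, 0.03))
  out <- normalize_initial_recoil(tab)
  expect_equal(out$v0_norm, c(1, 0.5))
  tab$v0 <- c(0.04, 0.04)
  expect_equal(normalize_initial_recoil(tab)$v0_norm, c(1, 1))
  # experiment-level multiplicative offsets cancel
  offs <- c(e1 = 1, e2 = 2.5, e3 = 0.4)
  tab3 <- expand.grid(experiment = names(offs),
                      condition = c("control", "kd"),
                      stringsAsFactors = FALSE)
  tab3$v0 <- ifelse(tab3$condition == "control", 0.06, 0.03) *
    offs[tab3$experiment]
  out3 <- normalize_initial_recoil(tab3)
  ctrl <- out3$v0_norm[out3$condition == "control"]
  expect_equal(sd(ctrl), 0)
  expect_equal(unique(out3$v0_norm[out3$condition == "kd"]), 0.5)
  # missing control names the experiment
  expect_error(normalize_initial_recoil(
    data.frame(experiment = "e9", condition = "kd", v0 = 1)), "e9")
})
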