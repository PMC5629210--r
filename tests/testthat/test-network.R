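test_that("default model has the published architecture", {
  m <- build_default_model()
  expect_length(m$nodes, 6)
  expect_setequal(m$nodes, c("RhoA", "ROCK1", "NMIIA", "Rnd3", "p190B",
                             "SRGAP1"))
  has_edge <- function(s, t, sg) any(m$edges$source == s &
                                       m$edges$target == t &
                                       m$edges$sign == sg)
  expect_true(has_edge("SRGAP1", "RhoA", "repression"))
  expect_true(has_edge("RhoA", "ROCK1", "stimulation"))
  expect_true(has_edge("ROCK1", "NMIIA", "stimulation"))
  expect_true(has_edge("NMIIA", "ROCK1", "stimulation"))
  expect_true(has_edge("ROCK1", "Rnd3", "repression"))
  expect_true(has_edge("Rnd3", "p190B", "stimulation"))
  expect_true(has_edge("p190B", "RhoA", "repression"))
  expect_true(all(m$edges$strength > 0) && all(m$edges$K > 0) &&
                all(m$edges$hill > 0))
  expect_identical(m$forcing, list(t_ramp = 200, rate = 0.0075))
})

test_that("model construction validates topology and parameters", {
  edges <- data.frame(source = "A", target = "B", sign = "stimulation",
                      strength = 1, K = 0.5, hill = 2)
  expect_error(srgap_network(c("A"), edges, c(A = 0), c(A = 1)),
               "not declared")
  expect_error(srgap_network(c("A", "B"), rbind(edges, edges),
                             c(A = 0, B = 0), c(A = 1, B = 1)),
               "duplicate")
  edges$strength <- -1
  expect_error(srgap_network(c("A", "B"), edges, c(A = 0, B = 0),
                             c(A = 1, B = 1)), "> 0")
})

test_that("uncoupled species decay exponentially", {
  m <- uncoupled_model(c("A", "B"))
  tr <- simulate_network(m, c(A = 1, B = 1), t_end = 5, dt_out = 0.5)
  expect_equal(tr$A, exp(-tr$time), tolerance = 1e-7)
  expect_equal(tr$B, exp(-tr$time), tolerance = 1e-7)
})

test_that("simulation validates inputs and stays non-negative", {
  m <- build_default_model()
  expect_error(simulate_network(m, c(RhoA = 1), t_end = 10), "missing node")
  tr <- simulate_network(m, t_end = 400)
  expect_true(all(as.matrix(tr[m$nodes]) >= 0))
})

test_that("trajectory is independent of the output grid density", {
  m <- build_default_model()
  t1 <- simulate_network(m, t_end = 300, dt_out = 1, forcing = NULL)
  t5 <- simulate_network(m, t_end = 300, dt_out = 5, forcing = NULL)
  shared <- intersect(t1$time, t5$time)
  expect_equal(t1$RhoA[match(shared, t1$time)],
               t5$RhoA[match(shared, t5$time)], tolerance = 1e-6)
})

test_that("integrated steady state matches a damped root-search oracle", {
  m <- build_default_model()
  tr <- simulate_network(m, t_end = 2000, dt_out = 2000, forcing = NULL)
  integrated <- setNames(as.numeric(tr[nrow(tr), -1]), m$nodes)
  # damped fixed-point iteration x <- x + lambda * f(x) from the same basin
  f <- oracle_rhs(m)
  x <- setNames(rep(1, 6), m$nodes); x["SRGAP1"] <- 0
  for (i in 1:20000) {
    step <- f(x)
    x <- pmax(x + 0.2 * step, 0)
    if (sqrt(sum(step^2)) < 1e-13) break
  }
  expect_lt(max(abs(integrated - x) / pmax(abs(x), 1e-12)), 1e-6)
})

test_that("SRGAP1-free model is bistable with verified stable states", {
  m <- build_default_model()
  states <- bistability_scan(m)
  expect_equal(nrow(states), 2)
  expect_gt(states$RhoA[1], states$RhoA[2])  # sorted by RhoA
  # active state: RhoA/NMIIA high, antagonists suppressed
  expect_gt(states$NMIIA[1], states$NMIIA[2])
  expect_lt(states$Rnd3[1], states$Rnd3[2])
  expect_lt(states$p190B[1], states$p190B[2])
  f <- oracle_rhs(m)
  dyn <- setdiff(m$nodes, "SRGAP1")
  for (i in 1:2) {
    x <- setNames(as.numeric(states[i, m$nodes]), m$nodes)
    expect_lt(sqrt(sum(f(x)^2)), 1e-8)
    J <- oracle_jacobian(function(v) {
      y <- x; y[dyn] <- v; unname(f(y)[dyn])
    }, unname(x[dyn]))
    expect_true(all(Re(eigen(J, only.values = TRUE)$values) < 0))
  }
  # the all-ones initial condition lands in the high-RhoA basin
  hi <- simulate_network(m, t_end = 1000, dt_out = 1000, forcing = NULL)
  expect_equal(hi$RhoA[nrow(hi)], states$RhoA[1], tolerance = 1e-4)
})

test_that("interaction-free network has a single basal/removal fixed point", {
  m <- uncoupled_model(c("RhoA", "X"), basal = 0.6, removal = 2)
  states <- bistability_scan(m, levels = c(0.05, 1, 3))
  expect_equal(nrow(states), 1)
  expect_equal(as.numeric(states[1, c("RhoA", "X")]), c(0.3, 0.3),
               tolerance = 1e-6)
})

test_that("regime classification handles constant and ramp trajectories", {
  expect_error(classify_regime(data.frame(time = 0, RhoA = 1), 0.2, 0.9),
               "exceed")
  tr_hi <- data.frame(time = 0:10, RhoA = rep(1, 11))
  expect_true(all(classify_regime(tr_hi, 1, 0.1)$labels == "active-tuned"))
  tr_lo <- data.frame(time = 0:10, RhoA = rep(0.1, 11))
  expect_true(all(classify_regime(tr_lo, 1, 0.1)$labels ==
                    "switched-inactive"))
  res <- srgap1_ramp_experiment(build_default_model())
  r <- rle(res$report$labels)
  expect_identical(r$values, c("active-tuned", "switched-inactive"))
})

test_that("ramp produces monotone RhoA decline then a positive switch", {
  m <- build_default_model()
  res <- srgap1_ramp_experiment(m)
  rep <- res$report
  expect_gt(rep$switch_srgap1, 0)
  tr <- res$trajectory
  pre <- tr$RhoA[tr$time >= m$forcing$t_ramp & tr$time <= rep$switch_time]
  expect_true(all(diff(pre) <= 1e-6))
})

test_that("zero ramp slope reproduces the unforced simulation", {
  m <- build_default_model(ramp_rate = 0)
  res <- srgap1_ramp_experiment(m, t_end = 400)
  plain <- simulate_network(m, t_end = 400, forcing = NULL)
  expect_equal(res$trajectory$RhoA, plain$RhoA, tolerance = 1e-9)
  expect_true(all(res$report$labels == "active-tuned"))
})

test_that("frozen-SRGAP1 sweep shows hysteresis around the switch", {
  m <- build_default_model()
  sw <- bistable_switch_levels(m)
  expect_gt(sw$down, 0)
  expect_gte(sw$down, sw$up)
  # bisection oracle: just below the switch the active branch persists,
  # just above it the network falls to the inactive branch
  hi0 <- simulate_network(m, t_end = 1000, dt_out = 1000, forcing = NULL)
  hi0 <- setNames(as.numeric(hi0[nrow(hi0), -1]), m$nodes)
  freeze <- function(s) {
    init <- hi0; init["SRGAP1"] <- s
    tr <- simulate_network(m, init, t_end = 3000, dt_out = 3000,
                           forcing = NULL)
    tr$RhoA[nrow(tr)]
  }
  states <- bistability_scan(m)
  mid <- mean(states$RhoA)
  expect_gt(freeze(sw$down - 0.02), mid)
  expect_lt(freeze(sw$down + 0.02), mid)
})

test_that("halving solver tolerance moves the switch time by < 1%", {
  m <- build_default_model()
  t1 <- srgap1_ramp_experiment(m)$report$switch_time
  t2 <- srgap1_ramp_experiment(m, rtol = 5e-9, atol = 5e-11)$report$switch_time
  expect_lt(abs(t1 - t2) / t1, 0.01)
})
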