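# Junctional RhoA-NMII signaling network with SRGAP1 as orthogonal antagonist.
#
# The model is a system of pairwise stimulators/repressors of junctional
# localization: each dynamic species X_i follows
#
#   dX_i/dt = basal_i + sum_stimulators w * H(X_j)
#             - X_i * ( removal_i + sum_repressors w * H(X_j) )
#
# with a saturating Hill response H(x) = x^n / (K^n + x^n). Repression acts
# multiplicatively on first-order removal, so non-negative initial conditions
# stay non-negative. SRGAP1 is exogenous: it is never produced by the network
# and either stays at its initial value or follows a linear ramp schedule.

#' Construct a junctional signaling network model
#'
#' Builds a network of pairwise stimulation/repression interactions among
#' junctional species. Species abundances are dimensionless junctional
#' amounts (localized = active); time is in dimensionless model units.
#'
#' @param nodes character vector of species names.
#' @param edges data.frame with columns `source`, `target`,
#'   `sign` (`"stimulation"` or `"repression"`), `strength`, `K`, `hill`.
#' @param basal named numeric vector of basal production rates (>= 0).
#' @param removal named numeric vector of first-order removal rates (> 0).
#' @param exogenous name of the externally forced species (no production or
#'   removal dynamics of its own), or `NULL`.
#' @param forcing list with `t_ramp` (ramp start time) and `rate`
#'   (linear increase per time unit) applied to the exogenous species,
#'   or `NULL` for no forcing.
#' @return an object of class `srgap_network`.
#' @seealso [build_default_model()], [simulate_network()]
#' @export
srgap_network <- function(nodes, edges, basal, removal,
                          exogenous = NULL, forcing = NULL) {
  nodes <- as.character(nodes)
  assert_that(!anyDuplicated(nodes), "duplicate node names")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "sign", "strength", "K", "hill")
  assert_that(all(req %in% names(edges)),
              paste("edges must have columns:", paste(req, collapse = ", ")))
  bad <- setdiff(c(edges$source, edges$target), nodes)
  if (length(bad)) stopf("edge endpoint(s) not declared as nodes: %s",
                         paste(unique(bad), collapse = ", "))
  if (anyDuplicated(edges[c("source", "target")]))
    stopf("duplicate (source, target) edge")
  assert_that(all(edges$sign %in% c("stimulation", "repression")),
              "edge sign must be 'stimulation' or 'repression'")
  assert_that(all(edges$strength > 0) && all(edges$K > 0) &&
                all(edges$hill > 0), "edge parameters must be > 0")
  basal <- basal[nodes]; removal <- removal[nodes]
  assert_that(!anyNA(basal) && !anyNA(removal),
              "basal and removal must be named for every node")
  assert_that(all(basal >= 0), "basal rates must be >= 0")
  dyn <- setdiff(nodes, exogenous)
  assert_that(all(removal[dyn] > 0), "removal rates must be > 0")
  if (!is.null(exogenous))
    assert_that(exogenous %in% nodes, "exogenous species must be a node")
  if (!is.null(forcing)) {
    assert_that(is.list(forcing) && all(c("t_ramp", "rate") %in% names(forcing)),
                "forcing must be list(t_ramp=, rate=)")
    assert_that(forcing$rate >= 0 && forcing$t_ramp >= 0,
                "forcing schedule values must be non-negative")
  }
  structure(list(nodes = nodes, edges = edges, basal = basal,
                 removal = removal, exogenous = exogenous,
                 forcing = forcing),
            class = "srgap_network")
}

#' Default six-node SRGAP1/RhoA network
#'
#' The default architecture couples a positive feedback loop
#' (RhoA -> ROCK1 -> NMIIA -> ROCK1, the cortical-anchoring loop) to a
#' double-negative branch (ROCK1 -| Rnd3 -> p190B -| RhoA), which together
#' make the SRGAP1-free subnetwork bistable: one state with RhoA/ROCK1/NMIIA
#' high and Rnd3/p190B suppressed, and one with the antagonists dominant.
#' SRGAP1 represses RhoA orthogonally to this feedback and is treated as an
#' exogenous species whose level is set by a forcing schedule
#' (default: constant until t = 200, then +0.0075 per time unit).
#'
#' The parameter set is a documented default chosen so that the SRGAP1-free
#' subnetwork is bistable and the ramp produces a graded decline followed by
#' a switch; all values can be overridden by constructing the model directly
#' or via a JSON config ([read_network_config()]).
#'
#' @param t_ramp ramp start time (model time units).
#' @param ramp_rate linear SRGAP1 increase per time unit.
#' @return an `srgap_network` object.
#' @examples
#' m <- build_default_model()
#' print(m)
#' @export
build_default_model <- function(t_ramp = 200, ramp_rate = 0.0075) {
  nodes <- c("RhoA", "ROCK1", "NMIIA", "Rnd3", "p190B", "SRGAP1")
  edges <- data.frame(
    source = c("RhoA", "NMIIA", "ROCK1", "ROCK1", "Rnd3", "p190B", "SRGAP1"),
    target = c("ROCK1", "ROCK1", "NMIIA", "Rnd3", "p190B", "RhoA", "RhoA"),
    sign = c("stimulation", "stimulation", "stimulation", "repression",
             "stimulation", "repression", "repression"),
    strength = c(1.0, 0.35, 1.5, 8, 1.5, 5, 5),
    K = c(0.85, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5), hill = 4,
    stringsAsFactors = FALSE)
  basal <- c(RhoA = 1, ROCK1 = 0.05, NMIIA = 0.05, Rnd3 = 1,
             p190B = 0.05, SRGAP1 = 0)
  removal <- c(RhoA = 1, ROCK1 = 1, NMIIA = 1, Rnd3 = 1, p190B = 1,
               SRGAP1 = 0)
  srgap_network(nodes, edges, basal, removal, exogenous = "SRGAP1",
                forcing = list(t_ramp = t_ramp, rate = ramp_rate))
}

#' @export
print.srgap_network <- function(x, ...) {
  cat("Junctional signaling network:", length(x$nodes), "species\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  arrows <- ifelse(x$edges$sign == "stimulation", "->", "-|")
  cat("  edges:\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("    %s %s %s  (w=%g, K=%g, n=%g)\n",
                x$edges$source[i], arrows[i], x$edges$target[i],
                x$edges$strength[i], x$edges$K[i], x$edges$hill[i]))
  if (!is.null(x$exogenous))
    cat("  exogenous:", x$exogenous,
        if (!is.null(x$forcing))
          sprintf(" (ramp +%g/t from t=%g)", x$forcing$rate, x$forcing$t_ramp)
        else "", "\n")
  invisible(x)
}

hill_response <- function(x, K, n) {
  x <- pmax(x, 0)
  xn <- x^n
  xn / (K^n + xn)
}

# Right-hand side of the network ODE at state x (named), with the exogenous
# species' derivative set by `exo_rate`.
network_rhs <- function(model, x, exo_rate = 0) {
  e <- model$edges
  act <- hill_response(x[e$source], e$K, e$hill) * e$strength
  dx <- model$basal - x * model$removal
  for (i in seq_len(nrow(e))) {
    tgt <- e$target[i]
    if (e$sign[i] == "stimulation") dx[tgt] <- dx[tgt] + act[i]
    else dx[tgt] <- dx[tgt] - x[tgt] * act[i]
  }
  if (!is.null(model$exogenous)) dx[model$exogenous] <- exo_rate
  dx
}

#' Simulate the network ODE
#'
#' Deterministic integration with a stiff-capable adaptive solver
#' (\code{deSolve::ode}, method \code{lsoda}). The exogenous species follows
#' its forcing schedule exactly: constant before `t_ramp`, linear increase at
#' `rate` per time unit afterwards. Integration is split at the ramp onset so
#' the derivative discontinuity never degrades accuracy.
#'
#' @param model an `srgap_network`.
#' @param init named numeric vector covering every node (values >= 0).
#' @param t_end end time (> 0).
#' @param dt_out output grid spacing (results are solver-grid independent up
#'   to tolerance).
#' @param rtol,atol solver tolerances.
#' @param forcing override the model's forcing schedule (`NULL` disables it).
#' @return a `network_trajectory`: data.frame with `time` plus one column per
#'   node, with the applied forcing recorded as an attribute.
#' @examples
#' m <- build_default_model()
#' tr <- simulate_network(m, t_end = 300, forcing = NULL)
#' tail(tr, 1)
#' @export
simulate_network <- function(model, init = NULL, t_end, dt_out = 1,
                             rtol = 1e-8, atol = 1e-10,
                             forcing = model$forcing) {
  assert_that(t_end > 0, "t_end must be > 0")
  if (is.null(init)) {
    init <- stats::setNames(rep(1, length(model$nodes)), model$nodes)
    if (!is.null(model$exogenous)) init[model$exogenous] <- 0
  }
  missing <- setdiff(model$nodes, names(init))
  if (length(missing))
    stopf("initial state missing node(s): %s", paste(missing, collapse = ", "))
  init <- init[model$nodes]
  assert_that(all(init >= 0), "initial concentrations must be >= 0")

  ramp_active <- !is.null(forcing) && !is.null(model$exogenous) &&
    forcing$rate > 0 && forcing$t_ramp < t_end
  legs <- if (ramp_active && forcing$t_ramp > 0) {
    list(c(0, forcing$t_ramp, 0), c(forcing$t_ramp, t_end, forcing$rate))
  } else if (ramp_active) {
    list(c(0, t_end, forcing$rate))
  } else {
    list(c(0, t_end, 0))
  }

  pieces <- list()
  state <- init
  for (leg in legs) {
    times <- unique(c(seq(leg[1], leg[2], by = dt_out), leg[2]))
    rate <- leg[3]
    fn <- function(t, y, parms) {
      names(y) <- model$nodes
      list(unname(network_rhs(model, y, exo_rate = rate)))
    }
    out <- deSolve::ode(y = unname(state), times = times, func = fn,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    out <- as.data.frame(out)
    names(out) <- c("time", model$nodes)
    if (anyNA(out) || any(!is.finite(as.matrix(out))))
      stopf("integration failure: non-finite state near t = %g",
            out$time[which(!stats::complete.cases(out))[1]])
    state <- stats::setNames(as.numeric(out[nrow(out), -1]), model$nodes)
    pieces[[length(pieces) + 1]] <- out
  }
  traj <- do.call(rbind, pieces)
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  rownames(traj) <- NULL
  # tolerate tiny solver undershoot; genuine negativity is an error
  vals <- as.matrix(traj[model$nodes])
  if (any(vals < -1e-8))
    stopf("integration failure: negative concentration near t = %g",
          traj$time[which(apply(vals < -1e-8, 1, any))[1]])
  traj[model$nodes] <- pmax(vals, 0)
  structure(traj,
            forcing = if (ramp_active) forcing else NULL,
            model = model,
            class = c("network_trajectory", "data.frame"))
}

#' @export
plot.network_trajectory <- function(x, nodes = NULL, ...) {
  model <- attr(x, "model")
  nodes <- nodes %||% model$nodes
  graphics::matplot(x$time, as.matrix(x[nodes]), type = "l", lty = 1,
                    xlab = "time (model units)",
                    ylab = "junctional concentration", ...)
  graphics::legend("topright", legend = nodes, col = seq_along(nodes),
                   lty = 1, bty = "n")
  invisible(x)
}

# Integrate to equilibrium: chunked integration until ||RHS|| < tol or t_max.
# Returns list(state, converged, t).
integrate_to_steady <- function(model, init, srgap1 = NULL, tol = 1e-9,
                                t_max = 1e5, chunk = 500) {
  state <- init[model$nodes]
  if (!is.null(srgap1) && !is.null(model$exogenous))
    state[model$exogenous] <- srgap1
  t <- 0
  repeat {
    tr <- simulate_network(model, state, t_end = chunk, dt_out = chunk,
                           forcing = NULL)
    state <- stats::setNames(as.numeric(tr[nrow(tr), -1]), model$nodes)
    t <- t + chunk
    rhs <- network_rhs(model, state, exo_rate = 0)
    if (sqrt(sum(rhs^2)) < tol) return(list(state = state, converged = TRUE, t = t))
    if (t >= t_max) return(list(state = state, converged = FALSE, t = t))
  }
}

#' Scan initial conditions for stable fixed points
#'
#' Holds the exogenous species (SRGAP1) at a fixed level, integrates the
#' network to equilibrium from a grid of initial conditions, clusters the
#' endpoints by proximity (tolerance 1e-4 in state space) and returns the
#' distinct stable states sorted by descending RhoA level. Stability is
#' verified through the eigenvalues of a finite-difference Jacobian.
#'
#' @param model an `srgap_network`.
#' @param srgap1 frozen SRGAP1 level (default 0).
#' @param init_grid matrix of initial states (one row per start, columns =
#'   dynamic nodes); default: all corner combinations of `levels` per node.
#' @param levels values combined per dynamic node for the default grid.
#' @param cluster_tol proximity tolerance for merging endpoints.
#' @return data.frame of stable states (one row per state, columns = nodes,
#'   plus `n_basin` counting starts that converged there), with non-converged
#'   starts recorded in attribute `"flagged"`.
#' @examples
#' \donttest{
#' states <- bistability_scan(build_default_model())
#' nrow(states)  # 2: bistable
#' }
#' @export
bistability_scan <- function(model, srgap1 = 0, init_grid = NULL,
                             levels = c(0.05, 1.5), cluster_tol = 1e-4) {
  dyn <- setdiff(model$nodes, model$exogenous)
  if (is.null(init_grid)) {
    init_grid <- as.matrix(expand.grid(rep(list(levels), length(dyn))))
    colnames(init_grid) <- dyn
  }
  ends <- list(); flagged <- integer(0)
  for (i in seq_len(nrow(init_grid))) {
    init <- stats::setNames(rep(0, length(model$nodes)), model$nodes)
    init[colnames(init_grid)] <- init_grid[i, ]
    res <- integrate_to_steady(model, init, srgap1 = srgap1)
    if (!res$converged) { flagged <- c(flagged, i); next }
    ends[[length(ends) + 1]] <- res$state
  }
  assert_that(length(ends) > 0, "no start converged to a fixed point")
  E <- do.call(rbind, ends)
  # greedy proximity clustering
  reps <- list()
  for (i in seq_len(nrow(E))) {
    hit <- FALSE
    for (j in seq_along(reps)) {
      if (sqrt(sum((E[i, ] - reps[[j]]$state)^2)) < cluster_tol) {
        reps[[j]]$n <- reps[[j]]$n + 1L; hit <- TRUE; break
      }
    }
    if (!hit) reps[[length(reps) + 1]] <- list(state = E[i, ], n = 1L)
  }
  # keep only verified-stable fixed points
  keep <- vapply(reps, function(r) {
    rhs <- network_rhs(model, r$state, exo_rate = 0)
    if (sqrt(sum(rhs^2)) >= 1e-8) return(FALSE)
    dyn_idx <- match(dyn, model$nodes)
    f <- function(v) {
      x <- r$state; x[dyn_idx] <- v
      unname(network_rhs(model, x, exo_rate = 0)[dyn_idx])
    }
    J <- fd_jacobian(f, unname(r$state[dyn_idx]))
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  reps <- reps[keep]
  out <- as.data.frame(do.call(rbind, lapply(reps, `[[`, "state")))
  names(out) <- model$nodes
  out$n_basin <- vapply(reps, `[[`, integer(1), "n")
  out <- out[order(-out$RhoA), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, flagged = flagged)
}

#' Classify a trajectory into tuned vs switched regimes
#'
#' Labels each time point of a RhoA trajectory as `"active-tuned"` or
#' `"switched-inactive"`. A point is switched once RhoA falls below
#' `inactive_ref + switch_fraction * (active_ref - inactive_ref)` and never
#' recrosses that threshold upward.
#'
#' @param trajectory a `network_trajectory` (or data.frame with `time` and
#'   `RhoA`, and optionally `SRGAP1`).
#' @param active_ref,inactive_ref RhoA reference levels of the active and
#'   inactive branches (`active_ref > inactive_ref`).
#' @param switch_fraction position of the threshold between the branches.
#' @return a `regime_report`: list with per-point `labels`, `switch_time`,
#'   `switch_srgap1` (SRGAP1 level at the switch, `NA` if none), and the
#'   reference levels.
#' @export
classify_regime <- function(trajectory, active_ref, inactive_ref,
                            switch_fraction = 0.5) {
  assert_that(active_ref > inactive_ref,
              "active_ref must exceed inactive_ref")
  assert_that(switch_fraction > 0 && switch_fraction < 1,
              "switch_fraction must be in (0,1)")
  thr <- inactive_ref + switch_fraction * (active_ref - inactive_ref)
  rho <- trajectory$RhoA
  below <- rho < thr
  # switched from the first index after which RhoA never recrosses upward
  idx <- NA_integer_
  if (any(below)) {
    stays_below <- rev(cumprod(rev(below))) > 0
    if (any(stays_below)) idx <- which(stays_below)[1]
  }
  labels <- rep("active-tuned", length(rho))
  if (!is.na(idx)) labels[idx:length(rho)] <- "switched-inactive"
  structure(list(
    labels = labels,
    switch_time = if (is.na(idx)) NA_real_ else trajectory$time[idx],
    switch_srgap1 = if (!is.na(idx) && "SRGAP1" %in% names(trajectory))
      trajectory$SRGAP1[idx] else NA_real_,
    active_ref = active_ref, inactive_ref = inactive_ref,
    threshold = thr), class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  n_sw <- sum(x$labels == "switched-inactive")
  cat("Regime report:", length(x$labels), "time points,",
      n_sw, "switched-inactive\n")
  cat(sprintf("  active ref %.4g, inactive ref %.4g (threshold %.4g)\n",
              x$active_ref, x$inactive_ref, x$threshold))
  if (!is.na(x$switch_time))
    cat(sprintf("  switch at t = %.4g (SRGAP1 = %.4g)\n",
                x$switch_time, x$switch_srgap1))
  else cat("  no switch detected\n")
  invisible(x)
}

#' SRGAP1 ramp experiment
#'
#' Runs the Fig.-style ramp protocol: all species initialized to one except
#' SRGAP1 at zero, the network left to settle on the active branch (the ramp
#' start default of t = 200 includes a 100-time-unit pre-equilibration), then
#' SRGAP1 increased linearly. The post-ramp RhoA trajectory is classified
#' into the tuning regime (RhoA declines on the active branch) and, if the
#' ramp runs long enough, the switched regime, with the SRGAP1 level at the
#' switch reported. Branch reference levels are the frozen-SRGAP1 = 0 steady
#' states reached from the all-ones and near-zero initial conditions.
#'
#' @param model an `srgap_network` carrying a forcing schedule.
#' @param t_end end of the simulation (model time units).
#' @param dt_out output grid spacing.
#' @param switch_fraction passed to [classify_regime()].
#' @return list with `trajectory` and `report` (a `regime_report`).
#' @examples
#' \donttest{
#' res <- srgap1_ramp_experiment(build_default_model())
#' res$report
#' }
#' @export
srgap1_ramp_experiment <- function(model, t_end = 1200, dt_out = 1,
                                   switch_fraction = 0.5, rtol = 1e-8,
                                   atol = 1e-10) {
  assert_that(!is.null(model$forcing), "model carries no ramp schedule")
  init <- stats::setNames(rep(1, length(model$nodes)), model$nodes)
  if (!is.null(model$exogenous)) init[model$exogenous] <- 0
  traj <- simulate_network(model, init, t_end = t_end, dt_out = dt_out,
                           rtol = rtol, atol = atol)

  hi <- integrate_to_steady(model, init, srgap1 = 0)$state
  lo_init <- stats::setNames(rep(0.01, length(model$nodes)), model$nodes)
  lo <- integrate_to_steady(model, lo_init, srgap1 = 0)$state
  if (hi["RhoA"] - lo["RhoA"] < 1e-6) {
    report <- structure(list(labels = rep("active-tuned", nrow(traj)),
                             switch_time = NA_real_, switch_srgap1 = NA_real_,
                             active_ref = unname(hi["RhoA"]),
                             inactive_ref = unname(lo["RhoA"]),
                             threshold = NA_real_), class = "regime_report")
  } else {
    report <- classify_regime(traj, active_ref = unname(hi["RhoA"]),
                              inactive_ref = unname(lo["RhoA"]),
                              switch_fraction = switch_fraction)
  }
  list(trajectory = traj, report = report)
}

#' Frozen-SRGAP1 switch thresholds (hysteresis)
#'
#' Locates, by bisection on frozen-SRGAP1 steady states, the SRGAP1 level at
#' which the active branch is lost when SRGAP1 increases (`down`) and the
#' level at which the inactive branch is lost when SRGAP1 decreases (`up`).
#' For a bistable switch `down >= up`; when the inactive branch is stable all
#' the way to SRGAP1 = 0 the up-switch is reported as 0 (no recovery for
#' non-negative SRGAP1).
#'
#' @param model an `srgap_network`.
#' @param s_max upper bound of the search interval.
#' @param tol bisection tolerance on the SRGAP1 level.
#' @return list(down =, up =) switch levels.
#' @export
bistable_switch_levels <- function(model, s_max = 2, tol = 1e-3) {
  hi_init <- stats::setNames(rep(1, length(model$nodes)), model$nodes)
  lo_init <- stats::setNames(rep(0.01, length(model$nodes)), model$nodes)
  hi0 <- integrate_to_steady(model, hi_init, srgap1 = 0)$state
  lo0 <- integrate_to_steady(model, lo_init, srgap1 = 0)$state
  mid <- (hi0["RhoA"] + lo0["RhoA"]) / 2

  # the branch from the active basin is "alive" at level s while it remains
  # distinct from the branch reached from the inactive basin
  on_active <- function(s) {
    st_hi <- integrate_to_steady(model, hi0, srgap1 = s)$state
    st_lo <- integrate_to_steady(model, lo0, srgap1 = s)$state
    (st_hi["RhoA"] - st_lo["RhoA"]) > 1e-3
  }
  on_inactive <- function(s) {
    st_lo <- integrate_to_steady(model, lo0, srgap1 = s)$state
    st_lo["RhoA"] < mid
  }
  down <- if (on_active(s_max)) Inf else {
    a <- 0; b <- s_max
    while (b - a > tol) { m <- (a + b) / 2; if (on_active(m)) a <- m else b <- m }
    (a + b) / 2
  }
  up <- if (on_inactive(0)) 0 else {
    a <- 0; b <- down
    while (b - a > tol) { m <- (a + b) / 2; if (on_inactive(m)) b <- m else a <- m }
    (a + b) / 2
  }
  list(down = unname(down), up = unname(up))
}
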