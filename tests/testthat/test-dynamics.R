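test_that("a stress-free state is a fixed point of the integrator", {
  st <- sim_state(make_fixture("flat_strip_10"))
  st1 <- step_state(st, 0.01)
  expect_equal(st1$ar$P, st$ar$P, tolerance = 1e-14)
  expect_equal(st1$time, 0.01)
})

test_that("one-dof overdamped spring follows its analytic exponential decay", {
  # strip with every vertex pinned except one; the only restoring force
  # along x is the single tangential spring (k = 1), so
  # eta dx/dt = -k (x - rest)  =>  x(t) = rest + delta exp(-k t / eta)
  tis <- opticcup:::build_strip(2, length = 1, thickness = 1, x_start = 1)
  pars <- mechanics_params(k_v = 1e-12, k_s = 1e-12, k_h = 1e-12)
  free_id <- 2L                       # distal apical vertex
  delta <- 0.01
  tis$vertices$x[free_id] <- tis$vertices$x[free_id] + delta
  pinned <- rep(TRUE, 4); pinned[free_id] <- FALSE
  st <- sim_state(tis, pars, pinned = pinned)
  dt <- 1e-3
  for (i in seq_len(1000)) st <- step_state(st, dt)  # t = 1
  x_num <- st$ar$P[free_id, 1]
  x_ref <- 2 + delta * exp(-1)
  expect_equal(x_num, x_ref, tolerance = 0.01)
})

test_that("halving the time step converges at first order", {
  run_dt <- function(dt) {
    st <- sim_state(phase1_deepen(build_vesicle(12)))
    n <- round(0.5 / dt)
    for (i in seq_len(n)) st <- step_state(st, dt)
    st$ar$P
  }
  p1 <- run_dt(4e-3)
  p2 <- run_dt(2e-3)
  p3 <- run_dt(1e-3)
  e1 <- max(abs(p1 - p3))
  e2 <- max(abs(p2 - p3))
  expect_lt(e1, 1e-3)
  expect_lt(e2, 0.75 * e1)
})

test_that("total energy is non-increasing under frozen parameters at the stable dt", {
  st <- sim_state(phase1_deepen(build_vesicle(20)))
  dt <- 0.5 * check_stability(st)
  e_prev <- total_energy(st)$total
  for (i in seq_len(300)) {
    st <- step_state(st, dt)
    if (i %% 5 == 0) {
      e <- total_energy(st)$total
      expect_lt(e - e_prev, 1e-9)
      e_prev <- e
    }
  }
})

test_that("runs are deterministic", {
  cfg <- sim_config(n_per_surface = 16, schedule = phase_schedule(
    settle = 0.5, phase2 = 0.5, phase3 = 0.5, phase4 = 0.5,
    equilibrate = 0.5))
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$final_state$ar$P, t2$final_state$ar$P)
})

test_that("compiled and R engines integrate identically at a common step", {
  # a fixed dt below both stability bounds makes the two integration
  # paths follow the same step sequence
  cfg <- sim_config(n_per_surface = 12, dt = 2e-4,
                    schedule = phase_schedule(
    settle = 0.2, phase2 = 0.2, phase3 = 0.2, phase4 = 0.2,
    equilibrate = 0.2))
  tc <- run_simulation(cfg, engine = "cpp")
  tr <- run_simulation(cfg, engine = "r")
  expect_lt(max(abs(tc$final_state$ar$P - tr$final_state$ar$P)), 1e-10)
  expect_lt(max(abs(tc$final_state$ar$l0 - tr$final_state$ar$l0)), 1e-10)
  expect_lt(max(abs(tc$final_state$ar$kk - tr$final_state$ar$kk)), 1e-12)
})

test_that("with all rules disabled the vesicle settles to a force-free equilibrium", {
  cfg <- sim_config(n_per_surface = 16,
    schedule = phase_schedule(settle = 1500, phase2 = 1, phase3 = 1,
                              phase4 = 1, equilibrate = 1500,
                              rule1 = FALSE, rule2 = FALSE,
                              rule3 = FALSE),
    stride = 100000)
  traj <- run_simulation(cfg)
  expect_identical(traj$termination, "completed")
  st <- traj$final_state
  F <- opticcup:::force_arrays(st$ar, st$params)
  # the pole pair is axis-constrained: its x-component is carried by the
  # constraint, not by motion
  F[st$ar$pole, 1] <- 0
  expect_lt(max(abs(F[st$ar$free, ])), 1e-6)
  expect_identical(classify_outcome(traj)$outcome, "flat")
})

test_that("pinned vertices never move and the pole stays on the axis", {
  cfg <- sim_config(n_per_surface = 16, schedule = phase_schedule(
    settle = 0.5, phase2 = 0.5, phase3 = 0.5, phase4 = 0.5,
    equilibrate = 0.5))
  traj <- run_simulation(cfg)
  n <- 16
  p0 <- traj$snapshots[[1]]$P
  for (s in traj$snapshots) {
    expect_equal(s$P[c(1, n + 1), ], p0[c(1, n + 1), ], tolerance = 0)
    expect_equal(s$P[c(n, 2 * n), 1], c(0, 0), tolerance = 0)
  }
})

test_that("stability estimate scales inversely with stiffness and reacts to rule 2", {
  tis <- phase1_deepen(build_vesicle(20))
  pars <- mechanics_params()
  est1 <- check_stability(tis, pars)
  tis2 <- tis
  tis2$springs$k <- 2 * tis2$springs$k
  pars2 <- mechanics_params(k_a = 2, k_b = 2, k_t = 0.2, k_v = 2 * pars$k_v,
                            k_s = 2 * pars$k_s, k_h = 2 * pars$k_h)
  expect_equal(check_stability(tis2, pars2), est1 / 2, tolerance = 1e-12)
  # hinge stiffening (rule 2 endpoint) lowers the stable step
  st <- sim_state(tis, pars)
  st$time <- st$schedule$boundaries[["t3"]]
  st <- apply_schedule(st, dt = 0)
  expect_lt(check_stability(st), est1)
})

test_that("non-finite forces abort with a diagnostic state", {
  tis <- make_fixture("flat_strip_10")
  # collapse two vertices to make a spring length zero
  tis$vertices$x[2] <- tis$vertices$x[1]
  tis$vertices$z[2] <- tis$vertices$z[1]
  st <- sim_state(tis)
  expect_error(step_state(st, 1e-3), "non-finite")
})
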