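small_state <- function(n = 20, sch = phase_schedule(),
                        pars = mechanics_params()) {
  sim_state(phase1_deepen(build_vesicle(n)), pars, sch)
}

test_that("Phase 0 / Phase 1 setup enforces the protocol ratios and guards", {
  tis0 <- build_vesicle(20, prestress = FALSE)
  tis <- phase0_prestress(tis0)
  expect_error(phase0_prestress(tis), "already")
  expect_error(phase1_deepen(tis0), "phase0_prestress")
  sp0 <- tis$springs
  tis1 <- phase1_deepen(tis)
  expect_error(phase1_deepen(tis1), "already")
  sp1 <- tis1$springs
  reg <- tis1$elements$region[sp1$element]
  ap_ret <- sp1$kind == "apical" & reg %in% c("RPE", "hinge", "NR")
  ap_non <- sp1$kind == "apical" & reg == "non_retinal"
  # retinal apical springs: a further 10% shortening relative to Phase 0
  expect_identical(sp1$l0[ap_ret], 0.9 * sp1$phase0_l0[ap_ret])
  ba <- sp1[sp1$kind == "basal", ]
  expect_equal(sp1$l0[ap_ret] /
                 ba$l0[match(sp1$element[ap_ret], ba$element)],
               rep(0.774, sum(ap_ret)), tolerance = 1e-12)
  # non-retinal apical springs and all stiffnesses untouched
  expect_identical(sp1$l0[ap_non], sp0$l0[ap_non])
  expect_identical(sp1$k, sp0$k)
})

test_that("schedule construction validates boundaries and ramps", {
  expect_error(phase_schedule(phase2 = 0), "positive")
  expect_error(phase_schedule(phase3 = -1), "positive")
  expect_error(phase_schedule(lambda = -1), "lambda")
  expect_error(phase_schedule(G_final = 0), "G_final")
  sch <- phase_schedule()
  b <- sch$boundaries
  expect_true(all(diff(b) > 0))
  ramps <- schedule_ramps(sch)
  expect_equal(sort(unique(ramps$rule)), 1:3)
  expect_silent(validate_ramps(ramps))
  # contradictory ramps on the same quantity x region are rejected
  clash <- tibble::tibble(rule = c(1L, 9L),
                          quantity = "apical_l0", region = "NR",
                          t_start = c(0, 0.5), t_end = c(1, 1.5),
                          mode = "multiplicative_to", value = 2)
  expect_error(validate_ramps(clash), "overlapping")
  # disabled rules drop out of the table
  expect_equal(nrow(schedule_ramps(
    phase_schedule(rule1 = FALSE, rule2 = FALSE, rule3 = FALSE))), 0)
})

test_that("ramp endpoints reproduce the printed factors exactly", {
  st <- small_state()
  b <- st$schedule$boundaries
  st$time <- b[["t3"]]          # end of Phase 3
  st <- apply_schedule(st, dt = 0)
  ar <- st$ar
  nrs <- opticcup:::nr_tangential(ar)
  ha <- opticcup:::hinge_apical(ar)
  expect_identical(ar$kk[nrs], 0.25 * ar$phase0_k[nrs])
  expect_identical(ar$kk[ha], 10 * ar$phase0_k[ha])
  expect_identical(ar$l0[ha], 0.10 * ar$phase0_l0[ha])
  # held thereafter
  st$time <- b[["t_end"]]
  st <- apply_schedule(st, dt = 0)
  expect_identical(st$ar$kk[nrs], 0.25 * st$ar$phase0_k[nrs])
  # basal hinge springs and all transmural springs untouched
  hb <- ar$skind == 2L & ar$region_sp == 3L
  expect_identical(ar$l0[hb], st$template$springs$l0[hb])
  tm <- ar$skind == 3L
  expect_identical(ar$l0[tm], st$template$springs$l0[tm])
})

test_that("growth ramp interpolates linearly and respects its regions", {
  st <- small_state()
  b <- st$schedule$boundaries
  ar0 <- st$ar
  st$time <- (b[["t3"]] + b[["t4"]]) / 2    # mid-Phase 4, g = 1.5
  st <- apply_schedule(st, dt = 0)
  ar <- st$ar
  grow_el <- opticcup:::growth_elements(ar)
  gs <- ar$skind <= 2 & grow_el[ar$sel]
  expect_equal(ar$l0[gs], 1.5 * ar0$l0[gs], tolerance = 1e-12)
  expect_equal(ar$Veq[grow_el], 1.5 * ar0$Veq[grow_el], tolerance = 1e-12)
  # V_eq scales by the same factor as the tangential natural lengths
  expect_equal(unique(round(ar$Veq[grow_el] / ar0$Veq[grow_el], 10)), 1.5)
  # proximal-half RPE, non-retinal, and transmural quantities unscaled
  expect_identical(ar$Veq[!grow_el], ar0$Veq[!grow_el])
  expect_identical(ar$l0[ar$skind == 3L], ar0$l0[ar$skind == 3L])
  rpe <- which(ar$region_el == 2L)
  prox_rpe <- utils::head(rpe, length(rpe) - floor(length(rpe) / 2))
  expect_false(any(grow_el[prox_rpe]))
  # at and beyond the end of Phase 4 the factor is exactly G_final
  st$time <- b[["t_end"]]
  st <- apply_schedule(st, dt = 0)
  expect_equal(st$ar$l0[gs], 2 * ar0$l0[gs], tolerance = 1e-12)
})

test_that("rule 1 length relaxation creeps natural lengths to current lengths", {
  st <- small_state()
  b <- st$schedule$boundaries
  st$time <- b[["t1"]]
  ar0 <- st$ar
  nrs <- opticcup:::nr_tangential(ar0)
  l <- opticcup:::spring_lengths(ar0)
  e0 <- sum(0.5 * ar0$kk[nrs] * (l[nrs] - ar0$l0[nrs])^2)
  expect_gt(e0, 0)
  # positions frozen; creep alone drives l0 -> l exponentially
  dt <- 0.01
  for (i in 1:500) {
    st$time <- b[["t1"]]   # hold the clock inside the Phase 2 window
    st <- rule1_relaxation(st, dt)
  }
  ar <- st$ar
  e1 <- sum(0.5 * ar$kk[nrs] * (l[nrs] - ar$l0[nrs])^2)
  expect_lt(e1 / e0, 1e-10)
  # springs outside the NR are untouched
  expect_identical(ar$l0[!nrs], ar0$l0[!nrs])
})

test_that("default relaxation rate drains NR strain energy within Phase 2", {
  # lambda is chosen so that exp(-2 * lambda * phase2) < 5%
  sch <- phase_schedule()
  span <- sch$boundaries[["t2"]] - sch$boundaries[["t1"]]
  expect_lt(exp(-2 * sch$lambda * span), 0.05)
})

test_that("disabled rules leave every parameter constant", {
  sch <- phase_schedule(rule1 = FALSE, rule2 = FALSE, rule3 = FALSE)
  st <- small_state(sch = sch)
  ar0 <- st$ar
  for (tt in c(0.5, 1.5, 2.5, 3.5, 4.9)) {
    st$time <- tt
    st <- apply_schedule(st, dt = 0.01)
    expect_identical(st$ar$l0, ar0$l0)
    expect_identical(st$ar$kk, ar0$kk)
    expect_identical(st$ar$Veq, ar0$Veq)
  }
})

test_that("ramps are continuous at their window boundaries", {
  st <- small_state()
  b <- st$schedule$boundaries
  eps <- 1e-8
  ha <- opticcup:::hinge_apical(st$ar)
  st$time <- b[["t2"]] + eps
  st <- apply_schedule(st, dt = 0)
  before <- st$template$springs$l0[ha]   # Phase 1 value
  expect_equal(st$ar$l0[ha], before, tolerance = 1e-6)
})
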