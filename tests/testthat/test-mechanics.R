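pars <- mechanics_params()

test_that("every energy term is zero exactly at its rest configuration", {
  st <- make_fixture("flat_strip_10")
  expect_equal(elastic_energy(st, pars), 0)
  expect_equal(volumetric_energy(st, pars), 0)
  expect_equal(distortion_energy(st, pars), 0)
  expect_equal(hoop_energy(st, pars), 0)
  e <- total_energy(st, pars)
  expect_equal(e$total, 0)
  f <- forces(st, pars)
  expect_lt(max(abs(c(f$f_x, f$f_z))), 1e-12)
  # stress-free arc mesh likewise
  arc <- make_fixture("ring_arc")
  expect_equal(total_energy(arc, pars)$total, 0, tolerance = 1e-24)
  fa <- forces(arc, pars)
  expect_lt(max(abs(c(fa$f_x, fa$f_z))), 1e-12)
})

test_that("energy terms match independent per-spring / per-element oracles", {
  for (seed in 1:6) {
    tis <- perturbed_strip(seed)
    expect_equal(elastic_energy(tis, pars), oracle_elastic(tis),
                 tolerance = 1e-12)
    expect_equal(volumetric_energy(tis, pars),
                 oracle_volumetric(tis, pars$k_v), tolerance = 1e-12)
    expect_equal(distortion_energy(tis, pars),
                 oracle_distortion(tis, pars$k_s), tolerance = 1e-12)
    e <- total_energy(tis, pars)
    expect_equal(e$total, e$elastic + e$volumetric + e$distortion + e$hoop,
                 tolerance = 1e-15)
    expect_true(all(c(e$elastic, e$volumetric, e$distortion, e$hoop) >= 0))
  }
})

test_that("hand-computed energy values are reproduced", {
  # two tangential springs stretched by 0.5 at unit stiffness: 2 * (1/2)(0.5)^2
  sq <- opticcup:::build_strip(2, length = 1, thickness = 1, x_start = 0.5)
  sq$vertices$x[sq$vertices$arc == 2] <-
    sq$vertices$x[sq$vertices$arc == 2] + 0.5
  expect_equal(elastic_energy(sq, pars), 0.25, tolerance = 1e-14)
  # volume inflated to 1.1 V_eq at k_v = 1: (1/2)(0.1)^2 V_eq
  p1 <- mechanics_params(k_v = 1)
  sq2 <- opticcup:::build_strip(2, length = 1, thickness = 1, x_start = 0.5)
  ap <- sq2$vertices$surface == "apical"
  sq2$vertices$z[ap] <- 1.1 * sq2$vertices$z[ap]
  expect_equal(volumetric_energy(sq2, p1),
               unname(0.005 * sq2$elements$V_eq[1]), tolerance = 1e-12)
})

test_that("hoop force is radial, linear in relative strain, zero at reference", {
  st <- make_fixture("flat_strip_10")
  f0 <- hoop_force(st, pars)
  expect_equal(max(abs(f0$f_x)), 0)
  st$vertices$x <- 1.1 * st$vertices$x  # +10% circumferential strain
  f <- hoop_force(st, pars)
  expect_equal(f$f_x, rep(-pars$k_h * 0.1, 20), tolerance = 1e-12)
  expect_equal(f$f_z, rep(0, 20))
  # total axial component of the hoop field vanishes on any mesh
  arc <- perturbed_arc(3)
  expect_equal(sum(hoop_force(arc, pars)$f_z), 0)
  # pole vertices (x0 = 0) carry no hoop force
  ves <- build_vesicle(20)
  fp <- hoop_force(ves, pars)
  expect_equal(fp$f_x[fp$arc == 20], c(0, 0))
})

test_that("analytic forces match central finite differences on random meshes", {
  hstep <- 1e-6
  for (seed in 1:20) {
    tis <- if (seed %% 2) perturbed_strip(seed) else perturbed_arc(seed)
    F <- as.matrix(forces(tis, pars)[, c("f_x", "f_z")])
    en <- function(t) total_energy(t, pars)$total
    nv <- nrow(tis$vertices)
    probe <- unique(round(seq(1, nv, length.out = 8)))
    for (v in probe) {
      for (cc in c("x", "z")) {
        tp <- tis; tm <- tis
        tp$vertices[[cc]][v] <- tp$vertices[[cc]][v] + hstep
        tm$vertices[[cc]][v] <- tm$vertices[[cc]][v] - hstep
        fd <- -(en(tp) - en(tm)) / (2 * hstep)
        an <- unname(F[v, if (cc == "x") 1L else 2L])
        expect_equal(an, fd, tolerance = 1e-5,
                     label = sprintf("force[%d,%s] seed %d", v, cc, seed))
      }
    }
  }
})

test_that("corner penalty fade-out at tiny edges keeps an exact gradient", {
  # shrink the apical edge of a single element below the regularization
  # length so the weighted branch of the self-righting term is active
  sq <- opticcup:::build_strip(2, length = 1, thickness = 1, x_start = 1)
  sq$vertices$x[1] <- 1.49
  sq$vertices$x[2] <- 1.51   # apical edge ~0.028; product < l_reg^2
  sq$vertices$z[2] <- 1.02
  ar <- opticcup:::tissue_arrays(sq)
  W <- opticcup:::corner_weights(ar$P, ar$C, ar$l_reg)
  expect_true(any(W < 1))
  F <- as.matrix(forces(sq, pars)[, c("f_x", "f_z")])
  en <- function(t) total_energy(t, pars)$total
  hstep <- 1e-7
  for (v in 1:4) {
    for (cc in c("x", "z")) {
      tp <- sq; tm <- sq
      tp$vertices[[cc]][v] <- tp$vertices[[cc]][v] + hstep
      tm$vertices[[cc]][v] <- tm$vertices[[cc]][v] - hstep
      fd <- -(en(tp) - en(tm)) / (2 * hstep)
      expect_equal(unname(F[v, if (cc == "x") 1L else 2L]), fd,
                   tolerance = 1e-4)
    }
  }
})

test_that("compiled force kernel agrees with the R reference", {
  for (seed in 1:5) {
    tis <- perturbed_arc(seed)
    ar <- opticcup:::tissue_arrays(tis)
    Fr <- opticcup:::force_arrays(ar, pars)
    Fc <- opticcup:::cpp_forces(ar$P, ar$si - 1L, ar$sj - 1L, ar$kk,
                                ar$l0, ar$C - 1L, ar$Veq, ar$th_eq,
                                ar$sigma, ar$x0, pars$k_v, pars$k_s,
                                pars$k_h, pars$hoop_relief, ar$l_reg)
    expect_lt(max(abs(Fr - Fc)), 1e-13)
  }
})

test_that("axial translation is free; off-axis translation acts through axisymmetric terms only", {
  tis <- perturbed_strip(11)
  e0 <- total_energy(tis, pars)
  tz <- tis; tz$vertices$z <- tz$vertices$z + 0.37
  ez <- total_energy(tz, pars)
  expect_equal(ez$total, e0$total, tolerance = 1e-12)
  # moving off-axis leaves the planar terms unchanged; the hoop term and
  # the volumetric term (whose element volume carries the 2*pi*xbar
  # circumferential weight) both respond
  tx <- tis; tx$vertices$x <- tx$vertices$x + 0.1
  ex <- total_energy(tx, pars)
  expect_equal(ex$elastic, e0$elastic, tolerance = 1e-12)
  expect_equal(ex$distortion, e0$distortion, tolerance = 1e-12)
  expect_gt(ex$hoop, e0$hoop)
  expect_false(isTRUE(all.equal(ex$volumetric, e0$volumetric)))
})

test_that("prestressed vesicle stores elastic energy; breakdown is consistent", {
  ves <- phase1_deepen(build_vesicle(40))
  e <- total_energy(ves, pars)
  expect_gt(e$elastic, 0)
  expect_equal(e$total, e$elastic + e$volumetric + e$distortion + e$hoop,
               tolerance = 1e-15)
  expect_true(all(tidy(e)$energy >= 0))
})

test_that("mechanics parameters are validated", {
  expect_error(mechanics_params(k_v = -1), "k_v")
  expect_error(mechanics_params(eta = 0), "eta")
  expect_error(mechanics_params(k_h = Inf), "k_h")
})
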