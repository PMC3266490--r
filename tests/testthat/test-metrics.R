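# synthetic epithelium whose apical chain lies on a given parametric curve,
# with the basal chain offset outward along the curve normal
curve_tissue <- function(fx, fz, tt, thickness = 0.05) {
  A <- cbind(fx(tt), fz(tt))
  d <- cbind(fx(tt + 1e-6) - fx(tt - 1e-6), fz(tt + 1e-6) - fz(tt - 1e-6))
  d <- d / sqrt(rowSums(d^2))
  nrm <- cbind(d[, 2], -d[, 1])   # outward normal for CCW curves
  B <- A + thickness * nrm
  opticcup:::assemble_tissue(A, B, mechanics_params(), geometry_params(),
                             kind = "strip")
}

test_that("signed curvature recovers circles exactly and is zero on lines", {
  # apical surface on a circle of radius 2 (dome radius 2.05, thickness .1)
  ves <- build_vesicle(30, geometry_params(radius = 2.05, thickness = 0.1),
                       prestress = FALSE)
  cp <- curvature_profile(ves)
  expect_equal(cp$kappa, rep(0.5, nrow(cp)), tolerance = 1e-9)
  # collinear chain
  st <- make_fixture("flat_strip_10")
  expect_equal(curvature_profile(st)$kappa, rep(0, 8))
})

test_that("curvature sign convention: Phase 1 vesicle is apically concave throughout", {
  ves <- make_fixture("phase1_vesicle")
  cp <- curvature_profile(ves)
  retinal <- cp$region %in% c("RPE", "hinge", "NR")
  expect_true(all(cp$kappa[retinal] > 0))
  expect_gt(mean_nr_curvature(ves), 0)
})

test_that("curvature matches the analytic osculating circle of a smooth arc", {
  a <- 1.3; b <- 0.8
  tt <- seq(0.2, pi / 2 - 0.2, length.out = 60)
  tis <- curve_tissue(function(t) a * cos(t), function(t) b * sin(t), tt)
  cp <- curvature_profile(tis)
  kappa_true <- a * b / (a^2 * sin(tt)^2 + b^2 * cos(tt)^2)^(3 / 2)
  ratio <- cp$kappa / kappa_true[cp$arc]
  expect_true(all(abs(ratio - 1) < 0.02))
})

test_that("hinge apical angle is pi/2 for rectangular elements", {
  st <- make_fixture("flat_strip_10")
  expect_equal(hinge_apical_angle(st), pi / 2, tolerance = 1e-12)
})

test_that("classification demands a completed trajectory and is pure", {
  cfg <- sim_config(n_per_surface = 16, schedule = phase_schedule(
    settle = 0.4, phase2 = 0.4, phase3 = 0.4, phase4 = 0.4,
    equilibrate = 0.4))
  traj <- run_simulation(cfg)
  bad <- traj
  bad$termination <- "aborted: synthetic"
  expect_error(classify_outcome(bad), "refusing")
  o1 <- classify_outcome(traj)
  o2 <- classify_outcome(traj)
  expect_identical(o1, o2)
  expect_s3_class(glance(o1), "tbl_df")
  expect_equal(nrow(glance(o1)), 1)
})

test_that("flattening index is invariant under rigid translation", {
  cfg <- sim_config(n_per_surface = 16, schedule = phase_schedule(
    settle = 0.4, phase2 = 0.4, phase3 = 0.4, phase4 = 0.4,
    equilibrate = 0.4))
  traj <- run_simulation(cfg)
  i0 <- nr_flattening_index(traj)
  shifted <- traj
  shifted$snapshots <- lapply(shifted$snapshots, function(s) {
    s$P[, 2] <- s$P[, 2] + 3.7
    s
  })
  expect_equal(nr_flattening_index(shifted), i0, tolerance = 1e-12)
})

test_that("invagination depth is a relative displacement measure", {
  ves <- make_fixture("phase1_vesicle")
  expect_equal(invagination_depth(ves, ves), 0)
  expect_equal(invagination_depth(ves, ves, measure = "pole"), 0)
  pushed <- ves
  pole <- pushed$vertices$surface == "apical" &
    pushed$vertices$arc == pushed$meta$n
  pushed$vertices$z[pole] <- pushed$vertices$z[pole] - 0.2
  expect_equal(invagination_depth(pushed, ves, measure = "pole"), 0.2,
               tolerance = 1e-12)
  expect_equal(invagination_depth(ves, pushed, measure = "pole"), -0.2,
               tolerance = 1e-12)
  # displacing the whole NR apical surface registers in the mean measure
  nr_arcs <- unique(c(ves$elements$a1[ves$elements$region == "NR"],
                      ves$elements$a2[ves$elements$region == "NR"]))
  shifted <- ves
  sel <- shifted$vertices$surface == "apical" &
    shifted$vertices$arc %in% nr_arcs
  shifted$vertices$z[sel] <- shifted$vertices$z[sel] - 0.1
  expect_equal(invagination_depth(shifted, ves), 0.1, tolerance = 1e-12)
})
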