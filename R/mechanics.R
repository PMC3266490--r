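#' Mechanical constants of the vertex model
#'
#' All constants are dimensionless: lengths are in units of the dome radius
#' and stiffnesses in units of the tangential spring constant. `k_a`, `k_b`,
#' `k_t` are the apical/basal/transmural spring stiffnesses used when a mesh
#' is built (the Phase 0 prestress afterwards enforces `k_a = k_b` and
#' `k_t = 0.1 k_b`); the per-spring values then live on the tissue itself.
#' `k_v` penalizes relative volume change of an element, `k_s` penalizes
#' deviation of element corner angles from their stress-free values (the
#' "self-righting" resistance to shear), `k_h` scales the apparent radial
#' hoop force that stands in for the circumferential elasticity of the
#' revolved 3D vesicle, and `eta` is the virtual viscosity that sets the
#' time scale of the overdamped flow.
#'
#' @param k_a,k_b,k_t Apical, basal, transmural spring stiffness.
#' @param k_v Volumetric elastic constant.
#' @param k_s Self-righting (corner-angle) elastic constant.
#' @param eta Viscosity of the overdamped dynamics.
#' @param k_h Hoop stiffness (per-vertex apparent radial force).
#' @param hoop_relief Circumferential compression-relief factor in
#'   \[0, 1\]: the hoop force on a vertex *inside* its stress-free radius
#'   (`x < x0`, circumferential compression) is scaled by
#'   `1 - hoop_relief`. The default 0 is the symmetric linear hoop; 1
#'   gives a pure tension-field hoop in which circumferential compression
#'   is entirely shed, as non-axisymmetric buckling would shed it in 3D.
#'   Exposed as an exploration dimension of the hoop model.
#' @return An object of class `ov_mechanics`.
#' @export
mechanics_params <- function(k_a = 1, k_b = 1, k_t = 0.1, k_v = 0.3,
                             k_s = 2e-4, eta = 1, k_h = 1e-3,
                             hoop_relief = 0) {
  vals <- list(k_a = k_a, k_b = k_b, k_t = k_t, k_v = k_v, k_s = k_s,
               eta = eta, k_h = k_h)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(hoop_relief) || length(hoop_relief) != 1 ||
      !is.finite(hoop_relief) || hoop_relief < 0 || hoop_relief > 1)
    stop("`hoop_relief` must be in [0, 1]", call. = FALSE)
  vals$hoop_relief <- hoop_relief
  structure(vals, class = "ov_mechanics")
}

# ---- internal flat-array representation used by the dynamics core --------

tissue_arrays <- function(tissue) {
  stopifnot(inherits(tissue, "ov_tissue"))
  n <- tissue$meta$n
  sp <- tissue$springs
  el <- tissue$elements
  region_el <- match(el$region, region_levels)
  free <- rep(TRUE, 2L * n)
  free[c(1L, n + 1L)] <- FALSE  # proximal boundary pinned
  list(
    P = tissue_positions(tissue),
    n = n,
    si = sp$i, sj = sp$j,
    skind = match(sp$kind, c("apical", "basal", "transmural")),
    sel = sp$element,
    l0 = sp$l0, kk = sp$k,
    phase0_l0 = sp$phase0_l0, phase0_k = sp$phase0_k,
    C = element_corners(tissue),
    Veq = el$V_eq,
    th_eq = as.matrix(el[, c("th_eq_a1", "th_eq_a2", "th_eq_b2",
                             "th_eq_b1")]),
    sigma = tissue$meta$sigma,
    region_el = region_el,
    region_sp = region_el[sp$element],
    x0 = tissue$vertices$x0,
    free = free,
    # only dome meshes have distal vertices constrained to the axis
    pole = if (identical(tissue$meta$kind, "vesicle")) c(n, 2L * n)
           else integer(0),
    l_reg = tissue$meta$l_reg %||% 0,
    thickness = tissue$meta$geometry$thickness)
}

as_arrays <- function(x) {
  if (inherits(x, "ov_state")) x$ar
  else if (inherits(x, "ov_tissue")) tissue_arrays(x)
  else stop("expected an `ov_tissue` or `ov_state`", call. = FALSE)
}

spring_lengths <- function(ar) {
  dx <- ar$P[ar$si, 1] - ar$P[ar$sj, 1]
  dz <- ar$P[ar$si, 2] - ar$P[ar$sj, 2]
  sqrt(dx * dx + dz * dz)
}

# accumulate per-vertex contributions (idx may repeat)
acc_force <- function(F, idx, contrib) {
  s <- rowsum(contrib, idx)
  rows <- as.integer(rownames(s))
  F[rows, ] <- F[rows, ] + s
  F
}

en_elastic <- function(ar) {
  l <- spring_lengths(ar)
  sum(0.5 * ar$kk * (l - ar$l0)^2)
}

en_volumetric <- function(ar, k_v) {
  q <- quad_volumes(ar$P, ar$C, ar$sigma)
  sum(0.5 * k_v * (q$V - ar$Veq)^2 / ar$Veq)
}

# corner-weight factors: the self-righting penalty of a corner fades
# with the product of its two edge lengths once either drops below the
# regularization length l_reg (sub-resolution edges carry no meaningful
# angle; this also bounds the term's local stiffness by ~k_s / l_reg^2)
corner_weights <- function(P, C, l_reg) {
  W <- matrix(1, nrow(C), 4)
  if (l_reg <= 0) return(W)
  for (m in 1:4) {
    p <- C[, m]
    a <- C[, (m - 2) %% 4 + 1]
    b <- C[, m %% 4 + 1]
    lu <- sqrt((P[a, 1] - P[p, 1])^2 + (P[a, 2] - P[p, 2])^2)
    lv <- sqrt((P[b, 1] - P[p, 1])^2 + (P[b, 2] - P[p, 2])^2)
    W[, m] <- pmin(1, lu * lv / l_reg^2)
  }
  W
}

en_distortion <- function(ar, k_s) {
  th <- corner_angles(ar$P, ar$C, ar$sigma)
  W <- corner_weights(ar$P, ar$C, ar$l_reg)
  sum(0.5 * k_s * W * (th - ar$th_eq)^2)
}

# circumferential weight per vertex: full k_h when stretched beyond the
# stress-free radius, (1 - hoop_relief) k_h when compressed inside it
hoop_weight <- function(ar, params) {
  ifelse(ar$P[, 1] > ar$x0, 1, 1 - params$hoop_relief)
}

en_hoop <- function(ar, k_h, w) {
  # circumferential elasticity: stretch beyond the stress-free radius at
  # full stiffness; compression inside it at the relieved stiffness (in
  # 3D most circumferential compression is shed by out-of-plane buckling)
  off <- ar$x0 > 0
  sum(0.5 * w[off] * k_h * (ar$P[off, 1] - ar$x0[off])^2 / ar$x0[off])
}

check_elements <- function(ar, where = "energy evaluation") {
  ok <- quad_simple(ar$P, ar$C, ar$sigma)
  q <- quad_volumes(ar$P, ar$C, ar$sigma)
  bad <- which(!ok | q$A <= 0)
  if (length(bad) > 0)
    stop("degenerate element(s) at ", where, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

force_arrays <- function(ar, params) {
  P <- ar$P
  nv <- nrow(P)
  F <- matrix(0, nv, 2)

  # Hookean springs
  dx <- P[ar$si, 1] - P[ar$sj, 1]
  dz <- P[ar$si, 2] - P[ar$sj, 2]
  l <- sqrt(dx * dx + dz * dz)
  cf <- ar$kk * (l - ar$l0) / l
  Fi <- cbind(-cf * dx, -cf * dz)
  F <- acc_force(F, c(ar$si, ar$sj), rbind(Fi, -Fi))

  # volumetric constraint
  q <- quad_volumes(P, ar$C, ar$sigma)
  dUdV <- params$k_v * (q$V - ar$Veq) / ar$Veq
  for (m in 1:4) {
    mp <- (m - 2) %% 4 + 1  # previous corner
    mn <- m %% 4 + 1        # next corner
    dAdx <- ar$sigma * 0.5 * (q$Z[, mn] - q$Z[, mp])
    dAdz <- ar$sigma * 0.5 * (q$X[, mp] - q$X[, mn])
    dVdx <- 2 * pi * (q$A / 4 + q$xbar * dAdx)
    dVdz <- 2 * pi * q$xbar * dAdz
    F <- acc_force(F, ar$C[, m], cbind(-dUdV * dVdx, -dUdV * dVdz))
  }

  # self-righting corner-angle penalty (edge-weighted; see
  # corner_weights for the sub-resolution fade-out)
  sigma <- ar$sigma
  l_reg <- ar$l_reg
  for (m in 1:4) {
    mp <- (m - 2) %% 4 + 1
    mn <- m %% 4 + 1
    p <- ar$C[, m]; a <- ar$C[, mp]; b <- ar$C[, mn]
    ux <- P[a, 1] - P[p, 1]; uy <- P[a, 2] - P[p, 2]
    vx <- P[b, 1] - P[p, 1]; vy <- P[b, 2] - P[p, 2]
    s <- -sigma * (ux * vy - uy * vx)
    cc <- ux * vx + uy * vy
    r2 <- s * s + cc * cc
    th <- atan2(s, cc)
    dth <- th - ar$th_eq[, m]
    lu <- sqrt(ux * ux + uy * uy)
    lv <- sqrt(vx * vx + vy * vy)
    wgt <- if (l_reg > 0) pmin(1, lu * lv / l_reg^2) else rep(1, length(lu))
    w <- params$k_s * wgt * dth
    du_x <- (-sigma * cc * vy - s * vx) / r2
    du_y <- ( sigma * cc * vx - s * vy) / r2
    dv_x <- ( sigma * cc * uy - s * ux) / r2
    dv_y <- (-sigma * cc * ux - s * uy) / r2
    Fa_x <- -w * du_x; Fa_y <- -w * du_y
    Fb_x <- -w * dv_x; Fb_y <- -w * dv_y
    soft <- l_reg > 0 & wgt < 1
    if (any(soft)) {
      # gradient of the weight itself: dw/du = (lv / l_reg^2) * u / lu
      cw <- 0.5 * params$k_s * dth^2 / l_reg^2
      gu <- ifelse(soft, cw * lv / lu, 0)
      gv <- ifelse(soft, cw * lu / lv, 0)
      Fa_x <- Fa_x - gu * ux; Fa_y <- Fa_y - gu * uy
      Fb_x <- Fb_x - gv * vx; Fb_y <- Fb_y - gv * vy
    }
    F <- acc_force(F, a, cbind(Fa_x, Fa_y))
    F <- acc_force(F, b, cbind(Fb_x, Fb_y))
    F <- acc_force(F, p, cbind(-(Fa_x + Fb_x), -(Fa_y + Fb_y)))
  }

  # hoop force: apparent radial restoring force from circumferential
  # strain, compression side scaled down by the relief factor
  w <- hoop_weight(ar, params)
  off <- ar$x0 > 0
  F[off, 1] <- F[off, 1] -
    w[off] * params$k_h * (P[off, 1] - ar$x0[off]) / ar$x0[off]

  F
}

# ---- exported energy / force surface -------------------------------------

#' Elastic strain energy of the springs
#'
#' `U_e = sum over springs of (k/2) (l - l0)^2` with per-spring stiffness
#' and natural length taken from the tissue.
#'
#' @param x An `ov_tissue` or `ov_state`.
#' @param params An [mechanics_params()] object.
#' @return Non-negative scalar.
#' @export
elastic_energy <- function(x, params = mechanics_params()) {
  en_elastic(as_arrays(x))
}

#' Volumetric constraint energy
#'
#' `U_v = sum over elements of (k_v/2) ((V - V_eq)/V_eq)^2 V_eq`, with the
#' axisymmetric element volume of [element_volume()]. The `V_eq` scaling
#' keeps `k_v` dimensionally consistent while equilibrium volumes grow.
#'
#' @inheritParams elastic_energy
#' @return Non-negative scalar.
#' @export
volumetric_energy <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  check_elements(ar)
  en_volumetric(ar, params$k_v)
}

#' Self-righting distortion energy
#'
#' `U_s = sum over elements and corners of (k_s/2) (theta - theta_eq)^2`
#' over the two apical and two basal corner angles of every element,
#' resisting shear distortion of the quadrilaterals.
#'
#' @inheritParams elastic_energy
#' @return Non-negative scalar.
#' @export
distortion_energy <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  th <- corner_angles(ar$P, ar$C, ar$sigma)
  if (!all(is.finite(th)))
    stop("undefined corner angle (coincident corner points)", call. = FALSE)
  en_distortion(ar, params$k_s)
}

#' Hoop potential energy
#'
#' `U_h = sum over off-axis vertices of (w k_h/2) (x - x0)^2 / x0`, the
#' potential whose gradient is the apparent radial hoop force; `x0` is the
#' stress-free off-axis distance recorded at construction. The weight `w`
#' is 1 for circumferential stretch (`x > x0`) and `1 - hoop_relief` for
#' compression (`x < x0`), most of which would be shed by out-of-plane
#' buckling in 3D. On-axis vertices (`x0 = 0`) contribute nothing.
#'
#' @inheritParams elastic_energy
#' @return Non-negative scalar.
#' @export
hoop_energy <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  en_hoop(ar, params$k_h, hoop_weight(ar, params))
}

#' Apparent radial hoop force per vertex
#'
#' Linearized circumferential elasticity of the revolved vesicle:
#' `f_x = -w k_h (x - x0)/x0` with `w = 1` beyond the stress-free radius
#' and `w = 1 - hoop_relief` inside it; zero axial component, zero for
#' on-axis vertices.
#'
#' @inheritParams elastic_energy
#' @return A tibble with one row per vertex: `id`, `surface`, `arc`,
#'   `f_x`, `f_z`.
#' @export
hoop_force <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  w <- hoop_weight(ar, params)
  fx <- ifelse(ar$x0 > 0,
               -w * params$k_h * (ar$P[, 1] - ar$x0) / ar$x0, 0)
  n <- ar$n
  tibble::tibble(id = seq_len(2L * n),
                 surface = rep(c("apical", "basal"), each = n),
                 arc = rep(seq_len(n), 2L),
                 f_x = fx, f_z = 0)
}

#' Total potential energy with breakdown
#'
#' @inheritParams elastic_energy
#' @return An `ov_energy` object: a list with components `elastic`,
#'   `volumetric`, `distortion`, `hoop`, `total`.
#' @export
total_energy <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  check_elements(ar)
  e <- en_elastic(ar)
  v <- en_volumetric(ar, params$k_v)
  s <- en_distortion(ar, params$k_s)
  h <- en_hoop(ar, params$k_h, hoop_weight(ar, params))
  structure(list(elastic = e, volumetric = v, distortion = s, hoop = h,
                 total = e + v + s + h),
            class = "ov_energy")
}

#' @export
print.ov_energy <- function(x, ...) {
  cat(sprintf(
    "<ov_energy> total %.6g (elastic %.3g, volumetric %.3g, distortion %.3g, hoop %.3g)\n",
    x$total, x$elastic, x$volumetric, x$distortion, x$hoop))
  invisible(x)
}

#' @export
tidy.ov_energy <- function(x, ...) {
  tibble::tibble(term = c("elastic", "volumetric", "distortion", "hoop",
                          "total"),
                 energy = c(x$elastic, x$volumetric, x$distortion, x$hoop,
                            x$total))
}

#' Forces on every vertex
#'
#' The analytic gradient `-dU/dr_i` of [total_energy()] for every vertex.
#' Pinned vertices report their raw force; masking immobile vertices is the
#' integrator's job.
#'
#' @inheritParams elastic_energy
#' @return A tibble with one row per vertex: `id`, `surface`, `arc`,
#'   `f_x`, `f_z`.
#' @export
forces <- function(x, params = mechanics_params()) {
  ar <- as_arrays(x)
  F <- force_arrays(ar, params)
  n <- ar$n
  tibble::tibble(id = seq_len(2L * n),
                 surface = rep(c("apical", "basal"), each = n),
                 arc = rep(seq_len(n), 2L),
                 f_x = F[, 1], f_z = F[, 2])
}
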