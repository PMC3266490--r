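#' Geometry of the meridional epithelium section
#'
#' Parameters describing the axisymmetric half-dome section of the optic
#' vesicle: the mid-surface dome radius, the epithelial thickness, and the
#' arc fractions of the four regions (proximal to distal: non-retinal
#' neuroepithelium, RPE, hinge, neural retina).
#'
#' Lengths are dimensionless; the dome radius sets the unit. The apical
#' surface is the inner one (facing the vesicle lumen), so the apical arc is
#' shorter than the basal arc.
#'
#' @param radius Mid-surface dome radius (default 1; the length unit).
#' @param thickness Epithelial thickness (default 0.16 radii,
#'   comparable to the transmural natural length of the default
#'   mesh so the stress-free reference is consistent).
#' @param fractions Named non-negative fractions of the element range
#'   assigned to each region, ordered proximal to distal. Must sum to 1.
#' @return An object of class `ov_geometry`.
#' @export
#' @examples
#' geometry_params()
geometry_params <- function(radius = 1, thickness = 0.16,
                            fractions = c(non_retinal = 0.20, RPE = 0.34,
                                          hinge = 0.06, NR = 0.40)) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("`radius` must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1 ||
      !is.finite(thickness) || thickness <= 0)
    stop("`thickness` must be a positive finite scalar", call. = FALSE)
  if (thickness >= 2 * radius)
    stop("`thickness` must be smaller than the dome diameter", call. = FALSE)
  if (is.null(names(fractions)) || !setequal(names(fractions), region_levels))
    stop("`fractions` must be named: ",
         paste(region_levels, collapse = ", "), call. = FALSE)
  fractions <- fractions[region_levels]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
  structure(list(radius = radius, thickness = thickness,
                 fractions = fractions),
            class = "ov_geometry")
}

# Split n_el elements into contiguous regional blocks by fraction
# (largest-remainder apportionment; every region with a positive fraction
# keeps at least one element so the hinge never vanishes on coarse meshes).
region_counts <- function(n_el, fractions) {
  ideal <- fractions * n_el
  counts <- floor(ideal)
  rem <- n_el - sum(counts)
  if (rem > 0) {
    ord <- order(ideal - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  repeat {
    empty <- which(fractions > 0 & counts == 0)
    donors <- which(counts >= 2)
    if (length(empty) == 0 || length(donors) == 0) break
    take <- donors[which.max(counts[donors])]
    counts[take] <- counts[take] - 1
    counts[empty[1]] <- 1
  }
  as.integer(counts)
}

# Corner order of every quadrilateral element, matching the column order of
# the element table: (apical_i, apical_i+1, basal_i+1, basal_i).
corner_cols <- c("a1", "a2", "b2", "b1")

# Interior corner angles of each element, nel x 4, in the corner_cols order.
# sigma is the (constant) polygon orientation sign of the mesh; angles of a
# simple quadrilateral come out positive.
corner_angles <- function(P, C, sigma) {
  th <- matrix(0, nrow(C), 4)
  for (m in 1:4) {
    p <- C[, m]
    a <- C[, (m - 2) %% 4 + 1]  # previous corner (cyclic)
    b <- C[, m %% 4 + 1]        # next corner (cyclic)
    ux <- P[a, 1] - P[p, 1]; uy <- P[a, 2] - P[p, 2]
    vx <- P[b, 1] - P[p, 1]; vy <- P[b, 2] - P[p, 2]
    s <- -sigma * (ux * vy - uy * vx)
    cc <- ux * vx + uy * vy
    th[, m] <- atan2(s, cc)
  }
  th
}

# Signed planar area (orientation-corrected), centroid distance from the
# axis, and axisymmetric volume V = 2*pi*xbar*A of every element.
quad_volumes <- function(P, C, sigma) {
  X <- matrix(P[C, 1], nrow(C), 4)
  Z <- matrix(P[C, 2], nrow(C), 4)
  A <- 0.5 * sigma *
    (X[, 1] * Z[, 2] - X[, 2] * Z[, 1] +
     X[, 2] * Z[, 3] - X[, 3] * Z[, 2] +
     X[, 3] * Z[, 4] - X[, 4] * Z[, 3] +
     X[, 4] * Z[, 1] - X[, 1] * Z[, 4])
  xbar <- unname(rowMeans(X))
  A <- unname(A)
  list(A = A, xbar = xbar, V = 2 * pi * xbar * A, X = X, Z = Z)
}

tri_area <- function(x1, z1, x2, z2, x3, z3) {
  0.5 * ((x2 - x1) * (z3 - z1) - (x3 - x1) * (z2 - z1))
}

# A quadrilateral is simple iff at least one diagonal splits it into two
# triangles of equal sign; a bowtie fails both splits.
quad_simple <- function(P, C, sigma) {
  X <- matrix(P[C, 1], nrow(C), 4)
  Z <- matrix(P[C, 2], nrow(C), 4)
  t1 <- sigma * tri_area(X[, 1], Z[, 1], X[, 2], Z[, 2], X[, 3], Z[, 3])
  t2 <- sigma * tri_area(X[, 1], Z[, 1], X[, 3], Z[, 3], X[, 4], Z[, 4])
  t3 <- sigma * tri_area(X[, 2], Z[, 2], X[, 3], Z[, 3], X[, 4], Z[, 4])
  t4 <- sigma * tri_area(X[, 2], Z[, 2], X[, 4], Z[, 4], X[, 1], Z[, 1])
  ok_diag1 <- t1 > 0 & t2 > 0
  ok_diag2 <- t3 > 0 & t4 > 0
  ok_diag1 | ok_diag2
}

# Assemble an ov_tissue from ordered apical and basal vertex chains
# (n x 2 matrices, proximal first).
assemble_tissue <- function(A, B, mechanics, geometry, kind) {
  n <- nrow(A)
  stopifnot(nrow(B) == n)
  P <- rbind(A, B)
  vertices <- tibble::tibble(
    id = seq_len(2L * n),
    surface = rep(c("apical", "basal"), each = n),
    arc = rep(seq_len(n), 2L),
    x = P[, 1], z = P[, 2],
    x0 = P[, 1])
  ia <- seq_len(n - 1L)
  si <- c(ia, n + ia, seq_len(n))
  sj <- c(ia + 1L, n + ia + 1L, n + seq_len(n))
  l <- sqrt((P[si, 1] - P[sj, 1])^2 + (P[si, 2] - P[sj, 2])^2)
  springs <- tibble::tibble(
    kind = rep(c("apical", "basal", "transmural"), c(n - 1L, n - 1L, n)),
    i = si, j = sj,
    element = c(ia, ia, pmin(seq_len(n), n - 1L)),
    l0 = l,
    k = rep(c(mechanics$k_a, mechanics$k_b, mechanics$k_t),
            c(n - 1L, n - 1L, n)),
    phase0_l0 = NA_real_,
    phase0_k = NA_real_)
  counts <- region_counts(n - 1L, geometry$fractions)
  region <- rep(region_levels, counts)
  C <- cbind(a1 = ia, a2 = ia + 1L, b2 = n + ia + 1L, b1 = n + ia)
  sigma <- sign(0.5 * (
    P[C[1, 1], 1] * P[C[1, 2], 2] - P[C[1, 2], 1] * P[C[1, 1], 2] +
    P[C[1, 2], 1] * P[C[1, 3], 2] - P[C[1, 3], 1] * P[C[1, 2], 2] +
    P[C[1, 3], 1] * P[C[1, 4], 2] - P[C[1, 4], 1] * P[C[1, 3], 2] +
    P[C[1, 4], 1] * P[C[1, 1], 2] - P[C[1, 1], 1] * P[C[1, 4], 2]))
  if (sigma == 0) stop("degenerate first element at construction",
                       call. = FALSE)
  if (!all(quad_simple(P, C, sigma)))
    stop("self-intersecting element at construction", call. = FALSE)
  q <- quad_volumes(P, C, sigma)
  th <- corner_angles(P, C, sigma)
  elements <- tibble::tibble(
    element = ia,
    a1 = C[, 1], a2 = C[, 2], b2 = C[, 3], b1 = C[, 4],
    region = region,
    V_eq = q$V,
    th_eq_a1 = th[, 1], th_eq_a2 = th[, 2],
    th_eq_b2 = th[, 3], th_eq_b1 = th[, 4])
  # corner-angle regularization length: below this edge length the
  # self-righting penalty fades out (sub-resolution edges carry no
  # meaningful corner angle); fixed at construction
  l_reg <- 0.25 * min(l[seq_len(2L * (n - 1L))])
  structure(list(vertices = vertices, springs = springs, elements = elements,
                 meta = list(n = n, geometry = geometry, sigma = sigma,
                             kind = kind, prestressed = FALSE,
                             phase1 = FALSE, l_reg = l_reg)),
            class = "ov_tissue")
}

#' Build the meridional half-dome vesicle mesh
#'
#' Discretizes a half dome of the optic vesicle (a quarter-circle meridian
#' from the proximal equator to the distal pole) into `n_per_surface`
#' apical and `n_per_surface` basal vertices joined by apical, basal, and
#' transmural springs, giving `n_per_surface - 1` quadrilateral elements.
#' The mesh is built stress-free (every spring at its natural length;
#' equilibrium volumes, equilibrium corner angles, and reference off-axis
#' distances recorded from this configuration) and, by default, the Phase 0
#' prestress of [phase0_prestress()] is then applied.
#'
#' @param n_per_surface Number of vertices per surface (>= 8).
#' @param geometry An [geometry_params()] object.
#' @param mechanics A [mechanics_params()] object; supplies the baseline
#'   spring stiffnesses stored on the mesh.
#' @param prestress Apply the Phase 0 prestress (default `TRUE`).
#' @return An object of class `ov_tissue` with tibbles `vertices`,
#'   `springs`, `elements`.
#' @seealso [phase0_prestress()], [phase1_deepen()], [make_fixture()]
#' @export
#' @examples
#' tis <- build_vesicle(20)
#' tis
build_vesicle <- function(n_per_surface = 100, geometry = geometry_params(),
                          mechanics = mechanics_params(), prestress = TRUE) {
  n <- as.integer(n_per_surface)
  if (is.na(n) || n < 8)
    stop("`n_per_surface` must be at least 8 (degenerate curvature below)",
         call. = FALSE)
  R <- geometry$radius; h <- geometry$thickness
  Ra <- R - h / 2; Rb <- R + h / 2
  if (Ra <= 0) stop("`thickness` too large for `radius`", call. = FALSE)
  phi <- seq(0, pi / 2, length.out = n)
  A <- cbind(Ra * cos(phi), Ra * sin(phi))
  B <- cbind(Rb * cos(phi), Rb * sin(phi))
  A[n, 1] <- 0; B[n, 1] <- 0  # pole exactly on the symmetry axis
  A[n, 2] <- Ra; B[n, 2] <- Rb
  tis <- assemble_tissue(A, B, mechanics, geometry, kind = "vesicle")
  if (prestress) tis <- phase0_prestress(tis)
  tis
}

# Flat-strip mesh (test fixture): basal chain at z = 0, apical chain at
# z = thickness, spanning x in [x_start, x_start + length]. Stress-free.
build_strip <- function(n, length = 1, thickness = 0.1, x_start = 1,
                        mechanics = mechanics_params(),
                        geometry = geometry_params(thickness = thickness)) {
  n <- as.integer(n)
  if (n < 2) stop("strip needs at least 2 vertices per surface",
                  call. = FALSE)
  x <- seq(x_start, x_start + length, length.out = n)
  A <- cbind(x, rep(thickness, n))
  B <- cbind(x, rep(0, n))
  assemble_tissue(A, B, mechanics, geometry, kind = "strip")
}

#' Region label of an element
#'
#' @param tissue An `ov_tissue`.
#' @param element_index Element index (1-based, proximal to distal).
#' @return One of `"non_retinal"`, `"RPE"`, `"hinge"`, `"NR"`.
#' @export
region_of <- function(tissue, element_index) {
  stopifnot(inherits(tissue, "ov_tissue"))
  n_el <- nrow(tissue$elements)
  if (!is.numeric(element_index) || length(element_index) != 1 ||
      is.na(element_index) || element_index < 1 || element_index > n_el ||
      element_index != as.integer(element_index))
    stop("`element_index` must be an integer in 1..", n_el, call. = FALSE)
  tissue$elements$region[[as.integer(element_index)]]
}

#' Axisymmetric element volume
#'
#' The planar quadrilateral area in the meridional section multiplied by
#' the circumferential weight `2*pi*xbar`, where `xbar` is the mean corner
#' distance from the symmetry axis.
#'
#' @inheritParams region_of
#' @return Positive scalar volume.
#' @export
element_volume <- function(tissue, element_index) {
  stopifnot(inherits(tissue, "ov_tissue"))
  n_el <- nrow(tissue$elements)
  if (!is.numeric(element_index) || length(element_index) != 1 ||
      is.na(element_index) || element_index < 1 || element_index > n_el)
    stop("`element_index` must be an integer in 1..", n_el, call. = FALSE)
  i <- as.integer(element_index)
  P <- tissue_positions(tissue)
  C <- element_corners(tissue)[i, , drop = FALSE]
  sigma <- tissue$meta$sigma
  q <- quad_volumes(P, C, sigma)
  if (!quad_simple(P, C, sigma) || q$A <= 0 ||
      abs(q$A) < 1e-14 * max(abs(P)))
    stop("element ", i, " is degenerate (collinear or self-intersecting)",
         call. = FALSE)
  unname(q$V)
}

# position matrix (2n x 2) in vertex-id order
tissue_positions <- function(tissue) {
  cbind(tissue$vertices$x, tissue$vertices$z)
}

# corner-id matrix (nel x 4), columns a1, a2, b2, b1
element_corners <- function(tissue) {
  as.matrix(tissue$elements[, corner_cols])
}

#' @export
print.ov_tissue <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<ov_tissue> %s: %d vertices/surface, %d elements, %d springs\n",
    m$kind, m$n, nrow(x$elements), nrow(x$springs)))
  cat(sprintf("  prestressed: %s, phase1 deepening: %s\n",
              m$prestressed, m$phase1))
  counts <- table(factor(x$elements$region, levels = region_levels))
  cat("  regions (proximal->distal): ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ov_tissue <- function(x, ...) {
  x$vertices
}
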