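#' Signed curvature profile of the apical surface
#'
#' Discrete signed curvature at every interior apical vertex from the
#' circumscribed circle of the vertex and its two arc neighbours. The sign
#' convention is morphological: positive when the centre of the osculating
#' circle lies on the apical (interior) side of the surface ("apically
#' concave"), negative when it lies basally ("apically convex"). A
#' collinear triple has curvature 0.
#'
#' @param tissue An `ov_tissue` (or `ov_state`).
#' @return A tibble with one row per interior apical vertex: `arc`, `s`
#'   (arc length from the proximal end), `region` (region of the distal
#'   adjacent element), `kappa`.
#' @export
curvature_profile <- function(tissue) {
  if (inherits(tissue, "ov_state")) tissue <- as_tissue(tissue)
  stopifnot(inherits(tissue, "ov_tissue"))
  n <- tissue$meta$n
  if (n < 3) stop("need at least 3 apical vertices", call. = FALSE)
  v <- tissue$vertices
  A <- cbind(v$x[v$surface == "apical"], v$z[v$surface == "apical"])
  B <- cbind(v$x[v$surface == "basal"], v$z[v$surface == "basal"])
  seg <- sqrt(rowSums((A[-1, , drop = FALSE] - A[-n, , drop = FALSE])^2))
  if (any(seg == 0))
    stop("coincident apical vertices", call. = FALSE)
  s <- c(0, cumsum(seg))
  i <- 2:(n - 1)
  x1 <- A[i - 1, 1]; z1 <- A[i - 1, 2]
  x2 <- A[i, 1];     z2 <- A[i, 2]
  x3 <- A[i + 1, 1]; z3 <- A[i + 1, 2]
  d <- 2 * (x1 * (z2 - z3) + x2 * (z3 - z1) + x3 * (z1 - z2))
  scale2 <- (x1 - x3)^2 + (z1 - z3)^2
  kappa <- numeric(length(i))
  ok <- abs(d) > 1e-12 * pmax(scale2, 1e-300)
  q1 <- x1^2 + z1^2; q2 <- x2^2 + z2^2; q3 <- x3^2 + z3^2
  ux <- (q1 * (z2 - z3) + q2 * (z3 - z1) + q3 * (z1 - z2)) / d
  uz <- (q1 * (x3 - x2) + q2 * (x1 - x3) + q3 * (x2 - x1)) / d
  r <- sqrt((ux - x2)^2 + (uz - z2)^2)
  # apical normal: from the basal partner toward the apical vertex
  nx <- A[i, 1] - B[i, 1]; nz <- A[i, 2] - B[i, 2]
  side <- sign((ux - x2) * nx + (uz - z2) * nz)
  kappa[ok] <- (side / r)[ok]
  region_el <- tissue$elements$region
  tibble::tibble(arc = i, s = s[i],
                 region = region_el[pmin(i, n - 1L)],
                 kappa = kappa)
}

# arc indices of interior apical vertices inside the central `window`
# fraction of the NR block (trimmed to avoid hinge edge effects)
nr_window_arcs <- function(tissue, window = 0.5) {
  el <- tissue$elements
  nr <- which(el$region == "NR")
  n <- tissue$meta$n
  arcs <- unique(c(el$a1[nr], el$a2[nr] - 0L))
  arcs <- sort(arcs[arcs >= 2 & arcs <= n - 1])
  if (window < 1) {
    lo <- quantile(arcs, 0.5 - window / 2, type = 1)
    hi <- quantile(arcs, 0.5 + window / 2, type = 1)
    arcs <- arcs[arcs >= lo & arcs <= hi]
  }
  arcs
}

#' Summary signed apical curvature over the neural retina
#'
#' `mean_nr_curvature()` averages the signed curvature over the central
#' portion of the NR arc (default: central 50%, avoiding hinge edge
#' effects). `median_nr_curvature()` takes the median over all interior
#' NR vertices; in a folded cup the rim loops carry curvatures an order
#' of magnitude above the tissue scale, so the median — "is most of the
#' NR apically concave or apically convex?" — is the robust summary the
#' outcome classification uses.
#'
#' @inheritParams curvature_profile
#' @param window Central fraction of the NR arc to average over.
#' @return Scalar signed curvature summary.
#' @export
mean_nr_curvature <- function(tissue, window = 0.5) {
  if (inherits(tissue, "ov_state")) tissue <- as_tissue(tissue)
  cp <- curvature_profile(tissue)
  arcs <- nr_window_arcs(tissue, window)
  mean(cp$kappa[cp$arc %in% arcs])
}

#' @rdname mean_nr_curvature
#' @export
median_nr_curvature <- function(tissue) {
  if (inherits(tissue, "ov_state")) tissue <- as_tissue(tissue)
  cp <- curvature_profile(tissue)
  stats::median(cp$kappa[cp$region == "NR"])
}

# height of the NR above the hinge plane (the plane through the two
# mirror-image hinge-centre apical vertices of the full section is
# horizontal): either the apical pole vertex ("pole") or the mean over
# the NR apical vertices ("mean"; robust to which buckling mode carries
# the displacement)
nr_height <- function(tissue, measure = c("mean", "pole")) {
  measure <- match.arg(measure)
  if (inherits(tissue, "ov_state")) tissue <- as_tissue(tissue)
  el <- tissue$elements
  hinge <- which(el$region == "hinge")
  if (length(hinge) == 0) stop("hinge region is empty", call. = FALSE)
  hc <- hinge[ceiling(length(hinge) / 2)]
  v <- tissue$vertices
  ap <- v[v$surface == "apical", ]
  z_hinge <- ap$z[ap$arc == el$a1[hc]]
  z_nr <- if (measure == "pole") {
    ap$z[ap$arc == tissue$meta$n]
  } else {
    arcs <- unique(c(el$a1[el$region == "NR"], el$a2[el$region == "NR"]))
    mean(ap$z[ap$arc %in% arcs])
  }
  z_nr - z_hinge
}

#' Apical hinge angle
#'
#' Mean apical corner angle over the hinge elements; pi/2 for rectangular
#' elements, below pi/2 (acute) once the hinge has constricted apically.
#'
#' @inheritParams curvature_profile
#' @return Angle in radians.
#' @export
hinge_apical_angle <- function(tissue) {
  if (inherits(tissue, "ov_state")) tissue <- as_tissue(tissue)
  stopifnot(inherits(tissue, "ov_tissue"))
  el <- tissue$elements
  hinge <- which(el$region == "hinge")
  if (length(hinge) == 0) stop("hinge region is empty", call. = FALSE)
  P <- tissue_positions(tissue)
  C <- element_corners(tissue)[hinge, , drop = FALSE]
  th <- corner_angles(P, C, tissue$meta$sigma)
  mean(th[, 1:2])  # columns a1, a2 are the apical corners
}

#' NR flattening index
#'
#' Ratio of the mean absolute apical curvature over the NR at the end of
#' Phase 2 to that at the end of Phase 1 (the settling window). Below 1
#' when rule 1 has flattened the presumptive NR.
#'
#' @param trajectory An `ov_trajectory` whose snapshots cover Phases 1-2.
#' @return Scalar ratio.
#' @export
nr_flattening_index <- function(trajectory) {
  stopifnot(inherits(trajectory, "ov_trajectory"))
  b <- trajectory$boundaries
  t1 <- snapshot_tissue(trajectory, b[["t1"]])
  t2 <- snapshot_tissue(trajectory, b[["t2"]])
  arcs <- nr_window_arcs(t1, window = 1)
  k1 <- curvature_profile(t1)
  k2 <- curvature_profile(t2)
  mean(abs(k2$kappa[k2$arc %in% arcs])) /
    mean(abs(k1$kappa[k1$arc %in% arcs]))
}

#' Invagination depth of a state relative to a reference
#'
#' Displacement of the NR apical surface toward the vesicle interior,
#' measured relative to the plane of the hinge-centre apical vertices:
#' positive when the NR has moved inside, negative when it has moved
#' further out. `measure = "mean"` (the default, used by the outcome
#' classification) averages over the NR apical vertices and registers
#' the displacement whichever buckling mode carries it; `measure =
#' "pole"` tracks the single NR-centre (pole) vertex.
#'
#' @param tissue Current `ov_tissue` (or `ov_state`).
#' @param reference Reference `ov_tissue` (normally the settled Phase 1
#'   vesicle).
#' @param measure `"mean"` or `"pole"`.
#' @return Scalar depth (length units).
#' @export
invagination_depth <- function(tissue, reference,
                               measure = c("mean", "pole")) {
  measure <- match.arg(measure)
  nr_height(reference, measure) - nr_height(tissue, measure)
}

#' Classify the morphological outcome of a run
#'
#' On the final state, relative to the settled Phase 1 vesicle:
#' `invaginated` if the invagination depth exceeds `d_min` *and* the NR
#' apical curvature summary has flipped sign (apically concave to
#' apically convex); `evaginated` if the depth is below `-d_min` with no
#' sign flip; otherwise `flat`. The curvature summary is the median over
#' the NR ([median_nr_curvature()]): in a folded cup the rim loops carry
#' extreme local curvatures of both signs, so the median captures the
#' categorical claim — the bulk of the NR has become apically convex —
#' where a windowed mean is dominated by the fold apices. The windowed
#' mean is also computed and reported.
#'
#' @param trajectory A completed `ov_trajectory`.
#' @param d_min Depth threshold; default half the epithelial thickness.
#' @param window Central NR fraction for the reported curvature mean.
#' @return An `ov_outcome` object (see [glance.ov_outcome()]).
#' @export
classify_outcome <- function(trajectory, d_min = NULL, window = 0.5) {
  stopifnot(inherits(trajectory, "ov_trajectory"))
  if (!identical(trajectory$termination, "completed"))
    stop("refusing to classify an aborted trajectory (",
         trajectory$termination, ")", call. = FALSE)
  th <- trajectory$template$meta$geometry$thickness
  if (is.null(d_min)) d_min <- 0.5 * th
  b <- trajectory$boundaries
  ref <- snapshot_tissue(trajectory, b[["t1"]])
  fin <- snapshot_tissue(trajectory, b[["t_end"]])
  depth <- invagination_depth(fin, ref, measure = "mean")
  k_ref <- median_nr_curvature(ref)
  k_fin <- median_nr_curvature(fin)
  flipped <- (k_ref > 0) && (k_fin < 0)
  outcome <- if (depth > d_min && flipped) "invaginated"
  else if (depth < -d_min && !flipped) "evaginated"
  else "flat"
  structure(list(outcome = outcome,
                 invagination_depth = depth,
                 pole_depth = invagination_depth(fin, ref,
                                                 measure = "pole"),
                 d_min = d_min,
                 nr_curvature = k_fin,
                 nr_curvature_ref = k_ref,
                 mean_nr_curvature = mean_nr_curvature(fin, window),
                 curvature_flipped = flipped,
                 hinge_apical_angle = hinge_apical_angle(fin),
                 nr_flattening = nr_flattening_index(trajectory)),
            class = "ov_outcome")
}

#' @export
print.ov_outcome <- function(x, ...) {
  cat(sprintf("<ov_outcome> %s\n", x$outcome))
  cat(sprintf("  invagination depth %.4g (threshold %.3g)\n",
              x$invagination_depth, x$d_min))
  cat(sprintf("  median NR apical curvature %.4g (Phase 1 reference %.4g)\n",
              x$nr_curvature, x$nr_curvature_ref))
  cat(sprintf("  hinge apical angle %.4g rad, NR flattening index %.3g\n",
              x$hinge_apical_angle, x$nr_flattening))
  invisible(x)
}

#' One-row summary of an outcome
#'
#' @param x An `ov_outcome`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ov_outcome <- function(x, ...) {
  tibble::tibble(outcome = x$outcome,
                 invagination_depth = x$invagination_depth,
                 nr_curvature = x$nr_curvature,
                 nr_curvature_ref = x$nr_curvature_ref,
                 mean_nr_curvature = x$mean_nr_curvature,
                 curvature_flipped = x$curvature_flipped,
                 hinge_apical_angle = x$hinge_apical_angle,
                 nr_flattening = x$nr_flattening,
                 d_min = x$d_min)
}

#' @export
tidy.ov_outcome <- function(x, ...) {
  tibble::tibble(
    metric = c("invagination_depth", "nr_curvature", "nr_curvature_ref",
               "mean_nr_curvature", "hinge_apical_angle",
               "nr_flattening", "d_min"),
    value = c(x$invagination_depth, x$nr_curvature, x$nr_curvature_ref,
              x$mean_nr_curvature, x$hinge_apical_angle,
              x$nr_flattening, x$d_min))
}
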