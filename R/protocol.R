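#' Phase schedule and rule ramps
#'
#' Encodes the timeline of the morphogenetic protocol. Phases 0 and 1 are
#' applied as instantaneous setup before the dynamics ([phase0_prestress()],
#' [phase1_deepen()]); the clock then runs through a Phase 1 settling
#' window, Phases 2-4, and a final equilibration window. The three local
#' rules act as continuous ramps:
#'
#' * **Rule 1 (NR relaxation)** - from the start of Phase 2 to the end of
#'   the run, the natural lengths of apical and basal springs in the NR
#'   creep toward their current lengths at rate `lambda` (releasing
#'   stored tangential strain energy and keeping the NR plastic through
#'   invagination); over Phase 3 the NR apical/basal stiffnesses ramp
#'   linearly down to 25% of their Phase 0 values and are then held.
#' * **Rule 2 (hinge apical constriction)** - over Phase 3 the hinge apical
#'   natural lengths ramp linearly to 10% of Phase 0 and the hinge apical
#'   stiffness to 10x Phase 0, then held.
#' * **Rule 3 (tangential growth)** - over Phase 4 the apical/basal natural
#'   lengths and equilibrium volumes of the NR and the distal half of the
#'   RPE scale by a factor growing linearly from 1 to `G_final`, then held.
#'
#' @param settle,phase2,phase3,phase4,equilibrate Durations (dimensionless
#'   time units) of the Phase 1 settling window, Phases 2-4, and the final
#'   equilibration window.
#' @param lambda Rule 1 natural-length relaxation rate (per time unit)
#'   for springs under tension. The default 3 drives NR tangential
#'   elastic energy below 5% of its Phase 1 value by the end of Phase 2.
#' @param lambda_c Relaxation rate for springs under compression
#'   (default `lambda / 10`). Tension releases quickly (loss of the
#'   actomyosin prestress); compression remodels more slowly, so folds
#'   driven into the NR are gradually made plastic instead of springing
#'   back, without letting compressed edges ratchet to zero length on
#'   the folding timescale.
#' @param G_final Rule 3 growth fold at the end of Phase 4.
#' @param rule1,rule2,rule3 Enable flags for the three rules.
#' @return An object of class `ov_schedule` with named boundary times
#'   `t0 < t1 < t2 < t3 < t4 < t_end` (Phase 2 starts at `t1`).
#' @export
phase_schedule <- function(settle = 150, phase2 = 150, phase3 = 150,
                           phase4 = 150, equilibrate = 450, lambda = 3,
                           lambda_c = 0,
                           creep_through = TRUE, G_final = 2,
                           rule1 = TRUE, rule2 = TRUE, rule3 = TRUE) {
  durs <- c(settle = settle, phase2 = phase2, phase3 = phase3,
            phase4 = phase4, equilibrate = equilibrate)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all phase durations must be positive and finite", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0)
    stop("`lambda` must be non-negative", call. = FALSE)
  if (!is.finite(lambda_c) || lambda_c < 0)
    stop("`lambda_c` must be non-negative", call. = FALSE)
  if (!is.finite(G_final) || G_final <= 0)
    stop("`G_final` must be positive", call. = FALSE)
  b <- cumsum(c(t0 = 0, durs))
  names(b) <- c("t0", "t1", "t2", "t3", "t4", "t_end")
  sched <- structure(list(boundaries = b, lambda = lambda,
                          lambda_c = lambda_c,
                          creep_through = isTRUE(creep_through),
                          G_final = G_final,
                          rule1 = isTRUE(rule1), rule2 = isTRUE(rule2),
                          rule3 = isTRUE(rule3)),
                     class = "ov_schedule")
  validate_ramps(schedule_ramps(sched))
  sched
}

#' Ramp table of a schedule
#'
#' The canonical tabular description of what each enabled rule changes,
#' where, and when. Used for schedule validation and reporting.
#'
#' @param schedule An [phase_schedule()] object.
#' @return A tibble with columns `rule`, `quantity`, `region`, `t_start`,
#'   `t_end`, `mode`, `value` (final factor relative to Phase 0, or the
#'   relaxation rate).
#' @export
schedule_ramps <- function(schedule) {
  b <- schedule$boundaries
  out <- list()
  if (schedule$rule1) {
    out <- c(out, list(
      tibble::tibble(rule = 1L,
                     quantity = c("apical_l0", "basal_l0"),
                     region = "NR", t_start = b[["t1"]],
                     t_end = if (schedule$creep_through) b[["t_end"]]
                             else b[["t2"]],
                     mode = "relax_to_current", value = schedule$lambda),
      tibble::tibble(rule = 1L,
                     quantity = c("apical_k", "basal_k"),
                     region = "NR", t_start = b[["t2"]], t_end = b[["t3"]],
                     mode = "multiplicative_to", value = 0.25)))
  }
  if (schedule$rule2) {
    out <- c(out, list(
      tibble::tibble(rule = 2L,
                     quantity = c("apical_l0", "apical_k"),
                     region = "hinge", t_start = b[["t2"]],
                     t_end = b[["t3"]],
                     mode = "multiplicative_to", value = c(0.10, 10))))
  }
  if (schedule$rule3) {
    out <- c(out, list(
      tibble::tibble(rule = 3L,
                     quantity = rep(c("apical_l0", "basal_l0", "V_eq"), 2),
                     region = rep(c("NR", "RPE_distal"), each = 3),
                     t_start = b[["t3"]], t_end = b[["t4"]],
                     mode = "multiplicative_to", value = schedule$G_final)))
  }
  if (length(out) == 0)
    return(tibble::tibble(rule = integer(), quantity = character(),
                          region = character(), t_start = numeric(),
                          t_end = numeric(), mode = character(),
                          value = numeric()))
  dplyr::bind_rows(out)
}

#' Validate a ramp table
#'
#' Rejects ill-formed windows and contradictory ramps: two
#' absolute-valued (`multiplicative_to`) ramps that target the same
#' quantity in the same region over overlapping time windows. A
#' rate-based `relax_to_current` creep composes with a multiplicative
#' ramp and may overlap one (rule 1's creep runs through rule 3's growth
#' window).
#'
#' @param ramps A tibble as returned by [schedule_ramps()].
#' @return The ramp table, invisibly, if valid.
#' @export
validate_ramps <- function(ramps) {
  if (nrow(ramps) == 0) return(invisible(ramps))
  if (any(ramps$t_start >= ramps$t_end))
    stop("ramp windows must have t_start < t_end", call. = FALSE)
  if (any(ramps$mode == "multiplicative_to" & ramps$value <= 0))
    stop("final ramp factors must be positive", call. = FALSE)
  if (any(ramps$mode == "relax_to_current" & ramps$value < 0))
    stop("relaxation rates must be non-negative", call. = FALSE)
  n <- nrow(ramps)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        same <- ramps$quantity[a] == ramps$quantity[b] &&
          ramps$region[a] == ramps$region[b] &&
          ramps$mode[a] == "multiplicative_to" &&
          ramps$mode[b] == "multiplicative_to"
        overlap <- ramps$t_start[a] < ramps$t_end[b] &&
          ramps$t_start[b] < ramps$t_end[a]
        if (same && overlap)
          stop("overlapping ramps target ", ramps$quantity[a], " in ",
               ramps$region[a], call. = FALSE)
      }
    }
  }
  invisible(ramps)
}

phase_of <- function(t, b) {
  if (t < b[["t1"]]) "phase1"
  else if (t < b[["t2"]]) "phase2"
  else if (t < b[["t3"]]) "phase3"
  else if (t < b[["t4"]]) "phase4"
  else "equilibration"
}

ramp_frac <- function(t, t0, t1) min(max((t - t0) / (t1 - t0), 0), 1)

#' @export
print.ov_schedule <- function(x, ...) {
  b <- x$boundaries
  cat("<ov_schedule>\n")
  cat(sprintf("  phase 1 settle [%g, %g), phase 2 [%g, %g), phase 3 [%g, %g), phase 4 [%g, %g), equilibration [%g, %g]\n",
              b[["t0"]], b[["t1"]], b[["t1"]], b[["t2"]], b[["t2"]],
              b[["t3"]], b[["t3"]], b[["t4"]], b[["t4"]], b[["t_end"]]))
  cat(sprintf("  rules: 1 (NR relaxation) %s, 2 (hinge constriction) %s, 3 (growth) %s\n",
              x$rule1, x$rule2, x$rule3))
  cat(sprintf("  lambda = %g, G_final = %g\n", x$lambda, x$G_final))
  invisible(x)
}

# ---- Phase 0 / Phase 1 setup ---------------------------------------------

#' Apply the Phase 0 prestress
#'
#' Starting from a stress-free mesh: every apical natural length is set 14%
#' shorter than its basal counterpart (`l0_a = 0.86 l0_b`) with equal
#' spring constants, and the transmural springs are made 10 times longer
#' and 10 times softer than the basal springs. The resulting natural
#' lengths and stiffnesses are recorded as the Phase 0 reference that the
#' rule ramps refer back to.
#'
#' @param tissue A freshly built, stress-free `ov_tissue`.
#' @return The prestressed tissue.
#' @export
phase0_prestress <- function(tissue) {
  stopifnot(inherits(tissue, "ov_tissue"))
  if (isTRUE(tissue$meta$prestressed))
    stop("Phase 0 prestress has already been applied", call. = FALSE)
  sp <- tissue$springs
  n <- tissue$meta$n
  ap <- which(sp$kind == "apical")
  ba <- which(sp$kind == "basal")
  tr <- which(sp$kind == "transmural")
  # apical and basal springs are stored in the same element order
  sp$l0[ap] <- 0.86 * sp$l0[ba]
  sp$k[ap] <- sp$k[ba]
  # transmural reference: mean natural length/stiffness of adjacent basal
  # springs (all equal on a uniform mesh)
  bl <- sp$l0[ba]; bk <- sp$k[ba]
  left <- c(NA, bl); right <- c(bl, NA)
  ref_l <- rowMeans(cbind(left, right), na.rm = TRUE)
  kleft <- c(NA, bk); kright <- c(bk, NA)
  ref_k <- rowMeans(cbind(kleft, kright), na.rm = TRUE)
  sp$l0[tr] <- 10 * ref_l
  sp$k[tr] <- 0.1 * ref_k
  sp$phase0_l0 <- sp$l0
  sp$phase0_k <- sp$k
  tissue$springs <- sp
  tissue$meta$prestressed <- TRUE
  tissue
}

#' Apply the Phase 1 deepening
#'
#' The apical springs of the retinal epithelium (RPE, hinge, and NR
#' regions) are shortened a further 10% relative to Phase 0
#' (`l0_a = 0.774 l0_b` net), fitting the larger curvature of the
#' evaginated optic vesicle. The non-retinal region and all stiffnesses
#' are untouched.
#'
#' @param tissue A Phase 0 prestressed `ov_tissue`.
#' @return The deepened tissue.
#' @export
phase1_deepen <- function(tissue) {
  stopifnot(inherits(tissue, "ov_tissue"))
  if (!isTRUE(tissue$meta$prestressed))
    stop("apply `phase0_prestress()` first", call. = FALSE)
  if (isTRUE(tissue$meta$phase1))
    stop("Phase 1 deepening has already been applied", call. = FALSE)
  sp <- tissue$springs
  region_sp <- tissue$elements$region[sp$element]
  sel <- sp$kind == "apical" & region_sp %in% retinal_regions
  sp$l0[sel] <- 0.90 * sp$phase0_l0[sel]
  tissue$springs <- sp
  tissue$meta$phase1 <- TRUE
  tissue
}

# ---- rule application -----------------------------------------------------

# region codes: 1 non_retinal, 2 RPE, 3 hinge, 4 NR
nr_tangential <- function(ar) {
  ar$skind <= 2 & ar$region_sp == 4L
}

hinge_apical <- function(ar) {
  ar$skind == 1L & ar$region_sp == 3L
}

# elements subject to rule 3: NR plus the distal half (by element count)
# of the RPE block
growth_elements <- function(ar) {
  idx <- seq_along(ar$region_el)
  nr <- ar$region_el == 4L
  rpe <- which(ar$region_el == 2L)
  grow <- nr
  if (length(rpe) > 0) {
    n_distal <- floor(length(rpe) / 2)
    if (n_distal > 0) grow[utils::tail(rpe, n_distal)] <- TRUE
  }
  grow
}

capture_base <- function(state, key, value) {
  if (is.null(state$base[[key]])) assign(key, value, envir = state$base)
  state$base[[key]]
}

#' Rule 1: neural-retina relaxation
#'
#' From the start of Phase 2 onward, the natural lengths of NR apical and
#' basal springs creep toward their current lengths
#' (`l0 <- l0 + lambda (l - l0) dt`), releasing the stored tangential
#' strain energy and keeping the NR effectively plastic throughout
#' invagination (its actomyosin tone, once lost, stays low). From the end
#' of Phase 2 through Phase 3 the NR apical/basal stiffnesses ramp
#' linearly to 25% of Phase 0 and are then held. Inert outside its
#' windows and region.
#'
#' @param state An `ov_state` (see [sim_state()]).
#' @param dt Time increment used for the rate-based length relaxation.
#' @return The updated state.
#' @export
rule1_relaxation <- function(state, dt) {
  sched <- state$schedule
  if (!sched$rule1) return(state)
  b <- sched$boundaries
  t <- state$time
  ar <- state$ar
  sel <- nr_tangential(ar)
  t_creep_end <- if (sched$creep_through) Inf else b[["t2"]]
  if (t >= b[["t1"]] && t < t_creep_end &&
      (sched$lambda > 0 || sched$lambda_c > 0)) {
    # asymmetric creep: natural lengths chase current lengths at rate
    # lambda under tension (release of the actomyosin prestress) and at
    # the slower lambda_c under compression (slow remodelling that makes
    # driven folds plastic without ratcheting edges to zero length on
    # the folding timescale)
    l <- spring_lengths(ar)
    up <- sel & l > ar$l0
    dn <- sel & l <= ar$l0
    ar$l0[up] <- ar$l0[up] + sched$lambda * (l[up] - ar$l0[up]) * dt
    if (sched$lambda_c > 0)
      ar$l0[dn] <- ar$l0[dn] + sched$lambda_c * (l[dn] - ar$l0[dn]) * dt
  }
  if (t >= b[["t2"]]) {
    f <- ramp_frac(t, b[["t2"]], b[["t3"]])
    base <- capture_base(state, "rule1_k", ar$kk[sel])
    target <- 0.25 * ar$phase0_k[sel]
    ar$kk[sel] <- if (f >= 1) target else base + (target - base) * f
  }
  state$ar <- ar
  state
}

#' Rule 2: hinge apical constriction
#'
#' Over Phase 3 the hinge apical natural lengths ramp linearly to 10% of
#' their Phase 0 values and the hinge apical stiffness to 10x Phase 0;
#' both are held thereafter. Inert outside its window and region.
#'
#' @inheritParams rule1_relaxation
#' @return The updated state.
#' @export
rule2_apical_constriction <- function(state) {
  sched <- state$schedule
  if (!sched$rule2) return(state)
  b <- sched$boundaries
  t <- state$time
  if (t < b[["t2"]]) return(state)
  ar <- state$ar
  sel <- hinge_apical(ar)
  f <- ramp_frac(t, b[["t2"]], b[["t3"]])
  base_l <- capture_base(state, "rule2_l0", ar$l0[sel])
  base_k <- capture_base(state, "rule2_k", ar$kk[sel])
  target_l <- 0.10 * ar$phase0_l0[sel]
  target_k <- 10 * ar$phase0_k[sel]
  if (f >= 1) {
    ar$l0[sel] <- target_l
    ar$kk[sel] <- target_k
  } else {
    ar$l0[sel] <- base_l + (target_l - base_l) * f
    ar$kk[sel] <- base_k + (target_k - base_k) * f
  }
  state$ar <- ar
  state
}

#' Rule 3: tangential growth
#'
#' Over Phase 4 the apical/basal natural lengths and equilibrium volumes
#' of the NR and the distal half of the RPE scale by a factor growing
#' linearly from 1 at the start of Phase 4 to `G_final` at its end, then
#' held. The natural-length scaling is applied multiplicatively (each call
#' applies the growth accrued since the previous one), so it composes
#' with the rule 1 length creep that stays active in the NR. Transmural
#' springs are untouched. Inert outside its window and regions.
#'
#' @inheritParams rule1_relaxation
#' @return The updated state.
#' @export
rule3_growth <- function(state) {
  sched <- state$schedule
  if (!sched$rule3) return(state)
  b <- sched$boundaries
  t <- state$time
  if (t < b[["t3"]]) return(state)
  ar <- state$ar
  grow_el <- growth_elements(ar)
  ssel <- ar$skind <= 2 & grow_el[ar$sel]
  f <- ramp_frac(t, b[["t3"]], b[["t4"]])
  g <- 1 + (sched$G_final - 1) * f
  g_prev <- capture_base(state, "rule3_g", 1)
  base_v <- capture_base(state, "rule3_Veq", ar$Veq[grow_el])
  ar$l0[ssel] <- ar$l0[ssel] * (g / g_prev)
  ar$Veq[grow_el] <- if (f >= 1) sched$G_final * base_v else base_v * g
  assign("rule3_g", g, envir = state$base)
  state$ar <- ar
  state
}

#' Apply all scheduled rules at the current clock
#'
#' Dispatches rules 1-3 according to the schedule's windows, regions, and
#' enable flags. Disabled rules are skipped entirely, which supports the
#' rules-1-and-2-omitted evagination control.
#'
#' @inheritParams rule1_relaxation
#' @param schedule An [phase_schedule()]; defaults to the one stored in
#'   the state.
#' @return The updated state (with its phase label refreshed).
#' @export
apply_schedule <- function(state, schedule = state$schedule, dt) {
  stopifnot(inherits(state, "ov_state"))
  state$schedule <- schedule
  # absolute ramps first, growth second, length creep last, so that the
  # creep always acts on the post-growth natural lengths
  state <- rule2_apical_constriction(state)
  state <- rule3_growth(state)
  state <- rule1_relaxation(state, dt)
  state$phase <- phase_of(state$time, schedule$boundaries)
  state
}
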