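#' Create a simulation state
#'
#' Wraps a tissue together with mechanical constants, a phase schedule, a
#' clock, and the flat arrays used by the integrator.
#'
#' @param tissue An `ov_tissue` (normally prestressed and deepened).
#' @param params An [mechanics_params()] object.
#' @param schedule An [phase_schedule()] object.
#' @param pinned Optional logical vector (one per vertex) overriding the
#'   default constraint set (proximal boundary pinned, pole vertices held
#'   on the symmetry axis); mainly for tests.
#' @return An object of class `ov_state`.
#' @export
sim_state <- function(tissue, params = mechanics_params(),
                      schedule = phase_schedule(), pinned = NULL) {
  ar <- tissue_arrays(tissue)
  if (!is.null(pinned)) {
    stopifnot(is.logical(pinned), length(pinned) == nrow(ar$P))
    ar$free <- !pinned
  }
  structure(list(time = 0, phase = phase_of(0, schedule$boundaries),
                 ar = ar, params = params, schedule = schedule,
                 base = new.env(parent = emptyenv()), step = 0L,
                 template = tissue),
            class = "ov_state")
}

#' @export
print.ov_state <- function(x, ...) {
  cat(sprintf("<ov_state> t = %.4g (%s), step %d, %d vertices\n",
              x$time, x$phase, x$step, nrow(x$ar$P)))
  invisible(x)
}

#' Recover a tissue from a state
#'
#' Writes the current vertex positions, spring parameters, and equilibrium
#' volumes back into tibble form.
#'
#' @param state An `ov_state`.
#' @return An `ov_tissue`.
#' @export
as_tissue <- function(state) {
  stopifnot(inherits(state, "ov_state"))
  tis <- state$template
  tis$vertices$x <- state$ar$P[, 1]
  tis$vertices$z <- state$ar$P[, 2]
  tis$springs$l0 <- state$ar$l0
  tis$springs$k <- state$ar$kk
  tis$elements$V_eq <- state$ar$Veq
  tis
}

ov_abort <- function(message, state) {
  structure(class = c("ov_instability", "error", "condition"),
            list(message = message, call = NULL, state = state))
}

#' One explicit Euler step of the overdamped flow
#'
#' `r_i <- r_i + (dt/eta) F_i` for free vertices; pinned vertices are held
#' and pole vertices are projected back onto the symmetry axis (`x = 0`)
#' after the step.
#'
#' @param state An `ov_state`.
#' @param dt Positive time step.
#' @return The advanced state.
#' @export
step_state <- function(state, dt) {
  stopifnot(inherits(state, "ov_state"), dt > 0)
  ar <- state$ar
  F <- force_arrays(ar, state$params)
  if (!all(is.finite(F)))
    stop(ov_abort(sprintf("non-finite force at t = %.6g", state$time),
                  state))
  mv <- (dt / state$params$eta) * F
  mv[!ar$free, ] <- 0
  ar$P <- ar$P + mv
  ar$P[ar$pole, 1] <- 0
  state$ar <- ar
  state$time <- state$time + dt
  state$step <- state$step + 1L
  state$phase <- phase_of(state$time, state$schedule$boundaries)
  state
}

#' Estimate the largest stable explicit time step
#'
#' Returns `eta / (c * k_eff)` where `k_eff` bounds the stiffest
#' per-vertex restoring response of the current configuration: incident
#' spring stiffnesses (including the current 10x hinge stiffening once
#' rule 2 has acted), the volumetric term, the corner-angle term, and the
#' hoop term. `c` is a safety factor.
#'
#' @param x An `ov_tissue` or `ov_state`.
#' @param params An [mechanics_params()] object (taken from the state when
#'   `x` is a state).
#' @param c_safety Safety factor (default 4).
#' @return A positive time step estimate.
#' @export
check_stability <- function(x, params = NULL, c_safety = 4) {
  ar <- as_arrays(x)
  if (is.null(params))
    params <- if (inherits(x, "ov_state")) x$params else mechanics_params()
  nv <- nrow(ar$P)
  keff <- numeric(nv)
  # springs: longitudinal stiffness k plus the transverse stiffness of a
  # stretched spring, k (1 - l0/l) when positive; the transverse response
  # of a compressed spring is destabilizing (negative curvature), which
  # gradient descent follows without a step-size penalty
  l <- spring_lengths(ar)
  ks <- ar$kk * (1 + pmax(0, 1 - ar$l0 / l))
  for (idx in list(ar$si, ar$sj)) {
    s <- rowsum(ks, idx)
    rows <- as.integer(rownames(s))
    keff[rows] <- keff[rows] + s
  }
  # volumetric: k_v |dV/dr|^2 / V_eq per corner
  q <- quad_volumes(ar$P, ar$C, ar$sigma)
  for (m in 1:4) {
    mp <- (m - 2) %% 4 + 1; mn <- m %% 4 + 1
    dVdx <- 2 * pi * (q$A / 4 +
                        q$xbar * ar$sigma * 0.5 * (q$Z[, mn] - q$Z[, mp]))
    dVdz <- 2 * pi * q$xbar * ar$sigma * 0.5 * (q$X[, mp] - q$X[, mn])
    kv <- params$k_v * (dVdx^2 + dVdz^2) / ar$Veq
    s <- rowsum(kv, ar$C[, m])
    rows <- as.integer(rownames(s))
    keff[rows] <- keff[rows] + s
  }
  # corner-angle term: |dtheta/dr| ~ 1/edge length, capped by the
  # sub-resolution fade-out of the penalty at l_reg
  min_edge <- max(min(l), ar$l_reg %||% 0)
  keff <- keff + 8 * params$k_s / min_edge^2
  # hoop
  off <- ar$x0 > 0
  keff[off] <- keff[off] + params$k_h / ar$x0[off]
  params$eta / (c_safety * max(keff))
}

# Ramps active within phase segment `seg` (1 = settle, 2 = Phase 2,
# 3 = Phase 3, 4 = Phase 4, 5 = equilibration), with base values taken
# from the current arrays (the segment starts exactly at each window
# start, so current values are the window-start baselines).
segment_ramps <- function(ar, sch, seg) {
  out <- list(relax_idx = integer(0), lambda = 0, lambda_c = 0,
              l0r_idx = integer(0), l0r_base = numeric(0),
              l0r_target = numeric(0),
              kr_idx = integer(0), kr_base = numeric(0),
              kr_target = numeric(0),
              vr_idx = integer(0), vr_base = numeric(0),
              vr_target = numeric(0),
              grow_idx = integer(0), G = 1)
  creep_here <- if (sch$creep_through) seg >= 2 else seg == 2
  if (creep_here && sch$rule1) {
    out$relax_idx <- which(nr_tangential(ar))
    out$lambda <- sch$lambda
    out$lambda_c <- sch$lambda_c
  }
  if (seg == 3) {
    if (sch$rule1) {
      idx <- which(nr_tangential(ar))
      out$kr_idx <- c(out$kr_idx, idx)
      out$kr_base <- c(out$kr_base, ar$kk[idx])
      out$kr_target <- c(out$kr_target, 0.25 * ar$phase0_k[idx])
    }
    if (sch$rule2) {
      idx <- which(hinge_apical(ar))
      out$kr_idx <- c(out$kr_idx, idx)
      out$kr_base <- c(out$kr_base, ar$kk[idx])
      out$kr_target <- c(out$kr_target, 10 * ar$phase0_k[idx])
      out$l0r_idx <- idx
      out$l0r_base <- ar$l0[idx]
      out$l0r_target <- 0.10 * ar$phase0_l0[idx]
    }
  }
  if (seg == 4 && sch$rule3) {
    grow_el <- growth_elements(ar)
    # natural-length growth is multiplicative so that it composes with
    # the rule 1 creep acting on the same NR springs
    out$grow_idx <- which(ar$skind <= 2 & grow_el[ar$sel])
    out$G <- sch$G_final
    eidx <- which(grow_el)
    out$vr_idx <- eidx
    out$vr_base <- ar$Veq[eidx]
    out$vr_target <- sch$G_final * ar$Veq[eidx]
  }
  out
}

#' Run the full simulation
#'
#' Builds the vesicle, applies the Phase 0 prestress and Phase 1
#' deepening, then integrates the overdamped dynamics through the Phase 1
#' settling window, Phases 2-4, and the final equilibration window while
#' the scheduled rules ramp the tissue parameters. Deterministic: no
#' randomness enters the core loop.
#'
#' The default engine is the compiled core; `engine = "r"` runs the pure-R
#' reference integrator ([apply_schedule()] + [step_state()]), useful for
#' cross-checks on small meshes.
#'
#' @param config A [sim_config()] object.
#' @param engine `"cpp"` (compiled core, default) or `"r"`.
#' @return An object of class `ov_trajectory`: snapshots (vertex positions
#'   and energy breakdown) at the configured stride and at every phase
#'   boundary, the final state, and a termination status.
#' @export
#' @examples
#' \donttest{
#' traj <- run_simulation(sim_config(n_per_surface = 40))
#' classify_outcome(traj)
#' }
run_simulation <- function(config = sim_config(), engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  config <- validate_config(config)
  tis <- build_vesicle(config$n_per_surface, config$geometry,
                       config$mechanics, prestress = TRUE)
  tis <- phase1_deepen(tis)
  state <- sim_state(tis, config$mechanics, config$schedule)
  b <- config$schedule$boundaries
  sch <- config$schedule
  pars <- config$mechanics
  snaps <- list()
  take <- function(state) {
    p <- state$params
    ar <- state$ar
    # a transiently self-intersecting corner at a fold apex is tolerated
    # mid-run; only a truly inverted element (non-positive area) aborts
    if (any(quad_volumes(ar$P, ar$C, ar$sigma)$A <= 0))
      stop(ov_abort(sprintf("inverted element at t = %.6g", state$time),
                    state))
    e <- en_elastic(ar)
    v <- en_volumetric(ar, p$k_v)
    s <- en_distortion(ar, p$k_s)
    h <- en_hoop(ar, p$k_h, hoop_weight(ar, p))
    list(time = state$time, phase = state$phase, step = state$step,
         P = ar$P,
         energy = c(elastic = e, volumetric = v, distortion = s,
                    hoop = h, total = e + v + s + h))
  }
  snaps[[1]] <- take(state)
  termination <- "completed"
  res <- tryCatch({
    for (seg in seq_len(length(b) - 1)) {
      t_a <- b[[seg]]; t_b <- b[[seg + 1]]
      ar <- state$ar
      ramp <- segment_ramps(ar, sch, seg)
      if (engine == "cpp") {
        res <- cpp_run_segment(
          ar$P, ar$si - 1L, ar$sj - 1L, ar$kk, ar$l0, ar$C - 1L, ar$Veq,
          ar$th_eq, ar$sigma, ar$x0, ar$free, ar$pole - 1L,
          pars$k_v, pars$k_s, pars$k_h, pars$hoop_relief, ar$l_reg,
          pars$eta, t_a, t_b, config$dt %||% -1, 4, 200L,
          config$max_steps, config$stride,
          as.integer(ramp$relax_idx - 1L), ramp$lambda, ramp$lambda_c,
          as.integer(ramp$l0r_idx - 1L), ramp$l0r_base, ramp$l0r_target,
          as.integer(ramp$kr_idx - 1L), ramp$kr_base, ramp$kr_target,
          as.integer(ramp$vr_idx - 1L), ramp$vr_base, ramp$vr_target,
          as.integer(ramp$grow_idx - 1L), ramp$G)
        ar$P <- res$P
        ar$l0 <- res$l0
        ar$kk <- res$kk
        ar$Veq <- res$Veq
        state$ar <- ar
        state$step <- state$step + as.integer(min(res$steps_done,
                                                  .Machine$integer.max))
        state$time <- res$t_end
        state$phase <- phase_of(state$time, b)
        for (s in res$snapshots) {
          snaps[[length(snaps) + 1]] <-
            list(time = s$time, phase = phase_of(s$time, b),
                 step = NA_integer_, P = s$P, energy = s$energy)
        }
        if (res$status != "completed")
          stop(ov_abort(sprintf("%s at t = %.6g", res$status, state$time),
                        state))
        state$time <- t_b
        state$phase <- phase_of(state$time, b)
      } else {
        # fixed per-segment step from the stability bound at the segment
        # start and at the segment-end parameter values
        ar_end <- ar
        ar_end$l0[ramp$l0r_idx] <- ramp$l0r_target
        ar_end$kk[ramp$kr_idx] <- ramp$kr_target
        ar_end$Veq[ramp$vr_idx] <- ramp$vr_target
        ar_end$l0[ramp$grow_idx] <- ramp$G * ar_end$l0[ramp$grow_idx]
        state_end <- state; state_end$ar <- ar_end
        dt_max <- min(check_stability(state), check_stability(state_end))
        if (!is.null(config$dt)) dt_max <- min(dt_max, config$dt)
        n_steps <- max(1L, ceiling((t_b - t_a) / dt_max - 1e-9))
        if (n_steps > config$max_steps)
          stop(ov_abort(sprintf(
            "segment %d needs %d steps, over the %g-step budget",
            seg, n_steps, config$max_steps), state))
        dt <- (t_b - t_a) / n_steps
        for (i in seq_len(n_steps)) {
          state <- apply_schedule(state, dt = dt)
          state <- step_state(state, dt)
          if (state$step %% config$stride == 0L)
            snaps[[length(snaps) + 1]] <- take(state)
        }
        state$time <- t_b
        state$phase <- phase_of(state$time, b)
        state <- apply_schedule(state, dt = 0)
      }
      snaps[[length(snaps) + 1]] <- take(state)
    }
    state
  }, ov_instability = function(cond) {
    termination <<- paste0("aborted: ", conditionMessage(cond))
    cond$state
  })
  state <- res
  structure(list(snapshots = snaps, config = config,
                 template = tis, boundaries = b,
                 termination = termination, final_state = state),
            class = "ov_trajectory")
}

#' @export
print.ov_trajectory <- function(x, ...) {
  cat(sprintf("<ov_trajectory> %d snapshots, t in [%.3g, %.3g], %s\n",
              length(x$snapshots), x$snapshots[[1]]$time,
              x$snapshots[[length(x$snapshots)]]$time, x$termination))
  invisible(x)
}

#' Energy log of a trajectory
#'
#' @param x An `ov_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per snapshot: `time`, `phase`, `step`,
#'   and the energy breakdown `U_e`, `U_v`, `U_s`, `U_h`, `total`.
#' @export
tidy.ov_trajectory <- function(x, ...) {
  tibble::tibble(
    time = vapply(x$snapshots, `[[`, numeric(1), "time"),
    phase = vapply(x$snapshots, `[[`, character(1), "phase"),
    step = vapply(x$snapshots, `[[`, integer(1), "step"),
    U_e = vapply(x$snapshots, function(s) s$energy[["elastic"]],
                 numeric(1)),
    U_v = vapply(x$snapshots, function(s) s$energy[["volumetric"]],
                 numeric(1)),
    U_s = vapply(x$snapshots, function(s) s$energy[["distortion"]],
                 numeric(1)),
    U_h = vapply(x$snapshots, function(s) s$energy[["hoop"]], numeric(1)),
    total = vapply(x$snapshots, function(s) s$energy[["total"]],
                   numeric(1)))
}

# index of the snapshot closest to `time` (ties -> earlier snapshot)
snapshot_index <- function(trajectory, time) {
  ts <- vapply(trajectory$snapshots, `[[`, numeric(1), "time")
  which.min(abs(ts - time))
}

#' Tissue geometry at a snapshot
#'
#' Reconstructs an `ov_tissue` with the vertex positions of the snapshot
#' closest to `time`. Spring parameters are those of the trajectory
#' template (positions are all the morphometric functions need).
#'
#' @param trajectory An `ov_trajectory`.
#' @param time Requested time; the nearest stored snapshot is used.
#' @return An `ov_tissue`.
#' @export
snapshot_tissue <- function(trajectory, time) {
  stopifnot(inherits(trajectory, "ov_trajectory"))
  i <- snapshot_index(trajectory, time)
  tis <- trajectory$template
  tis$vertices$x <- trajectory$snapshots[[i]]$P[, 1]
  tis$vertices$z <- trajectory$snapshots[[i]]$P[, 2]
  tis
}
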