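#' Simulation configuration
#'
#' Bundles geometry, mechanics, schedule, and integrator settings; all
#' downstream positivity/ordering constraints are validated before a run.
#'
#' @param n_per_surface Vertices per surface (default 100).
#' @param geometry An [geometry_params()] object.
#' @param mechanics An [mechanics_params()] object.
#' @param schedule An [phase_schedule()] object.
#' @param dt Optional fixed time step; `NULL` (default) uses the
#'   [check_stability()] estimate, recomputed per phase segment.
#' @param stride Snapshot stride in steps (default 25).
#' @param max_steps Step budget per phase segment; a run whose stability
#'   estimate would require more steps aborts with a diagnostic
#'   termination instead of grinding (guards against stiffness collapse
#'   in pathological parameter regimes).
#' @return An object of class `ov_config`.
#' @export
sim_config <- function(n_per_surface = 100, geometry = geometry_params(),
                       mechanics = mechanics_params(),
                       schedule = phase_schedule(), dt = NULL,
                       stride = 25, max_steps = 5e7) {
  cfg <- structure(list(n_per_surface = as.integer(n_per_surface),
                        geometry = geometry, mechanics = mechanics,
                        schedule = schedule, dt = dt,
                        stride = as.integer(stride),
                        max_steps = max_steps),
                   class = "ov_config")
  validate_config(cfg)
}

validate_config <- function(config) {
  if (!inherits(config, "ov_config"))
    stop("expected an `ov_config`", call. = FALSE)
  if (is.na(config$n_per_surface) || config$n_per_surface < 8)
    stop("`n_per_surface` must be at least 8", call. = FALSE)
  if (!inherits(config$geometry, "ov_geometry"))
    stop("`geometry` must come from geometry_params()", call. = FALSE)
  if (!inherits(config$mechanics, "ov_mechanics"))
    stop("`mechanics` must come from mechanics_params()", call. = FALSE)
  if (!inherits(config$schedule, "ov_schedule"))
    stop("`schedule` must come from phase_schedule()", call. = FALSE)
  if (!is.null(config$dt) &&
      (!is.numeric(config$dt) || length(config$dt) != 1 ||
       !is.finite(config$dt) || config$dt <= 0))
    stop("`dt` must be NULL or a positive scalar", call. = FALSE)
  if (is.na(config$stride) || config$stride < 1)
    stop("`stride` must be a positive integer", call. = FALSE)
  if (is.null(config$max_steps) || !is.numeric(config$max_steps) ||
      config$max_steps < 1)
    stop("`max_steps` must be a positive number", call. = FALSE)
  validate_ramps(schedule_ramps(config$schedule))
  config
}

#' @export
print.ov_config <- function(x, ...) {
  cat(sprintf("<ov_config> n_per_surface = %d, dt = %s, stride = %d\n",
              x$n_per_surface,
              if (is.null(x$dt)) "auto" else format(x$dt), x$stride))
  print(x$schedule)
  invisible(x)
}

config_to_list <- function(config) {
  sch <- config$schedule
  b <- sch$boundaries
  list(
    n_per_surface = config$n_per_surface,
    geometry = list(radius = config$geometry$radius,
                    thickness = config$geometry$thickness,
                    fractions = as.list(config$geometry$fractions)),
    mechanics = unclass(config$mechanics)[c("k_a", "k_b", "k_t", "k_v",
                                            "k_s", "eta", "k_h",
                                            "hoop_relief")],
    schedule = list(settle = b[["t1"]] - b[["t0"]],
                    phase2 = b[["t2"]] - b[["t1"]],
                    phase3 = b[["t3"]] - b[["t2"]],
                    phase4 = b[["t4"]] - b[["t3"]],
                    equilibrate = b[["t_end"]] - b[["t4"]],
                    lambda = sch$lambda, lambda_c = sch$lambda_c,
                    creep_through = sch$creep_through,
                    G_final = sch$G_final,
                    rule1 = sch$rule1, rule2 = sch$rule2,
                    rule3 = sch$rule3),
    dt = config$dt,
    stride = config$stride,
    max_steps = config$max_steps)
}

config_from_list <- function(lst) {
  sim_config(
    n_per_surface = lst$n_per_surface,
    geometry = geometry_params(radius = lst$geometry$radius,
                               thickness = lst$geometry$thickness,
                               fractions = unlist(lst$geometry$fractions)),
    mechanics = do.call(mechanics_params, lst$mechanics),
    schedule = do.call(phase_schedule, lst$schedule),
    dt = lst$dt,
    stride = lst$stride,
    max_steps = lst$max_steps)
}

check_keys <- function(user, ref, path = "") {
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        is.list(user[[nm]]))
      check_keys(user[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  invisible(TRUE)
}

merge_lists <- function(ref, user) {
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        is.list(user[[nm]]))
      ref[[nm]] <- merge_lists(ref[[nm]], user[[nm]])
    else ref[[nm]] <- user[[nm]]
  }
  ref
}

#' Write a configuration to a YAML file
#'
#' @param config An [sim_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(config_to_list(config), path,
                   precision = 15L)
  invisible(path)
}

#' Read and validate a configuration from a YAML file
#'
#' Missing keys fall back to package defaults; unknown keys are rejected
#' with their key path. The returned configuration has passed the full
#' validation of [sim_config()].
#'
#' @param path A YAML file as written by [save_config()]; partial files
#'   are allowed.
#' @return An `ov_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- config_to_list(sim_config())
  check_keys(user, ref)
  config_from_list(merge_lists(ref, user))
}

#' Deterministic test fixtures
#'
#' Small meshes used throughout the unit tests:
#' `single_element` (one quadrilateral, stress-free),
#' `flat_strip_10` (10 vertices per surface, flat, stress-free),
#' `ring_arc` (quarter-arc vesicle mesh, 16 vertices per surface,
#' stress-free), and `phase1_vesicle` (the full default vesicle after
#' Phase 0 prestress and Phase 1 deepening).
#'
#' @param name One of `"single_element"`, `"flat_strip_10"`,
#'   `"ring_arc"`, `"phase1_vesicle"`.
#' @return An `ov_tissue`.
#' @export
make_fixture <- function(name = c("single_element", "flat_strip_10",
                                  "ring_arc", "phase1_vesicle")) {
  name <- match.arg(name)
  switch(name,
    single_element = build_strip(2, length = 1, thickness = 1,
                                 x_start = 1),
    flat_strip_10 = build_strip(10, length = 1, thickness = 0.1,
                                x_start = 1),
    ring_arc = build_vesicle(16, prestress = FALSE),
    phase1_vesicle = phase1_deepen(build_vesicle(100)))
}

# ---- plotting -------------------------------------------------------------

element_polygons <- function(tissue) {
  el <- tissue$elements
  v <- tissue$vertices
  ids <- c(rbind(el$a1, el$a2, el$b2, el$b1))
  tibble::tibble(element = rep(el$element, each = 4),
                 region = factor(rep(el$region, each = 4),
                                 levels = region_levels),
                 x = v$x[ids], z = v$z[ids])
}

region_fills <- c(non_retinal = "grey70", RPE = "#8c6bb1",
                  hinge = "#e31a1c", NR = "#33a02c")

#' Plot a meridional section
#'
#' Draws the quadrilateral elements of the section coloured by region,
#' optionally mirrored across the symmetry axis to suggest the full
#' revolved vesicle.
#'
#' @param object An `ov_tissue`.
#' @param mirror Also draw the x < 0 mirror image (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ov_tissue <- function(object, mirror = TRUE, ...) {
  df <- element_polygons(object)
  if (mirror) {
    df <- dplyr::bind_rows(
      dplyr::mutate(df, side = "right"),
      dplyr::mutate(df, x = -.data$x, side = "left",
                    element = -.data$element))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z,
                                   group = .data$element,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_manual(values = region_fills, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (off-axis distance)", y = "z (axial)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ov_state <- function(object, ...) {
  autoplot.ov_tissue(as_tissue(object), ...)
}

#' Plot selected snapshots of a trajectory
#'
#' @param object An `ov_trajectory`.
#' @param times Snapshot times to draw; defaults to the phase boundaries.
#' @param mirror Mirror across the symmetry axis.
#' @param ... Unused.
#' @return A ggplot object, faceted by snapshot time.
#' @export
autoplot.ov_trajectory <- function(object, times = NULL, mirror = TRUE,
                                   ...) {
  if (is.null(times)) times <- as.numeric(object$boundaries)
  dfs <- lapply(times, function(t) {
    tis <- snapshot_tissue(object, t)
    i <- snapshot_index(object, t)
    df <- element_polygons(tis)
    df$time <- object$snapshots[[i]]$time
    df$phase <- object$snapshots[[i]]$phase
    df
  })
  df <- dplyr::bind_rows(dfs)
  df$panel <- sprintf("t = %.2f (%s)", df$time, df$phase)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  if (mirror) {
    df <- dplyr::bind_rows(
      df,
      dplyr::mutate(df, x = -.data$x, element = -.data$element))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z,
                                   group = .data$element,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_manual(values = region_fills, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "x", y = "z", fill = "region") +
    ggplot2::theme_minimal()
}

#' Energy-term traces of a run
#'
#' @param trajectory An `ov_trajectory`.
#' @param log_scale Log-scale the energy axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_energy <- function(trajectory, log_scale = TRUE) {
  df <- tidy(trajectory)
  long <- tidyr::pivot_longer(df, c("U_e", "U_v", "U_s", "U_h", "total"),
                              names_to = "term", values_to = "energy")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$energy,
                                          colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = as.numeric(trajectory$boundaries),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "time", y = "energy", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Render a snapshot to an image file
#'
#' @param state An `ov_state`, `ov_tissue`, or `ov_trajectory` (final
#'   snapshot).
#' @param path Output image path (extension selects the device, e.g.
#'   `.png`).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, width = 6, height = 5,
                            dpi = 150) {
  p <- if (inherits(state, "ov_trajectory")) {
    autoplot.ov_tissue(snapshot_tissue(
      state, state$snapshots[[length(state$snapshots)]]$time))
  } else if (inherits(state, "ov_state")) {
    autoplot.ov_state(state)
  } else if (inherits(state, "ov_tissue")) {
    autoplot.ov_tissue(state)
  } else stop("cannot render this object", call. = FALSE)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

# ---- sweeps ---------------------------------------------------------------

#' Outcome sweep over growth fold, mesh resolution, and rule flags
#'
#' Runs the full simulation over a grid of conditions and tabulates the
#' classified outcomes; operationalizes the robustness checks (growth
#' fold, mesh refinement, single-rule knockouts).
#'
#' @param G_final Growth folds to sweep.
#' @param n_per_surface Mesh resolutions to sweep.
#' @param rules List of rule-flag triples, each
#'   `c(rule1 =, rule2 =, rule3 =)`; default full protocol only.
#' @param config Base configuration.
#' @return A tibble with one row per run: the condition, the outcome, and
#'   the headline morphometrics.
#' @export
sweep_outcomes <- function(G_final = 2, n_per_surface = 100,
                           rules = list(c(rule1 = TRUE, rule2 = TRUE,
                                          rule3 = TRUE)),
                           config = sim_config()) {
  grid <- expand.grid(G = G_final, n = n_per_surface,
                      r = seq_along(rules))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    fl <- rules[[grid$r[i]]]
    sch <- config$schedule
    cfg <- sim_config(
      n_per_surface = grid$n[i],
      geometry = config$geometry, mechanics = config$mechanics,
      schedule = phase_schedule(
        settle = sch$boundaries[["t1"]] - sch$boundaries[["t0"]],
        phase2 = sch$boundaries[["t2"]] - sch$boundaries[["t1"]],
        phase3 = sch$boundaries[["t3"]] - sch$boundaries[["t2"]],
        phase4 = sch$boundaries[["t4"]] - sch$boundaries[["t3"]],
        equilibrate = sch$boundaries[["t_end"]] - sch$boundaries[["t4"]],
        lambda = sch$lambda, lambda_c = sch$lambda_c,
        creep_through = sch$creep_through, G_final = grid$G[i],
        rule1 = fl[["rule1"]], rule2 = fl[["rule2"]],
        rule3 = fl[["rule3"]]),
      dt = config$dt, stride = config$stride)
    traj <- run_simulation(cfg)
    oc <- classify_outcome(traj)
    dplyr::bind_cols(
      tibble::tibble(G_final = grid$G[i], n_per_surface = grid$n[i],
                     rule1 = fl[["rule1"]], rule2 = fl[["rule2"]],
                     rule3 = fl[["rule3"]]),
      glance(oc))
  })
  dplyr::bind_rows(out)
}
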