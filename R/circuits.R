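#' Rate constants for the spatial Langevin circuit variants
#'
#' Parameters of the per-cell gene circuits and extracellular fields used by
#' the lattice simulator. Concentrations are in arbitrary units (a.u.), rates
#' in 1/h, diffusion in grid-units^2/h. The defaults are the package's
#' calibrated fixture: quorum-signal diffusion lengths of about ten grid
#' units, toggle switching over a few hours, and an oscillator period of tens
#' of hours.
#'
#' Module membership (used by [apply_timescales()]):
#' quorum-sensing readouts `k_U`, `k_V` (tau_QS); toggle `k_T`, `d_T`, `k_W`
#' (tau_T); oscillator `a_A`, `b_A`, `d_A`, `a_R`, `d_R` (tau_osc); throttle
#' synthase and AI3 field `s3`, `D3`, `kdeg3` (tau_thr); AI1/AI2 fields
#' `s1`, `s2`, `D1`, `D2`, `kdeg1`, `kdeg2` (tau_sig). Hill thresholds are
#' never rescaled, so module steady states are invariant under time-scale
#' changes.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `circuit_params`.
#' @export
circuit_params <- function(...) {
  p <- list(
    # quorum-sensing readouts: U tracks Hact(AI1), V tracks Hinh(AI2)
    k_U = 1, K_U = 0.8, n_U = 3,
    k_V = 1, K_V = 0.8, n_V = 3,
    # toggle switch (mutual repression, AND-gate drive on the on-side)
    k_T = 0.5, d_T = 0.5, K_T = 0.5, n_T = 4, k_W = 0.4,
    # oscillator (activator A, repressor R); period ~40 h, gate open ~1/3 cycle
    a_A = 2.2, b_A = 0.09, d_A = 0.9, K_AA = 0.35, K_R = 0.37,
    a_R = 0.05, d_R = 0.033, K_AR = 0.45, n_osc = 4,
    K_gate = 0.35, n_gate = 4,
    # throttle (AI3 synthase gated by the rising toggle on-state)
    s3 = 0.3, K_act = 0.4, n_act = 2, K_rep = 0.5, n_rep = 2,
    # extracellular fields
    s1 = 0.1, s2 = 0.1, D1 = 2, D2 = 2, D3 = 2,
    kdeg1 = 0.02, kdeg2 = 0.02, kdeg3 = 0.2,
    # population events
    k_div = 0.05, k_kill = 0.02, theta_G = 2, n_G = 4,
    # commitment rule: half the toggle's high steady state, debounced
    c_commit = 0.5, debounce = 3)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown circuit parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  class(p) <- "circuit_params"
  p
}

#' Assemble a circuit variant
#'
#' Describes one of the three stochastic-tier systems as data: species list,
#' extracellular fields, rate-law table and commitment-gate definition.
#' System 2 is the plain toggle-commitment design (uncommitted cells secrete
#' AI1, committed cells secrete AI2; the AND gate `W = U * V` drives the
#' toggle). System 3 multiplies the gate by `Hinh(R; K_gate)` so commitment
#' can only fire near an oscillator peak (repressor low). System 4 multiplies
#' the gate by `Hinh(AI3; K_rep)`, where AI3 is secreted transiently by cells
#' whose toggle is switching (lateral-inhibition throttle).
#'
#' @param system_id 2, 3 or 4.
#' @param params A [circuit_params()] list.
#' @return An object of class `circuit_variant`.
#' @export
build_system <- function(system_id, params = circuit_params()) {
  if (!system_id %in% 2:4) stop("unknown system id: ", system_id)
  species <- c("U", "V", "Ton", "Toff")
  fields <- list(
    AI1 = list(name = "AI1", D = params$D1, k_deg = params$kdeg1,
               secreted_by = "uncommitted", rate = params$s1),
    AI2 = list(name = "AI2", D = params$D2, k_deg = params$kdeg2,
               secreted_by = "committed", rate = params$s2))
  gate <- "U * V"
  if (system_id == 3) {
    species <- c(species, "A", "R")
    gate <- "U * V * Hinh(R; K_gate)"
  }
  if (system_id == 4) {
    fields$AI3 <- list(name = "AI3", D = params$D3, k_deg = params$kdeg3,
                       secreted_by = "uncommitted (toggle switching)",
                       rate = params$s3)
    gate <- "U * V * Hinh(AI3; K_rep)"
  }
  rate_laws <- data.frame(
    species = species,
    production = c("k_U * Hact(AI1; K_U)", "k_V * Hinh(AI2; K_V)",
                   "k_T * Hinh(Toff; K_T) + k_W * W", "k_T * Hinh(Ton; K_T)",
                   if (system_id == 3) c("a_A * Hact(A; K_AA) * Hinh(R; K_R) + b_A",
                                         "a_R * Hact(A; K_AR)")),
    decay = c("k_U * U", "k_V * V", "d_T * Ton", "d_T * Toff",
              if (system_id == 3) c("d_A * A", "d_R * R")))
  structure(list(system_id = system_id, species = species, fields = fields,
                 gate = gate, rate_laws = rate_laws, params = params),
            class = "circuit_variant")
}

#' Rescale module kinetics by time-scale multipliers
#'
#' Multiplies every production and decay rate belonging to a module by
#' `1 / tau_module` (a `tau` of 3 makes the module three times slower).
#' Because thresholds are untouched, each module's steady-state input-output
#' behaviour is unchanged; only how fast it processes signals varies.
#'
#' @param params A [circuit_params()] list.
#' @param tau Named list/vector with any of `tau_sig`, `tau_QS`, `tau_T`,
#'   `tau_osc`, `tau_thr` (all > 0; missing entries default to 1).
#' @return A rescaled `circuit_params` list.
#' @export
apply_timescales <- function(params, tau = list()) {
  known <- c("tau_sig", "tau_QS", "tau_T", "tau_osc", "tau_thr")
  tau <- as.list(tau)
  unknown <- setdiff(names(tau), known)
  if (length(unknown)) stop("unknown module tag(s): ", paste(unknown, collapse = ", "))
  tv <- stats::setNames(rep(1, length(known)), known)
  tv[names(tau)] <- unlist(tau)
  if (any(tv <= 0)) stop("tau components must be > 0")
  members <- list(
    tau_sig = c("s1", "s2", "D1", "D2", "kdeg1", "kdeg2"),
    tau_QS  = c("k_U", "k_V"),
    tau_T   = c("k_T", "d_T", "k_W"),
    tau_osc = c("a_A", "b_A", "d_A", "a_R", "d_R"),
    tau_thr = c("s3", "D3", "kdeg3"))
  out <- params
  for (m in known) {
    for (f in members[[m]]) out[[f]] <- out[[f]] / tv[[m]]
  }
  out
}

#' Largest stable integration step for a parameter set
#'
#' The explicit diffusion stencil requires `dt <= h^2 / (4 max D)`; returns
#' the smaller of `dt_max` and 90% of that bound.
#'
#' @param params A [circuit_params()] list.
#' @param system_id 2, 3 or 4 (AI3 diffusion counts only for system 4).
#' @param h Grid spacing.
#' @param dt_max Upper cap on the step (h).
#' @return A stable `dt`.
#' @export
stable_dt <- function(params, system_id = 2, h = 1, dt_max = 0.1) {
  maxD <- max(params$D1, params$D2, if (system_id == 4) params$D3 else 0)
  if (maxD <= 0) return(dt_max)
  min(dt_max, 0.9 * h^2 / (4 * maxD))
}

#' Simulation configuration for the lattice Langevin engine
#'
#' @param system_id 2, 3 or 4.
#' @param params A [circuit_params()] list (already time-scale adjusted if
#'   desired, see [apply_timescales()]).
#' @param nrow,ncol Lattice dimensions.
#' @param h Grid spacing (grid units).
#' @param dt Integration step (h); must satisfy `dt <= h^2 / (4 max D)`.
#' @param T Total simulated time (h).
#' @param dt_out Output interval (h) for population series and cell traces.
#' @param snap_every Field/lattice snapshot interval (h); 0 disables extra
#'   snapshots beyond the initial one.
#' @param omega Cell volume / system size: molecule-count scale controlling
#'   Langevin noise amplitude (noise ~ 1/sqrt(omega)).
#' @param seed Integer seed (counter-based streams derive from it).
#' @param n0 Initial number of uncommitted cells (centred block).
#' @param burn_in Fraction of the run treated as transient by downstream
#'   metrics.
#' @param trace_max Maximum number of per-cell traces recorded per output time.
#' @return A `sim_config` list.
#' @export
sim_config <- function(system_id = 2, params = circuit_params(),
                       nrow = 25, ncol = 25, h = 1, dt = 0.1, T = 600,
                       dt_out = 2, snap_every = 100, omega = 300, seed = 1,
                       n0 = 10, burn_in = 0.5, trace_max = 200) {
  stopifnot(system_id %in% 2:4, nrow >= 3, ncol >= 3, dt > 0, T > 0, omega > 0)
  maxD <- max(params$D1, params$D2, if (system_id == 4) params$D3 else 0)
  if (maxD > 0 && dt > h^2 / (4 * maxD) + 1e-12) {
    stop("dt violates the diffusion stability bound dt <= h^2/(4 max D)")
  }
  structure(list(system_id = system_id, params = params, nrow = nrow,
                 ncol = ncol, h = h, dt = dt, T = T, dt_out = dt_out,
                 snap_every = snap_every, omega = omega, seed = seed, n0 = n0,
                 burn_in = burn_in, trace_max = trace_max),
            class = "sim_config")
}

#' Run a spatial stochastic simulation
#'
#' Operator-split loop (fields, then intracellular chemistry, then discrete
#' events) over `T / dt` steps. Fully reproducible: all randomness derives
#' from `config$seed` through counter-based streams.
#'
#' @param config A [sim_config()].
#' @return A `trajectory_bundle`: `populations` (data frame time/uncommitted/
#'   committed), `traces` (long data frame of per-cell species), `events`,
#'   `snapshots` (cell-type and field matrices), `cells` (final cell table),
#'   `extinct` flag, and the originating `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out_every <- max(1L, round(config$dt_out / config$dt))
  snap_every <- if (config$snap_every > 0) max(1L, round(config$snap_every / config$dt)) else 0L
  raw <- cpp_engine_run(config$system_id, unclass(config$params),
                        config$nrow, config$ncol, config$h, config$dt,
                        config$T, out_every, snap_every, config$omega,
                        config$seed, config$n0, config$trace_max)
  sp <- if (config$system_id == 3) c("U", "V", "Ton", "Toff", "A", "R") else c("U", "V", "Ton", "Toff")
  traces <- data.frame(time = raw$trace_time, cell_id = raw$trace_id,
                       type = raw$trace_type)
  tx <- raw$traces
  colnames(tx) <- sp
  traces <- cbind(traces, as.data.frame(tx))
  keep <- !is.na(raw$time)
  pops <- data.frame(time = raw$time[keep], uncommitted = raw$uncommitted[keep],
                     committed = raw$committed[keep])
  snaps <- list(time = raw$snap_time, type = raw$snap_type,
                AI1 = raw$snap_ai1, AI2 = raw$snap_ai2)
  if (config$system_id == 4) snaps$AI3 <- raw$snap_ai3
  structure(list(populations = pops, traces = traces, events = raw$events,
                 snapshots = snaps, cells = raw$cells, extinct = raw$extinct,
                 config = config),
            class = "trajectory_bundle")
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  p <- x$populations
  cat("<trajectory_bundle> system", x$config$system_id,
      sprintf("| %dx%d lattice | T = %g h | omega = %g\n",
              x$config$nrow, x$config$ncol, x$config$T, x$config$omega))
  cat(sprintf("  final populations: %d uncommitted, %d committed%s\n",
              p$uncommitted[nrow(p)], p$committed[nrow(p)],
              if (x$extinct) " (EXTINCT)" else ""))
  invisible(x)
}
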