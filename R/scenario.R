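# Configuration, fixtures, bundle persistence and reproducibility plumbing.

scenario_schema <- c("name", "system_id", "tier", "params", "lattice",
                     "omega", "T", "dt", "dt_out", "burn_in", "seed",
                     "analysis", "version")

#' Load and validate a scenario configuration (YAML)
#'
#' @param path Path to a YAML scenario file.
#' @return A `scenario_config` list with defaults injected (marked in
#'   `defaulted`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Validate a raw scenario list
#'
#' Unknown keys are an error (no silent ignore); missing tier-required
#' parameters are errors naming the key; defaults are injected and marked.
#'
#' @param raw Named list (parsed YAML).
#' @return A `scenario_config` list.
#' @export
validate_config <- function(raw) {
  unknown <- setdiff(names(raw), scenario_schema)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("system_id", "tier")) {
    if (is.null(raw[[k]])) stop("missing config key: ", k)
  }
  if (!raw$tier %in% c("ode", "langevin", "gillespie")) {
    stop("tier must be ode, langevin or gillespie")
  }
  defaulted <- character(0)
  defaults <- list(omega = 300, T = 600, dt = 0.1, dt_out = 2, burn_in = 0.5,
                   seed = 1, lattice = list(nrow = 25, ncol = 25, h = 1),
                   params = list(), version = "1")
  for (k in names(defaults)) {
    if (is.null(raw[[k]])) { raw[[k]] <- defaults[[k]]; defaulted <- c(defaulted, k) }
  }
  if (raw$tier == "ode") {
    if (!raw$system_id %in% 1:2) stop("ode tier supports systems 1-2")
    base <- population_params()
    bad <- setdiff(names(raw$params), names(unclass(base)))
    if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
    base[names(raw$params)] <- raw$params
    raw$params <- base
  } else {
    if (!raw$system_id %in% 2:4) stop("stochastic tiers support systems 2-4")
    raw$params <- do.call(circuit_params, raw$params)
  }
  rates <- unlist(unclass(raw$params))
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all parameters must be finite and >= 0")
  }
  raw$defaulted <- defaulted
  class(raw) <- "scenario_config"
  raw
}

#' Save a scenario configuration to YAML (round-trips with [load_config()])
#' @param config A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$defaulted <- NULL
  out$params <- as.list(unclass(out$params))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Fixture registry: calibrated scenario configurations
#'
#' Named, version-pinned parameter sets reproducing the qualitative regimes
#' the package's tests assert: oscillatory vs stable homeostasis for the
#' four-population model, en-masse commitment failure for system 2 and its
#' rescue by the oscillator (system 3) and throttle (system 4), the bistable
#' population-control module, and the module isolation harnesses.
#'
#' @param name One of the registry names (see [fixture_names()]).
#' @return List with `config` (a `scenario_config`, [upc_model()], or
#'   [circuit_params()] depending on the fixture) and `card` (character
#'   vector of the qualitative behaviours tests assert).
#' @export
fixture_generator <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) stop("unknown fixture: ", name)
  reg[[name]]()
}

#' @rdname fixture_generator
#' @export
fixture_names <- function() sort(names(fixture_registry()))

fixture_registry <- function() {
  sys1_osc <- population_params(
    k_div = 0.0583, k1 = 0.4447, k2 = 0.0061, k3 = 0.0053, k_death = 0.0052,
    theta_S = 100, theta_B = 35, theta_G = 170, n_S = 4, n_B = 10, n_G = 6)
  ode_cfg <- function(params, name) {
    validate_config(list(name = name, system_id = 1, tier = "ode",
                         params = as.list(unclass(params)), T = 12000, dt_out = 1))
  }
  lang_cfg <- function(system_id, name) {
    validate_config(list(name = name, system_id = system_id, tier = "langevin"))
  }
  list(
    `sys1-oscillatory` = function() {
      list(config = ode_cfg(sys1_osc, "sys1-oscillatory"),
           card = c("classify_dynamics(system1) == oscillatory",
                    "sustained beta-cell oscillations after burn-in"))
    },
    `sys1-stable` = function() {
      p <- sys1_osc; p$k_death <- 0.009
      list(config = ode_cfg(p, "sys1-stable"),
           card = c("classify_dynamics(system1) == stable"))
    },
    `sys2-default` = function() {
      list(config = lang_cfg(2, "sys2-default"),
           card = c("en-masse commitment episodes occur",
                    "S/N low relative to systems 3-4"))
    },
    `sys3-default` = function() {
      list(config = lang_cfg(3, "sys3-default"),
           card = c("no en-masse episode in >= 80% of seeds",
                    "S/N > sys2-default under matched seeds",
                    "only a fraction of cells commit per signalling wave"))
    },
    `sys4-default` = function() {
      list(config = lang_cfg(4, "sys4-default"),
           card = c("lateral inhibition: committed-committed neighbour Z < 0 at distance 1",
                    "S/N > sys2-default under matched seeds"))
    },
    `upc-bistable` = function() {
      list(config = upc_model(),
           card = c("forward switch-up density > reverse switch-down density",
                    "hysteresis metric > 0.05"))
    },
    `oscillator-isolated` = function() {
      list(config = circuit_params(),
           card = c("all replicates oscillate at fixture parameters",
                    "period ~40 h, gate open ~1/3 of the cycle"))
    },
    `throttle-isolated` = function() {
      list(config = circuit_params(),
           card = c("high drive + low AI3: switch probability ~1",
                    "high AI3: switch probability ~0 (masked times)",
                    "intermediate inputs: maximal switching-time SD"))
    })
}

#' Persist a trajectory bundle as a plain-text run directory
#'
#' Layout: `populations.csv`, `traces.csv`, `events.csv`, `cells.csv`,
#' `snapshots/<field>_<k>.csv`, and `meta.json` (config, extinction flag,
#' snapshot times).
#'
#' @param bundle A `trajectory_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
  utils::write.csv(bundle$populations, file.path(dir, "populations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$events), file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$cells), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  sn <- bundle$snapshots
  for (f in setdiff(names(sn), "time")) {
    for (k in seq_along(sn[[f]])) {
      utils::write.table(sn[[f]][[k]],
                         file.path(dir, "snapshots", sprintf("%s_%03d.csv", f, k)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  cfg <- unclass(bundle$config)
  cfg$params <- as.list(unclass(cfg$params))
  meta <- list(config = cfg, extinct = bundle$extinct,
               snapshot_times = sn$time,
               snapshot_fields = setdiff(names(sn), "time"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#' @param dir Run directory.
#' @return A `trajectory_bundle` (snapshot matrices and tables restored).
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  snaps <- list(time = meta$snapshot_times)
  for (f in meta$snapshot_fields) {
    files <- sort(list.files(file.path(dir, "snapshots"),
                             pattern = paste0("^", f, "_"), full.names = TRUE))
    snaps[[f]] <- lapply(files, function(p) {
      as.matrix(utils::read.table(p, sep = ",", header = FALSE))
    })
  }
  cfg <- meta$config
  prm <- do.call(if (cfg$system_id >= 2 && !is.null(cfg$params$k_U)) circuit_params
                 else population_params, cfg$params)
  structure(list(
    populations = utils::read.csv(file.path(dir, "populations.csv")),
    traces = utils::read.csv(file.path(dir, "traces.csv")),
    events = utils::read.csv(file.path(dir, "events.csv")),
    snapshots = snaps,
    cells = utils::read.csv(file.path(dir, "cells.csv")),
    extinct = isTRUE(meta$extinct),
    config = cfg),
    class = "trajectory_bundle")
}

#' Run manifest for reproducibility
#'
#' @param config The configuration used (any serialisable list).
#' @param seeds Seeds consumed.
#' @param outputs Character vector of output files.
#' @param wall_time Elapsed seconds.
#' @return A `run_manifest` list including a content hash of the config.
#' @export
run_manifest <- function(config, seeds, outputs, wall_time = NA_real_) {
  cfg <- unclass(config)
  cfg$params <- as.list(unclass(cfg$params))
  txt <- yaml::as.yaml(cfg)
  # polynomial rolling hash mod 2^31-1 (double arithmetic stays exact)
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  structure(list(config_hash = sprintf("%08x", h),
                 code_version = as.character(utils::packageVersion("homeostat")),
                 seeds = seeds, outputs = outputs, wall_time = wall_time),
            class = "run_manifest")
}
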