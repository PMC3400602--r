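# System-level robustness scans: S/N under noise (omega) ladders, division/
# killing rate ratios, and module time-scale ensembles with optimisation.

#' S/N of one engine run under a scenario configuration
#'
#' Runs the lattice simulation and reports the committed-count S/N over the
#' post-burn-in window. A run whose tissue goes extinct (or never commits)
#' scores 0: homeostasis failed.
#'
#' @param config A [sim_config()].
#' @return Scalar S/N (>= 0).
#' @export
snr_of_run <- function(config) {
  b <- run_simulation(config)
  if (b$extinct) return(0)
  out <- tryCatch(signal_to_noise(b), error = function(e) NULL)
  if (is.null(out)) return(0)
  if (!is.finite(out$snr)) return(0)
  out$snr
}

#' S/N across a noise (omega) ladder
#'
#' @param system_id 2, 3 or 4.
#' @param omegas Omega ladder (ascending).
#' @param seeds Seeds per omega.
#' @param ... Passed to [sim_config()] (e.g. smaller lattice/T for scans).
#' @return Data frame `omega`, `seed`, `snr`.
#' @export
omega_scan <- function(system_id, omegas = c(30, 100, 300, 1000, 3000),
                       seeds = 1:10, ...) {
  grid <- expand.grid(omega = omegas, seed = seeds)
  grid$snr <- vapply(seq_len(nrow(grid)), function(i) {
    snr_of_run(sim_config(system_id = system_id, omega = grid$omega[i],
                          seed = derive_seed(grid$seed[i], "omega", i), ...))
  }, 0)
  grid
}

#' S/N across division/killing rate ratios
#'
#' Varies `k_kill` at fixed `k_div` so that `k_div / k_kill` spans
#' `ratios`.
#'
#' @inheritParams omega_scan
#' @param ratios Ratios of `k_div / k_kill`.
#' @param params Base [circuit_params()].
#' @return Data frame `ratio`, `seed`, `snr`, `committed` (mean count).
#' @export
ratio_scan <- function(system_id, ratios = c(0.6, 1.25, 2.5, 5),
                       seeds = 1:5, params = circuit_params(), ...) {
  grid <- expand.grid(ratio = ratios, seed = seeds)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$k_kill <- p$k_div / grid$ratio[i]
    cfg <- sim_config(system_id = system_id, params = p,
                      seed = derive_seed(grid$seed[i], "ratio", i), ...)
    b <- run_simulation(cfg)
    x <- b$populations$committed
    x <- x[seq.int(ceiling(length(x) / 2), length(x))]
    snr <- if (b$extinct || all(x == 0) || stats::sd(x) == 0) 0 else mean(x) / stats::sd(x)
    c(snr = snr, committed = mean(x))
  })
  cbind(grid, do.call(rbind, res))
}

#' Random time-scale ensemble of full-system S/N
#'
#' Samples module time-scale vectors from [timescale_design()], applies them
#' with [apply_timescales()], and evaluates full-system S/N (averaged over
#' `seeds_per` engine seeds per vector).
#'
#' @param system_id 2, 3 or 4.
#' @param n_vectors Ensemble size.
#' @param seeds_per Engine seeds per vector.
#' @param root_seed Root seed (drives design and engine streams).
#' @param params Base [circuit_params()].
#' @param ... Passed to [sim_config()].
#' @return List with `samples` (matrix of tau vectors), `snr` (vector), and
#'   `per_seed` (matrix n_vectors x seeds_per).
#' @export
timescale_ensemble <- function(system_id, n_vectors = 30, seeds_per = 3,
                               root_seed = 1, params = circuit_params(), ...) {
  des <- timescale_design(system_id, seed = derive_seed(root_seed, "design", system_id))
  des$n_samples <- n_vectors
  X <- sample_parameters(des)
  per_seed <- matrix(NA_real_, n_vectors, seeds_per)
  for (i in seq_len(n_vectors)) {
    tau <- as.list(X[i, ])
    p <- apply_timescales(params, tau)
    for (s in seq_len(seeds_per)) {
      cfg <- sim_config(system_id = system_id, params = p,
                        dt = stable_dt(p, system_id),
                        seed = derive_seed(root_seed, "tsrun", i * 100 + s), ...)
      per_seed[i, s] <- snr_of_run(cfg)
    }
  }
  list(samples = X, snr = rowMeans(per_seed), per_seed = per_seed)
}

#' Gain in S/N from time-scale optimisation
#'
#' Selects the best-performing time-scale vector of a random ensemble and
#' re-estimates its S/N with independent seeds; reports the difference to
#' the ensemble mean (the improvement a time-scale-matched design buys over
#' an uninformed one).
#'
#' @inheritParams timescale_ensemble
#' @param reeval_seeds Seeds for the re-evaluation of the best vector.
#' @param ensemble Optional precomputed [timescale_ensemble()] result.
#' @return List with `ensemble_mean`, `optimized_snr`, `gain`, `best_tau`.
#' @export
timescale_optimize <- function(system_id, n_vectors = 30, seeds_per = 3,
                               reeval_seeds = 10, root_seed = 1,
                               params = circuit_params(), ensemble = NULL, ...) {
  if (is.null(ensemble)) {
    ensemble <- timescale_ensemble(system_id, n_vectors, seeds_per, root_seed,
                                   params, ...)
  }
  mean_snr <- mean(ensemble$snr, na.rm = TRUE)
  best <- which.max(ensemble$snr)
  tau <- as.list(ensemble$samples[best, ])
  p <- apply_timescales(params, tau)
  re <- vapply(seq_len(reeval_seeds), function(s) {
    snr_of_run(sim_config(system_id = system_id, params = p,
                          dt = stable_dt(p, system_id),
                          seed = derive_seed(root_seed, "reeval", s), ...))
  }, 0)
  list(ensemble_mean = mean_snr, optimized_snr = mean(re),
       gain = mean(re) - mean_snr, best_tau = tau,
       ensemble = ensemble)
}
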