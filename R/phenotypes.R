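# Isolation harnesses and phenotype extraction for the synthetic
# heterogeneity modules (oscillator, throttle), phenotype "images" over the
# throttle's two-input space, image feature extraction, and the
# phenotype-vs-rate-constant predictive comparison.

#' Simulate the isolated oscillator
#'
#' Single-cell Langevin replicates of the activator/repressor oscillator
#' with the commitment gate and population feedback disabled (AND-gate drive
#' clamped to zero, fields at zero).
#'
#' @param params A [circuit_params()] list.
#' @param n_cells Number of independent replicate cells.
#' @param T Simulated time per replicate (h).
#' @param seed Root seed (per-replicate streams derived from it).
#' @param omega Molecule-count scale; `Inf` (or very large) approaches the
#'   deterministic limit.
#' @param dt,dt_out Integration and output steps (h).
#' @return List of data frames (one per replicate) with `time`, `A`, `R`.
#' @export
isolate_oscillator <- function(params = circuit_params(), n_cells = 10,
                               T = 600, seed = 1, omega = 300, dt = 0.05,
                               dt_out = 1) {
  cv <- build_system(3, params)
  lapply(seq_len(n_cells), function(i) {
    tr <- single_cell_langevin(cv, T = T, dt = dt, dt_out = dt_out,
                               omega = min(omega, 1e12),
                               seed = derive_seed(seed, "osc", i), clamp_w = 0)
    tr[, c("time", "A", "R")]
  })
}

trace_phenotypes <- function(time, x, min_peaks = 3, min_rel_amp = 0.4) {
  lo <- min(x); hi <- max(x)
  # a noisy but flat trace is not an oscillation: require the half-range
  # amplitude to be a substantial fraction of the signal level
  if (hi - lo <= 0 || (hi - lo) < min_rel_amp * (hi + lo) / 2) return(NULL)
  thr <- (hi + lo) / 2
  above <- x >= thr
  # debounced threshold crossings
  cross_up <- which(diff(above) == 1) + 1L
  cross_dn <- which(diff(above) == -1) + 1L
  if (length(cross_up) < min_peaks) return(NULL)
  peaks <- vapply(seq_along(cross_up), function(k) {
    j_end <- cross_dn[cross_dn > cross_up[k]][1]
    if (is.na(j_end)) j_end <- length(x)
    i0 <- cross_up[k]
    max(x[i0:j_end])
  }, 0)
  troughs <- vapply(seq_along(cross_dn), function(k) {
    j_end <- cross_up[cross_up > cross_dn[k]][1]
    if (is.na(j_end)) j_end <- length(x)
    min(x[cross_dn[k]:j_end])
  }, 0)
  periods <- diff(time[cross_up])
  dur_high <- vapply(seq_along(cross_up), function(k) {
    j_end <- cross_dn[cross_dn > cross_up[k]][1]
    if (is.na(j_end)) return(NA_real_)
    time[j_end] - time[cross_up[k]]
  }, 0)
  dur_low <- vapply(seq_along(cross_dn), function(k) {
    j_end <- cross_up[cross_up > cross_dn[k]][1]
    if (is.na(j_end)) return(NA_real_)
    time[j_end] - time[cross_dn[k]]
  }, 0)
  list(periods = periods, peaks = peaks, troughs = troughs,
       dur_high = dur_high[!is.na(dur_high)], dur_low = dur_low[!is.na(dur_low)])
}

#' Extract oscillator phenotypes from replicate traces
#'
#' Peaks and troughs are detected by debounced half-range threshold
#' crossings; high/low durations from threshold occupancy. Statistics are
#' pooled across oscillating replicates; replicates with fewer than
#' `min_peaks` cycles are flagged non-oscillating and excluded from the
#' duration statistics.
#'
#' Phenotypes: mean/SD of the period, `high_value` (mean peak level),
#' `low_value` (mean trough level), `amplitude` (high - low), mean and SD of
#' the duration high, mean and CV of the duration low.
#'
#' @param traces List of data frames with `time` and the oscillating species
#'   (from [isolate_oscillator()]).
#' @param species Column analysed (default `"A"`).
#' @param min_peaks Minimum number of cycles for a replicate to count as
#'   oscillating.
#' @param burn_in Fraction of each trace discarded.
#' @return An `oscillator_phenotypes` list; `oscillating` is the fraction of
#'   oscillating replicates.
#' @export
extract_osc_phenotypes <- function(traces, species = "A", min_peaks = 3,
                                   burn_in = 0.2) {
  if (is.data.frame(traces)) traces <- list(traces)
  per_rep <- lapply(traces, function(tr) {
    keep <- tr$time >= burn_in * max(tr$time)
    trace_phenotypes(tr$time[keep], tr[[species]][keep], min_peaks)
  })
  osc <- !vapply(per_rep, is.null, TRUE)
  if (!any(osc)) {
    return(structure(list(oscillating = 0, n_replicates = length(traces)),
                     class = "oscillator_phenotypes"))
  }
  pool <- function(field) unlist(lapply(per_rep[osc], `[[`, field))
  periods <- pool("periods"); highs <- pool("peaks"); lows <- pool("troughs")
  dh <- pool("dur_high"); dl <- pool("dur_low")
  structure(list(
    period_mean = mean(periods), period_sd = stats::sd(periods),
    high_value = mean(highs), low_value = mean(lows),
    amplitude = mean(highs) - mean(lows),
    dur_high_mean = mean(dh), dur_high_sd = stats::sd(dh),
    dur_low_mean = mean(dl),
    dur_low_cv = stats::sd(dl) / mean(dl),
    oscillating = mean(osc), n_replicates = length(traces)),
    class = "oscillator_phenotypes")
}

#' Throttle phenotype image over the two-input space
#'
#' Single cells carrying the toggle + throttle circuit receive a clamped
#' commitment drive and a clamped external AI3 dose at time zero. Per input
#' pixel, replicate statistics of toggle switching are recorded: switch
#' probability, mean and SD of the time for the toggle output to reach
#' steady state (masked where no replicate switches - the "no switch"
#' regions), and the final output level.
#'
#' Steady state is declared when the (smoothed) trace first settles within
#' `epsilon` (relative) of its final level, the final level being the mean
#' over the last tenth of the run.
#'
#' @param params A [circuit_params()] list.
#' @param drive_grid Commitment-drive levels (log-spaced recommended).
#' @param ai3_grid External AI3 doses (log-spaced recommended).
#' @param reps Replicates per pixel (>= 30 for stable statistics).
#' @param T Simulated time (h).
#' @param seed Root seed.
#' @param omega Molecule-count scale.
#' @param epsilon Steady-state tolerance (relative).
#' @param dt,dt_out Integration/output steps.
#' @return A `throttle_image` list of matrices (`drive` x `ai3`):
#'   `switch_prob`, `t_ss_mean`, `t_ss_sd`, `final_level`, `n_switched`,
#'   plus the input grids.
#' @export
isolate_throttle <- function(params = circuit_params(),
                             drive_grid = 10^seq(-1.2, 0, length.out = 8),
                             ai3_grid = 10^seq(-2, 0.5, length.out = 8),
                             reps = 30, T = 60, seed = 1, omega = 300,
                             epsilon = 0.05, dt = 0.05, dt_out = 0.5) {
  cv <- build_system(4, params)
  nd <- length(drive_grid); na <- length(ai3_grid)
  sw <- ts_m <- ts_s <- fin <- nsw <- matrix(NA_real_, nd, na)
  for (i in seq_len(nd)) for (j in seq_len(na)) {
    t_ss <- rep(NA_real_, reps); switched <- logical(reps); last <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- single_cell_langevin(cv, T = T, dt = dt, dt_out = dt_out,
                                 omega = omega,
                                 seed = derive_seed(seed, "thr", (i * na + j) * 1000 + r),
                                 ai3 = ai3_grid[j], clamp_w = drive_grid[i])
      x <- tr$Ton
      # smooth against Langevin noise; final level from the trace tail
      k <- 5
      xs <- stats::filter(x, rep(1 / k, k), sides = 2)
      xs[is.na(xs)] <- x[is.na(xs)]
      xf <- mean(x[seq.int(floor(0.9 * length(x)), length(x))])
      last[r] <- xf
      switched[r] <- xf >= cv$params$c_commit
      if (switched[r]) {
        ok <- abs(xs - xf) <= epsilon * max(xf, 1e-12)
        # first time the smoothed trace settles into the band (5 consecutive
        # output samples; a literal stay-forever criterion is degenerate
        # under Langevin noise)
        run5 <- stats::filter(as.numeric(ok), rep(1, 5), sides = 1)
        idx <- which(run5 == 5)[1]
        if (!is.na(idx)) t_ss[r] <- tr$time[max(idx - 4, 1)]
      }
    }
    sw[i, j] <- mean(switched)
    nsw[i, j] <- sum(switched)
    fin[i, j] <- mean(last)
    if (any(switched & !is.na(t_ss))) {
      ts_m[i, j] <- mean(t_ss[switched], na.rm = TRUE)
      ts_s[i, j] <- stats::sd(t_ss[switched], na.rm = TRUE)
    }
  }
  structure(list(drive = drive_grid, ai3 = ai3_grid, switch_prob = sw,
                 t_ss_mean = ts_m, t_ss_sd = ts_s, final_level = fin,
                 n_switched = nsw, reps = reps),
            class = "throttle_image")
}

#' Scalar features of a throttle phenotype image
#'
#' Image-processing style features: switching-area fraction, boundary
#' location (drive at 50% switch probability at the lowest AI3 dose),
#' mean/max time-to-steady-state over the switching region, mean/max of its
#' SD (the variability band), and the final-level dynamic range. Masked
#' pixels are excluded throughout.
#'
#' @param image A [isolate_throttle()] result.
#' @return A named numeric `feature_vector`; all-`NA` when the image is
#'   fully masked.
#' @export
extract_image_features <- function(image) {
  stopifnot(inherits(image, "throttle_image"))
  sw <- image$switch_prob
  if (all(is.na(sw))) {
    return(structure(stats::setNames(rep(NA_real_, 8),
                                     c("switch_area", "boundary_drive",
                                       "t_ss_mean", "t_ss_max", "sd_mean",
                                       "sd_max", "band_area", "level_range")),
                     class = "feature_vector", all_masked = TRUE))
  }
  switching <- !is.na(sw) & sw >= 0.5
  # boundary: first drive whose switch probability reaches 0.5 at low AI3
  p_low <- sw[, 1]
  bidx <- which(p_low >= 0.5)[1]
  boundary <- if (is.na(bidx)) max(image$drive) else image$drive[bidx]
  ts <- image$t_ss_mean; sds <- image$t_ss_sd
  structure(c(
    switch_area = mean(switching),
    boundary_drive = boundary,
    t_ss_mean = mean(ts[switching], na.rm = TRUE),
    t_ss_max = suppressWarnings(max(ts[switching], na.rm = TRUE)),
    sd_mean = mean(sds[switching], na.rm = TRUE),
    sd_max = suppressWarnings(max(sds[switching], na.rm = TRUE)),
    band_area = mean(!is.na(sds) & sds > stats::median(sds, na.rm = TRUE)),
    level_range = max(image$final_level, na.rm = TRUE) -
      min(image$final_level, na.rm = TRUE)),
    class = "feature_vector", all_masked = FALSE)
}

#' Compare rate constants and phenotypes as predictors of S/N
#'
#' Three RS-HDMR cross-validation fits on identical folds: rates only,
#' phenotypes only, and both - quantifying how much more predictive
#' high-level module behaviour is than raw kinetics.
#'
#' @param rates Matrix of rate constants (rows = ensemble members).
#' @param phenotypes Matrix of module phenotypes/features (same rows).
#' @param snr S/N vector (same rows).
#' @param k Folds.
#' @param seed Fold seed (shared across the three fits).
#' @return Named list `cv_r2_rates`, `cv_r2_phenotypes`, `cv_r2_both`.
#' @export
compare_predictors <- function(rates, phenotypes, snr, k = 5, seed = 1) {
  rates <- as.matrix(rates); phenotypes <- as.matrix(phenotypes)
  stopifnot(nrow(rates) == nrow(phenotypes), nrow(rates) == length(snr))
  keep_col <- function(m) m[, apply(m, 2, function(c) stats::sd(c, na.rm = TRUE) > 0), drop = FALSE]
  rates <- keep_col(rates); phenotypes <- keep_col(phenotypes)
  # predictors are rank-transformed to [0,1] so skewed phenotype
  # distributions do not destabilise the polynomial bases; basis capacity is
  # adapted to the ensemble size (largest first-order degree whose training
  # folds satisfy n >= 3 x basis dimension; second order only when it fits)
  rank01 <- function(m) apply(m, 2, function(v) (rank(v) - 0.5) / length(v))
  fit_set <- function(X) {
    X <- rank01(X)
    n_train <- floor(nrow(X) * (k - 1) / k)
    p <- ncol(X)
    d1 <- max(c(1, which(n_train >= 3 * (p * (1:3) + 1))))
    use2 <- n_train >= 3 * (p * d1 + choose(p, 2) * 4 + 1)
    cv_r2(X, snr, k = k, seed = seed, order = if (use2) 2 else 1,
          degrees = c(d1, 2))
  }
  list(cv_r2_rates = fit_set(rates),
       cv_r2_phenotypes = fit_set(phenotypes),
       cv_r2_both = fit_set(cbind(rates, phenotypes)))
}

#' Average throttle images by S/N level
#'
#' Pixelwise means over images whose full-system S/N falls within
#' `+/- band` (relative) of each level. A pixel masked in every contributing
#' image stays masked.
#'
#' @param images List of [isolate_throttle()] results.
#' @param snr Vector of S/N values, one per image.
#' @param levels S/N level centres (default `c(5, 15, 25)`).
#' @param band Relative half-width of each level bin (default 0.2).
#' @param min_n Minimum images per bin; smaller bins are omitted with a note.
#' @param field Image matrix averaged (default `"t_ss_mean"`).
#' @return Named list of averaged matrices (one per retained level), with
#'   attribute `n_images`.
#' @export
average_images_by_snr <- function(images, snr, levels = c(5, 15, 25),
                                  band = 0.2, min_n = 3, field = "t_ss_mean") {
  stopifnot(length(images) == length(snr))
  out <- list()
  counts <- integer(0)
  for (lv in levels) {
    sel <- which(abs(snr - lv) <= band * lv)
    if (length(sel) < min_n) {
      message("level ", lv, ": only ", length(sel), " images; omitted")
      next
    }
    stack <- lapply(images[sel], `[[`, field)
    arr <- simplify2array(stack)
    avg <- apply(arr, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    out[[as.character(lv)]] <- avg
    counts[as.character(lv)] <- length(sel)
  }
  attr(out, "n_images") <- counts
  out
}

#' Rate-constant ensemble with module phenotypes and full-system S/N
#'
#' Samples a module's rate constants log-uniformly (half a decade around the
#' fixture values), runs the full system carrying that module to measure
#' homeostasis S/N, and phenotypes the module in isolation. This is the
#' input table for phenotypic sensitivity analysis, [compare_predictors()]
#' and Bayesian-network integration.
#'
#' @param module `"oscillator"` (system 3) or `"throttle"` (system 4).
#' @param n Ensemble size.
#' @param seeds_per Engine seeds averaged per vector.
#' @param root_seed Root seed.
#' @param spread Half-width of the sampling range in decades.
#' @param nrow,ncol,T Lattice and duration of the full-system runs.
#' @param params Base [circuit_params()].
#' @return List with `rates` (matrix), `phenotypes` (matrix), `snr` (vector).
#' @export
module_phenotype_ensemble <- function(module = c("oscillator", "throttle"),
                                      n = 80, seeds_per = 2, root_seed = 1,
                                      spread = 0.5,
                                      nrow = 15, ncol = 15, T = 400,
                                      params = circuit_params()) {
  module <- match.arg(module)
  vars <- if (module == "oscillator") {
    c("a_A", "b_A", "d_A", "K_AA", "K_R", "a_R", "d_R", "K_AR")
  } else {
    c("s3", "K_act", "K_rep", "kdeg3", "D3")
  }
  system_id <- if (module == "oscillator") 3 else 4
  centers <- unlist(params[vars])
  des <- sample_design(vars, data.frame(lo = centers * 10^-spread,
                                        hi = centers * 10^spread),
                       n_samples = n, seed = derive_seed(root_seed, "design", 1))
  X <- sample_parameters(des)
  phen <- NULL
  snr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- params
    p[vars] <- as.list(X[i, ])
    snr[i] <- mean(vapply(seq_len(seeds_per), function(s) {
      snr_of_run(sim_config(system_id = system_id, params = p,
                            nrow = nrow, ncol = ncol, T = T,
                            dt = stable_dt(p, system_id),
                            seed = derive_seed(root_seed, "snr", i * 100 + s)))
    }, 0))
    if (module == "oscillator") {
      tr <- isolate_oscillator(p, n_cells = 2, T = 300,
                               seed = derive_seed(root_seed, "phen", i))
      ph <- extract_osc_phenotypes(tr)
      # repressor operating range: the commitment gate reads R, so its low
      # and high deciles are phenotypes in their own right
      rpool <- unlist(lapply(tr, function(d) d$R[d$time >= 0.2 * max(d$time)]))
      row <- c(period_mean = 0, period_sd = 0, high_value = 0, low_value = 0,
               amplitude = 0, dur_high_mean = 0, dur_high_sd = 0,
               dur_low_mean = 0, dur_low_cv = 0, oscillating = ph$oscillating,
               r_low = unname(stats::quantile(rpool, 0.1)),
               r_high = unname(stats::quantile(rpool, 0.9)))
      if (ph$oscillating > 0) {
        for (f in setdiff(names(row), c("oscillating", "r_low", "r_high"))) {
          row[f] <- ph[[f]]
        }
      }
    } else {
      img <- isolate_throttle(p,
                              drive_grid = 10^seq(-1.2, 0, length.out = 4),
                              ai3_grid = 10^seq(-2, 0.5, length.out = 4),
                              reps = 6, T = 50,
                              seed = derive_seed(root_seed, "phen", i))
      fv <- extract_image_features(img)
      row <- unclass(fv)
      row[!is.finite(row)] <- 0
    }
    phen <- rbind(phen, row)
  }
  rownames(phen) <- NULL
  list(rates = X, phenotypes = phen, snr = snr)
}
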