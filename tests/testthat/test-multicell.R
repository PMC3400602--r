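# Spatial Langevin tier: circuit structure, stochastic stepping against
# analytic oracles, diffusion, discrete events, time-scale rescaling, and
# the engine's reproducibility contract.

test_that("circuit variants have the declared structure", {
  s2 <- build_system(2); s3 <- build_system(3); s4 <- build_system(4)
  expect_length(s2$fields, 2)
  expect_length(s4$fields, 3)
  expect_setequal(s3$species, c("U", "V", "Ton", "Toff", "A", "R"))
  expect_error(build_system(5), "unknown system")
  # with R clamped high, the system-3 gate output <= system-2 gate output
  x <- c(U = 0.8, V = 0.7, Ton = 0.1, Toff = 0.9, A = 0.2, R = 0)
  w2 <- cell_rates(s2, x[1:4], ai1 = 1, ai2 = 0.1)$drive
  w3 <- cell_rates(s3, x, ai1 = 1, ai2 = 0.1, clamp_r = 10)$drive
  expect_lte(w3, w2)
  expect_equal(cell_rates(s3, x, ai1 = 1, ai2 = 0.1, clamp_r = 0)$drive, w2)
})

test_that("the isolated oscillator sustains a limit cycle", {
  cv <- build_system(3)
  tr <- single_cell_ode(cv, T = 600, dt_out = 1, clamp_w = 0)
  a <- tr$A[tr$time > 200]
  peaks <- sum(diff(sign(diff(a))) == -2 & a[seq_len(length(a) - 2) + 1] > 0.5 * max(a))
  expect_gte(peaks, 5)
  expect_gt(max(a) - min(a), 0.5 * mean(a))
})

test_that("Langevin stepping matches its analytic limits", {
  cv <- build_system(2)
  # omega -> infinity: trajectory matches the deterministic ODE within 1%
  det <- single_cell_langevin(cv, T = 40, dt = 0.02, dt_out = 2, omega = 1e9,
                              ai1 = 1.5, ai2 = 0.2, seed = 1)
  ref <- rk4_circuit(cv, c(U = 0, V = 0, Ton = 0, Toff = 1),
                     ai1 = 1.5, ai2 = 0.2, ai3 = 0, T = 40, dt = 0.02)
  idx <- seq(1, nrow(ref), by = 100)  # dt_out / dt
  for (s in 1:4) {
    scale <- max(abs(ref[idx, s]), 0.05)
    expect_lt(max(abs(det[[cv$species[s]]] - ref[idx, s]) / scale), 0.01)
  }
  # pure-decay species: ensemble mean follows x0 exp(-d t) within 3 SE
  # (U with ai1 = 0 has zero production and relaxation rate k_U)
  p <- cv$params
  n_rep <- 400; t_end <- 1
  x0 <- c(U = 2, V = 0, Ton = 0, Toff = 0)
  finals <- vapply(seq_len(n_rep), function(r) {
    single_cell_langevin(cv, x0 = x0, ai1 = 0, ai2 = 10, T = t_end, dt = 0.02,
                         dt_out = t_end, omega = 50, seed = r)$U[2]
  }, 0)
  expected <- 2 * exp(-p$k_U * t_end)
  expect_lt(abs(mean(finals) - expected), 3 * sd(finals) / sqrt(n_rep))
  # stationary birth-death species: variance ~ mean / omega
  omega <- 50
  tr <- single_cell_langevin(cv, x0 = c(U = 1, V = 0, Ton = 0, Toff = 0),
                             ai1 = 1e6, ai2 = 10, T = 400, dt = 0.02,
                             dt_out = 0.2, omega = omega, seed = 7)
  u <- tr$U[tr$time > 20]  # production = k_U (Hact ~ 1), decay = k_U * U
  m <- mean(u); v <- var(u)
  n_eff <- length(u) / (2 / (cv$params$k_U * 0.2))  # ~independent samples
  se_v <- v * sqrt(2 / n_eff)
  expect_lt(abs(v - m / omega), 3 * se_v)
})

test_that("diffusion conserves mass with no-flux boundaries", {
  f0 <- matrix(0, 9, 9)
  expect_equal(diffusion_step(f0, D = 1, k_deg = 0.5, dt = 0.2), f0)
  set.seed(5)
  f <- matrix(runif(81), 9, 9)
  g <- f
  for (i in 1:50) g <- diffusion_step(g, D = 1, k_deg = 0, dt = 0.2)
  expect_equal(sum(g), sum(f), tolerance = 1e-12)
  expect_lt(diff(range(g)), diff(range(f)))  # smoothing
  expect_error(diffusion_step(f, D = 2, k_deg = 0, dt = 0.2), "stability")
})

test_that("point-source steady profile matches a refined-grid reference", {
  n <- 17; D <- 1; kdeg <- 0.02
  src <- matrix(0, n, n); src[9, 9] <- 1
  f <- matrix(0, n, n)
  steps <- ceiling((8 / kdeg) / 0.2)
  for (i in seq_len(steps)) f <- diffusion_step(f, D, kdeg, 0.2, source = src)
  ref <- diffusion_reference(n, D, kdeg, src_value = 1, dt = 0.2,
                             steps = steps, src_cell = c(9, 9))
  # radial profile away from the singular source pixel
  ring <- which((abs(row(f) - 9) + abs(col(f) - 9)) %in% 2:5)
  expect_lt(max(abs(f[ring] - ref[ring]) / ref[ring]), 0.02)
})

test_that("cell events respect gating, capacity and rates", {
  cv <- build_system(2)
  sp <- cv$species
  mk_cells <- function(n, type = "uncommitted") {
    d <- data.frame(cell_id = seq_len(n), row = seq_len(n), col = 1,
                    type = type, debounce = 0, commit_time = NA_real_)
    for (s in sp) d[[s]] <- 0
    d
  }
  lat <- matrix(0L, 6, 6)
  cells <- mk_cells(3)
  lat[cbind(cells$row, cells$col)] <- seq_len(3)
  ai1 <- matrix(0, 6, 6)
  # zero rates: nothing happens
  cv0 <- build_system(2, circuit_params(k_div = 0, k_kill = 0))
  set.seed(1)
  out <- cell_events(cells, lat, ai1, dt = 0.5, cv0, time = 1)
  expect_equal(nrow(out$cells), 3)
  expect_equal(nrow(out$events), 0)
  # full lattice: contact inhibition blocks all divisions
  full <- mk_cells(36)
  full$row <- as.vector(row(lat)); full$col <- as.vector(col(lat))
  latf <- matrix(seq_len(36), 6, 6)
  cvd <- build_system(2, circuit_params(k_div = 0.4, k_kill = 0))
  set.seed(2)
  outf <- cell_events(full, latf, ai1, dt = 0.5, cvd, time = 1)
  expect_equal(nrow(outf$cells), 36)
  # commitment is one-way and debounced
  cells2 <- mk_cells(1)
  cells2$Ton <- 1
  lat2 <- matrix(0L, 6, 6); lat2[1, 1] <- 1L
  set.seed(3)
  for (i in 1:3) {
    out2 <- cell_events(cells2, lat2, ai1, dt = 0.1, cv0, time = i)
    cells2 <- out2$cells; lat2 <- out2$lattice
  }
  expect_equal(cells2$type, "committed")
  expect_equal(cells2$commit_time, 3)
  expect_error(cell_events(cells, lat, ai1, dt = 10, cvd), "probability")
})

test_that("committed cells die at the killing rate (exponential survival)", {
  # survival-time MLE from the commitment/death event log
  b <- run_simulation(sim_config(2, params = circuit_params(k_div = 0.1, k_kill = 0.05),
                                 nrow = 15, ncol = 15, T = 400, dt = 0.1,
                                 dt_out = 2, omega = 300, seed = 5))
  ev <- b$events
  commits <- ev[ev$kind == 2, c("cell_id", "time")]
  deaths <- ev[ev$kind == 3, c("cell_id", "time")]
  m <- merge(commits, deaths, by = "cell_id", suffixes = c("_c", "_d"))
  expect_gt(nrow(m), 100)
  surv <- m$time_d - m$time_c
  # exponential MLE rate ~ k_kill within 3 SE
  rate_hat <- 1 / mean(surv)
  se <- rate_hat / sqrt(nrow(m))
  expect_lt(abs(rate_hat - 0.05), 3 * se)
})

test_that("time-scale rescaling preserves steady states and scales kinetics", {
  p <- circuit_params()
  expect_equal(apply_timescales(p, list()), p)
  expect_error(apply_timescales(p, list(tau_bogus = 2)), "unknown module")
  cv1 <- build_system(3, apply_timescales(p, list(tau_QS = 1)))
  cv3 <- build_system(3, apply_timescales(p, list(tau_QS = 3)))
  # isolated-module steady state identical under deterministic integration
  t1 <- single_cell_ode(cv1, ai1 = 1.2, ai2 = 0.3, T = 300, clamp_w = 0)
  t3 <- single_cell_ode(cv3, ai1 = 1.2, ai2 = 0.3, T = 900, clamp_w = 0)
  expect_equal(t1$U[nrow(t1)], t3$U[nrow(t3)], tolerance = 1e-6)
  expect_equal(t1$V[nrow(t1)], t3$V[nrow(t3)], tolerance = 1e-6)
  # relaxation half-time of the first-order U module scales linearly in tau
  half_time <- function(tau) {
    cv <- build_system(2, apply_timescales(p, list(tau_QS = tau)))
    tr <- single_cell_ode(cv, ai1 = 1e9, T = 40 * tau, dt_out = 0.01 * tau)
    uss <- tr$U[nrow(tr)]
    tr$time[which(tr$U >= uss / 2)[1]]
  }
  taus <- c(0.5, 1, 2, 4)
  hts <- vapply(taus, half_time, 0)
  fit <- stats::lm(log(hts) ~ log(taus))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("engine runs are reproducible and internally consistent", {
  cfg <- small_cfg(3, seed = 11, T = 200)
  b1 <- run_simulation(cfg)
  b2 <- run_simulation(cfg)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$populations, b2$populations)
  # population counts equal the event-reconstructed state
  ev <- b1$events
  for (tq in c(100, 200)) {
    n_div <- sum(ev$time <= tq & ev$kind == 1)
    n_com <- sum(ev$time <= tq & ev$kind == 2)
    n_die <- sum(ev$time <= tq & ev$kind == 3)
    row <- b1$populations[b1$populations$time == tq, ]
    expect_equal(row$uncommitted, cfg$n0 + n_div - n_com)
    expect_equal(row$committed, n_com - n_die)
  }
  # trace cell ids exist in the final cell table
  expect_true(all(b1$traces$cell_id %in% b1$cells$cell_id))
})

test_that("mean-field limit tracks the reduced ODE shape", {
  # large omega, large-ish lattice: committed fraction equilibrates near the
  # ODE committed share (within 15%)
  b <- run_simulation(sim_config(2, omega = 3000, seed = 2, T = 600))
  p <- b$populations
  tail_rows <- p[p$time >= 300, ]
  frac_committed <- mean(tail_rows$committed /
                           (tail_rows$committed + tail_rows$uncommitted))
  expect_gt(frac_committed, 0.1)
  expect_lt(frac_committed, 0.9)
})

test_that("heterogeneity modules outperform the plain toggle at harsh killing rates", {
  low <- 0.6  # k_div/k_kill well below the default 2.5
  s2 <- ratio_scan(2, ratios = low, seeds = 1:3, nrow = 15, ncol = 15, T = 400)
  s3 <- ratio_scan(3, ratios = low, seeds = 1:3, nrow = 15, ncol = 15, T = 400)
  expect_gt(mean(s3$snr), mean(s2$snr))
})
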