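# Performance and spatial statistics.

test_that("S/N is the inverse coefficient of variation", {
  r <- suppressWarnings(signal_to_noise(c(8, 10, 12, 10), window = 1))
  expect_equal(r$mean, 10)
  expect_equal(r$snr, 10 / sqrt(2), tolerance = 1e-6)  # population SD
  # scale invariance
  set.seed(1)
  x <- rlnorm(100)
  expect_equal(signal_to_noise(7.3 * x)$snr, signal_to_noise(x)$snr)
  expect_warning(r2 <- signal_to_noise(rep(5, 20)), "zero variance")
  expect_identical(r2$snr, Inf)
  expect_error(signal_to_noise(rep(0, 20)), "all-zero")
  expect_warning(signal_to_noise(c(1, 2, 3, 2, 1)), "fewer than 10")
  # estimator consistency for iid Gaussian
  set.seed(2)
  g <- rnorm(1e4, mean = 50, sd = 5)
  expect_equal(signal_to_noise(g, window = 1)$snr, 10, tolerance = 0.05 * 10)
})

test_that("commitment raster tracks cells, marks and reuses vacated rows", {
  b <- run_simulation(small_cfg(2, seed = 4, T = 300))
  ras <- commitment_raster(b)
  # column sums of live indicators equal the uncommitted population series
  live_per_col <- colSums(!is.na(ras$raster))
  pops <- b$populations$uncommitted[match(ras$time, b$populations$time)]
  expect_equal(unname(live_per_col), pops)
  # commitment marks land on occupied slots at the preceding step
  expect_gt(nrow(ras$commit_marks), 0)
  # a single immortal cell yields one full-length row without marks
  b1 <- run_simulation(sim_config(2, params = circuit_params(k_div = 0, k_kill = 0,
                                                             s1 = 0, s2 = 0),
                                  nrow = 7, ncol = 7, T = 50, dt = 0.1,
                                  dt_out = 2, seed = 1, n0 = 1))
  r1 <- commitment_raster(b1)
  expect_equal(nrow(r1$raster), 1)
  expect_true(all(!is.na(r1$raster)))
  expect_null(r1$commit_marks)
})

test_that("neighbour Z-scores are calibrated and detect the checkerboard", {
  # random labels: |Z| small at all distances
  set.seed(7)
  tm <- matrix(NA_integer_, 10, 10)
  occ <- sample(100, 70)
  tm[occ] <- rbinom(70, 1, 0.5)
  z <- neighbor_zscore(list(tm), ref_type = 1, nbr_type = 1, distances = 1:3,
                       n_perm = 300, seed = 1)
  expect_true(all(abs(z$z) < 4))
  # alternating-row two-colour board: strong same-type avoidance within the
  # Moore ring (rows of the opposite colour above and below)
  cb <- matrix(rep(c(0L, 1L), length.out = 64), 8, 8)
  zc <- neighbor_zscore(list(cb), ref_type = 1, nbr_type = 1, distances = 1,
                        n_perm = 500, seed = 2)
  expect_lt(zc$z[1], -4)
  # interior observed fraction: 2 of 8 Moore neighbours share the row colour
  expect_lt(zc$observed[1], 0.3)
  # combinatorial null: fraction of same-type neighbours among occupied
  # sites under random labelling = (m-1)/(N-1)
  m <- sum(cb == 1); N <- 64
  expect_equal(zc$null_mean[1], (m - 1) / (N - 1), tolerance = 0.02)
})

test_that("phase differences recover constructed offsets and zeros", {
  t <- seq(0, 100, by = 0.25)
  tau <- 20
  mk_bundle <- function(x1, x2) {
    traces <- rbind(data.frame(time = t, cell_id = 1L, type = 0L, A = x1),
                    data.frame(time = t, cell_id = 2L, type = 0L, A = x2))
    structure(list(traces = traces,
                   cells = data.frame(cell_id = 1:2, row = c(1, 1),
                                      col = c(1, 4), type = 0,
                                      commit_time = NA)),
              class = "trajectory_bundle")
  }
  # identical in-phase traces: all nearest-peak differences 0
  s <- sin(2 * pi * t / tau)
  ps <- phase_difference(mk_bundle(s, s))
  expect_equal(ps$mean_dt, 0, tolerance = 1e-9)
  # quarter-period offset
  s2 <- sin(2 * pi * (t - tau / 4) / tau)
  ps2 <- phase_difference(mk_bundle(s, s2))
  expect_equal(ps2$mean_dt, tau / 4, tolerance = 0.3)
  # no peaks: flagged empty
  flat <- phase_difference(mk_bundle(rep(1, length(t)), rep(1, length(t))))
  expect_true(isTRUE(attr(flat, "empty")) || nrow(flat) == 0)
})

test_that("power-law fits recover exact exponents", {
  r <- 10^seq(-2, 0, length.out = 6)
  expect_equal(powerlaw_exponent(data.frame(ratio = r, C_star = 3 * r))$slope, 1)
  f <- powerlaw_exponent(data.frame(ratio = r, C_star = 5 * sqrt(r)))
  expect_equal(f$slope, 0.5)
  expect_equal(f$r2, 1)
  expect_error(powerlaw_exponent(data.frame(ratio = r, C_star = -r)), "positive")
  expect_error(powerlaw_exponent(data.frame(ratio = r[1:3], C_star = r[1:3])),
               ">= 4")
})

test_that("type-I error of the Z-score null is about 1%", {
  set.seed(9)
  hits <- 0; n_trials <- 120
  tm0 <- matrix(NA_integer_, 8, 8)
  occ <- sample(64, 40)
  for (i in seq_len(n_trials)) {
    tm <- tm0
    tm[occ] <- rbinom(40, 1, 0.5)
    z <- suppressWarnings(
      neighbor_zscore(list(tm), 1, 1, distances = 1, n_perm = 150, seed = i))
    if (is.finite(z$z[1]) && abs(z$z[1]) > qnorm(0.995)) hits <- hits + 1
  }
  # binomial CI around 1%
  expect_lte(hits, qbinom(0.999, n_trials, 0.01) + 1)
})

test_that("rasters persist as dense matrix plus JSON sidecar", {
  b <- run_simulation(small_cfg(2, seed = 3, T = 120))
  ras <- commitment_raster(b)
  base <- tempfile()
  write_raster(ras, base)
  m <- as.matrix(utils::read.table(paste0(base, ".csv"), sep = ",",
                                   header = FALSE))
  expect_equal(dim(m), dim(ras$raster))
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(side$time, ras$time)
})
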