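# Module isolation harnesses, phenotype extraction, throttle images and the
# predictive comparison machinery.

test_that("oscillator phenotypes are recovered from constructed signals", {
  # square wave: period 10, 40% duty cycle
  t <- seq(0, 100, by = 0.1)
  sq <- ifelse(t %% 10 < 4, 1, 0)
  ph <- extract_osc_phenotypes(list(data.frame(time = t, A = sq)),
                               burn_in = 0, min_peaks = 3)
  expect_equal(ph$period_mean, 10, tolerance = 0.02)
  expect_equal(ph$dur_high_mean, 4, tolerance = 0.1)
  expect_equal(ph$period_sd, 0, tolerance = 1e-9)
  expect_equal(ph$amplitude, 1, tolerance = 1e-9)
  # noiseless sinusoid: amplitude = max - min
  s <- 2 + sin(2 * pi * t / 20)
  ph2 <- extract_osc_phenotypes(list(data.frame(time = t, A = s)), burn_in = 0)
  expect_equal(ph2$amplitude, ph2$high_value - ph2$low_value)
  expect_equal(ph2$high_value, 3, tolerance = 0.01)
  # jittered periods: period SD tracks the injected jitter
  set.seed(8)
  reps <- lapply(1:6, function(r) {
    periods <- 10 + rnorm(12, 0, 1)
    edges <- cumsum(periods)
    tt <- seq(0, max(edges) - 5, by = 0.05)
    phase <- vapply(tt, function(x) {
      k <- findInterval(x, c(0, edges))
      (x - c(0, edges)[k]) / periods[min(k, length(periods))]
    }, 0)
    data.frame(time = tt, A = ifelse(phase < 0.4, 1, 0))
  })
  ph3 <- extract_osc_phenotypes(reps, burn_in = 0)
  expect_equal(ph3$period_sd, 1, tolerance = 0.35)
  # degenerate trace: flagged non-oscillating
  ph4 <- extract_osc_phenotypes(list(data.frame(time = t, A = exp(-t))),
                                burn_in = 0)
  expect_equal(ph4$oscillating, 0)
})

test_that("isolated oscillator replicates oscillate at fixture parameters", {
  tr <- isolate_oscillator(n_cells = 4, T = 400, seed = 3, omega = 300)
  ph <- extract_osc_phenotypes(tr)
  expect_equal(ph$oscillating, 1)
  expect_gt(ph$period_mean, 15)
  expect_lt(ph$period_mean, 80)
  # deterministic limit reproduces a clean limit cycle
  trd <- isolate_oscillator(n_cells = 1, T = 400, seed = 1, omega = 1e9)
  phd <- extract_osc_phenotypes(trd)
  expect_equal(phd$oscillating, 1)
  expect_lt(phd$period_sd / phd$period_mean, 0.05)
  # degenerate parameters: non-oscillating flag
  p_bad <- circuit_params(d_R = 10)
  trb <- isolate_oscillator(p_bad, n_cells = 2, T = 300, seed = 1)
  expect_lt(extract_osc_phenotypes(trb)$oscillating, 1)
})

test_that("throttle images show the three input regimes", {
  img <- isolate_throttle(drive_grid = 10^seq(-1.4, 0, length.out = 6),
                          ai3_grid = c(0.01, 3),
                          reps = 15, T = 60, seed = 2)
  sw <- img$switch_prob[, 1]
  # high drive, low AI3: switching nearly certain
  expect_gt(sw[6], 0.9)
  # high AI3: no switching regardless of drive (masked time stats)
  expect_lt(max(img$switch_prob[, 2]), 0.1)
  expect_true(all(is.na(img$t_ss_mean[, 2])))
  # low drive: no switching
  expect_lt(sw[1], 0.1)
  # intermediate band (near the switching boundary): maximal time SD
  boundary <- which.min(abs(sw - 0.5))
  expect_true(boundary > 1 && boundary < 6)
  expect_gte(img$t_ss_sd[boundary, 1], img$t_ss_sd[6, 1])
})

test_that("image features summarise constructed images correctly", {
  grid_d <- 10^seq(-1, 0, length.out = 6)
  grid_a <- 10^seq(-2, 0, length.out = 5)
  mk <- function(sw, ts, sds, fin) {
    structure(list(drive = grid_d, ai3 = grid_a, switch_prob = sw,
                   t_ss_mean = ts, t_ss_sd = sds, final_level = fin,
                   n_switched = sw * 10, reps = 10),
              class = "throttle_image")
  }
  # all-switching uniform image
  ones <- matrix(1, 6, 5)
  f <- extract_image_features(mk(ones, ones * 3, ones * 0, ones))
  expect_equal(unname(f["switch_area"]), 1)
  expect_equal(unname(f["sd_mean"]), 0)
  expect_equal(unname(f["t_ss_mean"]), 3)
  expect_equal(unname(f["level_range"]), 0)
  # half-plane switching: boundary at the constructed threshold
  half <- matrix(0, 6, 5); half[4:6, ] <- 1
  fh <- extract_image_features(mk(half, ones * 2, ones * 0.5, ones))
  expect_equal(unname(fh["boundary_drive"]), grid_d[4])
  expect_equal(unname(fh["switch_area"]), 0.5)
  # fully masked image
  nas <- matrix(NA_real_, 6, 5)
  fm <- extract_image_features(mk(nas, nas, nas, nas))
  expect_true(all(is.na(fm)))
  expect_true(attr(fm, "all_masked"))
})

test_that("image averaging respects level bins and mask propagation", {
  img <- matrix(1:6, 2, 3)
  imgs <- lapply(c(1, 1.2, 0.8, 3), function(k) {
    structure(list(t_ss_mean = img * k), class = "throttle_image")
  })
  # identical images average to themselves
  same <- lapply(1:3, function(i) structure(list(t_ss_mean = img),
                                            class = "throttle_image"))
  av <- average_images_by_snr(same, snr = c(5, 5.2, 4.9), levels = 5)
  expect_equal(av[["5"]], img)
  # mask propagation: all-NA pixel stays NA
  m2 <- img; m2[1, 1] <- NA
  masked <- lapply(1:3, function(i) structure(list(t_ss_mean = m2),
                                              class = "throttle_image"))
  av2 <- average_images_by_snr(masked, snr = c(5, 5, 5), levels = 5)
  expect_true(is.na(av2[["5"]][1, 1]))
  # sparse bins are omitted
  expect_message(av3 <- average_images_by_snr(same, snr = c(5, 5, 30),
                                              levels = c(5, 15)),
                 "omitted")
  expect_null(av3[["15"]])
})

test_that("predictor comparison ranks informative feature sets", {
  set.seed(5)
  n <- 300
  rates <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("k", 1:3)))
  # phenotypes as noiseless functions of S/N: near-perfect prediction
  snr <- 5 + 2 * rates[, 1] + rnorm(n, 0, 2)
  phen <- cbind(ph1 = exp(snr / 10), ph2 = snr^3)
  cmp <- suppressWarnings(compare_predictors(rates, phen, snr))
  expect_gt(cmp$cv_r2_phenotypes, 0.95)
  expect_gt(cmp$cv_r2_phenotypes, cmp$cv_r2_rates)
  # matched folds: both >= max(single) - 0.05
  expect_gte(cmp$cv_r2_both,
             max(cmp$cv_r2_rates, cmp$cv_r2_phenotypes) - 0.05)
})
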