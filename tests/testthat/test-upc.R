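# UPC module: transfer curves and bistability, step objective, hysteresis,
# the GA optimiser, and sensitivity signatures with clustering.

test_that("transfer curves reflect feedback-driven bistability", {
  # (near-)zero feedback: forward and reverse identical (monostable)
  m0 <- upc_model(genes = c("Feedback gain" = 1e-9))
  c0 <- upc_transfer(m0)
  expect_equal(c0$forward, c0$reverse, tolerance = 1e-9)
  # bistable fixture: forward switch-up density > reverse switch-down
  mb <- upc_model()
  cb <- upc_transfer(mb)
  half <- (max(cb$forward) + min(cb$forward)) / 2
  up <- cb$density[which(cb$forward > half)[1]]
  dn <- cb$density[which(cb$reverse > half)[1]]
  expect_gt(up, dn)
  # branch-enumeration oracle: both stable branches exist inside the window
  mid <- sqrt(up * dn)
  expect_gte(length(upc_stable_branches(mb, mid)), 2)
  expect_equal(length(upc_stable_branches(mb, max(cb$density))), 1)
  # outputs bounded by Prod Y / Decay Y
  mhi <- upc_model(genes = c("Prod Y" = 3, "Decay Y" = 2))
  chi <- upc_transfer(mhi)
  expect_true(all(chi$forward <= 3 / 2 + 1e-9))
})

test_that("step objective and hysteresis metric match hand computations", {
  grid <- c(0.25, 0.5, 1.5, 4, 8)
  curve <- structure(data.frame(density = grid,
                                forward = c(0, 0, 0.5, 1, 1),
                                reverse = c(0, 0, 0.5, 1, 1)),
                     class = c("transfer_curve", "data.frame"))
  spec <- objective_spec(threshold_lo = 1, threshold_hi = 2, high_target = 1)
  expect_equal(step_objective(curve, spec), 0)  # perfect step
  # constant-high curve: loss = sum of below-threshold squared highs x 2 sweeps
  chigh <- curve; chigh$forward <- chigh$reverse <- rep(1, 5)
  expect_equal(step_objective(chigh, spec), 2 * 2 * 1^2)
  # forward-only spec ignores reverse corruption
  spec_f <- objective_spec(threshold_lo = 1, threshold_hi = 2, high_target = 1,
                           weight_reverse = 0)
  corrupted <- curve; corrupted$reverse <- corrupted$reverse + 100
  expect_equal(step_objective(corrupted, spec_f), step_objective(curve, spec_f))
  # hysteresis: one-cell shift of a unit step -> 1 / n_grid
  shifted <- curve
  shifted$forward <- c(0, 0, 0, 1, 1)
  shifted$reverse <- c(0, 0, 1, 1, 1)
  expect_equal(hysteresis_metric(shifted), 1 / 5)
  expect_equal(hysteresis_metric(shifted),
               hysteresis_metric(within(shifted, {
                 forward <- 3 * forward + 2; reverse <- 3 * reverse + 2
               })))
  expect_equal(hysteresis_metric(curve), 0)
  flat <- curve; flat$forward <- flat$reverse <- rep(1, 5)
  expect_error(hysteresis_metric(flat), "dynamic range")
})

test_that("the GA finds known optima and beats random search", {
  center <- c(p1 = 1, p2 = 1)
  target <- log10(c(3, 0.2))
  loss_fn <- function(g) sum((log10(g) - target)^2)
  runs <- run_ga(loss_fn, center, ga_config(pop_size = 40, generations = 80,
                                            runs = 2, seed = 9))
  for (r in runs) {
    expect_true(all(abs(log10(r$genes) - target) < 0.05))
    expect_true(all(diff(r$trace) <= 1e-12))  # elitism: non-increasing
  }
  # GA beats pure random search at equal evaluation budget on the UPC loss
  spec <- objective_spec()
  grid <- 10^seq(-1, 1, length.out = 15)
  upc_loss <- function(g) step_objective(upc_transfer(upc_model(g), grid), spec)
  budget_pop <- 30; budget_gen <- 25
  ga_best <- vapply(1:3, function(s) {
    run_ga(upc_loss, upc_model()$genes,
           ga_config(pop_size = budget_pop, generations = budget_gen,
                     runs = 1, seed = s))[[1]]$loss
  }, 0)
  rs_best <- vapply(1:3, function(s) {
    old <- homeostat:::local_rng(derive_seed(s, "rs", 1))
    lg0 <- log10(upc_model()$genes)
    vals <- replicate(budget_pop * (budget_gen + 1), {
      g <- 10^(lg0 + runif(length(lg0), -1.5, 1.5))
      upc_loss(stats::setNames(g, names(lg0)))
    })
    homeostat:::restore_rng(old)
    min(vals)
  }, 0)
  expect_lt(stats::median(ga_best), stats::median(rs_best))
})

test_that("bistability is necessary for hysteresis", {
  set.seed(12)
  lg0 <- log10(upc_model()$genes)
  grid <- 10^seq(-1, 1, length.out = 15)
  checked <- 0
  for (i in 1:20) {
    g <- stats::setNames(10^(lg0 + runif(length(lg0), -0.75, 0.75)), names(lg0))
    m <- upc_model(g)
    hy <- tryCatch(hysteresis_metric(upc_transfer(m, grid)),
                   error = function(e) NA)
    if (is.na(hy) || hy <= 0.05) next
    checked <- checked + 1
    # somewhere in the window two stable branches must coexist
    multi <- any(vapply(grid, function(d) {
      length(upc_stable_branches(m, d)) >= 2
    }, TRUE))
    expect_true(multi)
  }
  expect_gt(checked, 0)
})

test_that("sensitivity signatures identify the controlling parameter", {
  g <- upc_model()$genes
  # constructed response depending on a single rate
  sig <- local_sensitivity_signature(
    g, n = 200, seed = 2,
    output = function(curve, genes) log10(genes[["Decay Rec1"]]))
  expect_s3_class(sig, "sensitivity_signature")
  expect_length(sig, length(g))
  expect_gt(sig[["Decay Rec1"]], 0.9)
  expect_true(all(sig[setdiff(names(g), "Decay Rec1")] < 0.05))
  # reproducible across seeds within a small band
  sig_b <- local_sensitivity_signature(
    g, n = 400, seed = 99,
    output = function(curve, genes) log10(genes[["Decay Rec1"]]))
  expect_true(all(abs(sig - sig_b) < 0.05))
  # degenerate (constant) output: zero signature with flag
  sig0 <- local_sensitivity_signature(g, n = 200, seed = 3,
                                      output = function(curve) 1)
  expect_true(attr(sig0, "degenerate"))
  expect_true(all(sig0 == 0))
})

test_that("signature clustering separates constructed groups", {
  set.seed(6)
  a <- matrix(rep(c(0.8, 0.1, 0.05, 0.02), 10), 10, 4, byrow = TRUE) +
    matrix(runif(40, 0, 0.02), 10, 4)
  b <- matrix(rep(c(0.03, 0.1, 0.75, 0.02), 10), 10, 4, byrow = TRUE) +
    matrix(runif(40, 0, 0.02), 10, 4)
  sigs <- rbind(a, b)
  colnames(sigs) <- paste0("p", 1:4)
  cl <- cluster_signatures(sigs)
  expect_length(cl$major, 2)
  expect_length(unique(cl$labels[1:10]), 1)
  expect_length(unique(cl$labels[11:20]), 1)
  expect_false(cl$labels[1] == cl$labels[11])
  # row-permutation invariance of the composition
  perm <- sample(20)
  cl2 <- cluster_signatures(sigs[perm, ])
  tab1 <- sort(as.integer(table(cl$labels)))
  tab2 <- sort(as.integer(table(cl2$labels)))
  expect_equal(tab1, tab2)
  # dendrogram serialises to newick
  expect_match(cl$newick, "^\\(.*\\);$")
})
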