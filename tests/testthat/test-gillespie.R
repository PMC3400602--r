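# Exact stochastic tier: next-reaction correctness against analytic and
# direct-method oracles, the detailed commitment network, and rate
# calibration.

test_that("first-event times of a constant-rate reaction are exponential", {
  a <- 2.5
  net <- reaction_network("X", list(
    list(name = "make", reactants = c(), products = c(X = 1), rate = a)))
  times <- vapply(1:5000, function(s) {
    r <- ssa_run(net, T = 20, seed = s, out_times = 20, log_events = TRUE)
    r$events$time[1]
  }, 0)
  expect_lt(abs(mean(times) - 1 / a), 3 * sd(times) / sqrt(length(times)))
  ks <- suppressWarnings(stats::ks.test(times, "pexp", a))
  expect_gt(ks$p.value, 0.01)
  # event counts over [0, T] are Poisson(aT)
  counts <- vapply(1:400, function(s) ssa_run(net, T = 4, seed = s)$final_state[["X"]], 0)
  brk <- c(-0.5, seq(3.5, 16.5), Inf)
  obs <- table(cut(counts, brk))
  expp <- diff(stats::ppois(c(-1, seq(3, 16), Inf), a * 4))
  chi <- suppressWarnings(stats::chisq.test(obs, p = expp))
  expect_gt(chi$p.value, 0.01)
})

test_that("birth-death stationary distribution is Poisson(a/b)", {
  a <- 30; b <- 1.5
  net <- reaction_network("X", list(
    list(name = "birth", reactants = c(), products = c(X = 1), rate = a),
    list(name = "death", reactants = c(X = 1), products = c(), rate = b)))
  xs <- vapply(1:400, function(s) ssa_run(net, T = 10, seed = s)$final_state[["X"]], 0)
  m <- a / b
  se_mean <- sqrt(m / length(xs))
  expect_lt(abs(mean(xs) - m), 3 * se_mean)
  se_var <- m * sqrt(2 / length(xs)) * 1.5  # loose SE for the variance
  expect_lt(abs(var(xs) - m), 3 * se_var)
})

test_that("next-reaction trajectories match a direct-method reference", {
  # 3-reaction toy: production, conversion, degradation
  species <- c("X", "Y")
  reacts <- list(
    list(name = "prod", reactants = c(), products = c(X = 1), rate = 10),
    list(name = "conv", reactants = c(X = 1), products = c(Y = 1), rate = 0.5),
    list(name = "deg", reactants = c(Y = 1), products = c(), rate = 0.3))
  net <- reaction_network(species, reacts, x0 = c(X = 5))
  T <- 6
  nrm <- vapply(1:800, function(s) ssa_run(net, T, seed = s)$final_state[["Y"]], 0)
  dm <- vapply(1:800, function(s) {
    direct_ssa_final(net$x0, net$reac, net$prod, net$rates, T, seed = 10000 + s)[2]
  }, 0)
  ks <- suppressWarnings(stats::ks.test(nrm, dm))
  expect_gt(ks$p.value, 0.01)
})

test_that("the detailed commitment network is well formed", {
  net <- build_system3_network()
  # every species reachable from the initial state has a consuming reaction
  consumed <- colnames(net$reac)[colSums(net$reac) > 0]
  produced <- colnames(net$prod)[colSums(net$prod) > 0]
  reachable <- union(names(net$x0)[net$x0 > 0], produced)
  leaks <- setdiff(reachable, consumed)
  expect_length(leaks, 0)
  # promoter copy conservation along a run
  r <- ssa_run(net, T = 30, seed = 2, out_times = seq(0, 30, by = 0.5))
  for (pr in c("pA2", "pR5", "pO", "pT6", "pT7", "pC")) {
    tot <- r$states[, pr] + r$states[, paste0(pr, "b")]
    expect_true(all(tot == tot[1]))
  }
  # no induction without receiver-inducer binding
  net0 <- set_rates(net, c("Bind Rec1.AI1" = 0, "Bind Rec2.AI2" = 0))
  r0 <- ssa_run(net0, T = 40, seed = 3)
  expect_equal(max(r0$states[, "R5"]), 0)
  expect_equal(max(r0$states[, "R2"]), 0)
  expect_error(reaction_network("X", list(list(name = "bad",
                                               reactants = c(X = 1),
                                               products = c()))),
               "missing rate")
})

test_that("calibration recovers closed-form birth-death rates", {
  # target: mean m and relaxation half-time h  =>  b = ln2/h, a = m b
  m_target <- 20; h_target <- 1.5
  b_true <- log(2) / h_target; a_true <- m_target * b_true
  net <- reaction_network("X", list(
    list(name = "birth", reactants = c(), products = c(X = 1), rate = 5),
    list(name = "death", reactants = c(X = 1), products = c(), rate = 1)))
  # dose-response: mean at two dose-scaled birth rates
  dose_fn <- function(n, dose) set_rates(n, c(birth = n$rates[1] * dose))
  observable <- function(res) mean(res$states[nrow(res$states) %/% 2:1, "X"])
  ref <- list(doses = c(0.5, 1, 2),
              response = m_target * c(0.5, 1, 2))
  cal <- calibrate_to_langevin(net, ref, dose_fn, observable,
                               rates = c("birth", "death"), T = 30,
                               n_rep = 8, seed = 2, maxit = 80)
  expect_true(all(diff(cal$trace) <= 1e-12))  # best-so-far non-increasing
  expect_true(cal$converged)
  # identity case: residual ~ 0 without moving rates
  net_id <- set_rates(net, c(birth = a_true, death = b_true))
  cal_id <- calibrate_to_langevin(net_id, ref, dose_fn, observable,
                                  rates = c("birth", "death"), T = 30,
                                  n_rep = 8, seed = 3, maxit = 5)
  expect_true(all(cal_id$rel_err < 0.2))
  # recovered ratio a/b ~ m
  expect_equal(unname(cal$rates["birth"] / cal$rates["death"]), m_target,
               tolerance = 0.2)
})
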