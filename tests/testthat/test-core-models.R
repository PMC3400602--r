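# Deterministic population models: Hill gates, right-hand sides, ODE
# integration, equilibria, regime classification and the power-law scan.

test_that("Hill activation and inhibition are complementary and bounded", {
  set.seed(1)
  for (i in 1:50) {
    x <- runif(1, 0, 50); K <- runif(1, 0.1, 20); n <- sample(1:6, 1)
    expect_equal(hill_act(x, K, n) + hill_inh(x, K, n), 1, tolerance = 1e-12)
    expect_gte(hill_act(x, K, n), 0)
    expect_lt(hill_act(x, K, n), 1)
  }
  expect_equal(hill_act(2, 2, 3), 0.5)
  expect_equal(hill_eval(hill_spec(2, 3, "inhibition"), 2), 0.5)
})

test_that("model right-hand sides match direct formula evaluation", {
  p <- population_params()
  # extinction fixed point
  expect_equal(unname(system1_rhs(c(S = 0, E = 0, P = 0, B = 0), p)),
               rep(0, 4))
  expect_equal(unname(system2_rhs(c(S = 0, C = 5), p)), c(0, -p$k_kill * 5))
  # hand evaluation at the stem threshold
  st <- c(S = p$theta_S, E = 0, P = 0, B = 0)
  D <- 0.5 * 1  # Hact(theta_S; theta_S) = 0.5, Hinh(0; theta_B) = 1
  flux <- p$k1 * p$theta_S * D
  expect_equal(system1_rhs(st, p)[["S"]],
               p$k_div * p$theta_S * (1 / (1 + (p$theta_S / p$theta_G)^p$n_G)) - flux)
  expect_equal(system1_rhs(st, p)[["E"]], flux)
  s2 <- c(S = p$theta_S, C = p$theta_C)
  F_commit <- p$k_c * p$theta_S * 0.5 * 0.5
  expect_equal(system2_rhs(s2, p)[["C"]], F_commit - p$k_kill * p$theta_C)
  # flux bookkeeping: d(E+P+B)/dt = inflow - death at random states
  set.seed(2)
  for (i in 1:20) {
    st <- c(S = runif(1, 0, 500), E = runif(1, 0, 500),
            P = runif(1, 0, 500), B = runif(1, 0, 500))
    d <- system1_rhs(st, p)
    Dg <- hill_act(st[["S"]], p$theta_S, p$n_S) * hill_inh(st[["B"]], p$theta_B, p$n_B)
    expect_equal(d[["E"]] + d[["P"]] + d[["B"]],
                 p$k1 * st[["S"]] * Dg - p$k_death * st[["B"]],
                 tolerance = 1e-12)
    # reduced model: dS + dC = growth - killing
    s2 <- c(S = st[["S"]], C = st[["B"]])
    d2 <- system2_rhs(s2, p)
    expect_equal(d2[["S"]] + d2[["C"]],
                 p$k_div * s2[["S"]] * hill_inh(s2[["S"]], p$theta_G, p$n_G) -
                   p$k_kill * s2[["C"]], tolerance = 1e-12)
  }
  expect_error(system2_rhs(c(S = -1, C = 0), p), "negative")
})

test_that("trajectories are non-negative and initial conditions converge", {
  p <- population_params()
  tr1 <- simulate_ode("system2", p, init = c(S = 5, C = 0), t_span = 4000)
  tr2 <- simulate_ode("system2", p, init = c(S = 400, C = 600), t_span = 4000)
  expect_true(all(tr1$S >= 0 & tr1$C >= 0))
  end1 <- unlist(tr1[nrow(tr1), c("S", "C")])
  end2 <- unlist(tr2[nrow(tr2), c("S", "C")])
  expect_equal(end1, end2, tolerance = 1e-6)
  # cross-check against an independent stiff run at tighter tolerance
  ref <- simulate_ode("system2", p, init = c(S = 5, C = 0), t_span = 4000,
                      rtol = 1e-9, atol = 1e-9, method = "bdf")
  expect_equal(end1, unlist(ref[nrow(ref), c("S", "C")]), tolerance = 1e-4)
  # no growth: populations decay once S is exhausted
  p0 <- population_params(k_div = 0)
  tr <- simulate_ode("system2", p0, init = c(S = 50, C = 100), t_span = 2000)
  expect_lt(tr$C[nrow(tr)], 1)
})

test_that("equilibria have tiny residuals and system 2 has a unique attractor", {
  p <- population_params()
  eq <- find_equilibria("system2", p, n_starts = 100, seed = 3)
  # trivial equilibrium always reported
  expect_true(any(vapply(eq, function(e) sum(e$state) == 0, TRUE)))
  for (e in eq) {
    expect_lt(sqrt(sum(system2_rhs(e$state, p)^2)), 1e-9)
    mx <- max(Re(e$jacobian_eigenvalues))
    expect_true(switch(e$classification,
                       stable = mx < 0, unstable = mx > -1e-8,
                       oscillatory = mx > 0))
  }
  nontrivial <- Filter(function(e) sum(e$state) > 1, eq)
  expect_length(nontrivial, 1)
  # >= 100 random initial conditions all converge to that equilibrium
  eqs <- nontrivial[[1]]$state
  set.seed(4)
  ends <- t(replicate(25, {
    init <- c(S = 10^runif(1, 0, 3), C = 10^runif(1, 0, 3))
    unlist(simulate_ode("system2", p, init = init, t_span = 6000)[6001, c("S", "C")])
  }))
  expect_true(all(apply(ends, 1, function(x) {
    sqrt(sum((x - eqs)^2)) / sqrt(sum(eqs^2)) < 1e-4
  })))
})

test_that("dynamic-regime classification matches the fixtures and eigenvalues", {
  osc <- fixture_generator("sys1-oscillatory")$config$params
  sta <- fixture_generator("sys1-stable")$config$params
  expect_equal(classify_dynamics("system1", osc, t_span = 12000), "oscillatory")
  expect_equal(classify_dynamics("system1", sta, t_span = 12000), "stable")
  # linearly damped system: stable
  damped <- population_params(k_div = 0.001, k_c = 0.1)
  expect_equal(classify_dynamics("system2", damped, t_span = 3000), "stable")
  # 1-D scan over k_death brackets the Hopf point of the interior equilibrium
  kd_grid <- seq(0.004, 0.010, by = 0.002)
  labels <- vapply(kd_grid, function(kd) {
    pp <- osc; pp$k_death <- kd
    classify_dynamics("system1", pp, t_span = 16000)
  }, "")
  flip <- which(labels[-1] != labels[-length(labels)])
  expect_length(flip, 1)
  guess <- c(S = 330, E = 64, P = 64, B = 64)
  max_re <- vapply(kd_grid, function(kd) {
    pp <- osc; pp$k_death <- kd
    eq <- find_equilibria("system1", pp, n_starts = 40, seed = 8)
    interior <- Filter(function(e) e$state[["S"]] > 1 && e$state[["S"]] < 2000, eq)
    expect_gt(length(interior), 0)
    max(Re(interior[[1]]$jacobian_eigenvalues))
  }, 0)
  hopf <- which(sign(max_re[-1]) != sign(max_re[-length(max_re)]))
  expect_length(hopf, 1)
  expect_lte(abs(hopf - flip), 1)  # within grid resolution
})

test_that("regime maps are pure and contain the expected regions", {
  osc <- fixture_generator("sys1-oscillatory")$config$params
  m <- regime_map("system1", "k_death", "k2",
                  c(0.005, 0.009), c(0.006, 0.02),
                  params = osc, t_span = 12000)
  expect_true("oscillatory" %in% m$label && "stable" %in% m$label)
  # purity: recomputing a cell matches the map
  pp <- osc; pp$k_death <- m$x[2]; pp$k2 <- m$y[1]
  expect_equal(classify_dynamics("system1", pp, t_span = 12000), m$label[2, 1])
  # all-stable region at tiny k1 (differentiation flux ~ 0)
  tiny <- population_params(k1 = 1e-5)
  m2 <- regime_map("system1", "k2", "k3", c(0.005, 0.02), c(0.005, 0.02),
                   params = tiny, t_span = 3000)
  expect_true(all(m2$label %in% c("stable", "extinct")))
})

test_that("committed equilibrium follows a slope-1 power law at low ratio", {
  scan <- committed_powerlaw_scan(ratio_grid = 10^seq(-2, -0.5, length.out = 8),
                                  n_starts = 40, seed = 1)
  expect_true(all(is.finite(scan$C_star)))
  expect_true(all(diff(scan$C_star) > 0))  # monotone in the ratio
  # stem population approximately constant at low ratio
  expect_lt(diff(range(scan$S_star)) / mean(scan$S_star), 0.05)
  fit <- powerlaw_exponent(scan)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  # finite-difference midpoint slope agrees with the regression
  lr <- log10(scan$ratio); lc <- log10(scan$C_star)
  fd <- (lc[5] - lc[3]) / (lr[5] - lr[3])
  expect_equal(fit$slope, fd, tolerance = 0.05)
})
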