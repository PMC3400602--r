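#' Parameters for the population-level homeostasis models
#'
#' Rate constants and feedback thresholds for the four-population model
#' (system 1) and the reduced stem/committed two-population model (system 2).
#' Rates are per hour; thresholds are cell counts. The defaults are the
#' package's calibrated fixture: stem cells divide roughly once a day, the
#' full differentiation chain takes weeks (slow `k1..k3`), and commitment in
#' the reduced model is fast relative to division.
#'
#' @param k_div Stem-cell division rate (1/h).
#' @param k1,k2,k3 Sequential maturation rates S -> E -> P -> B (1/h).
#' @param k_death Beta-cell death rate (1/h), system 1.
#' @param k_c Lumped commitment rate for the reduced model (1/h).
#' @param k_kill Committed-cell killing rate (1/h), system 2.
#' @param theta_S Stem-density threshold gating differentiation (cells).
#' @param theta_B Beta-cell feedback threshold (cells), system 1.
#' @param theta_C Committed-pool feedback threshold (cells), system 2.
#' @param theta_G Growth-arrest (GAF) threshold (cells); defaults to `theta_S`
#'   because the same density signal drives both gates.
#' @param n_S,n_B,n_C,n_G Hill exponents of the corresponding gates.
#' @return A `population_params` list.
#' @export
population_params <- function(k_div = 0.03, k1 = 0.1, k2 = 0.01, k3 = 0.01,
                              k_death = 0.01, k_c = 0.1, k_kill = 0.01,
                              theta_S = 100, theta_B = 300, theta_C = 300,
                              theta_G = theta_S,
                              n_S = 2, n_B = 2, n_C = 2, n_G = 2) {
  p <- list(k_div = k_div, k1 = k1, k2 = k2, k3 = k3, k_death = k_death,
            k_c = k_c, k_kill = k_kill, theta_S = theta_S, theta_B = theta_B,
            theta_C = theta_C, theta_G = theta_G,
            n_S = n_S, n_B = n_B, n_C = n_C, n_G = n_G)
  rates <- c("k_div", "k1", "k2", "k3", "k_death", "k_c", "k_kill")
  if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
  if (any(unlist(p[c("theta_S", "theta_B", "theta_C", "theta_G")]) <= 0)) {
    stop("all thresholds must be > 0")
  }
  class(p) <- "population_params"
  p
}

state_names <- function(system) {
  if (identical(system, "system1")) c("S", "E", "P", "B") else c("S", "C")
}

check_state <- function(state, system) {
  nm <- state_names(system)
  if (!all(nm %in% names(state))) {
    stop("state must have components ", paste(nm, collapse = ", "))
  }
  if (any(!is.finite(unlist(state[nm])))) stop("non-finite state component")
  if (any(unlist(state[nm]) < 0)) stop("negative state component")
  unlist(state)[nm]
}

#' Right-hand side of the four-population model (system 1)
#'
#' Stem cells S self-renew under growth-arrest feedback and mature through
#' endodermic (E) and pancreatic (P) intermediates into beta cells (B) as
#' first-order steps. Differentiation is gated by the product of a
#' stem-density activation term and a beta-cell inhibition term; growth is
#' arrested at high stem density:
#' \deqn{dS = k_{div} S H^-(S;\theta_G) - k_1 S D, \quad
#'       D = H^+(S;\theta_S) H^-(B;\theta_B)}
#' \deqn{dE = k_1 S D - k_2 E;\ dP = k_2 E - k_3 P;\ dB = k_3 P - k_{death} B}
#'
#' @param state Named vector/list with components `S`, `E`, `P`, `B` (>= 0).
#' @param params A [population_params()] object.
#' @return Named numeric vector of time derivatives (1/h).
#' @export
system1_rhs <- function(state, params) {
  s <- check_state(state, "system1")
  D <- hill_act(s[["S"]], params$theta_S, params$n_S) *
    hill_inh(s[["B"]], params$theta_B, params$n_B)
  flux_diff <- params$k1 * s[["S"]] * D
  c(S = params$k_div * s[["S"]] * hill_inh(s[["S"]], params$theta_G, params$n_G) - flux_diff,
    E = flux_diff - params$k2 * s[["E"]],
    P = params$k2 * s[["E"]] - params$k3 * s[["P"]],
    B = params$k3 * s[["P"]] - params$k_death * s[["B"]])
}

#' Right-hand side of the reduced two-population model (system 2)
#'
#' The endodermic, pancreatic and beta-cell pools are merged into a single
#' committed population C; commitment is fast and one-way through the toggle
#' switch, so feedback acts on C directly:
#' \deqn{F = k_c S H^+(S;\theta_S) H^-(C;\theta_C)}
#' \deqn{dS = k_{div} S H^-(S;\theta_G) - F, \quad dC = F - k_{kill} C}
#'
#' @param state Named vector/list with components `S`, `C` (>= 0).
#' @inheritParams system1_rhs
#' @return Named numeric vector of time derivatives (1/h).
#' @export
system2_rhs <- function(state, params) {
  s <- check_state(state, "system2")
  F_commit <- params$k_c * s[["S"]] * hill_act(s[["S"]], params$theta_S, params$n_S) *
    hill_inh(s[["C"]], params$theta_C, params$n_C)
  c(S = params$k_div * s[["S"]] * hill_inh(s[["S"]], params$theta_G, params$n_G) - F_commit,
    C = F_commit - params$k_kill * s[["C"]])
}

model_rhs <- function(system) {
  switch(system,
         system1 = system1_rhs,
         system2 = system2_rhs,
         stop("unknown system: ", system))
}

#' Simulate a population-level model
#'
#' Integrates system 1 or the reduced system 2 with `deSolve::ode` (lsoda).
#' States are evaluated with a floor at zero inside the right-hand side so
#' trajectories remain non-negative to solver tolerance.
#'
#' @param system `"system1"` or `"system2"`.
#' @param params A [population_params()].
#' @param init Named initial state (defaults: 10 stem cells, others 0).
#' @param t_span Total simulated time (h), > 0.
#' @param dt_out Output interval (h).
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A data frame with columns `time` and one column per population.
#' @export
simulate_ode <- function(system = c("system2", "system1"), params = population_params(),
                         init = NULL, t_span = 2000, dt_out = 1,
                         rtol = 1e-8, atol = 1e-8, method = "lsoda") {
  system <- match.arg(system)
  stopifnot(t_span > 0, dt_out > 0)
  nm <- state_names(system)
  if (is.null(init)) {
    init <- stats::setNames(rep(0, length(nm)), nm)
    init["S"] <- 10
  }
  y0 <- check_state(init, system)
  rhs <- model_rhs(system)
  fn <- function(t, y, parms) {
    list(unname(rhs(pmax(y, 0), parms)))
  }
  out <- deSolve::ode(y = y0, times = seq(0, t_span, by = dt_out), func = fn,
                      parms = params, rtol = rtol, atol = atol, method = method)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed at t = ", max(out[, "time"]),
         "; last state: ", paste(round(out[nrow(out), -1], 4), collapse = ", "))
  }
  df <- as.data.frame(out)
  df[nm] <- lapply(df[nm], pmax, 0)
  df
}

num_jacobian <- function(rhs, y, params, eps = 1e-6) {
  n <- length(y)
  J <- matrix(0, n, n)
  f0 <- rhs(pmax(y, 0), params)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1)
    yp <- y; yp[j] <- yp[j] + h
    J[, j] <- (rhs(pmax(yp, 0), params) - f0) / h
  }
  J
}

newton_root <- function(rhs, y0, params, tol = 1e-12, maxit = 200) {
  y <- y0
  for (i in seq_len(maxit)) {
    f <- rhs(pmax(y, 0), params)
    if (sqrt(sum(f^2)) < tol) return(pmax(y, 0))
    J <- num_jacobian(rhs, y, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      y_new <- y - lambda * step
      f_new <- tryCatch(rhs(pmax(y_new, 0), params), error = function(e) NULL)
      if (!is.null(f_new) && sum(f_new^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6) return(NULL)
    y <- y_new
  }
  NULL
}

classify_eigenvalues <- function(ev, tol = 1e-8) {
  mx <- max(Re(ev))
  if (mx < -tol) return("stable")
  dominant <- ev[which.max(Re(ev))]
  if (abs(Im(dominant)) > tol) "oscillatory" else "unstable"
}

#' Locate equilibria of a population model
#'
#' Multi-start damped Newton iteration on the model right-hand side. Roots
#' are deduplicated by relative distance and each is reported with its
#' finite-difference Jacobian eigenvalues and a linear-stability class
#' (`stable`, `unstable`, or `oscillatory` when the dominant eigenvalue pair
#' is complex, i.e. Hopf-adjacent). The trivial extinction equilibrium at the
#' origin is always included.
#'
#' @inheritParams simulate_ode
#' @param n_starts Number of random initial guesses (>= 1).
#' @param seed Integer seed for the random starts.
#' @param dedupe_tol Relative distance below which two roots are merged.
#' @return A list of equilibrium reports: `state`, `residual_norm`,
#'   `jacobian_eigenvalues`, `classification`.
#' @export
find_equilibria <- function(system = c("system2", "system1"), params = population_params(),
                            n_starts = 100, seed = 1, dedupe_tol = 1e-6) {
  system <- match.arg(system)
  stopifnot(n_starts >= 1)
  rhs <- model_rhs(system)
  nm <- state_names(system)
  n <- length(nm)
  scale_ref <- max(params$theta_S, params$theta_C, params$theta_B)
  rng <- local_rng(seed)
  roots <- list(stats::setNames(rep(0, n), nm))
  starts <- list(stats::setNames(rep(scale_ref / 2, n), nm),
                 stats::setNames(rep(scale_ref / 10, n), nm))
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <-
      stats::setNames(10^stats::runif(n, -1, log10(scale_ref * 10)), nm)
  }
  for (y0 in starts) {
    r <- newton_root(rhs, y0, params)
    if (is.null(r)) next
    if (any(!is.finite(r)) || any(abs(rhs(r, params)) > 1e-8)) next
    is_new <- all(vapply(roots, function(x) {
      sqrt(sum((x - r)^2)) / max(sqrt(sum(r^2)), 1) > dedupe_tol
    }, logical(1)))
    if (is_new) roots <- c(roots, list(stats::setNames(r, nm)))
  }
  restore_rng(rng)
  lapply(roots, function(r) {
    res <- rhs(r, params)
    ev <- eigen(num_jacobian(rhs, r, params), only.values = TRUE)$values
    list(state = r,
         residual_norm = sqrt(sum(res^2)),
         jacobian_eigenvalues = ev,
         classification = classify_eigenvalues(ev))
  })
}

detect_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Classify the long-run dynamic regime of a model
#'
#' Simulates the model, discards a burn-in fraction, and inspects the
#' terminal population (B for system 1, C for system 2). The run is
#' `extinct` if every population ends below one cell-equivalent,
#' `oscillatory` if the post-burn-in series shows at least two full cycles
#' with sustained peak-to-trough amplitude above 5% of its mean, and
#' `stable` otherwise.
#'
#' @inheritParams simulate_ode
#' @param burn_in Fraction of the run discarded as transient.
#' @param amp_tol Relative peak-to-trough amplitude defining oscillation.
#' @return One of `"stable"`, `"oscillatory"`, `"extinct"`.
#' @export
classify_dynamics <- function(system = c("system2", "system1"), params = population_params(),
                              init = NULL, t_span = 4000, dt_out = 1,
                              burn_in = 0.5, amp_tol = 0.05) {
  system <- match.arg(system)
  traj <- simulate_ode(system, params, init, t_span, dt_out)
  nm <- state_names(system)
  tail_state <- unlist(traj[nrow(traj), nm])
  if (all(tail_state < 1)) return("extinct")
  target <- if (system == "system1") "B" else "C"
  x <- traj[[target]][traj$time >= burn_in * t_span]
  classify_series(x, amp_tol)
}

classify_series <- function(x, amp_tol = 0.05) {
  pk <- detect_peaks(x)
  tr <- detect_peaks(-x)
  if (length(pk) < 3 || length(tr) < 2) return("stable")
  # last two full cycles: the three final peaks and intervening troughs
  pk <- utils::tail(pk, 3)
  seg <- x[min(pk):max(pk)]
  amp <- max(seg) - min(seg)
  if (amp > amp_tol * mean(seg)) "oscillatory" else "stable"
}

#' Two-parameter regime map
#'
#' Classifies model dynamics on a 2-D grid of parameter values, one
#' [classify_dynamics()] call per grid cell. Failures are recorded as the
#' label `"failed"` rather than aborting the scan.
#'
#' @inheritParams classify_dynamics
#' @param param_x,param_y Names of the swept `population_params` fields.
#' @param x_values,y_values Coordinate vectors (length >= 2).
#' @return A list with `x`, `y` and a character matrix `label`
#'   (rows index `x_values`, columns `y_values`).
#' @export
regime_map <- function(system, param_x, param_y, x_values, y_values,
                       params = population_params(), init = NULL,
                       t_span = 4000, dt_out = 1) {
  stopifnot(length(x_values) >= 2, length(y_values) >= 2)
  lab <- matrix(NA_character_, length(x_values), length(y_values))
  for (i in seq_along(x_values)) {
    for (j in seq_along(y_values)) {
      p <- params
      p[[param_x]] <- x_values[i]
      p[[param_y]] <- y_values[j]
      lab[i, j] <- tryCatch(
        classify_dynamics(system, p, init, t_span, dt_out),
        error = function(e) "failed")
    }
  }
  list(x = x_values, y = y_values, label = lab)
}

#' Equilibrium scan over the division/killing rate ratio
#'
#' Varies `k_kill` at fixed `k_div` so that the ratio `k_div / k_kill` runs
#' over `ratio_grid`, and records the nontrivial equilibrium stem and
#' committed populations of the reduced model at each ratio. In the low-ratio
#' regime the committed population grows as a power law of the ratio with
#' exponent near 1 while the stem population stays nearly constant.
#'
#' @param params A [population_params()].
#' @param ratio_grid Positive values of `k_div / k_kill`.
#' @param n_starts,seed Passed to [find_equilibria()].
#' @return Data frame with columns `ratio`, `S_star`, `C_star` (`NA` where no
#'   nontrivial equilibrium was found).
#' @export
committed_powerlaw_scan <- function(params = population_params(),
                                    ratio_grid = 10^seq(-2, 0.5, length.out = 12),
                                    n_starts = 40, seed = 1) {
  stopifnot(all(ratio_grid > 0))
  res <- data.frame(ratio = ratio_grid, S_star = NA_real_, C_star = NA_real_)
  for (i in seq_along(ratio_grid)) {
    p <- params
    p$k_kill <- p$k_div / ratio_grid[i]
    eq <- find_equilibria("system2", p, n_starts = n_starts, seed = seed + i)
    nontrivial <- Filter(function(e) sum(e$state) > 1e-6 &&
                           e$classification == "stable", eq)
    if (length(nontrivial) == 0) next
    # largest stable equilibrium is the homeostatic branch
    best <- nontrivial[[which.max(vapply(nontrivial, function(e) sum(e$state), 0))]]
    res$S_star[i] <- best$state[["S"]]
    res$C_star[i] <- best$state[["C"]]
  }
  res
}
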