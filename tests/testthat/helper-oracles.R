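# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# direct-method (first-reaction-free) Gillespie: independent reference for
# the next-reaction implementation
direct_ssa_final <- function(x0, reac, prod, rates, T, seed) {
  set.seed(seed)
  x <- as.numeric(x0)
  t <- 0
  repeat {
    a <- vapply(seq_along(rates), function(r) {
      out <- rates[r]
      for (s in seq_along(x)) {
        k <- reac[r, s]
        if (k > 0) for (m in seq_len(k)) out <- out * max(x[s] - m + 1, 0) / m
      }
      out
    }, 0)
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > T) break
    mu <- sample.int(length(rates), 1, prob = a)
    x <- x + prod[mu, ] - reac[mu, ]
  }
  x
}

# fine-grid steady-state reference for a point source with decay
diffusion_reference <- function(n, D, kdeg, src_value, dt, steps, refine = 2,
                                src_cell = c(n %/% 2 + 1, n %/% 2 + 1)) {
  nf <- n * refine
  hf <- 1 / refine
  f <- matrix(0, nf, nf)
  src <- matrix(0, nf, nf)
  ctr_r <- ((src_cell[1] - 1) * refine + 1):(src_cell[1] * refine)
  ctr_c <- ((src_cell[2] - 1) * refine + 1):(src_cell[2] * refine)
  src[ctr_r, ctr_c] <- src_value  # same source density over the original cell
  dtf <- min(dt, 0.9 * hf^2 / (4 * D))
  for (i in seq_len(ceiling(steps * dt / dtf))) {
    f <- homeostat::diffusion_step(f, D, kdeg, dtf, h = hf, source = src)
  }
  # coarsen back by block sums / refine^2 (concentration average)
  coarse <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    bi <- ((i - 1) * refine + 1):(i * refine)
    bj <- ((j - 1) * refine + 1):(j * refine)
    coarse[i, j] <- mean(f[bi, bj])
  }
  coarse
}

# deterministic single-cell ODE of a circuit, integrated independently with
# a plain RK4 stepper (cross-check for the engine's large-omega limit)
rk4_circuit <- function(circuit, x0, ai1, ai2, ai3, T, dt) {
  x <- x0
  rhs <- function(x) {
    r <- homeostat::cell_rates(circuit, pmax(x, 0), ai1, ai2, ai3)
    r$prod - r$deg
  }
  out <- list(x)
  for (i in seq_len(ceiling(T / dt))) {
    k1 <- rhs(x); k2 <- rhs(x + dt / 2 * k1)
    k3 <- rhs(x + dt / 2 * k2); k4 <- rhs(x + dt * k3)
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    out[[i + 1]] <- x
  }
  do.call(rbind, out)
}

# small sim_config used throughout the suite: 15x15 lattice, 400 h default
small_cfg <- function(system_id, seed = 1, ...) {
  args <- list(...)
  if (is.null(args$T)) args$T <- 400
  do.call(sim_config, c(list(system_id = system_id, nrow = 15, ncol = 15,
                             seed = seed), args))
}
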