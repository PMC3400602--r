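# Single-step operations of the stochastic tier, exposed for direct use and
# for validation against analytic oracles. The production loop lives in the
# compiled engine; these functions share its rate laws via cpp_cell_rates.

#' Evaluate a cell's production/degradation rates
#'
#' Rate laws of the intracellular circuit for one cell given its local
#' extracellular signal levels. Shared by the compiled engine and the R-level
#' stepping functions.
#'
#' @param circuit A [build_system()] variant.
#' @param x Named species vector (a.u.).
#' @param ai1,ai2,ai3 Local field concentrations.
#' @param clamp_w Optional override of the AND-gate drive `U * V` (isolation
#'   harnesses); `NULL` for normal operation.
#' @param clamp_r Optional override of the oscillator repressor seen by the
#'   commitment gate.
#' @return List with `prod`, `deg` (named rates) and `drive` (gate output).
#' @export
cell_rates <- function(circuit, x, ai1 = 0, ai2 = 0, ai3 = 0,
                       clamp_w = NULL, clamp_r = NULL) {
  stopifnot(inherits(circuit, "circuit_variant"))
  xv <- unlist(x)[circuit$species]
  r <- cpp_cell_rates(circuit$system_id, unclass(circuit$params), unname(xv),
                      ai1, ai2, ai3,
                      if (is.null(clamp_w)) -1 else clamp_w,
                      if (is.null(clamp_r)) -1 else clamp_r)
  names(r$prod) <- circuit$species
  names(r$deg) <- circuit$species
  r
}

#' Advance cell states by one chemical-Langevin step
#'
#' Two-stage (Heun) stochastic Runge-Kutta update of the chemical Langevin
#' equation for every live cell:
#' \deqn{dx = (prod - deg)\,dt + \Omega^{-1/2}(\sqrt{prod}\,dW_1 -
#'   \sqrt{deg}\,dW_2)}
#' with the noise evaluated at the left point (Ito) and states clipped at 0.
#' Uses R's RNG; seed externally for reproducibility.
#'
#' @param cells Matrix of cell states (rows = cells, columns = species).
#' @param fields Data frame / matrix with per-cell local `ai1`, `ai2`, `ai3`.
#' @param circuit A [build_system()] variant.
#' @param dt Time step (h), > 0.
#' @param omega Molecule-count scale (noise ~ 1/sqrt(omega)).
#' @return Updated cell-state matrix.
#' @export
langevin_step <- function(cells, fields, circuit, dt, omega) {
  stopifnot(dt > 0, omega > 0)
  cells <- as.matrix(cells)
  n <- nrow(cells)
  fields <- as.data.frame(fields)
  if (!nrow(fields)) fields <- data.frame(ai1 = 0, ai2 = 0, ai3 = 0)
  fields <- fields[rep_len(seq_len(nrow(fields)), n), , drop = FALSE]
  for (f in c("ai1", "ai2", "ai3")) if (is.null(fields[[f]])) fields[[f]] <- 0
  for (i in seq_len(n)) {
    x <- cells[i, ]
    r0 <- cell_rates(circuit, x, fields$ai1[i], fields$ai2[i], fields$ai3[i])
    noise <- (sqrt(pmax(r0$prod, 0) * dt) * stats::rnorm(length(x)) -
                sqrt(pmax(r0$deg, 0) * dt) * stats::rnorm(length(x))) / sqrt(omega)
    xt <- pmax(x + (r0$prod - r0$deg) * dt + noise, 0)
    r1 <- cell_rates(circuit, xt, fields$ai1[i], fields$ai2[i], fields$ai3[i])
    x1 <- x + 0.5 * ((r0$prod - r0$deg) + (r1$prod - r1$deg)) * dt + noise
    if (any(!is.finite(x1))) {
      stop("non-finite state for cell ", i, " species ",
           paste(names(x1)[!is.finite(x1)], collapse = ","))
    }
    cells[i, ] <- pmax(x1, 0)
  }
  cells
}

#' One explicit diffusion-degradation step of an extracellular field
#'
#' 5-point Laplacian with no-flux boundaries, first-order degradation and a
#' per-site secretion source. The stability bound `dt <= h^2/(4 D)` is
#' enforced at call time.
#'
#' @param field Concentration matrix (>= 0).
#' @param D Diffusion coefficient (grid-units^2/h).
#' @param k_deg Degradation rate (1/h).
#' @param dt Time step (h).
#' @param h Grid spacing.
#' @param source Per-site secretion rate matrix (same shape as `field`).
#' @return Updated concentration matrix.
#' @export
diffusion_step <- function(field, D, k_deg, dt, h = 1, source = NULL) {
  if (is.null(source)) source <- matrix(0, nrow(field), ncol(field))
  cpp_diffuse_step(field, D, k_deg, dt, h, source)
}

#' Apply division, commitment and death events to a cell population
#'
#' Uncommitted cells divide with probability `k_div * Hinh(AI1_local;
#' theta_G) * dt` into a uniformly chosen empty Moore-neighbour site (blocked
#' when none is free; the daughter copies the parental concentrations).
#' Committed cells die with probability `k_kill * dt`. Commitment fires,
#' one-way, when the toggle on-state `Ton` has stayed at or above `c_commit`
#' for `debounce` consecutive calls.
#'
#' @param cells A data frame with columns `cell_id`, `row`, `col`, `type`
#'   (`"uncommitted"`/`"committed"`/`"dead"`), `debounce`, `commit_time`, and
#'   one column per species.
#' @param lattice Integer matrix, 0 for empty sites else the row index into
#'   `cells`.
#' @param ai1 Matrix of local AI1 (growth-arrest signal).
#' @param dt Time step (h).
#' @param circuit A [build_system()] variant (uses `k_div`, `k_kill`,
#'   `theta_G`, `n_G`, `c_commit`, `debounce`).
#' @param time Current simulation time, recorded on events.
#' @return List with updated `cells`, `lattice` and an `events` data frame.
#' @export
cell_events <- function(cells, lattice, ai1, dt, circuit, time = 0) {
  p <- circuit$params
  if (p$k_div * dt > 0.2 || p$k_kill * dt > 0.2) {
    stop("per-step event probability exceeds 0.2; decrease dt")
  }
  species <- circuit$species
  moore <- expand.grid(dr = -1:1, dc = -1:1)
  moore <- moore[!(moore$dr == 0 & moore$dc == 0), ]
  ev <- list()
  n0 <- nrow(cells)
  for (i in seq_len(n0)) {
    if (cells$type[i] == "dead") next
    if (cells$type[i] == "uncommitted") {
      a <- ai1[cells$row[i], cells$col[i]]
      if (stats::runif(1) < p$k_div * hill_inh(a, p$theta_G, p$n_G) * dt) {
        nr <- cells$row[i] + moore$dr
        nc <- cells$col[i] + moore$dc
        ok <- nr >= 1 & nr <= nrow(lattice) & nc >= 1 & nc <= ncol(lattice)
        ok[ok] <- lattice[cbind(nr[ok], nc[ok])] == 0
        if (any(ok)) {
          k <- sample(which(ok), 1)
          daughter <- cells[i, ]
          daughter$cell_id <- max(cells$cell_id) + 1
          daughter$row <- nr[k]; daughter$col <- nc[k]
          daughter$debounce <- 0; daughter$commit_time <- NA_real_
          cells <- rbind(cells, daughter)
          lattice[nr[k], nc[k]] <- nrow(cells)
          ev[[length(ev) + 1]] <- data.frame(time = time, kind = "division",
                                             cell_id = daughter$cell_id,
                                             parent_id = cells$cell_id[i])
        }
      }
      if (cells[i, "Ton"] >= p$c_commit) {
        cells$debounce[i] <- cells$debounce[i] + 1
        if (cells$debounce[i] >= p$debounce) {
          cells$type[i] <- "committed"
          cells$commit_time[i] <- time
          ev[[length(ev) + 1]] <- data.frame(time = time, kind = "commitment",
                                             cell_id = cells$cell_id[i],
                                             parent_id = NA_integer_)
        }
      } else {
        cells$debounce[i] <- 0
      }
    } else if (cells$type[i] == "committed") {
      if (stats::runif(1) < p$k_kill * dt) {
        cells$type[i] <- "dead"
        lattice[cells$row[i], cells$col[i]] <- 0
        ev[[length(ev) + 1]] <- data.frame(time = time, kind = "death",
                                           cell_id = cells$cell_id[i],
                                           parent_id = NA_integer_)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), kind = character(0),
               cell_id = integer(0), parent_id = integer(0))
  list(cells = cells, lattice = lattice, events = events)
}

#' Deterministic single-cell trajectory of a circuit variant
#'
#' Integrates one cell's rate laws as an ODE (infinite-volume limit of the
#' Langevin model) with clamped extracellular inputs. Used for calibration
#' and for validating the stochastic engine in the large-omega limit.
#'
#' @inheritParams cell_rates
#' @param x0 Initial species vector (defaults: toggle off, all else 0).
#' @param T Total time (h).
#' @param dt_out Output interval (h).
#' @return Data frame with `time` and one column per species.
#' @export
single_cell_ode <- function(circuit, x0 = NULL, ai1 = 0, ai2 = 0, ai3 = 0,
                            T = 200, dt_out = 0.5, clamp_w = NULL, clamp_r = NULL) {
  sp <- circuit$species
  if (is.null(x0)) {
    x0 <- stats::setNames(rep(0, length(sp)), sp)
    x0["Toff"] <- 1
  }
  fn <- function(t, y, parms) {
    r <- cell_rates(circuit, pmax(y, 0), ai1, ai2, ai3, clamp_w, clamp_r)
    list(unname(r$prod - r$deg))
  }
  out <- deSolve::ode(y = unlist(x0)[sp], times = seq(0, T, by = dt_out),
                      func = fn, parms = NULL, rtol = 1e-8, atol = 1e-8)
  as.data.frame(out)
}

#' Stochastic single-cell trajectory with clamped inputs
#'
#' Chemical-Langevin simulation of one cell with the extracellular fields
#' held constant, using the compiled engine's stepping kernel. This is the
#' isolation harness used for module phenotyping.
#'
#' @inheritParams single_cell_ode
#' @param omega Molecule-count scale.
#' @param seed Integer seed.
#' @param dt Integration step.
#' @return Data frame with `time` and one column per species.
#' @export
single_cell_langevin <- function(circuit, x0 = NULL, ai1 = 0, ai2 = 0, ai3 = 0,
                                 T = 200, dt = 0.05, dt_out = 0.5, omega = 300,
                                 seed = 1, clamp_w = NULL, clamp_r = NULL) {
  sp <- circuit$species
  if (is.null(x0)) {
    x0 <- stats::setNames(rep(0, length(sp)), sp)
    x0["Toff"] <- 1
  }
  out_every <- max(1L, round(dt_out / dt))
  m <- cpp_single_cell(circuit$system_id, unclass(circuit$params),
                       unname(unlist(x0)[sp]), ai1, ai2, ai3, T, dt, omega,
                       as.integer(seed), out_every,
                       if (is.null(clamp_w)) -1 else clamp_w,
                       if (is.null(clamp_r)) -1 else clamp_r)
  colnames(m) <- c("time", sp)
  as.data.frame(m)
}
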