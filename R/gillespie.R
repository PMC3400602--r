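# Exact stochastic tier: mass-action reaction networks simulated with the
# Gibson-modified next-reaction method.

#' Construct a mass-action reaction network
#'
#' Reactions are declared as data: each has a name, a reactant and a product
#' stoichiometry (named integer vectors over the species), and a rate
#' constant. Association rates are per molecule-pair per hour (already
#' divided by the cell volume), dissociation and decay rates per hour.
#'
#' @param species Character vector of species names.
#' @param reactions List of lists with elements `name`, `reactants`,
#'   `products` (named integer vectors; empty/missing names allowed), `rate`.
#' @param x0 Named integer vector of initial copy numbers (default 0).
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, reactions, x0 = NULL) {
  nr <- length(reactions)
  reac <- prod_ <- matrix(0L, nr, length(species),
                          dimnames = list(NULL, species))
  rates <- numeric(nr)
  nms <- character(nr)
  for (i in seq_len(nr)) {
    r <- reactions[[i]]
    if (is.null(r$rate) || !is.finite(r$rate)) {
      stop("missing rate for reaction ", if (!is.null(r$name)) r$name else i)
    }
    nms[i] <- if (!is.null(r$name)) r$name else paste0("r", i)
    for (s in names(r$reactants)) {
      if (!s %in% species) stop("unknown species ", s, " in ", nms[i])
      reac[i, s] <- as.integer(r$reactants[[s]])
    }
    for (s in names(r$products)) {
      if (!s %in% species) stop("unknown species ", s, " in ", nms[i])
      prod_[i, s] <- as.integer(r$products[[s]])
    }
    rates[i] <- r$rate
  }
  x <- stats::setNames(rep(0L, length(species)), species)
  if (!is.null(x0)) x[names(x0)] <- as.integer(x0)
  structure(list(species = species, reaction_names = nms, reac = reac,
                 prod = prod_, rates = rates, x0 = x),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", length(x$species), "species,",
      length(x$rates), "reactions\n")
  invisible(x)
}

#' Update rate constants of a network by reaction name
#' @param network A [reaction_network()].
#' @param rates Named numeric vector (names = reaction names).
#' @return The updated network.
#' @export
set_rates <- function(network, rates) {
  idx <- match(names(rates), network$reaction_names)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(names(rates)[is.na(idx)], collapse = ", "))
  network$rates[idx] <- unname(rates)
  network
}

#' Run an exact stochastic simulation
#'
#' Gibson-modified (next-reaction) Gillespie algorithm: per-reaction putative
#' firing times in an indexed priority queue; only propensities affected by
#' the fired reaction are recomputed.
#'
#' @param network A [reaction_network()].
#' @param T End time (h).
#' @param seed Integer seed.
#' @param out_times Times at which the state is recorded (default 100 evenly
#'   spaced points).
#' @param log_events Record the full event log (time, reaction)?
#' @param max_events Safety cap on the number of events.
#' @return List with `states` (matrix out_times x species), `final_state`,
#'   `n_events`, and optionally `events` (data frame time/reaction).
#' @export
ssa_run <- function(network, T, seed = 1, out_times = NULL,
                    log_events = FALSE, max_events = 1e7) {
  stopifnot(inherits(network, "reaction_network"), T > 0)
  if (is.null(out_times)) out_times <- seq(0, T, length.out = 101)
  raw <- cpp_ssa_run(unname(network$x0), network$reac, network$prod,
                     network$rates, T, as.integer(seed), out_times,
                     as.integer(max_events), log_events)
  states <- raw$states
  colnames(states) <- network$species
  out <- list(time = out_times, states = states,
              final_state = stats::setNames(raw$final_state, network$species),
              n_events = raw$n_events)
  if (log_events) {
    out$events <- data.frame(
      time = raw$event_time,
      reaction = network$reaction_names[raw$event_reaction])
  }
  out
}

#' Detailed reaction network of the oscillator-gated commitment circuit
#'
#' Mechanistic single-cell model of system 3 with explicit binding and
#' transcription events, following the naming convention `Bind X.Y`,
#' `Unbind X.Y`, `Decay X`, `Prod X`. Modules: AI1/AI2 exchange with the
#' local pool; receiver production, decay and inducer binding
#' (`Bind Rec1.AI1`, `Bind Rec2.AI2`); complex-promoter binding for the
#' activator promoter pA2 and the repressor promoter pR5
#' (`Bind pA2.Rec1.AI1`, `Bind pR5.Rec2.AI2`); transcription/translation of
#' repressors R1-R7, with R1 dimerising to R1D to drive the oscillator
#' (R4 its repressor) and R6/R7 forming the commitment toggle (R7 the
#' output); first-order decays throughout. Promoter copies are conserved by
#' construction of the binding/unbinding pairs. Rates are calibrated
#' defaults, not transcribed values; every reaction is data and can be
#' re-rated with [set_rates()].
#'
#' @param params Named list of rate overrides (reaction name -> rate).
#' @param ai1_influx,ai2_influx Zero-order local-pool influx rates standing
#'   for the population-density signal (molecules/h).
#' @param promoter_copies Copy number of each promoter (default 2).
#' @return A [reaction_network()].
#' @export
build_system3_network <- function(params = list(), ai1_influx = 60,
                                  ai2_influx = 20, promoter_copies = 2) {
  species <- c("AI1", "AI2", "Rec1", "Rec2", "C1", "C2",
               "pA2", "pA2b", "pR5", "pR5b",
               "pO", "pOb", "pT6", "pT6b", "pT7", "pT7b", "pC", "pCb",
               "R1", "R1D", "R2", "R4", "R5", "R6", "R7")
  rx <- function(name, reactants, products, rate) {
    list(name = name, reactants = reactants, products = products, rate = rate)
  }
  reactions <- list(
    # quorum-signal local pools
    rx("Influx AI1", c(), c(AI1 = 1), ai1_influx),
    rx("Decay AI1", c(AI1 = 1), c(), 0.5),
    rx("Influx AI2", c(), c(AI2 = 1), ai2_influx),
    rx("Decay AI2", c(AI2 = 1), c(), 0.5),
    # receivers
    rx("Prod Rec1", c(), c(Rec1 = 1), 20),
    rx("Decay Rec1", c(Rec1 = 1), c(), 0.5),
    rx("Prod Rec2", c(), c(Rec2 = 1), 20),
    rx("Decay Rec2", c(Rec2 = 1), c(), 0.5),
    # receiver-inducer binding
    rx("Bind Rec1.AI1", c(Rec1 = 1, AI1 = 1), c(C1 = 1), 0.02),
    rx("Unbind Rec1.AI1", c(C1 = 1), c(Rec1 = 1, AI1 = 1), 1),
    rx("Decay C1", c(C1 = 1), c(), 0.5),
    rx("Bind Rec2.AI2", c(Rec2 = 1, AI2 = 1), c(C2 = 1), 0.02),
    rx("Unbind Rec2.AI2", c(C2 = 1), c(Rec2 = 1, AI2 = 1), 1),
    rx("Decay C2", c(C2 = 1), c(), 0.5),
    # complex-promoter binding (UPC activator pA2; CPC repressor pR5)
    rx("Bind pA2.Rec1.AI1", c(pA2 = 1, C1 = 1), c(pA2b = 1), 0.05),
    rx("Unbind pA2.Rec1.AI1", c(pA2b = 1), c(pA2 = 1, C1 = 1), 1),
    rx("Bind pR5.Rec2.AI2", c(pR5 = 1, C2 = 1), c(pR5b = 1), 0.05),
    rx("Unbind pR5.Rec2.AI2", c(pR5b = 1), c(pR5 = 1, C2 = 1), 1),
    # UPC output R2 from bound pA2; CPC repressor R5 from bound pR5
    rx("Prod R2", c(pA2b = 1), c(pA2b = 1, R2 = 1), 10),
    rx("Decay R2", c(R2 = 1), c(), 0.5),
    rx("Prod R5", c(pR5b = 1), c(pR5b = 1, R5 = 1), 10),
    rx("Decay R5", c(R5 = 1), c(), 0.5),
    # oscillator: R1 autocatalytic via dimer R1D; R4 represses by removal
    rx("Prod R1 basal", c(pO = 1), c(pO = 1, R1 = 1), 2),
    rx("Bind pO.R1D", c(pO = 1, R1D = 1), c(pOb = 1), 0.05),
    rx("Unbind pO.R1D", c(pOb = 1), c(pO = 1, R1D = 1), 1),
    rx("Prod R1 active", c(pOb = 1), c(pOb = 1, R1 = 1), 40),
    rx("Dimerize R1", c(R1 = 2), c(R1D = 1), 0.05),
    rx("Undimerize R1D", c(R1D = 1), c(R1 = 2), 0.5),
    rx("Prod R4", c(pOb = 1), c(pOb = 1, R4 = 1), 4),
    rx("Sequester R1D.R4", c(R1D = 1, R4 = 1), c(R4 = 1), 0.05),
    rx("Decay R1", c(R1 = 1), c(), 1),
    rx("Decay R1D", c(R1D = 1), c(), 0.2),
    rx("Decay R4", c(R4 = 1), c(), 0.05),
    # commitment promoter pC: activated by R2, locked by R5 or R4
    rx("Bind pC.R2", c(pC = 1, R2 = 1), c(pCb = 1), 0.01),
    rx("Unbind pC.R2", c(pCb = 1), c(pC = 1, R2 = 1), 1),
    rx("Prod R7 drive", c(pCb = 1), c(pCb = 1, R7 = 1), 6),
    # toggle: R6/R7 mutual repression via promoter sequestration
    rx("Prod R7 toggle", c(pT7 = 1), c(pT7 = 1, R7 = 1), 10),
    rx("Bind pT7.R6", c(pT7 = 1, R6 = 1), c(pT7b = 1), 0.05),
    rx("Unbind pT7.R6", c(pT7b = 1), c(pT7 = 1, R6 = 1), 0.5),
    rx("Prod R6", c(pT6 = 1), c(pT6 = 1, R6 = 1), 10),
    rx("Bind pT6.R7", c(pT6 = 1, R7 = 1), c(pT6b = 1), 0.05),
    rx("Unbind pT6.R7", c(pT6b = 1), c(pT6 = 1, R7 = 1), 0.5),
    rx("Decay R6", c(R6 = 1), c(), 0.5),
    rx("Decay R7", c(R7 = 1), c(), 0.5))
  x0 <- c(pA2 = promoter_copies, pR5 = promoter_copies, pO = promoter_copies,
          pT6 = promoter_copies, pT7 = promoter_copies, pC = promoter_copies,
          Rec1 = 40, Rec2 = 40, R6 = 20)
  net <- reaction_network(species, reactions, x0)
  if (length(params)) net <- set_rates(net, unlist(params))
  net
}

#' Calibrate network rates against a reference dose-response
#'
#' Least-squares matching of the SSA ensemble-mean dose-response (and,
#' optionally, relaxation half-time) of a network observable to a reference
#' (typically the corresponding Langevin module). Optimises the named rates
#' in log10 space by Nelder-Mead; the objective is evaluated on a fixed set
#' of seeds so the optimisation surface is deterministic.
#'
#' @param network A [reaction_network()].
#' @param reference List with `doses` (values of the dosed quantity),
#'   `response` (target mean observable at each dose), and optionally
#'   `half_time` (target relaxation half-time, h).
#' @param dose_fn `function(network, dose) -> network` applying a dose.
#' @param observable `function(ssa_result) -> scalar` extracting the matched
#'   observable.
#' @param rates Character vector of reaction names to adjust.
#' @param T Simulation time per evaluation.
#' @param n_rep Replicates per dose.
#' @param seed Root seed.
#' @param maxit Optimiser iteration budget.
#' @return List with the adjusted `network`, `rates`, per-dose `residuals`,
#'   relative errors `rel_err`, `converged` (all within 20%), and the
#'   objective `trace` (best-so-far, non-increasing).
#' @export
calibrate_to_langevin <- function(network, reference, dose_fn, observable,
                                  rates, T = 50, n_rep = 10, seed = 1,
                                  maxit = 60) {
  stopifnot(length(reference$doses) == length(reference$response))
  idx <- match(rates, network$reaction_names)
  if (anyNA(idx)) stop("unknown rate(s): ", paste(rates[is.na(idx)], collapse = ", "))
  eval_net <- function(net) {
    vapply(seq_along(reference$doses), function(d) {
      nd <- dose_fn(net, reference$doses[d])
      mean(vapply(seq_len(n_rep), function(r) {
        observable(ssa_run(nd, T, seed = derive_seed(seed, "calib", d * 1000 + r)))
      }, 0))
    }, 0)
  }
  trace <- numeric(0)
  best <- Inf
  obj <- function(lg) {
    net <- network
    net$rates[idx] <- 10^lg
    resp <- eval_net(net)
    val <- sum((resp - reference$response)^2)
    best <<- min(best, val)
    trace <<- c(trace, best)
    val
  }
  fit <- stats::optim(log10(network$rates[idx]), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  network$rates[idx] <- 10^fit$par
  resp <- eval_net(network)
  rel <- abs(resp - reference$response) / pmax(abs(reference$response), 1e-12)
  list(network = network,
       rates = stats::setNames(network$rates[idx], rates),
       fitted_response = resp, residuals = resp - reference$response,
       rel_err = rel, converged = all(rel <= 0.2), trace = trace)
}
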