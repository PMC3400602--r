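# Two-compartment UPC (uncommitted population control) module: mechanistic
# positive-feedback model, forward/reverse transfer curves, step-function
# objective, hysteresis metric, GA optimisation, and clustered local
# sensitivity signatures.

upc_gene_names <- c("Prod Rec1", "Decay Rec1", "Bind Rec1.AI1",
                    "Unbind Rec1.AI1", "Bind pA2.Rec1.AI1",
                    "Unbind pA2.Rec1.AI1", "Prod Y", "Decay Y",
                    "Feedback gain")

#' Two-compartment UPC model
#'
#' Mechanistic model of the density-sensing module: the quorum signal AI1 in
#' the shared medium (influx proportional to the population density N)
#' exchanges with the intracellular compartment, binds the receiver protein
#' Rec1, and the resulting complex pair-binds the activator promoter pA2,
#' driving both the output Y and an AI1 synthase (positive feedback).
#'
#' The nine optimisable rate constants follow the reaction naming
#' convention: `Prod Rec1`, `Decay Rec1`, `Bind Rec1.AI1`,
#' `Unbind Rec1.AI1`, `Bind pA2.Rec1.AI1`, `Unbind pA2.Rec1.AI1`, `Prod Y`,
#' `Decay Y`, and `Feedback gain` (the strength of the bound-promoter-driven
#' synthase operon). The remaining rates (basal synthase `bS`, synthase
#' decay `dS`, secretion `ksyn`, compartment transport `ktr`, AI1 decays
#' `d1m`/`d1c`, density influx coefficient `kN`) are fixture constants.
#'
#' @param genes Named numeric vector overriding any of the nine optimisable
#'   rates.
#' @param fixed Named list overriding the fixture constants `bS`, `dS`,
#'   `ksyn`, `ktr`, `d1m`, `d1c`, `kN`.
#' @return A `upc_model` object.
#' @export
upc_model <- function(genes = NULL, fixed = list()) {
  g <- c("Prod Rec1" = 1, "Decay Rec1" = 0.5, "Bind Rec1.AI1" = 1,
         "Unbind Rec1.AI1" = 1, "Bind pA2.Rec1.AI1" = 1,
         "Unbind pA2.Rec1.AI1" = 0.25, "Prod Y" = 1, "Decay Y" = 1,
         "Feedback gain" = 0.5)
  if (!is.null(genes)) {
    bad <- setdiff(names(genes), names(g))
    if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
    g[names(genes)] <- genes
  }
  fx <- list(bS = 0.002, dS = 0.5, ksyn = 1, ktr = 1, d1m = 0.5,
             d1c = 0.1, kN = 0.1)
  bad <- setdiff(names(fixed), names(fx))
  if (length(bad)) stop("unknown fixture constant(s): ", paste(bad, collapse = ", "))
  fx[names(fixed)] <- fixed
  if (g[["Feedback gain"]] < 0 ||
      any(g[setdiff(names(g), "Feedback gain")] <= 0) ||
      any(unlist(fx) <= 0)) {
    stop("all rates must be > 0 (feedback gain may be 0)")
  }
  structure(list(genes = g, fixed = fx), class = "upc_model")
}

upc_par_vector <- function(model) {
  g <- model$genes
  fx <- model$fixed
  # C++ layout: kR dR kon koff konP koffP kY dY kfb bS dS ksyn ktr d1m d1c kN
  c(unname(g[upc_gene_names[1:8]]), g[["Feedback gain"]],
    fx$bS, fx$dS, fx$ksyn, fx$ktr, fx$d1m, fx$d1c, fx$kN)
}

#' Forward or reverse transfer curve of the UPC module
#'
#' Sequential continuation: the steady state at each population density is
#' taken on the stable branch nearest the previous density's steady state
#' (ascending order for the forward response, descending for the reverse).
#' With positive feedback strong enough for bistability the two sweeps
#' separate over the hysteresis window.
#'
#' @param model A [upc_model()].
#' @param density_grid Positive ascending density grid.
#' @param direction `"forward"`, `"reverse"`, or `"both"`.
#' @return A `transfer_curve`: data frame `density`, `forward`, `reverse`
#'   (output Y; only the requested sweeps present).
#' @export
upc_transfer <- function(model, density_grid = 10^seq(-1, 1, length.out = 15),
                         direction = c("both", "forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(all(density_grid > 0), !is.unsorted(density_grid))
  pv <- upc_par_vector(model)
  out <- data.frame(density = density_grid)
  if (direction %in% c("both", "forward")) {
    out$forward <- cpp_upc_transfer(pv, density_grid, TRUE)$output
  }
  if (direction %in% c("both", "reverse")) {
    out$reverse <- cpp_upc_transfer(pv, density_grid, FALSE)$output
  }
  class(out) <- c("transfer_curve", "data.frame")
  out
}

#' Stable steady-state branches at one density
#'
#' Equilibrium continuation oracle: all stable intracellular-AI1 branches at
#' a given density (more than one indicates bistability).
#'
#' @param model A [upc_model()].
#' @param density Population density.
#' @return Numeric vector of stable intracellular AI1 steady states.
#' @export
upc_stable_branches <- function(model, density) {
  cpp_upc_stable_branches(upc_par_vector(model), density)
}

#' Step-function objective specification
#'
#' Three components: zero output below the threshold band, an ignored
#' transition band, and high output above it.
#'
#' @param threshold_lo,threshold_hi Band edges (the excluded transition
#'   region; must lie strictly inside the density grid when applied).
#' @param high_target Desired output above the band.
#' @param low_target Desired output below the band (default 0).
#' @param weight_forward,weight_reverse Sweep weights; set
#'   `weight_reverse = 0` for the forward-only (hysteresis-prone) objective.
#' @return An `objective_spec` list.
#' @export
objective_spec <- function(threshold_lo = 0.8, threshold_hi = 2.5,
                           high_target = 0.8, low_target = 0,
                           weight_forward = 1, weight_reverse = 1) {
  stopifnot(threshold_hi > threshold_lo)
  structure(list(threshold_lo = threshold_lo, threshold_hi = threshold_hi,
                 high_target = high_target, low_target = low_target,
                 weight_forward = weight_forward,
                 weight_reverse = weight_reverse),
            class = "objective_spec")
}

#' Step-function loss of a transfer curve
#'
#' Sum of squared deviations from the low/high targets over the included
#' sweeps, with the transition band excluded.
#'
#' @param curve A [upc_transfer()] result with the sweeps required by `spec`.
#' @param spec An [objective_spec()].
#' @return Scalar loss.
#' @export
step_objective <- function(curve, spec) {
  d <- curve$density
  if (min(d) >= spec$threshold_lo || max(d) <= spec$threshold_hi) {
    stop("transition band must lie strictly inside the density grid")
  }
  target <- ifelse(d < spec$threshold_lo, spec$low_target,
                   ifelse(d > spec$threshold_hi, spec$high_target, NA_real_))
  keep <- !is.na(target)
  loss <- 0
  if (spec$weight_forward > 0) {
    if (is.null(curve$forward)) stop("forward sweep required")
    loss <- loss + spec$weight_forward * sum((curve$forward[keep] - target[keep])^2)
  }
  if (spec$weight_reverse > 0) {
    if (is.null(curve$reverse)) stop("reverse sweep required")
    loss <- loss + spec$weight_reverse * sum((curve$reverse[keep] - target[keep])^2)
  }
  loss
}

#' Hysteresis metric of a transfer curve
#'
#' Mean absolute forward/reverse separation over the grid, normalised by the
#' curve's dynamic range (invariant to affine output rescaling).
#'
#' @param curve A [upc_transfer()] result with both sweeps.
#' @return Scalar in `[0, ~1]`; 0 for identical sweeps.
#' @export
hysteresis_metric <- function(curve) {
  if (is.null(curve$forward) || is.null(curve$reverse)) {
    stop("both sweeps required")
  }
  rng <- max(curve$forward, curve$reverse) - min(curve$forward, curve$reverse)
  if (rng == 0) stop("zero dynamic range: hysteresis undefined")
  mean(abs(curve$forward - curve$reverse)) / rng
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size (>= 10).
#' @param generations Generations per run.
#' @param runs Independent GA runs.
#' @param tournament_k Tournament size.
#' @param crossover_p Per-gene uniform-crossover probability.
#' @param mutation_sigma Gaussian mutation SD in log10 decades.
#' @param mutation_rate Per-gene mutation probability.
#' @param bounds Decades around the nominal genes searched (+/-).
#' @param seed Root seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100, generations = 200, runs = 1,
                      tournament_k = 3, crossover_p = 0.5,
                      mutation_sigma = 0.1, mutation_rate = 0.1,
                      bounds = 0.75, seed = 1) {
  stopifnot(pop_size >= 10, crossover_p >= 0, crossover_p <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(pop_size = pop_size, generations = generations, runs = runs,
                 tournament_k = tournament_k, crossover_p = crossover_p,
                 mutation_sigma = mutation_sigma, mutation_rate = mutation_rate,
                 bounds = bounds, seed = seed),
            class = "ga_config")
}

#' Optimise a loss over log10 gene space with a real-coded GA
#'
#' Tournament selection, uniform crossover, Gaussian mutation and elitism 1
#' on log10-scaled genes. Each run derives its own RNG stream from the
#' config seed.
#'
#' @param loss_fn `function(named_gene_vector) -> scalar` (lower is better).
#' @param center Named nominal gene vector (search centres, linear scale).
#' @param config A [ga_config()].
#' @return List of runs, each with `genes` (best vector), `loss`, and
#'   `trace` (best-of-generation losses, non-increasing).
#' @export
run_ga <- function(loss_fn, center, config = ga_config()) {
  lg0 <- log10(center)
  p <- length(lg0)
  lo <- lg0 - config$bounds; hi <- lg0 + config$bounds
  runs <- vector("list", config$runs)
  for (run in seq_len(config$runs)) {
    old <- local_rng(derive_seed(config$seed, "ga", run))
    pop <- matrix(stats::runif(config$pop_size * p, rep(lo, each = config$pop_size),
                               rep(hi, each = config$pop_size)),
                  config$pop_size, p)
    fit <- apply(pop, 1, function(lg) loss_fn(stats::setNames(10^lg, names(center))))
    if (all(!is.finite(fit))) stop("all-invalid initial population")
    trace <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      newpop <- matrix(0, config$pop_size, p)
      best <- which.min(fit)
      newpop[1, ] <- pop[best, ]  # elitism
      for (i in 2:config$pop_size) {
        pick <- function() {
          cand <- sample.int(config$pop_size, config$tournament_k)
          cand[which.min(fit[cand])]
        }
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        cross <- stats::runif(p) < config$crossover_p
        child <- ifelse(cross, pb, pa)
        mut <- stats::runif(p) < config$mutation_rate
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, config$mutation_sigma)
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      fit <- apply(pop, 1, function(lg) loss_fn(stats::setNames(10^lg, names(center))))
      trace[gen] <- min(fit, na.rm = TRUE)
    }
    restore_rng(old)
    best <- which.min(fit)
    runs[[run]] <- list(genes = stats::setNames(10^pop[best, ], names(center)),
                        loss = fit[best], trace = cummin(trace))
  }
  runs
}

#' GA optimisation of the UPC module
#'
#' Convenience wrapper: optimises the nine named UPC rates against the
#' step-function objective on forward (and optionally reverse) transfer
#' sweeps.
#'
#' @param spec An [objective_spec()] (set `weight_reverse = 0` for the
#'   forward-only objective).
#' @param config A [ga_config()].
#' @param density_grid Density grid for the sweeps.
#' @param model Base [upc_model()] providing nominal genes and constants.
#' @return List of runs as in [run_ga()], each augmented with the final
#'   `hysteresis` of its optimised curve.
#' @export
optimize_upc <- function(spec = objective_spec(), config = ga_config(),
                         density_grid = 10^seq(-1, 1, length.out = 15),
                         model = upc_model()) {
  need <- if (spec$weight_reverse > 0) "both" else "forward"
  loss_fn <- function(genes) {
    m <- upc_model(genes, model$fixed)
    cur <- upc_transfer(m, density_grid, "both")
    step_objective(cur, spec)
  }
  runs <- run_ga(loss_fn, model$genes, config)
  for (i in seq_along(runs)) {
    cur <- upc_transfer(upc_model(runs[[i]]$genes, model$fixed), density_grid, "both")
    runs[[i]]$hysteresis <- hysteresis_metric(cur)
  }
  attr(runs, "direction") <- need
  runs
}

#' Local parameter-sensitivity signature
#'
#' Samples a log-uniform neighbourhood (default +/- 0.25 decades) around a
#' gene vector, evaluates the hysteresis metric at each sample, and fits
#' first-order RS-HDMR indices: the "sensitivity signature" of that
#' parameter neighbourhood.
#'
#' @param center Named gene vector (neighbourhood centre).
#' @param model Base [upc_model()] for the fixture constants.
#' @param radius_decades Neighbourhood half-width in decades.
#' @param n Number of samples (>= 20 per parameter).
#' @param seed Integer seed.
#' @param density_grid Density grid for the sweeps.
#' @param output `function(curve) -> scalar` (default [hysteresis_metric()]).
#' @return A `sensitivity_signature`: named index vector with attributes
#'   `center` and `degenerate` (TRUE when the output had no variance).
#' @export
local_sensitivity_signature <- function(center, model = upc_model(),
                                        radius_decades = 0.25,
                                        n = 20 * length(center), seed = 1,
                                        density_grid = 10^seq(-1, 1, length.out = 15),
                                        output = hysteresis_metric) {
  stopifnot(n >= 20 * length(center))
  des <- sample_design(names(center),
                       data.frame(lo = center * 10^-radius_decades,
                                  hi = center * 10^radius_decades),
                       n_samples = n, seed = seed)
  X <- sample_parameters(des)
  takes_genes <- length(formals(output)) >= 2
  base_genes <- model$genes
  y <- vapply(seq_len(n), function(i) {
    g <- base_genes
    g[colnames(X)] <- X[i, ]
    m <- upc_model(g, model$fixed)
    tryCatch({
      cur <- upc_transfer(m, density_grid, "both")
      if (takes_genes) output(cur, X[i, ]) else output(cur)
    }, error = function(e) NA_real_)
  }, 0)
  if (stats::var(y, na.rm = TRUE) %in% c(0, NA) || all(is.na(y))) {
    sig <- stats::setNames(rep(0, length(center)), names(center))
    return(structure(sig, center = center, degenerate = TRUE,
                     class = "sensitivity_signature"))
  }
  fit <- fit_hdmr(log10(X), y, order = 1)
  structure(fit$S1, center = center, degenerate = FALSE,
            class = "sensitivity_signature")
}

#' Cluster sensitivity signatures
#'
#' Hierarchical clustering (average linkage on correlation distance by
#' default). Major clusters are the branches at the 0.5 cophenetic cut that
#' contain at least 20% of the signatures.
#'
#' @param signatures Matrix (rows = neighbourhoods, columns = parameters) or
#'   list of signature vectors.
#' @param linkage hclust method (default `"average"`).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param cut_height Cophenetic cut defining clusters.
#' @param major_frac Minimum fraction of signatures for a "major" cluster.
#' @return List with `hclust`, `labels` (cluster id per signature),
#'   `major` (ids of major clusters), `newick` (dendrogram string).
#' @export
cluster_signatures <- function(signatures, linkage = "average",
                               distance = c("correlation", "euclidean"),
                               cut_height = 0.5, major_frac = 0.2) {
  distance <- match.arg(distance)
  m <- if (is.list(signatures)) do.call(rbind, signatures) else as.matrix(signatures)
  if (nrow(m) < 5) stop("need >= 5 signatures")
  if (is.null(rownames(m))) rownames(m) <- paste0("n", seq_len(nrow(m)))
  d <- if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    stats::as.dist(1 - cc)
  } else {
    stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, h = cut_height)
  tab <- table(labels)
  major <- as.integer(names(tab)[tab >= major_frac * nrow(m)])
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = labels, major = major, newick = nwk)
}
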