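# Constrained Bayesian-network structure inference over rate constants,
# module phenotypes and S/N: quantile discretisation, BDeu-scored greedy
# hill climbing under tier constraints, bootstrap edge scores, and an
# exhaustive-enumeration mode for small node sets (the testing oracle).
#
# Tier semantics: rate constants admit no parents; S/N admits no children;
# phenotype -> rate edges are forbidden; direct rate -> S/N edges are
# allowed.

#' Quantile-discretise a variable table
#'
#' @param table Data frame / matrix of numeric columns.
#' @param n_bins Number of quantile bins (default 3).
#' @param edges Optional list of precomputed bin edges (for round-tripping).
#' @return List with `data` (integer bins, 1-based), `edges` (per column).
#'   Constant columns collapse to a single bin with a warning.
#' @export
discretize <- function(table, n_bins = 3, edges = NULL) {
  table <- as.data.frame(table)
  out <- table
  used_edges <- list()
  for (nm in names(table)) {
    x <- table[[nm]]
    e <- if (!is.null(edges)) edges[[nm]] else {
      qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   na.rm = TRUE))
      if (length(qs) < 3) {
        warning("column ", nm, " is (nearly) constant: single bin")
      }
      qs
    }
    used_edges[[nm]] <- e
    out[[nm]] <- if (length(e) < 3) rep(1L, length(x)) else {
      as.integer(cut(x, breaks = e, include.lowest = TRUE, labels = FALSE))
    }
  }
  list(data = out, edges = used_edges)
}

# BDeu family score of node with given parents (columns are integer bins)
bdeu_family <- function(data, node, parents, ess = 1) {
  x <- data[[node]]
  r <- max(x)
  if (length(parents) == 0) {
    j <- rep(1L, length(x)); q <- 1L
  } else {
    pm <- as.matrix(data[parents])
    q <- prod(vapply(parents, function(p) max(data[[p]]), 0))
    j <- as.integer(factor(apply(pm, 1, paste, collapse = "\r")))
    # j indexes observed configs only; unobserved configs contribute 0
  }
  aj <- ess / q
  ajk <- ess / (q * r)
  s <- 0
  for (jc in unique(j)) {
    sel <- j == jc
    nij <- sum(sel)
    s <- s + lgamma(aj) - lgamma(aj + nij)
    tk <- tabulate(x[sel], nbins = r)
    s <- s + sum(lgamma(ajk + tk) - lgamma(ajk))
  }
  s
}

allowed_edge <- function(from, to, tiers) {
  if (from == to) return(FALSE)
  if (tiers[to] == "rate_constant") return(FALSE)  # rates admit no parents
  if (tiers[from] == "performance") return(FALSE)  # S/N admits no children
  TRUE
}

has_cycle <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  queue <- which(indeg == 0)
  seen <- 0
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1
    for (w in which(adj[v, ] == 1)) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  seen < n
}

score_dag <- function(data, adj, ess = 1) {
  sum(vapply(seq_len(ncol(adj)), function(i) {
    bdeu_family(data, colnames(adj)[i],
                colnames(adj)[adj[, i] == 1], ess)
  }, 0))
}

hill_climb <- function(data, tiers, ess = 1, max_parents = 3) {
  vars <- names(data)
  n <- length(vars)
  adj <- matrix(0L, n, n, dimnames = list(vars, vars))
  fam <- vapply(vars, function(v) bdeu_family(data, v, character(0), ess), 0)
  repeat {
    best_gain <- 1e-9; best_move <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (adj[i, j] == 0) {
        if (!allowed_edge(vars[i], vars[j], tiers)) next
        if (sum(adj[, j]) >= max_parents) next
        adj[i, j] <- 1L
        if (!has_cycle(adj)) {
          new_fam <- bdeu_family(data, vars[j], vars[adj[, j] == 1], ess)
          gain <- new_fam - fam[j]
          if (gain > best_gain) {
            best_gain <- gain; best_move <- list(op = "add", i = i, j = j, fam = new_fam)
          }
        }
        adj[i, j] <- 0L
      } else {
        adj[i, j] <- 0L
        new_fam <- bdeu_family(data, vars[j], vars[adj[, j] == 1], ess)
        gain <- new_fam - fam[j]
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list(op = "del", i = i, j = j, fam = new_fam)
        }
        adj[i, j] <- 1L
      }
    }
    if (is.null(best_move)) break
    adj[best_move$i, best_move$j] <- if (best_move$op == "add") 1L else 0L
    fam[best_move$j] <- best_move$fam
  }
  adj
}

#' Learn a constrained Bayesian-network structure with bootstrap edge scores
#'
#' Per bootstrap resample, greedy hill climbing on the BDeu score
#' (equivalent sample size 1) under the tier constraints. The edge score is
#' the fraction of resamples whose learned graph contains the edge.
#'
#' @param table Data frame of numeric variables (rows = ensemble members).
#' @param tiers Named character vector: `"rate_constant"`, `"phenotype"`, or
#'   `"performance"` per column (exactly one performance column, the S/N).
#' @param n_bootstrap Number of resamples (default 100).
#' @param seed Integer seed.
#' @param n_bins Discretisation bins.
#' @param max_parents In-degree cap for the search.
#' @param method `"hill_climb"` (default) or `"exact"` (exhaustive
#'   order-based enumeration; <= 6 nodes).
#' @return An `edge_scores` object: `scores` (directed matrix in `[0,1]`),
#'   `tiers`, `n_bootstrap`, `method`.
#' @export
learn_structure <- function(table, tiers, n_bootstrap = 100, seed = 1,
                            n_bins = 3, max_parents = 3,
                            method = c("hill_climb", "exact")) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  stopifnot(all(names(table) %in% names(tiers)))
  tiers <- tiers[names(table)]
  if (sum(tiers == "performance") != 1) {
    stop("exactly one performance column required")
  }
  if (method == "exact" && ncol(table) > 6) {
    stop("exact enumeration limited to 6 nodes")
  }
  disc <- discretize(table, n_bins)$data
  vars <- names(disc)
  acc <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (b in seq_len(n_bootstrap)) {
    old <- local_rng(derive_seed(seed, "bootstrap", b))
    idx <- sample.int(nrow(disc), replace = TRUE)
    restore_rng(old)
    d <- disc[idx, , drop = FALSE]
    adj <- if (method == "hill_climb") {
      hill_climb(d, tiers, max_parents = max_parents)
    } else {
      exact_search(d, tiers, max_parents = max_parents)
    }
    acc <- acc + adj
  }
  structure(list(scores = acc / n_bootstrap, tiers = tiers,
                 n_bootstrap = n_bootstrap, method = method),
            class = "edge_scores")
}

# exact order-based search: enumerate topological orders of the phenotype
# block (rates always first, S/N always last) and pick the best allowed
# parent set per node under each order
exact_search <- function(data, tiers, ess = 1, max_parents = 3) {
  vars <- names(data)
  rates <- vars[tiers == "rate_constant"]
  phen <- vars[tiers == "phenotype"]
  snr <- vars[tiers == "performance"]
  best_subsets <- function(node, candidates) {
    # best-scoring parent subset of size <= max_parents
    best <- list(score = bdeu_family(data, node, character(0), ess),
                 parents = character(0))
    if (length(candidates)) {
      for (k in seq_len(min(max_parents, length(candidates)))) {
        combs <- utils::combn(candidates, k, simplify = FALSE)
        for (ps in combs) {
          s <- bdeu_family(data, node, ps, ess)
          if (s > best$score) best <- list(score = s, parents = ps)
        }
      }
    }
    best
  }
  perms <- combinat_perms(phen)
  best_total <- -Inf; best_adj <- NULL
  for (ord in perms) {
    adj <- matrix(0L, length(vars), length(vars), dimnames = list(vars, vars))
    total <- sum(vapply(rates, function(v) bdeu_family(data, v, character(0), ess), 0))
    pred <- rates
    for (v in ord) {
      b <- best_subsets(v, pred)
      total <- total + b$score
      adj[b$parents, v] <- 1L
      pred <- c(pred, v)
    }
    b <- best_subsets(snr, pred)
    total <- total + b$score
    adj[b$parents, snr] <- 1L
    if (total > best_total) { best_total <- total; best_adj <- adj }
  }
  best_adj
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  do.call(c, lapply(seq_along(x), function(i) {
    lapply(combinat_perms(x[-i]), function(p) c(x[i], p))
  }))
}

#' Threshold bootstrap edge scores into a reported network
#'
#' @param scores An `edge_scores` object.
#' @param cutoff Minimum edge score in `(0, 1)`.
#' @return List with `edges` (data frame from/to/score), `direct_parents`
#'   (the highest-scoring direct parents of the S/N node among retained
#'   edges), and `empty` flag.
#' @export
threshold_edges <- function(scores, cutoff = 0.8) {
  stopifnot(inherits(scores, "edge_scores"), cutoff > 0, cutoff < 1)
  m <- scores$scores
  idx <- which(m >= cutoff, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[idx[, 1]],
                      to = colnames(m)[idx[, 2]],
                      score = m[idx])
  edges <- edges[order(-edges$score), ]
  snr <- names(scores$tiers)[scores$tiers == "performance"]
  to_snr <- edges[edges$to == snr, ]
  direct <- if (nrow(to_snr)) {
    to_snr$from[to_snr$score >= max(to_snr$score) - 1e-9]
  } else character(0)
  # constraint compliance is structural, but verify on output
  for (k in seq_len(nrow(edges))) {
    if (!allowed_edge(edges$from[k], edges$to[k], scores$tiers)) {
      stop("forbidden-direction edge in reported graph: ",
           edges$from[k], " -> ", edges$to[k])
    }
  }
  list(edges = edges, direct_parents = direct, empty = nrow(edges) == 0)
}

#' Export a thresholded network as DOT
#'
#' @param net A [threshold_edges()] result.
#' @param tiers Named tier vector (colours nodes by tier).
#' @param path Optional output file; otherwise the DOT string is returned.
#' @return The DOT text, invisibly if written to `path`.
#' @export
write_dot <- function(net, tiers, path = NULL) {
  col <- c(rate_constant = "palegreen", phenotype = "lightblue",
           performance = "lightgoldenrod")
  nodes <- unique(c(net$edges$from, net$edges$to, names(tiers)))
  lines <- c("digraph homeostat {",
             vapply(nodes, function(v) {
               sprintf("  \"%s\" [style=filled, fillcolor=%s];", v,
                       col[[tiers[[v]]]])
             }, ""),
             vapply(seq_len(nrow(net$edges)), function(i) {
               sprintf("  \"%s\" -> \"%s\" [label=\"%.2f\"%s];",
                       net$edges$from[i], net$edges$to[i], net$edges$score[i],
                       if (net$edges$from[i] %in% net$direct_parents &&
                           net$edges$to[i] == names(tiers)[tiers == "performance"])
                         ", penwidth=2" else "")
             }, ""),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
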