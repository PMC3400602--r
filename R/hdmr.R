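# Random-Sampling High Dimensional Model Representation (RS-HDMR):
# variance decomposition of a scalar output into first- and second-order
# component functions on orthonormal (shifted-Legendre) polynomial bases,
# with variance-based sensitivity indices and cross-validated prediction.

#' Log-uniform sampling design
#'
#' Each variable spans its range log-uniformly (the convention for rate
#' constants and time-scales: one order of magnitude around nominal values,
#' uniform in log space).
#'
#' @param vars Character vector of variable names.
#' @param ranges Matrix/data frame with columns `lo`, `hi` (rows = vars), all
#'   positive.
#' @param n_samples Number of samples (>= 10 per variable for fitting).
#' @param seed Integer seed.
#' @return A `sample_design` list.
#' @export
sample_design <- function(vars, ranges, n_samples = 30 * length(vars), seed = 1) {
  ranges <- as.data.frame(ranges)
  stopifnot(nrow(ranges) == length(vars), all(ranges$lo > 0),
            all(ranges$hi > ranges$lo))
  if (n_samples < 10 * length(vars)) {
    warning("fewer than 10 samples per variable; HDMR fits may be unstable")
  }
  structure(list(vars = vars, ranges = ranges, n_samples = n_samples,
                 seed = seed),
            class = "sample_design")
}

#' Draw a parameter sample matrix from a design
#'
#' @param design A [sample_design()].
#' @return `n_samples x n_vars` matrix, log-uniform within the ranges;
#'   reproducible given the design seed.
#' @export
sample_parameters <- function(design) {
  stopifnot(inherits(design, "sample_design"))
  old <- local_rng(design$seed)
  on.exit(restore_rng(old))
  p <- length(design$vars)
  m <- matrix(0, design$n_samples, p, dimnames = list(NULL, design$vars))
  for (j in seq_len(p)) {
    m[, j] <- 10^stats::runif(design$n_samples,
                              log10(design$ranges$lo[j]),
                              log10(design$ranges$hi[j]))
  }
  m
}

#' Time-scale sampling design for a system
#'
#' Module time-scale multipliers, each spanning one decade
#' (`[10^-0.5, 10^0.5]`) around 1: `tau_sig`, `tau_QS`, `tau_T` for every
#' system, plus `tau_osc` (system 3) or `tau_thr` (system 4).
#'
#' @param system_id 2, 3 or 4.
#' @param n_per_var Samples per variable (default 30).
#' @param seed Integer seed.
#' @return A [sample_design()].
#' @export
timescale_design <- function(system_id, n_per_var = 30, seed = 1) {
  stopifnot(system_id %in% 2:4)
  vars <- c("tau_sig", "tau_QS", "tau_T",
            if (system_id == 3) "tau_osc", if (system_id == 4) "tau_thr")
  sample_design(vars,
                data.frame(lo = rep(10^-0.5, length(vars)),
                           hi = rep(10^0.5, length(vars))),
                n_samples = n_per_var * length(vars), seed = seed)
}

#' Evaluate a runner over a sample matrix
#'
#' Maps each parameter row to a scalar output. Each sample gets a
#' deterministic simulation seed derived from `(root_seed, index)`, so
#' results are independent of evaluation order. Failed evaluations are
#' recorded as `NA`, never dropped silently.
#'
#' @param runner `function(params_named_vector, seed) -> scalar`.
#' @param samples Matrix from [sample_parameters()].
#' @param root_seed Root seed for per-sample seed derivation.
#' @return Numeric vector with attribute `n_failed`.
#' @export
evaluate_ensemble <- function(runner, samples, root_seed = 1) {
  n <- nrow(samples)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- derive_seed(root_seed, "ensemble", i)
    out[i] <- tryCatch(as.numeric(runner(samples[i, ], s)),
                       error = function(e) NA_real_)
  }
  attr(out, "n_failed") <- sum(is.na(out))
  out
}

# orthonormal shifted-Legendre polynomials on [0,1], degrees 1..3
shifted_legendre <- function(x, degree) {
  switch(degree,
         sqrt(3) * (2 * x - 1),
         sqrt(5) * (6 * x^2 - 6 * x + 1),
         sqrt(7) * (20 * x^3 - 30 * x^2 + 12 * x - 1))
}

hdmr_rescale <- function(X, ranges) {
  X <- as.matrix(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    lo <- ranges[j, 1]; hi <- ranges[j, 2]
    z <- (X[, j] - lo) / (hi - lo)
    if (any(z < -1e-9 | z > 1 + 1e-9)) {
      warning("inputs outside fitted ranges; clamping")
    }
    out[, j] <- pmin(pmax(z, 0), 1)
  }
  out
}

#' Fit an RS-HDMR expansion
#'
#' Decomposes `y = f0 + sum_i f_i(x_i) + sum_{i<j} f_ij(x_i, x_j) + eps` with
#' component functions on orthonormal shifted-Legendre bases (degree <= 3
#' first order; tensor degree <= 2 each for second order, fitted on the
#' first-order residuals). Sensitivity indices are empirical variance
#' shares, `S_i = Var(f_i) / Var(y)`; components with index below
#' `sig_floor` are zeroed. Total indices are `T_i = S_i + sum_j S_ij`.
#' Missing outputs are mean-imputed for fitting but excluded from variance
#' computations.
#'
#' @param X Input matrix (columns = variables, any positive scale).
#' @param y Output vector (may contain `NA`).
#' @param order 1 or 2.
#' @param degrees `c(first_order_degree, second_order_degree)`, at most
#'   `c(3, 2)`.
#' @param sig_floor Significance floor on indices (default 0.005).
#' @param ranges Optional fitted ranges (defaults to column ranges of `X`).
#' @return An `hdmr_expansion` object with `f0`, coefficient tables,
#'   indices `S1`, `S2`, totals `T`, and `n_missing`.
#' @export
fit_hdmr <- function(X, y, order = 2, degrees = c(3, 2), sig_floor = 0.005,
                     ranges = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("x", seq_len(p))
  colnames(X) <- vars
  d1 <- min(degrees[1], 3)
  d2 <- if (length(degrees) > 1) min(degrees[2], 2) else 2
  if (is.null(ranges)) {
    ranges <- cbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  }
  miss <- is.na(y)
  y_fit <- y
  y_fit[miss] <- mean(y, na.rm = TRUE)
  n <- length(y_fit)
  if (n < 3 * (p * d1 + 1)) stop("need n >= 3x the first-order basis dimension")
  Z <- hdmr_rescale(X, ranges)
  f0 <- mean(y[!miss])
  r <- y_fit - f0

  # first order: joint least squares over all variables' bases
  B1 <- matrix(0, n, p * d1)
  for (j in seq_len(p)) for (d in seq_len(d1)) {
    B1[, (j - 1) * d1 + d] <- shifted_legendre(Z[, j], d)
  }
  q <- qr(B1)
  if (q$rank < ncol(B1)) warning("rank-deficient first-order basis")
  a1 <- qr.coef(q, r)
  a1[is.na(a1)] <- 0
  coef1 <- matrix(a1, nrow = p, byrow = TRUE,
                  dimnames = list(vars, paste0("d", seq_len(d1))))
  F1 <- sapply(seq_len(p), function(j) B1[, (j - 1) * d1 + seq_len(d1), drop = FALSE] %*% coef1[j, ])
  r2nd <- r - rowSums(F1)

  pairs <- if (order >= 2 && p >= 2) utils::combn(p, 2) else matrix(0, 2, 0)
  coef2 <- vector("list", ncol(pairs))
  F2 <- matrix(0, n, ncol(pairs))
  if (ncol(pairs) > 0) {
    nb2 <- d2 * d2
    B2 <- matrix(0, n, ncol(pairs) * nb2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      col <- (k - 1) * nb2
      for (di in seq_len(d2)) for (dj in seq_len(d2)) {
        col <- col + 1
        B2[, col] <- shifted_legendre(Z[, i], di) * shifted_legendre(Z[, j], dj)
      }
    }
    q2 <- qr(B2)
    if (q2$rank < ncol(B2)) warning("rank-deficient second-order basis")
    a2 <- qr.coef(q2, r2nd)
    a2[is.na(a2)] <- 0
    for (k in seq_len(ncol(pairs))) {
      coef2[[k]] <- matrix(a2[(k - 1) * nb2 + seq_len(nb2)], d2, d2, byrow = TRUE)
      F2[, k] <- B2[, (k - 1) * nb2 + seq_len(nb2), drop = FALSE] %*% a2[(k - 1) * nb2 + seq_len(nb2)]
    }
  }

  vy <- stats::var(y[!miss])
  ok <- !miss
  S1 <- if (vy > 0) apply(F1[ok, , drop = FALSE], 2, stats::var) / vy else rep(0, p)
  names(S1) <- vars
  S2 <- matrix(0, p, p, dimnames = list(vars, vars))
  if (ncol(pairs) > 0 && vy > 0) {
    s2v <- apply(F2[ok, , drop = FALSE], 2, stats::var) / vy
    for (k in seq_len(ncol(pairs))) {
      S2[pairs[1, k], pairs[2, k]] <- S2[pairs[2, k], pairs[1, k]] <- s2v[k]
    }
  }
  # significance floor: zero both the index and the component function
  for (j in seq_len(p)) if (S1[j] < sig_floor) { S1[j] <- 0; coef1[j, ] <- 0 }
  if (ncol(pairs) > 0) {
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (S2[i, j] < sig_floor) { S2[i, j] <- S2[j, i] <- 0; coef2[[k]][] <- 0 }
    }
  }
  Tt <- S1 + rowSums(S2)
  structure(list(f0 = f0, vars = vars, ranges = ranges, d1 = d1, d2 = d2,
                 coef1 = coef1, pairs = pairs, coef2 = coef2,
                 S1 = S1, S2 = S2, total = Tt, var_y = vy,
                 n_missing = sum(miss), sig_floor = sig_floor),
            class = "hdmr_expansion")
}

#' @export
print.hdmr_expansion <- function(x, ...) {
  cat("<hdmr_expansion>", length(x$vars), "variables, f0 =", signif(x$f0, 4), "\n")
  ord <- order(x$total, decreasing = TRUE)
  for (j in ord) {
    cat(sprintf("  %-10s S = %.3f  T = %.3f\n", x$vars[j], x$S1[j], x$total[j]))
  }
  invisible(x)
}

#' Predict from a fitted RS-HDMR expansion
#'
#' @param object An `hdmr_expansion`.
#' @param newdata Input matrix with the fitted variables as columns. Inputs
#'   outside the fitted ranges are clamped with a warning.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.hdmr_expansion <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$vars, drop = FALSE]
  Z <- hdmr_rescale(X, object$ranges)
  n <- nrow(Z)
  yhat <- rep(object$f0, n)
  for (j in seq_along(object$vars)) {
    for (d in seq_len(object$d1)) {
      yhat <- yhat + object$coef1[j, d] * shifted_legendre(Z[, j], d)
    }
  }
  if (ncol(object$pairs) > 0) {
    for (k in seq_len(ncol(object$pairs))) {
      i <- object$pairs[1, k]; j <- object$pairs[2, k]
      cf <- object$coef2[[k]]
      for (di in seq_len(object$d2)) for (dj in seq_len(object$d2)) {
        if (cf[di, dj] != 0) {
          yhat <- yhat + cf[di, dj] * shifted_legendre(Z[, i], di) *
            shifted_legendre(Z[, j], dj)
        }
      }
    }
  }
  yhat
}

#' Cross-validated prediction accuracy of an RS-HDMR fit
#'
#' k-fold out-of-fold R-squared: folds are assigned deterministically from
#' `seed`, the expansion is refitted on each training split with the same
#' settings, and R2 is computed from pooled out-of-fold predictions.
#'
#' @inheritParams fit_hdmr
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return Out-of-fold R-squared (can be negative for uninformative models).
#' @export
cv_r2 <- function(X, y, k = 5, order = 2, degrees = c(3, 2),
                  sig_floor = 0.005, seed = 1) {
  X <- as.matrix(X)
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  old <- local_rng(seed)
  folds <- sample(rep_len(seq_len(k), n))
  restore_rng(old)
  ranges <- cbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  yhat <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_hdmr(X[tr, , drop = FALSE], y[tr], order = order,
                    degrees = degrees, sig_floor = sig_floor, ranges = ranges)
    yhat[!tr] <- suppressWarnings(predict(fit, X[!tr, , drop = FALSE]))
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Serialise an RS-HDMR expansion (or sampling design) to JSON
#'
#' @param x An `hdmr_expansion` or `sample_design`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hdmr_json <- function(x, path) {
  out <- if (inherits(x, "hdmr_expansion")) {
    list(kind = "hdmr_expansion", f0 = x$f0, vars = x$vars,
         ranges = as.data.frame(x$ranges), degrees = c(x$d1, x$d2),
         coef1 = as.data.frame(x$coef1), S1 = as.list(x$S1),
         S2 = as.data.frame(x$S2), total = as.list(x$total),
         sig_floor = x$sig_floor, n_missing = x$n_missing)
  } else if (inherits(x, "sample_design")) {
    list(kind = "sample_design", vars = x$vars,
         ranges = as.data.frame(x$ranges), n_samples = x$n_samples,
         seed = x$seed)
  } else stop("unsupported object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
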