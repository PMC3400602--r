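# Performance and spatial statistics: the S/N homeostasis metric,
# commitment rasters, neighbour-bias Z-scores, oscillator phase differences
# and power-law fits.

#' Signal-to-noise ratio of a population time series
#'
#' The homeostasis performance metric: the inverse coefficient of variation
#' of the committed-cell count over the evaluation window (by default the
#' final 50% of the series). Uses the population (not sample) standard
#' deviation.
#'
#' @param series Numeric vector (e.g. committed counts) or a
#'   `trajectory_bundle`, in which case its committed population series and
#'   burn-in fraction are used.
#' @param window Fraction of the series used, counted from the end.
#' @return A `performance_report` list: `snr`, `mean`, `sd`, `window`
#'   (index range used). A constant positive series yields `snr = Inf` with
#'   a warning.
#' @export
signal_to_noise <- function(series, window = 0.5) {
  if (inherits(series, "trajectory_bundle")) {
    window <- 1 - series$config$burn_in
    series <- series$populations$committed
  }
  stopifnot(is.numeric(series), window > 0, window <= 1)
  n <- length(series)
  i0 <- max(1L, n - floor(window * n) + 1L)
  x <- series[i0:n]
  if (length(x) < 2) stop("need >= 2 post-burn-in samples")
  if (length(x) < 10) warning("fewer than 10 post-burn-in samples; S/N estimate unstable")
  if (all(x == 0)) stop("all-zero series: S/N undefined")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  snr <- if (s == 0) {
    warning("zero variance: S/N reported as Inf")
    Inf
  } else m / s
  structure(list(snr = snr, mean = m, sd = s, window = c(i0, n)),
            class = "performance_report")
}

#' Commitment raster of single-cell module output
#'
#' Builds the row-per-cell heat-map representation of single-cell UPC output
#' (`U`) over time: each live uncommitted cell occupies a row, commitment is
#' marked, and rows vacated by committed cells are reassigned to newly
#' divided uncommitted cells ("null space" convention).
#'
#' @param bundle A `trajectory_bundle` with per-cell traces.
#' @param species Trace column shown (default `"U"`).
#' @return List with `raster` (rows = slots, columns = output times; `NA`
#'   where the slot is vacant), `commit_marks` (slot, time index),
#'   `row_cells` (slot-to-cell-id assignment over time).
#' @export
commitment_raster <- function(bundle, species = "U") {
  tr <- bundle$traces
  if (!species %in% names(tr)) stop("no trace column ", species)
  times <- sort(unique(tr$time))
  nt <- length(times)
  slot_of <- integer(0)     # cell_id -> slot
  raster <- matrix(NA_real_, 0, nt)
  row_cells <- matrix(NA_integer_, 0, nt)
  marks <- NULL
  committed_ids <- integer(0)
  for (ti in seq_len(nt)) {
    sub <- tr[tr$time == times[ti] & tr$type == 0, c("cell_id", species)]
    newly_committed <- tr$cell_id[tr$time == times[ti] & tr$type == 1]
    newly_committed <- setdiff(intersect(newly_committed, names2id(slot_of)), committed_ids)
    for (cid in newly_committed) {
      marks <- rbind(marks, c(slot = slot_of[[as.character(cid)]], t = ti))
      committed_ids <- c(committed_ids, cid)
    }
    # free slots of cells no longer tracked as uncommitted
    active <- as.character(sub$cell_id)
    freed <- setdiff(names(slot_of), active)
    free_slots <- sort(unname(slot_of[freed]))
    slot_of <- slot_of[active[active %in% names(slot_of)]]
    for (k in seq_len(nrow(sub))) {
      cid <- as.character(sub$cell_id[k])
      if (!cid %in% names(slot_of)) {
        if (length(free_slots)) {
          s <- free_slots[1]; free_slots <- free_slots[-1]
        } else {
          s <- nrow(raster) + 1L
          raster <- rbind(raster, rep(NA_real_, nt))
          row_cells <- rbind(row_cells, rep(NA_integer_, nt))
        }
        slot_of[cid] <- s
      }
      raster[slot_of[cid], ti] <- sub[[species]][k]
      row_cells[slot_of[cid], ti] <- sub$cell_id[k]
    }
  }
  list(raster = raster, commit_marks = marks, row_cells = row_cells,
       time = times)
}

names2id <- function(v) as.integer(names(v))

chebyshev_rings <- function(nr, nc, max_d) {
  # offsets grouped by Chebyshev distance
  lapply(seq_len(max_d), function(d) {
    off <- expand.grid(dr = -d:d, dc = -d:d)
    off[pmax(abs(off$dr), abs(off$dc)) == d, ]
  })
}

ring_fraction <- function(type_mat, ref_type, nbr_type, rings) {
  nr <- nrow(type_mat); nc <- ncol(type_mat)
  refs <- which(type_mat == ref_type, arr.ind = TRUE)
  if (nrow(refs) == 0) return(rep(NA_real_, length(rings)))
  vapply(rings, function(off) {
    tot <- 0L; hit <- 0L
    for (i in seq_len(nrow(refs))) {
      rr <- refs[i, 1] + off$dr; cc <- refs[i, 2] + off$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      v <- type_mat[cbind(rr[ok], cc[ok])]
      occ <- !is.na(v)
      tot <- tot + sum(occ)
      hit <- hit + sum(v[occ] == nbr_type)
    }
    if (tot == 0) NA_real_ else hit / tot
  }, 0)
}

#' Neighbour-bias Z-scores on lattice snapshots
#'
#' For each ring distance (Chebyshev, consistent with Moore neighbourhoods)
#' around cells of `ref_type`, measures the observed fraction of occupied
#' neighbour sites holding `nbr_type` cells, and compares it with a null
#' built by permuting type labels over the occupied sites. Z-scores are
#' averaged over snapshots.
#'
#' @param snapshots List of integer type matrices (`0` uncommitted, `1`
#'   committed, `NA` empty), e.g. `bundle$snapshots$type`.
#' @param ref_type,nbr_type Type codes of the reference and neighbour cells.
#' @param distances Ring distances evaluated (default 1:5).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return A `spatial_stats` data frame: `distance`, `z`, `observed`,
#'   `null_mean`, `null_sd`, `n_snapshots`; significance band at `p < 0.01`
#'   is `abs(z) > qnorm(0.995)`.
#' @export
neighbor_zscore <- function(snapshots, ref_type = 1, nbr_type = 1,
                            distances = 1:5, n_perm = 200, seed = 1) {
  stopifnot(n_perm >= 100)
  if (!is.list(snapshots)) snapshots <- list(snapshots)
  rings <- chebyshev_rings(nrow(snapshots[[1]]), ncol(snapshots[[1]]),
                           max(distances))[distances]
  zmat <- obs_mat <- mu_mat <- sd_mat <- NULL
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  used <- 0
  for (tm in snapshots) {
    occ <- which(!is.na(tm))
    labels <- tm[occ]
    if (sum(labels == ref_type) < 2 || sum(labels == nbr_type) < 2) next
    obs <- ring_fraction(tm, ref_type, nbr_type, rings)
    null_vals <- matrix(NA_real_, n_perm, length(rings))
    for (b in seq_len(n_perm)) {
      tmp <- tm
      tmp[occ] <- sample(labels)
      null_vals[b, ] <- ring_fraction(tmp, ref_type, nbr_type, rings)
    }
    mu <- colMeans(null_vals, na.rm = TRUE)
    sdv <- apply(null_vals, 2, stats::sd, na.rm = TRUE)
    zmat <- rbind(zmat, (obs - mu) / sdv)
    obs_mat <- rbind(obs_mat, obs); mu_mat <- rbind(mu_mat, mu)
    sd_mat <- rbind(sd_mat, sdv)
    used <- used + 1
  }
  if (used == 0) stop("fewer than 2 cells of a required type in every snapshot")
  structure(data.frame(distance = distances,
                       z = colMeans(zmat, na.rm = TRUE),
                       observed = colMeans(obs_mat, na.rm = TRUE),
                       null_mean = colMeans(mu_mat, na.rm = TRUE),
                       null_sd = colMeans(sd_mat, na.rm = TRUE),
                       n_snapshots = used),
            class = c("spatial_stats", "data.frame"))
}

#' Peak times of an oscillating trace
#'
#' Local maxima above the trace's 60th percentile with a minimum separation
#' of a quarter of the median inter-peak interval (iterated once to
#' stabilise the separation estimate).
#'
#' @param time,x Trace time and value vectors.
#' @return Numeric vector of peak times.
#' @export
peak_times <- function(time, x) {
  idx <- detect_peaks(x)
  idx <- idx[x[idx] > stats::quantile(x, 0.6)]
  if (length(idx) > 2) {
    min_sep <- stats::median(diff(time[idx])) / 4
    keep <- c(TRUE, diff(time[idx]) > min_sep)
    idx <- idx[keep]
  }
  time[idx]
}

#' Pairwise oscillator phase differences by distance
#'
#' For every pair of coexisting uncommitted cells with at least two detected
#' peaks each, collects the nearest-peak absolute time differences and bins
#' them by the pair's Euclidean grid distance.
#'
#' @param bundle A `trajectory_bundle` (system 3 fixture).
#' @param species Oscillating trace column (default `"A"`).
#' @param max_distance Largest bin (grid units).
#' @return A `phase_stats` data frame: `distance` (bin upper edge), `n`,
#'   `mean_dt`, `q1`, `q3`.
#' @export
phase_difference <- function(bundle, species = "A", max_distance = 10) {
  tr <- bundle$traces
  if (!species %in% names(tr)) stop("no trace column ", species)
  unc <- tr[tr$type == 0, ]
  ids <- unique(unc$cell_id)
  peaks <- lapply(ids, function(id) {
    s <- unc[unc$cell_id == id, ]
    peak_times(s$time, s[[species]])
  })
  names(peaks) <- ids
  keep <- vapply(peaks, function(p) length(p) >= 2, TRUE)
  ids <- ids[keep]; peaks <- peaks[keep]
  if (length(ids) < 2) {
    return(structure(data.frame(distance = numeric(0), n = integer(0),
                                mean_dt = numeric(0), q1 = numeric(0),
                                q3 = numeric(0)),
                     class = c("phase_stats", "data.frame"), empty = TRUE))
  }
  pos <- bundle$cells
  pos <- pos[match(ids, pos$cell_id), ]
  dists <- dts <- numeric(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      # coexistence: overlapping trace time ranges
      ti <- range(unc$time[unc$cell_id == ids[i]])
      tj <- range(unc$time[unc$cell_id == ids[j]])
      if (min(ti[2], tj[2]) <= max(ti[1], tj[1])) next
      pi_ <- peaks[[i]]; pj <- peaks[[j]]
      dt <- vapply(pi_, function(t0) min(abs(pj - t0)), 0)
      d <- sqrt((pos$row[i] - pos$row[j])^2 + (pos$col[i] - pos$col[j])^2)
      dists <- c(dists, rep(d, length(dt)))
      dts <- c(dts, dt)
    }
  }
  bins <- cut(dists, breaks = c(0, seq_len(max_distance)), labels = FALSE)
  ok <- !is.na(bins)
  agg <- lapply(split(dts[ok], bins[ok]), function(v) {
    c(n = length(v), mean_dt = mean(v),
      q1 = unname(stats::quantile(v, 0.25)), q3 = unname(stats::quantile(v, 0.75)))
  })
  out <- data.frame(distance = as.integer(names(agg)),
                    do.call(rbind, agg))
  structure(out[order(out$distance), ],
            class = c("phase_stats", "data.frame"))
}

#' Power-law exponent by log-log least squares
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, typically applied to
#' the committed-population equilibrium against the division/killing rate
#' ratio.
#'
#' @param table Data frame with the scan results.
#' @param x,y Column names (defaults `ratio`, `C_star`).
#' @param fit_range Optional `c(lo, hi)` restricting `x`.
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
powerlaw_exponent <- function(table, x = "ratio", y = "C_star",
                              fit_range = NULL) {
  xx <- table[[x]]; yy <- table[[y]]
  keep <- !is.na(xx) & !is.na(yy)
  if (!is.null(fit_range)) keep <- keep & xx >= fit_range[1] & xx <= fit_range[2]
  xx <- xx[keep]; yy <- yy[keep]
  if (length(xx) < 4) stop("need >= 4 points in range")
  if (any(xx <= 0) || any(yy <= 0)) stop("power-law fit needs positive values")
  fit <- stats::lm(log10(yy) ~ log10(xx))
  res <- stats::residuals(fit)
  ly <- log10(yy)
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, n = length(xx))
}

#' Detect en-masse commitment episodes
#'
#' An episode is a time window of length `window_frac * T` in which at least
#' `frac` of the uncommitted cells coexisting at the window start commit.
#'
#' Episodes are counted after the burn-in transient (growth from the small
#' founder population), consistent with the other homeostasis metrics.
#'
#' @param bundle A `trajectory_bundle`.
#' @param frac Fraction of coexisting uncommitted cells (default 0.5).
#' @param window_frac Window length as a fraction of the run (default 0.01).
#' @param burn_in Fraction of the run skipped (defaults to the bundle's).
#' @return List with `any` (logical) and `episodes` (data frame of window
#'   start time, uncommitted count, commitments).
#' @export
en_masse_episodes <- function(bundle, frac = 0.5, window_frac = 0.01,
                              burn_in = bundle$config$burn_in) {
  pops <- bundle$populations
  ev <- bundle$events
  commits <- ev$time[ev$kind == 2]
  Tend <- max(pops$time)
  w <- window_frac * Tend
  eps <- NULL
  idx <- which(pops$time >= burn_in * Tend)
  for (i in idx) {
    t0 <- pops$time[i]
    nu <- pops$uncommitted[i]
    if (nu < 4) next
    nc <- sum(commits >= t0 & commits < t0 + w)
    if (nc >= frac * nu) {
      eps <- rbind(eps, data.frame(time = t0, uncommitted = nu, commitments = nc))
    }
  }
  list(any = !is.null(eps), episodes = if (is.null(eps)) data.frame() else eps)
}

#' Write a commitment raster as a dense matrix with a JSON sidecar
#'
#' @param raster A [commitment_raster()] result.
#' @param path Base path; writes `<path>.csv` (dense matrix) and
#'   `<path>.json` (times, commit marks, row-to-cell-id map).
#' @return The two file paths, invisibly.
#' @export
write_raster <- function(raster, path) {
  csv <- paste0(path, ".csv"); side <- paste0(path, ".json")
  utils::write.table(raster$raster, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  jsonlite::write_json(
    list(time = raster$time,
         commit_marks = if (is.null(raster$commit_marks)) list() else
           as.data.frame(raster$commit_marks),
         row_cells = as.data.frame(raster$row_cells)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, side))
}
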