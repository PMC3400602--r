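# Reproducibility plumbing: one root seed, derived streams per stage.
# Sub-seeds are produced by integer mixing in double precision (exact below
# 2^53) and reduced mod 2^31-1 so they are valid R seeds everywhere.

#' Derive a deterministic sub-seed from a root seed
#'
#' All stochastic consumers in the package draw their seed from
#' `derive_seed(root, stage, index)` rather than sharing global RNG state,
#' so pipeline stages are reproducible independently of evaluation order.
#'
#' @param root Integer root seed.
#' @param stage Character stage name (e.g. `"ensemble"`, `"ga"`).
#' @param index Integer index within the stage (e.g. sample number).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stage = "main", index = 0) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 65521
  x <- (abs(root) %% 2147483647) * 48271 %% 2147483647
  x <- (x + h * 69621 + index * 16807) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  expr
}
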