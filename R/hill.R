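#' Hill activation and inhibition functions
#'
#' All feedback terms in the homeostasis circuits are modelled as Hill
#' functions. `hill_act` rises from 0 to 1 with half-maximum at `K`;
#' `hill_inh` is its complement, so `hill_act(x, K, n) + hill_inh(x, K, n) == 1`
#' for any input.
#'
#' @param x Input concentration or population size (non-negative).
#' @param K Threshold (half-maximum point), strictly positive.
#' @param n Hill exponent, >= 1.
#' @return Value in `[0, 1]`.
#' @examples
#' hill_act(2, K = 2, n = 2)  # 0.5 at threshold
#' hill_inh(0, K = 2, n = 2)  # 1 at zero input
#' @export
hill_act <- function(x, K, n = 2) {
  stopifnot(all(K > 0), all(n >= 1))
  xn <- (x / K)^n
  xn / (1 + xn)
}

#' @rdname hill_act
#' @export
hill_inh <- function(x, K, n = 2) {
  stopifnot(all(K > 0), all(n >= 1))
  1 / (1 + (x / K)^n)
}

#' Hill term specification
#'
#' A small record describing one Hill feedback term: its threshold, exponent
#' and mode (activation or inhibition). Used by circuit builders so every
#' gate is data, not code.
#'
#' @param K Threshold, > 0.
#' @param n Hill exponent, >= 1.
#' @param mode `"activation"` or `"inhibition"`.
#' @return An object of class `hill_spec`.
#' @export
hill_spec <- function(K, n = 2, mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  stopifnot(K > 0, n >= 1)
  structure(list(K = K, n = n, mode = mode), class = "hill_spec")
}

#' Evaluate a `hill_spec` at an input value
#' @param spec A [hill_spec()].
#' @param x Input value(s).
#' @return Hill function value(s) in `[0, 1]`.
#' @export
hill_eval <- function(spec, x) {
  stopifnot(inherits(spec, "hill_spec"))
  if (spec$mode == "activation") hill_act(x, spec$K, spec$n) else hill_inh(x, spec$K, spec$n)
}
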