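#' Measuring functions of the entropy-bound negentropy estimator
#'
#' The entropy-bound-minimization (EBM) estimator bounds the differential
#' entropy of a standardized source estimate using the expectations of a small
#' fixed set of nonlinearities ("measuring functions").  Four functions are
#' used, in this order:
#' \deqn{G_1(x) = x^4,\quad
#'       G_2(x) = |x|/(1+|x|),\quad
#'       G_3(x) = x|x|/(10+|x|),\quad
#'       G_4(x) = x/(1+x^2).}
#' \eqn{G_1} captures light (sub-Gaussian) tails, \eqn{G_2} heavy
#' (super-Gaussian) tails, and the two odd functions \eqn{G_3}, \eqn{G_4}
#' capture asymmetry.
#'
#' @param m Integer index of the measuring function, in `1:4`.
#' @return A list with elements `index`, `evaluate` (the scalar map
#'   \eqn{G_m}) and `derivative` (its pointwise first derivative \eqn{g_m}).
#' @seealso [evaluate_measuring_function()], [build_bound_table()]
#' @export
#' @examples
#' f <- measuring_function(1)
#' f$evaluate(2)    # 16
#' f$derivative(2)  # 32
measuring_function <- function(m) {
  m <- check_function_index(m)
  list(index = m,
       evaluate = function(x) evaluate_measuring_function(m, x),
       derivative = function(x) evaluate_measuring_function(m, x, deriv = TRUE))
}

#' Evaluate a measuring function or its derivative
#'
#' @param m Integer index in `1:4`; see [measuring_function()].
#' @param x Numeric vector of finite sample values.
#' @param deriv If `TRUE`, return the pointwise first derivative
#'   \eqn{g_m(x)} instead of \eqn{G_m(x)}.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' evaluate_measuring_function(2, 1)  # 0.5
evaluate_measuring_function <- function(m, x, deriv = FALSE) {
  m <- check_function_index(m)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be a finite numeric vector")
  a <- abs(x)
  if (!deriv) {
    switch(m,
           x^4,
           a / (1 + a),
           x * a / (10 + a),
           x / (1 + x^2))
  } else {
    switch(m,
           4 * x^3,
           sign(x) / (1 + a)^2,
           a * (20 + a) / (10 + a)^2,
           (1 - x^2) / (1 + x^2)^2)
  }
}

check_function_index <- function(m) {
  if (length(m) != 1L || !is.numeric(m) || is.na(m) || m != round(m) ||
      m < 1 || m > 4)
    stop("measuring-function index 'm' must be a single integer in 1..4")
  as.integer(m)
}
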