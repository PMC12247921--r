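#' Divisive normalization of a set of values
#'
#' Applies the canonical divisive normalization transform
#' \deqn{z_n = v_n / (\sigma + \sum_m v_m)}
#' to a vector of non-negative values. The contrast parameter \code{sigma}
#' controls the strength of the contextual rescaling: as \code{sigma} grows
#' the transform approaches a pure linear scaling, while for small
#' \code{sigma} the summed context dominates and outputs saturate.
#'
#' The transform preserves the order of its inputs and maps them into
#' \eqn{[0, 1)}. It is invariant under joint rescaling of the values and
#' \code{sigma} by the same positive constant.
#'
#' @param v numeric vector of non-negative values (the items in context).
#' @param sigma positive contrast parameter.
#' @return numeric vector of normalized values, same length as \code{v}.
#' @seealso [bundle_value_normalized()] for the implied bundle valuation,
#'   [normalization_responsiveness()] for its derivative.
#' @export
#' @examples
#' normalize_values(c(1, 1), sigma = 1)   # 1/3, 1/3
normalize_values <- function(v, sigma) {
  check_norm_args(v, sigma)
  v / (sigma + sum(v))
}

#' Normalized value of a bundle
#'
#' The valuation of a bundle implied by summing the divisively normalized
#' values of its members: for values summing to \eqn{\bar v},
#' \deqn{v_{bundle} = \bar v / (\sigma + \bar v).}
#' This function is strictly increasing and strictly concave in \eqn{\bar v}
#' for \code{sigma > 0}, which is the behavioral signature of sub-additive
#' bundle valuation: the more valuable the parts, the more the whole is
#' discounted relative to their sum.
#'
#' @inheritParams normalize_values
#' @return scalar normalized bundle value in \eqn{[0, 1)}.
#' @export
#' @examples
#' bundle_value_normalized(c(1, 1), sigma = 1)  # 2/3
bundle_value_normalized <- function(v, sigma) {
  check_norm_args(v, sigma)
  vbar <- sum(v)
  vbar / (sigma + vbar)
}

#' Responsiveness of the normalized value code
#'
#' Partial derivative of the normalization transform with respect to one of
#' its arguments:
#' \deqn{\partial Z(v_1, v_2) / \partial v_2 = \sigma / (\sigma + v_1 + v_2)^2.}
#' The derivative is positive, maximal when the second value is zero (a
#' single item in isolation), and strictly decreasing as the contextual
#' value grows. A neural measure that is linear in normalized value is
#' therefore predicted to respond less strongly to value on bundle trials
#' (\code{v2 > 0}) than on single-item trials: the attenuation prediction.
#'
#' @param v1,v2 non-negative values; the derivative is taken in \code{v2}.
#' @param sigma positive contrast parameter(s).
#' @return the derivative, vectorized over all arguments.
#' @export
normalization_responsiveness <- function(v1, v2, sigma) {
  check_norm_vec(c(v1, v2), sigma)
  sigma / (sigma + v1 + v2)^2
}

#' Second derivative of normalized bundle value
#'
#' Second derivative of \eqn{\bar v / (\sigma + \bar v)} with respect to the
#' summed item value \eqn{\bar v}:
#' \deqn{-2\sigma / (\sigma + \bar v)^3,}
#' strictly negative for \code{sigma > 0} — the normalized bundle value is
#' concave in the sum of its item values.
#'
#' @param v_bar non-negative summed item value (vectorized).
#' @param sigma positive contrast parameter(s).
#' @return the second derivative (negative).
#' @export
bundle_value_curvature <- function(v_bar, sigma) {
  check_norm_vec(v_bar, sigma)
  -2 * sigma / (sigma + v_bar)^3
}

# derivatives accept a vector of contrast parameters
check_norm_vec <- function(v, sigma) {
  if (!is.numeric(v) || anyNA(v) || any(v < 0))
    stop("values must be non-negative and non-missing", call. = FALSE)
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma <= 0))
    stop("'sigma' must be positive", call. = FALSE)
  invisible(TRUE)
}

check_norm_args <- function(v, sigma) {
  if (!is.numeric(v) || anyNA(v) || any(v < 0))
    stop("values must be non-negative and non-missing", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}
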