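# Bundle-value model families. Each maps constituent item values (vi, vj)
# to a predicted bundle value. Parameter vectors are named:
#   linear:      b0, b1, b2        vij = b0 + b1*vi + b2*vj
#   power:       b0, b1, b2, b3, b4  vij = b0 + b1*vi^b2 + b3*vj^b4
#   logarithmic: b0, b1, b3, b4, b5  vij = b0 + b1*log(b3+vi) + b4*log(b5+vj)
#   divnorm:     b0, b1, sigma     vij = b0 + b1*(vi+vj)/(sigma+vi+vj)
# (the logarithmic family's parameter numbering skips b2 by convention).

bundle_families <- c("linear", "power", "logarithmic", "divnorm")

family_param_names <- function(family) {
  switch(family,
    linear      = c("b0", "b1", "b2"),
    power       = c("b0", "b1", "b2", "b3", "b4"),
    logarithmic = c("b0", "b1", "b3", "b4", "b5"),
    divnorm     = c("b0", "b1", "sigma"),
    stop("unknown bundle-value family: ", family, call. = FALSE))
}

#' Predicted bundle value under a model family
#'
#' Evaluates one of the four bundle-value families at given item values.
#' Used both by the synthetic bid generator and by the model-fitting code.
#'
#' @param family one of \code{"linear"}, \code{"power"},
#'   \code{"logarithmic"}, \code{"divnorm"}.
#' @param params named numeric vector of the family's parameters (see
#'   [bundle_spec()] for the naming convention).
#' @param vi,vj item values (vectorized).
#' @return numeric vector of predicted bundle values.
#' @export
bundle_family_value <- function(family, params, vi, vj) {
  p <- as.list(params)
  switch(family,
    linear      = p$b0 + p$b1 * vi + p$b2 * vj,
    power       = p$b0 + p$b1 * vi^p$b2 + p$b3 * vj^p$b4,
    logarithmic = p$b0 + p$b1 * log(p$b3 + vi) + p$b4 * log(p$b5 + vj),
    divnorm     = {
      if (is.null(p$sigma) || p$sigma <= 0)
        stop("divnorm family requires sigma > 0", call. = FALSE)
      p$b0 + p$b1 * (vi + vj) / (p$sigma + vi + vj)
    },
    stop("unknown bundle-value family: ", family, call. = FALSE))
}

default_family_params <- function(family) {
  switch(family,
    linear      = c(b0 = 0.83, b1 = 0.73, b2 = 0.73),
    power       = c(b0 = 0.5, b1 = 1.0, b2 = 0.8, b3 = 1.0, b4 = 0.8),
    logarithmic = c(b0 = 0.3, b1 = 2.0, b3 = 1.0, b4 = 2.0, b5 = 1.0),
    divnorm     = c(b0 = 0.3, b1 = 20, sigma = 8))
}
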