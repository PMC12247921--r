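#' Value-coding scheme for synthetic multivoxel patterns
#'
#' Describes how trial value is embedded in a simulated region of
#' interest. Patterns are built as a low-rank linear code plus Gaussian
#' noise: a fixed unit-norm value direction carries the coded value, and
#' two further unit-norm directions carry trial-type and button-side
#' nuisance signals.
#'
#' Available schemes:
#' \describe{
#'   \item{absolute}{the raw bid is coded on a common scale across trial types.}
#'   \item{subtractive}{bid minus the mean bid of the trial's type.}
#'   \item{zscore}{bid z-scored within trial type (population s.d.).}
#'   \item{full_normalization}{a context-dependent divisive code in which the
#'     value coefficient differs by trial type: bundle-trial responsiveness
#'     equals \code{attenuation_ratio} times item-trial responsiveness by
#'     construction (via a trial-type interaction coefficient
#'     \eqn{b_2 = ratio - 1} on top of \eqn{b_1 = 1}, unit denominator).}
#'   \item{null}{no value signal; nuisance structure and noise only.}
#' }
#'
#' @param scheme one of the five schemes above.
#' @param w_value weight of the value signal (per unit coded value).
#' @param w_trial_type,w_side nuisance signal weights.
#' @param noise_sd i.i.d. Gaussian noise s.d. per voxel.
#' @param n_voxels number of voxels (>= 2).
#' @param attenuation_ratio bundle/item responsiveness ratio for the
#'   \code{full_normalization} scheme (in (0, 1] attenuates bundles).
#' @param geometry \code{"shared"} codes value on one direction for both
#'   trial types; \code{"orthogonal"} codes item value and bundle value on
#'   orthogonal directions (a condition-specific code).
#' @param norm_params optional named list overriding the
#'   full-normalization generator parameters (\code{b1}, \code{b2},
#'   \code{sigma}, \code{w_avg}, \code{w_1}, \code{w_v}).
#' @return object of class \code{coding_scheme}.
#' @export
coding_scheme <- function(scheme = c("absolute", "subtractive", "zscore",
                                     "full_normalization", "null"),
                          w_value = 1, w_trial_type = 1, w_side = 1,
                          noise_sd = 1, n_voxels = 200,
                          attenuation_ratio = 0.5,
                          geometry = c("shared", "orthogonal"),
                          norm_params = NULL) {
  scheme <- match.arg(scheme)
  geometry <- match.arg(geometry)
  if (n_voxels < 2) stop("n_voxels must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  np <- list(b1 = 1, b2 = attenuation_ratio - 1, sigma = 1,
             w_avg = 0, w_1 = 0, w_v = 0)
  if (!is.null(norm_params)) np[names(norm_params)] <- norm_params
  structure(list(scheme = scheme, w_value = w_value,
                 w_trial_type = w_trial_type, w_side = w_side,
                 noise_sd = noise_sd, n_voxels = n_voxels,
                 attenuation_ratio = attenuation_ratio,
                 geometry = geometry, norm_params = np),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat("Voxel coding scheme:", x$scheme, "(", x$geometry, "geometry )\n")
  cat(" value weight", x$w_value, "| nuisance (type, side):",
      x$w_trial_type, x$w_side, "| noise sd", x$noise_sd,
      "|", x$n_voxels, "voxels\n")
  if (x$scheme == "full_normalization")
    cat(" bundle/item responsiveness ratio:", x$attenuation_ratio, "\n")
  invisible(x)
}

# Coded value per trial under a scheme.
coded_value <- function(scheme, value, trial_kind) {
  is_bundle <- as.numeric(trial_kind == "bundle")
  switch(scheme$scheme,
    absolute = value,
    subtractive = value - stats::ave(value, trial_kind),
    zscore = zscore_by_condition(value, trial_kind),
    full_normalization =
      full_normalization_values(value, is_bundle, scheme$norm_params),
    null = rep(0, length(value)),
    stop("unknown scheme: ", scheme$scheme, call. = FALSE))
}

unit_vec <- function(n) { v <- stats::rnorm(n); v / sqrt(sum(v^2)) }

#' Simulate trial-wise multivoxel response patterns
#'
#' Generates a trials-by-voxels pattern matrix for one subject's schedule,
#' standing in for trial-wise GLM parameter-estimate (beta) maps. Each
#' trial's pattern is
#' \deqn{w_v \cdot codedValue \cdot u \; + \; w_{tt} [bundle] \cdot c
#'       \; + \; w_{side} [right] \cdot s \; + \; \epsilon,}
#' with \eqn{u, c, s} fixed unit-norm direction vectors drawn once per
#' dataset from the seed, and i.i.d. Gaussian noise. Under the
#' \code{"orthogonal"} geometry, item and bundle values are carried on
#' mutually orthogonal directions instead of a shared one.
#'
#' @param schedule trial schedule rows for a single subject.
#' @param wtp matching \code{wtp_data} (provides the bids).
#' @param scheme a [coding_scheme()].
#' @param seed integer seed (drives both directions and noise).
#' @param roi_label label attached to the dataset.
#' @return object of class \code{voxel_patterns}: list with
#'   \code{patterns} (n_trials x n_voxels matrix), \code{meta}
#'   (data.frame: \code{value}, \code{coded_value}, \code{trial_kind},
#'   \code{day}, \code{run}, \code{button_side}, \code{reference},
#'   \code{subject}), \code{roi_label} and \code{scheme}.
#' @export
simulate_voxel_patterns <- function(schedule, wtp, scheme, seed = 1,
                                    roi_label = "ROI") {
  stopifnot(inherits(scheme, "coding_scheme"))
  if (length(unique(schedule$subject)) != 1L)
    stop("schedule must contain exactly one subject", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  p <- scheme$n_voxels
  bid <- lookup_bids(schedule, wtp)
  cv <- coded_value(scheme, bid, schedule$trial_kind)

  u <- unit_vec(p)
  if (scheme$geometry == "orthogonal") {
    u2 <- unit_vec(p)
    u2 <- u2 - sum(u2 * u) * u          # Gram-Schmidt
    u2 <- u2 / sqrt(sum(u2^2))
  }
  cdir <- unit_vec(p)
  sdir <- unit_vec(p)

  is_bundle <- schedule$trial_kind == "bundle"
  is_right <- schedule$item_side == "right"
  X <- matrix(stats::rnorm(n * p, 0, scheme$noise_sd), n, p)
  if (scheme$geometry == "shared") {
    X <- X + (scheme$w_value * cv) %o% u
  } else {
    vi <- ifelse(is_bundle, 0, cv); vb <- ifelse(is_bundle, cv, 0)
    X <- X + (scheme$w_value * vi) %o% u + (scheme$w_value * vb) %o% u2
  }
  X <- X + (scheme$w_trial_type * as.numeric(is_bundle)) %o% cdir
  X <- X + (scheme$w_side * as.numeric(is_right)) %o% sdir

  meta <- data.frame(
    subject = schedule$subject, day = schedule$day, run = schedule$run,
    trial_kind = schedule$trial_kind, value = bid, coded_value = cv,
    button_side = schedule$item_side, reference = schedule$reference,
    stringsAsFactors = FALSE)
  structure(list(patterns = X, meta = meta, roi_label = roi_label,
                 scheme = scheme),
            class = "voxel_patterns")
}

#' @export
print.voxel_patterns <- function(x, ...) {
  cat("Voxel pattern dataset [", x$roi_label, "]: ",
      nrow(x$patterns), " trials x ", ncol(x$patterns), " voxels; scheme ",
      x$scheme$scheme, "\n", sep = "")
  invisible(x)
}
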