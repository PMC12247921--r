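# Condensed pairwise-index bookkeeping shared by all DSMs. Entries follow
# the ordering of stats::dist: for columns j = 1..n-1, rows i = j+1..n.
pair_index <- function(n) {
  j <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  i <- unlist(lapply(seq_len(n - 1L), function(k) seq.int(k + 1L, n)),
              use.names = FALSE)
  list(i = i, j = j)
}

new_dsm <- function(d, day, metric = "euclidean") {
  n <- length(day)
  px <- pair_index(n)
  valid <- day[px$i] != day[px$j]
  structure(list(d = as.numeric(d), i = px$i, j = px$j, valid = valid,
                 day = day, n = n, metric = metric), class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  cat("Dissimilarity matrix (condensed):", x$n, "trials,",
      length(x$d), "pairs,", sum(x$valid), "valid after day masking\n")
  invisible(x)
}

#' Trial-by-trial neural dissimilarity matrix
#'
#' Computes pairwise Euclidean distances between trial-wise multivoxel
#' patterns, stored in condensed form with a validity mask that excludes
#' every within-day pair — distances between trials recorded on the same
#' day are confounded by shared run/day structure and are removed from
#' all downstream fitting.
#'
#' @param data a \code{voxel_patterns} dataset, or a numeric matrix with
#'   a parallel \code{day} vector.
#' @param day day index per trial (required when \code{data} is a matrix).
#' @return object of class \code{dsm}: condensed distances \code{d},
#'   pair indices \code{i}, \code{j}, logical \code{valid} mask.
#' @export
compute_neural_dsm <- function(data, day = NULL) {
  if (inherits(data, "voxel_patterns")) {
    day <- data$meta$day
    data <- data$patterns
  }
  stopifnot(is.matrix(data), !is.null(day), length(day) == nrow(data))
  if (nrow(data) < 3) stop("need >= 3 trials", call. = FALSE)
  dsm <- new_dsm(stats::dist(data), day)
  if (!any(dsm$valid))
    stop("all trials share one day: no valid cross-day pairs", call. = FALSE)
  dsm
}

#' Model dissimilarity matrix from trial values
#'
#' Builds the model DSM for one of the simple value-coding hypotheses:
#' pairwise absolute differences of the transformed trial values, where
#' the transform is the identity (\code{absolute}), mean-centering within
#' trial type or stimulus category (\code{subtractive}), or z-scoring
#' within trial type (\code{zscore}).
#'
#' @param values trial values (WTP bids).
#' @param trial_types trial-type labels (item/bundle).
#' @param family \code{"absolute"}, \code{"subtractive"} or \code{"zscore"}.
#' @param day optional day index for the within-day mask (all pairs valid
#'   when omitted).
#' @param categories optional stimulus categories; with
#'   \code{subtract_by = "category"} the subtractive transform centers
#'   within these instead of within trial type.
#' @param subtract_by grouping for the subtractive transform.
#' @return a \code{dsm} object.
#' @export
build_model_dsm <- function(values, trial_types,
                            family = c("absolute", "subtractive", "zscore"),
                            day = NULL, categories = NULL,
                            subtract_by = c("trial_type", "category")) {
  family <- match.arg(family)
  subtract_by <- match.arg(subtract_by)
  v <- transform_values(values, trial_types, family, categories, subtract_by)
  if (is.null(day)) day <- seq_along(values)  # no masking
  new_dsm(stats::dist(v), day, metric = "value_difference")
}

transform_values <- function(values, trial_types, family,
                             categories = NULL,
                             subtract_by = "trial_type") {
  switch(family,
    absolute = values,
    subtractive = {
      g <- if (subtract_by == "category" && !is.null(categories))
        categories else trial_types
      values - stats::ave(values, g)
    },
    zscore = zscore_by_condition(values, trial_types),
    stop("unknown model-DSM family: ", family, call. = FALSE))
}

#' Context-normalized trial values
#'
#' The context-dependent normalization code: per-trial value
#' \deqn{\frac{b_1 AbsValue + b_2 AbsValue \cdot TrialCategory}
#'            {\sigma + w_{avg} AvgValue + w_1 TrialCategory + w_v AbsValue}}
#' where \code{TrialCategory} is 0 for single items and 1 for bundles and
#' \code{AvgValue} is the mean value within the trial's type. \eqn{b_2}
#' lets the value coefficient differ by trial type — attenuation on
#' bundle trials corresponds to \eqn{b_2 < 0} — while the denominator
#' weights implement divisive adaptation to the local value context.
#'
#' @param abs_value raw trial values (bids).
#' @param trial_category binary trial-type indicator (0 item, 1 bundle)
#'   or item/bundle labels.
#' @param params named list/vector with \code{b1}, \code{b2},
#'   \code{sigma}, \code{w_avg}, \code{w_1}, \code{w_v} (missing entries
#'   default to \code{sigma = 1} and 0 elsewhere).
#' @return numeric vector of normalized values.
#' @export
full_normalization_values <- function(abs_value, trial_category, params) {
  if (is.character(trial_category) || is.factor(trial_category))
    trial_category <- as.numeric(trial_category == "bundle")
  stopifnot(all(trial_category %in% c(0, 1)))
  p <- list(b1 = 0, b2 = 0, sigma = 1, w_avg = 0, w_1 = 0, w_v = 0)
  params <- as.list(params)
  p[names(params)] <- params
  avg <- stats::ave(abs_value, trial_category)
  den <- p$sigma + p$w_avg * avg + p$w_1 * trial_category +
    p$w_v * abs_value
  if (any(den <= 0))
    stop("non-positive normalization denominator", call. = FALSE)
  (p$b1 * abs_value + p$b2 * abs_value * trial_category) / den
}

rsa_families <- c("null", "absolute", "subtractive", "zscore",
                  "full_normalization")

# Nuisance DSMs: binary disagreement (0 same, 1 different).
binary_dsm_vec <- function(x) as.numeric(stats::dist(as.numeric(factor(x))) > 0)

rsa_design <- function(neural, trials) {
  stopifnot(inherits(neural, "dsm"))
  need <- c("value", "trial_kind", "button_side")
  if (!all(need %in% names(trials)))
    stop("trials need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(trials) != neural$n)
    stop("trial metadata (", nrow(trials), ") does not match DSM size (",
         neural$n, ")", call. = FALSE)
  keep <- neural$valid
  list(y = neural$d[keep],
       bp = binary_dsm_vec(trials$button_side)[keep],
       tt = binary_dsm_vec(trials$trial_kind)[keep],
       keep = keep,
       value = trials$value,
       tc = as.numeric(trials$trial_kind == "bundle"))
}

value_dsm_vec <- function(values, keep) as.numeric(stats::dist(values))[keep]

#' Fit a value-representation model to a neural DSM
#'
#' Fits the predicted-DSM model
#' \deqn{PredictedDSM = a_0 + a_1 ButtonPressDSM + a_2 TrialTypeDSM + ValueDSM}
#' to a neural DSM by least squares over the valid (cross-day) pairs,
#' where \code{ValueDSM} holds pairwise absolute differences of the
#' family's per-trial values. The value scale is carried inside the value
#' computation: \code{b1} multiplies the (transformed) value for the
#' \code{absolute}, \code{subtractive} and \code{zscore} families —
#' making the model linear in its parameters, solved exactly — and the
#' \code{full_normalization} family uses [full_normalization_values()]
#' with \code{sigma} fixed at 1 (removing the overall scale degeneracy)
#' and free \code{b1, b2, w_avg, w_1, w_v}, fitted by multi-start
#' bounded nonlinear least squares (\eqn{|b| \le 10}, denominator
#' weights \eqn{\ge 0}). The \code{null} family has no value component.
#'
#' @param neural a \code{dsm} from [compute_neural_dsm()].
#' @param trials data.frame with \code{value}, \code{trial_kind},
#'   \code{button_side} per trial (e.g. a \code{voxel_patterns} meta
#'   table).
#' @param family one of \code{"null"}, \code{"absolute"},
#'   \code{"subtractive"}, \code{"zscore"}, \code{"full_normalization"}.
#' @param seed multi-start seed (full normalization only).
#' @param n_starts number of optimizer starts.
#' @return object of class \code{rsa_fit}: \code{params} (a0–a2 and the
#'   family's value parameters), \code{rss}, \code{n_pairs}, \code{k},
#'   \code{BIC}, \code{value_coef_item} (b1), \code{value_coef_bundle}
#'   (b1 + b2 where the family has b2), \code{converged}.
#' @export
fit_rsa_model <- function(neural, trials, family = "full_normalization",
                          seed = 1, n_starts = 5) {
  family <- match.arg(family, rsa_families)
  dz <- rsa_design(neural, trials)
  y <- dz$y
  n <- length(y)
  Z <- cbind(a0 = 1, a1 = dz$bp, a2 = dz$tt)
  qrZ <- qr(Z)

  finish <- function(params, rss, k, item, bundle, converged) {
    bic <- n * log(rss / n) + (k + 1) * log(n)  # +1: residual variance
    structure(list(family = family, params = params, rss = rss,
                   n_pairs = n, k = k + 1, BIC = bic,
                   value_coef_item = item, value_coef_bundle = bundle,
                   converged = converged), class = "rsa_fit")
  }

  if (family == "null") {
    cf <- qr.coef(qrZ, y)
    rss <- sum(qr.resid(qrZ, y)^2)
    return(finish(cf, rss, k = 3, item = NA_real_, bundle = NA_real_,
                  converged = TRUE))
  }

  if (family %in% c("absolute", "subtractive", "zscore")) {
    v <- transform_values(dz$value, ifelse(dz$tc == 1, "bundle", "item"),
                          family)
    dv <- value_dsm_vec(v, dz$keep)
    X <- cbind(Z, b1 = dv)
    qrX <- qr(X)
    cf <- qr.coef(qrX, y)
    rss <- sum(qr.resid(qrX, y)^2)
    return(finish(cf, rss, k = 4, item = unname(cf["b1"]),
                  bundle = unname(cf["b1"]), converged = TRUE))
  }

  # full normalization: profile out a0..a2 for each candidate theta.
  # When w_v = 0 the per-trial value is linear in value within each trial
  # type, so (b1, b2, w_avg, w_1) are only identified up to a per-type
  # rescaling; a tiny ridge on the denominator weights breaks the tie
  # toward the parsimonious representation (weights at 0 unless the data
  # demand them) without materially affecting the fit.
  lam <- 1e-4 * sum(y^2)
  theta_rss <- function(theta) {
    vals <- tryCatch(
      full_normalization_values(dz$value, dz$tc,
                                list(b1 = theta[1], b2 = theta[2],
                                     sigma = 1, w_avg = theta[3],
                                     w_1 = theta[4], w_v = theta[5])),
      error = function(e) NULL)
    if (is.null(vals)) return(1e12)
    dv <- value_dsm_vec(vals, dz$keep)
    sum(qr.resid(qrZ, y - dv)^2) +
      lam * (theta[3]^2 + theta[4]^2 + theta[5]^2)
  }
  # b1 >= 0 fixes the sign convention (the value DSM only identifies the
  # coefficients up to a joint sign flip); b2 free within |b| <= 10.
  lower <- c(0, -10, 0, 0, 0)
  upper <- c(10, 10, 10, 10, 10)
  scale0 <- stats::sd(y) / max(stats::sd(dz$value), 1e-8)
  base <- c(min(max(scale0, 0.01), 5), 0, 0, 0, 0)
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1L) base else
      pmin(pmax(base + stats::rnorm(5, 0, c(0.5, 0.5, 0.2, 0.2, 0.05)),
                lower + 1e-6), upper - 1e-6)
    opt <- try(stats::optim(st, theta_rss, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 300)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("full-normalization RSA fit failed", call. = FALSE)
  polish <- try(stats::optim(best$par, theta_rss, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 500, factr = 1e4)),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value)
    best <- polish
  th <- best$par
  vals <- full_normalization_values(dz$value, dz$tc,
                                    list(b1 = th[1], b2 = th[2], sigma = 1,
                                         w_avg = th[3], w_1 = th[4],
                                         w_v = th[5]))
  dv <- value_dsm_vec(vals, dz$keep)
  cf_a <- qr.coef(qrZ, y - dv)
  rss <- sum(qr.resid(qrZ, y - dv)^2)
  params <- c(cf_a, b1 = th[1], b2 = th[2], sigma = 1,
              w_avg = th[3], w_1 = th[4], w_v = th[5])
  finish(params, rss, k = 8, item = th[1], bundle = th[1] + th[2],
         converged = best$convergence == 0)
}

#' @export
print.rsa_fit <- function(x, digits = 4, ...) {
  cat("RSA fit —", x$family, "family;", x$n_pairs, "valid pairs\n")
  print(round(x$params, digits))
  cat("RSS", signif(x$rss, 6), "| BIC", round(x$BIC, 1),
      if (!is.na(x$value_coef_item))
        paste("| value coef item", round(x$value_coef_item, digits),
              "bundle", round(x$value_coef_bundle, digits)) else "",
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Compare value-representation models by BIC
#'
#' Fits each family to the neural DSM and tabulates \eqn{\Delta BIC}
#' relative to the null (nuisance-only) model; more negative is a better
#' fit. Non-converged fits are flagged and excluded from the winner
#' determination.
#'
#' @inheritParams fit_rsa_model
#' @param families families to fit; the null family is always included
#'   as the reference.
#' @return data.frame of class \code{rsa_comparison}: per family
#'   \code{BIC}, \code{delta_bic} (vs null), \code{converged}; the
#'   best-fitting family name is in attribute \code{"winner"} and the
#'   fit objects in attribute \code{"fits"}.
#' @export
compare_rsa_models <- function(neural, trials, families = rsa_families,
                               seed = 1, n_starts = 5) {
  families <- union("null", match.arg(families, rsa_families,
                                      several.ok = TRUE))
  fits <- lapply(families, function(f)
    fit_rsa_model(neural, trials, f, seed = seed, n_starts = n_starts))
  names(fits) <- families
  bic0 <- fits[["null"]]$BIC
  tab <- data.frame(
    family = families,
    k = vapply(fits, function(f) f$k, 0),
    rss = vapply(fits, function(f) f$rss, 0),
    BIC = vapply(fits, function(f) f$BIC, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    stringsAsFactors = FALSE)
  tab$delta_bic <- tab$BIC - bic0
  ok <- tab$converged
  winner <- tab$family[ok][which.min(tab$delta_bic[ok])]
  rownames(tab) <- NULL
  attr(tab, "winner") <- winner
  attr(tab, "fits") <- fits
  class(tab) <- c("rsa_comparison", "data.frame")
  tab
}

#' Group test of value-coefficient attenuation
#'
#' Tests whether the bundle-trial value coefficient (\eqn{b_1 + b_2}) is
#' lower than the single-item coefficient (\eqn{b_1}) across
#' subject-by-ROI cells, using a paired two-sided t test of the
#' coefficient difference against 0. A negative mean difference with a
#' small p-value is the attenuation signature predicted by divisive (and
#' range) normalization.
#'
#' @param fits either a list of \code{rsa_fit} objects from the
#'   full-normalization family, or a data.frame with columns
#'   \code{item_coef} and \code{bundle_coef} (one row per cell).
#' @return list: \code{t}, \code{p}, \code{mean_difference},
#'   \code{se}, \code{n}, \code{df}.
#' @export
test_coefficient_attenuation <- function(fits) {
  if (is.data.frame(fits)) {
    item <- fits$item_coef; bundle <- fits$bundle_coef
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "rsa_fit")))
    item <- vapply(fits, function(f) f$value_coef_item, 0)
    bundle <- vapply(fits, function(f) f$value_coef_bundle, 0)
  }
  if (anyNA(item) || anyNA(bundle) || length(item) != length(bundle))
    stop("unmatched or missing coefficient cells", call. = FALSE)
  d <- bundle - item
  n <- length(d)
  if (all(d == 0))
    return(list(t = 0, p = 1, mean_difference = 0, se = 0, n = n,
                df = n - 1))
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = mean(d), se = stats::sd(d) / sqrt(n),
       n = n, df = unname(tt$parameter))
}

#' Correlation between two DSMs over valid pairs
#'
#' Exploratory Pearson comparison of a neural and a model DSM over the
#' pairs valid in both (the model-fitting route in [fit_rsa_model()] is
#' the primary analysis; this is the conventional RSA summary statistic).
#'
#' @param dsm1,dsm2 \code{dsm} objects over the same trials.
#' @return Pearson correlation.
#' @export
dsm_correlation <- function(dsm1, dsm2) {
  stopifnot(inherits(dsm1, "dsm"), inherits(dsm2, "dsm"),
            dsm1$n == dsm2$n)
  keep <- dsm1$valid & dsm2$valid
  stats::cor(dsm1$d[keep], dsm2$d[keep])
}

#' Simulate a neural DSM from the predicted-DSM model
#'
#' Generates a synthetic neural DSM directly from the predicted-DSM
#' equation: normalized values per trial (given generator parameters),
#' their pairwise-difference value DSM, plus nuisance contributions and
#' i.i.d. Gaussian noise on each pair. Used to validate model-selection
#' and attenuation recovery.
#'
#' @param trials data.frame with \code{value}, \code{trial_kind},
#'   \code{button_side}, \code{day}.
#' @param norm_params generator parameters for
#'   [full_normalization_values()].
#' @param a length-3 vector of nuisance coefficients (a0, a1, a2).
#' @param noise_sd Gaussian noise s.d. per pair.
#' @param seed integer seed.
#' @return a \code{dsm} object.
#' @export
simulate_rsa_dsm <- function(trials, norm_params, a = c(1, 0.5, 0.5),
                             noise_sd = 0.1, seed = 1) {
  set.seed(as.integer(seed))
  tc <- as.numeric(trials$trial_kind == "bundle")
  vals <- full_normalization_values(trials$value, tc, norm_params)
  dv <- as.numeric(stats::dist(vals))
  bp <- binary_dsm_vec(trials$button_side)
  tt <- binary_dsm_vec(trials$trial_kind)
  d <- a[1] + a[2] * bp + a[3] * tt + dv +
    stats::rnorm(length(dv), 0, noise_sd)
  new_dsm(d, trials$day, metric = "model_generated")
}
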