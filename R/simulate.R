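#' Specification of a generative bundle-valuation process
#'
#' Bundles together everything needed to simulate willingness-to-pay data:
#' the bundle-value family and its fixed parameters, subject-level
#' random-effect standard deviations, residual noise, and the latent
#' item-value distribution. The latent item values default to a truncated
#' exponential on \eqn{[0, 20]} with mean $3.30, mimicking the right-skewed
#' bid distributions typical of consumer-item auctions.
#'
#' @param family bundle-value family: \code{"linear"}, \code{"power"},
#'   \code{"logarithmic"} or \code{"divnorm"}.
#' @param params named numeric vector of fixed-effect parameters for the
#'   family (defaults provided per family; see [bundle_family_value()]).
#' @param re_sd length-2 numeric: standard deviations of the subject-level
#'   random effects on the intercept (\code{b0}) and the leading scale
#'   coefficient (\code{b1}, applied to every leading slope of the family).
#' @param noise_sd residual Gaussian noise s.d. on bids (dollars).
#' @param value_mean mean of the latent item-value distribution (dollars).
#' @param bid_max upper end of the bid scale (budget; bids are censored to
#'   \code{[0, bid_max]}).
#' @return object of class \code{bundle_spec}.
#' @export
bundle_spec <- function(family = "linear",
                        params = default_family_params(family),
                        re_sd = c(0.3, 0.08),
                        noise_sd = 1,
                        value_mean = 3.3,
                        bid_max = 20) {
  family <- match.arg(family, bundle_families)
  need <- family_param_names(family)
  if (!all(need %in% names(params)))
    stop("family '", family, "' requires parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (family == "divnorm" && params[["sigma"]] <= 0)
    stop("divnorm family requires sigma > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(family = family, params = params[need],
                 re_sd = rep(re_sd, length.out = 2L),
                 noise_sd = noise_sd, value_mean = value_mean,
                 bid_max = bid_max),
            class = "bundle_spec")
}

#' @export
print.bundle_spec <- function(x, ...) {
  cat("Generative bundle-value spec —", x$family, "family\n")
  print(x$params)
  cat("random-effect sd (intercept, scale):", x$re_sd,
      "| residual sd:", x$noise_sd, "\n")
  invisible(x)
}

# Latent item values: exponential with the spec's mean, truncated to
# [0, bid_max] by inverse-CDF sampling.
draw_latent_values <- function(n, value_mean, bid_max) {
  rate <- 1 / value_mean
  u <- stats::runif(n) * stats::pexp(bid_max, rate)
  stats::qexp(u, rate)
}

censor_bid <- function(x, bid_max) pmin(pmax(x, 0), bid_max)

# Per-family application of the intercept / leading-scale random effects.
apply_random_effects <- function(family, params, u0, u1) {
  p <- params
  p[["b0"]] <- p[["b0"]] + u0
  lead <- switch(family,
    linear = c("b1", "b2"), power = c("b1", "b3"),
    logarithmic = c("b1", "b4"), divnorm = "b1")
  p[lead] <- p[lead] + u1
  p
}

#' Simulate a willingness-to-pay bid dataset
#'
#' Generates per-subject BDM-auction bids for every roster item and every
#' bundle on each experimental day. Each subject carries a latent
#' subjective value for each item (drawn once, constant across days); item
#' bids re-elicit that value each day with additive Gaussian noise, and
#' bundle bids are generated by applying the spec's bundle-value family to
#' the latent item values, plus subject random effects and noise. All bids
#' are censored to the \eqn{[0, 20]} budget.
#'
#' @param spec a [bundle_spec()].
#' @param catalog a [build_item_roster()] stimulus catalog.
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return data.frame of class \code{wtp_data}, one row per bid:
#'   \code{subject}, \code{day}, \code{trial_kind} (\code{item}/\code{bundle}),
#'   \code{left_item}, \code{right_item} (\code{NA} for items),
#'   \code{category} (item category or bundle type), \code{bid},
#'   \code{latent} (the pre-noise, pre-censoring generating value), and for
#'   bundle rows \code{vi}, \code{vj} — the same-day observed bids of the
#'   constituent items, the covariates used in model fitting.
#' @export
simulate_wtp <- function(spec, catalog, n_subjects = 14, seed = 1) {
  stopifnot(inherits(spec, "bundle_spec"), inherits(catalog, "stimulus_catalog"),
            n_subjects >= 1)
  set.seed(as.integer(seed))
  items <- catalog$items
  n_items <- nrow(items)
  out <- vector("list", 0L)
  for (s in seq_len(n_subjects)) {
    latent <- draw_latent_values(n_items, spec$value_mean, spec$bid_max)
    names(latent) <- as.character(items$item_id)
    u0 <- stats::rnorm(1, 0, spec$re_sd[1])
    u1 <- stats::rnorm(1, 0, spec$re_sd[2])
    pars_s <- apply_random_effects(spec$family, spec$params, u0, u1)
    for (d in seq_len(catalog$n_days)) {
      roster <- catalog$rosters[[d]]
      rcat <- items$category[match(roster, items$item_id)]
      lat_i <- latent[as.character(roster)]
      item_bid <- censor_bid(lat_i + stats::rnorm(length(roster), 0, spec$noise_sd),
                             spec$bid_max)
      item_df <- data.frame(
        subject = s, day = d, trial_kind = "item",
        left_item = roster, right_item = NA_integer_,
        category = rcat, bid = unname(item_bid), latent = unname(lat_i),
        vi = NA_real_, vj = NA_real_,
        vi_latent = NA_real_, vj_latent = NA_real_,
        cat_i = NA_character_, cat_j = NA_character_,
        stringsAsFactors = FALSE)
      bundles <- enumerate_bundles(roster, rcat)
      vi_lat <- latent[as.character(bundles$left_item)]
      vj_lat <- latent[as.character(bundles$right_item)]
      lat_b <- bundle_family_value(spec$family, pars_s, vi_lat, vj_lat)
      b_bid <- censor_bid(lat_b + stats::rnorm(nrow(bundles), 0, spec$noise_sd),
                          spec$bid_max)
      bundle_df <- data.frame(
        subject = s, day = d, trial_kind = "bundle",
        left_item = bundles$left_item, right_item = bundles$right_item,
        category = bundles$bundle_type, bid = unname(b_bid),
        latent = unname(lat_b),
        vi = unname(item_bid[as.character(bundles$left_item)]),
        vj = unname(item_bid[as.character(bundles$right_item)]),
        vi_latent = unname(vi_lat), vj_latent = unname(vj_lat),
        cat_i = rcat[match(bundles$left_item, roster)],
        cat_j = rcat[match(bundles$right_item, roster)],
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- item_df
      out[[length(out) + 1L]] <- bundle_df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("wtp_data", "data.frame")
  attr(res, "spec") <- spec
  res
}

#' Simulate the outcome of a BDM auction trial
#'
#' In the Becker–DeGroot–Marschak mechanism the bid is compared against a
#' uniformly random price on the bid scale; the bidder purchases (and pays
#' the drawn price) iff the bid is at least the price. Truthful bidding is
#' the surplus-maximizing strategy under this mechanism.
#'
#' @param bid numeric vector of bids in \eqn{[0, 20]}.
#' @param seed optional integer seed.
#' @param bid_max top of the price range (default 20).
#' @return data.frame with \code{bid}, \code{price} (the drawn price),
#'   \code{purchased} and \code{price_paid}.
#' @export
simulate_bdm <- function(bid, seed = NULL, bid_max = 20) {
  if (any(bid < 0 | bid > bid_max))
    stop("bid out of [0, ", bid_max, "]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  price <- stats::runif(length(bid), 0, bid_max)
  purchased <- bid >= price
  data.frame(bid = bid, price = price, purchased = purchased,
             price_paid = ifelse(purchased, price, 0))
}

#' Expected surplus of a BDM bid
#'
#' Closed-form expected surplus for a bidder whose true value is
#' \code{true_value} and who bids \code{bid}: the price is uniform on
#' \eqn{[0, bid\_max]} and surplus \eqn{(value - price)} accrues when the
#' bid meets the price. Maximized at \code{bid == true_value}, which is
#' the incentive-compatibility property of the auction.
#'
#' @param bid numeric vector of candidate bids.
#' @param true_value the bidder's true value.
#' @param bid_max top of the price range.
#' @return expected surplus per bid.
#' @export
bdm_expected_surplus <- function(bid, true_value, bid_max = 20) {
  # E[(v - P) 1{bid >= P}] with P ~ U(0, bid_max)
  (true_value * bid - bid^2 / 2) / bid_max
}

#' Simulate choices against the reference amount
#'
#' Softmax (logistic) choice between the presented stimulus and the trial's
#' reference monetary amount: the stimulus is chosen with probability
#' \eqn{\text{logit}^{-1}((bid - reference - bias)/\tau)}, where the bias
#' applies on single-item trials only (a configurable money bias) and
#' \eqn{\tau} is the choice temperature. Reaction times are drawn from a
#' log-normal and truncated at the response deadline.
#'
#' @param schedule a [build_trial_schedule()] schedule.
#' @param wtp the matching \code{wtp_data}.
#' @param temperature positive softmax temperature (dollars).
#' @param money_bias dollar bias toward the money option on item trials.
#' @param seed integer seed.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time parameters (seconds).
#' @param deadline response deadline in seconds.
#' @return the schedule with added columns \code{bid}, \code{p_stimulus},
#'   \code{chose_stimulus} and \code{rt}.
#' @export
simulate_choices <- function(schedule, wtp, temperature = 1, money_bias = 0,
                             seed = 1, rt_meanlog = 0.1, rt_sdlog = 0.35,
                             deadline = 5) {
  stopifnot(temperature > 0)
  set.seed(as.integer(seed))
  bid <- lookup_bids(schedule, wtp)
  drive <- bid - schedule$reference -
    money_bias * (schedule$trial_kind == "item")
  p <- stats::plogis(drive / temperature)
  out <- as.data.frame(schedule)
  out$bid <- bid
  out$p_stimulus <- p
  out$chose_stimulus <- stats::runif(nrow(out)) < p
  out$rt <- pmin(stats::rlnorm(nrow(out), rt_meanlog, rt_sdlog), deadline)
  out
}

#' Use latent item values as model covariates
#'
#' Replaces the observed item-bid covariates \code{vi}, \code{vj} of a
#' synthetic bid dataset with the latent generating item values. Fitting
#' against the latent covariates is the parameter-recovery protocol:
#' it targets the generative model directly, without the attenuation
#' that noisy item bids would induce in the slope estimates.
#'
#' @param wtp a synthetic \code{wtp_data} with latent columns.
#' @return the dataset with \code{vi}, \code{vj} replaced.
#' @export
with_latent_covariates <- function(wtp) {
  if (!all(c("vi_latent", "vj_latent") %in% names(wtp)))
    stop("dataset has no latent item values (real data?)", call. = FALSE)
  wtp$vi <- wtp$vi_latent
  wtp$vj <- wtp$vj_latent
  wtp
}

# Bid for the stimulus of each schedule row (same subject and day).
lookup_bids <- function(schedule, wtp) {
  key_w <- paste(wtp$subject, wtp$day, wtp$trial_kind,
                 wtp$left_item, ifelse(is.na(wtp$right_item), 0L, wtp$right_item))
  is_item <- schedule$trial_kind == "item"
  key_s <- paste(schedule$subject, schedule$day, schedule$trial_kind,
                 schedule$left_item,
                 ifelse(is_item, 0L, schedule$right_item))
  m <- match(key_s, key_w)
  if (anyNA(m))
    stop("no bid found for schedule row ", which(is.na(m))[1L], call. = FALSE)
  wtp$bid[m]
}
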