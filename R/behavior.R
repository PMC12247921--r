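#' Fit a bundle-value model to willingness-to-pay data
#'
#' Fits one of four families relating a bundle's bid to the bids of its
#' constituent items: a linear combination, a power function, a
#' logarithmic function, or a divisive-normalization function of the two
#' item values (see [bundle_family_value()] for the forms). Sub-additive
#' valuation appears as slopes below 1 (linear family) or as concavity
#' (the three nonlinear families).
#'
#' With \code{random_effects = TRUE} (and at least two subjects) a
#' mixed-effects model is estimated across subjects with subject-specific
#' random effects on the intercept and on the leading scale coefficient
#' (restricted ML via \code{lme4::lmer} for the linear family, ML via
#' \code{nlme::nlme} for the nonlinear families). A non-converging mixed
#' fit, or a single-subject dataset, falls back to a fixed-effects fit
#' with a warning and a flag on the returned object. Nonlinear
#' fixed-effects fits use a linear least-squares warm start and
#' multi-start (best log-likelihood retained); exponents are
#' box-constrained to (0, 5] and the normalization constant bounded below
#' at 1e-6.
#'
#' @param wtp a \code{wtp_data} data.frame ([simulate_wtp()]) or any
#'   data.frame with columns \code{subject}, \code{bid}, \code{vi},
#'   \code{vj} (and \code{trial_kind == "bundle"} rows if present).
#' @param family \code{"linear"}, \code{"power"}, \code{"logarithmic"} or
#'   \code{"divnorm"}.
#' @param random_effects estimate subject random effects where possible.
#' @param n_starts number of multi-start attempts for nonlinear fits.
#' @param seed seed for start-value jitter (fits are deterministic given
#'   data and seed).
#' @return object of class \code{bundle_fit} with components
#'   \code{coefficients} (fixed effects, family naming), \code{se},
#'   \code{logLik}, \code{BIC}, \code{r_squared}, \code{method}
#'   (\code{lmer}/\code{nlme}/\code{lm}/\code{nls}), \code{converged},
#'   \code{ranef} (per-subject random effects or NULL) and the underlying
#'   \code{fit} object. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{logLik}, \code{plot}.
#' @export
fit_bundle_model <- function(wtp, family = "linear", random_effects = TRUE,
                             n_starts = 5, seed = 1) {
  family <- match.arg(family, bundle_families)
  df <- bundle_frame(wtp)
  n_subj <- length(unique(df$subject))
  if (nrow(df) == 0L) stop("no bundle records to fit", call. = FALSE)

  if (random_effects && n_subj < 2) {
    warning("single subject: falling back to fixed-effects fit")
    random_effects <- FALSE
  }

  if (random_effects) {
    fit <- try(fit_mixed(df, family, n_starts, seed), silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit)
    warning("mixed-effects fit failed to converge for family '", family,
            "'; falling back to fixed effects (",
            conditionMessage(attr(fit, "condition")), ")")
    out <- fit_fixed(df, family, n_starts, seed)
    out$converged <- FALSE
    out$note <- "mixed-effects fit failed; fixed-effects fallback"
    return(out)
  }
  fit_fixed(df, family, n_starts, seed)
}

# Bundle rows with complete fitting covariates.
bundle_frame <- function(wtp) {
  df <- as.data.frame(wtp)
  if (!is.null(df$trial_kind)) df <- df[df$trial_kind == "bundle", , drop = FALSE]
  need <- c("subject", "bid", "vi", "vj")
  if (!all(need %in% names(df)))
    stop("fitting data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[stats::complete.cases(df[, need]), need, drop = FALSE]
  df$vsum <- df$vi + df$vj
  df
}

new_bundle_fit <- function(family, method, fit, coefs, se, df, converged,
                           ranef = NULL) {
  pred <- bundle_family_value(family, coefs, df$vi, df$vj)
  fitted_cond <- tryCatch(as.numeric(stats::fitted(fit)),
                          error = function(e) pred)
  r2 <- 1 - sum((df$bid - fitted_cond)^2) / sum((df$bid - mean(df$bid))^2)
  structure(list(
    family = family, method = method, fit = fit,
    coefficients = coefs, se = se,
    logLik = as.numeric(stats::logLik(fit)), BIC = stats::BIC(fit),
    r_squared = r2, converged = converged, ranef = ranef,
    n = nrow(df), n_subjects = length(unique(df$subject)),
    data = df), class = "bundle_fit")
}

linear_warm_start <- function(df, family) {
  ls <- stats::lm(bid ~ vi + vj, data = df)
  b <- unname(stats::coef(ls))
  slope <- mean(b[2:3])
  vbar <- mean(df$vsum)
  switch(family,
    linear = c(b0 = b[1], b1 = b[2], b2 = b[3]),
    power = c(b0 = b[1], b1 = max(b[2], 0.1), b2 = 1,
              b3 = max(b[3], 0.1), b4 = 1),
    logarithmic = c(b0 = b[1], b1 = max(b[2], 0.05) * (1 + mean(df$vi)),
                    b3 = 1, b4 = max(b[3], 0.05) * (1 + mean(df$vj)), b5 = 1),
    divnorm = c(b0 = b[1], b1 = max(4 * slope * vbar, 0.5),
                sigma = max(vbar, 1)))
}

family_bounds <- function(family) {
  switch(family,
    power = list(lower = c(-Inf, -Inf, 1e-3, -Inf, 1e-3),
                 upper = c(Inf, Inf, 5, Inf, 5)),
    logarithmic = list(lower = c(-Inf, -Inf, 1e-6, -Inf, 1e-6),
                       upper = rep(Inf, 5)),
    divnorm = list(lower = c(-Inf, -Inf, 1e-6), upper = rep(Inf, 3)),
    list(lower = NULL, upper = NULL))
}

family_formula <- function(family) {
  switch(family,
    power = bid ~ b0 + b1 * vi^b2 + b3 * vj^b4,
    logarithmic = bid ~ b0 + b1 * log(b3 + vi) + b4 * log(b5 + vj),
    divnorm = bid ~ b0 + b1 * (vi + vj) / (sigma + vi + vj))
}

# Divisive-normalization fixed-effects fit by profiling: conditional on
# sigma the model is linear in (b0, b1), so the profile RSS is minimized
# over log(sigma) by 1-d optimization. This stays well-behaved even when
# the data are (near-)linear, where the optimum runs along the
# sigma -> Inf ridge and full Gauss-Newton gradients turn singular.
fit_divnorm_profile <- function(df) {
  n <- nrow(df)
  rss_at <- function(logs) {
    r <- df$vsum / (exp(logs) + df$vsum)
    sum(stats::lm.fit(cbind(1, r), df$bid)$residuals^2)
  }
  opt <- stats::optimize(rss_at, c(log(1e-6), log(1e6)), tol = 1e-10)
  s <- exp(opt$minimum)
  r <- df$vsum / (s + df$vsum)
  lf <- stats::lm.fit(cbind(1, r), df$bid)
  co <- c(b0 = unname(lf$coefficients[1]), b1 = unname(lf$coefficients[2]),
          sigma = s)
  rss <- sum(lf$residuals^2)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  G <- cbind(1, r, -co[["b1"]] * df$vsum / (s + df$vsum)^2)
  se <- tryCatch(sqrt(diag(solve(crossprod(G))) * rss / (n - 3)),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(co)
  fit <- structure(list(coefficients = co, se = se,
                        fitted.values = unname(lf$fitted.values),
                        logLik_value = ll, nobs = n, npar = 3L),
                   class = "divnorm_profile_fit")
  new_bundle_fit("divnorm", "nls", fit, co, se, df,
                 converged = is.finite(rss))
}

#' @export
logLik.divnorm_profile_fit <- function(object, ...)
  structure(object$logLik_value, df = object$npar + 1L,
            nobs = object$nobs, class = "logLik")

fit_fixed <- function(df, family, n_starts = 5, seed = 1) {
  if (family == "linear") {
    fit <- stats::lm(bid ~ vi + vj, data = df)
    co <- stats::coef(fit)
    # a noiseless fit triggers a harmless precision warning in summary.lm
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    names(co) <- names(se) <- c("b0", "b1", "b2")
    return(new_bundle_fit(family, "lm", fit, co, se, df, converged = TRUE))
  }
  if (family == "divnorm") return(fit_divnorm_profile(df))
  start0 <- linear_warm_start(df, family)
  bounds <- family_bounds(family)
  form <- family_formula(family)
  set.seed(as.integer(seed))
  best <- NULL
  for (k in seq_len(n_starts)) {
    st <- if (k == 1L) start0 else {
      jit <- start0 * stats::runif(length(start0), 0.5, 1.8)
      pmin(pmax(jit, bounds$lower + 1e-3), bounds$upper - 1e-3)
    }
    names(st) <- names(start0)
    fit <- try(minpack.lm::nlsLM(form, data = df, start = as.list(st),
                                 lower = bounds$lower, upper = bounds$upper,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ll <- as.numeric(stats::logLik(fit))
    if (is.null(best) || ll > best$ll) best <- list(fit = fit, ll = ll)
  }
  if (is.null(best))
    stop("nonlinear least-squares fit failed for family '", family, "'",
         call. = FALSE)
  fit <- best$fit
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[names(co)]
  new_bundle_fit(family, "nls", fit, co, se, df, converged = TRUE)
}

fit_mixed <- function(df, family, n_starts = 5, seed = 1) {
  if (family == "linear") {
    fit <- suppressMessages(
      lme4::lmer(bid ~ vi + vj + (1 + vsum || subject), data = df,
                 REML = TRUE))
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    names(co) <- names(se) <- c("b0", "b1", "b2")
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    # a singular fit (zero variance component) is a boundary solution,
    # not a convergence failure
    conv <- fit@optinfo$conv$opt == 0 &&
      (is.null(msgs) || all(grepl("singular|boundary", msgs)))
    return(new_bundle_fit(family, "lmer", fit, co, se, df, converged = conv,
                          ranef = lme4::ranef(fit)$subject))
  }
  # nonlinear mixed fit, warm-started from the pooled fixed-effects fit
  warm <- fit_fixed(df, family, n_starts, seed)
  start <- stats::coef(warm)
  form <- family_formula(family)
  pn <- family_param_names(family)
  fixed_form <- stats::as.formula(paste(paste(pn, collapse = " + "), "~ 1"))
  lead <- if (family == "divnorm") "b1" else "b1"
  random_form <- stats::as.formula(paste("b0 +", lead, "~ 1"))
  fit <- nlme::nlme(form, data = df, fixed = fixed_form,
                    random = nlme::pdDiag(random_form),
                    groups = ~subject, start = unname(start),
                    control = nlme::nlmeControl(maxIter = 100,
                                                pnlsMaxIter = 12,
                                                msMaxIter = 100,
                                                returnObject = FALSE))
  co <- nlme::fixef(fit)
  names(co) <- pn
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- pn
  new_bundle_fit(family, "nlme", fit, co, se, df, converged = TRUE,
                 ranef = nlme::ranef(fit))
}

#' @export
print.bundle_fit <- function(x, digits = 4, ...) {
  cat("Bundle-value model fit —", x$family, "family (", x$method, ")\n")
  print(round(x$coefficients, digits))
  cat("logLik", round(x$logLik, 2), "| BIC", round(x$BIC, 1),
      "| R-squared", round(x$r_squared, 4),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' @export
summary.bundle_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, std.error = object$se)
  structure(list(family = object$family, method = object$method,
                 coefficients = tab, logLik = object$logLik,
                 BIC = object$BIC, r_squared = object$r_squared,
                 n = object$n, n_subjects = object$n_subjects,
                 converged = object$converged),
            class = "summary.bundle_fit")
}

#' @export
print.summary.bundle_fit <- function(x, digits = 4, ...) {
  cat("Bundle-value model:", x$family, "(", x$method, "),",
      x$n, "bundles,", x$n_subjects, "subject(s)\n")
  print(round(x$coefficients, digits))
  cat("logLik", round(x$logLik, 2), "| BIC", round(x$BIC, 1),
      "| R-squared", round(x$r_squared, 4), "\n")
  if (!x$converged) cat("warning: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.bundle_fit <- function(object, ...) object$coefficients

#' Predict bundle values from a fitted model
#'
#' Population-level (fixed effects only) predictions of bundle value at
#' new item-value pairs.
#'
#' @param object a \code{bundle_fit}.
#' @param newdata data.frame with columns \code{vi} and \code{vj}; when
#'   omitted, the fitting data are used.
#' @param ... unused.
#' @export
predict.bundle_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  bundle_family_value(object$family, object$coefficients,
                      newdata$vi, newdata$vj)
}

#' @export
fitted.bundle_fit <- function(object, ...) as.numeric(stats::fitted(object$fit))

#' @export
residuals.bundle_fit <- function(object, ...)
  object$data$bid - fitted.bundle_fit(object)

#' @export
logLik.bundle_fit <- function(object, ...) stats::logLik(object$fit)

#' @export
plot.bundle_fit <- function(x, ...) {
  df <- x$data
  graphics::plot(df$vsum, df$bid, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("grey40", 0.4),
                 xlab = "sum of item values ($)",
                 ylab = "bundle bid ($)",
                 main = paste("Bundle value:", x$family, "fit"), ...)
  graphics::abline(0, 1, lty = 3)
  cur <- evaluate_fit_curve(x, v_max = max(df$vsum) / 2)
  graphics::lines(cur$sum, cur$value, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Evaluate a fitted bundle-value curve on the standard grid
#'
#' Evaluates the fitted function with both item values set equal, for
#' common values from 0 to \code{v_max} in steps of \code{step} (default
#' 0–10 by 0.01, i.e. 1001 grid points). The returned \code{sum} column is
#' the summed item value (twice the common value), the natural x-axis for
#' plotting bundle value against the additive benchmark.
#'
#' @param fit a converged \code{bundle_fit}.
#' @param v_max top of the common-value grid (dollars).
#' @param step grid step (dollars).
#' @return data.frame with columns \code{v} (common item value),
#'   \code{sum} (= 2 v) and \code{value} (predicted bundle value).
#' @export
evaluate_fit_curve <- function(fit, v_max = 10, step = 0.01) {
  stopifnot(inherits(fit, "bundle_fit"))
  v <- seq(0, v_max, by = step)
  data.frame(v = v, sum = 2 * v,
             value = bundle_family_value(fit$family, fit$coefficients, v, v))
}

#' Compare bundle-value model families by BIC
#'
#' Fits each requested family and tabulates fit quality. Two BIC
#' aggregations are reported: \code{bic_sum}, the sum across participants
#' of per-subject fixed-effects fits (each subject fitted separately),
#' and — when \code{mixed = TRUE} — \code{bic_mixed} from a single
#' mixed-effects fit across subjects. \code{delta_bic} is relative to the
#' best (lowest) \code{bic_sum} among converged families; non-converged
#' families are flagged and excluded from the ranking.
#'
#' @param wtp bid data as in [fit_bundle_model()].
#' @param families character vector of families to compare.
#' @param mixed also fit the (slower) mixed-effects models.
#' @param n_starts multi-start attempts per nonlinear fit.
#' @param seed start-jitter seed.
#' @return data.frame of class \code{bundle_model_comparison}: one row per
#'   family with \code{k} (fixed-parameter count), \code{bic_sum},
#'   \code{delta_bic}, \code{r_squared}, optionally \code{bic_mixed} and
#'   \code{delta_bic_mixed}, and \code{converged}.
#' @export
compare_bundle_models <- function(wtp,
                                  families = c("linear", "power",
                                               "logarithmic", "divnorm"),
                                  mixed = TRUE, n_starts = 3, seed = 1) {
  stopifnot(length(families) >= 2)
  df <- bundle_frame(wtp)
  subs <- unique(df$subject)
  rows <- lapply(families, function(fam) {
    bic_s <- 0; rss <- 0; ok <- TRUE
    for (s in subs) {
      fs <- try(fit_fixed(df[df$subject == s, , drop = FALSE], fam,
                          n_starts, seed), silent = TRUE)
      if (inherits(fs, "try-error")) { ok <- FALSE; break }
      bic_s <- bic_s + fs$BIC
      rss <- rss + sum(residuals.bundle_fit(fs)^2)
    }
    r2 <- if (ok) 1 - rss / sum((df$bid - mean(df$bid))^2) else NA_real_
    out <- data.frame(family = fam, k = length(family_param_names(fam)),
                      bic_sum = if (ok) bic_s else NA_real_,
                      r_squared = r2, converged = ok,
                      stringsAsFactors = FALSE)
    if (mixed) {
      fm <- try(suppressWarnings(
        fit_bundle_model(df, fam, random_effects = TRUE,
                         n_starts = n_starts, seed = seed)), silent = TRUE)
      mix_ok <- !inherits(fm, "try-error") && fm$converged &&
        fm$method %in% c("lmer", "nlme")
      out$bic_mixed <- if (mix_ok) fm$BIC else NA_real_
      out$r_squared_mixed <- if (mix_ok) fm$r_squared else NA_real_
      out$converged_mixed <- mix_ok
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab$delta_bic <- tab$bic_sum - min(tab$bic_sum, na.rm = TRUE)
  if (mixed && any(tab$converged_mixed))
    tab$delta_bic_mixed <- tab$bic_mixed -
      min(tab$bic_mixed, na.rm = TRUE)
  class(tab) <- c("bundle_model_comparison", "data.frame")
  tab
}

#' Linear bundle-value fits stratified by bundle type
#'
#' Fits the linear family separately within each bundle type (food,
#' trinket, mixed, same-item). Same-item bundles have perfectly collinear
#' item values, so a symmetric fixed-effects model with a common slope on
#' the summed value is fitted there (slope reported per item value, i.e.
#' \code{b1 = b2}); same-item strata also use fixed effects only. For
#' mixed bundles the covariates are ordered so that \code{vi} is the food
#' item's value and \code{vj} the trinket's.
#'
#' @param wtp bid data including a \code{category} column with bundle types.
#' @param types bundle types to fit; defaults to those present. Requesting
#'   a type with no data is an error naming the stratum.
#' @param random_effects use subject random effects where estimable.
#' @return list of class \code{bundle_type_fits}: per-type
#'   \code{bundle_fit} objects plus a \code{slopes} data.frame
#'   (\code{b0}, \code{b1}, \code{b2} and their standard errors per type).
#' @export
fit_by_bundle_type <- function(wtp, types = NULL, random_effects = TRUE) {
  df <- as.data.frame(wtp)
  df <- df[df$trial_kind == "bundle", , drop = FALSE]
  present <- intersect(c("food", "trinket", "mixed", "same_item"),
                       unique(df$category))
  if (is.null(types)) types <- present
  missing <- setdiff(types, present)
  if (length(missing))
    stop("empty bundle-type stratum: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fits <- list()
  for (ty in types) {
    sub <- df[df$category == ty, , drop = FALSE]
    if (ty == "mixed" && all(c("cat_i", "cat_j") %in% names(sub))) {
      flip <- sub$cat_i != "food"
      tmp <- sub$vi[flip]; sub$vi[flip] <- sub$vj[flip]; sub$vj[flip] <- tmp
    }
    fr <- bundle_frame(sub)
    if (ty == "same_item") {
      fit <- stats::lm(bid ~ vsum, data = fr)
      co <- stats::coef(fit)
      se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
      coefs <- c(b0 = unname(co[1]), b1 = unname(co[2]), b2 = unname(co[2]))
      ses <- c(b0 = unname(se[1]), b1 = unname(se[2]), b2 = unname(se[2]))
      fits[[ty]] <- new_bundle_fit("linear", "lm", fit, coefs, ses, fr,
                                   converged = TRUE)
    } else {
      fits[[ty]] <- suppressWarnings(
        fit_bundle_model(fr, "linear",
                         random_effects = random_effects &&
                           length(unique(fr$subject)) >= 2))
    }
  }
  slopes <- do.call(rbind, lapply(names(fits), function(ty) {
    f <- fits[[ty]]
    data.frame(bundle_type = ty, b0 = f$coefficients[["b0"]],
               b1 = f$coefficients[["b1"]], b2 = f$coefficients[["b2"]],
               se_b1 = f$se[["b1"]], stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, slopes = slopes), class = "bundle_type_fits")
}

#' @export
print.bundle_type_fits <- function(x, digits = 3, ...) {
  cat("Linear bundle-value fits by bundle type\n")
  tab <- x$slopes
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
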