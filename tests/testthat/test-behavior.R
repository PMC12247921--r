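test_that("noiseless linear data are recovered exactly, matching the closed form", {
  w <- with_latent_covariates(noiseless_linear_wtp(n_subjects = 3))
  w <- w[!(w$trial_kind == "bundle" & w$bid >= 20), ]  # interior rows
  f <- fit_bundle_model(w, "linear", random_effects = FALSE)
  # independent closed-form least-squares oracle (normal equations)
  b <- w[w$trial_kind == "bundle", ]
  X <- cbind(1, b$vi, b$vj)
  beta_hat <- solve(crossprod(X), crossprod(X, b$bid))
  expect_equal(unname(coef(f)), drop(beta_hat), tolerance = 1e-8)
  expect_equal(unname(coef(f)), c(0.83, 0.73, 0.73), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("noiseless divisive-normalization data are recovered to 1e-4", {
  cat0 <- default_catalog()
  spec <- bundle_spec("divnorm", params = c(b0 = 0, b1 = 2, sigma = 4),
                      re_sd = c(0, 0), noise_sd = 0)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 2,
                                           seed = 6))
  f <- fit_bundle_model(w, "divnorm", random_effects = FALSE)
  expect_equal(unname(coef(f)), c(0, 2, 4), tolerance = 1e-4)
})

test_that("power exponents are near 1 on linear-generated data", {
  cat0 <- default_catalog()
  spec <- bundle_spec("linear", params = c(b0 = 0.83, b1 = 0.74, b2 = 0.63),
                      re_sd = c(0, 0), noise_sd = 0)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 2,
                                           seed = 8))
  w <- w[!(w$trial_kind == "bundle" & w$bid >= 20), ]
  f <- fit_bundle_model(w, "power", random_effects = FALSE)
  expect_equal(unname(coef(f)[c("b2", "b4")]), c(1, 1), tolerance = 1e-3)
})

test_that("mixed-effects linear fit recovers generating coefficients", {
  cat0 <- default_catalog()
  spec <- bundle_spec("linear", params = c(b0 = 0.83, b1 = 0.73, b2 = 0.73),
                      noise_sd = 1)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 8,
                                           seed = 21))
  f <- suppressWarnings(fit_bundle_model(w, "linear"))
  expect_equal(f$method, "lmer")
  expect_equal(unname(coef(f)), c(0.83, 0.73, 0.73), tolerance = 0.15)
  expect_equal(nrow(f$ranef), 8L)
})

test_that("single-subject data fall back to fixed effects with a warning", {
  w <- noiseless_linear_wtp(n_subjects = 1)
  expect_warning(f <- fit_bundle_model(w, "linear"), "single subject")
  expect_true(f$method %in% c("lm", "nls"))
})

test_that("model comparison is deterministic and ranks the generating family", {
  cat0 <- default_catalog()
  spec <- bundle_spec("divnorm", params = c(b0 = 0.3, b1 = 20, sigma = 8),
                      noise_sd = 1)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 6,
                                           seed = 31))
  t1 <- compare_bundle_models(w, mixed = FALSE, n_starts = 2, seed = 1)
  t2 <- compare_bundle_models(w, mixed = FALSE, n_starts = 2, seed = 1)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(t1$family[which.min(t1$bic_sum)], "divnorm")
  expect_equal(min(t1$delta_bic, na.rm = TRUE), 0)
})

test_that("linear mixed fit equals closed-form least squares when RE variance is zero", {
  # with zero generating random effects and no noise, lmer's fixed
  # effects coincide with the normal-equations solution
  w <- with_latent_covariates(noiseless_linear_wtp(n_subjects = 3))
  w <- w[!(w$trial_kind == "bundle" & w$bid >= 20), ]
  b <- w[w$trial_kind == "bundle", ]
  X <- cbind(1, b$vi, b$vj)
  beta_hat <- drop(solve(crossprod(X), crossprod(X, b$bid)))
  f <- suppressWarnings(fit_bundle_model(w, "linear", random_effects = TRUE))
  expect_equal(unname(coef(f)), beta_hat, tolerance = 1e-6)
})

test_that("stratified fits recover type-specific slope ordering", {
  # generate with type-specific slopes patterned on the reported
  # stratified estimates; check the recovered ordering matches
  cat0 <- default_catalog()
  gen <- list(same_item = 0.61, trinket = 0.65, mixed = 0.71, food = 0.755)
  w <- noiseless_linear_wtp(cat0, n_subjects = 3, seed = 41)
  b <- w$trial_kind == "bundle"
  slope <- unlist(gen)[w$category[b]]
  set.seed(41)
  w$bid[b] <- pmin(pmax(0.8 + slope * (w$vi_latent[b] + w$vj_latent[b]) +
                          rnorm(sum(b), 0, 0.4), 0), 20)
  w <- with_latent_covariates(w)
  ft <- suppressWarnings(fit_by_bundle_type(w))
  est <- setNames(ft$slopes$b1, ft$slopes$bundle_type)
  expect_equal(names(sort(est)), names(sort(unlist(gen))))
  expect_equal(ft$fits$same_item$method, "lm")  # fixed effects only
})

test_that("stratified fitting handles missing strata", {
  w <- noiseless_linear_wtp(tiny_catalog(), n_subjects = 2)
  w_same <- w[w$trial_kind == "item" | w$category == "same_item", ]
  ft <- fit_by_bundle_type(w_same)
  expect_equal(names(ft$fits), "same_item")
  expect_error(fit_by_bundle_type(w_same, types = c("same_item", "food")),
               "food")
})

test_that("pooled data with one common slope yield agreeing per-type slopes", {
  cat0 <- default_catalog()
  spec <- bundle_spec("linear", params = c(b0 = 0.5, b1 = 0.7, b2 = 0.7),
                      re_sd = c(0, 0), noise_sd = 0.3)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 3,
                                           seed = 51))
  ft <- suppressWarnings(fit_by_bundle_type(w))
  expect_lt(max(ft$slopes$b1) - min(ft$slopes$b1), 0.08)
})

test_that("fitted curves are evaluated on the standard grid", {
  w <- with_latent_covariates(noiseless_linear_wtp(n_subjects = 2))
  f <- fit_bundle_model(w, "linear", random_effects = FALSE)
  cur <- evaluate_fit_curve(f)
  expect_equal(nrow(cur), 1001L)
  expect_equal(range(cur$sum), c(0, 20))
  # additive identity case traces the identity line in the sum
  f_id <- f; f_id$coefficients <- c(b0 = 0, b1 = 1, b2 = 1)
  cur_id <- evaluate_fit_curve(f_id)
  expect_equal(cur_id$value, cur_id$sum)
})

test_that("divnorm curves are increasing and concave on the grid", {
  cat0 <- default_catalog()
  spec <- bundle_spec("divnorm", params = c(b0 = 0.3, b1 = 20, sigma = 8),
                      noise_sd = 1)
  w <- with_latent_covariates(simulate_wtp(spec, cat0, n_subjects = 4,
                                           seed = 61))
  f <- fit_bundle_model(w, "divnorm", random_effects = FALSE)
  cur <- evaluate_fit_curve(f)
  expect_true(all(diff(cur$value) > 0))
  expect_true(all(diff(diff(cur$value)) <= 1e-12))
})

test_that("bundle_fit methods behave coherently", {
  w <- with_latent_covariates(noiseless_linear_wtp(n_subjects = 2))
  f <- fit_bundle_model(w, "linear", random_effects = FALSE)
  expect_equal(predict(f, data.frame(vi = 3, vj = 4)),
               sum(coef(f) * c(1, 3, 4)))
  expect_equal(length(residuals(f)), f$n)
  expect_equal(unname(stats::BIC(f$fit)), f$BIC)
  s <- summary(f)
  expect_s3_class(s, "summary.bundle_fit")
  expect_output(print(f), "linear family")
})
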