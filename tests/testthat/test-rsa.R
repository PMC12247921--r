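test_that("neural DSMs are Euclidean distances with day masking", {
  # 3-4-5 triangle across days; identical patterns at distance zero
  X <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- compute_neural_dsm(X, day = c(1, 2, 3))
  expect_equal(d$d, c(5, 0, 5))
  expect_true(all(d$valid))
  # within-day pairs masked
  d2 <- compute_neural_dsm(X, day = c(1, 1, 2))
  expect_equal(d2$valid, c(FALSE, TRUE, TRUE))
  expect_error(compute_neural_dsm(X, day = c(1, 1, 1)), "share one day")
})

test_that("valid-pair counts match the combinatorial oracle", {
  # 3 days x 10 trials: 435 total pairs minus 3 * C(10,2) within-day
  set.seed(2)
  X <- matrix(rnorm(30 * 4), 30, 4)
  day <- rep(1:3, each = 10)
  d <- compute_neural_dsm(X, day)
  expect_equal(length(d$d), 435L)
  expect_equal(sum(d$valid), 435L - 3L * choose(10, 2))
  # brute-force day mask check
  brute <- sum(outer(day, day, "!=")[lower.tri(diag(30))])
  expect_equal(sum(d$valid), brute)
})

test_that("condensed distances match a brute-force oracle on 8 trials", {
  set.seed(3)
  X <- matrix(rnorm(8 * 5), 8, 5)
  d <- compute_neural_dsm(X, day = rep(1:2, each = 4))
  for (k in seq_along(d$d)) {
    expect_equal(d$d[k], sqrt(sum((X[d$i[k], ] - X[d$j[k], ])^2)),
                 tolerance = 1e-10)
  }
  # symmetry and zero self-distance are structural in condensed form:
  # the full matrix reconstructed from it must be symmetric with 0 diag
  M <- matrix(0, 8, 8)
  M[cbind(d$i, d$j)] <- d$d; M[cbind(d$j, d$i)] <- d$d
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
})

test_that("model DSMs implement the stated value transforms", {
  d_abs <- build_model_dsm(c(3, 5), c("item", "item"), "absolute")
  expect_equal(d_abs$d, 2)
  # subtractive: items {2,4}, bundles {6,8}; low-vs-low dissimilarity 0
  v <- c(2, 4, 6, 8); tt <- c("item", "item", "bundle", "bundle")
  d_sub <- build_model_dsm(v, tt, "subtractive")
  k <- which(d_sub$i == 3 & d_sub$j == 1)
  expect_equal(d_sub$d[k], 0)
  # zscore model DSM is invariant to affine rescaling of one condition
  set.seed(4)
  v2 <- runif(12, 0, 10); tt2 <- rep(c("item", "bundle"), 6)
  dz1 <- build_model_dsm(v2, tt2, "zscore")
  v3 <- v2; bundle <- tt2 == "bundle"
  v3[bundle] <- 3.7 * v3[bundle] + 2.2
  dz2 <- build_model_dsm(v3, tt2, "zscore")
  expect_equal(dz1$d, dz2$d, tolerance = 1e-10)
})

test_that("context-normalized values reduce to the documented special cases", {
  # degenerate parameters: pure absolute coding
  expect_equal(full_normalization_values(c(2, 5), c(0, 0),
                                         list(b1 = 3)), c(6, 15))
  # direct substitution with value-dependent denominator
  p <- list(b1 = 1, b2 = -0.5, sigma = 1, w_v = 1)
  expect_equal(full_normalization_values(4, 0, p), 0.8)
  expect_equal(full_normalization_values(4, 1, p), 0.4)
  # subtractive-like attenuation: b2 halves the bundle coefficient
  vals <- full_normalization_values(c(4, 4), c(0, 1),
                                    list(b1 = 1, b2 = -0.5))
  expect_equal(vals[2], vals[1] / 2)
  expect_error(full_normalization_values(4, 1,
                                         list(b1 = 1, w_1 = -2)),
               "denominator")
})

test_that("RSA fits recover generating parameters at zero noise", {
  tr <- rsa_trials(25)
  np <- list(b1 = 0.4, b2 = -0.2, sigma = 1)
  d0 <- simulate_rsa_dsm(tr, np, a = c(1, 0.5, 0.5), noise_sd = 0, seed = 1)
  f <- fit_rsa_model(d0, tr, "full_normalization", seed = 1)
  expect_equal(unname(f$params[c("a0", "a1", "a2")]), c(1, 0.5, 0.5),
               tolerance = 1e-3)
  expect_equal(unname(f$params[c("b1", "b2")]), c(0.4, -0.2),
               tolerance = 1e-3)
  expect_equal(f$value_coef_bundle / f$value_coef_item, 0.5,
               tolerance = 1e-2)
})

test_that("value coefficients stay near zero on pure-noise DSMs", {
  tr <- rsa_trials(20)
  coefs <- vapply(1:8, function(s) {
    set.seed(200 + s)
    d <- bundleval:::new_dsm(abs(rnorm(choose(nrow(tr), 2), 1, 0.3)),
                             tr$day)
    f <- fit_rsa_model(d, tr, "absolute")
    f$value_coef_item
  }, 0)
  expect_lt(abs(mean(coefs)), 3 * stats::sd(coefs) / sqrt(length(coefs)) + 0.02)
})

test_that("BIC penalizes value parameters that explain nothing", {
  tr <- rsa_trials(20)
  set.seed(77)
  d <- bundleval:::new_dsm(abs(rnorm(choose(nrow(tr), 2), 1, 0.3)), tr$day)
  f_null <- fit_rsa_model(d, tr, "null")
  f_abs <- fit_rsa_model(d, tr, "absolute")
  expect_gt(f_abs$BIC, f_null$BIC - 1e-9)
  # at (hypothetically) equal RSS one extra parameter costs log(n)
  n <- f_null$n_pairs
  expect_equal(f_abs$k - f_null$k, 1L)
})

test_that("model comparison recovers the generating family", {
  tr <- rsa_trials(25)
  # full normalization generator with attenuation
  d_fn <- simulate_rsa_dsm(tr, list(b1 = 0.4, b2 = -0.2, sigma = 1),
                           noise_sd = 0.3, seed = 11)
  cmp_fn <- compare_rsa_models(d_fn, tr, seed = 1, n_starts = 3)
  expect_equal(attr(cmp_fn, "winner"), "full_normalization")
  # absolute generator: b2 = 0, no context terms
  d_abs <- simulate_rsa_dsm(tr, list(b1 = 0.4, b2 = 0, sigma = 1),
                            noise_sd = 0.3, seed = 12)
  cmp_abs <- compare_rsa_models(d_abs, tr, seed = 1, n_starts = 3)
  tab <- as.data.frame(cmp_abs)
  best <- min(tab$delta_bic)
  # absolute within one complexity penalty of the best fit
  expect_lt(tab$delta_bic[tab$family == "absolute"] - best,
            log(sum(d_abs$valid)) * 4 + 1)
  # null generator: no value family beats the null model
  set.seed(13)
  d_null <- bundleval:::new_dsm(abs(rnorm(choose(nrow(tr), 2), 1, 0.3)),
                                tr$day)
  cmp_null <- compare_rsa_models(d_null, tr, seed = 1, n_starts = 3)
  expect_equal(attr(cmp_null, "winner"), "null")
  expect_true(all(as.data.frame(cmp_null)$delta_bic >= 0))
})

test_that("attenuation test conventions and degenerate cases", {
  cells <- data.frame(item_coef = rep(0.5, 6), bundle_coef = rep(0.5, 6))
  at0 <- test_coefficient_attenuation(cells)
  expect_equal(at0$p, 1)
  expect_equal(at0$mean_difference, 0)
  cells2 <- data.frame(item_coef = seq(0.5, 0.6, length.out = 8),
                       bundle_coef = seq(0.25, 0.3, length.out = 8))
  at2 <- test_coefficient_attenuation(cells2)
  expect_lt(at2$p, 0.01)
  expect_lt(at2$mean_difference, 0)
  expect_lt(at2$t, 0)
  expect_error(test_coefficient_attenuation(
    data.frame(item_coef = c(1, NA), bundle_coef = c(1, 1))), "unmatched")
})

test_that("dsm correlation compares valid pairs only", {
  tr <- rsa_trials(15)
  np <- list(b1 = 0.4, b2 = -0.2, sigma = 1)
  d1 <- simulate_rsa_dsm(tr, np, noise_sd = 0.05, seed = 21)
  m <- build_model_dsm(tr$value, tr$trial_kind, "absolute", day = tr$day)
  expect_gt(dsm_correlation(d1, m), 0.2)
  expect_equal(dsm_correlation(d1, d1), 1)
})
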