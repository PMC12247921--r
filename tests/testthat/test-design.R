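test_that("item roster reproduces the 3-day/40-item design", {
  cat3 <- build_item_roster(40, 10, 10, 3, seed = 1)
  expect_equal(lengths(cat3$rosters), rep(20L, 3))
  expect_equal(length(unique(unlist(cat3$rosters))), 40L)
  # every pairwise roster intersection is exactly the shared block
  for (a in 1:2) for (b in (a + 1):3) {
    expect_setequal(intersect(cat3$rosters[[a]], cat3$rosters[[b]]),
                    cat3$shared)
  }
  # category balance per day
  for (d in 1:3) {
    cats <- cat3$items$category[match(cat3$rosters[[d]], cat3$items$item_id)]
    expect_equal(sum(cats == "food"), 10L)
  }
})

test_that("degenerate and infeasible rosters are handled", {
  r1 <- build_item_roster(1, 1, 0, 1, seed = 0)
  expect_equal(r1$rosters[[1]], 1L)
  expect_error(build_item_roster(40, 10, 9, 3), "infeasible")
})

test_that("bundle enumeration counts match n(n-1)/2 + n", {
  ros20 <- seq_len(20)
  b20 <- enumerate_bundles(ros20, rep(c("food", "trinket"), 10))
  expect_equal(nrow(b20), 210L)
  expect_equal(sum(b20$bundle_type == "same_item"), 20L)
  expect_equal(nrow(enumerate_bundles(7L, "food")), 1L)
  expect_equal(nrow(enumerate_bundles(1:5, rep("food", 5))), 15L)
  # brute-force oracle for n <= 8: count unordered pairs incl. self-pairs
  for (n in 1:8) {
    brute <- sum(outer(1:n, 1:n, "<="))
    expect_equal(nrow(enumerate_bundles(seq_len(n), rep("food", n))), brute)
  }
  expect_error(enumerate_bundles(c(1, 1, 2), rep("food", 3)), "duplicate")
})

test_that("bundle types follow member categories with canonical ordering", {
  b <- enumerate_bundles(c(3, 1, 2), c("food", "food", "trinket"))
  expect_true(all(b$left_item <= b$right_item))
  expect_equal(b$bundle_type[b$left_item == 1 & b$right_item == 3], "food")
  expect_equal(b$bundle_type[b$left_item == 2 & b$right_item == 3], "mixed")
  expect_equal(b$bundle_type[b$left_item == 2 & b$right_item == 2],
               "same_item")
})

test_that("trial schedules satisfy the run and day constraints", {
  cat0 <- default_catalog()
  w <- noiseless_linear_wtp(cat0, n_subjects = 1)
  sch <- build_trial_schedule(cat0, w, seed = 3)
  expect_equal(nrow(sch), 930L)  # 3 days x 5 runs x 62 trials
  per_run <- table(paste(sch$day, sch$run))
  expect_true(all(per_run == 62L))
  # each item exactly once per run
  items <- sch[sch$trial_kind == "item", ]
  expect_true(all(table(items$day, items$run) == 20L))
  for (d in 1:3) {
    ir <- items[items$day == d, ]
    expect_true(all(table(ir$left_item, ir$run) == 1L))
  }
  # each bundle exactly once per day, 42 per run
  bnd <- sch[sch$trial_kind == "bundle", ]
  key <- paste(bnd$day, bnd$left_item, bnd$right_item)
  expect_true(all(table(key) == 1L))
  expect_true(all(table(bnd$day, bnd$run) == 42L))
  # item and bundle trials interleave within runs (not blocked)
  r1 <- sch[sch$day == 1 & sch$run == 1, ]
  runs_of_kind <- rle(r1$trial_kind)
  expect_gt(length(runs_of_kind$lengths), 10)
})

test_that("schedules are reproducible under a fixed seed", {
  cat0 <- tiny_catalog()
  w <- noiseless_linear_wtp(cat0, n_subjects = 2)
  s1 <- build_trial_schedule(cat0, w, seed = 11)
  s2 <- build_trial_schedule(cat0, w, seed = 11)
  expect_identical(s1, s2)
  s3 <- build_trial_schedule(cat0, w, seed = 12)
  expect_false(identical(s1, s3))
})

test_that("missing bids abort scheduling with the stimulus named", {
  cat0 <- tiny_catalog()
  w <- noiseless_linear_wtp(cat0, n_subjects = 1)
  w2 <- w[!(w$trial_kind == "item" & w$left_item == w$left_item[1] &
              w$day == 1), ]
  expect_error(build_trial_schedule(cat0, w2, seed = 1), "missing bid")
})

test_that("reference amounts are per-category medians", {
  w <- data.frame(subject = 1, day = 1,
                  trial_kind = c("item", "item", "item", "bundle"),
                  bid = c(1, 2, 3, 7))
  refs <- compute_reference_amounts(w, 1, 1)
  expect_equal(unname(refs["item"]), 2)
  expect_equal(unname(refs["bundle"]), 7)
  w4 <- data.frame(subject = 1, day = 1,
                   trial_kind = c(rep("item", 4), "bundle"),
                   bid = c(1, 2, 3, 4, 5))
  expect_equal(unname(compute_reference_amounts(w4, 1, 1)["item"]), 2.5)
  expect_error(compute_reference_amounts(w, 2, 1), "no bids")
})

test_that("BDM mechanics follow the auction rule and reject bad bids", {
  out <- simulate_bdm(c(10, 3), seed = 1)
  expect_equal(out$purchased, out$bid >= out$price)
  expect_equal(out$price_paid, ifelse(out$purchased, out$price, 0))
  expect_error(simulate_bdm(25), "out of")
  expect_error(simulate_bdm(-1), "out of")
})

test_that("truthful bidding maximizes expected surplus", {
  grid <- seq(0, 20, by = 0.1)
  # closed form peaks at the true value
  es <- bdm_expected_surplus(grid, true_value = 8)
  expect_equal(grid[which.max(es)], 8)
  # Monte-Carlo oracle agrees within one grid step
  set.seed(3)
  price <- runif(40000, 0, 20)
  mc <- vapply(seq(6, 10, by = 0.5), function(b)
    mean((8 - price) * (b >= price)), 0)
  expect_equal(seq(6, 10, by = 0.5)[which.max(mc)], 8, tolerance = 0.51)
})

test_that("bid generation respects the budget and the family formula", {
  cat0 <- tiny_catalog()
  spec <- bundle_spec("linear", params = c(b0 = 0, b1 = 1, b2 = 1),
                      re_sd = c(0, 0), noise_sd = 0)
  w <- simulate_wtp(spec, cat0, n_subjects = 3, seed = 9)
  expect_true(all(w$bid >= 0 & w$bid <= 20))
  # zero noise, interior values: bundle bid equals vi + vj exactly
  b <- w[w$trial_kind == "bundle" & w$latent < 20, ]
  expect_equal(b$bid, b$vi_latent + b$vj_latent, tolerance = 1e-12)
  # divnorm direct substitution: b0=0, b1=2, sigma=4, vi=vj=2 -> 1
  expect_equal(bundle_family_value("divnorm", c(b0 = 0, b1 = 2, sigma = 4),
                                   2, 2), 1)
  # censoring: latent above budget records a bid of 20
  spec_hi <- bundle_spec("linear", params = c(b0 = 20, b1 = 1, b2 = 1),
                         re_sd = c(0, 0), noise_sd = 0)
  w_hi <- simulate_wtp(spec_hi, cat0, n_subjects = 1, seed = 9)
  expect_true(all(w_hi$bid[w_hi$trial_kind == "bundle"] == 20))
  # bit-reproducible
  expect_identical(simulate_wtp(spec, cat0, 2, seed = 4),
                   simulate_wtp(spec, cat0, 2, seed = 4))
})

test_that("choice simulation follows the logistic rule", {
  cat0 <- tiny_catalog()
  w <- noiseless_linear_wtp(cat0, n_subjects = 1)
  sch <- build_trial_schedule(cat0, w, seed = 3)
  # near-zero temperature: dominant bids always chosen
  ch <- simulate_choices(sch, w, temperature = 1e-9, seed = 1)
  dominant <- abs(ch$bid - ch$reference) > 1e-6
  expect_equal(ch$chose_stimulus[dominant],
               (ch$bid > ch$reference)[dominant])
  # symmetric case: probability one-half at bid == reference
  ch2 <- simulate_choices(sch, w, temperature = 2, money_bias = 0, seed = 2)
  at_ref <- abs(ch2$bid - ch2$reference) < 1e-9
  expect_true(all(abs(ch2$p_stimulus[at_ref] - 0.5) < 1e-9))
  # with the median reference the stimulus is chosen about half the time
  cat40 <- default_catalog()
  w40 <- simulate_wtp(bundle_spec("linear"), cat40, n_subjects = 4, seed = 6)
  sch40 <- build_trial_schedule(cat40, w40, seed = 7)
  ch40 <- simulate_choices(sch40, w40, temperature = 1, seed = 8)
  expect_equal(mean(ch40$chose_stimulus), 0.5, tolerance = 0.05)
})

test_that("voxel patterns implement the linear coding construction", {
  sc <- coding_scheme("absolute", w_value = 0.7, noise_sd = 0, n_voxels = 30)
  sp <- subject_patterns(sc, catalog = tiny_catalog())
  pat <- sp$patterns
  m <- pat$meta
  # two same-type same-side trials: pattern difference norm = |w * dValue|
  idx <- which(m$trial_kind == "item" & m$button_side == "left")
  i1 <- idx[1]; i2 <- idx[2]
  dn <- sqrt(sum((pat$patterns[i1, ] - pat$patterns[i2, ])^2))
  expect_equal(dn, abs(0.7 * (m$value[i1] - m$value[i2])), tolerance = 1e-10)
  # full normalization with ratio 0.5: bundle responsiveness is half
  scf <- coding_scheme("full_normalization", attenuation_ratio = 0.5,
                       noise_sd = 0, n_voxels = 30)
  spf <- subject_patterns(scf, catalog = tiny_catalog())
  mf <- spf$patterns$meta
  expect_equal(mf$coded_value[mf$trial_kind == "bundle"],
               0.5 * mf$value[mf$trial_kind == "bundle"])
  expect_equal(mf$coded_value[mf$trial_kind == "item"],
               mf$value[mf$trial_kind == "item"])
  # null scheme: zero coded value
  scn <- coding_scheme("null", n_voxels = 16)
  spn <- subject_patterns(scn, catalog = tiny_catalog())
  expect_true(all(spn$patterns$meta$coded_value == 0))
})
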