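#' Z-score values within condition
#'
#' Standardizes a value vector separately within each condition (trial
#' type), using the population standard-deviation convention (divide by
#' \eqn{n}, not \eqn{n-1}), so that e.g. two item values \{2, 4\} map to
#' \{-1, +1\}. This is the target transform used by the cross-decoding
#' analysis: it places single-item and bundle values on a common scale
#' despite their different distributions.
#'
#' @param values numeric vector.
#' @param conditions condition labels, same length.
#' @return standardized vector (mean 0, population s.d. 1 per condition).
#' @export
zscore_by_condition <- function(values, conditions) {
  stopifnot(length(values) == length(conditions))
  out <- numeric(length(values))
  for (g in unique(conditions)) {
    i <- which(conditions == g)
    if (length(unique(values[i])) < 2)
      stop("condition '", g, "' has constant values: z-score undefined",
           call. = FALSE)
    m <- mean(values[i])
    s <- sqrt(mean((values[i] - m)^2))
    out[i] <- (values[i] - m) / s
  }
  out
}

# Closed-form ridge regression with an unpenalized intercept: predictors
# and target are centered on the training set, coefficients solve
# (X'X + alpha I) b = X'y.
ridge_train <- function(X, y, alpha) {
  stopifnot(alpha > 0)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  b <- solve(crossprod(Xc) + diag(alpha, ncol(X)), crossprod(Xc, y - ym))
  list(coef = drop(b), intercept = ym - drop(xm %*% b))
}

ridge_predict <- function(model, X) drop(X %*% model$coef) + model$intercept

#' Cross-condition value decoding with leave-one-run-out CV
#'
#' Trains a ridge-regression decoder (regularization \code{alpha},
#' default \eqn{10^3}) on the multivoxel patterns of one trial type from
#' all runs but one, and predicts the (condition z-scored) values of the
#' held-out run's trials — scored separately for each test trial type by
#' the Pearson correlation between predicted and true values. Repeating
#' over held-out runs and both training conditions yields the four
#' train/test splits (item→item, item→bundle, bundle→item,
#' bundle→bundle); high accuracy on the cross-condition splits indicates
#' a value code shared between single items and bundles.
#'
#' @param data a \code{voxel_patterns} dataset for one subject/ROI.
#' @param train_condition \code{"item"}, \code{"bundle"}, or (default)
#'   \code{"both"} to compute all four splits.
#' @param alpha ridge penalty (> 0).
#' @return data.frame of class \code{decoding_result}: one row per
#'   train/test split with \code{accuracy} (mean Pearson r across folds)
#'   and \code{n_folds}; per-fold correlations are kept in the
#'   \code{"folds"} attribute.
#' @export
cross_decode <- function(data, train_condition = c("both", "item", "bundle"),
                         alpha = 1e3) {
  stopifnot(inherits(data, "voxel_patterns"))
  train_condition <- match.arg(train_condition)
  conds <- c("item", "bundle")
  trains <- if (train_condition == "both") conds else train_condition
  meta <- data$meta
  run_id <- paste(meta$day, meta$run)
  runs <- unique(run_id)
  if (length(runs) < 2) stop("need >= 2 runs for cross-validation",
                             call. = FALSE)
  y <- zscore_by_condition(meta$value, meta$trial_kind)

  fold_rows <- list()
  for (tr in trains) {
    for (rn in runs) {
      hold <- run_id == rn
      tr_idx <- which(!hold & meta$trial_kind == tr)
      if (length(tr_idx) < 2) {
        warning("fold ", rn, ": fewer than 2 training trials; skipped")
        next
      }
      mod <- ridge_train(data$patterns[tr_idx, , drop = FALSE], y[tr_idx],
                         alpha)
      for (te in conds) {
        te_idx <- which(hold & meta$trial_kind == te)
        if (length(te_idx) < 2) {
          warning("fold ", rn, ", test condition ", te,
                  ": fewer than 2 test trials; skipped")
          next
        }
        pred <- ridge_predict(mod, data$patterns[te_idx, , drop = FALSE])
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          train = tr, test = te, fold = rn,
          r = stats::cor(pred, y[te_idx]), stringsAsFactors = FALSE)
      }
    }
  }
  folds <- do.call(rbind, fold_rows)
  agg <- stats::aggregate(r ~ train + test, data = folds, FUN = mean)
  nfold <- stats::aggregate(r ~ train + test, data = folds, FUN = length)
  out <- data.frame(train = agg$train, test = agg$test,
                    split = paste0(agg$train, "->", agg$test),
                    accuracy = agg$r, n_folds = nfold$r,
                    stringsAsFactors = FALSE)
  out <- out[order(out$train, out$test), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  class(out) <- c("decoding_result", "data.frame")
  out
}

#' Group-level tests of decoding accuracy
#'
#' For each ROI and train/test split, tests the per-subject decoding
#' accuracies against chance (r = 0) with a two-sided one-sample Wilcoxon
#' signed-rank test, Benjamini–Hochberg FDR-corrected across ROIs within
#' each split at rate \code{q}. Additionally, for each training condition
#' and ROI, the paired difference in accuracy between the two test
#' conditions is tested with a paired (signed-rank) test, likewise
#' FDR-corrected across ROIs. All-zero samples yield p = 1 by convention.
#'
#' @param results data.frame with columns \code{subject}, \code{roi},
#'   \code{train}, \code{test}, \code{accuracy} (one row per
#'   subject/ROI/split; stack [cross_decode()] outputs).
#' @param q FDR rate (default 0.05).
#' @return list with \code{splits} (per ROI/split: mean accuracy,
#'   Wilcoxon p, BH-adjusted p, significance at \code{q}) and
#'   \code{differences} (per ROI/training condition: test-condition
#'   difference statistics).
#' @export
group_decoding_tests <- function(results, q = 0.05) {
  need <- c("subject", "roi", "train", "test", "accuracy")
  stopifnot(all(need %in% names(results)))
  results$split <- paste0(results$train, "->", results$test)

  safe_wilcox <- function(x, y = NULL) {
    v <- if (is.null(y)) x else x - y
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0,
                                        alternative = "two.sided")$p.value)
  }

  cells <- unique(results[, c("roi", "split")])
  sp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$roi == cells$roi[i] &
                     results$split == cells$split[i], , drop = FALSE]
    data.frame(roi = cells$roi[i], split = cells$split[i],
               n = nrow(sub), mean_accuracy = mean(sub$accuracy),
               p = safe_wilcox(sub$accuracy), stringsAsFactors = FALSE)
  }))
  sp$p_fdr <- stats::ave(sp$p, sp$split,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  sp$significant <- sp$p_fdr < q

  # paired test-condition differences within each training condition
  wide_key <- c("subject", "roi", "train")
  diffs <- list()
  for (tr in unique(results$train)) {
    sub <- results[results$train == tr, , drop = FALSE]
    w <- stats::reshape(sub[, c(wide_key, "test", "accuracy")],
                        idvar = wide_key, timevar = "test",
                        direction = "wide")
    names(w) <- sub("^accuracy\\.", "", names(w))
    tests <- setdiff(names(w), wide_key)
    if (length(tests) != 2) next
    for (roi in unique(w$roi)) {
      ww <- w[w$roi == roi, , drop = FALSE]
      d <- ww[[tests[1]]] - ww[[tests[2]]]
      diffs[[length(diffs) + 1L]] <- data.frame(
        roi = roi, train = tr,
        comparison = paste(tests[1], "-", tests[2]),
        mean_difference = mean(d), p = safe_wilcox(d),
        stringsAsFactors = FALSE)
    }
  }
  dt <- if (length(diffs)) do.call(rbind, diffs) else NULL
  if (!is.null(dt)) {
    dt$p_fdr <- stats::ave(dt$p, dt$train,
                           FUN = function(p) stats::p.adjust(p, "BH"))
    dt$significant <- dt$p_fdr < q
  }
  list(splits = sp, differences = dt)
}

#' Compare value regressors voxel-wise
#'
#' A simplified ROI-level analogue of comparing univariate GLMs with
#' different value regressors: for each variant of the value regressor
#' (raw bid; bid z-scored by trial type; bid minus the trial's reference
#' amount), every voxel (and the ROI mean signal) is regressed on the
#' variant plus trial-type and button-side nuisances, and the summed
#' log-likelihood and mean R-squared across voxels are reported. The
#' best-fitting variant indicates whether the region's signal tracks
#' absolute, normalized, or reference-relative value.
#'
#' @param data a \code{voxel_patterns} dataset (metadata must include the
#'   \code{reference} column for the reference-relative variant).
#' @param variants subset of \code{"absolute"},
#'   \code{"zscore_by_condition"}, \code{"value_minus_reference"}.
#' @return data.frame, one row per variant: \code{logLik_sum},
#'   \code{mean_r_squared}, \code{roi_mean_r_squared}, plus a
#'   \code{collinear} flag when two variants are numerically
#'   indistinguishable.
#' @export
voxelwise_value_regression <- function(data,
    variants = c("absolute", "zscore_by_condition", "value_minus_reference")) {
  stopifnot(inherits(data, "voxel_patterns"))
  variants <- match.arg(variants, several.ok = TRUE)
  meta <- data$meta
  reg <- list(
    absolute = meta$value,
    zscore_by_condition = zscore_by_condition(meta$value, meta$trial_kind),
    value_minus_reference = meta$value - meta$reference)
  reg <- reg[variants]
  cors <- if (length(reg) > 1)
    stats::cor(do.call(cbind, reg)) else matrix(1)
  collinear <- any(abs(cors[upper.tri(cors)]) > 1 - 1e-8)
  if (collinear) warning("some value variants are collinear")

  tt <- as.numeric(meta$trial_kind == "bundle")
  side <- as.numeric(meta$button_side == "right")
  Y <- data$patterns
  roi_mean <- rowMeans(Y)
  out <- do.call(rbind, lapply(variants, function(v) {
    X <- cbind(1, reg[[v]], tt, side)
    qr_x <- qr(X)
    res <- qr.resid(qr_x, Y)
    rss <- colSums(res^2)
    n <- nrow(Y)
    ll <- sum(-n / 2 * (log(2 * pi) + log(rss / n) + 1))
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- 1 - rss / tss
    rm_res <- qr.resid(qr_x, roi_mean)
    rm_r2 <- 1 - sum(rm_res^2) / sum((roi_mean - mean(roi_mean))^2)
    data.frame(variant = v, logLik_sum = ll, mean_r_squared = mean(r2),
               roi_mean_r_squared = rm_r2, stringsAsFactors = FALSE)
  }))
  out$collinear <- collinear
  rownames(out) <- NULL
  out
}
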