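#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the simulate → behavior → decode → RSA →
#' report pipeline in one serializable object. A single global seed fans
#' out deterministically to per-stage child seeds (child = base seed +
#' 1000 × stage index, kept within integer range), so a config reproduces
#' a run bit-for-bit.
#'
#' @param seed integer master seed (required).
#' @param out_dir output directory for all artifacts.
#' @param n_subjects number of synthetic subjects.
#' @param design list of [build_item_roster()] arguments.
#' @param generative a [bundle_spec()] for the bid generator.
#' @param scheme a [coding_scheme()] for the pattern generator.
#' @param rois character vector of ROI labels to simulate/analyze.
#' @param decoding list with \code{alpha} and \code{q}.
#' @param rsa list with \code{families}, \code{trials_per_day} (trials
#'   subsampled per day for DSM construction) and \code{n_starts}.
#' @param behavior list with \code{families} and \code{mixed}.
#' @param stages which stages to run.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(seed, out_dir = tempfile("bundleval_run_"),
                       n_subjects = 14,
                       design = list(n_total = 40, n_shared = 10,
                                     n_new_per_day = 10, n_days = 3),
                       generative = bundle_spec("divnorm"),
                       scheme = coding_scheme("full_normalization",
                                              n_voxels = 200),
                       rois = c("vmPFC", "OFCmed", "dmPFC"),
                       decoding = list(alpha = 1e3, q = 0.05),
                       rsa = list(families = rsa_families,
                                  trials_per_day = 30, n_starts = 3),
                       behavior = list(families = bundle_families,
                                       mixed = FALSE),
                       stages = c("simulate", "behavior", "decode",
                                  "rsa", "report")) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("config validation: a finite integer 'seed' is required",
         call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_subjects = n_subjects, design = design,
                 generative = generative, scheme = scheme, rois = rois,
                 decoding = decoding, rsa = rsa, behavior = behavior,
                 stages = stages),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a \code{run_config}.
#' @param path JSON file path.
#' @return \code{read_run_config} returns the reconstructed
#'   \code{run_config}; the write/read round trip is exact.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$generative <- unclass(x$generative)
  x$generative$params <- as.list(x$generative$params)
  x$scheme <- unclass(x$scheme)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- x$generative
  spec <- bundle_spec(gen$family, params = unlist(gen$params),
                      re_sd = gen$re_sd, noise_sd = gen$noise_sd,
                      value_mean = gen$value_mean, bid_max = gen$bid_max)
  sch <- x$scheme
  scheme <- coding_scheme(sch$scheme, w_value = sch$w_value,
                          w_trial_type = sch$w_trial_type,
                          w_side = sch$w_side, noise_sd = sch$noise_sd,
                          n_voxels = sch$n_voxels,
                          attenuation_ratio = sch$attenuation_ratio,
                          geometry = sch$geometry,
                          norm_params = sch$norm_params)
  run_config(seed = x$seed, out_dir = x$out_dir,
             n_subjects = x$n_subjects, design = x$design,
             generative = spec, scheme = scheme, rois = x$rois,
             decoding = x$decoding, rsa = x$rsa, behavior = x$behavior,
             stages = x$stages)
}

stage_seed <- function(config, k) (config$seed + 1000L * k) %% 2147483647L

#' Load a dataset from delimited files with validation
#'
#' @param path CSV file (bids, schedules, choices) or directory holding
#'   \code{patterns.csv} and \code{meta.csv} for a pattern dataset.
#' @param kind one of \code{"wtp"}, \code{"schedule"}, \code{"choices"},
#'   \code{"patterns"}.
#' @return the typed dataset (\code{wtp_data}, \code{trial_schedule},
#'   plain data.frame, or \code{voxel_patterns}). Schema violations
#'   (bids outside [0, 20], unknown trial kinds, pattern/metadata row
#'   mismatches) raise errors naming the offending row.
#' @export
load_dataset <- function(path, kind = c("wtp", "schedule", "choices",
                                        "patterns")) {
  kind <- match.arg(kind)
  if (kind == "patterns") {
    pm <- file.path(path, "patterns.csv")
    mm <- file.path(path, "meta.csv")
    if (!file.exists(pm) || !file.exists(mm))
      stop("pattern dataset needs patterns.csv and meta.csv in ", path,
           call. = FALSE)
    X <- as.matrix(utils::read.csv(pm, header = FALSE))
    meta <- utils::read.csv(mm, stringsAsFactors = FALSE)
    if (nrow(X) != nrow(meta))
      stop("pattern matrix has ", nrow(X), " rows but metadata has ",
           nrow(meta), call. = FALSE)
    if (any(!is.finite(X)))
      stop("non-finite entries in pattern matrix", call. = FALSE)
    lab <- if (file.exists(file.path(path, "roi.json")))
      jsonlite::read_json(file.path(path, "roi.json"))$roi_label else "ROI"
    return(structure(list(patterns = unname(X), meta = meta,
                          roi_label = lab, scheme = NULL),
                     class = "voxel_patterns"))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (kind == "wtp") {
    bad <- which(df$bid < 0 | df$bid > 20)
    if (length(bad))
      stop("bid out of [0,20] at row ", bad[1L], call. = FALSE)
    bad_kind <- which(!df$trial_kind %in% c("item", "bundle"))
    if (length(bad_kind))
      stop("unknown trial_kind at row ", bad_kind[1L], call. = FALSE)
    class(df) <- c("wtp_data", "data.frame")
  } else if (kind == "schedule") {
    bad_kind <- which(!df$trial_kind %in% c("item", "bundle"))
    if (length(bad_kind))
      stop("unknown trial_kind at row ", bad_kind[1L], call. = FALSE)
    class(df) <- c("trial_schedule", "data.frame")
  }
  df
}

#' Write a dataset to delimited files
#'
#' Data frames are written as a single CSV; \code{voxel_patterns} as a
#' directory holding \code{patterns.csv} (matrix, no header),
#' \code{meta.csv} and \code{roi.json}.
#'
#' @param x dataset to write.
#' @param path target file (or directory for patterns).
#' @export
write_dataset <- function(x, path) {
  if (inherits(x, "voxel_patterns")) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(x$patterns, file.path(path, "patterns.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.csv(x$meta, file.path(path, "meta.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(roi_label = x$roi_label),
                         file.path(path, "roi.json"), auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — synthetic data generation,
#' behavioral model fitting/comparison, cross-condition decoding with
#' group tests, RSA model comparison with the attenuation test, and a
#' summary report — writing every intermediate artifact under the
#' config's output directory and returning a manifest (also written as
#' \code{manifest.json}) recording the config, per-stage outputs, file
#' hashes and timings. A stage failure aborts with the stage name;
#' artifacts of completed stages persist.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("bundleval")),
                   seed = config$seed, stages = list(), files = character())
  outputs <- new.env()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "completed", seconds = round(proc.time()[["elapsed"]] - t0, 2),
      files = res)
    manifest$files <<- c(manifest$files, res)
    invisible(res)
  }

  run_stage("simulate", function() {
    s <- stage_seed(config, 1L)
    catalog <- do.call(build_item_roster, c(config$design, list(seed = s)))
    wtp <- simulate_wtp(config$generative, catalog, config$n_subjects,
                        seed = s)
    schedule <- build_trial_schedule(catalog, wtp, seed = s)
    choices <- simulate_choices(schedule, wtp, seed = s)
    outputs$catalog <- catalog; outputs$wtp <- wtp
    outputs$schedule <- schedule
    f1 <- file.path(config$out_dir, "wtp_bids.csv")
    f2 <- file.path(config$out_dir, "trial_schedule.csv")
    f3 <- file.path(config$out_dir, "choices.csv")
    write_dataset(wtp, f1); write_dataset(schedule, f2)
    write_dataset(choices, f3)
    c(f1, f2, f3)
  })

  run_stage("behavior", function() {
    cmp <- compare_bundle_models(outputs$wtp,
                                 families = config$behavior$families,
                                 mixed = isTRUE(config$behavior$mixed),
                                 seed = stage_seed(config, 2L))
    by_type <- fit_by_bundle_type(outputs$wtp)
    best <- cmp$family[which.min(cmp$bic_sum)]
    curve <- evaluate_fit_curve(
      suppressWarnings(fit_bundle_model(outputs$wtp, best,
                                        random_effects = FALSE)))
    outputs$behavior <- cmp; outputs$by_type <- by_type
    f1 <- file.path(config$out_dir, "behavior_model_comparison.csv")
    f2 <- file.path(config$out_dir, "behavior_type_slopes.csv")
    f3 <- file.path(config$out_dir, "behavior_best_curve.csv")
    utils::write.csv(as.data.frame(cmp), f1, row.names = FALSE)
    utils::write.csv(by_type$slopes, f2, row.names = FALSE)
    utils::write.csv(curve, f3, row.names = FALSE)
    c(f1, f2, f3)
  })

  make_patterns <- function(subject, roi_idx, seed_off) {
    sched_s <- outputs$schedule[outputs$schedule$subject == subject, ,
                                drop = FALSE]
    simulate_voxel_patterns(sched_s, outputs$wtp, config$scheme,
                            seed = stage_seed(config, seed_off) +
                              subject * 131L + roi_idx,
                            roi_label = config$rois[roi_idx])
  }

  run_stage("decode", function() {
    rows <- list()
    for (ri in seq_along(config$rois)) {
      for (s in seq_len(config$n_subjects)) {
        pat <- make_patterns(s, ri, 3L)
        res <- cross_decode(pat, alpha = config$decoding$alpha)
        res$subject <- s; res$roi <- config$rois[ri]
        rows[[length(rows) + 1L]] <- as.data.frame(res)
      }
    }
    acc <- do.call(rbind, rows)
    tests <- group_decoding_tests(acc, q = config$decoding$q)
    outputs$decoding <- acc; outputs$decoding_tests <- tests
    f1 <- file.path(config$out_dir, "decoding_accuracies.csv")
    f2 <- file.path(config$out_dir, "decoding_group_tests.csv")
    utils::write.csv(acc, f1, row.names = FALSE)
    utils::write.csv(tests$splits, f2, row.names = FALSE)
    c(f1, f2)
  })

  run_stage("rsa", function() {
    tpd <- config$rsa$trials_per_day
    tabs <- list(); fn_fits <- list()
    for (ri in seq_along(config$rois)) {
      for (s in seq_len(config$n_subjects)) {
        pat <- make_patterns(s, ri, 4L)
        set.seed(stage_seed(config, 4L) + s * 977L + ri)
        keep <- unlist(lapply(split(seq_len(nrow(pat$meta)),
                                    pat$meta$day),
                              function(ix) sample(ix, min(tpd, length(ix)))))
        pat$patterns <- pat$patterns[keep, , drop = FALSE]
        pat$meta <- pat$meta[keep, , drop = FALSE]
        neural <- compute_neural_dsm(pat)
        cmp <- compare_rsa_models(neural, pat$meta,
                                  families = config$rsa$families,
                                  seed = stage_seed(config, 4L) + s,
                                  n_starts = config$rsa$n_starts)
        tab <- as.data.frame(cmp)
        tab$subject <- s; tab$roi <- config$rois[ri]
        tab$winner <- attr(cmp, "winner")
        tabs[[length(tabs) + 1L]] <- tab
        if ("full_normalization" %in% names(attr(cmp, "fits")))
          fn_fits[[length(fn_fits) + 1L]] <-
            attr(cmp, "fits")$full_normalization
      }
    }
    rsa_tab <- do.call(rbind, tabs)
    atten <- if (length(fn_fits) >= 5)
      test_coefficient_attenuation(fn_fits) else NULL
    outputs$rsa <- rsa_tab; outputs$attenuation <- atten
    f1 <- file.path(config$out_dir, "rsa_model_comparison.csv")
    utils::write.csv(rsa_tab, f1, row.names = FALSE)
    files <- f1
    if (!is.null(atten)) {
      f2 <- file.path(config$out_dir, "rsa_attenuation.json")
      jsonlite::write_json(atten, f2, auto_unbox = TRUE, digits = NA)
      files <- c(files, f2)
    }
    files
  })

  run_stage("report", function() {
    f <- file.path(config$out_dir, "report.md")
    writeLines(render_report(manifest, config$out_dir), f)
    f
  })

  manifest$file_md5 <- as.list(tools::md5sum(
    manifest$files[file.exists(manifest$files)]))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}

# Builds the summary report from artifacts on disk, so regeneration from
# the same manifest is byte-identical.
render_report <- function(manifest, out_dir) {
  lines <- c("# Bundle valuation pipeline report", "")
  section <- function(title, stage, body_fun) {
    st <- manifest$stages[[stage]]
    lines <<- c(lines, paste("##", title), "")
    if (is.null(st) || identical(st$status, "skipped")) {
      lines <<- c(lines, "_Stage skipped._", "")
    } else {
      lines <<- c(lines, body_fun(), "")
    }
  }
  read_if <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  section("Synthetic bids and design", "simulate", function() {
    w <- read_if("wtp_bids.csv")
    c(paste0("Bids: ", nrow(w), " rows; ",
             length(unique(w$subject)), " subjects; bid range [",
             round(min(w$bid), 2), ", ", round(max(w$bid), 2), "]."))
  })
  section("Bundle-value model comparison", "behavior", function() {
    md_table(read_if("behavior_model_comparison.csv"))
  })
  section("Cross-condition decoding", "decode", function() {
    md_table(read_if("decoding_group_tests.csv"))
  })
  section("RSA model comparison", "rsa", function() {
    tab <- read_if("rsa_model_comparison.csv")
    agg <- stats::aggregate(delta_bic ~ family + roi, data = tab, FUN = mean)
    md_table(agg)
  })
  section("Value-coefficient attenuation", "rsa", function() {
    p <- file.path(out_dir, "rsa_attenuation.json")
    if (!file.exists(p)) return("_No attenuation test (too few fits)._")
    a <- jsonlite::read_json(p, simplifyVector = TRUE)
    paste0("Paired bundle - item coefficient difference: ",
           signif(a$mean_difference, 4), " (t = ", signif(a$t, 4),
           ", p = ", signif(a$p, 4), ", n = ", a$n, ").")
  })
  lines
}
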