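#' Build the item roster for a multi-day valuation experiment
#'
#' Constructs the stimulus catalog for a design in which a fixed core of
#' items recurs on every day of testing while fresh items are introduced
#' each day. The default reproduces a 3-day design with 40 unique items:
#' 10 items shared across all days plus 10 new items per day, each day's
#' 20-item roster split evenly between food items and non-comestible
#' consumer goods ("trinkets").
#'
#' @param n_total total number of unique items across the experiment.
#' @param n_shared number of items appearing on every day.
#' @param n_new_per_day number of fresh items introduced each day.
#' @param n_days number of experimental days.
#' @param seed integer seed controlling the category assignment shuffle.
#' @return an object of class \code{stimulus_catalog}: a list with
#'   \code{items} (data.frame of \code{item_id}, \code{category}),
#'   \code{rosters} (list of per-day item-id vectors), \code{shared}
#'   (ids of the recurring items) and \code{n_days}.
#' @export
#' @examples
#' cat3 <- build_item_roster(40, 10, 10, 3, seed = 1)
#' lengths(cat3$rosters)  # 20 20 20
build_item_roster <- function(n_total = 40, n_shared = 10, n_new_per_day = 10,
                              n_days = 3, seed = 1) {
  if (n_total != n_shared + n_days * n_new_per_day)
    stop("infeasible design: n_total must equal n_shared + n_days * n_new_per_day",
         call. = FALSE)
  if (n_shared < 1 || n_days < 1 || n_new_per_day < 0)
    stop("infeasible design: counts must be positive", call. = FALSE)

  ids <- seq_len(n_total)
  shared <- ids[seq_len(n_shared)]
  new_blocks <- if (n_new_per_day > 0)
    split(ids[-seq_len(n_shared)],
          rep(seq_len(n_days), each = n_new_per_day))
  else rep(list(integer(0)), n_days)

  # Balanced category split within the shared block and within each day's
  # fresh block keeps every day's roster at half food / half trinket
  # whenever the block sizes are even; odd blocks are split as evenly as
  # possible. The seed shuffles which ids receive which category.
  set.seed(as.integer(seed))
  assign_cats <- function(block_ids) {
    k <- length(block_ids)
    if (k == 0L) return(character(0))
    cats <- rep(c("food", "trinket"), length.out = k)
    sample(cats)
  }
  category <- character(n_total)
  category[shared] <- assign_cats(shared)
  for (d in seq_len(n_days)) category[new_blocks[[d]]] <- assign_cats(new_blocks[[d]])

  rosters <- lapply(seq_len(n_days), function(d) sort(c(shared, new_blocks[[d]])))
  structure(list(
    items = data.frame(item_id = ids, category = category,
                       stringsAsFactors = FALSE),
    rosters = rosters,
    shared = shared,
    n_days = n_days
  ), class = "stimulus_catalog")
}

#' @export
print.stimulus_catalog <- function(x, ...) {
  cat("Stimulus catalog:", nrow(x$items), "unique items over", x$n_days,
      "day(s);", length(x$shared), "shared across days\n")
  cat("Per-day roster sizes:", paste(lengths(x$rosters), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all bundles over a day's roster
#'
#' Forms every unordered pair of roster items, including the pairing of an
#' item with itself, and labels each pair by bundle type. A roster of
#' \eqn{n} items yields \eqn{n(n-1)/2 + n} bundles (e.g. 210 for a 20-item
#' day: 190 distinct pairs plus 20 same-item pairs).
#'
#' @param items integer vector of item ids (unique), or a data.frame with
#'   columns \code{item_id} and \code{category}.
#' @param categories character vector of categories parallel to
#'   \code{items} (ignored when \code{items} is a data.frame).
#' @return data.frame with columns \code{left_item}, \code{right_item}
#'   (canonical order \code{left_item <= right_item}) and
#'   \code{bundle_type} in \code{food}, \code{trinket}, \code{mixed},
#'   \code{same_item}.
#' @export
enumerate_bundles <- function(items, categories = NULL) {
  if (is.data.frame(items)) {
    categories <- items$category
    items <- items$item_id
  }
  if (anyDuplicated(items))
    stop("duplicate item ids in roster", call. = FALSE)
  if (is.null(categories)) categories <- rep(NA_character_, length(items))
  ord <- order(items)
  items <- items[ord]; categories <- categories[ord]
  n <- length(items)
  idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  li <- items[idx[, 2L]]; ri <- items[idx[, 1L]]   # li <= ri
  lc <- categories[idx[, 2L]]; rc <- categories[idx[, 1L]]
  type <- ifelse(li == ri, "same_item",
          ifelse(!is.na(lc) & !is.na(rc) & lc == rc, lc, "mixed"))
  type[li != ri & (is.na(lc) | is.na(rc))] <- NA_character_
  out <- data.frame(left_item = li, right_item = ri, bundle_type = type,
                    stringsAsFactors = FALSE)
  out[order(out$left_item, out$right_item), , drop = FALSE]
}

#' Per-category reference amounts for the choice task
#'
#' The choice task pits each stimulus against a reference monetary amount
#' equal to the participant's median willingness-to-pay bid for that
#' stimulus category on that day (single items against the median item
#' bid, bundles against the median bundle bid), so that the stimulus is
#' chosen on roughly half of trials. Even-sized bid sets use the midpoint
#' of the two central order statistics.
#'
#' @param wtp a \code{wtp_data} data.frame (see [simulate_wtp()]).
#' @param subject subject id.
#' @param day day index.
#' @return named numeric vector \code{c(item = ..., bundle = ...)}.
#' @export
compute_reference_amounts <- function(wtp, subject, day) {
  rows <- wtp[wtp$subject == subject & wtp$day == day, , drop = FALSE]
  ib <- rows$bid[rows$trial_kind == "item"]
  bb <- rows$bid[rows$trial_kind == "bundle"]
  if (length(ib) == 0L || length(bb) == 0L)
    stop("no bids for subject ", subject, " on day ", day, call. = FALSE)
  c(item = stats::median(ib), bundle = stats::median(bb))
}

#' Build an interleaved item/bundle choice-task trial schedule
#'
#' Lays out the scanner choice task for every subject in a bid dataset:
#' on each day, each roster item appears once per run and the day's
#' bundles are partitioned evenly across the runs (42 per run in the
#' default 5-run design, giving 62 trials per run). Item and bundle
#' trials are randomly interleaved within a run, the stimulus side is
#' assigned at random, and each trial carries the subject's per-category
#' reference amount for that day.
#'
#' @param catalog a \code{stimulus_catalog}.
#' @param wtp a \code{wtp_data} data.frame covering every roster stimulus
#'   for each subject and day (bids are required to derive reference
#'   amounts; missing bids raise an error naming the stimulus).
#' @param n_runs runs per day (default 5).
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @return data.frame of class \code{trial_schedule}, one row per trial:
#'   \code{subject}, \code{day}, \code{run}, \code{trial}, \code{trial_kind}
#'   (\code{item}/\code{bundle}), \code{left_item}, \code{right_item},
#'   \code{item_side} (\code{left}/\code{right}), \code{reference}.
#' @export
build_trial_schedule <- function(catalog, wtp, n_runs = 5, seed = 1) {
  stopifnot(inherits(catalog, "stimulus_catalog"))
  set.seed(as.integer(seed))
  subjects <- sort(unique(wtp$subject))
  out <- vector("list", 0L)
  for (s in subjects) {
    for (d in seq_len(catalog$n_days)) {
      roster <- catalog$rosters[[d]]
      cats <- catalog$items$category[match(roster, catalog$items$item_id)]
      bundles <- enumerate_bundles(roster, cats)
      day_rows <- wtp[wtp$subject == s & wtp$day == d, , drop = FALSE]
      # every stimulus must have a bid
      item_ok <- roster %in% day_rows$left_item[day_rows$trial_kind == "item"]
      if (!all(item_ok))
        stop("missing bid for item ", roster[!item_ok][1L],
             " (subject ", s, ", day ", d, ")", call. = FALSE)
      bkey <- paste(bundles$left_item, bundles$right_item)
      have <- day_rows$trial_kind == "bundle"
      bhave <- paste(day_rows$left_item[have], day_rows$right_item[have])
      if (!all(bkey %in% bhave))
        stop("missing bid for bundle ", bkey[!(bkey %in% bhave)][1L],
             " (subject ", s, ", day ", d, ")", call. = FALSE)
      refs <- compute_reference_amounts(wtp, s, d)
      # random even partition of the day's bundles across runs
      nb <- nrow(bundles)
      alloc <- sample(rep(seq_len(n_runs), length.out = nb))
      for (r in seq_len(n_runs)) {
        b <- bundles[alloc == r, , drop = FALSE]
        df <- data.frame(
          subject = s, day = d, run = r,
          trial_kind = c(rep("item", length(roster)), rep("bundle", nrow(b))),
          left_item = c(roster, b$left_item),
          right_item = c(roster, b$right_item),
          stringsAsFactors = FALSE)
        df <- df[sample(nrow(df)), , drop = FALSE]  # interleave
        df$trial <- seq_len(nrow(df))
        df$item_side <- sample(c("left", "right"), nrow(df), replace = TRUE)
        df$reference <- unname(refs[ifelse(df$trial_kind == "item", "item", "bundle")])
        out[[length(out) + 1L]] <- df
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("subject", "day", "run", "trial", "trial_kind",
                 "left_item", "right_item", "item_side", "reference")]
  class(res) <- c("trial_schedule", "data.frame")
  res
}
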