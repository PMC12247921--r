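# Shared fixtures, built in code. Small designs keep unit tests fast;
# the acceptance suite builds the full-size design itself.

default_catalog <- function(seed = 1) build_item_roster(40, 10, 10, 3, seed)

# tiny 3-day design: 8 items, 4 per day (2 shared + 2 new)
tiny_catalog <- function(seed = 1) build_item_roster(8, 2, 2, 3, seed)

noiseless_linear_wtp <- function(catalog = default_catalog(),
                                 params = c(b0 = 0.83, b1 = 0.73, b2 = 0.73),
                                 n_subjects = 2, seed = 5) {
  spec <- bundle_spec("linear", params = params, re_sd = c(0, 0),
                      noise_sd = 0)
  simulate_wtp(spec, catalog, n_subjects = n_subjects, seed = seed)
}

# single-subject schedule + patterns under a scheme
subject_patterns <- function(scheme, seed = 4, catalog = default_catalog(),
                             wtp_seed = 2, schedule_seed = 3) {
  w <- simulate_wtp(bundle_spec("linear"), catalog, n_subjects = 1,
                    seed = wtp_seed)
  sch <- build_trial_schedule(catalog, w, seed = schedule_seed)
  list(patterns = simulate_voxel_patterns(sch, w, scheme, seed = seed),
       schedule = sch, wtp = w)
}

# trial metadata for RSA tests: subsample of a real schedule
rsa_trials <- function(n_per_day = 25, seed = 7, subject = 1) {
  cat0 <- default_catalog()
  w <- simulate_wtp(bundle_spec("linear"), cat0, n_subjects = subject,
                    seed = 2)
  sch <- build_trial_schedule(cat0, w, seed = 3)
  sch <- sch[sch$subject == subject, , drop = FALSE]
  ch <- simulate_choices(sch, w, seed = seed)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(sch)), sch$day),
                        function(ix) sample(ix, n_per_day)))
  data.frame(value = ch$bid[keep], trial_kind = sch$trial_kind[keep],
             button_side = sch$item_side[keep], day = sch$day[keep])
}
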