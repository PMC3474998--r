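test_that("event schedule balances the nine categories in 7.5-s blocks", {
  ev <- make_event_schedule(n_repeats = 40, seed = 1)
  expect_equal(nrow(ev), 360L)
  counts <- table(ev$morph_fraction)
  expect_true(all(counts == 40L))
  expect_equal(sort(unique(ev$morph_fraction)), sort(morph_levels()))
  expect_equal(unique(diff(ev$onset_s)), 7.5)
  ev1 <- make_event_schedule(n_repeats = 1, seed = 2)
  expect_equal(nrow(ev1), 9L)
  expect_identical(make_event_schedule(n_repeats = 5, seed = 7),
                   make_event_schedule(n_repeats = 5, seed = 7))
})

test_that("choice probabilities follow the logistic psychometric function", {
  # closed form: P(choose A | f) = plogis(slope * (f - 0.5))
  ev <- make_event_schedule(n_repeats = 2, seed = 1)
  ev <- ev[rep(seq_len(nrow(ev)), length.out = 10000), ]
  ev$morph_fraction <- 0.7
  ev$onset_s <- (seq_len(nrow(ev)) - 1) * 7.5
  beh <- simulate_behavior(ev, slope = 10, no_decision_rate = 0, seed = 42)
  p_hat <- mean(beh$choice == "A")
  p_true <- plogis(2.0)
  se <- sqrt(p_true * (1 - p_true) / nrow(beh))
  expect_lt(abs(p_hat - p_true), 3 * se)

  # symmetry at the midpoint
  ev$morph_fraction <- 0.5
  beh <- simulate_behavior(ev, slope = 10, no_decision_rate = 0, seed = 43)
  expect_lt(abs(mean(beh$choice == "A") - 0.5), 3 * sqrt(0.25 / nrow(beh)))

  # steep slope at an original scene approaches certainty
  ev$morph_fraction <- 1
  beh <- simulate_behavior(ev, slope = 500, no_decision_rate = 0, seed = 44)
  expect_true(all(beh$choice == "A"))
  expect_true(all(beh$correct))
})

test_that("confidence increases with evidence and correctness is defined only for originals", {
  ev <- make_event_schedule(n_repeats = 200, seed = 3)
  beh <- simulate_behavior(ev, seed = 8)
  conf_amb <- mean(beh$confidence[beh$morph_fraction == 0.5], na.rm = TRUE)
  conf_orig <- mean(beh$confidence[beh$morph_fraction %in% c(0, 1)], na.rm = TRUE)
  expect_gt(conf_orig, conf_amb)
  expect_true(all(is.na(beh$correct[!beh$morph_fraction %in% c(0, 1)])))
  bad <- ev
  bad$morph_fraction[1] <- 1.2
  expect_error(simulate_behavior(bad, seed = 1), "morph fractions")
})

test_that("trial-exclusion rules match the stated criteria and are idempotent", {
  toy <- data.frame(
    onset_s = (0:5) * 7.5,
    morph_fraction = rep(1, 6),
    choice = c("none", "B", "A", "A", "A", "A"),
    confidence = c(NA, 3L, 1L, 3L, 2L, 3L),
    correct = c(NA, FALSE, TRUE, TRUE, TRUE, TRUE),
    decision_made = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  kept <- filter_trials(toy, "original_scenes")
  expect_equal(nrow(kept), 3L)     # drops: no decision, incorrect, "not sure"
  expect_equal(attr(kept, "trial_index"), 4:6)
  twice <- filter_trials(kept, "original_scenes")
  expect_equal(twice[names(toy)], kept[names(toy)], ignore_attr = TRUE)
  expect_equal(attr(twice, "trial_index"), attr(kept, "trial_index"))

  all_good <- toy[4:6, ]
  expect_equal(nrow(filter_trials(all_good, "original_scenes")), 3L)
  expect_warning(filter_trials(toy, "morph50"), "no trials retained")
})

test_that("default behavioral model yields exclusion rates near the observed 9%/24%", {
  ev <- make_event_schedule(n_repeats = 1000, seed = 5)
  beh <- simulate_behavior(ev, seed = 6)
  orig <- beh[beh$morph_fraction %in% c(0, 1), ]
  amb <- beh[beh$morph_fraction == 0.5, ]
  excl_orig <- 1 - nrow(filter_trials(beh, "original_scenes")) / nrow(orig)
  excl_amb <- 1 - nrow(filter_trials(beh, "morph50")) / nrow(amb)
  expect_gt(excl_orig, 0.04); expect_lt(excl_orig, 0.15)
  expect_gt(excl_amb, 0.18); expect_lt(excl_amb, 0.31)
})

test_that("event tables round-trip through tab-delimited text", {
  ev <- simulate_behavior(make_event_schedule(n_repeats = 2, seed = 1), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path)
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$choice, ev$choice)
  expect_equal(back$confidence, ev$confidence)
})
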