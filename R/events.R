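#' Morph continuum used by the scene-decision task
#'
#' Nine stimulus categories expressed as the proportion of scene A in the
#' image: the two originals (1.0 and 0.0) and seven morphs.
#'
#' @return Numeric vector of the nine scene-A proportions.
#' @export
morph_levels <- function() {
  c(1.0, 0.7, 0.6, 0.55, 0.5, 0.45, 0.4, 0.3, 0.0)
}

#' Build a pseudo-random event schedule for one scanning run
#'
#' Each of the nine morph categories is presented `n_repeats` times in a
#' pseudo-random order with exactly balanced counts (so neither scene
#' dominates). Every trial occupies a fixed block: stimulus/decision window,
#' confidence window, then rest, after which the next trial starts.
#'
#' @param n_repeats Presentations per category (default 40, i.e. 360 trials).
#' @param stimulus_dur_s,confidence_dur_s,rest_dur_s Trial phase durations in
#'   seconds (defaults 2.5, 3, 2).
#' @param seed Integer seed for the trial-order permutation.
#' @return A data.frame event table with columns `onset_s`, `morph_fraction`,
#'   `choice`, `confidence`, `correct`, `decision_made` (behavioral columns
#'   `NA` until filled by [simulate_behavior()]).
#' @export
make_event_schedule <- function(n_repeats = 40L, stimulus_dur_s = 2.5,
                                confidence_dur_s = 3, rest_dur_s = 2,
                                seed = NULL) {
  stopifnot(n_repeats >= 1L, stimulus_dur_s > 0, confidence_dur_s >= 0,
            rest_dur_s >= 0)
  fractions <- rep(morph_levels(), each = n_repeats)
  ord <- with_seed(seed, sample.int(length(fractions)))
  block <- stimulus_dur_s + confidence_dur_s + rest_dur_s
  n <- length(fractions)
  ev <- data.frame(
    onset_s = (seq_len(n) - 1) * block,
    morph_fraction = fractions[ord],
    choice = rep(NA_character_, n),
    confidence = rep(NA_integer_, n),
    correct = rep(NA, n),
    decision_made = rep(NA, n),
    stringsAsFactors = FALSE
  )
  attr(ev, "stimulus_dur_s") <- stimulus_dur_s
  attr(ev, "block_dur_s") <- block
  ev
}

check_events <- function(events) {
  need <- c("onset_s", "morph_fraction", "choice", "confidence", "correct",
            "decision_made")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  if (any(diff(events$onset_s) <= 0)) stop("onsets must be strictly increasing")
  if (any(events$morph_fraction < 0 | events$morph_fraction > 1))
    stop("morph fractions must lie in [0, 1]")
  invisible(events)
}

#' Simulate choices and confidence ratings for an event schedule
#'
#' The probability of choosing scene A follows a logistic psychometric
#' function of the scene-A proportion, `P(A) = plogis(slope * (f - 0.5))`,
#' which yields the sigmoid accuracy profile characteristic of morph-decision
#' behavior. Confidence (1 = not sure, 2 = fairly sure, 3 = very sure) is
#' drawn from an ordinal model whose expected rating increases with stimulus
#' evidence `|f - 0.5|`; its intercepts default to values that reproduce
#' realistic "not sure" rates (roughly a fifth of fully ambiguous trials, a
#' few percent of unambiguous ones). A small fraction of trials is marked as
#' having no decision. Correctness is defined only for the two original
#' scenes (f = 0 or 1).
#'
#' @param events Event table from [make_event_schedule()].
#' @param slope Psychometric slope (> 0); default 10.
#' @param no_decision_rate Probability a trial ends without a decision
#'   (default 0.02).
#' @param conf_intercepts Length-2 numeric `c(q1, q3)`: logit intercepts of
#'   `P(conf = 1)` and `P(conf = 3)` at `|f - 0.5| = 0`.
#' @param conf_slope Evidence slope shared by the two confidence logits.
#' @param seed Integer seed.
#' @return The event table with `choice`, `confidence`, `correct` and
#'   `decision_made` filled in.
#' @export
simulate_behavior <- function(events, slope = 10, no_decision_rate = 0.02,
                              conf_intercepts = c(-1.27, -1.0),
                              conf_slope = 3.0, seed = NULL) {
  check_events(events)
  stopifnot(slope > 0, no_decision_rate >= 0, no_decision_rate < 1)
  with_seed(seed, {
    n <- nrow(events)
    f <- events$morph_fraction
    p_a <- plogis(slope * (f - 0.5))
    choice <- ifelse(runif(n) < p_a, "A", "B")
    decision_made <- runif(n) >= no_decision_rate
    choice[!decision_made] <- "none"
    d <- abs(f - 0.5)
    p1 <- plogis(conf_intercepts[1] - conf_slope * d)
    p3 <- plogis(conf_intercepts[2] + conf_slope * d)
    u <- runif(n)
    confidence <- ifelse(u < p1, 1L, ifelse(u < p1 + (1 - p1 - p3), 2L, 3L))
    confidence[!decision_made] <- NA_integer_
    correct <- rep(NA, n)
    orig <- f %in% c(0, 1) & decision_made
    correct[orig] <- (f[orig] == 1 & choice[orig] == "A") |
      (f[orig] == 0 & choice[orig] == "B")
    events$choice <- choice
    events$confidence <- confidence
    events$correct <- correct
    events$decision_made <- decision_made
    events
  })
}

#' Apply the MVPA trial-exclusion rules
#'
#' Two rule sets mirror the two families of analyses. For the original-scene
#' analyses (`"original_scenes"`): keep only trials showing an original scene
#' (f = 0 or 1) where a decision was made, the decision was correct, and
#' confidence was at least "fairly sure". For the fully ambiguous morphs
#' (`"morph50"`): keep only 50% morph trials with a decision and confidence
#' at least "fairly sure" — there is no correctness rule because the 50%
#' morph has no right answer. The filter is idempotent.
#'
#' @param events Event table with behavior columns filled.
#' @param analysis `"original_scenes"` or `"morph50"`.
#' @return Filtered event table (rows keep their original `onset_s`); an
#'   attribute `"trial_index"` records the retained row numbers.
#' @export
filter_trials <- function(events, analysis = c("original_scenes", "morph50")) {
  analysis <- match.arg(analysis)
  check_events(events)
  f <- events$morph_fraction
  keep <- switch(analysis,
    original_scenes = f %in% c(0, 1) & events$decision_made %in% TRUE &
      events$correct %in% TRUE & events$confidence >= 2L,
    morph50 = f == 0.5 & events$decision_made %in% TRUE &
      events$confidence >= 2L
  )
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    warning(sprintf("filter_trials('%s'): no trials retained", analysis))
  prev <- attr(events, "trial_index")
  out <- events[keep, , drop = FALSE]
  attr(out, "trial_index") <- if (is.null(prev)) which(keep) else prev[keep]
  attr(out, "stimulus_dur_s") <- attr(events, "stimulus_dur_s")
  out
}

#' Read / write a tab-delimited event table
#'
#' @param events Event table.
#' @param path File path.
#' @return `read_events_tsv` returns the event table; `write_events_tsv`
#'   returns `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  check_events(events)
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  check_events(ev)
  ev
}
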