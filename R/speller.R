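# Three-step four-target copy speller with UNDO, and the three-condition
# electrode-reduction study harness.

#' Three-step speller layout
#'
#' The interface shows four boxes: three carry letter groups and the fourth is
#' UNDO. A symbol is typed in three selections (group, subgroup, symbol). The
#' default layout splits the 27-symbol alphabet (A-Z plus underscore) into
#' three groups of nine, each into three triples, then singletons; any
#' alphabet whose size is a power of three works.
#'
#' @param alphabet Ordered character vector of symbols.
#' @param n_steps Selections per symbol.
#' @param undo_index Index of the UNDO target.
#' @return A list of class `"speller_layout"`.
#' @export
speller_layout <- function(alphabet = c(LETTERS, "_"), n_steps = 3L,
                           undo_index = 4L) {
  n_groups <- 3L
  if (length(alphabet) != n_groups^n_steps)
    stop(sprintf("alphabet must hold %d symbols for %d three-way steps",
                 n_groups^n_steps, n_steps))
  structure(list(alphabet = alphabet, n_steps = as.integer(n_steps),
                 n_groups = n_groups, undo_index = as.integer(undo_index)),
            class = "speller_layout")
}

#' Targets required to spell a word without errors
#'
#' Expands each symbol into its `n_steps` selections (group, subgroup,
#' symbol), i.e. the base-3 digits of the symbol's position in the alphabet.
#'
#' @param word Character string over the layout's alphabet.
#' @param layout A `"speller_layout"`.
#' @return Integer vector of planned targets (values in 1..3), of length
#'   `n_steps * nchar(word)`.
#' @export
plan_required_selections <- function(word, layout = speller_layout()) {
  stopifnot(inherits(layout, "speller_layout"))
  syms <- strsplit(word, "")[[1]]
  idx <- match(syms, layout$alphabet)
  if (anyNA(idx))
    stop(sprintf("symbol(s) not in the layout alphabet: %s",
                 paste(unique(syms[is.na(idx)]), collapse = " ")))
  if (length(idx) == 0) return(integer(0))
  unlist(lapply(idx - 1L, function(i) {
    digits <- integer(layout$n_steps)
    for (s in rev(seq_len(layout$n_steps))) {
      digits[s] <- i %% layout$n_groups
      i <- i %/% layout$n_groups
    }
    digits + 1L
  }))
}

#' Simulate copy-spelling one word
#'
#' Steps through the word's selection plan, producing each selection with the
#' online decoder. A wrong selection leaves the interface one step down a
#' wrong path, so UNDO becomes the required target until the error is
#' reverted; each additional wrong selection during recovery requires one more
#' UNDO. The run is abandoned after `max_consecutive_timeouts` timeouts in a
#' row or when the attempt budget is exhausted; a run with zero correct
#' selections (or an abandoned run) is non-functional.
#'
#' Accuracy is the share of correct selections among all issued selections,
#' corrections included in the tally: a recovery (the erroneous selection and
#' every UNDO it necessitates) adds to the denominator but not to the correct
#' count, so one error costs exactly two selections of accuracy. Timeouts
#' issue no selection. The information transfer rate uses active stimulation
#' time only (gaze-shift and cue pauses excluded).
#'
#' @param subject A `"subject_model"`.
#' @param word Word to copy-spell.
#' @param filters A `"cvep_filters"` trained on the subject's montage.
#' @param codes List of per-class `"sample_timeline"`s.
#' @param cfg A `"decoder_config"`.
#' @param layout A `"speller_layout"`.
#' @param noise_scale Noise multiplier.
#' @param max_consecutive_timeouts Abandon after this many timeouts in a row.
#' @param max_attempt_factor Attempt budget as a multiple of the plan length.
#' @param decoder Optional stub: a `function(target_class)` returning a
#'   `"selection_event"`; replaces the online decoder (used for protocol
#'   tests).
#' @return A list of class `"run_result"`: `word`, `events` (one row per
#'   attempt), `accuracy` (percent), `itr` (bits/min), `n_selections`,
#'   `active_seconds`, `functional`, `abandoned`.
#' @export
run_copy_spelling <- function(subject, word, filters, codes,
                              cfg = decoder_config(),
                              layout = speller_layout(), noise_scale = 1,
                              max_consecutive_timeouts = 3L,
                              max_attempt_factor = 5,
                              decoder = NULL) {
  plan <- plan_required_selections(word, layout)
  if (is.null(decoder))
    decoder <- function(target)
      run_selection(subject, target, filters, codes, cfg,
                    noise_scale = noise_scale)
  max_attempts <- ceiling(max_attempt_factor * max(length(plan), 1L))

  pos <- 1L
  pending_undo <- 0L
  consec_timeouts <- 0L
  abandoned <- FALSE
  rows <- list()
  while (pos <= length(plan)) {
    if (length(rows) >= max_attempts) {
      abandoned <- TRUE
      break
    }
    recovering <- pending_undo > 0L
    target <- if (recovering) layout$undo_index else plan[pos]
    ev <- decoder(target)
    # recovery selections are corrections: never counted as correct output
    rows[[length(rows) + 1L]] <-
      data.frame(target = target,
                 predicted = if (ev$timed_out) NA_integer_ else ev$predicted,
                 correct = !ev$timed_out && !recovering &&
                   ev$predicted == target,
                 recovery = recovering,
                 timed_out = ev$timed_out,
                 latency = ev$latency)
    if (ev$timed_out) {
      consec_timeouts <- consec_timeouts + 1L
      if (consec_timeouts >= max_consecutive_timeouts) {
        abandoned <- TRUE
        break
      }
      next
    }
    consec_timeouts <- 0L
    correct <- ev$predicted == target
    if (pending_undo > 0L) {
      pending_undo <- pending_undo + (if (correct) -1L else 1L)
    } else if (correct) {
      pos <- pos + 1L
    } else {
      pending_undo <- 1L
    }
  }
  events <- do.call(rbind, rows)
  if (is.null(events))
    events <- data.frame(target = integer(0), predicted = integer(0),
                         correct = logical(0), recovery = logical(0),
                         timed_out = logical(0), latency = numeric(0))
  n_sel <- sum(!events$timed_out)
  n_correct <- sum(events$correct)
  acc <- if (n_sel > 0) accuracy(events) else NA_real_
  active <- sum(events$latency)
  itr <- if (n_sel > 0 && active > 0)
    itr_bits_per_min(acc / 100, N = length(filters$filters),
                     selections = n_sel, active_seconds = active)
  else NA_real_
  structure(list(word = word, events = events, accuracy = acc, itr = itr,
                 n_selections = n_sel, active_seconds = active,
                 functional = !abandoned && n_correct > 0,
                 abandoned = abandoned),
            class = "run_result")
}

#' Run the three-condition electrode-reduction study on a synthetic cohort
#'
#' For every subject: (1) calibrate on the full 16-electrode montage and
#' copy-spell the task words (baseline); (2) restrict both the stream and the
#' already-trained filters to the six retained electrodes and spell again
#' (reduced, no retraining); (3) recalibrate natively on the six electrodes
#' and spell again (reduced, retrained). A round is stopped early when a word
#' run is abandoned; accuracy and ITR are pooled over the round's words and
#' reported only for functional rounds, mirroring the dashes of the published
#' subject table.
#'
#' @param cohort Data frame from [make_cohort()] (columns `subject_id`,
#'   `seed`, `focus`, `snr_db`).
#' @param words Words spelled in every round.
#' @param cfg A `"decoder_config"`.
#' @param layout A `"speller_layout"`.
#' @param base_code Base `"stimulus_code"`.
#' @param nb Training blocks per calibration.
#' @param ridge CCA ridge.
#' @param ... Passed on to [run_copy_spelling()].
#' @return A data frame with one row per subject × condition: `subject`,
#'   `condition` (`baseline16`, `reduced6_noretrain`, `reduced6_retrained`),
#'   `accuracy`, `itr` (both `NA` for non-functional rounds), `functional`.
#' @export
run_three_condition_study <- function(cohort, words = c("HAVE_FUN", "PROGRAM"),
                                      cfg = decoder_config(),
                                      layout = speller_layout(),
                                      base_code = generate_m_sequence(),
                                      nb = 6L, ridge = 1e-8, ...) {
  codes <- class_timelines(base_code, fs = cfg$fs, n_cycles = 2L)
  reduced <- montage_reduced6()
  out <- vector("list", nrow(cohort) * 3L)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    res <- with_seed(row$seed, {
      subj16 <- sample_subject(row$seed, focus_target = row$focus,
                               snr_db = row$snr_db, fs = cfg$fs)
      ts16 <- simulate_training_session(subj16, codes, nb = nb)
      f16 <- train_classifier(ts16, codes, ridge = ridge)

      subj6 <- restrict_channels(subj16, reduced)
      f6_stale <- restrict_channels(f16, reduced)

      ts6 <- simulate_training_session(subj6, codes, nb = nb)
      f6_new <- train_classifier(ts6, codes, ridge = ridge)

      list(
        baseline16 = spell_round(subj16, words, f16, codes, cfg, layout, ...),
        reduced6_noretrain = spell_round(subj6, words, f6_stale, codes, cfg,
                                         layout, ...),
        reduced6_retrained = spell_round(subj6, words, f6_new, codes, cfg,
                                         layout, ...))
    })
    for (j in seq_along(res)) {
      r <- res[[j]]
      out[[(i - 1L) * 3L + j]] <-
        data.frame(subject = row$subject_id, condition = names(res)[j],
                   accuracy = r$accuracy, itr = r$itr,
                   functional = r$functional)
    }
  }
  do.call(rbind, out)
}

# one experimental round: spell the words in order, stop early on abandonment,
# pool events across words
spell_round <- function(subject, words, filters, codes, cfg, layout, ...) {
  events <- list()
  abandoned <- FALSE
  for (w in words) {
    rr <- run_copy_spelling(subject, w, filters, codes, cfg, layout, ...)
    events[[length(events) + 1L]] <- rr$events
    if (rr$abandoned) {
      abandoned <- TRUE
      break
    }
  }
  ev <- do.call(rbind, events)
  n_sel <- sum(!ev$timed_out)
  n_correct <- sum(ev$correct)
  functional <- !abandoned && n_correct > 0
  acc <- if (functional && n_sel > 0) accuracy(ev) else NA_real_
  active <- sum(ev$latency)
  itr <- if (functional && n_sel > 0 && active > 0)
    itr_bits_per_min(acc / 100, N = length(filters$filters),
                     selections = n_sel, active_seconds = active)
  else NA_real_
  list(accuracy = acc, itr = itr, functional = functional,
       abandoned = abandoned, events = ev)
}
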