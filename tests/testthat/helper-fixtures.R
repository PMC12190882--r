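# Shared fixtures, built once per test run.

base_code <- generate_m_sequence()
codes2 <- class_timelines(base_code, fs = 600, n_cycles = 2)

# a near-impulse kernel: the evoked response then reproduces the ±1-coded
# timeline exactly, which is the regime where noiseless training rho -> 1
impulse_kernel <- c(1)

fixture_env <- new.env()

# calibrated default subject + filters, shared by decoder and speller tests
trained_fixture <- function() {
  if (is.null(fixture_env$filters)) {
    subj <- sample_subject(4242L, focus_target = 0.7, snr_db = 3)
    ts <- with_seed(1L, simulate_training_session(subj, codes2))
    fixture_env$subject <- subj
    fixture_env$filters <- train_classifier(ts, codes2)
  }
  list(subject = fixture_env$subject, filters = fixture_env$filters)
}

# fraction of runs whose selection was correct (timeouts count as failures)
selection_accuracy_rate <- function(subject, filters, n_runs, seed,
                                    cfg = decoder_config()) {
  with_seed(seed, {
    hits <- vapply(seq_len(n_runs), function(i) {
      target <- (i - 1L) %% 4L + 1L
      ev <- run_selection(subject, target, filters, codes2, cfg)
      isTRUE(ev$correct)
    }, logical(1))
    mean(hits)
  })
}

with_seed <- cvepsim:::with_seed
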