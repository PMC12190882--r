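# Online selection loop: block-wise buffering, per-class correlations against
# the circularly aligned code templates, the certainty margin, and the
# thresholded selection rule.

#' Decoder configuration
#'
#' @param beta Certainty-margin threshold: a selection is issued only when the
#'   gap between the largest and second-largest class correlation exceeds
#'   `beta` (strictly). Initialized at 0.15; the operating range hand-tuned in
#'   practice is about 0.10-0.30.
#' @param block_size Samples per buffered block (30 samples = 0.05 s at
#'   600 Hz).
#' @param fs Sampling rate, Hz.
#' @param min_eval_samples Minimum buffered samples before the first
#'   evaluation (default one full code cycle, 630 samples).
#' @param max_trial_seconds Stimulation timeout for a single selection.
#' @param gaze_shift_seconds Post-selection pause added to wall-clock time but
#'   not to stimulation latency.
#' @return A list of class `"decoder_config"`.
#' @export
decoder_config <- function(beta = 0.15, block_size = 30L, fs = 600,
                           min_eval_samples = 630L, max_trial_seconds = 10,
                           gaze_shift_seconds = 2) {
  if (beta <= 0) stop("beta must be positive")
  structure(list(beta = beta, block_size = as.integer(block_size), fs = fs,
                 min_eval_samples = as.integer(min_eval_samples),
                 max_trial_seconds = max_trial_seconds,
                 gaze_shift_seconds = gaze_shift_seconds),
            class = "decoder_config")
}

#' Create an empty decoder buffer state
#'
#' @param n_channels Channel count of the incoming stream.
#' @param capacity Buffer capacity in samples (default two code cycles).
#' @param cycle_samples Code cycle length in samples.
#' @return A list of class `"decoder_state"` with fields `buffer`, `n_y`
#'   (samples buffered), `code_phase` (0-based sample index into the code
#'   cycle at buffer start) and `elapsed` (seconds).
#' @export
new_decoder_state <- function(n_channels, capacity = 1260L,
                              cycle_samples = 630L) {
  structure(list(buffer = matrix(0, n_channels, capacity),
                 n_y = 0L, capacity = as.integer(capacity),
                 cycle_samples = as.integer(cycle_samples),
                 code_phase = 0L, elapsed = 0),
            class = "decoder_state")
}

#' Append one block of EEG to the decoder buffer
#'
#' Appends `block_size` samples; once the buffer is full it slides, dropping
#' the oldest block and advancing the code phase accordingly.
#'
#' @param state A `"decoder_state"`.
#' @param block Channels × `block_size` matrix.
#' @param cfg A `"decoder_config"`.
#' @return The updated state.
#' @export
push_block <- function(state, block, cfg = decoder_config()) {
  stopifnot(inherits(state, "decoder_state"))
  bs <- cfg$block_size
  if (!is.matrix(block) || nrow(block) != nrow(state$buffer) ||
      ncol(block) != bs)
    stop(sprintf("block must be a %d x %d matrix",
                 nrow(state$buffer), bs))
  if (state$n_y + bs > state$capacity) {
    keep <- state$capacity - bs
    state$buffer[, seq_len(keep)] <- state$buffer[, bs + seq_len(keep)]
    state$buffer[, keep + seq_len(bs)] <- block
    state$code_phase <- (state$code_phase + bs) %% state$cycle_samples
  } else {
    state$buffer[, state$n_y + seq_len(bs)] <- block
    state$n_y <- state$n_y + bs
  }
  state$elapsed <- state$elapsed + bs / cfg$fs
  state
}

#' Reset the decoder buffer (post-selection clear)
#'
#' @param state A `"decoder_state"`.
#' @return The cleared state (no samples buffered, code phase 0).
#' @export
reset_state <- function(state) {
  state$n_y <- 0L
  state$code_phase <- 0L
  state$elapsed <- 0
  state
}

# lambda for one class: correlation between the spatially filtered buffer and
# the template projection (identical template rows make w_y act as the scalar
# sum(w_y), so only its sign affects the Pearson correlation)
lambda_one <- function(px, seg, w_y_sum) {
  if (stats::sd(px) == 0 || stats::sd(seg) == 0) return(0)
  sign_y <- if (w_y_sum < 0) -1 else 1
  sign_y * stats::cor(px, seg)
}

#' Evaluate the class correlations of the current buffer
#'
#' For each class, the template segment is the length-`n_y` stretch of that
#' class's periodic code timeline starting at the buffer's code phase; the
#' class correlation is the Pearson correlation between the spatially
#' filtered buffer and the filtered template. The certainty margin is the gap
#' between the two largest correlations (0 under ties).
#'
#' @param state A `"decoder_state"` with at least `min_eval_samples` buffered.
#' @param filters A `"cvep_filters"`.
#' @param codes List of per-class `"sample_timeline"`s.
#' @param cfg A `"decoder_config"`.
#' @return List of class `"evaluation"`: `lambdas` (K correlations), `margin`,
#'   `best` (argmax class, ties broken toward the lowest index).
#' @export
evaluate_buffer <- function(state, filters, codes, cfg = decoder_config()) {
  stopifnot(inherits(state, "decoder_state"), inherits(filters, "cvep_filters"))
  if (state$n_y < cfg$min_eval_samples)
    stop(sprintf("buffer holds %d samples; %d required before evaluation",
                 state$n_y, cfg$min_eval_samples))
  n_y <- state$n_y
  buf <- state$buffer[, seq_len(n_y), drop = FALSE]
  lambdas <- vapply(seq_along(filters$filters), function(k) {
    f <- filters$filters[[k]]
    cyc <- codes[[k]]$values[seq_len(codes[[k]]$cycle_samples)]
    seg <- cyc[((state$code_phase + seq_len(n_y) - 1L) %%
                  length(cyc)) + 1L]
    px <- drop(crossprod(f$w_x, buf))
    lambda_one(px, seg, sum(f$w_y))
  }, numeric(1))
  sorted <- sort(lambdas, decreasing = TRUE)
  margin <- if (length(sorted) > 1) sorted[1] - sorted[2] else sorted[1]
  structure(list(lambdas = lambdas, margin = margin,
                 best = which.max(lambdas)),
            class = "evaluation")
}

#' Apply the selection rule to an evaluation
#'
#' @param ev An `"evaluation"`.
#' @param cfg A `"decoder_config"`.
#' @return The argmax class index if the certainty margin strictly exceeds
#'   `cfg$beta`, otherwise `NA`.
#' @export
maybe_select <- function(ev, cfg = decoder_config()) {
  if (ev$margin > cfg$beta) ev$best else NA_integer_
}

#' Decode a fixed recorded stream
#'
#' Replays a channels × samples recording through the online loop: blocks are
#' buffered, the class correlations are evaluated at every block boundary once
#' the minimum buffer fill is reached (templates truncated to the current
#' fill; after two code cycles the buffer slides), and the first strict
#' margin crossing issues the selection. The stream is assumed to start at
#' code phase 0.
#'
#' @param data Channels × samples matrix.
#' @param filters A `"cvep_filters"` with matching channel count.
#' @param codes List of per-class `"sample_timeline"`s.
#' @param cfg A `"decoder_config"`.
#' @param trace Keep the per-evaluation correlation trace.
#' @return List of class `"selection_event"`: `predicted` (class or `NA`),
#'   `latency` (seconds of stimulation consumed), `timed_out`, `margin`,
#'   `lambdas`, and (with `trace = TRUE`) a data frame `trace` with one row
#'   per evaluation.
#' @export
decode_stream <- function(data, filters, codes, cfg = decoder_config(),
                          trace = FALSE) {
  m <- nrow(data)
  if (m != length(filters$filters[[1]]$w_x))
    stop("channel count of the stream does not match the trained filters")
  K <- length(filters$filters)
  bs <- cfg$block_size
  cap <- filters$n_samples
  cyc_len <- codes[[1]]$cycle_samples
  n_total <- (ncol(data) %/% bs) * bs

  w_y_sign <- vapply(filters$filters,
                     function(f) if (sum(f$w_y) < 0) -1 else 1, numeric(1))
  px <- vapply(filters$filters,
               function(f) drop(crossprod(f$w_x, data[, seq_len(n_total),
                                                      drop = FALSE])),
               numeric(n_total))            # n_total x K
  tmpl <- vapply(codes, function(tl) {
    cyc <- tl$values[seq_len(tl$cycle_samples)]
    cyc[((seq_len(n_total) - 1L) %% cyc_len) + 1L]
  }, numeric(n_total))                      # n_total x K

  eval_pts <- seq(bs * ceiling(cfg$min_eval_samples / bs), n_total, by = bs)
  tr <- if (trace) vector("list", length(eval_pts)) else NULL
  for (j in seq_along(eval_pts)) {
    t_end <- eval_pts[j]
    w0 <- max(1L, t_end - cap + 1L)
    lambdas <- vapply(seq_len(K), function(k) {
      a <- px[w0:t_end, k]
      b <- tmpl[w0:t_end, k]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      w_y_sign[k] * stats::cor(a, b)
    }, numeric(1))
    sorted <- sort(lambdas, decreasing = TRUE)
    margin <- sorted[1] - sorted[2]
    if (trace)
      tr[[j]] <- c(time = t_end / cfg$fs, lambdas, margin = margin)
    if (margin > cfg$beta) {
      out <- structure(
        list(predicted = which.max(lambdas), latency = t_end / cfg$fs,
             timed_out = FALSE, margin = margin, lambdas = lambdas),
        class = "selection_event")
      if (trace) out$trace <- trace_frame(tr[seq_len(j)], K)
      return(out)
    }
  }
  out <- structure(
    list(predicted = NA_integer_, latency = n_total / cfg$fs,
         timed_out = TRUE, margin = NA_real_, lambdas = rep(NA_real_, K)),
    class = "selection_event")
  if (trace) out$trace <- trace_frame(tr, K)
  out
}

trace_frame <- function(rows, K) {
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("time", paste0("lambda", seq_len(K)), "margin")
  df
}

#' Run one closed-loop selection on a synthetic subject
#'
#' Streams a freshly simulated flicker response of the attended target through
#' [decode_stream()]. The stimulation stream starts at code phase 0 and runs
#' until the margin threshold is crossed or `max_trial_seconds` elapse; after
#' a selection the buffer is cleared and the gaze-shift pause contributes to
#' wall-clock time only.
#'
#' @param subject A `"subject_model"` recorded with the filters' montage.
#' @param target_class Attended class index.
#' @param filters A `"cvep_filters"`.
#' @param codes List of per-class `"sample_timeline"`s.
#' @param cfg A `"decoder_config"`.
#' @param noise_scale Noise multiplier (0 = noiseless).
#' @param trace Keep the per-evaluation trace.
#' @return A `"selection_event"` with additional fields `true_class`,
#'   `correct` and `wall_seconds` (latency plus the gaze-shift pause when a
#'   selection was issued).
#' @export
run_selection <- function(subject, target_class, filters, codes,
                          cfg = decoder_config(), noise_scale = 1,
                          trace = FALSE) {
  if (!identical(subject$montage$names, filters$montage$names))
    stop("montage of the subject stream does not match the trained filters")
  ep <- simulate_epoch(subject, codes[[target_class]],
                       duration = cfg$max_trial_seconds,
                       label = target_class, t0_code_phase = 0L,
                       noise_scale = noise_scale)
  ev <- decode_stream(ep$data, filters, codes, cfg, trace = trace)
  ev$true_class <- target_class
  ev$correct <- !ev$timed_out && ev$predicted == target_class
  ev$wall_seconds <- ev$latency +
    if (ev$timed_out) 0 else cfg$gaze_shift_seconds
  ev
}

#' @export
print.selection_event <- function(x, ...) {
  if (x$timed_out)
    cat(sprintf("<selection_event> timed out after %.2f s\n", x$latency))
  else
    cat(sprintf("<selection_event> class %d after %.2f s (margin %.3f)\n",
                x$predicted, x$latency, x$margin))
  invisible(x)
}
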