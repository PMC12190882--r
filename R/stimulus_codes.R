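#' Generate a maximal-length binary sequence (m-sequence)
#'
#' Runs a Fibonacci linear-feedback shift register (LFSR) and returns one full
#' period of its output. For a register of length \eqn{r} with a primitive
#' feedback polynomial the period is \eqn{2^r - 1}; the default degree-6
#' register (feedback \eqn{x^6 + x^5 + 1}) produces the 63-bit sequence used
#' to drive the flicker of all speller targets, with one bit displayed per
#' 4 frames of a 240 Hz monitor (60 bits/s, 1.05 s per cycle).
#'
#' @param register_length Number of register stages \eqn{r} (\eqn{\ge 2}).
#' @param taps Integer indices (in `1:register_length`) of the stages XOR-ed
#'   into the feedback bit. Must correspond to a primitive polynomial for a
#'   maximal-length sequence; non-primitive taps raise an error naming the
#'   achieved period.
#' @param initial_state 0/1 vector of length `register_length`, not all zero.
#' @param bit_rate Presentation rate of the code in bits per second.
#' @param shift_step Circular shift, in bits, separating consecutive class
#'   codes (see [class_code()]).
#' @param K Number of stimulus classes derivable from this base code.
#'
#' @return An object of class `"stimulus_code"`: a list with elements `bits`
#'   (0/1 integer vector), `bit_rate`, `class_index` (1 for the base code),
#'   `shift_step`, `K`, `register_length` and `taps`.
#'
#' @examples
#' code <- generate_m_sequence()
#' length(code$bits)  # 63
#' sum(code$bits)     # 32 ones, 31 zeros
#' @export
generate_m_sequence <- function(register_length = 6L,
                                taps = c(6L, 5L),
                                initial_state = rep(1L, register_length),
                                bit_rate = 60,
                                shift_step = 4L,
                                K = 4L) {
  register_length <- as.integer(register_length)
  if (register_length < 2L)
    stop("register_length must be >= 2")
  taps <- as.integer(taps)
  if (length(taps) < 1L || any(taps < 1L | taps > register_length))
    stop("taps must be indices in 1:register_length")
  state <- as.integer(initial_state)
  if (length(state) != register_length || !all(state %in% c(0L, 1L)))
    stop("initial_state must be a 0/1 vector of length register_length")
  if (all(state == 0L))
    stop("initial_state must not be all zeros (the LFSR would be stuck)")

  period_max <- 2L^register_length - 1L
  start <- state
  bits <- integer(period_max)
  period <- NA_integer_
  for (i in seq_len(period_max)) {
    bits[i] <- state[register_length]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-register_length])
    if (identical(state, start) && i < period_max) {
      period <- i
      break
    }
  }
  if (!is.na(period))
    stop(sprintf(paste0("taps do not define a primitive feedback polynomial: ",
                        "achieved period %d < %d"), period, period_max))
  if (!identical(state, start))
    stop(sprintf("LFSR state did not return to its start after %d steps",
                 period_max))

  structure(
    list(bits = bits,
         bit_rate = bit_rate,
         class_index = 1L,
         shift_step = as.integer(shift_step),
         K = as.integer(K),
         register_length = register_length,
         taps = taps),
    class = "stimulus_code")
}

#' Derive the stimulus code of a target class by circular shifting
#'
#' Class codes are time-shifted copies of one base m-sequence: class \eqn{k}
#' uses the base code circularly shifted by \eqn{(k-1)\cdot}`shift_step` bits.
#' A positive shift rotates bits toward later positions (bit \eqn{i} moves to
#' position \eqn{i + s \bmod L}), so class 2's code is the base code delayed
#' by 4 bits at the default step.
#'
#' @param base A `"stimulus_code"` (normally the base code, `class_index` 1).
#' @param k Target class index in `1:base$K`.
#' @param shift_step Shift between consecutive classes, in bits.
#' @return A `"stimulus_code"` for class `k`.
#' @examples
#' base <- generate_m_sequence()
#' c2 <- class_code(base, 2)         # base delayed by 4 bits
#' @export
class_code <- function(base, k, shift_step = base$shift_step) {
  stopifnot(inherits(base, "stimulus_code"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > base$K)
    stop(sprintf("class index k must be in 1..%d", base$K))
  out <- base
  out$bits <- rotate_bits(base$bits, (k - 1L) * as.integer(shift_step))
  out$class_index <- k
  out$shift_step <- as.integer(shift_step)
  out
}

# rotate toward later positions: element i moves to i + shift (mod n)
rotate_bits <- function(bits, shift) {
  n <- length(bits)
  shift <- ((shift %% n) + n) %% n
  if (shift == 0) return(bits)
  bits[((seq_len(n) - 1L - shift) %% n) + 1L]
}

#' Expand a stimulus code into a sample-rate timeline
#'
#' Replicates each code bit over `fs / bit_rate` consecutive samples and tiles
#' the resulting cycle `n_cycles` times, producing the piecewise-constant 0/1
#' luminance timeline seen by the decoder. At the defaults (63 bits at
#' 60 bits/s, 600 Hz, 2 cycles) this is the 1260-sample trial timeline.
#'
#' @param code A `"stimulus_code"`.
#' @param fs Sampling rate in Hz; must be an integer multiple of
#'   `code$bit_rate` (no resampling is performed).
#' @param n_cycles Number of complete code cycles.
#' @return An object of class `"sample_timeline"`: list with `values`
#'   (0/1 vector), `fs`, `n_cycles`, `cycle_samples`, `cycle_duration`
#'   (seconds), `bit_rate` and `class_index`.
#' @examples
#' tl <- code_to_timeline(generate_m_sequence(), fs = 600, n_cycles = 2)
#' length(tl$values)  # 1260
#' @export
code_to_timeline <- function(code, fs = 600, n_cycles = 2L) {
  stopifnot(inherits(code, "stimulus_code"))
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  ratio <- fs / code$bit_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("fs (%g Hz) must be an integer multiple of the bit rate (%g bits/s)",
                 fs, code$bit_rate))
  ratio <- as.integer(round(ratio))
  cycle <- rep(code$bits, each = ratio)
  structure(
    list(values = rep.int(cycle, n_cycles),
         fs = fs,
         n_cycles = as.integer(n_cycles),
         cycle_samples = length(cycle),
         cycle_duration = length(code$bits) / code$bit_rate,
         bit_rate = code$bit_rate,
         class_index = code$class_index),
    class = "sample_timeline")
}

#' Periodic autocorrelation of a stimulus code in ±1 coding
#'
#' Computes \eqn{\sum_i s_i s_{i+l}} (indices mod length) with bits mapped
#' \eqn{0 \to -1}, \eqn{1 \to +1}. For an m-sequence this is two-valued:
#' the sequence length at lag 0 and \eqn{-1} at every other lag, which is why
#' circularly shifted class codes are nearly orthogonal.
#'
#' @param code A `"stimulus_code"`.
#' @param lags Integer lags (default: all lags `0:(L-1)`).
#' @return Numeric vector of autocorrelation values, one per lag.
#' @export
code_autocorrelation <- function(code, lags = seq_along(code$bits) - 1L) {
  stopifnot(inherits(code, "stimulus_code"))
  s <- 2 * code$bits - 1
  vapply(lags, function(l) sum(s * rotate_bits(s, l)), numeric(1))
}

#' @export
print.stimulus_code <- function(x, ...) {
  cat(sprintf("<stimulus_code> class %d: %d bits at %g bits/s (%d ones)\n",
              x$class_index, length(x$bits), x$bit_rate, sum(x$bits)))
  invisible(x)
}

#' Read and write stimulus codes as plain text or JSON
#'
#' The text form is a single line of `0`/`1` characters (one per bit); the
#' JSON form additionally records the bit rate, register taps and class
#' metadata so a code can be regenerated exactly.
#'
#' @param code A `"stimulus_code"`.
#' @param path File path.
#' @return `read_code_text()` and `read_code_json()` return a
#'   `"stimulus_code"`; the writers return `path` invisibly.
#' @name code_io
#' @export
write_code_text <- function(code, path) {
  stopifnot(inherits(code, "stimulus_code"))
  writeLines(paste(code$bits, collapse = ""), path)
  invisible(path)
}

#' @rdname code_io
#' @param bit_rate Bit rate to attach when reading the bare text form.
#' @export
read_code_text <- function(path, bit_rate = 60) {
  line <- trimws(readLines(path, n = 1L))
  bits <- as.integer(strsplit(line, "")[[1]])
  if (!all(bits %in% c(0L, 1L))) stop("code file must contain only 0/1 characters")
  structure(
    list(bits = bits, bit_rate = bit_rate, class_index = 1L,
         shift_step = 4L, K = 4L,
         register_length = NA_integer_, taps = NA_integer_),
    class = "stimulus_code")
}

#' @rdname code_io
#' @export
write_code_json <- function(code, path) {
  stopifnot(inherits(code, "stimulus_code"))
  jsonlite::write_json(unclass(code), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname code_io
#' @export
read_code_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("bits", "class_index", "shift_step", "K",
              "register_length", "taps"))
    x[[f]] <- as.integer(x[[f]])
  structure(x[c("bits", "bit_rate", "class_index", "shift_step", "K",
                "register_length", "taps")],
            class = "stimulus_code")
}

#' Sample-rate timelines for every target class
#'
#' Convenience wrapper producing the list of per-class timelines used for
#' calibration templates and online decoding.
#'
#' @param base Base `"stimulus_code"`.
#' @param fs Sampling rate in Hz.
#' @param n_cycles Cycles per timeline.
#' @return List of `base$K` `"sample_timeline"` objects.
#' @export
class_timelines <- function(base, fs = 600, n_cycles = 2L) {
  lapply(seq_len(base$K), function(k)
    code_to_timeline(class_code(base, k), fs = fs, n_cycles = n_cycles))
}
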