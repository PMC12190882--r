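# Synthetic EEG forward model.
#
# Subjects are generative stand-ins for participants: a temporal response
# kernel (the evoked response to one luminance reversal), a spatial topography
# over the montage, a small response latency, and a structured noise model
# (spatially mixed pink sources + independent pink + white + a 10 Hz rhythm).
# The `focus` parameter is the fraction of topography energy on the six
# retained electrodes and is the modeling device that drives the
# electrode-reduction phenomenology.

#' VEP-like evoked response kernel
#'
#' Damped oscillation used as the impulse response to a single code bit
#' reversal: \eqn{h(t) = \cos(2\pi f t)\, e^{-t/\tau}}, normalized to unit
#' energy. The sharp onset concentrates energy within one code bit (16.7 ms
#' at 60 bits/s), which is what makes raw-code template matching viable; the
#' ringing frequency and decay are configurable.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Kernel support, seconds.
#' @param freq Ringing frequency, Hz.
#' @param damping Exponential decay time constant, seconds.
#' @return Numeric vector of `round(duration * fs)` samples with unit energy.
#' @export
vep_kernel <- function(fs = 600, duration = 0.25, freq = 12, damping = 0.02) {
  t <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  h <- cos(2 * pi * freq * t) * exp(-t / damping)
  h / sqrt(sum(h^2))
}

#' Noise model specification
#'
#' Relative variance fractions of the background-noise components. The pink
#' budget `1 - white_fraction - alpha_fraction` is split between spatially
#' mixed shared sources (fraction `spatial_mix`, which give the noise a
#' cross-channel covariance structure that spatial filters can exploit) and
#' channel-independent pink noise.
#'
#' @param pink_alpha Spectral exponent of the 1/f^alpha components.
#' @param white_fraction Variance fraction of white sensor noise.
#' @param alpha_fraction Variance fraction of the narrowband alpha rhythm.
#' @param spatial_mix Share of the pink budget carried by shared sources.
#' @param n_sources Number of shared pink sources.
#' @param alpha_freq Alpha rhythm frequency, Hz.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(pink_alpha = 1, white_fraction = 0.15,
                       alpha_fraction = 0.15, spatial_mix = 0.6,
                       n_sources = 8L, alpha_freq = 10) {
  stopifnot(white_fraction >= 0, alpha_fraction >= 0,
            white_fraction + alpha_fraction <= 1,
            spatial_mix >= 0, spatial_mix <= 1)
  structure(list(pink_alpha = pink_alpha, white_fraction = white_fraction,
                 alpha_fraction = alpha_fraction, spatial_mix = spatial_mix,
                 n_sources = as.integer(n_sources), alpha_freq = alpha_freq),
            class = "noise_spec")
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw a synthetic subject
#'
#' Samples the generative parameters of one subject: the evoked kernel, a
#' random spatial topography rescaled so that exactly `focus_target` of its
#' squared-gain mass lies on the six retained electrodes, a response latency
#' drawn uniformly from `latency_range`, the noise mixing structure, and the
#' target signal-to-noise ratio. Identical seeds yield identical subjects.
#'
#' `snr_db` is the array-level evoked-to-noise variance ratio: total evoked
#' variance summed over channels (the topography has unit norm) divided by the
#' per-channel noise variance (noise power is uniform across channels).
#'
#' @param seed Integer seed; fully determines the subject.
#' @param focus_target Fraction of topography energy on the reduced montage,
#'   in `[0, 1]`.
#' @param snr_db Evoked-to-noise variance ratio in dB (see Details).
#' @param fs Sampling rate, Hz.
#' @param montage Montage the subject is recorded with.
#' @param kernel Optional numeric kernel overriding [vep_kernel()].
#' @param latency_range Range (seconds) of the uniform response latency.
#' @param noise Noise specification from [noise_spec()].
#' @return An object of class `"subject_model"`.
#' @export
sample_subject <- function(seed, focus_target = 0.6, snr_db = 3, fs = 600,
                           montage = montage_full16(), kernel = NULL,
                           latency_range = c(0.002, 0.006),
                           noise = noise_spec()) {
  if (focus_target < 0 || focus_target > 1)
    stop("focus_target must lie in [0, 1]")
  m <- length(montage$names)
  red_idx <- montage_indices(montage_reduced6(), montage)
  with_seed(seed, {
    z <- stats::rnorm(m)
    topo <- numeric(m)
    zr <- z[red_idx]
    zo <- z[-red_idx]
    if (focus_target > 0) topo[red_idx] <- zr / sqrt(sum(zr^2)) * sqrt(focus_target)
    if (focus_target < 1 && length(zo) > 0)
      topo[-red_idx] <- zo / sqrt(sum(zo^2)) * sqrt(1 - focus_target)
    names(topo) <- montage$names
    latency <- stats::runif(1, latency_range[1], latency_range[2])
    ap <- stats::rnorm(m)
    ap <- ap / sqrt(sum(ap^2))
    mix <- matrix(stats::rnorm(m * noise$n_sources), nrow = m)
    mix <- mix / sqrt(rowSums(mix^2))  # unit-variance shared noise per channel
    structure(
      list(kernel = if (is.null(kernel)) vep_kernel(fs) else kernel,
           topography = topo,
           latency = latency,
           noise_spec = noise,
           snr_db = snr_db,
           focus = focus_target,
           alpha_pattern = ap,
           noise_mix = mix,
           snr_ref_norm2 = sum(topo^2),
           fs = fs,
           montage = montage,
           seed = seed,
           cache = new.env(parent = emptyenv())),
      class = "subject_model")
  })
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "<subject_model> seed %s: %d channels, focus %.2f, snr %.1f dB, latency %.1f ms\n",
    format(x$seed), length(x$topography), x$focus, x$snr_db, 1000 * x$latency))
  invisible(x)
}

# 1/f^alpha noise via spectral shaping; returns n x n_series matrix,
# each column ~ unit variance
pink_noise <- function(n, n_series = 1L, alpha = 1) {
  nf <- floor(n / 2)
  freqs <- seq_len(nf)
  amp <- freqs^(-alpha / 2)
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    phases <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phases)
    full <- complex(real = numeric(n))
    full[2:(nf + 1)] <- spec
    if (n %% 2 == 0) {
      full[nf + 1] <- complex(real = Re(spec[nf]))  # real Nyquist bin
      if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
    } else {
      full[n:(n - nf + 1)] <- Conj(spec)
    }
    x <- Re(stats::fft(full, inverse = TRUE))
    out[, j] <- x / stats::sd(x)
  }
  out
}

# evoked 1-D response over one code cycle: circular convolution of the
# +/-1-coded cycle with the kernel, circularly delayed by the latency
evoked_cycle <- function(subject, timeline) {
  key <- sprintf("ev_%d_%d", timeline$class_index, timeline$cycle_samples)
  cache <- subject$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  cyc <- 2 * timeline$values[seq_len(timeline$cycle_samples)] - 1
  h <- subject$kernel
  nh <- length(h)
  if (nh >= length(cyc)) stop("kernel longer than one code cycle")
  if (nh > 1) {
    padded <- c(cyc[(length(cyc) - nh + 2):length(cyc)], cyc)
    ev <- as.numeric(stats::filter(padded, h, method = "convolution",
                                   sides = 1))
    ev <- ev[-seq_len(nh - 1)]
  } else {
    ev <- h * cyc
  }
  d <- round(subject$latency * subject$fs) %% length(ev)
  if (d > 0) ev <- c(ev[(length(ev) - d + 1):length(ev)], ev[1:(length(ev) - d)])
  cache[[key]] <- ev
  ev
}

# evoked segment of length n starting at code phase t0 (0-based), tiled
evoked_segment <- function(subject, timeline, n, t0 = 0L) {
  ev <- evoked_cycle(subject, timeline)
  idx <- ((t0 + seq_len(n) - 1L) %% length(ev)) + 1L
  ev[idx]
}

# m x n structured noise with ~unit average channel variance; uses the
# current global RNG state
make_noise <- function(subject, n) {
  sp <- subject$noise_spec
  m <- nrow(subject$noise_mix)
  pink_budget <- 1 - sp$white_fraction - sp$alpha_fraction
  w_shared <- sp$spatial_mix * pink_budget
  w_indep <- (1 - sp$spatial_mix) * pink_budget
  noise <- matrix(0, m, n)
  if (w_shared > 0) {
    src <- pink_noise(n, sp$n_sources, sp$pink_alpha)
    noise <- noise + sqrt(w_shared) * (subject$noise_mix %*% t(src))
  }
  if (w_indep > 0)
    noise <- noise + sqrt(w_indep) * t(pink_noise(n, m, sp$pink_alpha))
  if (sp$white_fraction > 0)
    noise <- noise + sqrt(sp$white_fraction) * matrix(stats::rnorm(m * n), m, n)
  if (sp$alpha_fraction > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- sqrt(2) * sin(2 * pi * sp$alpha_freq * seq_len(n) / subject$fs + phase)
    noise <- noise +
      sqrt(sp$alpha_fraction * m) * (subject$alpha_pattern %o% osc)
  }
  noise
}

#' Simulate one EEG epoch
#'
#' Forward model: `data = topography %o% evoked + noise`, where the evoked
#' 1-D signal is the subject's kernel circularly convolved with the ±1-coded
#' stimulus timeline (the timeline is tiled periodically if `duration` exceeds
#' it), delayed by the subject's latency. Noise is scaled so that the
#' array-level evoked-to-noise variance ratio equals the subject's `snr_db`;
#' the current global RNG state controls the noise only.
#'
#' @param subject A `"subject_model"`.
#' @param timeline A `"sample_timeline"` for the attended class.
#' @param duration Epoch length in seconds (default: the timeline length).
#' @param label Class label to attach (or `NA` for unlabeled).
#' @param t0_code_phase 0-based sample offset of the code cycle at epoch start.
#' @param noise_scale Multiplier on the calibrated noise amplitude (0 gives a
#'   noiseless epoch).
#' @return An object of class `"cvep_epoch"`: list with `data`
#'   (channels × samples), `fs`, `label`, `t0_code_phase`, `montage`.
#' @export
simulate_epoch <- function(subject, timeline, duration = NULL, label = NA,
                           t0_code_phase = 0L, noise_scale = 1) {
  stopifnot(inherits(subject, "subject_model"),
            inherits(timeline, "sample_timeline"))
  if (length(timeline$values) == 0) stop("timeline is empty")
  n <- if (is.null(duration)) length(timeline$values)
       else round(duration * subject$fs)
  if (n < 1) stop("epoch duration must cover at least one sample")
  ev <- evoked_segment(subject, timeline, n, t0 = as.integer(t0_code_phase))
  data <- subject$topography %o% ev
  if (noise_scale > 0) {
    sigma_n <- noise_sigma(subject, timeline)
    data <- data + (noise_scale * sigma_n) * make_noise(subject, n)
  }
  rownames(data) <- subject$montage$names
  structure(list(data = data, fs = subject$fs, label = label,
                 t0_code_phase = as.integer(t0_code_phase),
                 montage = subject$montage),
            class = "cvep_epoch")
}

# Per-channel noise SD realizing the subject's array-level snr_db.
# The reference topography norm is the one fixed at sampling time, so
# restricting channels keeps the physical noise floor unchanged and the
# effective SNR of a reduced recording scales with the retained evoked energy.
noise_sigma <- function(subject, timeline) {
  ev <- evoked_cycle(subject, timeline)
  var_e <- mean((ev - mean(ev))^2) * subject$snr_ref_norm2
  sqrt(var_e / 10^(subject$snr_db / 10))
}

#' @export
print.cvep_epoch <- function(x, ...) {
  cat(sprintf("<cvep_epoch> %d channels x %d samples at %g Hz, label %s\n",
              nrow(x$data), ncol(x$data), x$fs, format(x$label)))
  invisible(x)
}

#' Simulate a calibration session
#'
#' Records `nb` blocks; within each block the subject fixates each of the K
#' targets once (order shuffled within block by default), producing
#' `nb * K` labeled trials of two code cycles each (1260 samples at the
#' defaults), all starting at code phase 0.
#'
#' @param subject A `"subject_model"`.
#' @param codes List of K per-class `"sample_timeline"`s (two cycles each),
#'   e.g. from [class_timelines()].
#' @param nb Number of training blocks.
#' @param shuffle Shuffle target order within each block.
#' @param noise_scale Noise multiplier passed to [simulate_epoch()].
#' @return An object of class `"trial_set"`: list with `trials` (list of
#'   channels × samples matrices), `labels`, `fs`, `montage`, `n_samples`.
#' @export
simulate_training_session <- function(subject, codes, nb = 6L, shuffle = TRUE,
                                      noise_scale = 1) {
  if (nb < 1) stop("nb must be >= 1")
  K <- length(codes)
  if (K < 1) stop("at least one class timeline is required")
  trials <- list()
  labels <- integer(0)
  for (b in seq_len(nb)) {
    order_k <- if (shuffle) sample.int(K) else seq_len(K)
    for (k in order_k) {
      ep <- simulate_epoch(subject, codes[[k]], label = k,
                           t0_code_phase = 0L, noise_scale = noise_scale)
      trials[[length(trials) + 1L]] <- ep$data
      labels <- c(labels, k)
    }
  }
  structure(list(trials = trials, labels = labels, fs = subject$fs,
                 montage = subject$montage,
                 n_samples = ncol(trials[[1]])),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (%d channels x %d samples), classes: %s\n",
              length(x$trials), nrow(x$trials[[1]]), x$n_samples,
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

#' Write / read a trial set as delimited text plus a JSON sidecar
#'
#' Each trial is stored as one tab-separated numeric file
#' (`trial_###.tsv`, channels in rows); `meta.json` records the sampling
#' rate, labels and montage so the set round-trips exactly.
#'
#' @param ts A `"trial_set"`.
#' @param dir Directory to write into (created if needed).
#' @return `read_trial_set()` returns a `"trial_set"`; the writer returns
#'   `dir` invisibly.
#' @export
write_trial_set <- function(ts, dir) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts$trials)) {
    utils::write.table(ts$trials[[i]],
                       file.path(dir, sprintf("trial_%03d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(fs = ts$fs, labels = ts$labels,
               montage = ts$montage$names,
               reference = ts$montage$reference, ground = ts$montage$ground,
               n_samples = ts$n_samples, n_trials = length(ts$trials))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("trial_%03d.tsv", i)), sep = "\t"))
    dimnames(m) <- NULL
    m
  })
  structure(list(trials = trials, labels = as.integer(meta$labels),
                 fs = meta$fs,
                 montage = new_montage(meta$montage, meta$reference,
                                       meta$ground),
                 n_samples = meta$n_samples),
            class = "trial_set")
}

#' Define a synthetic cohort
#'
#' Draws per-subject focus and SNR values and derives one reproducible seed
#' per subject. The defaults are the study conditions used by the
#' electrode-reduction experiment harness: focus uniform on `[0.2, 0.9]` and
#' array SNR uniform on `[-8, 0]` dB (single-trial evoked energy well below
#' the background EEG, as in real recordings).
#'
#' @param n Number of subjects.
#' @param seed Cohort-level seed.
#' @param focus_range Range of the uniform focus distribution.
#' @param snr_db_range Range of the uniform SNR distribution, dB.
#' @return A data frame with columns `subject_id`, `seed`, `focus`, `snr_db`.
#' @export
make_cohort <- function(n = 40L, seed = 1L, focus_range = c(0.2, 0.9),
                        snr_db_range = c(-8, 0)) {
  with_seed(seed, {
    data.frame(
      subject_id = seq_len(n),
      seed = sample.int(.Machine$integer.max - 1L, n),
      focus = stats::runif(n, focus_range[1], focus_range[2]),
      snr_db = stats::runif(n, snr_db_range[1], snr_db_range[2]))
  })
}

#' Read a cohort definition from YAML
#'
#' Accepts either explicit per-subject entries (`subjects:` with `seed`,
#' `focus`, `snr_db`) or generator parameters (`n`, `seed`, `focus_range`,
#' `snr_db_range`) handed to [make_cohort()].
#'
#' @param path YAML file path.
#' @return A cohort data frame as from [make_cohort()].
#' @export
read_cohort_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  # a bare `n:` key is a YAML 1.1 boolean token; undo that reading
  names(y)[names(y) %in% c("FALSE", "n_subjects")] <- "n"
  if (!is.null(y$subjects)) {
    df <- do.call(rbind, lapply(y$subjects, as.data.frame))
    if (is.null(df$subject_id)) df$subject_id <- seq_len(nrow(df))
    return(df[, c("subject_id", "seed", "focus", "snr_db")])
  }
  do.call(make_cohort, y[intersect(names(y),
                                   c("n", "seed", "focus_range",
                                     "snr_db_range"))])
}
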