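# Performance metrics (accuracy, Wolpaw ITR) and the paired categorical
# statistics used for the electrode-reduction comparisons, plus the packaged
# subject-level performance table.

#' Selection accuracy
#'
#' Percentage of correctly selected targets among all issued selections,
#' UNDO corrections included. Timed-out attempts issue no selection and are
#' excluded.
#'
#' @param events Data frame with logical columns `correct` and `timed_out`
#'   (as produced by [run_copy_spelling()]).
#' @return Accuracy in percent.
#' @export
accuracy <- function(events) {
  n_sel <- sum(!events$timed_out)
  if (n_sel == 0) stop("accuracy is undefined without any selections")
  100 * sum(events$correct) / n_sel
}

#' Wolpaw bits per selection
#'
#' \deqn{B = \log_2 N + P \log_2 P + (1-P)\log_2\frac{1-P}{N-1}}
#' with \eqn{N} targets and observed accuracy \eqn{P} (as a proportion);
#' the \eqn{P\log_2 P} and \eqn{(1-P)\log_2(\cdot)} terms are taken as 0 in
#' the limits \eqn{P \to 0} and \eqn{P \to 1}.
#'
#' @param P Accuracy as a proportion in `(0, 1]` (chance is `1/N`).
#' @param N Number of targets.
#' @return Bits per selection.
#' @examples
#' wolpaw_bits(1, 4)     # 2 bits
#' wolpaw_bits(0.25, 4)  # 0 bits (chance)
#' @export
wolpaw_bits <- function(P, N = 4) {
  if (N < 2) stop("N must be >= 2")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  term1 <- ifelse(P > 0, P * log2(P), 0)
  term2 <- ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  log2(N) + term1 + term2
}

#' Information transfer rate in bits per minute
#'
#' Wolpaw bits per selection multiplied by selections per minute of active
#' stimulation time (selection pauses excluded).
#'
#' @param P Accuracy as a proportion.
#' @param N Number of targets.
#' @param selections Number of issued selections.
#' @param active_seconds Active stimulation time in seconds.
#' @return ITR in bits/min.
#' @export
itr_bits_per_min <- function(P, N = 4, selections, active_seconds) {
  if (active_seconds <= 0) stop("active_seconds must be positive")
  wolpaw_bits(P, N) * selections * 60 / active_seconds
}

study_conditions <- c("baseline16", "reduced6_noretrain", "reduced6_retrained")

#' Load a subject × condition study table
#'
#' Reads a wide CSV with one row per subject and per-condition accuracy and
#' ITR columns, where a dash (or empty cell) marks a non-functional round, and
#' returns it in long form. The default is the packaged transcription of the
#' published 38-subject table.
#'
#' @param path CSV path; `NULL` loads the packaged fixture.
#' @return A data frame of class `"study_table"` with columns `subject`,
#'   `condition` (one of `baseline16`, `reduced6_noretrain`,
#'   `reduced6_retrained`), `accuracy`, `itr`; `NA` entries mark
#'   non-functional rounds.
#' @export
load_study_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subject_table.csv", package = "cvepsim",
                        mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE,
                         colClasses = "character")
  expected <- c("subject",
                "accuracy_baseline16", "accuracy_reduced6_noretrain",
                "accuracy_reduced6_retrained",
                "itr_baseline16", "itr_reduced6_noretrain",
                "itr_reduced6_retrained")
  if (!identical(names(raw), expected))
    stop(sprintf("malformed study table header: expected columns %s",
                 paste(expected, collapse = ", ")))
  parse_num <- function(x, col) {
    x[x %in% c("-", "")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0)
      stop(sprintf("malformed value '%s' in column %s, line %d",
                   x[bad[1]], col, bad[1] + 1L))
    out
  }
  long <- do.call(rbind, lapply(study_conditions, function(cond) {
    data.frame(
      subject = as.integer(raw$subject),
      condition = cond,
      accuracy = parse_num(raw[[paste0("accuracy_", cond)]],
                           paste0("accuracy_", cond)),
      itr = parse_num(raw[[paste0("itr_", cond)]], paste0("itr_", cond)))
  }))
  mism <- is.na(long$accuracy) != is.na(long$itr)
  if (any(mism))
    stop("accuracy and ITR missingness disagree for some subject/condition")
  class(long) <- c("study_table", "data.frame")
  long
}

#' Convert a simulated study result to a study table
#'
#' @param x Data frame from [run_three_condition_study()].
#' @return A `"study_table"` (columns `subject`, `condition`, `accuracy`,
#'   `itr`).
#' @export
as_study_table <- function(x) {
  out <- x[, c("subject", "condition", "accuracy", "itr")]
  class(out) <- c("study_table", "data.frame")
  out
}

#' Mean and SD of a measure within one condition
#'
#' @param table A `"study_table"`.
#' @param condition Condition name.
#' @param measure `"accuracy"` or `"itr"`.
#' @return Named vector `c(mean, sd, n)` over the present (functional) values.
#' @export
condition_summary <- function(table, condition, measure = c("accuracy", "itr")) {
  measure <- match.arg(measure)
  vals <- table[[measure]][table$condition == condition]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2)
    stop(sprintf("need at least 2 present values in condition %s", condition))
  c(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Binary functionality matrix of a study table
#'
#' @param table A `"study_table"`.
#' @return Subjects × conditions 0/1 matrix (1 = functional round, i.e. a
#'   present accuracy value).
#' @export
functionality_matrix <- function(table) {
  subjects <- sort(unique(table$subject))
  mat <- sapply(study_conditions, function(cond) {
    v <- table$accuracy[match(
      paste(subjects, cond),
      paste(table$subject, table$condition))]
    as.integer(!is.na(v))
  })
  rownames(mat) <- subjects
  mat
}

#' Functionality counts, transitions and failure rates
#'
#' Derives from the missingness pattern: per-condition functional counts, the
#' transitions between the two reduced conditions (subjects who regained
#' functionality after retraining, who lost it, and who remained
#' non-functional), and per-condition failure rates in percent.
#'
#' @param table A `"study_table"`.
#' @return List with `functional` (named counts), `regained`, `lost`,
#'   `remained_failed`, `failure_rate` (named percentages), `n_subjects`.
#' @export
functionality_and_transitions <- function(table) {
  f <- functionality_matrix(table)
  n <- nrow(f)
  list(
    functional = colSums(f),
    regained = sum(f[, "reduced6_noretrain"] == 0 &
                     f[, "reduced6_retrained"] == 1),
    lost = sum(f[, "reduced6_noretrain"] == 1 &
                 f[, "reduced6_retrained"] == 0),
    remained_failed = sum(f[, "reduced6_noretrain"] == 0 &
                            f[, "reduced6_retrained"] == 0),
    failure_rate = 100 * (n - colSums(f)) / n,
    n_subjects = n)
}

#' McNemar chi-square statistic from discordant counts
#'
#' Uncorrected statistic \eqn{(b-c)^2/(b+c)} by default; the
#' continuity-corrected variant \eqn{(|b-c|-1)^2/(b+c)} is available behind
#' `corrected`.
#'
#' @param b,c Discordant pair counts.
#' @param corrected Apply the continuity correction.
#' @return The chi-square statistic (1 degree of freedom).
#' @export
mcnemar_chi2 <- function(b, c, corrected = FALSE) {
  if (b + c == 0) stop("McNemar statistic undefined when b + c = 0")
  if (corrected) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
}

#' Cochran's Q test statistic for matched binary outcomes
#'
#' \deqn{Q = (k-1)\,\frac{k \sum_j C_j^2 - T^2}{k T - \sum_i R_i^2}}
#' over a subjects × conditions 0/1 matrix with column sums \eqn{C_j}, row
#' sums \eqn{R_i} and grand total \eqn{T}; `df = k - 1`.
#'
#' @param mat Subjects × conditions binary matrix.
#' @return List with `Q` and `df`.
#' @export
cochran_q <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two conditions")
  if (!all(mat %in% c(0, 1))) stop("matrix must be binary")
  k <- ncol(mat)
  Cj <- colSums(mat)
  Ri <- rowSums(mat)
  Tt <- sum(mat)
  denom <- k * Tt - sum(Ri^2)
  if (denom == 0)
    stop("degenerate denominator: every subject has a constant outcome")
  list(Q = (k - 1) * (k * sum(Cj^2) - Tt^2) / denom, df = k - 1)
}

#' Paired Cohen's d with a percentile-bootstrap confidence interval
#'
#' \eqn{d = \bar{x - y} / \mathrm{sd}(x - y)} for paired vectors, with a
#' seeded percentile bootstrap over subjects.
#'
#' @param x,y Paired numeric vectors of equal length (>= 3).
#' @param conf Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return List with `d` and `ci` (length-2 vector).
#' @export
cohens_d_paired <- function(x, y, conf = 0.95, n_boot = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must be paired vectors of equal length >= 3")
  # no differences at all is a well-defined null effect; a constant nonzero
  # difference has an undefined standardized size
  d_of <- function(diff) {
    s <- stats::sd(diff)
    if (s == 0) {
      if (all(diff == 0)) return(0)
      stop("zero variance of the paired differences")
    }
    mean(diff) / s
  }
  diff <- x - y
  d <- d_of(diff)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      di <- diff[sample.int(length(diff), replace = TRUE)]
      s <- stats::sd(di)
      if (s == 0) return(if (all(di == 0)) 0 else NA_real_)
      mean(di) / s
    }, numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE)
  })
  list(d = d, ci = ci)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a numeric variable and a dichotomous one coded
#' 0/1.
#'
#' @param x Numeric vector.
#' @param group Logical or 0/1 vector of the same length.
#' @return The correlation coefficient.
#' @export
point_biserial <- function(x, group) {
  stats::cor(x, as.numeric(group))
}

#' Reproduce the summary statistics of the packaged subject table
#'
#' Recomputes, from the subject-level table alone, every summary that is
#' arithmetically determined by it: condition means and SDs, functionality
#' counts, retraining transitions, failure rates, the McNemar statistics of
#' the two baseline contrasts, and Cochran's Q over the functionality matrix.
#'
#' @param table A `"study_table"` (default: the packaged fixture).
#' @return A nested list of reproduced quantities, suitable for JSON export.
#' @export
reproduce_fixture_report <- function(table = load_study_table()) {
  f <- functionality_and_transitions(table)
  fm <- functionality_matrix(table)
  b_nr <- sum(fm[, "baseline16"] == 1 & fm[, "reduced6_noretrain"] == 0)
  c_nr <- sum(fm[, "baseline16"] == 0 & fm[, "reduced6_noretrain"] == 1)
  b_rt <- sum(fm[, "baseline16"] == 1 & fm[, "reduced6_retrained"] == 0)
  c_rt <- sum(fm[, "baseline16"] == 0 & fm[, "reduced6_retrained"] == 1)
  summaries <- lapply(study_conditions, function(cond)
    list(accuracy = as.list(condition_summary(table, cond, "accuracy")),
         itr = as.list(condition_summary(table, cond, "itr"))))
  names(summaries) <- study_conditions
  list(
    condition_summaries = summaries,
    functional = as.list(f$functional),
    regained = f$regained,
    lost = f$lost,
    remained_failed = f$remained_failed,
    failure_rate = as.list(f$failure_rate),
    mcnemar = list(
      baseline_vs_noretrain = list(b = b_nr, c = c_nr,
                                   chi2 = mcnemar_chi2(b_nr, c_nr)),
      baseline_vs_retrained = list(b = b_rt, c = c_rt,
                                   chi2 = mcnemar_chi2(b_rt, c_rt))),
    cochran_q = cochran_q(fm))
}
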