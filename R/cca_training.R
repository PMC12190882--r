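# Calibration: per-class trial averaging, stimulus templates, and the
# ridge-regularised canonical correlation that yields one spatial-filter pair
# per target class.

#' Average the training trials of one class
#'
#' Element-wise mean of all trials carrying the given label, the class-average
#' response used as the EEG side of the canonical correlation.
#'
#' @param trials A `"trial_set"`.
#' @param class_index Target class label.
#' @return A channels × samples matrix with attributes `class_index` and
#'   `nb_used` (number of trials averaged).
#' @export
average_trials <- function(trials, class_index) {
  stopifnot(inherits(trials, "trial_set"))
  sel <- which(trials$labels == class_index)
  if (length(sel) == 0)
    stop(sprintf("no trials with class label %s", format(class_index)))
  dims <- dim(trials$trials[[sel[1]]])
  acc <- matrix(0, dims[1], dims[2])
  for (i in sel) {
    ti <- trials$trials[[i]]
    if (!identical(dim(ti), dims))
      stop("trials of one class differ in shape")
    acc <- acc + ti
  }
  out <- acc / length(sel)
  attr(out, "class_index") <- class_index
  attr(out, "nb_used") <- length(sel)
  out
}

#' Build the ideal stimulus template of a class
#'
#' Stacks `m` identical copies of the 0/1 code timeline, one per channel, so
#' the template has the same shape as an averaged EEG response. Its rows being
#' identical makes the template-side covariance rank one; the CCA solver
#' handles this with a ridge.
#'
#' @param code_timeline A `"sample_timeline"`.
#' @param m Number of channels.
#' @return An `m` × `n` 0/1 matrix.
#' @export
build_template <- function(code_timeline, m) {
  stopifnot(inherits(code_timeline, "sample_timeline"))
  if (m < 1) stop("m must be >= 1")
  matrix(rep(code_timeline$values, each = m), nrow = m)
}

#' Leading canonical correlation of two multichannel signals
#'
#' Finds unit-norm weight vectors `w_x`, `w_y` maximizing the Pearson
#' correlation between the projections `w_x' X` and `w_y' Y`. Rows are
#' centered, a ridge is added to both auto-covariances (required because the
#' stimulus template's covariance is rank-deficient by construction), and the
#' leading pair is obtained from the singular value decomposition of the
#' symmetrically whitened cross-covariance. The sign convention fixes
#' `rho >= 0` and a positive first nonzero entry of `w_x`, making the result
#' deterministic.
#'
#' @param X Channels × samples matrix (EEG side).
#' @param Y Channels × samples matrix (template side), same sample count.
#' @param ridge Nonnegative ridge added to both auto-covariance diagonals.
#' @return List with `w_x`, `w_y` (unit norm) and `rho` (in `[0, 1]`), the
#'   Pearson correlation of the two projections.
#' @export
canonical_correlation <- function(X, Y, ridge = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of samples")
  n <- ncol(X)
  if (n <= max(nrow(X), nrow(Y)))
    stop("need more samples than channels")
  if (ridge < 0) stop("ridge must be nonnegative")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  if (sum(Xc^2) < 1e-24)
    stop("degenerate input: zero variance on the X (EEG) side")
  if (sum(Yc^2) < 1e-24)
    stop("degenerate input: zero variance on the Y (template) side")

  Sxx <- tcrossprod(Xc) / (n - 1) + diag(ridge, nrow(X))
  Syy <- tcrossprod(Yc) / (n - 1) + diag(ridge, nrow(Y))
  Sxy <- tcrossprod(Xc, Yc) / (n - 1)
  Wx <- inv_sqrt_sym(Sxx)
  Wy <- inv_sqrt_sym(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy, nu = 1, nv = 1)
  w_x <- drop(Wx %*% sv$u[, 1])
  w_y <- drop(Wy %*% sv$v[, 1])
  w_x <- w_x / sqrt(sum(w_x^2))
  w_y <- w_y / sqrt(sum(w_y^2))

  first <- which(abs(w_x) > 1e-12)[1]
  if (!is.na(first) && w_x[first] < 0) {
    w_x <- -w_x; w_y <- -w_y
  }
  r <- stats::cor(drop(crossprod(w_x, Xc)), drop(crossprod(w_y, Yc)))
  if (is.na(r)) r <- 0
  if (r < 0) {
    w_y <- -w_y
    r <- -r
  }
  list(w_x = w_x, w_y = w_y, rho = min(r, 1))
}

# symmetric inverse square root; eigenvalues floored at a small positive
# value (the caller's ridge guarantees positivity up to rounding)
inv_sqrt_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps * max(abs(e$values), 1))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Train the per-class spatial filters
#'
#' For each of the K classes: average that class's training trials, build the
#' ideal stimulus template from its code timeline, and solve the canonical
#' correlation between the two, yielding one spatial-filter pair per class.
#'
#' @param trials A `"trial_set"` covering all K classes.
#' @param codes List of K per-class `"sample_timeline"`s matching the trial
#'   length.
#' @param ridge Ridge passed to [canonical_correlation()].
#' @return An object of class `"cvep_filters"`: list with `filters` (per
#'   class: `w_x`, `w_y`, `rho`, `class_index`), `montage`, `fs`, `n_samples`.
#' @export
train_classifier <- function(trials, codes, ridge = 1e-8) {
  stopifnot(inherits(trials, "trial_set"))
  K <- length(codes)
  missing <- setdiff(seq_len(K), unique(trials$labels))
  if (length(missing) > 0)
    stop(sprintf("missing training trials for class(es): %s",
                 paste(missing, collapse = ", ")))
  m <- nrow(trials$trials[[1]])
  filters <- lapply(seq_len(K), function(k) {
    xbar <- average_trials(trials, k)
    tmpl <- build_template(codes[[k]], m)
    cc <- canonical_correlation(xbar, tmpl, ridge = ridge)
    list(w_x = cc$w_x, w_y = cc$w_y, rho = cc$rho, class_index = k)
  })
  structure(list(filters = filters, montage = trials$montage,
                 fs = trials$fs, n_samples = trials$n_samples),
            class = "cvep_filters")
}

#' @export
print.cvep_filters <- function(x, ...) {
  rhos <- vapply(x$filters, `[[`, numeric(1), "rho")
  cat(sprintf("<cvep_filters> %d classes, %d channels; training rho: %s\n",
              length(x$filters), length(x$filters[[1]]$w_x),
              paste(sprintf("%.3f", rhos), collapse = " ")))
  invisible(x)
}

#' Serialize trained filters to JSON
#'
#' Stores per-class weights and training correlations together with the
#' montage so decode runs are reproducible across processes.
#'
#' @param filters A `"cvep_filters"`.
#' @param path JSON file path.
#' @return `read_filters_json()` returns a `"cvep_filters"`; the writer
#'   returns `path` invisibly.
#' @export
write_filters_json <- function(filters, path) {
  stopifnot(inherits(filters, "cvep_filters"))
  out <- list(
    montage = filters$montage$names,
    reference = filters$montage$reference,
    ground = filters$montage$ground,
    fs = filters$fs,
    n_samples = filters$n_samples,
    filters = lapply(filters$filters, function(f)
      list(class_index = f$class_index, rho = f$rho,
           w_x = f$w_x, w_y = f$w_y)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filters_json
#' @export
read_filters_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  filters <- lapply(seq_len(nrow(x$filters)), function(i)
    list(w_x = x$filters$w_x[[i]], w_y = x$filters$w_y[[i]],
         rho = x$filters$rho[i], class_index = x$filters$class_index[i]))
  structure(list(filters = filters,
                 montage = new_montage(x$montage, x$reference, x$ground),
                 fs = x$fs, n_samples = x$n_samples),
            class = "cvep_filters")
}
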