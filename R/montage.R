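#' Electrode montages
#'
#' `montage_full16()` is the 16-electrode occipito-parietal layout used for
#' calibration and the baseline condition; `montage_reduced6()` is the
#' six-electrode subset retained after electrode removal. Reference is Cz,
#' ground AFz, in both cases.
#'
#' @return An object of class `"montage"`: list with `names` (ordered
#'   electrode labels), `reference` and `ground`.
#' @examples
#' montage_reduced6()$names  # PO3 POz PO4 O1 Oz O2
#' @export
montage_full16 <- function() {
  new_montage(c("P7", "P3", "Pz", "P4", "P8",
                "PO7", "PO3", "POz", "PO4", "PO8",
                "O1", "Oz", "O2", "O9", "Iz", "O10"))
}

#' @rdname montage_full16
#' @export
montage_reduced6 <- function() {
  new_montage(c("PO3", "POz", "PO4", "O1", "Oz", "O2"))
}

new_montage <- function(names, reference = "Cz", ground = "AFz") {
  structure(list(names = names, reference = reference, ground = ground),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes (ref %s, gnd %s): %s\n",
              length(x$names), x$reference, x$ground,
              paste(x$names, collapse = " ")))
  invisible(x)
}

# positions of `subset` electrodes within `full`, preserving subset order;
# errors on unknown labels
montage_indices <- function(subset, full) {
  sub_names <- if (inherits(subset, "montage")) subset$names else subset
  full_names <- if (inherits(full, "montage")) full$names else full
  idx <- match(sub_names, full_names)
  if (anyNA(idx))
    stop(sprintf("unknown electrode label(s): %s",
                 paste(sub_names[is.na(idx)], collapse = ", ")))
  idx
}

#' Restrict channels to a sub-montage
#'
#' Keeps only the rows / entries corresponding to the retained electrodes, in
#' their original relative order. Works on epochs, trial sets, subject models
#' and plain weight vectors, so a spatial filter trained on the full montage
#' can be applied unchanged to a reduced recording (the "no retraining"
#' condition).
#'
#' @param x A `"cvep_epoch"`, `"trial_set"`, `"subject_model"`, or a numeric
#'   weight vector.
#' @param subset Target `"montage"` (or character vector of labels); must be a
#'   subset of the montage of `x`.
#' @param ... Further arguments passed to methods.
#' @return An object of the same kind as `x`, restricted to `subset`.
#' @export
restrict_channels <- function(x, subset, ...) UseMethod("restrict_channels")

#' @rdname restrict_channels
#' @param montage Montage describing the entries of a bare numeric vector.
#' @export
restrict_channels.numeric <- function(x, subset, montage = montage_full16(), ...) {
  idx <- montage_indices(subset, montage)
  if (length(x) != length(montage$names))
    stop("weight vector length does not match its montage")
  x[idx]
}

#' @rdname restrict_channels
#' @export
restrict_channels.cvep_epoch <- function(x, subset, ...) {
  idx <- montage_indices(subset, x$montage)
  x$data <- x$data[idx, , drop = FALSE]
  x$montage <- if (inherits(subset, "montage")) subset else new_montage(subset)
  x
}

#' @rdname restrict_channels
#' @export
restrict_channels.trial_set <- function(x, subset, ...) {
  idx <- montage_indices(subset, x$montage)
  x$trials <- lapply(x$trials, function(m) m[idx, , drop = FALSE])
  x$montage <- if (inherits(subset, "montage")) subset else new_montage(subset)
  x
}

#' @rdname restrict_channels
#' @export
restrict_channels.subject_model <- function(x, subset, ...) {
  idx <- montage_indices(subset, x$montage)
  x$topography <- x$topography[idx]
  x$alpha_pattern <- x$alpha_pattern[idx]
  x$noise_mix <- x$noise_mix[idx, , drop = FALSE]
  x$montage <- if (inherits(subset, "montage")) subset else new_montage(subset)
  x
}

#' @rdname restrict_channels
#' @export
restrict_channels.cvep_filters <- function(x, subset, ...) {
  idx <- montage_indices(subset, x$montage)
  x$filters <- lapply(x$filters, function(f) {
    f$w_x <- f$w_x[idx]
    f$w_y <- f$w_y[idx]
    f
  })
  x$montage <- if (inherits(subset, "montage")) subset else new_montage(subset)
  x
}
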