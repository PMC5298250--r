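#' Labeled stimulus sets
#'
#' A `labeled_stimulus_set` holds a matrix of contrast-normalized stimulus
#' vectors (one per row), an integer level index per stimulus, and the
#' latent-variable value attached to each level. The relative number of
#' stimuli per level implicitly defines the prior over the latent variable:
#' p(X_i) = N_i / N.
#'
#' Every stimulus row must be mean-subtracted and scaled to unit Euclidean
#' norm ("contrast normalized"); the constructor validates this.
#'
#' @param stimuli numeric matrix, N rows (stimuli) by d columns (dimensions).
#'   Each row must have zero mean and unit Euclidean norm (tolerance 1e-10).
#' @param labels integer vector of length N; `labels[i]` is the index into
#'   `levels` of stimulus i's latent-variable value.
#' @param levels numeric vector of the latent-variable value at each level
#'   (task units, e.g. arcmin of disparity). Must be distinct as indices;
#'   values themselves may repeat only in degenerate test constructions.
#' @return An object of class `labeled_stimulus_set` with components
#'   `stimuli`, `labels`, `levels`, and `counts` (stimuli per level).
#' @examples
#' s <- t(apply(matrix(rnorm(20), 4), 1, normalize_stimulus))
#' set <- labeled_stimulus_set(s, c(1L, 1L, 2L, 2L), levels = c(-1, 1))
#' stimulus_prior(set)
#' @export
labeled_stimulus_set <- function(stimuli, labels, levels) {
  stimuli <- as.matrix(stimuli)
  storage.mode(stimuli) <- "double"
  labels <- as.integer(labels)
  levels <- as.numeric(levels)
  if (nrow(stimuli) != length(labels))
    stop("number of stimulus rows (", nrow(stimuli),
         ") does not match number of labels (", length(labels), ")")
  n_lvl <- length(levels)
  if (n_lvl < 1L) stop("at least one latent-variable level is required")
  if (any(labels < 1L | labels > n_lvl))
    stop("labels must index into 'levels' (1..", n_lvl, ")")
  .check_normalized_rows(stimuli)
  counts <- tabulate(labels, nbins = n_lvl)
  structure(
    list(stimuli = stimuli, labels = labels, levels = levels, counts = counts),
    class = "labeled_stimulus_set"
  )
}

.check_normalized_rows <- function(stimuli, tol = 1e-8) {
  mu <- rowMeans(stimuli)
  nrm <- sqrt(rowSums(stimuli^2))
  bad <- which(abs(mu) > tol | abs(nrm - 1) > tol)
  if (length(bad))
    stop("stimulus row ", bad[1L],
         " is not contrast normalized (mean ", format(mu[bad[1L]]),
         ", norm ", format(nrm[bad[1L]]), ")")
  invisible(TRUE)
}

#' @export
print.labeled_stimulus_set <- function(x, ...) {
  cat("labeled_stimulus_set:", nrow(x$stimuli), "stimuli x",
      ncol(x$stimuli), "dimensions,", length(x$levels), "levels\n")
  cat("  levels:", paste(signif(x$levels, 4), collapse = " "), "\n")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Implied prior over latent-variable levels
#'
#' The prior probability of level i is the fraction of training stimuli that
#' carry that label, N_i / N.
#'
#' @param set a [labeled_stimulus_set()].
#' @return numeric vector of level probabilities summing to 1.
#' @export
stimulus_prior <- function(set) {
  set$counts / sum(set$counts)
}

#' Contrast-normalize a stimulus vector
#'
#' Subtracts the mean and scales to unit Euclidean norm, mapping a raw
#' intensity vector to the unitless contrast signal the response model
#' operates on. The result is invariant to affine rescaling x -> a*x + b
#' for a > 0.
#'
#' @param x numeric vector with at least 2 elements.
#' @return numeric vector with zero mean and unit norm.
#' @export
normalize_stimulus <- function(x) {
  if (length(x) < 2L) stop("a stimulus needs at least 2 elements")
  x <- x - mean(x)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("zero-contrast stimulus: input is constant")
  x / nrm
}

#' Extract the sub-set of stimuli with given row indices
#'
#' Keeps the level table intact (all levels remain, possibly with zero
#' count), so use with care: decoding requires every level to retain at
#' least one stimulus.
#'
#' @param set a [labeled_stimulus_set()].
#' @param idx integer vector of row indices to keep.
#' @return a new `labeled_stimulus_set`.
#' @export
subset_stimuli <- function(set, idx) {
  labeled_stimulus_set(set$stimuli[idx, , drop = FALSE], set$labels[idx],
                       set$levels)
}
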