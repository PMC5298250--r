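# Synthetic training sets with the statistical structure the method
# assumes: discrete latent-variable levels, many contrast-normalized
# stimuli per level, and latent information carried primarily by the
# covariance of quadrature filter-pair responses ("energy-like" tasks, as
# in disparity- or motion-energy computations).
#
# Each stimulus is a pair of half-windows modeled on a binocular pair: the
# first half is a windowed sinusoid with random phase and amplitude, the
# second half is the same sinusoid with its phase shifted in proportion to
# the stimulus's latent value (a disparity-like shift), plus independent
# pixel noise. Because the absolute phase is random, no single linear
# filter's mean response carries the latent value; the relative phase -- a
# second-order (covariance) property -- does.

#' Configuration of the synthetic energy task
#'
#' @param d stimulus dimensionality; must be even (two concatenated
#'   half-windows of d/2 samples).
#' @param n_levels number of latent-variable levels (>= 2).
#' @param level_range range of latent values; levels are equally spaced over
#'   it. Defaults to -15..15 (arcmin-like units, matching a disparity task).
#' @param n_per_level stimuli per level.
#' @param carrier_freq carrier frequency in cycles per half-window.
#' @param shift_gain phase shift (radians) per latent unit applied to the
#'   second half-window. The default pi/30 maps the +/-15 default range onto
#'   a +/-pi/2 relative phase sweep; sweeping further would alias, since a
#'   +pi and a -pi interocular phase shift produce identical stimuli.
#' @param pixel_noise_sd standard deviation of independent Gaussian pixel
#'   noise added to both half-windows, relative to carrier amplitude ~1.
#' @param seed integer seed making generation deterministic.
#' @return object of class `energy_task_config`.
#' @export
energy_task_config <- function(d = 16, n_levels = 19,
                               level_range = c(-15, 15), n_per_level = 400,
                               carrier_freq = 2, shift_gain = pi / 30,
                               pixel_noise_sd = 0.1, seed = 1) {
  if (d %% 2 != 0 || d < 4) stop("d must be an even integer >= 4")
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (n_per_level < 1) stop("n_per_level must be >= 1")
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  structure(list(d = as.integer(d), n_levels = as.integer(n_levels),
                 level_range = as.numeric(level_range),
                 n_per_level = as.integer(n_per_level),
                 carrier_freq = carrier_freq, shift_gain = shift_gain,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
            class = "energy_task_config")
}

#' Generate a labeled energy-task stimulus set
#'
#' Draws `n_per_level` stimuli at each of `n_levels` equally spaced latent
#' values. Each stimulus has a uniformly random carrier phase and a
#' log-uniform random amplitude (over one decade), a Hann spatial window,
#' a phase shift of `shift_gain * X_i` between its two half-windows, and
#' independent Gaussian pixel noise; the concatenated vector is then
#' mean-subtracted and unit-normalized. With `shift_gain = 0` the level
#' label carries no information about the stimulus.
#'
#' @param config an [energy_task_config()].
#' @return a [labeled_stimulus_set()] of N = n_levels * n_per_level stimuli.
#' @examples
#' set <- generate_energy_task_set(energy_task_config(d = 16, n_levels = 5,
#'                                                    n_per_level = 20))
#' @export
generate_energy_task_set <- function(config) {
  stopifnot(inherits(config, "energy_task_config"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(config$seed)

  h <- config$d %/% 2L
  n <- seq_len(h) - 1L
  window <- 0.5 * (1 - cos(2 * pi * (n + 0.5) / h))   # Hann window
  omega <- 2 * pi * config$carrier_freq * n / h
  levels <- seq(config$level_range[1], config$level_range[2],
                length.out = config$n_levels)
  N <- config$n_levels * config$n_per_level
  stimuli <- matrix(NA_real_, N, config$d)
  labels <- rep(seq_len(config$n_levels), each = config$n_per_level)

  for (row in seq_len(N)) {
    shift <- config$shift_gain * levels[labels[row]]
    for (attempt in 1:100) {
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- 10^stats::runif(1, -1, 0)       # log-uniform over one decade
      left <- amp * window * sin(omega + phase)
      right <- amp * window * sin(omega + phase + shift)
      x <- c(left, right) +
        stats::rnorm(config$d, sd = config$pixel_noise_sd)
      x <- x - mean(x)
      nrm <- sqrt(sum(x^2))
      if (nrm > 0) break
    }
    if (nrm == 0)
      stop("could not generate a non-degenerate stimulus for row ", row,
           " after 100 attempts")
    stimuli[row, ] <- x / nrm
  }
  labeled_stimulus_set(stimuli, labels, levels)
}

#' Quadrature filter pair for the energy task
#'
#' The canonical binocular quadrature pair for the generator's carrier:
#' filter 1 is (windowed) cosine in both half-windows, filter 2 is cosine
#' paired with sine. Useful as a reference encoding whose response
#' covariance tracks the latent value.
#'
#' @param config an [energy_task_config()].
#' @return a [filter_bank()] with 2 filters.
#' @export
quadrature_pair <- function(config) {
  h <- config$d %/% 2L
  n <- seq_len(h) - 1L
  window <- 0.5 * (1 - cos(2 * pi * (n + 0.5) / h))
  omega <- 2 * pi * config$carrier_freq * n / h
  f1 <- c(window * cos(omega), window * cos(omega))
  f2 <- c(window * cos(omega), window * sin(omega))
  f1 <- f1 - mean(f1); f2 <- f2 - mean(f2)
  filter_bank(cbind(f1 / sqrt(sum(f1^2)), f2 / sqrt(sum(f2^2))))
}

#' Impose a prior by culling stimuli
#'
#' Returns a subset of `set` whose per-level counts are proportional to
#' `target_weights` at the largest feasible scale: desired counts are
#' round(c * w_i) with c = min over positive-weight levels of N_i / w_i,
#' clamped to at least 1 stimulus for any level with positive weight.
#' Stimuli to keep are drawn uniformly at random within each level;
#' stimulus vectors are never modified, only membership changes.
#'
#' @param set a [labeled_stimulus_set()].
#' @param target_weights non-negative weights, one per level.
#' @param seed integer seed for the within-level draws.
#' @return a new, smaller [labeled_stimulus_set()].
#' @export
apply_prior_by_culling <- function(set, target_weights, seed = 1) {
  n_lvl <- length(set$levels)
  if (length(target_weights) != n_lvl)
    stop("target_weights must have one entry per level (", n_lvl, ")")
  if (any(target_weights < 0)) stop("target_weights must be non-negative")
  pos <- target_weights > 0
  if (!any(pos)) stop("at least one target weight must be positive")
  if (any(pos & set$counts == 0))
    stop("level ", which(pos & set$counts == 0)[1L],
         " has positive weight but no stimuli")
  scale <- min(set$counts[pos] / target_weights[pos])
  desired <- ifelse(pos, pmax(1L, round(scale * target_weights)), 0L)
  desired <- pmin(desired, set$counts)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  keep <- integer(0)
  for (i in seq_len(n_lvl)) {
    rows <- which(set$labels == i)
    if (desired[i] == length(rows)) keep <- c(keep, rows)
    else if (desired[i] > 0) keep <- c(keep, sample(rows, desired[i]))
  }
  subset_stimuli(set, sort(keep))
}

#' PCA baseline filters
#'
#' The top-q eigenvectors of the stimulus covariance matrix, ignoring level
#' labels: the task-agnostic variance-maximizing encoding that methods
#' without a decoder (and SGD runs with ~1 stimulus per level per batch)
#' tend toward. Columns are unit norm with a deterministic sign convention
#' (largest-magnitude element positive); eigenvalues are returned as an
#' attribute, in non-increasing order.
#'
#' @param set a [labeled_stimulus_set()] (or a stimulus matrix).
#' @param q number of components, 1 <= q <= d.
#' @return a [filter_bank()] with attribute `"eigenvalues"`.
#' @export
pca_baseline_filters <- function(set, q) {
  s <- if (inherits(set, "labeled_stimulus_set")) set$stimuli else as.matrix(set)
  d <- ncol(s)
  if (q < 1 || q > d) stop("q must be between 1 and d = ", d)
  eg <- eigen(stats::cov(s), symmetric = TRUE)
  rank_tol <- max(eg$values) * 1e-10
  if (sum(eg$values > rank_tol) < q)
    stop("stimulus covariance has rank < q = ", q)
  F <- eg$vectors[, seq_len(q), drop = FALSE]
  for (j in seq_len(q)) {
    peak <- which.max(abs(F[, j]))
    if (F[peak, j] < 0) F[, j] <- -F[, j]
    F[, j] <- F[, j] / sqrt(sum(F[, j]^2))
  }
  fb <- filter_bank(F)
  attr(fb, "eigenvalues") <- eg$values[seq_len(q)]
  fb
}

#' Mean cosine similarity between two filter banks
#'
#' For each filter in `fa`, the maximum absolute cosine similarity with any
#' filter of `fb`, averaged over filters. Sign- and order-insensitive,
#' matching how learned receptive fields are compared with reference
#' filters (a contrast-reversed filter is an equivalent encoding).
#'
#' @param fa,fb filter banks (d x q matrices).
#' @return scalar in [0, 1].
#' @export
filter_correlation <- function(fa, fb) {
  A <- unclass(as.matrix(fa)); B <- unclass(as.matrix(fb))
  cs <- abs(crossprod(A, B)) /
    outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  mean(apply(cs, 1, max))
}
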