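#' Filter banks
#'
#' A `filter_bank` is a d x q matrix whose columns are encoding filters
#' (receptive fields) constrained to unit Euclidean norm. The mean response
#' of filter t to stimulus s is the inner product f_t' s; because both are
#' unit norm, mean responses lie in [-1, 1].
#'
#' @param filters numeric matrix, d rows by q columns; each column must have
#'   unit norm (tolerance 1e-8).
#' @return object of class `filter_bank` (the matrix, with class attribute).
#' @export
filter_bank <- function(filters) {
  filters <- as.matrix(filters)
  storage.mode(filters) <- "double"
  nrm <- sqrt(colSums(filters^2))
  bad <- which(abs(nrm - 1) > 1e-8)
  if (length(bad))
    stop("filter ", bad[1L], " does not have unit norm (", format(nrm[bad[1L]]), ")")
  structure(filters, class = c("filter_bank", "matrix"))
}

#' Random unit-norm filters
#'
#' Independent standard-normal entries, each column normalized to unit norm.
#' Used to initialize gradient descent.
#'
#' @param d stimulus dimensionality.
#' @param q number of filters.
#' @return a [filter_bank()].
#' @export
random_filters <- function(d, q) {
  f <- matrix(stats::rnorm(d * q), d, q)
  filter_bank(sweep(f, 2, sqrt(colSums(f^2)), "/"))
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("filter_bank:", nrow(x), "dimensions x", ncol(x), "filters\n")
  invisible(x)
}

#' Response noise model
#'
#' Gaussian response noise whose variance is a linear function of the mean
#' response magnitude: sigma^2 = alpha * |r| + sigma0^2. With fano factor
#' alpha > 0 this is "scaled additive" (Poisson-like) noise, the widely used
#' simple model of spiking variability in early visual cortex; with
#' alpha = 0 the noise is constant additive. Noise is independent across
#' filters (diagonal covariance).
#'
#' Defaults alpha = 1.36 and sigma0^2 = 0.23 (response units squared) are
#' consistent with response properties measured in early visual cortex.
#'
#' @param fano_factor alpha >= 0, unitless slope of variance vs |mean|.
#' @param baseline_var sigma0^2 > 0, variance floor at zero mean response.
#' @param mode "scaled_additive" or "constant_additive"; inferred from
#'   `fano_factor` when omitted. `constant_additive` requires alpha = 0.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(fano_factor = 1.36, baseline_var = 0.23,
                        mode = NULL) {
  if (fano_factor < 0) stop("fano_factor must be >= 0")
  if (baseline_var <= 0) stop("baseline_var must be > 0")
  if (is.null(mode))
    mode <- if (fano_factor == 0) "constant_additive" else "scaled_additive"
  mode <- match.arg(mode, c("scaled_additive", "constant_additive"))
  if (mode == "constant_additive" && fano_factor != 0)
    stop("constant_additive mode requires fano_factor = 0")
  structure(list(fano_factor = fano_factor, baseline_var = baseline_var,
                 mode = mode),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model (", x$mode, "): alpha = ", x$fano_factor,
      ", sigma0^2 = ", x$baseline_var, "\n", sep = "")
  invisible(x)
}

#' Mean filter responses
#'
#' Noiseless responses r[i, t] = f_t' s_i for every stimulus i and filter t.
#'
#' @param filters a [filter_bank()] (or d x q matrix of unit-norm columns).
#' @param set a [labeled_stimulus_set()], or a plain stimulus matrix.
#' @return N x q matrix of mean responses, each entry in [-1, 1].
#' @export
mean_responses <- function(filters, set) {
  s <- if (inherits(set, "labeled_stimulus_set")) set$stimuli else as.matrix(set)
  if (ncol(s) != nrow(filters))
    stop("stimulus dimensionality (", ncol(s),
         ") does not match filter length (", nrow(filters), ")")
  s %*% unclass(filters)
}

#' Response noise variances
#'
#' Elementwise sigma^2 = alpha * |r| + sigma0^2. In constant-additive mode
#' (alpha = 0) the result is sigma0^2 everywhere.
#'
#' @param means matrix (or vector) of mean responses.
#' @param noise a [noise_model()].
#' @return object with the shape of `means`, variances > 0.
#' @export
response_variances <- function(means, noise) {
  noise$fano_factor * abs(means) + noise$baseline_var
}

#' Sample noisy responses
#'
#' Independent Gaussian samples R = r + eta, eta ~ N(0, sigma^2), one per
#' entry. Deterministic given `seed`.
#'
#' @param means N x q matrix of mean responses.
#' @param variances N x q matrix of noise variances (> 0).
#' @param seed optional integer seed for the local RNG stream.
#' @return N x q matrix of noisy responses.
#' @export
sample_noisy_responses <- function(means, variances, seed = NULL) {
  means <- as.matrix(means)
  variances <- as.matrix(variances)
  stopifnot(all(dim(means) == dim(variances)), all(variances > 0))
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  means + matrix(stats::rnorm(length(means), sd = sqrt(variances)),
                 nrow(means), ncol(means))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Log-likelihood of a response vector given one stimulus
#'
#' Log of the product of q univariate Gaussian densities (independent noise
#' across filters): log p(R | s) for a single stimulus with mean responses
#' `stimulus_means` and variances `stimulus_vars`.
#'
#' @param R numeric response vector of length q.
#' @param stimulus_means mean responses of the stimulus, length q.
#' @param stimulus_vars response variances, length q, all > 0.
#' @return scalar log density.
#' @export
log_likelihood <- function(R, stimulus_means, stimulus_vars) {
  stopifnot(length(R) == length(stimulus_means),
            length(R) == length(stimulus_vars), all(stimulus_vars > 0))
  sum(stats::dnorm(R, mean = stimulus_means, sd = sqrt(stimulus_vars),
                   log = TRUE))
}

# Log-likelihood matrix: row i = decoded response i, column j = training
# stimulus j. responses is Nr x q; means/vars are Nj x q. Works one filter at
# a time with outer differences, so memory is O(Nr * Nj) per filter pass.
.log_likelihood_matrix <- function(responses, means, vars) {
  nr <- nrow(responses)
  nj <- nrow(means)
  q <- ncol(means)
  ll <- matrix(0, nr, nj)
  for (t in seq_len(q)) {
    d <- outer(responses[, t], means[, t], "-")
    v <- vars[, t]
    ll <- ll - 0.5 * sweep(d^2, 2, v, "/") -
      matrix(0.5 * log(2 * pi * v), nr, nj, byrow = TRUE)
  }
  ll
}
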