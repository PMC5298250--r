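# Bayes-optimal decoder: closed-form posterior over latent-variable levels
# from noisy filter responses, optimal estimators, and expected cost.
#
# For a response vector R, the posterior at level i is
#   p(X_i | R) = Y_i / Z,  Y_i = sum_{j in level i} p(R | s_ij),
#                          Z  = sum over all stimuli of p(R | s_ij),
# i.e. the sum of within-level stimulus likelihoods normalized by the sum of
# all stimulus likelihoods. The counts-implied prior N_i/N and the uniform
# within-level stimulus probability 1/N_i cancel out of the long-form Bayes
# expression to give this form. All arithmetic is in log space with
# log-sum-exp reductions; with thousands of stimuli raw Gaussian densities
# underflow.

.ops_env <- new.env(parent = emptyenv())
.ops_env$count <- 0

.ops_add <- function(n) {
  .ops_env$count <- .ops_env$count + n
  invisible(NULL)
}

#' Likelihood-evaluation operation counter
#'
#' The decoder keeps an instrumented counter of posterior-evaluation work,
#' in the same units used to reason about complexity: decoding one response
#' against a reference set of N stimuli grouped into N_lvl levels counts
#' N * N_lvl operations. Evaluating the posterior for every stimulus in a
#' set of size N therefore counts N^2 * N_lvl.
#'
#' @return `ops_count()` returns the operations accumulated since the last
#'   reset; `ops_reset()` zeroes the counter and invisibly returns the
#'   previous total.
#' @export
ops_count <- function() .ops_env$count

#' @rdname ops_count
#' @export
ops_reset <- function() {
  old <- .ops_env$count
  .ops_env$count <- 0
  invisible(old)
}

#' Predicted operation counts for full and batch decoding
#'
#' Evaluating the posterior probability distribution for all N stimuli in a
#' training set with N_lvl levels requires N^2 * N_lvl operations. With
#' stochastic gradient descent on batches of N_bch stimuli, each batch
#' requires N_bch^2 * N_lvl operations and one pass through the data uses
#' k = N / N_bch batches, so a pass costs about N_bch * N_lvl * N -- a
#' factor k fewer operations than the full evaluation.
#'
#' @param N total number of stimuli.
#' @param N_lvl number of latent-variable levels.
#' @param N_bch batch size (stimuli per batch), N_bch <= N.
#' @return operation count (numeric, to avoid integer overflow).
#' @examples
#' operation_count_full(10000, 20)  # 2e9
#' @export
operation_count_full <- function(N, N_lvl) {
  stopifnot(N >= 1, N_lvl >= 1)
  as.numeric(N)^2 * N_lvl
}

#' @rdname operation_count_full
#' @export
operation_count_batch <- function(N, N_bch, N_lvl) {
  stopifnot(N >= 1, N_lvl >= 1, N_bch >= 1, N_bch <= N)
  as.numeric(N_bch) * N_lvl * N
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over groups of columns. ll: Nr x Nj, groups: list of
# column index vectors. Returns Nr x length(groups).
.grouped_logsumexp <- function(ll, groups) {
  out <- matrix(NA_real_, nrow(ll), length(groups))
  for (g in seq_along(groups)) {
    block <- ll[, groups[[g]], drop = FALSE]
    m <- apply(block, 1, max)
    out[, g] <- m + log(rowSums(exp(block - m)))
  }
  out
}

#' Posterior over latent-variable levels for one response vector
#'
#' Computes the level posterior p(X_i | R) as the sum of within-level
#' stimulus likelihoods over the total likelihood, together with its
#' numerator/denominator decomposition. Internally in log space; the
#' returned `Y` and `Z` are rescaled by exp(-max log Y) so they are finite
#' and satisfy Z = sum(Y) exactly (the posterior is invariant to this common
#' rescaling).
#'
#' @param R response vector of length q.
#' @param set a [labeled_stimulus_set()]; every level must have at least one
#'   stimulus.
#' @param filters a [filter_bank()].
#' @param noise a [noise_model()].
#' @return object of class `posterior_decomposition`: list with `posterior`
#'   (length N_lvl, sums to 1), `Y`, `Z`, `log_Y`, `log_Z`, and `levels`.
#' @export
posterior_over_levels <- function(R, set, filters, noise) {
  if (any(set$counts == 0))
    stop("every latent-variable level needs at least one stimulus")
  means <- mean_responses(filters, set)
  vars <- response_variances(means, noise)
  ll <- .log_likelihood_matrix(matrix(R, nrow = 1), means, vars)
  .ops_add(nrow(means) * length(set$levels))
  groups <- split(seq_along(set$labels), factor(set$labels,
                                                levels = seq_along(set$levels)))
  log_Y <- drop(.grouped_logsumexp(ll, groups))
  .posterior_from_logY(log_Y, set$levels)
}

.posterior_from_logY <- function(log_Y, levels) {
  m <- max(log_Y)
  if (!is.finite(m))
    stop("numerical degeneracy: all stimulus likelihoods vanished")
  Y <- exp(log_Y - m)
  Z <- sum(Y)
  structure(
    list(posterior = Y / Z, Y = Y, Z = Z,
         log_Y = log_Y, log_Z = m + log(Z), levels = levels),
    class = "posterior_decomposition"
  )
}

#' @export
print.posterior_decomposition <- function(x, ...) {
  cat("posterior over", length(x$posterior), "levels:\n")
  print(stats::setNames(signif(x$posterior, 4), signif(x$levels, 4)))
  invisible(x)
}

# Log-posterior matrix for many decoded responses at once.
# responses: Nr x q. Returns list(log_post = Nr x N_lvl normalized
# log-posteriors, log_Y, log_Z). Counts Nr * N * N_lvl operations.
.posterior_matrix <- function(responses, set, filters, noise) {
  if (any(set$counts == 0))
    stop("every latent-variable level needs at least one stimulus")
  means <- mean_responses(filters, set)
  vars <- response_variances(means, noise)
  n_lvl <- length(set$levels)
  groups <- split(seq_along(set$labels),
                  factor(set$labels, levels = seq_len(n_lvl)))
  nr <- nrow(responses)
  log_Y <- matrix(NA_real_, nr, n_lvl)
  # block over decoded responses to bound the Nr x N likelihood matrix
  block <- max(1L, min(nr, floor(2^22 / max(1, nrow(means)))))
  for (start in seq(1L, nr, by = block)) {
    idx <- start:min(nr, start + block - 1L)
    ll <- .log_likelihood_matrix(responses[idx, , drop = FALSE], means, vars)
    log_Y[idx, ] <- .grouped_logsumexp(ll, groups)
  }
  .ops_add(nr * nrow(means) * n_lvl)
  m <- apply(log_Y, 1, max)
  log_Z <- m + log(rowSums(exp(log_Y - m)))
  list(log_post = log_Y - log_Z, log_Y = log_Y, log_Z = log_Z)
}

#' Optimal estimators read out from the posterior
#'
#' `map_estimate()` returns the latent value of the level with maximal
#' posterior mass (ties broken toward the lowest level index); it is the
#' optimal estimator under 0-1 (L0) cost. `mmse_estimate()` returns the
#' posterior mean, optimal under squared-error (L2) cost; it requires
#' numeric latent values.
#'
#' @param post a `posterior_decomposition`, or a bare probability vector.
#' @param levels latent values; defaults to those stored in `post`.
#' @return a single latent value.
#' @export
map_estimate <- function(post, levels = NULL) {
  p <- if (inherits(post, "posterior_decomposition")) post$posterior else post
  if (is.null(levels))
    levels <- if (inherits(post, "posterior_decomposition")) post$levels else
      stop("levels must be supplied with a bare probability vector")
  levels[which.max(p)]   # which.max takes the first maximum: lowest index
}

#' @rdname map_estimate
#' @export
mmse_estimate <- function(post, levels = NULL) {
  p <- if (inherits(post, "posterior_decomposition")) post$posterior else post
  if (is.null(levels))
    levels <- if (inherits(post, "posterior_decomposition")) post$levels else
      stop("levels must be supplied with a bare probability vector")
  if (!is.numeric(levels)) stop("posterior-mean estimation needs numeric levels")
  sum(levels * p)
}

#' Cost specification
#'
#' Chooses the cost function the decoder (and filter learning) minimizes:
#' `"L0_KL"` is the KL-divergence form of the 0-1 cost, the negative
#' log-posterior at the correct level (MAP readout); `"L2"` is squared
#' error of the posterior-mean estimate (MMSE readout), which requires
#' numeric latent values.
#'
#' @param kind "L0_KL" or "L2".
#' @return object of class `cost_spec`.
#' @export
cost_spec <- function(kind = c("L0_KL", "L2")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "cost_spec")
}

#' Per-stimulus decoding costs
#'
#' `kl_cost_stimulus()` is the negative log-posterior probability at the
#' stimulus's correct level; `l2_cost_stimulus()` is the squared error of
#' the posterior-mean estimate. With `approx = TRUE` (default) the posterior
#' is evaluated at the noiseless mean response vector, the standard
#' approximation to the expected cost under response noise; with
#' `approx = FALSE` the cost is a Monte-Carlo average over `n_draws` noisy
#' response samples.
#'
#' @param stimulus_index row index of the decoded stimulus in `set`.
#' @param set a [labeled_stimulus_set()].
#' @param filters a [filter_bank()].
#' @param noise a [noise_model()].
#' @param approx logical; evaluate at the noiseless mean response?
#' @param n_draws Monte-Carlo draws when `approx = FALSE`.
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return scalar cost >= 0.
#' @export
kl_cost_stimulus <- function(stimulus_index, set, filters, noise,
                             approx = TRUE, n_draws = 1000, seed = NULL) {
  .cost_stimulus(stimulus_index, set, filters, noise, cost_spec("L0_KL"),
                 approx, n_draws, seed)
}

#' @rdname kl_cost_stimulus
#' @export
l2_cost_stimulus <- function(stimulus_index, set, filters, noise,
                             approx = TRUE, n_draws = 1000, seed = NULL) {
  .cost_stimulus(stimulus_index, set, filters, noise, cost_spec("L2"),
                 approx, n_draws, seed)
}

.cost_stimulus <- function(stimulus_index, set, filters, noise, spec,
                           approx, n_draws, seed) {
  k <- set$labels[stimulus_index]
  mean_r <- drop(mean_responses(filters,
                                set$stimuli[stimulus_index, , drop = FALSE]))
  if (approx) {
    responses <- matrix(mean_r, nrow = 1)
  } else {
    v <- response_variances(mean_r, noise)
    responses <- sample_noisy_responses(
      matrix(mean_r, n_draws, length(mean_r), byrow = TRUE),
      matrix(v, n_draws, length(v), byrow = TRUE), seed = seed)
  }
  pm <- .posterior_matrix(responses, set, filters, noise)
  costs <- .costs_from_log_post(pm$log_post, set$levels, k, spec)
  mean(costs)
}

.costs_from_log_post <- function(log_post, levels, true_level_idx, spec) {
  if (spec$kind == "L0_KL") {
    -log_post[, true_level_idx]
  } else {
    xhat <- drop(exp(log_post) %*% levels)
    (xhat - levels[true_level_idx])^2
  }
}

#' Expected 0-1 error of the MAP readout (diagnostic)
#'
#' One minus the posterior mass at the MAP level, the raw expected 0-1 cost
#' of the optimal single-level choice. Exposed for inspection; filter
#' learning uses the KL form ([kl_cost_stimulus()]) as the operational L0
#' cost.
#'
#' @inheritParams map_estimate
#' @return scalar in [0, 1].
#' @export
zero_one_cost <- function(post, levels = NULL) {
  p <- if (inherits(post, "posterior_decomposition")) post$posterior else post
  1 - max(p)
}

#' Total expected cost of a filter bank on a training set
#'
#' The objective of accuracy maximization analysis: the mean over all
#' training stimuli of the per-stimulus expected decoding cost, computed
#' from the closed-form posterior. With `approx = TRUE` each stimulus's
#' posterior is evaluated at its noiseless mean response.
#'
#' @param set a [labeled_stimulus_set()].
#' @param filters a [filter_bank()].
#' @param noise a [noise_model()].
#' @param spec a [cost_spec()].
#' @param approx logical; evaluate posteriors at noiseless mean responses.
#' @param decode_set optional second `labeled_stimulus_set` whose stimuli
#'   are decoded against `set` (used internally by batch SGD); defaults to
#'   decoding `set` against itself.
#' @return scalar mean cost.
#' @export
total_cost <- function(set, filters, noise, spec = cost_spec("L0_KL"),
                       approx = TRUE, decode_set = NULL) {
  if (!approx)
    return(mean(vapply(seq_along(set$labels), function(i)
      .cost_stimulus(i, set, filters, noise, spec, FALSE, 1000, NULL),
      numeric(1))))
  dec <- if (is.null(decode_set)) set else decode_set
  responses <- mean_responses(filters, dec)
  pm <- .posterior_matrix(responses, set, filters, noise)
  costs <- vapply(seq_along(dec$labels), function(i)
    .costs_from_log_post(pm$log_post[i, , drop = FALSE], set$levels,
                         dec$labels[i], spec),
    numeric(1))
  mean(costs)
}
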