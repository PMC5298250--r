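# Analytic gradients of the total expected cost with respect to the
# encoding filters, for the KL-divergence (0-1) and squared-error costs.
#
# Every stimulus likelihood p(R | s_j) depends on a filter f_t through
# three routes, all of which must be chained through:
#   * the Gaussian mean      m_jt = f_t' s_j        (d m / d f_t = s_j),
#   * the noise variance     v_jt = a |m_jt| + s0^2 (d v / d f_t = a sign(m_jt) s_j),
#   * the decoded response   R_it = f_t' s_i        (d R / d f_t = s_i),
# the last because, under the noiseless-mean approximation, the response
# being decoded is itself a filter output of the decoded stimulus.
#
# Writing l_j = log p(R_i | s_j) and d = R_it - m_jt:
#   d l_j / d f_t = (d / v)(s_j - s_i)
#                 + a sign(m_jt) (d^2 - v) / (2 v^2) * s_j .
# The cost gradients are weighted sums of these per-stimulus terms:
#   KL:  grad C_i = sum_j (wZ_ij - [lev(j) = k_i] wY_ij) dl_j
#        with wZ_ij = p(R_i|s_j)/Z_i, wY_ij = p(R_i|s_j)/Y_{i,k_i}
#        (from the numerator/denominator split of -log(Y_k/Z));
#   L2:  grad C_i = 2 (Xhat_i - X_{k_i}) sum_j wZ_ij (X_lev(j) - Xhat_i) dl_j
#        (from the gradient of the posterior-mean estimate through the
#        gradient of the posterior at each level).
# Both reduce to the same accumulation with different coefficients c_ij.

.grad_total_cost <- function(set, filters, noise, spec,
                             decode_set = NULL, block = NULL) {
  dec <- if (is.null(decode_set)) set else decode_set
  F <- unclass(filters)
  d <- nrow(F)
  q <- ncol(F)
  S <- set$stimuli
  M <- S %*% F                               # reference means, N_ref x q
  V <- response_variances(M, noise)
  Sd <- dec$stimuli
  R <- Sd %*% F                              # decoded responses, N_dec x q
  n_ref <- nrow(S)
  n_dec <- nrow(Sd)
  n_lvl <- length(set$levels)
  alpha <- noise$fano_factor
  lev_of_j <- set$labels
  groups <- split(seq_len(n_ref), factor(lev_of_j, levels = seq_len(n_lvl)))
  if (any(set$counts == 0))
    stop("every latent-variable level needs at least one stimulus")
  if (is.null(block)) block <- max(1L, min(n_dec, floor(2^21 / n_ref)))

  grad <- matrix(0, d, q)
  total <- 0
  sgnM <- sign(M)
  for (start in seq(1L, n_dec, by = block)) {
    idx <- start:min(n_dec, start + block - 1L)
    Rb <- R[idx, , drop = FALSE]
    ll <- .log_likelihood_matrix(Rb, M, V)   # nb x n_ref
    log_Y <- .grouped_logsumexp(ll, groups)  # nb x n_lvl
    m <- apply(log_Y, 1, max)
    log_Z <- m + log(rowSums(exp(log_Y - m)))
    k <- dec$labels[idx]
    nb <- length(idx)
    wZ <- exp(ll - log_Z)                    # nb x n_ref

    if (spec$kind == "L0_KL") {
      log_Yk <- log_Y[cbind(seq_len(nb), k)]
      wY <- exp(ll - log_Yk)
      cmat <- wZ - wY * (matrix(lev_of_j, nb, n_ref, byrow = TRUE) == k)
      total <- total + sum(log_Z - log_Yk)
    } else {
      post <- exp(log_Y - log_Z)             # nb x n_lvl
      xhat <- drop(post %*% set$levels)
      err <- xhat - set$levels[k]
      cmat <- (2 * err) * wZ *
        (matrix(set$levels[lev_of_j], nb, n_ref, byrow = TRUE) - xhat)
      total <- total + sum(err^2)
    }

    for (t in seq_len(q)) {
      Dt <- outer(Rb[, t], M[, t], "-")
      DoV <- sweep(Dt, 2, V[, t], "/")
      Wt <- cmat * DoV
      # variance chain-rule term: a sign(m) (d^2 - v) / (2 v^2)
      At <- if (alpha > 0) {
        cmat * sweep(Dt^2, 2, V[, t], "-") *
          matrix(alpha * sgnM[, t] / (2 * V[, t]^2), nb, n_ref, byrow = TRUE)
      } else 0
      coef_ref <- colSums(Wt + At)
      coef_dec <- rowSums(Wt)
      grad[, t] <- grad[, t] + drop(crossprod(S, coef_ref)) -
        drop(crossprod(Sd[idx, , drop = FALSE], coef_dec))
    }
  }
  .ops_add(as.numeric(n_dec) * n_ref * n_lvl)
  list(grad = grad / n_dec, cost_at_point = total / n_dec)
}

#' Analytic gradient of the total KL-divergence (0-1) cost
#'
#' Gradient, with respect to every filter, of the mean negative
#' log-posterior at the correct level across the training set, evaluated
#' under the noiseless-mean-response approximation. The gradient chains
#' through the Gaussian means, the scaled-additive noise variances, and the
#' decoded responses themselves (see the header of this file).
#'
#' @param set a [labeled_stimulus_set()].
#' @param filters a [filter_bank()] (or d x q matrix).
#' @param noise a [noise_model()].
#' @param decode_set optional set of stimuli to decode against `set`
#'   (defaults to `set` itself; used by batch SGD).
#' @return list with `grad` (d x q matrix) and `cost_at_point` (scalar).
#' @export
grad_total_cost_kl <- function(set, filters, noise, decode_set = NULL) {
  .grad_total_cost(set, filters, noise, cost_spec("L0_KL"), decode_set)
}

#' Analytic gradient of the total squared-error cost
#'
#' Gradient of the mean squared error of the posterior-mean (MMSE) estimate
#' across the training set, under the noiseless-mean-response
#' approximation. Requires numeric latent values.
#'
#' @inheritParams grad_total_cost_kl
#' @return list with `grad` (d x q matrix) and `cost_at_point` (scalar).
#' @export
grad_total_cost_l2 <- function(set, filters, noise, decode_set = NULL) {
  .grad_total_cost(set, filters, noise, cost_spec("L2"), decode_set)
}

#' Central finite-difference gradient (verification oracle)
#'
#' Numerical gradient of an arbitrary scalar cost of the filter matrix, by
#' central differences per element: 2*d*q cost evaluations. This is the
#' standard check on the analytic expressions; it is also the reason the
#' analytic gradient matters, since finite differencing costs a factor of
#' the filter dimensionality more per gradient.
#'
#' @param cost_fn function taking a d x q filter matrix, returning a scalar.
#' @param filters d x q matrix at which to differentiate.
#' @param step finite-difference step (default 1e-6).
#' @return list with `grad` (d x q matrix) and `cost_at_point`.
#' @export
finite_difference_gradient <- function(cost_fn, filters, step = 1e-6) {
  stopifnot(step > 0)
  F <- unclass(as.matrix(filters))
  g <- matrix(NA_real_, nrow(F), ncol(F))
  for (j in seq_len(ncol(F))) {
    for (i in seq_len(nrow(F))) {
      Fp <- F; Fp[i, j] <- F[i, j] + step
      Fm <- F; Fm[i, j] <- F[i, j] - step
      g[i, j] <- (cost_fn(Fp) - cost_fn(Fm)) / (2 * step)
    }
  }
  list(grad = g, cost_at_point = cost_fn(F))
}
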