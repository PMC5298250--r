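# Encoding fidelity within the subspace spanned by a filter pair: rotation
# of the pair in its own 2-D subspace, Gram-Schmidt orthogonalization,
# noise-power matching between scaled and constant additive noise models,
# cost landscapes over rotation angle and angle difference, and the
# uncertainty-ellipse geometry mapping diagonal response noise from the
# filter basis into an orthonormal basis of the subspace.
#
# Angles are degrees at every interface (as in the figures the analysis
# produces); radians are used internally.

.deg2rad <- function(x) x * pi / 180

#' Orthonormal frame of a filter pair's subspace
#'
#' Builds an orthonormal basis E (d x 2) spanning the same subspace as the
#' unit-norm pair (f1, f2), with the first basis vector aligned with f1 so
#' that rotation angle 0 corresponds to the input pair. B = E'[f1 f2] holds
#' the pair's 2-D coordinates; its columns are unit norm and their inner
#' product equals the filter cosine similarity rho = f1'f2.
#'
#' @param f1,f2 unit-norm, linearly independent filter vectors.
#' @return object of class `subspace_frame`: list with `E` (d x 2), `B`
#'   (2 x 2), and `rho`.
#' @export
build_frame <- function(f1, f2) {
  f1 <- as.numeric(f1); f2 <- as.numeric(f2)
  stopifnot(length(f1) == length(f2))
  if (abs(sqrt(sum(f1^2)) - 1) > 1e-8 || abs(sqrt(sum(f2^2)) - 1) > 1e-8)
    stop("filters must have unit norm")
  rho <- sum(f1 * f2)
  e1 <- f1
  r2 <- f2 - rho * e1
  nrm <- sqrt(sum(r2^2))
  if (nrm < 1e-8)
    stop("filters are collinear: the spanned subspace is 1-dimensional")
  e2 <- r2 / nrm
  E <- cbind(e1, e2, deparse.level = 0)
  B <- crossprod(E, cbind(f1, f2, deparse.level = 0))
  structure(list(E = E, B = B, rho = rho), class = "subspace_frame")
}

#' @export
print.subspace_frame <- function(x, ...) {
  cat("subspace_frame: d =", nrow(x$E), ", rho =", signif(x$rho, 4),
      "(angle difference", signif(acos(x$rho) * 180 / pi, 4), "deg)\n")
  invisible(x)
}

#' Rotate a filter pair within its spanned subspace
#'
#' Applies a 2-D rotation by `theta_degrees` to the pair's coordinates and
#' maps back through the frame. Unit norms, the mutual angle (hence rho),
#' and the spanned subspace are all preserved; only the pair's orientation
#' within the subspace changes. A 180-degree rotation is a contrast
#' reversal of both filters, which the response model treats as an
#' identical encoding.
#'
#' @param frame a [build_frame()] result.
#' @param theta_degrees rotation angle in degrees.
#' @return d x 2 matrix of the rotated filter pair.
#' @export
rotate_pair <- function(frame, theta_degrees) {
  th <- .deg2rad(theta_degrees)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  frame$E %*% (R %*% frame$B)
}

#' Construct a pair at a given rotation angle and angle difference
#'
#' f1 = E (cos theta, sin theta)', f2 = E (cos(theta + delta),
#' sin(theta + delta))'. The resulting cosine similarity is cos(delta);
#' delta = 90 gives an orthogonal pair.
#'
#' @param frame a [build_frame()] result (only its basis `E` is used).
#' @param theta rotation angle, degrees.
#' @param delta angle difference, degrees, strictly inside (0, 180).
#' @return d x 2 matrix of the constructed pair.
#' @export
set_angle_difference <- function(frame, theta, delta) {
  if (delta <= 0 || delta >= 180)
    stop("delta must lie strictly between 0 and 180 degrees (collinear otherwise)")
  th <- .deg2rad(theta); dl <- .deg2rad(delta)
  frame$E %*% cbind(c(cos(th), sin(th)), c(cos(th + dl), sin(th + dl)))
}

#' Gram-Schmidt orthogonalization of a filter pair
#'
#' Keeps f1; removes f2's component along f1 and renormalizes. The result
#' is an orthonormal pair spanning the same subspace.
#'
#' @param f1,f2 unit-norm, linearly independent vectors.
#' @return d x 2 matrix with orthonormal columns.
#' @export
gram_schmidt_orthogonalize <- function(f1, f2) {
  fr <- build_frame(f1, f2)
  fr$E
}

#' Power-matched constant additive noise model
#'
#' Constant additive model whose variance equals the average scaled
#' additive variance over all (stimulus, filter) pairs:
#' sigma_const^2 = mean(alpha |r| + sigma0^2). Matching the overall noise
#' power makes costs under the two noise models directly comparable.
#'
#' @param set a [labeled_stimulus_set()].
#' @param filters a [filter_bank()].
#' @param scaled_noise a scaled-additive [noise_model()] (alpha > 0).
#' @return a constant-additive [noise_model()].
#' @export
matched_constant_noise <- function(set, filters, scaled_noise) {
  if (scaled_noise$fano_factor <= 0)
    stop("scaled_noise must have fano_factor > 0")
  v <- response_variances(mean_responses(filters, set), scaled_noise)
  noise_model(fano_factor = 0, baseline_var = mean(v),
              mode = "constant_additive")
}

#' Cost landscape over rotation angle (and angle difference)
#'
#' Total decoding cost of the filter pair as it is rotated within its
#' subspace. With `delta_grid = NULL` the pair itself is rotated (its angle
#' difference fixed at the input pair's); otherwise pairs are constructed
#' at every (theta, delta) combination via [set_angle_difference()].
#'
#' @param set a [labeled_stimulus_set()].
#' @param frame a [build_frame()] result.
#' @param theta_grid rotation angles, degrees (default 0, 5, ..., 355).
#' @param delta_grid angle differences, degrees, or NULL.
#' @param noise a [noise_model()].
#' @param spec a [cost_spec()].
#' @return object of class `rotation_landscape`: list with `theta_grid`,
#'   `delta_grid`, and `cost` (vector over theta, or matrix theta x delta).
#' @export
rotation_cost_landscape <- function(set, frame, theta_grid = seq(0, 355, by = 5),
                                    delta_grid = NULL,
                                    noise = noise_model(),
                                    spec = cost_spec("L0_KL")) {
  eval_pair <- function(pair)
    total_cost(set, filter_bank(pair), noise, spec)
  if (is.null(delta_grid)) {
    cost <- vapply(theta_grid, function(th)
      eval_pair(rotate_pair(frame, th)), numeric(1))
  } else {
    cost <- matrix(NA_real_, length(theta_grid), length(delta_grid))
    for (j in seq_along(delta_grid))
      cost[, j] <- vapply(theta_grid, function(th)
        eval_pair(set_angle_difference(frame, th, delta_grid[j])), numeric(1))
  }
  structure(list(theta_grid = theta_grid, delta_grid = delta_grid,
                 cost = cost),
            class = "rotation_landscape")
}

#' @export
print.rotation_landscape <- function(x, ...) {
  cat("rotation_landscape:", length(x$theta_grid), "rotation angles")
  if (!is.null(x$delta_grid))
    cat(" x", length(x$delta_grid), "angle differences")
  cat("; min cost", format(min(x$cost)), "\n")
  invisible(x)
}

#' Uncertainty ellipse of an encoded stimulus in the subspace basis
#'
#' Response noise is independent across filters (diagonal covariance in the
#' filter basis), but when the filters are correlated the implied
#' uncertainty about the stimulus's position in the orthonormal subspace
#' basis is an oblique ellipse. The linear map from filter responses to
#' subspace coordinates is u = B^-T r, so the noise covariance maps to
#' U = B^-T diag(sigma^2) B^-1. Oblique ellipse orientations produced this
#' way reflect filter correlation, not noise correlation.
#'
#' @param frame a [build_frame()] result.
#' @param mean_response length-2 vector of mean filter responses r.
#' @param variances length-2 vector of response noise variances.
#' @return list with `center` (2-vector, subspace coordinates) and
#'   `covariance` (2 x 2).
#' @export
uncertainty_ellipse <- function(frame, mean_response, variances) {
  stopifnot(length(mean_response) == 2, length(variances) == 2,
            all(variances > 0))
  if (abs(frame$rho) > 0.999)
    stop("filters too close to collinear (|rho| > 0.999): mapping is ill-conditioned")
  Binv <- solve(frame$B)
  center <- drop(t(Binv) %*% mean_response)
  covariance <- t(Binv) %*% diag(variances) %*% Binv
  list(center = center, covariance = covariance)
}
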