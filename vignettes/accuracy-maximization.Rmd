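---
title: "Learning task-optimal encoding filters with amasgd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning task-optimal encoding filters with amasgd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amasgd)
```

## The problem

A sensory system observes a high-dimensional proximal stimulus (an image
patch, a binocular signal pair) and must estimate a scalar latent variable
(a disparity, a speed) that is not available directly in any single
dimension of the stimulus. Accuracy maximization analysis asks: which small
set of linear receptive fields extracts the most useful information in the
stimulus *for that specific task*? Unlike PCA or ICA, which summarize the
stimulus ensemble regardless of what is to be estimated, the method scores
an encoding by how well an ideal Bayesian decoder estimates the latent
variable from the encoder's noisy responses, and descends that score
directly.

## The model

**Stimuli.** Training data are N stimulus vectors grouped into N_lvl
discrete levels of the latent variable X. Each stimulus is mean-subtracted
and scaled to unit Euclidean norm ("contrast normalized"). The relative
number of stimuli per level defines the prior, p(X_i) = N_i / N, which can
be manipulated by randomly culling stimuli per level
(`apply_prior_by_culling()`).

**Encoding.** q filters, each constrained to unit norm, respond with
r_t = f_t' s plus independent Gaussian noise whose variance grows linearly
with the mean response magnitude:

    sigma_t^2 = alpha * |r_t| + sigma_0^2 .

This "scaled additive" (Poisson-like) noise is the standard simple model of
response variability in early visual cortex. Defaults alpha = 1.36 and
sigma_0^2 = 0.23 (response units squared) are physiologically motivated
values; alpha = 0 gives the constant-additive special case. Noise is
independent across filters (diagonal covariance). Because both stimuli and
filters are unit norm, mean responses live in [-1, 1]; no physical
calibration of response units is attempted.

**Decoding.** The posterior over levels has a closed form: the sum of
within-level stimulus likelihoods over the sum of all stimulus likelihoods.
The counts-based prior and the uniform within-level stimulus probability
cancel, which is why no explicit density model of p(s | X) is needed — the
training set itself is the generative model. Two costs are supported: the
KL form of the 0-1 cost, −log p(X_correct | R), whose optimal readout is
the MAP level, and squared error of the posterior-mean (MMSE) estimate.
Expected cost is evaluated, by default, at the noiseless mean response of
each stimulus (`approx = TRUE`); a Monte-Carlo mode averaging over noisy
response draws is retained for verification.

On the approximation: the Monte-Carlo expectation and the noiseless-mean
evaluation agree to within a modest relative discrepancy at realistic noise
levels, but the gap is *not* guaranteed to vanish as the noise scale
shrinks — the curvature of the log posterior with respect to the response
grows like the inverse noise variance while the response scatter shrinks
like the variance, so their product (a Jensen-type correction) stays
roughly constant. The tests therefore assert bounded agreement rather than
convergence. Filter learning always uses the approximation.

## Gradients

The gradient of the total cost with respect to every filter is analytic,
which is what makes descent practical: finite differencing costs a factor
of the filter dimensionality more per gradient evaluation. Each stimulus
likelihood depends on a filter through the Gaussian mean, through the
scaled-additive variance (derivative alpha * sign(r) * s), and — under the
noiseless-mean evaluation — through the decoded response itself, which is a
filter output of the decoded stimulus. All three routes are chained
through; the implementation is validated against central finite differences
to relative error below 1e-4 (measured: ~1e-8) on randomized instances of
both cost functions. At r = 0 the derivative of |r| is taken to be 0
(a measure-zero event for continuous stimulus ensembles).

## Constrained descent

Filters live on the product of unit hyperspheres. Each iteration projects
the Euclidean gradient of every filter onto the tangent plane at that
filter, f_grd = f_euclid − (f' f_euclid) f, steps against the *jointly*
normalized stacked tangent gradient (so all filters share one descent
direction of unit length), and renormalizes each filter column. The
renormalization is the simplest retraction; the projected step leaves the
sphere only at second order, and restoring feasibility exactly keeps the
unit-norm invariant to 1e-12 throughout. Whether one renormalizes or uses
an exact geodesic retraction is immaterial at these step sizes; the
renormalization was chosen for simplicity.

The stochastic variant draws a *stratified* batch each iteration —
`batch_stimuli_per_level` stimuli uniformly without replacement from every
level — because batch sizes are conventionally quoted per level and a batch
missing a level entirely would break the posterior. A candidate step is
kept only if the cost *on that same batch* decreased; this guards against
"easy" batches masquerading as progress. The step size starts at
`step_size_init` (default 0.05, a tunable; the scale is set by unit-norm
filters) and decays 1% per iteration; the run stops at `max_iters`. The
landscape is non-convex, so `n_restarts` independent random initializations
(standard-normal, normalized) are run and the best final full-set cost
kept. The fixed decay schedule stops *near* a first-order point rather than
at one: tests verify that a further step at the final step size changes the
cost by less than 1e-4 relative, not that the raw gradient norm is tiny.

Complexity: evaluating all N posteriors against the full set costs
N^2 N_lvl likelihood operations (2 billion at N = 10,000, N_lvl = 20); one
pass of batches of size N_bch costs about N_bch N_lvl N — linear rather
than quadratic in N. The package instruments this accounting
(`ops_count()`, `count_operations_per_pass()`) rather than just asserting
it.

Batch size trades speed for fidelity. With ~1 stimulus per level per batch,
the level posterior degenerates to a stimulus posterior, the task
degenerates to stimulus identification, and the learned filters drift
toward PCA filters; with ≥30 stimuli per level they match full-batch
descent. Both effects are reproduced on the synthetic task below.

## The synthetic energy task

The natural-stimulus training sets the method is normally applied to are
out of scope here; `generate_energy_task_set()` emulates their essential
statistical structure instead. Each stimulus is two concatenated
half-windows modeled on a binocular pair: a Hann-windowed sinusoid with
uniformly random phase and log-uniform random amplitude (over one decade, a
free choice — the amplitude law of normalized natural stimuli is not
standardized), the second half phase-shifted by `shift_gain * X` plus
independent pixel noise (sd 0.1 relative to unit carrier amplitude), then
contrast normalized. Because the absolute phase is random, no linear
filter's *mean* response carries X; only the covariance of a quadrature
pair's responses does — the "energy-model" structure characteristic of
disparity and motion tasks.

Defaults mirror the scale of the disparity study the method is associated
with: 19 levels spanning −15..15 (arcmin-like units), 400 stimuli per level
(7,600 total), d = 16. `shift_gain` defaults to pi/30 so the +/-15 range
maps onto a +/-pi/2 relative phase sweep: mapping onto a full +/-pi sweep
would make the two extreme levels *identical* (a +pi and a −pi interocular
phase shift produce the same stimulus distribution — phase aliasing), so
the half-cycle sweep is the largest faithful choice. What the generator
does **not** emulate: natural amplitude spectra, spatial-frequency
diversity, broadband structure, or photoreceptor/optics front ends. Passing
tests on this task demonstrate the machinery — posterior, gradients,
constrained descent, batch-size effects — not performance on natural
stimuli.

Test and verification runs use reduced instances of the same generator
(typically 5 levels x 50–100 stimuli, d = 16), sizes chosen to exercise
every code path at desk scale.

## Subspace analyses

With noiseless (or constant-additive, orthogonal-filter) encodings, any
basis of a filter pair's 2-D subspace encodes equally well; scaled additive
noise breaks this degeneracy and makes the particular filters matter.
`build_frame()` erects an orthonormal basis with the first vector aligned
to filter 1 (so rotation angle 0 is the input pair), `rotate_pair()` and
`set_angle_difference()` parameterize pairs by orientation theta and mutual
angle delta (cosine similarity rho = cos delta), and
`rotation_cost_landscape()` maps cost over these. Exact symmetries serve as
verification: cost(theta) = cost(theta + 180) always (contrast reversal of
both filters; means negate, variances are even in the mean); an orthogonal
pair under scaled noise is 90-degree periodic (rotation by 90 permutes the
pair up to sign); an orthogonal pair under constant additive noise is
rotation invariant (isotropic Gaussian). For noise-model comparisons,
`matched_constant_noise()` equates the average noise power. On energy-like
tasks the scaled-additive landscape minimum sits below the power-matched
constant-additive minimum: scaled noise shrinks variance for
near-origin (hard) stimuli, aligning encoding uncertainty with
task-irrelevant stimulus variation. `uncertainty_ellipse()` maps the
diagonal response-noise covariance into the subspace basis
(U = B^-T diag(sigma^2) B^-1), showing how correlated filters tilt the
uncertainty ellipses even though the noise itself is independent.

## Numerical choices

- All likelihood arithmetic is in log space with log-sum-exp reductions;
  with thousands of stimuli, raw Gaussian densities underflow. The
  posterior's numerator/denominator decomposition is returned rescaled by
  the largest numerator so that Z = sum(Y) holds exactly in finite
  arithmetic.
- MAP ties break toward the lowest level index; PCA eigenvector signs are
  fixed by making the largest-magnitude element positive. Both choices are
  purely for determinism.
- Culling rounds desired counts to nearest and keeps at least one stimulus
  in any level with positive weight, since an empty level makes the
  posterior undefined.
- `set_angle_difference()` requires delta strictly inside (0, 180) and
  `uncertainty_ellipse()` refuses |rho| > 0.999: collinear pairs span a
  1-D subspace and the coordinate map becomes singular.
- Every sampling routine takes an explicit seed and restores the caller's
  RNG state; identical configuration and seed reproduce identical
  artifacts, byte for byte in the binary container.

## A short example

```{r example, eval = FALSE}
set <- generate_energy_task_set(
  energy_task_config(d = 16, n_levels = 5, n_per_level = 100, seed = 1))
noise <- noise_model()           # alpha = 1.36, sigma0^2 = 0.23
trace <- run_sgd(set, noise, sgd_config(q = 2, batch_stimuli_per_level = 30,
                                        max_iters = 200, seed = 1))
trace$final_cost                                  # learned encoding
total_cost(set, pca_baseline_filters(set, 2), noise)  # task-agnostic baseline
```

## Limitations

Responses are signed (no half-rectification) and response noise is
uncorrelated across filters, exactly as in the model definition; Poisson or
Bernoulli likelihoods are not implemented. Landscape analyses cover filter
pairs only. The step-size schedule is the fixed 1%-decay rule; adaptive
schemes are intentionally out of scope. Conclusions drawn from the
synthetic task transfer to natural stimuli only insofar as the
covariance-carried-information structure does.
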