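test_that("the posterior is the normalized sum of within-level likelihoods", {
  nm <- noise_model()
  # two levels, one stimulus each, response equidistant from both -> (.5, .5)
  s <- rbind(normalize_stimulus(c(1, 0, -1, 0)),
             -normalize_stimulus(c(1, 0, -1, 0)))
  set <- labeled_stimulus_set(s, 1:2, c(-1, 1))
  fb <- filter_bank(cbind(normalize_stimulus(c(0, 1, 0, -1))))
  post <- posterior_over_levels(0.0, set, fb, nm)
  expect_equal(post$posterior, c(0.5, 0.5))
  expect_equal(post$Z, sum(post$Y))

  # random instances: sums to 1, matches the long-form Bayes oracle
  for (seed in 1:8) {
    set <- random_set(d = 6, n_levels = 4, per_level = 3, seed = seed)
    fb <- random_filters(6, 2)
    set.seed(seed + 100)
    R <- runif(2, -1, 1)
    post <- posterior_over_levels(R, set, fb, nm)
    expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
    expect_equal(post$posterior, longform_posterior(R, set, fb, nm),
                 tolerance = 1e-10)
  }
})

test_that("the long-form oracle also agrees under a non-uniform prior", {
  nm <- noise_model()
  set <- random_set(d = 6, n_levels = 3, per_level = 20, seed = 41)
  culled <- apply_prior_by_culling(set, c(4, 2, 1), seed = 2)
  fb <- random_filters(6, 2)
  R <- c(0.2, -0.4)
  expect_equal(posterior_over_levels(R, culled, fb, nm)$posterior,
               longform_posterior(R, culled, fb, nm), tolerance = 1e-10)
})

test_that("with one stimulus per level the level posterior is the stimulus posterior", {
  nm <- noise_model()
  set <- random_set(d = 8, n_levels = 5, per_level = 1, seed = 3)
  fb <- random_filters(8, 2)
  R <- c(0.1, 0.6)
  post <- posterior_over_levels(R, set, fb, nm)
  means <- mean_responses(fb, set)
  vars <- response_variances(means, nm)
  ll <- vapply(1:5, function(j) log_likelihood(R, means[j, ], vars[j, ]),
               numeric(1))
  expect_equal(post$posterior, exp(ll) / sum(exp(ll)), tolerance = 1e-12)
})

test_that("MAP minimizes expected 0-1 cost; ties break to the lowest level", {
  expect_equal(map_estimate(c(0.2, 0.5, 0.3), levels = c(-1, 0, 1)), 0)
  expect_equal(map_estimate(c(0.5, 0.5), levels = c(-1, 1)), -1)
  set.seed(77)
  for (rep in 1:100) {
    p <- runif(5); p <- p / sum(p)
    lv <- sort(rnorm(5))
    est <- map_estimate(p, levels = lv)
    # exhaustive enumeration of every single-level choice
    exp01 <- 1 - p
    expect_equal(1 - p[match(est, lv)], min(exp01))
    expect_equal(zero_one_cost(p), min(exp01))
  }
})

test_that("the posterior mean minimizes expected squared error", {
  expect_equal(mmse_estimate(c(0.5, 0.5), levels = c(-1, 1)), 0)
  expect_equal(mmse_estimate(c(0, 1, 0), levels = c(-2, 3, 9)), 3)
  set.seed(78)
  for (rep in 1:100) {
    p <- runif(4); p <- p / sum(p)
    lv <- sort(runif(4, -2, 2))
    est <- mmse_estimate(p, levels = lv)
    grid <- seq(-2.5, 2.5, by = 0.001)
    exp_se <- vapply(grid, function(c) sum(p * (c - lv)^2), numeric(1))
    expect_lte(sum(p * (est - lv)^2), min(exp_se) + 1e-9)
  }
})

test_that("per-stimulus costs hit their closed-form special cases", {
  nm <- noise_model()
  set <- random_set(d = 6, n_levels = 4, per_level = 3, seed = 11)
  fb <- random_filters(6, 2)
  k <- kl_cost_stimulus(2, set, fb, nm)
  post <- posterior_over_levels(drop(set$stimuli[2, ] %*% unclass(fb)),
                                set, fb, nm)
  expect_equal(k, -log(post$posterior[set$labels[2]]), tolerance = 1e-12)
  expect_gte(k, 0)
  # uniform posterior costs log(N_lvl); point mass costs 0
  expect_equal(-log(1 / 4), log(4))

  l2 <- l2_cost_stimulus(2, set, fb, nm)
  xhat <- mmse_estimate(post)
  expect_equal(l2, (xhat - set$levels[set$labels[2]])^2, tolerance = 1e-12)

  # oracle chain: long-form posterior -> posterior mean -> squared error
  lp <- longform_posterior(drop(set$stimuli[2, ] %*% unclass(fb)), set, fb, nm)
  expect_equal(l2, (sum(lp * set$levels) - set$levels[set$labels[2]])^2,
               tolerance = 1e-10)
})

test_that("Monte-Carlo cost agrees with the noiseless-mean approximation", {
  # The approximation evaluates the posterior at the mean response instead
  # of averaging over noisy responses. The two agree to within a modest
  # relative discrepancy (the Jensen gap does not vanish with the noise
  # scale, because the log-posterior curvature grows as the noise shrinks),
  # and the Monte-Carlo estimate itself is stable across RNG streams.
  set <- random_set(d = 8, n_levels = 3, per_level = 4, seed = 19)
  fb <- random_filters(8, 2)
  nm <- noise_model()
  a <- kl_cost_stimulus(3, set, fb, nm, approx = TRUE)
  m <- kl_cost_stimulus(3, set, fb, nm, approx = FALSE, n_draws = 4000,
                        seed = 5)
  expect_lt(abs(m - a) / a, 0.25)
  m2 <- kl_cost_stimulus(3, set, fb, nm, approx = FALSE, n_draws = 4000,
                         seed = 6)
  expect_lt(abs(m2 - m) / m, 0.05)
  # same contract for the squared-error cost
  a2 <- l2_cost_stimulus(3, set, fb, nm, approx = TRUE)
  m3 <- l2_cost_stimulus(3, set, fb, nm, approx = FALSE, n_draws = 4000,
                         seed = 5)
  expect_lt(abs(m3 - a2) / a2, 0.25)
})

test_that("total cost averages per-stimulus costs and matches brute force", {
  nm <- noise_model()
  set <- random_set(d = 6, n_levels = 3, per_level = 4, seed = 29)
  fb <- random_filters(6, 2)
  expect_equal(total_cost(set, fb, nm), bruteforce_total_kl_cost(set, fb, nm),
               tolerance = 1e-10)
  # single-stimulus-per-level set: total equals the mean of stimulus costs
  per <- vapply(seq_along(set$labels), function(i)
    kl_cost_stimulus(i, set, fb, nm), numeric(1))
  expect_equal(total_cost(set, fb, nm), mean(per), tolerance = 1e-12)
  # duplicating every stimulus leaves the total cost unchanged
  dup <- labeled_stimulus_set(rbind(set$stimuli, set$stimuli),
                              c(set$labels, set$labels), set$levels)
  expect_equal(total_cost(dup, fb, nm), total_cost(set, fb, nm),
               tolerance = 1e-12)
})

test_that("KL cost is invariant to relabeling level values; L2 is not", {
  nm <- noise_model()
  set <- random_set(d = 6, n_levels = 3, per_level = 4, seed = 37)
  fb <- random_filters(6, 2)
  relab <- labeled_stimulus_set(set$stimuli, set$labels, c(10, -3, 2))
  expect_equal(total_cost(relab, fb, nm, cost_spec("L0_KL")),
               total_cost(set, fb, nm, cost_spec("L0_KL")))
  expect_gt(abs(total_cost(relab, fb, nm, cost_spec("L2")) -
                  total_cost(set, fb, nm, cost_spec("L2"))), 1e-3)
})

test_that("responses farther out along the manifold decode more confidently", {
  cfg <- energy_task_config(d = 16, n_levels = 5, n_per_level = 60, seed = 13)
  set <- generate_energy_task_set(cfg)
  fb <- quadrature_pair(cfg)
  nm <- noise_model()
  # scale a mid-level mean response outward; correct-level mass should trend up
  i <- which(set$labels == 3)[1]
  R0 <- drop(set$stimuli[i, ] %*% unclass(fb))
  mass <- vapply(c(0.5, 1, 2), function(sc)
    posterior_over_levels(sc * R0, set, fb, nm)$posterior[3], numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("operation counts follow the quadratic and linear laws", {
  expect_equal(operation_count_full(10000, 20), 2e9)
  expect_equal(operation_count_batch(100, 100, 7),
               operation_count_full(100, 7))
  expect_equal(operation_count_batch(1000, 50, 19) * 2,
               operation_count_batch(1000, 100, 19))
})
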