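test_that("tangent-plane projection removes the radial component", {
  f <- c(1, 0)
  expect_equal(project_gradient_to_tangent(f, c(1, 1)), c(0, 1))
  expect_equal(project_gradient_to_tangent(f, c(3, 0)), c(0, 0))
  expect_equal(project_gradient_to_tangent(f, c(0, 2)), c(0, 2))
  set.seed(83)
  for (rep in 1:20) {
    f <- normalize_stimulus(rnorm(8)); f <- f / sqrt(sum(f^2))
    g <- rnorm(8)
    t <- project_gradient_to_tangent(f, g)
    expect_lt(abs(sum(f * t)), 1e-12)
  }
})

test_that("a descent step stays on the unit sphere", {
  f <- c(1, 0)
  expect_equal(sgd_step(f, c(0, 1), 1), c(1, -1) / sqrt(2))
  expect_equal(sgd_step(f, c(0, 1), 0), f)
  expect_equal(sgd_step(f, c(0, 0), 0.5), f)   # converged direction: no-op
  set.seed(89)
  for (rep in 1:20) {
    f <- rnorm(6); f <- f / sqrt(sum(f^2))
    g <- project_gradient_to_tangent(f, rnorm(6))
    expect_equal(sqrt(sum(sgd_step(f, g, runif(1, 0, 0.5))^2)), 1,
                 tolerance = 1e-12)
  }
})

test_that("small steps along the projected gradient reduce the cost", {
  nm <- noise_model()
  set <- random_set(d = 8, n_levels = 3, per_level = 5, seed = 97)
  set.seed(4)
  F <- unclass(random_filters(8, 2))
  g <- grad_total_cost_kl(set, F, nm)
  tang <- sapply(1:2, function(t) project_gradient_to_tangent(F[, t], g$grad[, t]))
  gn <- sqrt(sum(tang^2))
  F_new <- sapply(1:2, function(t) sgd_step(F[, t], tang[, t], 1e-4, gn))
  expect_lt(total_cost(set, F_new, nm), g$cost_at_point)
})

test_that("batches are stratified with exact per-level composition", {
  set <- random_set(d = 6, n_levels = 4, per_level = 20, seed = 101)
  b <- sample_batch(set, 5, seed = 3)
  expect_equal(b$counts, rep(5L, 4))
  expect_identical(sample_batch(set, 5, seed = 3)$stimuli, b$stimuli)
  # per_level = full level count returns the whole set
  whole <- sample_batch(set, 20, seed = 1)
  expect_identical(whole$stimuli, set$stimuli)
  expect_error(sample_batch(set, 21), "exceeds")
  # 30 per level on 19 levels is the conventional 570-stimulus batch
  big <- random_set(d = 4, n_levels = 19, per_level = 30, seed = 5)
  expect_equal(nrow(sample_batch(big, 30)$stimuli), 570)
})

test_that("SGD maintains the constraint geometry at every iteration", {
  set <- small_energy_set(n_per_level = 20)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 2, batch_stimuli_per_level = 10,
                                    max_iters = 40, seed = 7))
  expect_lt(max(tr$max_norm_dev), 1e-10)
  expect_lt(max(tr$max_tangent_dot), 1e-12)
  expect_equal(sqrt(colSums(unclass(tr$filters)^2)), c(1, 1),
               tolerance = 1e-12)
})

test_that("accepted steps strictly reduce the same-batch cost", {
  set <- small_energy_set(n_per_level = 20)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 2, batch_stimuli_per_level = 5,
                                    max_iters = 60, seed = 11))
  acc <- which(tr$accepted)
  expect_gt(length(acc), 0)
  expect_true(all(tr$batch_cost[acc] < tr$batch_cost_pre[acc]))
  # step size decays by 1% per iteration
  expect_equal(tr$step_size, 0.05 * 0.99^(0:59), tolerance = 1e-12)
})

test_that("with the full set as batch, SGD equals full-batch descent", {
  set <- small_energy_set(n_per_level = 10)
  nm <- noise_model()
  cfgs <- sgd_config(q = 2, batch_stimuli_per_level = 10, max_iters = 25,
                     seed = 13)
  tr_sgd <- run_sgd(set, nm, cfgs)
  tr_full <- run_full_gd(set, nm, cfgs)
  expect_equal(unclass(tr_sgd$filters), unclass(tr_full$filters),
               tolerance = 1e-12)
  expect_equal(tr_sgd$batch_cost, tr_full$batch_cost, tolerance = 1e-12)
})

test_that("full-batch descent converges in cost to a first-order rest point", {
  set <- small_energy_set(n_per_level = 30)
  nm <- noise_model()
  set.seed(17)
  init <- random_filters(16, 2)
  g0 <- grad_total_cost_kl(set, init, nm)
  tr <- run_full_gd(set, nm, sgd_config(q = 2, max_iters = 200, seed = 17),
                    init_filters = init)
  expect_lt(tr$final_cost, g0$cost_at_point)
  # full-batch acceptance makes the trajectory monotone non-increasing
  expect_true(all(diff(tr$batch_cost) <= 1e-12))
  # first-order rest: another step along the steepest constrained descent
  # direction, at the final (decayed) step size, buys essentially nothing
  F <- unclass(tr$filters)
  g1 <- grad_total_cost_kl(set, F, nm)
  tang <- sapply(1:2, function(t)
    project_gradient_to_tangent(F[, t], g1$grad[, t]))
  gn <- sqrt(sum(tang^2))
  eps_final <- tr$step_size[length(tr$step_size)]
  F_more <- sapply(1:2, function(t) sgd_step(F[, t], tang[, t], eps_final, gn))
  gain <- tr$final_cost - total_cost(set, F_more, nm)
  expect_lt(abs(gain) / tr$final_cost, 1e-4)
})

test_that("SGD batch costs trend downward and stabilize", {
  set <- small_energy_set(n_per_level = 50)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 2, batch_stimuli_per_level = 30,
                                    max_iters = 120, seed = 19))
  n <- length(tr$batch_cost)
  early <- mean(tr$batch_cost[1:(n / 4)])
  late <- mean(tr$batch_cost[(3 * n / 4):n])
  expect_lt(late, early)
  # over the final quarter the batch costs have stabilized: no upward trend
  # beyond batch-to-batch noise (slope of a least-squares fit ~ 0)
  q4 <- tr$batch_cost[(3 * n / 4):n]
  slope <- coef(lm(q4 ~ seq_along(q4)))[2]
  expect_lt(abs(slope) * length(q4), 0.05 * mean(q4))
})

test_that("learned filters beat the PCA baseline on the energy task", {
  set <- small_energy_set(n_per_level = 50)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 2, batch_stimuli_per_level = 30,
                                    max_iters = 150, seed = 5))
  pca <- pca_baseline_filters(set, 2)
  expect_lt(tr$final_cost, total_cost(set, pca, nm))
})

test_that("multiple restarts keep the best final cost", {
  set <- small_energy_set(n_per_level = 15)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 1, batch_stimuli_per_level = 15,
                                    max_iters = 30, n_restarts = 3, seed = 23))
  expect_length(tr$restart_costs, 3)
  expect_equal(tr$final_cost, min(tr$restart_costs))
})

test_that("sequential-pairs mode freezes earlier filters", {
  set <- small_energy_set(n_per_level = 15)
  nm <- noise_model()
  tr <- run_sgd(set, nm, sgd_config(q = 4, batch_stimuli_per_level = 15,
                                    max_iters = 20, seed = 29,
                                    learn_mode = "sequential_pairs"))
  expect_equal(ncol(unclass(tr$filters)), 4)
  expect_lt(max(abs(sqrt(colSums(unclass(tr$filters)^2)) - 1)), 1e-10)
})

test_that("the instrumented counter reproduces the complexity laws", {
  nm <- noise_model()
  fb <- random_filters(6, 2)
  mk <- function(per) random_set(d = 6, n_levels = 5, per_level = per,
                                 seed = 31)
  s1 <- mk(40)   # N = 200
  s2 <- mk(80)   # N = 400
  full1 <- count_operations_per_pass(s1, fb, nm, full = TRUE)
  full2 <- count_operations_per_pass(s2, fb, nm, full = TRUE)
  expect_equal(full1, operation_count_full(200, 5))
  expect_equal(full2 / full1, 4)   # doubling N quadruples the full pass
  b1 <- count_operations_per_pass(s1, fb, nm, per_level = 10)
  b2 <- count_operations_per_pass(s2, fb, nm, per_level = 10)
  expect_equal(b1, operation_count_batch(200, 50, 5))
  expect_equal(b2 / b1, 2)         # doubling N doubles the batch pass
})
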