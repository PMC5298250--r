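# Shared fixture builders. All randomness is locally seeded so fixtures are
# reproducible and independent of test order.

# Tiny labeled set with random contrast-normalized stimuli.
random_set <- function(d = 6, n_levels = 3, per_level = 4, seed = 1,
                       levels = seq(-1, 1, length.out = n_levels)) {
  set.seed(seed)
  n <- n_levels * per_level
  s <- t(apply(matrix(rnorm(n * d), n, d), 1, normalize_stimulus))
  labeled_stimulus_set(s, rep(seq_len(n_levels), each = per_level), levels)
}

# Small energy-task set (the synthetic study conditions at reduced scale).
small_energy_set <- function(d = 16, n_levels = 5, n_per_level = 50,
                             seed = 3) {
  generate_energy_task_set(energy_task_config(
    d = d, n_levels = n_levels, level_range = c(-15, 15),
    n_per_level = n_per_level, seed = seed))
}

# Independent long-form Bayes posterior (explicit prior x within-level
# stimulus probability, raw densities): the oracle the closed-form
# sum-of-likelihoods expression must reproduce.
longform_posterior <- function(R, set, filters, noise) {
  means <- set$stimuli %*% unclass(filters)
  vars <- noise$fano_factor * abs(means) + noise$baseline_var
  lik <- vapply(seq_len(nrow(means)), function(j)
    prod(dnorm(R, means[j, ], sqrt(vars[j, ]))), numeric(1))
  n_lvl <- length(set$levels)
  prior <- set$counts / sum(set$counts)
  pXgivenR <- vapply(seq_len(n_lvl), function(i)
    sum(lik[set$labels == i]) / set$counts[i] * prior[i], numeric(1))
  pXgivenR / sum(pXgivenR)
}

# Brute-force total KL cost: explicit double loop over decoded stimuli and
# reference stimuli, raw densities, no shared code with the implementation.
bruteforce_total_kl_cost <- function(set, filters, noise) {
  F <- unclass(filters)
  n <- nrow(set$stimuli)
  costs <- numeric(n)
  for (i in seq_len(n)) {
    R <- drop(set$stimuli[i, ] %*% F)
    lik <- numeric(n)
    for (j in seq_len(n)) {
      m <- drop(set$stimuli[j, ] %*% F)
      v <- noise$fano_factor * abs(m) + noise$baseline_var
      lik[j] <- prod(dnorm(R, m, sqrt(v)))
    }
    Y <- sum(lik[set$labels == set$labels[i]])
    costs[i] <- -log(Y / sum(lik))
  }
  mean(costs)
}
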