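# Constrained filter learning: (stochastic) gradient descent on the
# product of unit hyperspheres. The unit-norm constraint means the descent
# direction must lie in the tangent plane of the sphere at the current
# filter; after each step the filters are renormalized (the simplest
# retraction, restoring feasibility exactly).

#' Project a Euclidean gradient onto the sphere's tangent plane
#'
#' f_grd = f_euclid - (f' f_euclid) f: removes the component of the
#' unconstrained gradient along the unit-norm filter itself, leaving the
#' direction of steepest constrained descent.
#'
#' @param f unit-norm filter vector.
#' @param grad_euclid gradient in the unconstrained space, same length.
#' @return vector orthogonal to `f`.
#' @export
project_gradient_to_tangent <- function(f, grad_euclid) {
  grad_euclid - drop(crossprod(f, grad_euclid)) * f
}

#' One constrained descent step for a single filter
#'
#' f_new = f - eps * f_grd / ||f_grd||, renormalized to unit norm. A zero
#' tangent gradient leaves the filter unchanged (a converged direction).
#'
#' @param f unit-norm filter vector.
#' @param f_grd tangent-plane gradient for this filter.
#' @param eps step size.
#' @param grad_norm norm to scale the step by; defaults to ||f_grd||. Joint
#'   multi-filter updates pass the stacked gradient norm here so that all
#'   filters share one normalized descent direction.
#' @return updated unit-norm filter vector.
#' @export
sgd_step <- function(f, f_grd, eps, grad_norm = sqrt(sum(f_grd^2))) {
  if (grad_norm == 0) return(f)
  f_new <- f - eps * f_grd / grad_norm
  f_new / sqrt(sum(f_new^2))
}

#' SGD configuration
#'
#' @param q number of filters to learn.
#' @param batch_stimuli_per_level stimuli drawn per level per batch
#'   (stratified sampling); batch size is this times the number of levels.
#' @param step_size_init initial step size eps0 (default 0.05).
#' @param step_decay fractional step-size decrease per iteration
#'   (default 0.01, i.e. 1% per iteration).
#' @param max_iters iteration limit (the stopping rule).
#' @param n_restarts independent random restarts; the restart with the best
#'   final full-training-set cost is kept.
#' @param seed integer seed controlling initialization and batch draws.
#' @param cost a [cost_spec()].
#' @param learn_mode "joint" (all q filters updated together, default) or
#'   "sequential_pairs" (filters learned two at a time, earlier pairs
#'   frozen).
#' @param track_full_cost record the full-training-set cost after each
#'   complete pass (adds full-set evaluations; off by default).
#' @return object of class `sgd_config`.
#' @export
sgd_config <- function(q = 2, batch_stimuli_per_level = 30,
                       step_size_init = 0.05, step_decay = 0.01,
                       max_iters = 200, n_restarts = 1, seed = 1,
                       cost = cost_spec("L0_KL"), learn_mode = "joint",
                       track_full_cost = FALSE) {
  if (step_decay <= 0 || step_decay >= 1) stop("step_decay must be in (0, 1)")
  if (batch_stimuli_per_level < 1) stop("batch_stimuli_per_level must be >= 1")
  learn_mode <- match.arg(learn_mode, c("joint", "sequential_pairs"))
  structure(list(q = as.integer(q),
                 batch_stimuli_per_level = as.integer(batch_stimuli_per_level),
                 step_size_init = step_size_init, step_decay = step_decay,
                 max_iters = as.integer(max_iters),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 cost = cost, learn_mode = learn_mode,
                 track_full_cost = isTRUE(track_full_cost)),
            class = "sgd_config")
}

#' Stratified batch sample
#'
#' Draws `per_level` stimuli uniformly without replacement from every
#' level, so each batch represents all latent-variable levels equally
#' (batch sizes are conventionally quoted as stimuli per level).
#'
#' @param set a [labeled_stimulus_set()].
#' @param per_level stimuli to draw per level; must not exceed any level's
#'   count.
#' @param seed optional integer seed.
#' @return a [labeled_stimulus_set()] with per_level * N_lvl stimuli.
#' @export
sample_batch <- function(set, per_level, seed = NULL) {
  if (per_level > min(set$counts))
    stop("per_level (", per_level, ") exceeds the smallest level count (",
         min(set$counts), ")")
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  keep <- unlist(lapply(seq_along(set$levels), function(i) {
    rows <- which(set$labels == i)
    if (per_level == length(rows)) rows else sample(rows, per_level)
  }))
  subset_stimuli(set, sort(keep))
}

.grad_for <- function(set, filters, noise, spec, decode_set = NULL) {
  if (spec$kind == "L0_KL")
    grad_total_cost_kl(set, filters, noise, decode_set)
  else
    grad_total_cost_l2(set, filters, noise, decode_set)
}

# One descent run (one restart). Batches are decoded against themselves,
# exactly as the full method decodes the training set against itself.
.descent_run <- function(set, noise, config, init_filters, full_batch) {
  F <- unclass(init_filters)
  d <- nrow(F); q <- ncol(F)
  eps <- config$step_size_init
  n_it <- config$max_iters
  trace <- list(batch_cost = numeric(n_it), batch_cost_pre = numeric(n_it),
                accepted = logical(n_it), step_size = numeric(n_it),
                max_norm_dev = numeric(n_it), max_tangent_dot = numeric(n_it))
  iters_per_pass <- if (full_batch) 1L else
    max(1L, floor(min(set$counts) / config$batch_stimuli_per_level))
  full_cost <- numeric(0)

  for (it in seq_len(n_it)) {
    batch <- if (full_batch) set else
      sample_batch(set, config$batch_stimuli_per_level)
    g <- .grad_for(batch, F, noise, config$cost)
    cost_pre <- g$cost_at_point
    # project every filter's gradient onto its tangent plane
    G <- g$grad
    tang <- sapply(seq_len(q), function(t)
      project_gradient_to_tangent(F[, t], G[, t]))
    tang <- matrix(tang, d, q)
    gnorm <- sqrt(sum(tang^2))
    trace$max_tangent_dot[it] <- if (gnorm > 0)
      max(abs(colSums(F * tang))) else 0
    if (gnorm > 0) {
      F_new <- matrix(sapply(seq_len(q), function(t)
        sgd_step(F[, t], tang[, t], eps, grad_norm = gnorm)), d, q)
      cost_post <- total_cost(batch, F_new, noise, config$cost)
      accept <- cost_post < cost_pre
      if (accept) F <- F_new
    } else {
      accept <- FALSE
      cost_post <- cost_pre
    }
    trace$batch_cost[it] <- if (accept) cost_post else cost_pre
    trace$batch_cost_pre[it] <- cost_pre
    trace$accepted[it] <- accept
    trace$step_size[it] <- eps
    trace$max_norm_dev[it] <- max(abs(sqrt(colSums(F^2)) - 1))
    eps <- eps * (1 - config$step_decay)
    if (config$track_full_cost && it %% iters_per_pass == 0L)
      full_cost <- c(full_cost, total_cost(set, F, noise, config$cost))
  }
  trace$full_cost_per_pass <- full_cost
  trace$filters <- filter_bank(F)
  trace
}

#' Learn filters by constrained stochastic gradient descent
#'
#' Iterates: draw a stratified batch, compute the batch cost and analytic
#' gradient, project each filter's gradient onto the tangent plane of the
#' unit sphere, take a normalized step, renormalize, and keep the update
#' only if the same batch's cost decreased. The step size decays by
#' `step_decay` each iteration and the run stops at `max_iters`. Because the
#' cost landscape is non-convex, `n_restarts` independent random
#' initializations are run and the restart with the lowest final
#' full-training-set cost is returned. Deterministic given `config$seed`.
#'
#' @param set a [labeled_stimulus_set()].
#' @param noise a [noise_model()].
#' @param config an [sgd_config()].
#' @param init_filters optional initial [filter_bank()] (one restart only).
#' @return object of class `training_trace`: list with `filters` (the
#'   learned bank), `final_cost` (full-set cost), per-iteration vectors
#'   `batch_cost`, `accepted`, `step_size`, `max_norm_dev`,
#'   `max_tangent_dot`, optional `full_cost_per_pass`, and `restart_costs`.
#' @export
run_sgd <- function(set, noise, config, init_filters = NULL) {
  .run_descent(set, noise, config, init_filters, full_batch = FALSE)
}

#' Learn filters by full-batch gradient descent
#'
#' The same constrained descent loop with the entire training set as the
#' batch on every iteration: the benchmark the stochastic variant is
#' compared against.
#'
#' @inheritParams run_sgd
#' @return a `training_trace` (see [run_sgd()]).
#' @export
run_full_gd <- function(set, noise, config, init_filters = NULL) {
  .run_descent(set, noise, config, init_filters, full_batch = TRUE)
}

.run_descent <- function(set, noise, config, init_filters, full_batch) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(config$seed)
  d <- ncol(set$stimuli)

  run_one <- function(init) {
    if (config$learn_mode == "sequential_pairs" && config$q > 2) {
      frozen <- NULL
      trace <- NULL
      for (start in seq(1L, config$q, by = 2L)) {
        nq <- min(2L, config$q - start + 1L)
        init_blk <- unclass(init)[, start:(start + nq - 1L), drop = FALSE]
        # frozen filters still shape the posterior: learn the new pair with
        # the frozen bank appended, but only update the new columns
        trace <- .descent_run_frozen(set, noise, config, init_blk, frozen,
                                     full_batch)
        frozen <- cbind(frozen, unclass(trace$filters))
      }
      trace$filters <- filter_bank(frozen)
      trace
    } else {
      .descent_run(set, noise, config, init, full_batch)
    }
  }

  if (!is.null(init_filters)) {
    traces <- list(run_one(filter_bank(as.matrix(init_filters))))
  } else {
    traces <- lapply(seq_len(config$n_restarts), function(r)
      run_one(random_filters(d, config$q)))
  }
  finals <- vapply(traces, function(tr)
    total_cost(set, tr$filters, noise, config$cost), numeric(1))
  best <- which.min(finals)
  out <- traces[[best]]
  out$final_cost <- finals[best]
  out$restart_costs <- finals
  class(out) <- "training_trace"
  out
}

# Sequential mode: learn `init_blk` columns while `frozen` columns are held
# fixed; gradients of frozen columns are zeroed.
.descent_run_frozen <- function(set, noise, config, init_blk, frozen,
                                full_batch) {
  if (is.null(frozen)) return(.descent_run(set, noise, config,
                                           filter_bank(init_blk), full_batch))
  nfroz <- ncol(frozen)
  F <- cbind(frozen, init_blk)
  d <- nrow(F); q <- ncol(F)
  eps <- config$step_size_init
  n_it <- config$max_iters
  trace <- list(batch_cost = numeric(n_it), accepted = logical(n_it),
                step_size = numeric(n_it), max_norm_dev = numeric(n_it),
                max_tangent_dot = numeric(n_it))
  for (it in seq_len(n_it)) {
    batch <- if (full_batch) set else
      sample_batch(set, config$batch_stimuli_per_level)
    g <- .grad_for(batch, F, noise, config$cost)
    G <- g$grad
    G[, seq_len(nfroz)] <- 0
    tang <- matrix(sapply(seq_len(q), function(t)
      project_gradient_to_tangent(F[, t], G[, t])), d, q)
    gnorm <- sqrt(sum(tang^2))
    trace$max_tangent_dot[it] <- if (gnorm > 0)
      max(abs(colSums(F * tang))) else 0
    if (gnorm > 0) {
      F_new <- matrix(sapply(seq_len(q), function(t)
        sgd_step(F[, t], tang[, t], eps, grad_norm = gnorm)), d, q)
      cost_post <- total_cost(batch, F_new, noise, config$cost)
      accept <- cost_post < g$cost_at_point
      if (accept) F <- F_new
    } else accept <- FALSE
    trace$batch_cost[it] <- if (accept) cost_post else g$cost_at_point
    trace$accepted[it] <- accept
    trace$step_size[it] <- eps
    trace$max_norm_dev[it] <- max(abs(sqrt(colSums(F^2)) - 1))
    eps <- eps * (1 - config$step_decay)
  }
  trace$filters <- filter_bank(F[, (nfroz + 1L):q, drop = FALSE])
  trace
}

#' @export
print.training_trace <- function(x, ...) {
  cat("training_trace:", length(x$batch_cost), "iterations,",
      sum(x$accepted), "accepted steps\n")
  cat("  final full-set cost:", format(x$final_cost), "\n")
  invisible(x)
}

#' Measured likelihood-evaluation operations for one pass
#'
#' Runs the instrumented counter over one pass of decoding: the full
#' training set against itself (`full = TRUE`, N^2 * N_lvl operations) or
#' k = N/N_bch stratified batches against themselves (about
#' N_bch * N_lvl * N operations). This measures what the decoder actually
#' did, for comparison with [operation_count_full()] /
#' [operation_count_batch()].
#'
#' @param set a [labeled_stimulus_set()].
#' @param filters a [filter_bank()].
#' @param noise a [noise_model()].
#' @param per_level batch size in stimuli per level (ignored when
#'   `full = TRUE`).
#' @param full evaluate the full set in one batch?
#' @return numeric operation count.
#' @export
count_operations_per_pass <- function(set, filters, noise, per_level = 30,
                                      full = FALSE) {
  ops_reset()
  if (full) {
    total_cost(set, filters, noise)
  } else {
    k <- floor(min(set$counts) / per_level)
    for (b in seq_len(max(1L, k))) {
      batch <- sample_batch(set, per_level, seed = b)
      total_cost(batch, filters, noise)
    }
  }
  n <- ops_count()
  ops_reset()
  n
}
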