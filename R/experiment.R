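# Experiment orchestration: one YAML config describes a full reproducible
# run (generate -> train -> evaluate -> optional landscape), and
# run_experiment() executes it, writing filters, traces, costs, and a
# manifest to an output directory.

#' Build a run configuration
#'
#' @param task either a list of [energy_task_config()] arguments (a set is
#'   generated) or a list with `file` (a stimulus-set path to load).
#' @param noise list of [noise_model()] arguments.
#' @param cost "L0_KL" or "L2".
#' @param optimizer list of [sgd_config()] arguments (without `cost`).
#' @param landscape optional list with `theta_grid` (and optionally
#'   `delta_grid`); computed on the two leading learned filters.
#' @param seed master seed; stage seeds are derived from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(task = list(), noise = list(), cost = "L0_KL",
                       optimizer = list(), landscape = NULL, seed = 1) {
  structure(list(task = task, noise = noise, cost = cost,
                 optimizer = optimizer, landscape = landscape,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with top-level keys `task`, `noise`, `cost`,
#'   `optimizer`, optional `landscape`, and `seed`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(task = y$task %||% list(), noise = y$noise %||% list(),
             cost = y$cost %||% "L0_KL", optimizer = y$optimizer %||% list(),
             landscape = y$landscape, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured run end to end
#'
#' Stages: obtain the training set (generate or load), learn filters by
#' stochastic gradient descent, evaluate per-stimulus and total costs, and
#' optionally compute a rotation landscape for the two leading filters.
#' Artifacts written to `out_dir`: `stimuli.txt` (generated sets only),
#' `filters.txt`, `trace.txt` (per-iteration log), `costs.txt`,
#' `landscape.txt` (optional), and `manifest.yaml` recording the config,
#' its hash, the seed, and package/R versions. Identical config and seed
#' reproduce identical artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the set, trace, costs, and paths.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  set <- stage("data", {
    if (!is.null(config$task$file)) {
      read_stimulus_set(config$task$file)
    } else {
      args <- config$task
      args$seed <- args$seed %||% config$seed
      s <- do.call(energy_task_config, args)
      s <- generate_energy_task_set(s)
      write_stimulus_set(s, file.path(out_dir, "stimuli.txt"))
      s
    }
  })

  noise <- do.call(noise_model, config$noise)
  opt_args <- config$optimizer
  opt_args$cost <- cost_spec(config$cost)
  opt_args$seed <- opt_args$seed %||% config$seed
  opt <- do.call(sgd_config, opt_args)

  trace <- stage("train", run_sgd(set, noise, opt))
  write_filters(trace$filters, file.path(out_dir, "filters.txt"))
  utils::write.table(
    data.frame(iteration = seq_along(trace$batch_cost),
               batch_cost = trace$batch_cost, accepted = trace$accepted,
               step_size = trace$step_size),
    file.path(out_dir, "trace.txt"), row.names = FALSE, quote = FALSE)

  costs <- stage("evaluate", {
    spec <- cost_spec(config$cost)
    per <- vapply(seq_along(set$labels), function(i)
      .cost_stimulus(i, set, trace$filters, noise, spec, TRUE, 0, NULL),
      numeric(1))
    list(per_stimulus = per, total = mean(per))
  })
  utils::write.table(
    data.frame(stimulus = seq_along(costs$per_stimulus),
               cost = costs$per_stimulus),
    file.path(out_dir, "costs.txt"), row.names = FALSE, quote = FALSE)
  say("total cost: ", format(costs$total))

  if (!is.null(config$landscape)) {
    stage("landscape", {
      F <- unclass(trace$filters)
      fr <- build_frame(F[, 1], F[, 2])
      th <- config$landscape$theta_grid %||% seq(0, 355, by = 5)
      ls <- rotation_cost_landscape(set, fr, theta_grid = th,
                                    delta_grid = config$landscape$delta_grid,
                                    noise = noise,
                                    spec = cost_spec(config$cost))
      df <- if (is.null(ls$delta_grid)) {
        data.frame(theta = ls$theta_grid, cost = ls$cost)
      } else {
        expand.grid(theta = ls$theta_grid, delta = ls$delta_grid) |>
          cbind(cost = as.vector(ls$cost))
      }
      utils::write.table(df, file.path(out_dir, "landscape.txt"),
                         row.names = FALSE, quote = FALSE)
    })
  }

  manifest <- list(
    config = unclass(config),
    config_hash = .config_hash(config),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("amasgd")),
    total_cost = costs$total
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("done; artifacts in ", out_dir)
  invisible(list(set = set, trace = trace, costs = costs, out_dir = out_dir))
}

# Deterministic hash of the config: a polynomial rolling hash (mod a
# Mersenne prime) over its serialized YAML text.
.config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
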