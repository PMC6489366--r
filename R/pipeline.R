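# Stage runner tying generators, gating, growth fitting, simulation and
# inference into configured, logged, reproducible runs.

pipeline_stages <- c("generate", "gate", "growth", "simulate", "sweep",
                     "fit", "compete")

# allowed config keys per stage (beyond the common ones)
stage_keys <- list(
  common = c("stage", "out_dir", "seed", "verbose"),
  generate = c("mechanism", "mean_lambda", "mean_gamma", "mean_omega",
               "sd_logit_lambda", "sd_log_gamma", "sd_logit_omega",
               "n_replicates", "n_passages", "dilution_factor",
               "tau_per_passage", "initial_fraction", "initial_total",
               "n_events", "noise", "phi", "bottleneck"),
  gate = c("events", "reference", "scatter_quantile", "min_events",
           "resolve_decades"),
  growth = c("input", "blank", "grid_size", "n_restarts"),
  simulate = c("lambda_loss", "gamma", "omega", "mechanism", "n_passages",
               "dilution_factor", "tau_per_passage", "initial_fraction",
               "initial_total"),
  sweep = c("lambda_loss", "gamma", "omega", "mechanism", "n_passages",
            "dilution_factor", "tau_per_passage", "initial_fraction",
            "initial_total", "parameter", "values"),
  fit = c("input", "mechanism", "n_chains", "n_steps", "n_walkers", "thin",
          "overlap_threshold", "n_passages", "dilution_factor",
          "tau_per_passage", "initial_fraction", "initial_total", "priors",
          "force", "n_predictive"),
  compete = c("input", "mechanism", "tau", "n_chains", "n_steps", "thin",
              "overlap_threshold", "priors")
)

config_protocol <- function(cfg, n_passages_default = 37) {
  passaging_protocol(
    dilution_factor = cfg$dilution_factor %||% 1000,
    n_passages = cfg$n_passages %||% n_passages_default,
    tau_per_passage = cfg$tau_per_passage %||%
      log(cfg$dilution_factor %||% 1000),
    initial_fraction = cfg$initial_fraction %||% 1,
    initial_total = cfg$initial_total %||% 1e9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_priors <- function(cfg) {
  if (is.null(cfg$priors)) return(prior_spec())
  do.call(prior_spec, lapply(cfg$priors, unlist))
}

#' Run one stage of the plasmid-stability pipeline
#'
#' Executes a configured stage (`generate`, `gate`, `growth`, `simulate`,
#' `sweep`, `fit` or `compete`), writing its artifacts, a log and an echo of
#' the configuration into `out_dir`. Unknown configuration keys are
#' rejected so that typos fail loudly rather than silently using defaults.
#'
#' @param config A named list of settings, or the path of a JSON file
#'   holding one. Required keys: `stage` and `out_dir`; `seed` defaults to
#'   1. Stage-specific keys are documented in the package vignette.
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a list with `status` (0 on success), `out_dir` and
#'   the paths of the artifacts written.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  if (is.null(config$stage) || !config$stage %in% pipeline_stages)
    stop("config$stage must be one of: ", paste(pipeline_stages, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stage <- config$stage
  allowed <- c(stage_keys$common, stage_keys[[stage]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  config$seed <- config$seed %||% 1

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
  }
  artifacts <- character(0)
  emit <- function(name, writer, obj) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    artifacts <<- c(artifacts, p)
    log_msg("wrote %s", p)
  }

  log_msg("stage '%s' (seed %s)", stage, format(config$seed))
  switch(stage,
    generate = {
      truth <- hierarchical_truth(
        mechanism = config$mechanism %||% "TA",
        mean_lambda = config$mean_lambda %||% 0.01,
        mean_gamma = config$mean_gamma %||% 0.9,
        mean_omega = config$mean_omega %||% 0.95,
        sd_logit_lambda = config$sd_logit_lambda %||% 0.3,
        sd_log_gamma = config$sd_log_gamma %||% 0.05,
        sd_logit_omega = config$sd_logit_omega %||% 0.3,
        n_replicates = config$n_replicates %||% 9,
        seed = config$seed)
      protocol <- config_protocol(config)
      synth <- generate_loss_curves(
        truth, protocol,
        n_events = config$n_events %||% 10000,
        noise = config$noise %||% "binomial",
        phi = config$phi %||% 500,
        bottleneck = isTRUE(config$bottleneck),
        seed = config$seed + 1L)
      emit("curves.csv", write_loss_curves, synth$curves)
      emit("truth.csv", write_csv_precise, synth$truth)
    },
    gate = {
      paths <- config$events
      if (is.null(paths)) stop("gate stage needs 'events': CSV path(s)")
      samples <- lapply(paths, read_events)
      names(samples) <- sub("\\.csv$", "", basename(unlist(paths)))
      curves <- batch_fractions(
        samples,
        reference = config$reference %||% 3,
        scatter_quantile = config$scatter_quantile %||% 0.05,
        min_events = config$min_events %||% 50,
        resolve_decades = config$resolve_decades %||% 0.2)
      emit("curves.csv", write_loss_curves, curves)
    },
    growth = {
      if (is.null(config$input)) stop("growth stage needs 'input': growth CSV")
      curve <- read_growth_curve(config$input)
      fit <- fit_growth_gp(curve, blank = config$blank %||% 0,
                           grid_size = config$grid_size %||% 200,
                           n_restarts = config$n_restarts %||% 5,
                           seed = config$seed)
      summ <- data.frame(label = curve$label[1L] %||% "sample",
                         mu_max = fit$mu_max, mu_max_sd = fit$mu_max_sd,
                         t_at_max = fit$t_at_max,
                         doubling_time = fit$doubling_time)
      emit("growth_fit.csv", write_csv_precise, summ)
      emit("growth_grid.csv", write_csv_precise, fit$grid)
    },
    simulate = {
      params <- psk_params(config$lambda_loss %||% 0.01,
                           config$gamma %||% 0.9,
                           config$omega %||% 0,
                           mechanism = config$mechanism %||% "NONE")
      curve <- simulate_loss_curve(params, config_protocol(config))
      emit("curves.csv", write_loss_curves, curve)
    },
    sweep = {
      params <- psk_params(config$lambda_loss %||% 0.01,
                           config$gamma %||% 0.9,
                           config$omega %||% 0,
                           mechanism = config$mechanism %||% "NONE")
      if (is.null(config$parameter) || is.null(config$values))
        stop("sweep stage needs 'parameter' and 'values'")
      sw <- parameter_sweep(params, config_protocol(config),
                            config$parameter, unlist(config$values))
      emit("sweep.csv", write_csv_precise, sw)
    },
    fit = {
      if (is.null(config$input)) stop("fit stage needs 'input': curves CSV")
      curves <- read_loss_curves(config$input)
      protocol <- config_protocol(config, n_passages_default = max(curves$passage))
      fit <- fit_hierarchical(
        curves, protocol, priors = config_priors(config),
        mechanism = config$mechanism %||% "TA",
        n_chains = config$n_chains %||% 4,
        n_steps = config$n_steps %||% 3000,
        n_walkers = config$n_walkers,
        thin = config$thin %||% 4,
        seed = config$seed,
        overlap_threshold = config$overlap_threshold %||% 0.35)
      log_msg("fit converged: %s (mean accept %.2f)", fit$converged,
              fit$settings$accept_rate)
      if (!fit$converged && !isTRUE(config$force))
        log_msg("warning: Rhat >= 1.01; summaries written but flagged")
      ps <- write_posterior(fit, out_dir)
      artifacts <- c(artifacts, ps)
      env <- posterior_predictive(fit, protocol,
                                  n_draws = config$n_predictive %||% 200,
                                  seed = config$seed, force = TRUE)
      emit("envelope.csv", write_csv_precise, env)
    },
    compete = {
      if (is.null(config$input)) stop("compete stage needs 'input': series CSV")
      series <- read_competition(config$input)
      fit <- fit_competition(
        series, priors = config_priors(config),
        mechanism = config$mechanism %||% "BACTERIOCIN",
        tau = config$tau %||% log(1000),
        n_chains = config$n_chains %||% 4,
        n_steps = config$n_steps %||% 2000,
        thin = config$thin %||% 2,
        seed = config$seed,
        overlap_threshold = config$overlap_threshold %||% 0.35)
      ps <- write_posterior(fit, out_dir)
      artifacts <- c(artifacts, ps)
    }
  )

  write_config(config, file.path(out_dir, "config.json"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(status = 0L, out_dir = out_dir,
                 artifacts = c(artifacts,
                               file.path(out_dir, "config.json"),
                               file.path(out_dir, "log.txt"))))
}
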