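# Configuration, presets, fixtures and experiment dispatch.
#
# Configs are plain YAML with four sections (model, protocol, noise, output)
# plus a top-level seed.  Unknown keys are rejected by name; omitted keys
# fall back to the standard defaults of each model.

config_schema <- list(
  model = c("type", "N", "winh", "tau", "beta", "Tu", "Td",
            "weight_family", "a", "b", "p", "amplitude", "width",
            "asymmetry_fraction", "weights", "n_dendrites",
            "nmda_exponent", "r_bound"),
  protocol = c("preset", "dt", "t_encode", "t_memory", "IA", "IA_grid",
               "center", "width", "settle", "stim_freqs", "stim_dur",
               "memory_dur", "freq_max", "freq_step", "dwell",
               "record_window", "mode"),
  noise = c("sigma", "sigma_list", "IA_list", "n_trials", "T",
            "s_values", "noise_during_encoding"),
  output = c("dir", "write_csv", "write_json"))

model_defaults <- list(
  ring = list(N = 360, winh = 1 / 360, tau = 50, beta = 1, Tu = 9, Td = 2,
              weight_family = "power_law", a = 18, b = 2, p = 2,
              asymmetry_fraction = 0, r_bound = 1000),
  rate_autapse = list(Tu = 9, Td = 2, beta = 1, tau = 50,
                      weight_family = "power_law", a = 18, b = 2, p = 2,
                      n_dendrites = 10),
  spiking_autapse = list(n_dendrites = 10, nmda_exponent = -0.54))

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration, rejects unknown keys by name, and fills in
#' the standard defaults for the chosen model type (ring defaults: `N = 360`,
#' `winh = 1/360`, `tau = 50` ms, `Tu = 9`, `Td = 2`).
#'
#' @param path path to a YAML file, or a list with the same structure.
#' @return a validated config list of class `experiment_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c(names(config_schema), "seed"))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(config_schema)) {
    keys <- names(cfg[[sec]])
    bad <- setdiff(keys, config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  type <- cfg$model$type
  if (is.null(type)) stop("missing required key: model$type")
  if (!type %in% names(model_defaults))
    stop("unknown model type: ", type)
  cfg$model <- modifyList(model_defaults[[type]],
                          cfg$model[setdiff(names(cfg$model), "type")])
  cfg$model$type <- type
  if (is.null(cfg$protocol)) cfg$protocol <- list()
  if (is.null(cfg$noise)) cfg$noise <- list(sigma = 0)
  if (is.null(cfg$noise$sigma)) cfg$noise$sigma <- 0
  if (is.null(cfg$output)) cfg$output <- list()
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Save a configuration
#'
#' Writes the resolved configuration back to YAML; `load_config()` of the
#' written file round-trips to the same resolved config.
#'
#' @param config an `experiment_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

config_weight_profile <- function(mod) {
  switch(mod$weight_family,
         power_law = weight_profile("power_law", a = mod$a, b = mod$b,
                                    p = mod$p, domain = 1000),
         gaussian = weight_profile("gaussian", amplitude = mod$amplitude,
                                   width = mod$width, domain = 1000),
         linear_design = design_linear_weights(),
         stop("unknown weight_family: ", mod$weight_family))
}

#' Figure-preset configurations
#'
#' `list_presets()` names the bundled experiment presets; `preset_config()`
#' returns the corresponding resolved configuration.  Each preset encodes
#' one of the standard protocols: the single-dendrite hysteresis sweep
#' (`fig2b`), the spiking graded-storage staircase (`fig2c`), the autapse
#' stimulus-memory mapping (`fig3f`), the ring encode/memory runs (`fig4c`),
#' the dense stimulus-memory mapping (`fig4d`, amplitudes 0 to 60 in steps
#' of 0.1), the linear-design mapping (`fig4fg`), band tracing (`fig5a`),
#' the amplitude-drift noise experiment (`fig6b`) and the location-diffusion
#' experiments without (`fig7ab`) and with (`fig7c`) weight asymmetry.
#'
#' @return `list_presets()`: character vector; `preset_config()`: an
#'   `experiment_config`.
#' @export
list_presets <- function() names(preset_registry)

#' @rdname list_presets
#' @param name preset name.
#' @export
preset_config <- function(name) {
  if (!name %in% names(preset_registry))
    stop("unknown preset: ", name)
  load_config(preset_registry[[name]])
}

preset_registry <- list(
  fig2b = list(model = list(type = "spiking_autapse"),
               protocol = list(preset = "hysteresis", freq_max = 70,
                               freq_step = 1, dwell = 1400,
                               record_window = 1000)),
  fig2c = list(model = list(type = "spiking_autapse"),
               protocol = list(preset = "graded_storage", settle = 1200,
                               stim_freqs = seq(20, 65, by = 5),
                               stim_dur = 400, memory_dur = 800)),
  fig3f = list(model = list(type = "rate_autapse", n_dendrites = 1000,
                            a = 18, b = 2, p = 1),
               protocol = list(preset = "ma_map",
                               IA_grid = seq(0, 60, by = 1))),
  fig4c = list(model = list(type = "ring"),
               protocol = list(preset = "encode_memory",
                               IA = c(8, 16, 24, 32), center = 180,
                               width = 10, t_encode = 1000,
                               t_memory = 1000, dt = 1)),
  fig4d = list(model = list(type = "ring"),
               protocol = list(preset = "ma_map",
                               IA_grid = seq(0, 60, by = 0.1),
                               center = 180, width = 10, dt = 1)),
  fig4fg = list(model = list(type = "ring", weight_family = "linear_design"),
                protocol = list(preset = "ma_map", IA_grid = 0:35,
                                center = 180, width = 10, dt = 1)),
  fig5a = list(model = list(type = "ring"),
               protocol = list(preset = "band_trace", IA = c(20, 40, 80),
                               dt = 0.01)),
  fig6b = list(model = list(type = "ring"),
               protocol = list(t_encode = 1000, t_memory = 10000, dt = 1),
               noise = list(sigma_list = c(3, 6, 9),
                            IA_list = c(10, 15, 20), n_trials = 10),
               seed = 1),
  fig7ab = list(model = list(type = "ring"),
                protocol = list(dt = 1),
                noise = list(sigma = 10, n_trials = 400, T = 10000,
                             s_values = 0:10),
                seed = 1),
  fig7c = list(model = list(type = "ring", asymmetry_fraction = 0.05),
               protocol = list(dt = 1),
               noise = list(sigma = 10, n_trials = 400, T = 10000,
                            s_values = c(0, 8)),
               seed = 1))

#' Deterministic miniature model fixtures
#'
#' Small instances with hand-enumerable behavior, used by the test suite
#' and useful for exploration:
#' * `two-unit-latch`: an autapse with weights `(3, 1.2)`, `Tu = 9`,
#'   `Td = 2`; its stable memory rates are exactly `{0, 1, 2}`.
#' * `tiny-autapse`: a six-dendrite power-law autapse.
#' * `tiny-ring`: a 24-neuron ring with the base power-law weights,
#'   rotation-equivariant by construction.
#'
#' @param name fixture name.
#' @return the model object.
#' @export
make_fixture <- function(name) {
  switch(name,
    "two-unit-latch" = autapse_model(c(3, 1.2), Tu = 9, Td = 2),
    "tiny-autapse" = autapse_model(18 / (0:5 + 2), Tu = 9, Td = 2),
    "tiny-ring" = ring_model(N = 24, winh = 1 / 24),
    stop("unknown fixture: ", name))
}

#' Run an experiment from a configuration
#'
#' Dispatches a validated configuration to the matching protocol, writes the
#' resolved config, tidy CSV results and a JSON summary into the output
#' directory, and returns a run record sufficient to re-execute the run.
#' All randomness is governed by the config seed.
#'
#' @param config an `experiment_config`, a list, or a path to a YAML file.
#' @param out_dir output directory (overrides `output$dir`; default
#'   `tempfile()`).
#' @return list of class `run_record`: the resolved `config`, `seed`,
#'   `files` written, package `version`, and the in-memory `result`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config
         else load_config(config)
  if (is.null(out_dir)) out_dir <- cfg$output$dir
  if (is.null(out_dir)) out_dir <- tempfile("dendband-run-")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pr <- cfg$protocol
  mod <- cfg$model
  dt <- if (is.null(pr$dt)) 1 else pr$dt

  result <- NULL
  csv <- NULL
  summary <- list()
  if (mod$type == "spiking_autapse") {
    params <- spiking_params(n_dendrites = mod$n_dendrites,
                             nmda_exponent = mod$nmda_exponent)
    if (identical(pr$preset, "hysteresis")) {
      result <- run_hysteresis_sweep(params,
        freq_max = if (is.null(pr$freq_max)) 70 else pr$freq_max,
        freq_step = if (is.null(pr$freq_step)) 1 else pr$freq_step,
        dwell = if (is.null(pr$dwell)) 1400 else pr$dwell,
        record_window = if (is.null(pr$record_window)) 1000
                        else pr$record_window)
      csv <- result$table
      summary$thresholds <- result$thresholds
    } else {
      result <- run_graded_storage(params,
        settle = if (is.null(pr$settle)) 1200 else pr$settle,
        stim_freqs = if (is.null(pr$stim_freqs)) seq(20, 65, 5)
                     else pr$stim_freqs,
        stim_dur = if (is.null(pr$stim_dur)) 400 else pr$stim_dur,
        memory_dur = if (is.null(pr$memory_dur)) 800 else pr$memory_dur)
      csv <- result$staircase
      summary$up_counts <- result$staircase$up_count
      summary$memory_rates <- result$staircase$memory_rate
    }
  } else if (mod$type == "rate_autapse") {
    prof <- config_weight_profile(mod)
    w <- weight_at(prof, seq_len(mod$n_dendrites) - 1)
    am <- autapse_model(w, Tu = mod$Tu, Td = mod$Td, beta = mod$beta,
                        tau = mod$tau)
    grid <- if (is.null(pr$IA_grid)) seq(0, 30, by = 1) else pr$IA_grid
    result <- stimulus_memory_map(am, grid, dt = dt)
    csv <- result
    summary$fixed_points <- autapse_fixed_points(am)
  } else if (mod$type == "ring") {
    prof <- if (mod$weight_family == "linear_design") design_linear_weights()
            else config_weight_profile(mod)
    rm_ <- ring_model(N = mod$N, profile = prof, winh = mod$winh,
                      tau = mod$tau, beta = mod$beta, Tu = mod$Tu,
                      Td = mod$Td,
                      asymmetry_fraction = mod$asymmetry_fraction,
                      r_bound = mod$r_bound)
    if (identical(pr$preset, "band_trace")) {
      traces <- lapply(pr$IA, function(ia)
        cbind(IA = ia,
              trace_band_simulated(rm_, "up", IA = ia, dt = dt)$trace))
      result <- do.call(rbind, traces)
      csv <- result
    } else if (identical(pr$preset, "ma_map") ||
               identical(pr$preset, "encode_memory")) {
      grid <- if (!is.null(pr$IA_grid)) pr$IA_grid else pr$IA
      ma <- vapply(grid, function(ia)
        run_encode_memory_ring(rm_, IA = ia,
                               center = if (is.null(pr$center)) 180
                                        else pr$center,
                               width = if (is.null(pr$width)) 10
                                       else pr$width,
                               t_encode = if (is.null(pr$t_encode)) 1000
                                          else pr$t_encode,
                               t_memory = if (is.null(pr$t_memory)) 1000
                                          else pr$t_memory,
                               dt = dt, thin = 0)$amplitude,
        numeric(1))
      result <- data.frame(IA = grid, MA = ma)
      csv <- result
      summary$MA <- ma
    } else if (!is.null(cfg$noise$s_values)) {
      result <- location_diffusion_experiment(
        s_values = cfg$noise$s_values, sigma = cfg$noise$sigma,
        n_trials = cfg$noise$n_trials, T = cfg$noise$T, dt = dt,
        seed = cfg$seed, N = mod$N, winh = mod$winh, tau = mod$tau,
        beta = mod$beta, asymmetry_fraction = mod$asymmetry_fraction)
      csv <- result$variance
      summary$final_variance <- result$final$var_location
    } else if (!is.null(cfg$noise$sigma_list)) {
      result <- amplitude_drift_experiment(
        rm_, sigma_list = cfg$noise$sigma_list, IA_list = cfg$noise$IA_list,
        n_trials = cfg$noise$n_trials, dt = dt, seed = cfg$seed,
        t_encode = if (is.null(pr$t_encode)) 1000 else pr$t_encode,
        t_memory = if (is.null(pr$t_memory)) 10000 else pr$t_memory)
      csv <- result$timeseries
      summary$survival <- result$survival$survived
    } else {
      mem <- run_encode_memory_ring(rm_,
        IA = if (is.null(pr$IA)) 32 else pr$IA[1],
        dt = dt, sigma = cfg$noise$sigma)
      result <- mem
      csv <- data.frame(neuron = seq_len(mod$N), rate = mem$memory_rates)
      summary$amplitude <- mem$amplitude
      summary$location <- mem$location
    }
  }

  files <- character(0)
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  files <- c(files, cfg_path)
  if (!is.null(csv) && !isFALSE(cfg$output$write_csv)) {
    csv_path <- file.path(out_dir, "result.csv")
    write.csv(csv, csv_path, row.names = FALSE)
    files <- c(files, csv_path)
  }
  if (!isFALSE(cfg$output$write_json)) {
    json_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(seed = cfg$seed, model = mod$type,
                              summary = summary),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    files <- c(files, json_path)
  }
  rec <- list(config = cfg, seed = cfg$seed, files = files,
              version = as.character(utils::packageVersion("dendband")),
              result = result)
  class(rec) <- "run_record"
  rec
}
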