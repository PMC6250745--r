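#' Default run configuration
#'
#' Mirrors the reference experimental setup: a 96 x 128 network with a
#' 15 x 15 connection field, beta/k = 100 (beta = 50, k = 0.5), 15
#' iterations per difference frame, stimulus gain 0.02 on 0-255
#' intensities, 8-bit fixed-point I/O and 256-fan-in/fan-out cores.
#'
#' @return nested configuration list
#' @export
default_run_config <- function() {
  list(
    grid = list(height = 96L, width = 128L),
    kernel = list(J0 = 1, a = 2, R = 15L),
    dynamics = list(beta = 50, k = 0.5, iterations_per_frame = 15L),
    stimulus = list(gain = 0.02),
    quantization = list(enabled = FALSE, io_bits = 8L),
    constraints = list(fan_in = 256L, fan_out = 256L),
    evaluation = list(protocol = "OPE", tre_segments = 20L),
    seed = 1L
  )
}

# deep-merge override values into a base list
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads the configuration file and fills unspecified keys from
#' [default_run_config()]. Recognized keys include `grid.height`,
#' `grid.width`, `kernel.J0`, `kernel.a`, `kernel.R`, `dynamics.beta`,
#' `dynamics.k`, `dynamics.iterations_per_frame` and `stimulus.gain`.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return configuration list
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

.cfg_objects <- function(cfg) {
  list(grid = grid_spec(cfg$grid$height, cfg$grid$width),
       kernel = kernel_spec(cfg$kernel$J0, cfg$kernel$a, cfg$kernel$R),
       params = dynamics_params(cfg$dynamics$beta, cfg$dynamics$k,
                                cfg$dynamics$iterations_per_frame),
       constraints = core_constraints(fan_in = cfg$constraints$fan_in,
                                      fan_out = cfg$constraints$fan_out))
}

#' Generate and write a synthetic sequence (CLI backend)
#'
#' @param out_dir output sequence directory (OTB layout)
#' @param config path to a YAML config or a config list
#' @param n_frames,seed generator overrides
#' @return the output path, invisibly
#' @export
cmd_synth <- function(out_dir, config = NULL, n_frames = 40L, seed = NULL) {
  cfg <- if (is.list(config)) .merge_config(default_run_config(), config)
         else load_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  sc <- synthetic_scene_config(n_frames = n_frames, seed = cfg$seed)
  video <- generate_synthetic_video(sc)
  write_otb_sequence(video, out_dir)
  message(sprintf("wrote %d frames + ground truth to %s", n_frames, out_dir))
  invisible(out_dir)
}

#' Track a sequence and evaluate (CLI backend)
#'
#' Loads an OTB-layout sequence, runs the selected backend, writes the
#' predicted trajectory (CSV) and metric summaries, and returns the metric
#' list.
#'
#' @param seq_dir sequence directory
#' @param out_dir output directory for trajectory and metrics
#' @param config YAML path or config list
#' @param mode `"float"`, `"quantized"` or `"mapped"`
#' @return metrics from [run_ope()], invisibly
#' @export
cmd_track <- function(seq_dir, out_dir = seq_dir, config = NULL,
                      mode = c("float", "quantized", "mapped")) {
  mode <- match.arg(mode)
  cfg <- if (is.list(config)) .merge_config(default_run_config(), config)
         else load_run_config(config)
  ob <- .cfg_objects(cfg)
  sequence <- load_otb_sequence(seq_dir)
  tracker <- cann_tracker(ob$grid, ob$kernel, ob$params,
                          gain = cfg$stimulus$gain, mode = mode,
                          constraints = ob$constraints)
  pred <- tracker(sequence$frames, as.numeric(sequence$gt[1, c("x", "y", "w", "h")]))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pred, file.path(out_dir, sprintf("trajectory_%s.csv", mode)),
                   row.names = FALSE)
  metrics <- .metric_curves(pred[, c("x", "y", "w", "h")], sequence$gt)
  export_metrics(metrics, file.path(out_dir, sprintf("metrics_%s", mode)))
  message(sprintf("[%s] AUC %.3f, mean center error %.2f px",
                  mode, metrics$auc, metrics$mean_delta))
  invisible(metrics)
}

#' Plan a mapping and report resources (CLI backend)
#'
#' @param config YAML path or config list
#' @param out optional path for the placement JSON
#' @return the [resource_report()], invisibly; the report is printed
#' @export
cmd_plan <- function(config = NULL, out = NULL) {
  cfg <- if (is.list(config)) .merge_config(default_run_config(), config)
         else load_run_config(config)
  ob <- .cfg_objects(cfg)
  placement <- plan_full_mapping(ob$grid, ob$kernel, ob$constraints)
  viol <- validate_placement(placement)
  if (length(viol) > 0) stop(paste(viol, collapse = "\n"), call. = FALSE)
  if (!is.null(out)) write_placement_json(placement, out)
  rep <- resource_report(placement)
  print(rep)
  invisible(rep)
}
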