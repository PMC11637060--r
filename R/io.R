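# Serialization: phantom specs as JSON, datasets on disk, SoS maps and PA
# images as 32-bit TIFF, model checkpoints with a JSON sidecar.

#' Serialize a phantom spec to JSON
#'
#' @param spec a [phantom_spec()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
spec_to_json <- function(spec, path = NULL) {
  x <- unclass(spec)
  x$inclusions <- lapply(x$inclusions, unclass)
  x$layers <- lapply(x$layers %||% list(), unclass)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a phantom spec from JSON
#'
#' @param json a JSON string or file path.
#' @return A [phantom_spec()].
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  phantom_spec(
    background_sos = x$background_sos,
    inclusions = lapply(x$inclusions, function(i) {
      ellipse_inclusion(i$center, i$semi_axes, i$orientation, i$sos,
                        i$echogenicity)
    }),
    layers = if (length(x$layers)) lapply(x$layers, function(l) {
      layer_inclusion(l$z_top, l$sos, l$amplitude, l$periods, l$phase,
                      l$echogenicity)
    }) else NULL,
    scatterer_density = x$scatterer_density,
    pattern_id = x$pattern_id, rng_seed = x$rng_seed
  )
}

#' Write an RF dataset to disk
#'
#' Stores the RF array (`N x 128 x 1024`), the SoS labels
#' (`N x 384 x 384`), the seed and the JSON-serialized specs in one
#' container, mirroring the logical acquisition layout.
#'
#' @param dataset an `rf_dataset` from [simulate_rf_dataset()].
#' @param path output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_rf_dataset <- function(dataset, path) {
  obj <- list(rf = dataset$rf, sos_label = dataset$labels,
              spec = vapply(dataset$specs, function(s)
                as.character(spec_to_json(s)), character(1)),
              seed = dataset$seed, sim_settings = dataset$sim_settings)
  saveRDS(obj, path)
  invisible(path)
}

#' Read an RF dataset from disk
#'
#' @param path file written by [write_rf_dataset()].
#' @return An `rf_dataset`.
#' @export
read_rf_dataset <- function(path) {
  obj <- readRDS(path)
  structure(list(rf = obj$rf, labels = obj$sos_label,
                 specs = lapply(obj$spec, spec_from_json),
                 seed = obj$seed, sim_settings = obj$sim_settings),
            class = "rf_dataset")
}

#' Export a SoS map or PA image as 32-bit float TIFF
#'
#' @param x a [sos_map()], [pa_image()] or matrix.
#' @param path output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_tiff32 <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  v <- if (inherits(x, "pa_image")) x$values else as.matrix(unclass(x))
  storage.mode(v) <- "double"
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Save a model checkpoint with a JSON sidecar
#'
#' @param fit a fit object from [train_sosnet()] / [fine_tune()], or a bare
#'   `sosnet`.
#' @param path checkpoint path (`.rds`); the sidecar is written to
#'   `paste0(path, ".json")` and the history (if any) to `paste0(path,
#'   ".history.csv")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "sosnet")) fit else fit$model
  saveRDS(model, path)
  side <- list(seed = model$seed,
               params = count_params(model),
               head = !is.null(model$head),
               enc_widths = model$cfg$enc_widths,
               dec_widths = model$cfg$dec_widths)
  if (!inherits(fit, "sosnet") && !is.null(fit$history)) {
    side$best_epoch <- fit$best_epoch
    side$final_train_rmse <- tail(fit$history$train_rmse, 1)
    side$final_valid_rmse <- tail(fit$history$valid_rmse, 1)
    utils::write.csv(fit$history, paste0(path, ".history.csv"),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return A `sosnet`.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a simulation profile as YAML
#'
#' Stores the scalar settings of a [sim_profile()] (grid size and spacing,
#' CFL number, absorbing-layer thickness, transmit frequency and burst
#' length, recorded time, noise settings, reconstruction spacing) in a
#' human-editable YAML file.
#'
#' @param sim a [sim_profile()] list.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_sim_profile <- function(sim, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for YAML profiles")
  }
  cfg <- list(grid_n = sim$grid$nz, dx = sim$grid$dx, pml = sim$grid$pml,
              cfl = sim$grid$cfl, c_max = sim$grid$c_max, fc = sim$fc,
              n_cycles = sim$n_cycles, t_end = sim$t_end,
              snr_range = sim$snr_range,
              use_system_noise = sim$use_system_noise,
              autofocus_step = sim$autofocus_step,
              recon_dx = sim$recon$dx)
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Read a simulation profile from YAML
#'
#' @param path file written by [write_sim_profile()].
#' @return A [sim_profile()] list.
#' @export
read_sim_profile <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for YAML profiles")
  }
  cfg <- yaml::read_yaml(path)
  sim_profile(grid_n = cfg$grid_n, fc = cfg$fc, recon_dx = cfg$recon_dx,
              t_end = cfg$t_end, snr_range = unlist(cfg$snr_range),
              use_system_noise = cfg$use_system_noise,
              autofocus_step = cfg$autofocus_step, n_cycles = cfg$n_cycles)
}
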