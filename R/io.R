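#' Configuration, containers and export formats
#'
#' Experiment configuration is a flat YAML (or JSON) file; a completed run
#' is written as one RDS container (maps, activity, traces, provenance)
#' with NIfTI parametric maps and CSV traces as interchange views.
#'
#' @name io_cli
#' @keywords internal
NULL

.default_config <- function() {
  list(
    geometry = "small",
    frame_durations_s = NULL,            # NULL -> 24-frame default scheme
    feng = unclass(default_feng_input()),
    kinetics = list(gray = unclass(table1_kinetics()$gray),
                    white = unclass(table1_kinetics()$white)),
    phantom_preset = "default",
    attenuation_mu = 0.098,
    decay_const = fdg_decay_const(),
    noise_fractions = c(0.1, 0.2, 0.4, 0.8),
    n_outer = 10,
    n_em = 2,
    n_reps = 20,
    seed = 1,
    target_msin = 200,
    scatter_frac = 0.5
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a flat YAML/JSON configuration, fills missing keys with the
#' packaged defaults (scaled-down geometry, 24-frame scheme, reference
#' kinetics and bolus input), and rejects unknown keys so typos cannot pass
#' silently. Validation errors name the offending key.
#'
#' @param path config file path, or NULL for the pure defaults
#' @return an `experiment_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- tryCatch(
      if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE) else
          yaml::read_yaml(path),
      error = function(e) stop("cannot parse ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!is.list(user)) stop("config file must contain a key-value mapping")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (!cfg$geometry %in% c("full", "small", "tiny"))
    stop("config key 'geometry' must be one of full/small/tiny")
  if (any(cfg$noise_fractions < 0) || any(cfg$noise_fractions > 1))
    stop("config key 'noise_fractions' must lie in [0, 1]")
  if (any(cfg$n_outer < 1)) stop("config key 'n_outer' must be >= 1")
  if (cfg$n_em < 1) stop("config key 'n_em' must be >= 1")
  if (cfg$n_reps < 1) stop("config key 'n_reps' must be >= 1")
  req_feng <- c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3", "t0")
  if (!all(req_feng %in% names(cfg$feng)))
    stop("config key 'feng' must provide ", paste(req_feng, collapse = ","))
  for (rg in c("gray", "white"))
    if (!all(c("K1", "k2", "k3", "k4", "fv") %in% names(cfg$kinetics[[rg]])))
      stop("config key 'kinetics$", rg, "' must provide K1,k2,k3,k4,fv")
  structure(cfg, class = "experiment_config")
}

#' Materialize the objects described by a configuration
#'
#' @param cfg an `experiment_config`
#' @return list with grid, sino, system model (with attenuation), phantom,
#'   frame scheme, Feng input and decay constant
#' @export
build_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  geo <- geometry_preset(cfg$geometry)
  fs <- if (is.null(cfg$frame_durations_s)) default_frame_scheme() else {
    end <- cumsum(cfg$frame_durations_s) / 60
    frame_scheme(c(0, end[-length(end)]), end)
  }
  fi <- do.call(feng_input, cfg$feng)
  params <- list(gray = do.call(kinetic_params, cfg$kinetics$gray),
                 white = do.call(kinetic_params, cfg$kinetics$white))
  ph <- make_phantom(geo$grid, cfg$phantom_preset, params)
  att <- attenuation_map(geo$grid, cfg$attenuation_mu,
                         support = ph$label > 0L)
  sm <- build_system(geo$grid, geo$sino, att)
  list(grid = geo$grid, sino = geo$sino, sm = sm, ph = ph, fs = fs,
       fi = fi, dk = cfg$decay_const)
}

## Stable hash of an R object (via serialization to a temp file).
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write a parametric map as NIfTI
#'
#' The voxel size is the grid spacing `fov/n` in cm (stored in the NIfTI
#' pixdim fields).
#'
#' @param map n x n matrix
#' @param grid the `image_grid` the map lives on
#' @param path output path (.nii or .nii.gz)
#' @return `path`, invisibly
#' @export
write_map_nifti <- function(map, grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  img <- RNifti::asNifti(array(map, dim = c(grid$n, grid$n, 1)),
                         reference = list(
                           pixdim = c(-1, grid$d, grid$d, 1, 0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the outputs of a reconstruction run
#'
#' Creates `dir` and writes: `run.rds` (the full container: maps, activity,
#' traces, provenance), one NIfTI per parametric map, `trace.csv` with the
#' per-iteration log-likelihood (and MSE when available), and
#' `provenance.json` (config hash, seed, package version).
#'
#' @param state a `recon_state`
#' @param dir output directory
#' @param config the `experiment_config` used (hashed into provenance)
#' @return named list of written paths, invisibly
#' @export
write_outputs <- function(state, dir, config = NULL) {
  stopifnot(inherits(state, "recon_state"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("output directory is not writable: ", dir)
  paths <- list()
  for (p in names(state$maps))
    paths[[paste0("map_", p)]] <-
      write_map_nifti(state$maps[[p]], state$grid,
                      file.path(dir, paste0(p, ".nii.gz")))
  tr <- data.frame(iteration = seq_along(state$loglik),
                   loglik = state$loglik)
  if (!is.null(state$mse_trace))
    tr <- cbind(tr, as.data.frame(state$mse_trace))
  paths$trace <- file.path(dir, "trace.csv")
  utils::write.csv(tr, paths$trace, row.names = FALSE)
  prov <- list(config_hash = if (is.null(config)) NA_character_ else
                 .config_hash(unclass(config)),
               seed = state$seed,
               noise_fraction = state$noise_fraction,
               package_version =
                 as.character(utils::packageVersion("dynpet")))
  paths$provenance <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       null = "null")
  paths$container <- file.path(dir, "run.rds")
  saveRDS(list(state = state, provenance = prov), paths$container)
  invisible(paths)
}

#' Read back a run container
#'
#' @param dir directory previously written by [write_outputs()]
#' @return list with `state` and `provenance`
#' @export
read_container <- function(dir) {
  f <- file.path(dir, "run.rds")
  if (!file.exists(f)) stop("no run container under ", dir)
  readRDS(f)
}

#' Export ROI metrics in long format
#'
#' @param state a `recon_state`
#' @param ph the `phantom` providing labels and truth
#' @param path output CSV path
#' @return the metrics data frame, invisibly
#' @export
write_metrics_csv <- function(state, ph, path) {
  truth <- phantom_truth_maps(ph)
  stats <- roi_stats(state$maps, ph$label)
  regions <- list(gray = ph$label == 1L, white = ph$label == 2L)
  stats$mse <- mapply(function(p, rg)
    mse_map(truth[[p]], state$maps[[p]], regions[[rg]]),
    stats$parameter, stats$region)
  stats$noise_fraction <- state$noise_fraction
  stats$iteration <- state$config$n_outer
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(stats)
}
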