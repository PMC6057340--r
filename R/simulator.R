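#' Dynamic PET simulation
#'
#' End-to-end generation of a dynamic brain-like PET acquisition: a
#' procedural two-region phantom, per-voxel activity from the analytic
#' compartment model, and Poisson sinograms with attenuation, a smooth
#' scatter term, uniform randoms and radioactive decay.
#'
#' @name simulator
#' @keywords internal
NULL

#' Procedural two-region brain-like phantom
#'
#' A deterministic stand-in for a segmented brain slice: an elliptical head
#' whose outer shell is gray matter and whose interior two-lobe structure is
#' white matter. Each region carries the reference kinetic parameter set
#' (see [table1_kinetics()]).
#'
#' @param grid an `image_grid`
#' @param preset phantom preset id; currently `"default"`
#' @param params named list with `gray` and `white` `kinetic_params`
#' @return a `phantom`: label image (0 background, 1 gray, 2 white) plus
#'   per-label parameters
#' @export
make_phantom <- function(grid, preset = "default",
                         params = table1_kinetics()) {
  stopifnot(inherits(grid, "image_grid"))
  if (!identical(preset, "default")) stop("unknown phantom preset: ", preset)
  if (!all(c("gray", "white") %in% names(params)))
    stop("params must provide gray and white kinetic_params")
  R <- grid$fov / 2
  x <- grid$xc / R; y <- grid$yc / R    # normalized [-1, 1] coordinates
  head <- (x / 0.70)^2 + (y / 0.56)^2 <= 1
  lobe_l <- ((x + 0.24) / 0.30)^2 + (y / 0.36)^2 <= 1
  lobe_r <- ((x - 0.24) / 0.30)^2 + (y / 0.36)^2 <= 1
  white <- (lobe_l | lobe_r) & head
  label <- integer(grid$J)
  label[head] <- 1L
  label[white] <- 2L
  structure(list(label = matrix(label, grid$n, grid$n), grid = grid,
                 params = list(gray = params$gray, white = params$white),
                 preset = preset),
            class = "phantom")
}

#' Ground-truth parametric maps of a phantom
#'
#' @param ph a `phantom`
#' @return named list of n x n matrices K1, k2, k3, k4, fv, Ki
#' @export
phantom_truth_maps <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  n <- ph$grid$n
  out <- list()
  for (p in c("K1", "k2", "k3", "k4", "fv")) {
    m <- matrix(0, n, n)
    m[ph$label == 1L] <- ph$params$gray[[p]]
    m[ph$label == 2L] <- ph$params$white[[p]]
    out[[p]] <- m
  }
  ki <- matrix(0, n, n)
  ki[ph$label == 1L] <- ki_macro(ph$params$gray)
  ki[ph$label == 2L] <- ki_macro(ph$params$white)
  out$Ki <- ki
  out
}

#' Simulate noiseless dynamic activity from a phantom
#'
#' Every labeled voxel receives the analytic model TAC of its region's
#' kinetic parameters (decay-corrected tissue response plus blood term);
#' background stays zero.
#'
#' @param ph a `phantom`
#' @param fi a `feng_input`
#' @param fs a `frame_scheme`
#' @param dk decay constant (min^-1)
#' @return a `dyn_image`: J x M activity matrix plus grid and scheme
#' @export
simulate_activity <- function(ph, fi = default_feng_input(),
                              fs = default_frame_scheme(),
                              dk = fdg_decay_const()) {
  stopifnot(inherits(ph, "phantom"))
  tac_g <- tissue_tac_analytic(ph$params$gray, fi, fs, dk)$values
  tac_w <- tissue_tac_analytic(ph$params$white, fi, fs, dk)$values
  X <- matrix(0, ph$grid$J, fs$n_frames)
  lab <- as.vector(ph$label)
  X[lab == 1L, ] <- matrix(tac_g, sum(lab == 1L), fs$n_frames, byrow = TRUE)
  X[lab == 2L, ] <- matrix(tac_w, sum(lab == 2L), fs$n_frames, byrow = TRUE)
  structure(list(values = X, grid = ph$grid, scheme = fs,
                 feng = fi, dk = dk),
            class = "dyn_image")
}

## Smooth (scatter-like) sinogram: Gaussian blur along the radial dimension.
.blur_radial <- function(S, nbins, sd_bins = 8) {
  half <- ceiling(3 * sd_bins)
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  apply_one <- function(col) {
    m <- matrix(col, nbins)
    nang <- ncol(m)
    padded <- rbind(matrix(0, half, nang), m, matrix(0, half, nang))
    out <- apply(padded, 2, function(v) stats::filter(v, k, sides = 2))
    out[(half + 1):(half + nbins), , drop = FALSE]
  }
  res <- apply(S, 2, function(col) as.vector(apply_one(col)))
  matrix(res, nrow(S), ncol(S))
}

#' Simulate a dynamic Poisson sinogram series
#'
#' Projects the dynamic activity through the system model, calibrates a
#' global count scale, adds an additive expectation `r` made of a smooth
#' scatter component (Gaussian-blurred true sinogram) and flat randoms, and
#' draws Poisson counts. The additive term's expectation per frame equals
#' `noise_fraction` times `mSin`, the mean of that frame's noiseless true
#' sinogram.
#'
#' @param sm a `system_model`
#' @param dyn a `dyn_image`
#' @param noise_fraction scatter+randoms fraction of `mSin` in `[0, 1]`
#' @param seed master RNG seed; per-frame substreams are derived from it
#' @param count_scale global calibration factor mapping projected activity
#'   to expected counts; if NULL, chosen so that the largest frame has
#'   `mSin = target_msin`
#' @param target_msin target mean counts/bin in the highest-count frame
#' @param scatter_frac share of the additive budget given to scatter (the
#'   remainder is uniform randoms)
#' @param sample if FALSE, return the noiseless expectation instead of
#'   Poisson draws
#' @return a `dyn_sinogram`: integer (or noiseless) counts `y` (I x M), the
#'   additive expectation `r`, per-frame `msin`, and the calibration
#' @export
simulate_sinograms <- function(sm, dyn, noise_fraction, seed,
                               count_scale = NULL, target_msin = 200,
                               scatter_frac = 0.5, sample = TRUE) {
  stopifnot(inherits(sm, "system_model"), inherits(dyn, "dyn_image"))
  if (noise_fraction < 0) stop("noise_fraction must be nonnegative")
  if (noise_fraction > 1) stop("noise_fraction must not exceed 1")
  if (scatter_frac < 0 || scatter_frac > 1)
    stop("scatter_frac must lie in [0, 1]")
  proj <- forward_project(sm, dyn$values)          # I x M, activity units
  if (is.null(count_scale)) {
    peak <- max(colMeans(proj))
    if (peak <= 0) stop("cannot calibrate counts for an empty phantom")
    count_scale <- target_msin / peak
  }
  ybar <- proj * count_scale
  msin <- colMeans(ybar)
  M <- ncol(ybar)
  r <- matrix(0, nrow(ybar), M)
  if (noise_fraction > 0) {
    smooth <- .blur_radial(ybar, sm$sino$nbins)
    smooth_mean <- colMeans(smooth)
    for (m in seq_len(M)) {
      sc <- if (smooth_mean[m] > 0)
        smooth[, m] * (scatter_frac * noise_fraction * msin[m] /
                         smooth_mean[m]) else 0
      r[, m] <- sc + (1 - scatter_frac) * noise_fraction * msin[m]
    }
  }
  y <- ybar + r
  if (sample) {
    set.seed(seed)
    frame_seeds <- sample.int(.Machine$integer.max, M)
    for (m in seq_len(M)) {
      set.seed(frame_seeds[m])
      y[, m] <- stats::rpois(nrow(y), y[, m])
    }
  }
  structure(list(y = y, r = r, scheme = dyn$scheme, sino = sm$sino,
                 count_scale = count_scale, msin = msin,
                 noise_fraction = noise_fraction, seed = seed,
                 sampled = sample),
            class = "dyn_sinogram")
}

#' @export
print.dyn_sinogram <- function(x, ...) {
  cat(sprintf("Dynamic sinogram: %d bins x %d angles x %d frames, noise %.0f%% of mSin, seed %s\n",
              x$sino$nbins, x$sino$nangles, x$scheme$n_frames,
              100 * x$noise_fraction, format(x$seed)))
  invisible(x)
}

#' Monte-Carlo repetition of the simulation + reconstruction pipeline
#'
#' Repeats simulate-and-reconstruct with independent seeds and summarizes
#' the per-parameter map MSE (optionally per region) across replicates.
#' Failed replicates are reported in the result, never dropped silently.
#'
#' @param sm a `system_model`
#' @param ph a `phantom`
#' @param fi,fs,dk input model, frame scheme, decay constant
#' @param noise_fraction additive-term fraction of mSin
#' @param n_reps number of replicates
#' @param seeds integer vector of length `n_reps` (master seed per replicate)
#' @param cfg a `recon_config`
#' @param ... further arguments to [simulate_sinograms()]
#' @return a `mc_result`: per-replicate final maps, per-replicate and
#'   summary (mean/sd over replicates) MSE per parameter and region, and
#'   the per-iteration MSE traces
#' @export
run_monte_carlo <- function(sm, ph, fi = default_feng_input(),
                            fs = default_frame_scheme(),
                            dk = fdg_decay_const(),
                            noise_fraction = 0.1, n_reps = 3,
                            seeds = seq_len(n_reps),
                            cfg = recon_config(), ...) {
  stopifnot(inherits(ph, "phantom"))
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (length(seeds) != n_reps) stop("seeds must have length n_reps")
  truth <- phantom_truth_maps(ph)
  dyn <- simulate_activity(ph, fi, fs, dk)
  regions <- list(gray = ph$label == 1L, white = ph$label == 2L)
  pars <- c("K1", "k2", "k3", "k4", "fv", "Ki")
  reps <- vector("list", n_reps)
  errors <- character(0)
  rows <- list()
  for (rep in seq_len(n_reps)) {
    res <- tryCatch({
      sg <- simulate_sinograms(sm, dyn, noise_fraction, seed = seeds[rep],
                               ...)
      icm_em(sm, sg, fi, fs, dk, cfg, truth = truth)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("replicate %d (seed %s): %s", rep,
                                  format(seeds[rep]), conditionMessage(res)))
      reps[[rep]] <- NULL
      next
    }
    reps[[rep]] <- res
    maps <- res$maps
    for (p in pars) for (rg in names(regions)) {
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep, seed = seeds[rep], parameter = p, region = rg,
        mse = mse_map(truth[[p]], maps[[p]], regions[[rg]]))
    }
  }
  if (length(errors))
    warning("failed replicates:\n", paste(errors, collapse = "\n"))
  per_rep <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(per_rep)) {
    summary <- stats::aggregate(mse ~ parameter + region, per_rep,
                                function(v) c(mean = mean(v), sd = stats::sd(v)))
    summary <- data.frame(summary[c("parameter", "region")],
                          mse_mean = summary$mse[, "mean"],
                          mse_sd = summary$mse[, "sd"])
  }
  structure(list(replicates = reps, mse = per_rep, summary = summary,
                 failed = errors, noise_fraction = noise_fraction,
                 seeds = seeds),
            class = "mc_result")
}
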