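#' Evaluation metrics for parametric maps
#'
#' @name metrics
#' @keywords internal
NULL

#' Mean squared error between two maps
#'
#' `MSE = mean((true - est)^2)` over the masked voxels. By default the mask
#' should be the phantom support (background is never fitted, so including
#' it would deflate the error arbitrarily).
#'
#' @param true_map,est_map matrices on the same grid
#' @param mask logical matrix/vector selecting the voxels to compare; NULL
#'   means all voxels
#' @return the mean squared difference (nonnegative scalar)
#' @export
mse_map <- function(true_map, est_map, mask = NULL) {
  if (!all(dim(true_map) == dim(est_map)))
    stop("maps must share the same grid")
  if (is.null(mask)) mask <- rep(TRUE, length(true_map))
  mask <- as.vector(mask)
  if (!any(mask)) stop("mask selects no voxels")
  d <- as.vector(true_map)[mask] - as.vector(est_map)[mask]
  mean(d^2)
}

#' Normalized log-likelihood trace
#'
#' Rescales a log-likelihood trace to `[0, 1]` via
#' `(L - Lmin) / (Lmax - Lmin)`, where the extremes are taken over the
#' trace itself. Invariant under affine transformations of the trace.
#'
#' @param trace numeric log-likelihood values, one per iteration
#' @return normalized trace in `[0, 1]`
#' @export
norm_loglik <- function(trace) {
  if (length(trace) < 2) stop("trace must have at least 2 values")
  lmin <- min(trace); lmax <- max(trace)
  if (lmax <= lmin) stop("constant trace cannot be normalized")
  (trace - lmin) / (lmax - lmin)
}

#' Per-region statistics of parametric maps
#'
#' Arithmetic mean and (sample, n-1) standard deviation of each map over
#' each labeled region.
#'
#' @param maps named list of matrices (e.g. K1..k4, fv, Ki)
#' @param labels integer label matrix on the same grid (0 = background)
#' @param which_labels named integer vector of labels to evaluate; default
#'   `c(gray = 1, white = 2)`
#' @return data frame with columns region, parameter, mean, sd, n_voxels
#' @export
roi_stats <- function(maps, labels, which_labels = c(gray = 1L, white = 2L)) {
  if (!length(maps) || is.null(names(maps)))
    stop("maps must be a named list of matrices")
  lab <- as.vector(labels)
  rows <- list()
  for (rg in names(which_labels)) {
    sel <- lab == which_labels[[rg]]
    if (!any(sel))
      stop("label ", which_labels[[rg]], " (", rg, ") selects no voxels")
    for (p in names(maps)) {
      v <- as.vector(maps[[p]])[sel]
      rows[[length(rows) + 1]] <- data.frame(
        region = rg, parameter = p, mean = mean(v), sd = stats::sd(v),
        n_voxels = sum(sel))
    }
  }
  do.call(rbind, rows)
}
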