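#' ICM-EM direct parametric reconstruction
#'
#' Alternating two-step estimation of voxel-wise kinetic parameter maps
#' directly from dynamic sinogram counts: (i) a bounded nonlinear
#' least-squares fit of the analytic compartment model to each voxel's
#' provisional activity TAC, and (ii) MLEM-style multiplicative Poisson
#' updates of the activity, restarted each cycle from the model-predicted
#' activity.
#'
#' @name reconstruction
#' @keywords internal
NULL

#' Reconstruction configuration
#'
#' @param n_outer number of outer (alternating) iterations
#' @param n_em EM sub-iterations per outer iteration (default 2)
#' @param lower,upper box bounds for `[K1, k2, k3, k4, fv]`; defaults are
#'   0..10 for the rate constants and 0..1 for fv
#' @param init_k initial value for all rate constants (default 0.1)
#' @param init_fv initial fractional blood volume (default 0.1)
#' @param init_x initial activity inside the FOV (default 1.0)
#' @param nls_max_iter per-voxel optimizer iteration cap
#' @param nls_ftol relative decrease of the voxel objective below which the
#'   voxel is considered converged
#' @param nls_ptol step-size tolerance on the parameters
#' @return a `recon_config`
#' @export
recon_config <- function(n_outer = 10, n_em = 2,
                         lower = c(0, 0, 0, 0, 0),
                         upper = c(10, 10, 10, 10, 1),
                         init_k = 0.1, init_fv = 0.1, init_x = 1.0,
                         nls_max_iter = 50, nls_ftol = 1e-8,
                         nls_ptol = 1e-8) {
  if (n_outer < 1 || n_em < 1) stop("n_outer and n_em must be at least 1")
  if (length(lower) != 5 || length(upper) != 5 || any(lower >= upper))
    stop("bounds must be length-5 with lower < upper")
  structure(list(n_outer = as.integer(n_outer), n_em = as.integer(n_em),
                 lower = lower, upper = upper, init_k = init_k,
                 init_fv = init_fv, init_x = init_x,
                 nls_max_iter = as.integer(nls_max_iter),
                 nls_ftol = nls_ftol, nls_ptol = nls_ptol),
            class = "recon_config")
}

## Solve the V stacked 5x5 SPD systems (A[v,,] ) x[v,] = b[v,] by a
## vectorized Cholesky factorization: every scalar operation of the fixed
## 5x5 recursion is carried out on length-V vectors at once.
.chol_solve_batch <- function(A, b) {
  P <- dim(A)[2]
  V <- dim(A)[1]
  L <- array(0, c(V, P, P))
  for (j in seq_len(P)) {
    s <- A[, j, j]
    if (j > 1) for (k in seq_len(j - 1)) s <- s - L[, j, k]^2
    L[, j, j] <- sqrt(pmax(s, 1e-300))
    if (j < P) for (i in (j + 1):P) {
      s <- A[, i, j]
      if (j > 1) for (k in seq_len(j - 1)) s <- s - L[, i, k] * L[, j, k]
      L[, i, j] <- s / L[, j, j]
    }
  }
  y <- matrix(0, V, P)
  for (i in seq_len(P)) {
    s <- b[, i]
    if (i > 1) for (k in seq_len(i - 1)) s <- s - L[, i, k] * y[, k]
    y[, i] <- s / L[, i, i]
  }
  x <- matrix(0, V, P)
  for (i in rev(seq_len(P))) {
    s <- y[, i]
    if (i < P) for (k in (i + 1):P) s <- s - L[, k, i] * x[, k]
    x[, i] <- s / L[, i, i]
  }
  x
}

## Batched box-constrained Levenberg-Marquardt over independent voxels.
## xhat: V x M target TACs; theta0: V x 5 starting points. All voxels are
## iterated simultaneously: the model and its finite-difference Jacobian
## are evaluated as V x M matrix operations and the 5x5 normal equations
## are solved per voxel. A step is accepted only if it lowers that voxel's
## sum of squares, so the per-voxel objective never increases.
.batch_nls <- function(xhat, theta0, fi, tmid, dk, cfg) {
  V <- nrow(xhat); M <- ncol(xhat); P <- 5L
  lower <- cfg$lower; upper <- cfg$upper
  theta <- theta0
  fitted <- .model_tac_matrix(theta, fi, tmid, dk)
  sse <- rowSums((fitted - xhat)^2)
  lambda <- rep(1e-3, V)
  active <- rep(TRUE, V)
  n_fail <- 0L
  for (it in seq_len(cfg$nls_max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    th <- theta[idx, , drop = FALSE]
    res <- fitted[idx, , drop = FALSE] - xhat[idx, , drop = FALSE]
    ## forward-difference Jacobian, one batched model call per parameter
    Jcols <- vector("list", P)
    h <- matrix(0, length(idx), P)
    for (p in seq_len(P)) {
      hp <- 1e-6 * pmax(abs(th[, p]), 0.01)
      hp <- ifelse(th[, p] + hp > upper[p], -hp, hp)
      thp <- th
      thp[, p] <- thp[, p] + hp
      Jcols[[p]] <- (.model_tac_matrix(thp, fi, tmid, dk) -
                       fitted[idx, , drop = FALSE]) / hp
      h[, p] <- hp
    }
    ## per-voxel normal equations with Marquardt damping
    g <- matrix(0, length(idx), P)      # J^T r
    A <- array(0, c(length(idx), P, P)) # J^T J
    for (p in seq_len(P)) {
      g[, p] <- rowSums(Jcols[[p]] * res)
      for (q in p:P) {
        v <- rowSums(Jcols[[p]] * Jcols[[q]])
        A[, p, q] <- v
        A[, q, p] <- v
      }
    }
    ## damped normal matrix; the damping diagonal is floored so parameters
    ## the model is currently insensitive to (zero Jacobian column) cannot
    ## make the system singular, keeping it SPD for the batched Cholesky
    dgmax <- pmax(A[, 1, 1], A[, 2, 2], A[, 3, 3], A[, 4, 4], A[, 5, 5],
                  1e-12)
    Ad <- A
    for (p in seq_len(P))
      Ad[, p, p] <- A[, p, p] +
        lambda[idx] * pmax(A[, p, p], 1e-10 * dgmax, 1e-12)
    step <- .chol_solve_batch(Ad, -g)
    cand <- pmin(pmax(th + step, matrix(lower, length(idx), P, byrow = TRUE)),
                 matrix(upper, length(idx), P, byrow = TRUE))
    fit_cand <- .model_tac_matrix(cand, fi, tmid, dk)
    sse_cand <- rowSums((fit_cand - xhat[idx, , drop = FALSE])^2)
    better <- sse_cand < sse[idx]
    moved <- rowSums(abs(cand - th)) > 0
    acc <- which(better & moved)
    rej <- which(!(better & moved))
    if (length(acc)) {
      ai <- idx[acc]
      improve <- (sse[ai] - sse_cand[acc]) <= cfg$nls_ftol * pmax(sse[ai], 1e-30)
      small <- rowSums(abs(cand[acc, , drop = FALSE] -
                             th[acc, , drop = FALSE])) < cfg$nls_ptol
      theta[ai, ] <- cand[acc, , drop = FALSE]
      fitted[ai, ] <- fit_cand[acc, , drop = FALSE]
      sse[ai] <- sse_cand[acc]
      lambda[ai] <- pmax(lambda[ai] / 3, 1e-12)
      active[ai[improve | small]] <- FALSE
    }
    if (length(rej)) {
      ri <- idx[rej]
      lambda[ri] <- lambda[ri] * 10
      active[ri[lambda[ri] > 1e8]] <- FALSE
    }
  }
  n_fail <- sum(active)
  list(theta = theta, sse = sse, n_active = n_fail)
}

#' Kinetic-fitting step of ICM-EM
#'
#' Fits the bounded two-tissue model to every voxel TAC of the provisional
#' activity estimate by batched Levenberg-Marquardt in kinetic-constant
#' space (the model itself is always evaluated through the auxiliary
#' parameterization and the analytic convolution). Steps are accepted only
#' when they reduce the voxel's residual sum of squares, so each voxel's
#' objective is monotone non-increasing from its starting point; a voxel
#' whose optimization fails keeps its previous parameters.
#'
#' @param xhat V x M matrix of provisional voxel TACs (fitted voxels only)
#' @param theta V x 5 matrix of starting parameters `[K1,k2,k3,k4,fv]`
#' @param fi a `feng_input`
#' @param tmid frame mid-times (min)
#' @param dk decay constant (min^-1)
#' @param cfg a `recon_config`
#' @return list with the updated `theta`, per-voxel `sse`, and `n_active`
#'   (voxels stopped by the iteration cap)
#' @export
nls_step <- function(xhat, theta, fi, tmid, dk = fdg_decay_const(),
                     cfg = recon_config()) {
  stopifnot(is.matrix(xhat), is.matrix(theta), nrow(xhat) == nrow(theta),
            ncol(theta) == 5)
  .batch_nls(xhat, theta, fi, tmid, dk, cfg)
}

## Poisson log-likelihood sum(y log(ybar) - ybar) with 0*log(0) = 0.
## Errors if counts are observed where the expectation is exactly zero.
.poisson_loglik <- function(y, ybar) {
  pos <- ybar > 0
  if (any(y[!pos] > 0))
    stop("positive counts observed where the model expectation is zero")
  sum(y[pos] * log(ybar[pos])) - sum(ybar)
}

## One or more MLEM sub-iterations at fixed expected additive term r.
## X: J x M activity (updated in place); P is the (count-calibrated)
## system matrix, sens its column sums. Bins with zero forward projection
## and zero counts are skipped by the 0/0 := 0 convention.
.em_update <- function(P, sens, y, r, X, n_em, mask) {
  inv_sens <- numeric(length(sens))
  inv_sens[mask] <- 1 / sens[mask]
  for (s in seq_len(n_em)) {
    fwd <- as.matrix(P %*% X) + r
    if (any(y[fwd == 0] > 0))
      stop("positive counts in a bin with zero model expectation ",
           "(and no additive term)")
    ratio <- matrix(0, nrow(y), ncol(y))
    nz <- fwd > 0
    ratio[nz] <- y[nz] / fwd[nz]
    X <- X * (as.matrix(Matrix::crossprod(P, ratio)) * inv_sens)
  }
  X
}

#' EM activity update given parametric maps
#'
#' Starting from the model-predicted activity `xbar = f(t, theta)`, applies
#' `n_em` multiplicative MLEM sub-iterations with the additive
#' scatter+randoms expectation in the denominator's forward model. The
#' Poisson log-likelihood is non-decreasing over the sub-iterations, and
#' data that exactly equal `P xbar + r` are a fixed point.
#'
#' @param sm a `system_model`
#' @param sg a `dyn_sinogram` (counts `y`, additive term `r`, calibration)
#' @param xbar J x M model-predicted activity
#' @param n_em number of sub-iterations
#' @return updated J x M activity estimate
#' @export
em_step <- function(sm, sg, xbar, n_em = 2) {
  stopifnot(inherits(sm, "system_model"), inherits(sg, "dyn_sinogram"))
  P <- sm$P * sg$count_scale
  sens <- sm$sens * sg$count_scale
  mask <- sens > 0
  .em_update(P, sens, sg$y, sg$r, xbar, n_em, mask)
}

#' ICM-EM direct reconstruction
#'
#' Alternates the voxel-wise kinetic fit ([nls_step()]) and the EM activity
#' update ([em_step()]) for `cfg$n_outer` iterations, starting from activity
#' 1.0 inside the FOV and all rate constants at `cfg$init_k`. After each
#' outer iteration the Poisson log-likelihood of the model-predicted
#' sinogram (including the additive term) is recorded. Voxels outside the
#' FOV support are never fitted and stay zero.
#'
#' @param sm a `system_model`
#' @param sg a `dyn_sinogram`
#' @param fi a `feng_input` (the plasma model used for fitting)
#' @param fs frame scheme; defaults to the sinogram's own
#' @param dk decay constant (min^-1)
#' @param cfg a `recon_config`
#' @param truth optional named list of ground-truth maps (K1..fv, Ki); when
#'   given, per-iteration map MSE over the truth support is recorded
#' @return a `recon_state`: parameter maps (named n x n matrices including
#'   the derived Ki), final activity, log-likelihood trace, and (with
#'   `truth`) an MSE trace
#' @export
icm_em <- function(sm, sg, fi, fs = NULL, dk = fdg_decay_const(),
                   cfg = recon_config(), truth = NULL) {
  stopifnot(inherits(sm, "system_model"), inherits(sg, "dyn_sinogram"))
  if (is.null(fs)) fs <- sg$scheme
  if (sm$sino$I != nrow(sg$y)) stop("system model and sinogram disagree")
  if (fs$n_frames != ncol(sg$y))
    stop("frame scheme and sinogram disagree")
  n <- sm$grid$n; J <- sm$grid$J; M <- fs$n_frames
  Pc <- sm$P * sg$count_scale
  sens <- sm$sens * sg$count_scale
  fit_mask <- as.vector(sm$grid$mask) & sens > 0
  V <- sum(fit_mask)
  X <- matrix(0, J, M)
  X[fit_mask, ] <- cfg$init_x
  theta <- matrix(rep(c(rep(cfg$init_k, 4), cfg$init_fv), each = V), V, 5)
  loglik <- numeric(cfg$n_outer)
  mse_trace <- NULL
  pars <- c("K1", "k2", "k3", "k4", "fv", "Ki")
  if (!is.null(truth)) {
    tmask <- truth$K1 > 0
    mse_trace <- matrix(NA_real_, cfg$n_outer, length(pars),
                        dimnames = list(NULL, pars))
  }
  for (it in seq_len(cfg$n_outer)) {
    fit <- .batch_nls(X[fit_mask, , drop = FALSE], theta, fi, fs$t_mid, dk,
                      cfg)
    theta <- fit$theta
    xbar <- matrix(0, J, M)
    xbar[fit_mask, ] <- .model_tac_matrix(theta, fi, fs$t_mid, dk)
    loglik[it] <- .poisson_loglik(sg$y, as.matrix(Pc %*% xbar) + sg$r)
    X <- .em_update(Pc, sens, sg$y, sg$r, xbar, cfg$n_em, fit_mask)
    if (!is.null(truth)) {
      maps_it <- .theta_to_maps(theta, fit_mask, n)
      for (p in pars)
        mse_trace[it, p] <- mse_map(truth[[p]], maps_it[[p]], tmask)
    }
  }
  maps <- .theta_to_maps(theta, fit_mask, n)
  structure(list(maps = maps, activity = X, loglik = loglik,
                 mse_trace = mse_trace, theta = theta,
                 fit_mask = fit_mask, config = cfg, grid = sm$grid,
                 scheme = fs, feng = fi, dk = dk,
                 noise_fraction = sg$noise_fraction, seed = sg$seed),
            class = "recon_state")
}

## Expand the fitted V x 5 parameter block into named n x n maps (+ Ki).
.theta_to_maps <- function(theta, fit_mask, n) {
  pars <- c("K1", "k2", "k3", "k4", "fv")
  maps <- list()
  for (p in seq_along(pars)) {
    m <- numeric(n * n)
    m[fit_mask] <- theta[, p]
    maps[[pars[p]]] <- matrix(m, n, n)
  }
  ki <- numeric(n * n)
  ki[fit_mask] <- .ki_vec(theta[, 1], theta[, 2], theta[, 3])
  maps$Ki <- matrix(ki, n, n)
  maps
}

#' Frame-by-frame MLEM reference reconstruction
#'
#' Standard per-frame MLEM with the additive scatter+randoms term, used as
#' the indirect (reconstruct-then-fit) baseline. Initialized uniformly at
#' 1.0 inside the FOV.
#'
#' @param sm a `system_model`
#' @param sg a `dyn_sinogram`
#' @param n_iter number of MLEM iterations
#' @return list with the J x M activity `x` and the per-iteration Poisson
#'   log-likelihood trace
#' @export
mlem_reference <- function(sm, sg, n_iter = 20) {
  stopifnot(inherits(sm, "system_model"), inherits(sg, "dyn_sinogram"))
  Pc <- sm$P * sg$count_scale
  sens <- sm$sens * sg$count_scale
  mask <- as.vector(sm$grid$mask) & sens > 0
  X <- matrix(0, sm$grid$J, ncol(sg$y))
  X[mask, ] <- 1
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    X <- .em_update(Pc, sens, sg$y, sg$r, X, 1L, mask)
    trace[it] <- .poisson_loglik(sg$y, as.matrix(Pc %*% X) + sg$r)
  }
  list(x = X, loglik = trace)
}

#' Voxel-wise kinetic fit of reconstructed activity (indirect baseline)
#'
#' Fits the compartment model independently to each voxel TAC of an
#' already-reconstructed activity series, completing the conventional
#' reconstruct-then-fit pipeline.
#'
#' @param x J x M activity matrix
#' @param mask logical J-vector of voxels to fit
#' @param fi,fs,dk input model, frame scheme, decay constant
#' @param cfg a `recon_config` (bounds and optimizer settings)
#' @return named list of n-free maps as in [icm_em()] (requires `n`)
#' @param n image grid size
#' @export
indirect_fit <- function(x, mask, fi, fs, dk = fdg_decay_const(),
                         cfg = recon_config(), n = sqrt(length(mask))) {
  V <- sum(mask)
  theta0 <- matrix(rep(c(rep(cfg$init_k, 4), cfg$init_fv), each = V), V, 5)
  fit <- .batch_nls(x[mask, , drop = FALSE], theta0, fi, fs$t_mid, dk, cfg)
  .theta_to_maps(fit$theta, mask, n)
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf("ICM-EM reconstruction: %d outer x %d EM iterations, %d fitted voxels\n",
              x$config$n_outer, x$config$n_em, sum(x$fit_mask)))
  cat(sprintf("  final log-likelihood: %.6g\n",
              x$loglik[length(x$loglik)]))
  invisible(x)
}
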