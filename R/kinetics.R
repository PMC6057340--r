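#' Two-tissue compartment kinetics with an analytic Feng-input convolution
#'
#' The kinetic core of the package: the irreversible/reversible two-tissue
#' compartment model in its auxiliary bi-exponential form, the Feng plasma
#' input model, and a fully analytic expression for the tissue time-activity
#' curve (TAC) that avoids numerical convolution.
#'
#' @name kinetics
#' @keywords internal
NULL

## ---- constructors -----------------------------------------------------------

#' Kinetic parameter set of the two-tissue compartment model
#'
#' @param K1 plasma-to-tissue transfer rate (ml.min^-1.g^-1)
#' @param k2,k3,k4 tissue rate constants (min^-1)
#' @param fv fractional blood volume (dimensionless, in \[0, 1\])
#' @return an object of class `kinetic_params`
#' @export
kinetic_params <- function(K1, k2, k3, k4, fv = 0) {
  v <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, fv = fv)
  if (any(!is.finite(v))) stop("kinetic parameters must be finite")
  if (any(v[1:4] < 0) || any(v[1:4] > 10))
    stop("rate constants must lie in [0, 10]")
  if (fv < 0 || fv > 1) stop("fv must lie in [0, 1]")
  structure(as.list(v), class = "kinetic_params")
}

#' Auxiliary bi-exponential parameter set
#'
#' Reparameterization of the two-tissue impulse response as
#' `alpha1*exp(-beta1*t) + alpha2*exp(-beta2*t)`, with `beta1 <= beta2`.
#'
#' @param fv fractional blood volume
#' @param alpha1,alpha2 exponential amplitudes (units of K1)
#' @param beta1,beta2 exponential decay rates (min^-1), `beta1 <= beta2`
#' @return an object of class `aux_params`
#' @export
aux_params <- function(fv, alpha1, alpha2, beta1, beta2) {
  v <- c(fv = fv, alpha1 = alpha1, alpha2 = alpha2,
         beta1 = beta1, beta2 = beta2)
  if (any(!is.finite(v))) stop("auxiliary parameters must be finite")
  if (beta1 < 0 || beta2 < 0) stop("beta rates must be nonnegative")
  if (beta1 > beta2) stop("beta1 must not exceed beta2")
  structure(as.list(v), class = "aux_params")
}

#' Feng plasma input function parameters
#'
#' Bolus plasma model for FDG-like tracers: a linear ramp times a fast
#' exponential plus two slower exponential tails, delayed by `t0`.
#'
#' @param A1 ramp amplitude (concentration per minute)
#' @param A2,A3 tail amplitudes (concentration)
#' @param lambda1,lambda2,lambda3 inverse time constants (min^-1),
#'   expected ordering `lambda1 > lambda2 > lambda3 > 0`
#' @param t0 tracer appearance delay (min)
#' @return an object of class `feng_input`
#' @export
feng_input <- function(A1, A2, A3, lambda1, lambda2, lambda3, t0 = 0) {
  v <- c(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
         lambda2 = lambda2, lambda3 = lambda3, t0 = t0)
  if (any(!is.finite(v))) stop("Feng input parameters must be finite")
  structure(as.list(v), class = "feng_input")
}

#' Frame timing scheme
#'
#' @param start,end frame start and end times (min); frames must be
#'   contiguous, non-overlapping and strictly increasing
#' @return an object of class `frame_scheme` with derived mid-times `t_mid`
#' @export
frame_scheme <- function(start, end) {
  if (length(start) != length(end) || length(start) < 1)
    stop("start and end must be non-empty vectors of equal length")
  if (any(end <= start)) stop("each frame must have end > start")
  if (length(start) > 1 &&
      any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("frames must be contiguous")
  structure(list(start = start, end = end, t_mid = (start + end) / 2,
                 n_frames = length(start)), class = "frame_scheme")
}

#' Default 24-frame 40-minute acquisition scheme
#'
#' 12 x 10 s, 2 x 30 s, 3 x 60 s, 2 x 120 s, 4 x 300 s and 1 x 600 s,
#' the standard clinical brain FDG protocol used throughout the package.
#'
#' @return a `frame_scheme`
#' @export
default_frame_scheme <- function() {
  dur_s <- c(rep(10, 12), rep(30, 2), rep(60, 3), rep(120, 2),
             rep(300, 4), 600)
  end <- cumsum(dur_s) / 60
  frame_scheme(start = c(0, end[-length(end)]), end = end)
}

#' Reference simulation constants
#'
#' `table1_kinetics()` returns the gray- and white-matter kinetic parameter
#' sets used by the brain-phantom simulation; `default_feng_input()` the
#' matching bolus input model; `fdg_decay_const()` the 18F decay constant
#' ln(2)/109.8 per minute.
#'
#' @return `table1_kinetics()`: named list of two `kinetic_params`;
#'   `default_feng_input()`: a `feng_input`; `fdg_decay_const()`: a scalar.
#' @export
table1_kinetics <- function() {
  list(
    gray  = kinetic_params(K1 = 0.6805, k2 = 0.3945, k3 = 0.0533,
                           k4 = 0.0031, fv = 0.0985),
    white = kinetic_params(K1 = 0.4091, k2 = 0.3276, k3 = 0.0451,
                           k4 = 0.0015, fv = 0.1160)
  )
}

#' @rdname table1_kinetics
#' @export
default_feng_input <- function() {
  feng_input(A1 = 10, A2 = 0.5, A3 = 2,
             lambda1 = 0.5, lambda2 = 0.05, lambda3 = 0.005, t0 = 0)
}

#' @rdname table1_kinetics
#' @export
fdg_decay_const <- function() log(2) / 109.8

## ---- Feng input -------------------------------------------------------------

#' Evaluate the Feng plasma input function
#'
#' `Cp(t) = (A1*(t-t0) - A2 - A3) exp(-lambda1 (t-t0)) + A2 exp(-lambda2 (t-t0))
#'  + A3 exp(-lambda3 (t-t0))` for `t >= t0`, and 0 before the appearance
#' delay; the curve is continuous (value 0) at `t0`.
#'
#' @param fi a `feng_input`
#' @param t time vector (min)
#' @return plasma concentration at `t`
#' @export
feng_cp <- function(fi, t) {
  stopifnot(inherits(fi, "feng_input"))
  if (any(!is.finite(t))) stop("time vector must be finite")
  ts <- t - fi$t0
  out <- numeric(length(t))
  on <- ts >= 0
  u <- ts[on]
  out[on] <- (fi$A1 * u - fi$A2 - fi$A3) * exp(-fi$lambda1 * u) +
    fi$A2 * exp(-fi$lambda2 * u) + fi$A3 * exp(-fi$lambda3 * u)
  out
}

## ---- kinetic <-> auxiliary maps --------------------------------------------

## Vectorized core of the forward map; kp components as equal-length vectors.
## beta1,2 are the negated eigenvalues of the 2x2 compartmental rate matrix;
## a repeated eigenvalue (discriminant 0) is lifted by a 1e-9 perturbation of
## k2 so the bi-exponential form stays well defined.
.aux_vec <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  deg <- which(sqrt(pmax(disc, 0)) < 1e-12 & s > 0)
  if (length(deg)) {
    k2[deg] <- k2[deg] + 1e-9
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
  }
  sq <- sqrt(pmax(disc, 0))
  beta1 <- (s - sq) / 2
  beta2 <- (s + sq) / 2
  denom <- beta2 - beta1
  alpha1 <- ifelse(denom > 0, K1 * (k3 + k4 - beta1) / denom, 0)
  alpha2 <- ifelse(denom > 0, K1 * (beta2 - k3 - k4) / denom, K1)
  list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
}

#' Map kinetic constants to auxiliary bi-exponential parameters
#'
#' The two-tissue impulse response solves a linear 2-compartment ODE system;
#' its eigendecomposition yields decay rates
#' `beta_{1,2} = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4))/2` and
#' amplitudes `alpha1 = K1 (k3+k4-beta1)/(beta2-beta1)`,
#' `alpha2 = K1 (beta2-k3-k4)/(beta2-beta1)`.
#'
#' @param kp a `kinetic_params`
#' @return an `aux_params`
#' @export
aux_from_kinetic <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k2 + kp$k3 + kp$k4 <= 0)
    stop("k2 + k3 + k4 must be positive for a two-tissue response")
  a <- .aux_vec(kp$K1, kp$k2, kp$k3, kp$k4)
  aux_params(fv = kp$fv, alpha1 = a$alpha1, alpha2 = a$alpha2,
             beta1 = a$beta1, beta2 = a$beta2)
}

#' Recover kinetic constants from auxiliary parameters
#'
#' Inverts the bi-exponential parameterization using `K1 = alpha1 + alpha2`,
#' `k2 + k3 + k4 = beta1 + beta2`, `k2 * k4 = beta1 * beta2` and the alpha
#' equations. When `k2` is (numerically) zero the k3/k4 split is not
#' identifiable; the irreversible convention `k4 = 0` is returned.
#'
#' @param ap an `aux_params`
#' @return a `kinetic_params`
#' @export
kinetic_from_aux <- function(ap) {
  stopifnot(inherits(ap, "aux_params"))
  K1 <- ap$alpha1 + ap$alpha2
  if (K1 <= 0) stop("alpha1 + alpha2 must be positive (K1 = 0 has no inverse)")
  bsum <- ap$beta1 + ap$beta2
  bprod <- ap$beta1 * ap$beta2
  k34 <- ap$beta1 + ap$alpha1 * (ap$beta2 - ap$beta1) / K1
  k2 <- bsum - k34
  tol <- 1e-9 * max(1, bsum)
  if (k2 < -tol)
    stop("inconsistent auxiliary parameters: implied k2 = ", signif(k2, 6),
         " is negative")
  k2 <- max(k2, 0)
  if (k2 > 1e-12) {
    k4 <- bprod / k2
  } else {
    k4 <- 0
  }
  k3 <- k34 - k4
  if (k3 < -tol)
    stop("inconsistent auxiliary parameters: implied k3 = ", signif(k3, 6),
         " is negative")
  if (k4 < -tol)
    stop("inconsistent auxiliary parameters: implied k4 = ", signif(k4, 6),
         " is negative")
  kinetic_params(K1 = K1, k2 = k2, k3 = max(k3, 0), k4 = max(k4, 0),
                 fv = ap$fv)
}

#' Tissue impulse response function
#'
#' `c(t) = alpha1 exp(-beta1 t) + alpha2 exp(-beta2 t)`; at `t = 0` this is
#' `alpha1 + alpha2 = K1`.
#'
#' @param ap an `aux_params`
#' @param t nonnegative time vector (min)
#' @return response values at `t`
#' @export
irf <- function(ap, t) {
  stopifnot(inherits(ap, "aux_params"))
  if (any(t < 0)) stop("the impulse response is defined for t >= 0")
  ap$alpha1 * exp(-ap$beta1 * t) + ap$alpha2 * exp(-ap$beta2 * t)
}

## ---- analytic convolution ---------------------------------------------------

## Convolution of the Feng input with exp(-beta t), as a matrix over
## (beta values x times). Times are shifted by t0; zero before appearance.
## Term-by-term expansion of conv(Cp, exp(-beta .)) in the elementary
## kernels
##   E(l, b, t) = conv(e^{-l .}, e^{-b .})(t) = (e^{-l t} - e^{-b t})/(b - l)
##   D(l, b, t) = conv(t e^{-l .}, e^{-b .})(t) = (t e^{-l t} - E)/(b - l)
## gives  A1 * D(l1,b,t) - (A2+A3) * E(l1,b,t)
##        + A2 * E(l2,b,t) + A3 * E(l3,b,t).
## Near-coincident rates |b - l| < thresh use the series limits
## E -> t e^{-l t} (1 - d t/2 + d^2 t^2/6),
## D -> t^2 e^{-l t} (1/2 - d t/6 + d^2 t^2/24), so values stay finite.
## The compartment exponential e^{-b t} is computed once and shared.
.conv_cp_exp <- function(fi, beta, t, thresh = 1e-8) {
  ts <- t - fi$t0
  on <- ts >= 0
  out <- matrix(0, length(beta), length(t))
  if (!any(on)) return(out)
  u <- ts[on]
  nb <- length(beta); nt <- length(u)
  eb <- exp(-outer(beta, u))
  Efun <- function(lambda) {
    el <- exp(-lambda * u)
    d <- beta - lambda
    elm <- matrix(el, nb, nt, byrow = TRUE)
    deg <- which(abs(d) < thresh)
    dd <- d
    dd[deg] <- 1                       # placeholder; rows overwritten below
    E <- (elm - eb) / dd
    if (length(deg)) {
      dv <- d[deg]
      E[deg, ] <- matrix(u * el, length(deg), nt, byrow = TRUE) *
        (1 - outer(dv, u) / 2 + outer(dv^2, u^2) / 6)
    }
    list(E = E, el = el, d = d, deg = deg)
  }
  e1 <- Efun(fi$lambda1)
  e2 <- Efun(fi$lambda2)
  e3 <- Efun(fi$lambda3)
  ## D for lambda1
  dd <- e1$d
  dd[e1$deg] <- 1
  D1 <- (matrix(u * e1$el, nb, nt, byrow = TRUE) - e1$E) / dd
  if (length(e1$deg)) {
    dv <- e1$d[e1$deg]
    D1[e1$deg, ] <- matrix(u^2 * e1$el, length(e1$deg), nt, byrow = TRUE) *
      (0.5 - outer(dv, u) / 6 + outer(dv^2, u^2) / 24)
  }
  out[, on] <- fi$A1 * D1 - (fi$A2 + fi$A3) * e1$E +
    fi$A2 * e2$E + fi$A3 * e3$E
  out
}

## Fully vectorized model TAC for many voxels at once. theta is a J x 5
## matrix with columns K1, k2, k3, k4, fv; returns a J x M matrix of
## decay-corrected tissue concentrations at times `t`.
.model_tac_matrix <- function(theta, fi, t, dk) {
  K1 <- theta[, 1]; k2 <- theta[, 2]; k3 <- theta[, 3]
  k4 <- theta[, 4]; fv <- theta[, 5]
  a <- .aux_vec(K1, k2, k3, k4)
  J <- nrow(theta); M <- length(t)
  tissue <- a$alpha1 * .conv_cp_exp(fi, a$beta1, t) +
    a$alpha2 * .conv_cp_exp(fi, a$beta2, t)
  decay <- exp(-dk * t)
  cp <- feng_cp(fi, t)
  (1 - fv) * tissue * matrix(decay, J, M, byrow = TRUE) +
    fv * matrix(cp, J, M, byrow = TRUE)
}

#' Analytic tissue time-activity curve
#'
#' Evaluates the two-tissue compartment model response to the Feng input in
#' closed form at the frame mid-times:
#' `CT(t) = (1-fv) * [Cp (x) (alpha1 e^{-beta1 t} + alpha2 e^{-beta2 t})](t)
#'  * exp(-dk t) + fv * Cp(t)`,
#' where the convolution `(x)` is expanded analytically term by term so no
#' temporal discretization is involved. Near-coincident decay rates
#' (`|beta - lambda| < 1e-8`) switch to the exact limit kernels, so the
#' result is always finite.
#'
#' @param p an `aux_params` or `kinetic_params` (converted internally)
#' @param fi a `feng_input`
#' @param fs a `frame_scheme`
#' @param dk radioactive decay constant (min^-1), default 18F
#' @return a `tac` object (values at frame mid-times plus the scheme)
#' @export
tissue_tac_analytic <- function(p, fi, fs, dk = fdg_decay_const()) {
  stopifnot(inherits(fi, "feng_input"), inherits(fs, "frame_scheme"))
  if (dk < 0) stop("decay constant must be nonnegative")
  if (inherits(p, "kinetic_params")) {
    theta <- matrix(c(p$K1, p$k2, p$k3, p$k4, p$fv), 1, 5)
  } else if (inherits(p, "aux_params")) {
    kp <- if (p$alpha1 + p$alpha2 > 0) kinetic_from_aux(p) else
      list(K1 = 0, k2 = 0, k3 = 0, k4 = 0, fv = p$fv)
    theta <- matrix(c(kp$K1, kp$k2, kp$k3, kp$k4, p$fv), 1, 5)
  } else stop("p must be kinetic_params or aux_params")
  vals <- drop(.model_tac_matrix(theta, fi, fs$t_mid, dk))
  tac(vals, fs)
}

#' Time-activity curve container
#'
#' @param values concentration per frame
#' @param fs the associated `frame_scheme`
#' @return a `tac` object
#' @export
tac <- function(values, fs) {
  stopifnot(inherits(fs, "frame_scheme"))
  if (length(values) != fs$n_frames)
    stop("TAC length must equal the number of frames")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(values = as.numeric(values), scheme = fs), class = "tac")
}

#' Export a TAC as a data frame
#'
#' @param x a `tac`
#' @return data frame with columns frame_start, frame_end, t_mid, value
#' @export
tac_table <- function(x) {
  stopifnot(inherits(x, "tac"))
  data.frame(frame_start = x$scheme$start, frame_end = x$scheme$end,
             t_mid = x$scheme$t_mid, value = x$values)
}

#' Numeric-convolution tissue TAC (quadrature oracle)
#'
#' Reference implementation of the tissue model by trapezoidal-rule
#' convolution of a finely sampled plasma input with the bi-exponential
#' impulse response, followed by decay correction and the blood term. Used
#' as an independent check of [tissue_tac_analytic()]; it converges to the
#' analytic curve at second order in the grid step.
#'
#' @param kp a `kinetic_params`
#' @param cp sampled input: list/data.frame with uniform grid `t` (starting
#'   at 0) and `values`
#' @param fs a `frame_scheme`
#' @param dk decay constant (min^-1)
#' @return a `tac` at the frame mid-times (linear interpolation on the grid)
#' @export
tissue_tac_numeric <- function(kp, cp, fs, dk = fdg_decay_const()) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(fs, "frame_scheme"))
  tg <- cp$t; cv <- cp$values
  if (length(tg) < 2 || length(tg) != length(cv))
    stop("cp must provide matching t and values vectors")
  dt <- diff(tg)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("cp grid must be uniform")
  dt <- dt[1]
  shortest <- min(fs$end - fs$start)
  if (dt > shortest / 10)
    warning("input grid coarser than 1/10 of the shortest frame; ",
            "the quadrature may be inaccurate")
  ap <- aux_from_kinetic(kp)
  h <- ap$alpha1 * exp(-ap$beta1 * tg) + ap$alpha2 * exp(-ap$beta2 * tg)
  n <- length(tg)
  ## trapezoid-rule causal convolution on the grid
  full <- stats::convolve(cv, rev(h), type = "open")[seq_len(n)]
  conv <- dt * (full - 0.5 * (cv[1] * h + cv * h[1]))
  ct <- (1 - kp$fv) * conv * exp(-dk * tg) + kp$fv * cv
  vals <- stats::approx(tg, ct, xout = fs$t_mid, rule = 2)$y
  tac(vals, fs)
}

## ---- macroparameter and input fitting --------------------------------------

#' Net-influx macroparameter Ki
#'
#' `Ki = K1 * k3 / (k2 + k3)`, the clinically used FDG uptake-rate index.
#'
#' @param kp a `kinetic_params`
#' @return Ki (same units as K1)
#' @export
ki_macro <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k2 + kp$k3 <= 0) stop("Ki requires k2 + k3 > 0")
  kp$K1 * kp$k3 / (kp$k2 + kp$k3)
}

## Vectorized Ki over parameter vectors; 0 where k2 + k3 == 0.
.ki_vec <- function(K1, k2, k3) ifelse(k2 + k3 > 0, K1 * k3 / (k2 + k3), 0)

#' Fit the Feng input model to a sampled blood curve
#'
#' Bounded Levenberg-Marquardt nonlinear least squares on the 7 Feng
#' parameters, evaluated at the frame mid-times.
#'
#' @param x a `tac` (or numeric vector with `fs` supplied)
#' @param fs frame scheme, defaulting to the TAC's own
#' @param start optional `feng_input` starting point
#' @param fit_t0 logical; fit the appearance delay (default TRUE)
#' @return a `feng_input` with attributes `rss` and `converged`
#' @export
fit_feng <- function(x, fs = NULL, start = NULL, fit_t0 = TRUE) {
  if (inherits(x, "tac")) {
    vals <- x$values
    if (is.null(fs)) fs <- x$scheme
  } else vals <- as.numeric(x)
  stopifnot(inherits(fs, "frame_scheme"))
  if (fs$n_frames < 7)
    stop("fitting the 7-parameter input model needs at least 7 frames")
  tm <- fs$t_mid
  if (all(vals == 0)) {
    out <- feng_input(0, 0, 0, 0.5, 0.05, 0.005, 0)
    attr(out, "rss") <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (is.null(start)) {
    pk <- max(vals)
    start <- feng_input(A1 = pk * exp(1) * 0.5, A2 = pk * 0.02, A3 = pk * 0.1,
                        lambda1 = 0.5, lambda2 = 0.05, lambda3 = 0.005,
                        t0 = 0)
  }
  p0 <- unlist(start)[c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3",
                        "t0")]
  lower <- c(0, 0, 0, 1e-4, 1e-5, 1e-6, 0)
  upper <- c(Inf, Inf, Inf, 20, 2, 0.2, max(tm) / 2)
  if (!fit_t0) upper[7] <- lower[7] <- p0["t0"]
  resid_fn <- function(p) {
    fi <- feng_input(p[1], p[2], p[3], p[4], p[5], p[6], p[7])
    feng_cp(fi, tm) - vals
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  out <- feng_input(p[1], p[2], p[3], p[4], p[5], p[6], p[7])
  rss <- sum(fit$fvec^2)
  conv <- fit$info %in% 1:4
  if (!conv)
    warning("Feng fit did not fully converge (info = ", fit$info,
            ", residual sum of squares = ", signif(rss, 6), ")")
  attr(out, "rss") <- rss
  attr(out, "converged") <- conv
  out
}

## ---- serialization ----------------------------------------------------------

#' Read or write parameter sets as flat key-value files
#'
#' `kinetic_params` and `feng_input` objects round-trip through YAML (or
#' JSON) files with exactly the keys K1,k2,k3,k4,fv and
#' A1,A2,A3,lambda1,lambda2,lambda3,t0.
#'
#' @param x a `kinetic_params` or `feng_input`
#' @param path file path (.yaml/.yml or .json)
#' @return `write_params` returns `path` invisibly; `read_params` the object
#' @export
write_params <- function(x, path) {
  stopifnot(inherits(x, "kinetic_params") || inherits(x, "feng_input"))
  lst <- lapply(unclass(x), as.numeric)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
  kin <- c("K1", "k2", "k3", "k4", "fv")
  fen <- c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3", "t0")
  if (all(kin %in% names(lst)))
    return(do.call(kinetic_params, lst[kin]))
  if (all(fen %in% names(lst)))
    return(do.call(feng_input, lst[fen]))
  stop("file does not contain a recognizable parameter set")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-tissue kinetic parameters:\n")
  cat(sprintf("  K1 = %.4g  k2 = %.4g  k3 = %.4g  k4 = %.4g  fv = %.4g\n",
              x$K1, x$k2, x$k3, x$k4, x$fv))
  invisible(x)
}

#' @export
print.feng_input <- function(x, ...) {
  cat("Feng plasma input model:\n")
  cat(sprintf("  A = [%.4g, %.4g, %.4g]  lambda = [%.4g, %.4g, %.4g]  t0 = %.4g\n",
              x$A1, x$A2, x$A3, x$lambda1, x$lambda2, x$lambda3, x$t0))
  invisible(x)
}
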