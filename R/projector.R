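#' 2D strip-integral tomographic system model
#'
#' A sparse parallel-beam system matrix on a square pixel basis with a
#' strip-integral detector model, optionally folding per-LOR attenuation
#' factors into the coefficients. The same coefficient set serves forward
#' and back projection, so the pair is exactly adjoint.
#'
#' @name projector
#' @keywords internal
NULL

#' Square image grid
#'
#' @param n grid size (n x n pixels)
#' @param fov field of view (cm); pixel size is `fov/n`
#' @return an `image_grid` with pixel centers and the circular FOV mask
#' @export
image_grid <- function(n, fov) {
  if (n < 2 || fov <= 0) stop("invalid grid")
  d <- fov / n
  centers <- (seq_len(n) - (n + 1) / 2) * d
  xc <- rep(centers, times = n)     # column-major: x varies fastest
  yc <- rep(centers, each = n)
  mask <- sqrt(xc^2 + yc^2) <= fov / 2
  structure(list(n = n, fov = fov, d = d, xc = xc, yc = yc,
                 mask = matrix(mask, n, n), J = n * n),
            class = "image_grid")
}

#' Parallel-beam sinogram geometry
#'
#' Radial bins are centered on the FOV with spacing `fov/nbins` (the strip
#' width equals the bin spacing); angles span `[0, pi)` uniformly.
#'
#' @param nbins number of radial bins
#' @param nangles number of projection angles
#' @param fov field of view (cm)
#' @return a `sino_geometry`
#' @export
sino_geometry <- function(nbins, nangles, fov) {
  if (nbins < 2 || nangles < 1 || fov <= 0) stop("invalid sinogram geometry")
  w <- fov / nbins
  s <- (seq_len(nbins) - (nbins + 1) / 2) * w
  theta <- (seq_len(nangles) - 1) * pi / nangles
  structure(list(nbins = nbins, nangles = nangles, fov = fov, w = w,
                 s = s, theta = theta, I = nbins * nangles),
            class = "sino_geometry")
}

#' Uniform attenuation map
#'
#' @param grid an `image_grid`
#' @param mu linear attenuation coefficient (cm^-1), default 0.098 (water at
#'   511 keV)
#' @param support logical matrix of object support; default the circular FOV
#' @return attenuation image (n x n matrix, cm^-1)
#' @export
attenuation_map <- function(grid, mu = 0.098, support = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  if (mu < 0) stop("attenuation coefficient must be nonnegative")
  if (is.null(support)) support <- grid$mask
  att <- matrix(0, grid$n, grid$n)
  att[support] <- mu
  att
}

## Integral from 0 to u (u >= 0) of f(s) = min(b, max(0, c1 - |s|)) with
## c1 = (a+b)/2, the projected profile of a square pixel (a >= b >= 0).
.trap_cdf <- function(u, a, b) {
  c1 <- (a + b) / 2
  c2 <- (a - b) / 2
  sgn <- sign(u)
  u <- abs(u)
  u <- pmin(u, c1)
  flat <- pmin(u, c2)
  ramp <- pmax(u - c2, 0)
  sgn * (b * flat + b * ramp - ramp^2 / 2)
}

#' Build the tomographic system model
#'
#' Each coefficient `p_ij` is the area of pixel `j` inside the detection
#' strip of LOR `i`, divided by the strip width (so projections are in
#' line-integral units), multiplied by the attenuation survival factor
#' `exp(-integral of mu along LOR i)`. Pixels outside the circular FOV get
#' zero coefficients. Coefficients are assembled in a fixed (angle, bin,
#' pixel) order, so repeated builds are identical.
#'
#' @param grid an `image_grid`
#' @param sino a `sino_geometry` with the same FOV
#' @param att attenuation image (n x n, cm^-1) or NULL for none
#' @return a `system_model` with the sparse matrix `P` (I x J), per-LOR
#'   attenuation factors and the sensitivity image `sens = colSums(P)`
#' @export
build_system <- function(grid, sino, att = NULL) {
  stopifnot(inherits(grid, "image_grid"), inherits(sino, "sino_geometry"))
  if (abs(grid$fov - sino$fov) > 1e-9)
    stop("grid and sinogram FOV must agree")
  d <- grid$d; w <- sino$w
  jj <- which(as.vector(grid$mask))
  x <- grid$xc[jj]; y <- grid$yc[jj]
  nb <- sino$nbins
  s_off <- (nb + 1) / 2
  ii_all <- vector("list", sino$nangles)
  jj_all <- vector("list", sino$nangles)
  ww_all <- vector("list", sino$nangles)
  for (ang in seq_len(sino$nangles)) {
    th <- sino$theta[ang]
    a <- abs(cos(th)) * d; b <- abs(sin(th)) * d
    if (a < b) { tmp <- a; a <- b; b <- tmp }
    s0 <- x * cos(th) + y * sin(th)
    halfspan <- (a + b) / 2
    kmax <- ceiling((halfspan + w / 2) / w)
    ks <- seq(-kmax, kmax)
    ctr <- round(s0 / w + s_off)
    bins <- outer(ctr, ks, "+")            # npix x nk candidate bins
    edge_lo <- (bins - 0.5 - s_off) * w - s0
    edge_hi <- edge_lo + w
    if (b > 1e-12 * d) {
      wt <- (d * d) / (a * b) *
        (.trap_cdf(edge_hi, a, b) - .trap_cdf(edge_lo, a, b))
    } else {
      ov <- pmax(pmin(edge_hi, a / 2) - pmax(edge_lo, -a / 2), 0)
      wt <- (d * d) / a * ov
    }
    keep <- which(wt > 1e-14 & bins >= 1 & bins <= nb)
    ii_all[[ang]] <- (ang - 1L) * nb + as.integer(bins[keep])
    jj_all[[ang]] <- jj[(keep - 1L) %% length(jj) + 1L]
    ww_all[[ang]] <- wt[keep] / w
  }
  P <- Matrix::sparseMatrix(i = unlist(ii_all), j = unlist(jj_all),
                            x = unlist(ww_all),
                            dims = c(sino$I, grid$J))
  att_factor <- rep(1, sino$I)
  if (!is.null(att)) {
    if (!all(dim(att) == c(grid$n, grid$n)))
      stop("attenuation map must match the image grid")
    if (any(att < 0)) stop("attenuation must be nonnegative")
    att_factor <- as.numeric(exp(-(P %*% as.vector(att))))
    P <- Matrix::Diagonal(x = att_factor) %*% P
    P <- methods::as(P, "CsparseMatrix")
  }
  structure(list(P = P, grid = grid, sino = sino,
                 att_factor = att_factor,
                 sens = Matrix::colSums(P)),
            class = "system_model")
}

## Coerce an image (n x n matrix, J vector, or J x M matrix) to a J x M
## matrix for projection.
.as_image_matrix <- function(sm, image) {
  J <- sm$grid$J
  if (is.matrix(image) && all(dim(image) == c(sm$grid$n, sm$grid$n)))
    return(matrix(as.vector(image), J, 1))
  if (is.matrix(image) && nrow(image) == J) return(image)
  if (length(image) == J) return(matrix(image, J, 1))
  stop("image shape does not match the system model grid")
}

#' Forward projection
#'
#' @param sm a `system_model`
#' @param image an n x n matrix, length-J vector, or J x M matrix (one
#'   column per frame)
#' @return sinogram values: I-vector (single image) or I x M matrix
#' @export
forward_project <- function(sm, image) {
  stopifnot(inherits(sm, "system_model"))
  X <- .as_image_matrix(sm, image)
  out <- as.matrix(sm$P %*% X)
  if (ncol(out) == 1) drop(out) else out
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param sm a `system_model`
#' @param sinogram an I-vector or I x M matrix
#' @return image values: J-vector or J x M matrix
#' @export
back_project <- function(sm, sinogram) {
  stopifnot(inherits(sm, "system_model"))
  I <- sm$sino$I
  Y <- if (is.matrix(sinogram)) sinogram else matrix(sinogram, ncol = 1)
  if (nrow(Y) != I) stop("sinogram shape does not match the system model")
  out <- as.matrix(Matrix::crossprod(sm$P, Y))
  if (ncol(out) == 1) drop(out) else out
}

#' Geometry presets
#'
#' `preset = "full"`: 111 x 111 grid, 70 cm FOV, 367 bins x 315 angles
#' (full-size brain protocol). `preset = "small"`: 64 x 64 grid, 95 bins x
#' 96 angles, same FOV — the desk-scale setting used by the test suite.
#' `preset = "tiny"`: 32 x 32 grid, 47 bins x 48 angles, for quick checks.
#'
#' @param preset one of "full", "small", "tiny"
#' @return list with `grid` and `sino`
#' @export
geometry_preset <- function(preset = c("small", "full", "tiny")) {
  preset <- match.arg(preset)
  switch(preset,
         full = list(grid = image_grid(111, 70),
                      sino = sino_geometry(367, 315, 70)),
         small = list(grid = image_grid(64, 70),
                      sino = sino_geometry(95, 96, 70)),
         tiny  = list(grid = image_grid(32, 70),
                      sino = sino_geometry(47, 48, 70)))
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("PET system model: %d x %d grid (FOV %.1f cm), %d bins x %d angles, %d nonzeros\n",
              x$grid$n, x$grid$n, x$grid$fov, x$sino$nbins, x$sino$nangles,
              length(x$P@x)))
  invisible(x)
}
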