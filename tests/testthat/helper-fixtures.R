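# Shared fixtures built in code: tiny geometries and simulations kept small
# enough that every unit test runs in seconds.

tiny_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- geometry_preset("tiny")
      cache <<- list(grid = geo$grid, sino = geo$sino,
                     sm = build_system(geo$grid, geo$sino))
    }
    cache
  }
})

tiny_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- tiny_geometry()
      ph <- make_phantom(geo$grid)
      fi <- default_feng_input()
      fs <- default_frame_scheme()
      dk <- fdg_decay_const()
      dyn <- simulate_activity(ph, fi, fs, dk)
      cache <<- list(grid = geo$grid, sino = geo$sino, sm = geo$sm,
                     ph = ph, fi = fi, fs = fs, dk = dk, dyn = dyn)
    }
    cache
  }
})

# A random small Poisson tomography instance (dense nonnegative system,
# strictly positive sensitivities) for EM property tests.
random_em_instance <- function(seed, I = 8, J = 8, M = 2) {
  set.seed(seed)
  P <- matrix(stats::runif(I * J), I, J)
  P[stats::runif(I * J) < 0.3] <- 0
  P <- P + 1e-3                                  # keep sensitivities positive
  xtrue <- matrix(stats::rexp(J * M, rate = 0.5), J, M)
  r <- matrix(stats::runif(I * M, 0, 0.5), I, M)
  y <- matrix(stats::rpois(I * M, P %*% xtrue + r), I, M)
  list(P = Matrix::Matrix(P, sparse = TRUE), sens = colSums(P),
       xtrue = xtrue, r = r, y = y)
}
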