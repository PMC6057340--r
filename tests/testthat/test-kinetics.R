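test_that("Feng input is zero before t0, continuous at t0, and matches
           term-by-term evaluation", {
  fi <- feng_input(A1 = 10, A2 = 0.5, A3 = 2,
                   lambda1 = 0.5, lambda2 = 0.05, lambda3 = 0.005, t0 = 2)
  expect_identical(feng_cp(fi, fi$t0 - 1), 0)
  expect_identical(feng_cp(fi, fi$t0), 0)       # -A2 - A3 + A2 + A3 = 0
  # independent term-wise arithmetic at selected times (t0 = 0 parameters)
  fi0 <- default_feng_input()
  for (t in c(0.25, 1, 5, 20, 40)) {
    direct <- (10 * t - 0.5 - 2) * exp(-0.5 * t) +
      0.5 * exp(-0.05 * t) + 2 * exp(-0.005 * t)
    expect_equal(feng_cp(fi0, t), direct, tolerance = 1e-12)
  }
  expect_error(feng_input(NA, 1, 1, 1, 1, 1), "finite")
})

test_that("auxiliary decay rates equal the negated eigenvalues of the
           compartmental rate matrix", {
  for (kp in table1_kinetics()) {
    ap <- aux_from_kinetic(kp)
    K <- matrix(c(-(kp$k2 + kp$k3), kp$k4,
                  kp$k3, -kp$k4), 2, 2, byrow = TRUE)
    ev <- sort(-eigen(K, only.values = TRUE)$values)
    expect_equal(c(ap$beta1, ap$beta2), ev, tolerance = 1e-12)
    expect_equal(ap$alpha1 + ap$alpha2, kp$K1, tolerance = 1e-12)
    expect_lte(ap$beta1, ap$beta2)
  }
})

test_that("one-tissue limit collapses to a single exponential", {
  ap <- aux_from_kinetic(kinetic_params(K1 = 1, k2 = 0.5, k3 = 0, k4 = 0))
  expect_equal(ap$alpha1, 0)
  expect_equal(ap$alpha2, 1)
  expect_equal(ap$beta1, 0)
  expect_equal(ap$beta2, 0.5)
})

test_that("kinetic -> aux -> kinetic round trip is the identity", {
  set.seed(11)
  worst <- 0
  for (i in 1:200) {
    k <- stats::runif(4, 1e-4, 10)
    kp <- kinetic_params(k[1], k[2], k[3], k[4], stats::runif(1))
    back <- kinetic_from_aux(aux_from_kinetic(kp))
    rel <- max(abs(unlist(kp) - unlist(back)) / pmax(abs(unlist(kp)), 1e-12))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
  # reference white-matter set recovered through the aux representation
  white <- table1_kinetics()$white
  back <- kinetic_from_aux(aux_from_kinetic(white))
  expect_equal(unlist(back)[1:4], c(K1 = 0.4091, k2 = 0.3276, k3 = 0.0451,
                                    k4 = 0.0015), tolerance = 1e-8)
})

test_that("degenerate auxiliary sets are rejected with informative errors", {
  expect_error(kinetic_from_aux(aux_params(0.1, 0, 0, 0, 1)), "K1 = 0")
  expect_error(kinetic_from_aux(aux_params(0, -0.5, 2, 0.9, 1)), "k3")
  expect_error(aux_from_kinetic(kinetic_params(1, 0, 0, 0)), "positive")
})

test_that("impulse response starts at K1, decays monotonically, and matches
           the ODE solution", {
  kp <- table1_kinetics()$gray
  ap <- aux_from_kinetic(kp)
  expect_equal(irf(ap, 0), ap$alpha1 + ap$alpha2)
  expect_equal(irf(ap, 0), kp$K1, tolerance = 1e-12)
  tt <- seq(0, 40, by = 0.5)
  v <- irf(ap, tt)
  expect_true(all(diff(v) <= 0))
  expect_identical(irf(aux_params(0, 0, 0, 1, 2), tt), rep(0, length(tt)))
  # independent oracle: integrate the free/bound compartment ODEs and
  # compare the summed impulse response at t = 1 min
  ode <- deSolve::ode(
    y = c(Cf = kp$K1, Cb = 0), times = c(0, 1),
    func = function(t, y, p) {
      list(c(-(kp$k2 + kp$k3) * y[1] + kp$k4 * y[2],
             kp$k3 * y[1] - kp$k4 * y[2]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(irf(ap, 1), sum(ode[2, c("Cf", "Cb")]), tolerance = 1e-8)
})

test_that("analytic TAC equals the fine-grid numeric convolution", {
  fi <- default_feng_input()
  fs <- default_frame_scheme()
  dk <- fdg_decay_const()
  tg <- seq(0, 40, by = 0.001)
  cp <- list(t = tg, values = feng_cp(fi, tg))
  for (kp in table1_kinetics()) {
    an <- tissue_tac_analytic(kp, fi, fs, dk)$values
    nu <- tissue_tac_numeric(kp, cp, fs, dk)$values
    expect_lt(max(abs(an - nu) / pmax(abs(nu), 1e-12)), 1e-4)
  }
})

test_that("analytic TAC respects the blood-only and empty-voxel limits and
           near-coincident rate handling", {
  fi <- default_feng_input()
  fs <- default_frame_scheme()
  # fv = 1: the tissue term is multiplied by zero, leaving the input curve
  kp <- kinetic_params(0.5, 0.3, 0.05, 0.01, fv = 1)
  expect_equal(tissue_tac_analytic(kp, fi, fs)$values,
               feng_cp(fi, fs$t_mid), tolerance = 1e-12)
  # alpha1 = alpha2 = 0 and fv = 0: identically zero
  z <- tissue_tac_analytic(aux_params(0, 0, 0, 0, 1), fi, fs)$values
  expect_identical(z, rep(0, fs$n_frames))
  # beta crossing a lambda value stays finite and continuous
  for (k2 in c(0.05 - 2e-9, 0.05, 0.05 + 2e-9)) {
    v <- tissue_tac_analytic(kinetic_params(1, k2, 0, 0, 0), fi, fs)$values
    expect_true(all(is.finite(v)))
  }
  v1 <- tissue_tac_analytic(kinetic_params(1, 0.05 - 1e-9, 0, 0, 0), fi,
                            fs)$values
  v2 <- tissue_tac_analytic(kinetic_params(1, 0.05 + 1e-9, 0, 0, 0), fi,
                            fs)$values
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("numeric convolution recovers the IRF for an impulse input and
           converges at second order", {
  fs <- frame_scheme(seq(0, 9), seq(1, 10))
  kp <- kinetic_params(0.7, 0.4, 0.05, 0.003, fv = 0)
  ap <- aux_from_kinetic(kp)
  dt <- 0.001
  tg <- seq(0, 10, by = dt)
  # discrete delta of unit area convolves to the impulse response
  # trapezoid quadrature gives the first grid point half weight, so the
  # unit-area discrete delta has height 2/dt
  imp <- c(2 / dt, rep(0, length(tg) - 1))
  out <- tissue_tac_numeric(kp, list(t = tg, values = imp), fs, dk = 0)
  expect_equal(out$values, irf(ap, fs$t_mid), tolerance = 1e-3)
  # zero input -> zero output
  zed <- tissue_tac_numeric(kp, list(t = tg, values = rep(0, length(tg))),
                            fs, dk = 0)
  expect_identical(zed$values, rep(0, fs$n_frames))
  # error halves by ~4x when the grid step halves (trapezoid quadrature)
  fi <- default_feng_input()
  fs24 <- default_frame_scheme()
  an <- tissue_tac_analytic(table1_kinetics()$gray, fi, fs24)$values
  err <- sapply(c(0.004, 0.002, 0.001), function(h) {
    tg <- seq(0, 40, by = h)
    nu <- tissue_tac_numeric(table1_kinetics()$gray,
                             list(t = tg, values = feng_cp(fi, tg)),
                             fs24)$values
    max(abs(an - nu))
  })
  expect_gt(err[2] / err[3], 3.3)
  expect_lt(err[2] / err[3], 4.7)
  expect_warning(
    tissue_tac_numeric(table1_kinetics()$gray,
                       list(t = seq(0, 40, by = 0.05),
                            values = feng_cp(fi, seq(0, 40, by = 0.05))),
                       fs24), "grid coarser")
})

test_that("Ki macroparameter follows K1*k3/(k2+k3) and its limits", {
  kp <- table1_kinetics()$gray
  expect_equal(ki_macro(kp), 0.6805 * 0.0533 / (0.3945 + 0.0533))
  expect_equal(ki_macro(kinetic_params(1, 0.5, 0, 0.1)), 0)
  expect_equal(ki_macro(kinetic_params(1, 0, 0.5, 0.1)), 1)
  expect_error(ki_macro(kinetic_params(1, 0, 0, 0.1)), "k2 \\+ k3")
  ki <- ki_macro(kp)
  expect_gte(ki, 0)
  expect_lte(ki, kp$K1)
})

test_that("Feng model fitting recovers generating parameters", {
  fi <- default_feng_input()
  fs <- default_frame_scheme()
  truth <- feng_cp(fi, fs$t_mid)
  fit <- fit_feng(tac(truth, fs))
  p <- unlist(fit)[1:6]
  expect_lt(max(abs(p - unlist(fi)[1:6]) / unlist(fi)[1:6]), 0.01)
  expect_lt(attr(fit, "rss"), sum((feng_cp(fi, fs$t_mid) - truth)^2) + 1e-10)
  # all-zero curve pins the amplitudes at zero
  f0 <- fit_feng(tac(rep(0, fs$n_frames), fs))
  expect_identical(c(f0$A1, f0$A2, f0$A3), c(0, 0, 0))
  # mild Gaussian noise: the bolus ramp parameters stay within 10% and
  # the fitted curve within 1% RMS of the truth (the slow-tail pair
  # A2/lambda2 and lambda3 trade off against each other and are not
  # individually identifiable at this noise level)
  set.seed(21)
  noisy <- truth + stats::rnorm(length(truth), sd = 0.01 * max(truth))
  fitn <- fit_feng(tac(pmax(noisy, 0), fs), fit_t0 = FALSE)
  expect_lt(abs(fitn$A1 - fi$A1) / fi$A1, 0.10)
  expect_lt(abs(fitn$lambda1 - fi$lambda1) / fi$lambda1, 0.10)
  expect_lt(sqrt(mean((feng_cp(fitn, fs$t_mid) - truth)^2)) / max(truth),
            0.01)
})

test_that("frame schemes validate timing and expose mid-times", {
  fs <- default_frame_scheme()
  expect_equal(fs$n_frames, 24)
  expect_equal(fs$end[24], 40)
  expect_equal(fs$t_mid, (fs$start + fs$end) / 2)
  expect_error(frame_scheme(c(0, 2), c(1, 3)), "contiguous")
  expect_error(frame_scheme(0, 0), "end > start")
})

test_that("parameter sets round-trip through YAML and JSON key-value files", {
  kp <- table1_kinetics()$gray
  fi <- default_feng_input()
  fy <- file.path(tempdir(), "kp.yaml")
  fj <- file.path(tempdir(), "fi.json")
  write_params(kp, fy)
  write_params(fi, fj)
  expect_equal(unlist(read_params(fy)), unlist(kp))
  expect_equal(unlist(read_params(fj)), unlist(fi))
  ft <- file.path(tempdir(), "junk.yaml")
  yaml::write_yaml(list(a = 1), ft)
  expect_error(read_params(ft), "recognizable")
})

test_that("TAC export table carries the frame timing", {
  fs <- default_frame_scheme()
  x <- tac(seq_len(fs$n_frames) * 1.0, fs)
  tab <- tac_table(x)
  expect_named(tab, c("frame_start", "frame_end", "t_mid", "value"))
  expect_equal(tab$t_mid, fs$t_mid)
  expect_error(tac(1:3, fs), "length")
})
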