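test_that("decay_kernel matches the closed form and scales with B0", {
  dk <- decay_kernel(11.7, 2.6752e8)
  expect_equal(dk$a, 2 * pi * 2.6752e8 * 11.7 / (9 * sqrt(3)) * 1e-6,
               tolerance = 1e-12)
  expect_equal(signif(dk$a_khz_per_ppm, 3), 1.26)
  # linear in B0: a(3 T) = a(11.7 T) * 3/11.7 ~ 0.323 kHz/ppm
  expect_equal(decay_kernel(3)$a_khz_per_ppm,
               dk$a_khz_per_ppm * 3 / 11.7, tolerance = 1e-12)
  expect_equal(decay_kernel(3)$a_khz_per_ppm, 0.3234851, tolerance = 1e-6)
  expect_error(decay_kernel(0), "B0")
  expect_error(decay_kernel(3, -1), "gamma")
})

test_that("synthesize_signal applies the Lorentz-sphere phase factor", {
  # chi = 0 -> y = M exactly, real positive
  m <- c(1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25, 0.2)
  y0 <- synthesize_signal(m, rep(0, 8), p8)
  expect_equal(y0, complex(real = m, imaginary = 0))

  # M = 1, chi = 0.1 ppm, t = 0.01 s -> arg ~ 2.0865 rad
  p1 <- acq_params(echo_times = 0.01)
  y1 <- synthesize_signal(1, 0.1, p1)
  expect_equal(Arg(y1), 2.086656, tolerance = 1e-6)

  # conjugation symmetry: negating chi conjugates y
  set.seed(5)
  chi <- stats::rnorm(8, 0, 0.02)
  expect_equal(synthesize_signal(m, -chi, p8),
               Conj(synthesize_signal(m, chi, p8)), tolerance = 1e-12)

  expect_error(synthesize_signal(m[1:4], chi, p8), "shape")

  # 4D array form agrees with the vector form
  M4 <- array(stats::runif(2 * 2 * 2 * 8, 0.2, 1), c(2, 2, 2, 8))
  X4 <- array(stats::rnorm(2 * 2 * 2 * 8, 0, 0.02), c(2, 2, 2, 8))
  Y4 <- synthesize_signal(M4, X4, p8)
  off <- 3 + 8 * (0:7)
  expect_equal(Y4[off], synthesize_signal(M4[off], X4[off], p8),
               tolerance = 1e-12)
})

test_that("model_signal limits: t = 0, one pool, symmetric cancellation", {
  a <- decay_kernel(p8$B0, p8$gamma)$a
  th <- list(alpha0 = 0.3, alpha_plus = 0.5, alpha_minus = 0.2,
             r2star0 = 44, chi_plus = 0.02, chi_minus = -0.03)
  expect_equal(model_signal(th, a, 0, p8), complex(real = 1, imaginary = 0))

  th0 <- list(alpha0 = 0.7, alpha_plus = 0, alpha_minus = 0,
              r2star0 = 60, chi_plus = 0.02, chi_minus = -0.02)
  s <- model_signal(th0, a, p8$echo_times, p8)
  expect_equal(Im(s), rep(0, 8))
  expect_equal(Re(s), 0.7 * exp(-60 * p8$echo_times))

  # equal amplitudes with opposite chi: phases cancel pairwise -> S real;
  # both pools decay at R2*0 + a*0.05, with a cosine beat from the
  # counter-rotating phase factors
  ths <- list(alpha0 = 0, alpha_plus = 0.5, alpha_minus = 0.5,
              r2star0 = 50, chi_plus = 0.05, chi_minus = -0.05)
  ss <- model_signal(ths, a, p8$echo_times, p8)
  expect_lt(max(abs(Im(ss))), 1e-15)
  bb <- chisep:::phase_rate(p8)
  expect_equal(Re(ss),
               cos(bb * 0.05 * p8$echo_times) *
                 exp(-(50 + a * 0.05) * p8$echo_times),
               tolerance = 1e-12)
  expect_error(model_signal(ths, a, -0.001, p8), ">= 0")
})

test_that("fit_three_pool recovers noiseless one- and two-pool voxels", {
  a <- decay_kernel(p8$B0, p8$gamma)$a
  y1 <- model_signal(list(alpha0 = 1, alpha_plus = 0, alpha_minus = 0,
                          r2star0 = 60, chi_plus = 0, chi_minus = 0),
                     a, p8$echo_times, p8)
  f1 <- fit_three_pool(y1, p8)
  expect_lt(abs(f1$alpha0 - 1), 0.01)
  expect_lt(abs(f1$r2star0 - 60) / 60, 0.01)
  expect_gte(f1$C0, 0.99)

  y2 <- model_signal(list(alpha0 = 0.6, alpha_plus = 0.4, alpha_minus = 0,
                          r2star0 = 50, chi_plus = 0.03, chi_minus = 0),
                     a, p8$echo_times, p8)
  f2 <- fit_three_pool(y2, p8)
  expect_lt(abs(f2$chi_plus - 0.03) / 0.03, 0.10)
  expect_lt(abs(f2$C_plus - 0.4), 0.05)

  # errors
  expect_error(fit_three_pool(y2[1:4], acq_params(echo_times = p8$echo_times[1:4])),
               ">= 6 echoes")
  expect_error(fit_three_pool(rep(0 + 0i, 8), p8), "all-zero")
  ybad <- y2; ybad[3] <- NaN + 0i
  expect_error(fit_three_pool(ybad, p8), "NaN")
})

test_that("fit_three_pool is a fixed point at its own optimum", {
  a <- decay_kernel(p8$B0, p8$gamma)$a
  set.seed(21)
  sv <- sim_voxel(0.35, 0.3, 0.025, -0.018, 55, snr = 60)
  f <- fit_three_pool(sv$y, p8)
  # regenerate a noiseless voxel from the fitted parameters and refit
  y2 <- model_signal(f[c("alpha0", "alpha_plus", "alpha_minus", "r2star0",
                         "chi_plus", "chi_minus")], a, p8$echo_times, p8)
  f2 <- fit_three_pool(y2, p8)
  expect_lt(abs(f2$chi_plus - f$chi_plus), 1e-3)
  expect_lt(abs(f2$chi_minus - f$chi_minus), 1e-3)
  expect_lt(abs(f2$r2star0 - f$r2star0) / f$r2star0, 0.01)
  expect_lt(abs(f2$C_plus - f$C_plus), 0.01)
})

test_that("objective trace is non-increasing and constraints always hold", {
  set.seed(31)
  for (i in 1:25) {
    repeat {
      Cp <- stats::runif(1, 0.1, 0.6); Cm <- stats::runif(1, 0.1, 0.6)
      if (Cp + Cm <= 0.9) break
    }
    sv <- sim_voxel(Cp, Cm,
                    stats::runif(1, 0.005, 0.05),
                    -stats::runif(1, 0.005, 0.05),
                    stats::runif(1, 30, 80),
                    snr = sample(c(20, 40, Inf), 1))
    f <- fit_three_pool(sv$y, p8)
    expect_true(all(diff(f$objective) <= 1e-10))
    expect_true(f$alpha0 >= 0 && f$alpha_plus >= 0 && f$alpha_minus >= 0)
    expect_gt(f$r2star0, 0)
    expect_true(f$chi_plus >= 0 && f$chi_plus < 0.1)
    expect_true(f$chi_minus <= 0 && f$chi_minus > -0.1)
    expect_gte(f$pcs, 0)
    expect_lte(f$dcs, 0)
  }
})

test_that("signal_fractions normalizes, flags degenerate voxels", {
  fr <- signal_fractions(1, 1, 2)
  expect_equal(c(fr$C0, fr$C_plus, fr$C_minus), c(0.25, 0.25, 0.5))
  fr2 <- signal_fractions(2, 0, 0)
  expect_equal(c(fr2$C0, fr2$C_plus, fr2$C_minus), c(1, 0, 0))
  fr0 <- signal_fractions(c(0, 1), c(0, 1), c(0, 2))
  expect_false(fr0$valid[1])
  expect_true(fr0$valid[2])
  expect_equal(fr0$C0[1], 0)
  a0 <- array(stats::runif(27, 0.1, 1), c(3, 3, 3))
  ap <- array(stats::runif(27, 0, 1), c(3, 3, 3))
  am <- array(stats::runif(27, 0, 1), c(3, 3, 3))
  fr3 <- signal_fractions(a0, ap, am)
  expect_equal(fr3$C0 + fr3$C_plus + fr3$C_minus, array(1, c(3, 3, 3)),
               tolerance = 1e-9)
  expect_error(signal_fractions(-1, 0, 0), ">= 0")
})

test_that("composite_maps is the fraction-weighted susceptibility", {
  cm <- composite_maps(list(C_plus = 0.5, C_minus = 0.2), 0.02, -0.01)
  expect_equal(cm$PCS, 0.01)           # 10 ppb
  expect_equal(to_ppb(cm$PCS), 10)
  expect_equal(cm$DCS, -0.002)
  expect_equal(composite_maps(list(C_plus = 0.3, C_minus = 0), 0.02, -0.05)$DCS, 0)
  neutral <- composite_maps(list(C_plus = 0, C_minus = 0), 0, 0)
  expect_equal(neutral$PCS, 0)
  expect_equal(neutral$DCS, 0)
})

test_that("volume fitter applies the magnitude floor and fills maps", {
  p <- acq_params()
  a <- decay_kernel(p$B0, p$gamma)$a
  ph <- make_phantom(c(16, 16, 16), "shells", seed = 12)
  ser <- forward_signal(ph, p)
  mask <- ph$mask$mask
  # per-echo chi implied by the voxel phase (voxelwise mode has no dipole)
  b <- chisep:::phase_rate(p)
  tearr <- aperm(array(p$echo_times, c(8, 16, 16, 16)), c(2, 3, 4, 1))
  chi_t <- ser$phase / (b * tearr)
  # kill the signal in a corner of the mask to trigger the floor
  low <- which(mask)[1:5]
  nxyz <- 16^3
  for (e in 0:7) ser$magnitude[low + nxyz * e] <- 1e-6
  sub <- mask & array(seq_len(nxyz) %% 29 == 0, dim(mask))  # subsample
  sub[low] <- TRUE
  fit <- fit_three_pool_volume(ser$magnitude, chi_t, sub, p, a)
  expect_true(all(!fit$fitted_mask[low]))
  expect_equal(fit$n_fitted, sum(fit$fitted_mask))
  tm <- truth_maps(ph)
  fitted <- fit$fitted_mask
  # noiseless voxelwise data: fitted bulk PCS+DCS tracks the truth closely
  expect_gt(stats::cor(fit$pcs[fitted] + fit$dcs[fitted],
                       tm$chi_bulk[fitted]), 0.95)
  expect_true(all(fit$pcs[fitted] >= 0))
  expect_true(all(fit$dcs[fitted] <= 0))
})
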