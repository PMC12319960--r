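test_that("phantom generation is deterministic and covers the source types", {
  ph1 <- make_phantom(c(32, 32, 32), "shells", seed = 1)
  ph2 <- make_phantom(c(32, 32, 32), "shells", seed = 1)
  expect_identical(ph1$labels$labels, ph2$labels$labels)
  expect_identical(ph1$param_table, ph2$param_table)
  expect_identical(ph1$background_coeffs, ph2$background_coeffs)

  tab <- ph1$param_table
  expect_gte(nrow(tab), 4L)
  expect_true(any(tab$chi_plus > 0 & tab$chi_minus == 0))   # para-dominant
  expect_true(any(tab$chi_minus < 0 & tab$chi_plus == 0))   # dia-dominant
  expect_true(any(tab$chi_plus > 0 & tab$chi_minus < 0))    # mixed
  expect_true(any(tab$chi_plus == 0 & tab$chi_minus == 0))  # neutral
  expect_true(all(tab$chi_plus >= 0 & tab$chi_plus < 0.1))
  expect_true(all(tab$chi_minus <= 0 & tab$chi_minus > -0.1))
  expect_true(all(tab$r2star0 > 0))

  expect_error(make_phantom(c(8, 32, 32), "shells"), ">= 16")
  expect_error(make_phantom(c(32, 32, 32), "nope"), "arg")

  # every label in the volume is named, alphas positive in mask
  tm <- truth_maps(ph1)
  msk <- ph1$mask$mask
  expect_true(all(tm$alpha0[msk] + tm$alpha_plus[msk] + tm$alpha_minus[msk] > 0))
})

test_that("two_group layout draws the lesion effect per group", {
  chiA <- vapply(1:10, function(s) {
    ph <- make_phantom(c(24, 24, 24), "two_group", seed = s)
    with(ph$param_table, chi_plus[name == "lesion"])
  }, numeric(1))
  chiB <- vapply(1:10, function(s) {
    ph <- make_phantom(c(24, 24, 24), "two_group", seed = s,
                       config = list(group = "B"))
    with(ph$param_table, chi_plus[name == "lesion"])
  }, numeric(1))
  expect_true(all(chiA > 0))
  # group B shifted by the configured effect (0.025 ppm >> draw s.d.)
  expect_gt(min(chiB), max(chiA))
  ph <- make_phantom(c(24, 24, 24), "two_group", seed = 1)
  expect_true("lesion" %in% ph$labels$names)
  expect_gt(sum(ph$labels$labels == 6L), 0)
})

test_that("forward_signal reproduces the three-pool model pointwise", {
  a <- decay_kernel(p8$B0, p8$gamma)$a
  # single neutral pool: |S| = exp(-R t), phase 0
  one <- model_signal(list(alpha0 = 1, alpha_plus = 0, alpha_minus = 0,
                           r2star0 = 50, chi_plus = 0, chi_minus = 0),
                      a, 0.02, p8)
  expect_equal(Mod(one), exp(-1), tolerance = 1e-12)
  expect_equal(Arg(one), 0)

  # t = 0: S = alpha0 + alpha+ + alpha-
  s0 <- model_signal(list(alpha0 = 0.2, alpha_plus = 0.3, alpha_minus = 0.4,
                          r2star0 = 77, chi_plus = 0.03, chi_minus = -0.02),
                     a, 0, p8)
  expect_equal(s0, complex(real = 0.9, imaginary = 0))

  # pure paramagnetic pool phase: (2/3) chi gamma B0 t * 1e-6
  sp <- model_signal(list(alpha0 = 0, alpha_plus = 1, alpha_minus = 0,
                          r2star0 = 0, chi_plus = 0.1, chi_minus = 0),
                     a, 0.01, p8)
  expect_equal(Arg(sp), wrap_phase(2.086656), tolerance = 1e-6)

  # the volume forward model agrees with the scalar model at a probe voxel
  ph <- make_phantom(c(24, 24, 24), "shells", seed = 2)
  ser <- forward_signal(ph, p8)
  tm <- truth_maps(ph)
  v <- which(ph$labels$labels == 4L)[1]  # a mixed voxel
  th <- list(alpha0 = tm$alpha0[v], alpha_plus = tm$alpha_plus[v],
             alpha_minus = tm$alpha_minus[v], r2star0 = tm$r2star0[v],
             chi_plus = tm$chi_plus[v], chi_minus = tm$chi_minus[v])
  sref <- model_signal(th, a, p8$echo_times, p8)
  nxyz <- prod(dim(ph$labels$labels))
  off <- v + nxyz * (0:7)
  expect_equal(ser$magnitude[off], Mod(sref), tolerance = 1e-12)
  expect_equal(ser$phase[off], wrap_phase(Arg(sref)), tolerance = 1e-12)
})

test_that("single-pool log-magnitude is linear in t with slope -(R + a|chi|)", {
  a <- decay_kernel(p8$B0, p8$gamma)$a
  t <- p8$echo_times
  for (chi in c(0.02, -0.03)) {
    th <- list(alpha0 = 0,
               alpha_plus = if (chi > 0) 1 else 0,
               alpha_minus = if (chi < 0) 1 else 0,
               r2star0 = 40, chi_plus = max(chi, 0), chi_minus = min(chi, 0))
    y <- model_signal(th, a, t, p8)
    slope <- stats::coef(stats::lm(log(Mod(y)) ~ t))[2]
    expect_equal(unname(slope), -(40 + a * abs(chi)), tolerance = 1e-9)
  }
})

test_that("forward_field: uniform susceptibility gives background-only phase", {
  ph <- make_phantom(c(24, 24, 24), "shells", seed = 3)
  # collapse all regions to one uniform mixed composition
  ph$param_table$chi_plus <- 0.02
  ph$param_table$chi_minus <- -0.01
  ph$param_table$alpha0 <- 0.4
  ph$param_table$alpha_plus <- 0.3
  ph$param_table$alpha_minus <- 0.3
  ph$param_table$r2star0 <- 50
  tm <- truth_maps(ph)
  # chi_bulk uniform inside mask but 0 outside: zero out the outside too by
  # checking the kernel property directly on a truly uniform volume
  k <- dipole_kernel(c(24, 24, 24), p8$voxel_size, p8$b0_dir)
  unif <- array(0.011, c(24, 24, 24))
  fld <- chisep:::apply_multiplier(unif, k$values)
  expect_lt(max(abs(fld)), 1e-12)

  ser1 <- forward_field(ph, p8, add_background = TRUE)
  ser2 <- forward_field(ph, p8, add_background = TRUE)
  expect_identical(ser1$phase, ser2$phase)   # determinism
  expect_identical(ser1$magnitude, ser2$magnitude)
})

test_that("forward_field matches the analytic sphere dipole field", {
  n <- 48
  ph <- make_phantom(c(n, n, n), "shells", seed = 1)
  # sphere of chi = 0.05 ppm at centre, zero elsewhere, no background
  shape <- c(n, n, n)
  co <- chisep:::normalized_coords(shape)
  rad_vox <- 6
  rr <- sqrt(co$x^2 + co$y^2 + co$z^2) * (n / 2)
  chi <- array(0, shape)
  chi[rr <= rad_vox] <- 0.05
  k <- dipole_kernel(shape, c(1, 1, 1), c(0, 0, 1))
  fld <- chisep:::apply_multiplier(chi, k$values)  # ppm field shift
  # analytic external field of a uniformly "magnetized" sphere:
  # delta(r) = (chi/3) (R/r)^3 (3 cos^2 theta - 1); internal field = 0
  cx <- (seq_len(n) - (n + 1) / 2)  # sphere centre per normalized_coords
  X <- array(rep(cx, times = n * n), shape)
  Y <- array(rep(rep(cx, each = n), times = n), shape)
  Z <- array(rep(cx, each = n * n), shape)
  r <- sqrt(X^2 + Y^2 + Z^2)
  cos2 <- ifelse(r > 0, (Z / pmax(r, 1e-9))^2, 0)
  Rv <- (sum(chi > 0) * 3 / (4 * pi))^(1 / 3)  # radius from actual volume
  ana <- (0.05 / 3) * (Rv / pmax(r, 1e-9))^3 * (3 * cos2 - 1)
  sel <- r > rad_vox + 3 & r < n / 2 - 6  # outside, away from boundary/wrap
  err <- abs(fld[sel] - ana[sel])
  scale <- max(abs(ana[sel]))
  expect_lt(stats::quantile(err, 0.95) / scale, 0.05)
  # interior field (Lorentz-corrected) is ~ 0 away from the surface
  expect_lt(max(abs(fld[r < rad_vox - 2])) / 0.05, 0.02)
})

test_that("add_noise has the stated level, is seeded, and Inf is identity", {
  ph <- make_phantom(c(24, 24, 24), "shells", seed = 4)
  ser <- forward_signal(ph, p8)
  expect_identical(add_noise(ser, Inf), ser)

  n1 <- add_noise(ser, 20, seed = 42, mask = ph$mask$mask)
  n2 <- add_noise(ser, 20, seed = 42, mask = ph$mask$mask)
  expect_identical(n1$magnitude, n2$magnitude)

  m1 <- ser$magnitude[, , , 1]
  nominal <- mean(m1[ph$mask$mask]) / 20
  clean <- ser$magnitude * exp(1i * ser$phase)
  noisy <- n1$magnitude * exp(1i * n1$phase)
  emp <- stats::sd(Re(noisy - clean))
  expect_lt(abs(emp - nominal) / nominal, 0.03)
  expect_error(add_noise(ser, -1), "snr")
})
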