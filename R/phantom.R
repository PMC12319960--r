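# Digital phantom with known three-pool ground truth.
#
# The generator stands in for fixed ex-vivo mouse-brain acquisitions: an
# ellipsoidal "brain" of labelled regions, each with its own three-pool
# parameters (alpha0/alpha+/alpha-, chi+/chi-, R2*0), surrounded by signal-
# free background (the specimens are immersed in a proton-free fluid).
# Two forward modes are provided: "voxelwise" evaluates the three-pool
# complex signal model exactly at every voxel (validates the fitter in
# isolation), and "field" additionally propagates the bulk susceptibility
# through the nonlocal dipole kernel and adds a smooth harmonic background
# field (validates the unwrap / V-SHARP / inversion chain).

#' Region parameter presets
#'
#' Three-pool parameters per phantom region. Susceptibilities are in ppm,
#' R2*0 in s^-1, alphas in arbitrary signal units. Values are desk-scale
#' stand-ins for gray matter contrast at 11.7 T: |chi| of a few hundredths
#' of a ppm and R2*0 around 40-60 s^-1.
#' @keywords internal
phantom_param_presets <- function() {
  data.frame(
    name        = c("neutral_core", "paramagnetic", "diamagnetic", "mixed",
                    "neutral_rim", "lesion"),
    alpha0      = c(1.00, 0.65, 0.70, 0.40, 0.90, 0.55),
    alpha_plus  = c(0.00, 0.35, 0.00, 0.30, 0.00, 0.30),
    alpha_minus = c(0.00, 0.00, 0.30, 0.30, 0.00, 0.15),
    chi_plus    = c(0.000, 0.020, 0.000, 0.010, 0.000, 0.010),
    chi_minus   = c(0.000, 0.000, -0.015, -0.010, 0.000, -0.005),
    r2star0     = c(45, 50, 55, 50, 40, 55),
    stringsAsFactors = FALSE
  )
}

# Per-subject draw of a two_group parameter table: every region parameter
# gets lognormal between-subject variation (CV `subject_cv`), and the lesion
# chi+ is drawn N(lesion_mu, lesion_sd), shifted by `effect_ppm` in group B.
two_group_param_draw <- function(seed, group = c("A", "B"),
                                 effect_ppm = 0.025,
                                 subject_cv = 0.10,
                                 lesion_mu = 0.010, lesion_sd = 0.0015) {
  group <- match.arg(group)
  tab <- phantom_param_presets()
  with_seed(seed, {
    mu <- lesion_mu + if (group == "B") effect_ppm else 0
    tab$chi_plus[tab$name == "lesion"] <- max(1e-4, stats::rnorm(1, mu, lesion_sd))
    for (col in c("alpha0", "alpha_plus", "alpha_minus", "chi_plus",
                  "chi_minus", "r2star0")) {
      jit <- exp(stats::rnorm(nrow(tab), 0, subject_cv))
      tab[[col]] <- tab[[col]] * jit
    }
    tab
  })
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

normalized_coords <- function(shape) {
  cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
  list(
    x = array(rep(cx, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
    z = array(rep(cz, each = shape[1] * shape[2]), shape)
  )
}

#' Generate a labelled digital phantom with three-pool ground truth
#'
#' @param grid_shape Length-3 integer vector, each entry >= 16.
#' @param layout One of `"shells"` (concentric shells), `"layered_slab"`
#'   (laminae along z, a cartoon of hippocampal layers), or `"two_group"`
#'   (shells plus an off-centre "lesion" sphere whose chi+ is drawn per
#'   subject, shifted by a configurable effect size in group B).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param config Optional list; for `two_group`: `group` ("A"/"B"),
#'   `effect_ppm` (default 0.025), `subject_cv` (default 0.10), `lesion_mu`,
#'   `lesion_sd`. For all layouts: `snr` (default 40).
#' @return A `phantom_truth` object: `labels` ([label_volume()]), `mask`
#'   ([brain_mask()]), `param_table` (one row per region), harmonic
#'   `background_coeffs` (rad/s), `snr`, `seed`, `layout`.
#' @examples
#' ph <- make_phantom(c(24, 24, 24), "shells", seed = 1)
#' ph$param_table$name
#' @export
make_phantom <- function(grid_shape, layout = c("shells", "layered_slab",
                                                "two_group"),
                         seed = 1L, config = list()) {
  layout <- match.arg(layout)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stop("grid_shape must be three integers, each >= 16")
  }
  co <- normalized_coords(grid_shape)
  r <- sqrt((co$x / 0.88)^2 + (co$y / 0.82)^2 + (co$z / 0.88)^2)
  mask <- r < 1
  labels <- array(0L, grid_shape)

  assign_shells <- function() {
    lab <- array(0L, grid_shape)
    lab[mask & r < 0.30] <- 1L                 # neutral_core
    lab[mask & r >= 0.30 & r < 0.50] <- 2L     # paramagnetic
    lab[mask & r >= 0.50 & r < 0.70] <- 3L     # diamagnetic
    lab[mask & r >= 0.70 & r < 0.88] <- 4L     # mixed
    lab[mask & r >= 0.88] <- 5L                # neutral_rim
    lab
  }

  if (layout == "shells") {
    labels <- assign_shells()
    names_tab <- c(`1` = "neutral_core", `2` = "paramagnetic",
                   `3` = "diamagnetic", `4` = "mixed", `5` = "neutral_rim")
    ptab <- phantom_param_presets()[c(1, 2, 3, 4, 5), ]
    ptab$label <- 1:5
  } else if (layout == "layered_slab") {
    labels <- array(0L, grid_shape)
    # cycling laminae along z inside the ellipsoid
    zi <- slice.index(labels, 3)
    thick <- max(2L, grid_shape[3] %/% 10L)
    lam <- 1L + ((zi - 1L) %/% thick) %% 5L
    labels[mask] <- lam[mask]
    names_tab <- c(`1` = "neutral_core", `2` = "paramagnetic",
                   `3` = "diamagnetic", `4` = "mixed", `5` = "neutral_rim")
    ptab <- phantom_param_presets()[c(1, 2, 3, 4, 5), ]
    ptab$label <- 1:5
  } else { # two_group
    labels <- assign_shells()
    les <- sqrt(((co$x - 0.35) / 0.22)^2 + (co$y / 0.22)^2 +
                ((co$z - 0.2) / 0.22)^2) < 1
    labels[les & mask] <- 6L
    names_tab <- c(`1` = "neutral_core", `2` = "paramagnetic",
                   `3` = "diamagnetic", `4` = "mixed", `5` = "neutral_rim",
                   `6` = "lesion")
    grp <- config$group %||% "A"
    ptab <- two_group_param_draw(
      seed, group = grp,
      effect_ppm = config$effect_ppm %||% 0.025,
      subject_cv = config$subject_cv %||% 0.10,
      lesion_mu = config$lesion_mu %||% 0.010,
      lesion_sd = config$lesion_sd %||% 0.0015)
    ptab$label <- 1:6
  }

  # harmonic 2nd-order background field (rad/s), from sources outside the
  # brain, scaled so peak in-mask phase at the last default echo is ~3*pi
  bg <- with_seed(seed + 104729L, stats::rnorm(8))
  basis <- with(co, list(x, y, z, x * y, x * z, y * z,
                         x^2 - y^2, y^2 - z^2))
  f_bg <- Reduce(`+`, Map(function(c, b) c * b, as.list(bg), basis))
  te_last <- 0.004 + 0.0038 * 7
  scale <- (3 * pi / te_last) / max(abs(f_bg[mask]))
  bg <- bg * scale

  structure(
    list(labels = label_volume(labels, names_tab),
         mask = brain_mask(mask),
         param_table = ptab[, c("label", "name", "alpha0", "alpha_plus",
                                "alpha_minus", "chi_plus", "chi_minus",
                                "r2star0")],
         background_coeffs = bg,
         snr = config$snr %||% 40,
         seed = as.integer(seed),
         layout = layout,
         grid_shape = grid_shape),
    class = "phantom_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, %s grid, %d regions, seed %d\n",
              x$layout, paste(x$grid_shape, collapse = "x"),
              nrow(x$param_table), x$seed))
  invisible(x)
}

#' Expand phantom truth into voxelwise parameter maps
#'
#' @param truth A [make_phantom()] object.
#' @return List of 3D maps: `alpha0`, `alpha_plus`, `alpha_minus`,
#'   `chi_plus`, `chi_minus`, `r2star0`, fraction maps `C0`, `C_plus`,
#'   `C_minus`, and the bulk susceptibility `chi_bulk = C+ chi+ + C- chi-`
#'   (ppm). Background voxels are zero.
#' @export
truth_maps <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  lab <- truth$labels$labels
  tab <- truth$param_table
  lut <- function(col) {
    v <- numeric(max(tab$label) + 1L)
    v[tab$label + 1L] <- tab[[col]]
    array(v[lab + 1L], dim(lab))
  }
  m <- list(alpha0 = lut("alpha0"), alpha_plus = lut("alpha_plus"),
            alpha_minus = lut("alpha_minus"), chi_plus = lut("chi_plus"),
            chi_minus = lut("chi_minus"), r2star0 = lut("r2star0"))
  tot <- m$alpha0 + m$alpha_plus + m$alpha_minus
  safe <- ifelse(tot > 0, tot, 1)
  m$C0 <- ifelse(tot > 0, m$alpha0 / safe, 0)
  m$C_plus <- ifelse(tot > 0, m$alpha_plus / safe, 0)
  m$C_minus <- ifelse(tot > 0, m$alpha_minus / safe, 0)
  m$chi_bulk <- m$C_plus * m$chi_plus + m$C_minus * m$chi_minus
  m
}

# Evaluate the stored harmonic background polynomial (rad/s) on the grid.
background_field <- function(truth) {
  co <- normalized_coords(truth$grid_shape)
  basis <- with(co, list(x, y, z, x * y, x * z, y * z,
                         x^2 - y^2, y^2 - z^2))
  Reduce(`+`, Map(function(c, b) c * b,
                  as.list(truth$background_coeffs), basis))
}

#' Forward-simulate the three-pool signal voxelwise (no dipole field)
#'
#' Evaluates the three-pool complex signal model at every voxel:
#' `S(t) = a0 exp(-R t) + a+ exp(-(R + a chi+) t + i b chi+ t)
#'       + a- exp(-(R - a chi-) t + i b chi- t)`
#' with `b = (2/3) gamma B0 1e-6` rad/s per ppm (Lorentz sphere factor) and
#' `a` the static-dephasing magnitude decay kernel in s^-1/ppm.
#'
#' @param truth A [make_phantom()] object.
#' @param params [acq_params()].
#' @param a Decay kernel in s^-1/ppm; default [decay_kernel()] at `params`.
#' @return A noiseless [complex_echo_series()].
#' @export
forward_signal <- function(truth, params = acq_params(),
                           a = decay_kernel(params$B0, params$gamma)$a) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (a <= 0) stop("decay kernel a must be > 0")
  te <- params$echo_times
  if (any(te <= 0)) stop("echo times must be positive")
  m <- truth_maps(truth)
  b <- (2 / 3) * params$gamma * params$B0 * 1e-6
  shp <- c(truth$grid_shape, length(te))
  mag <- array(0, shp); ph <- array(0, shp)
  for (i in seq_along(te)) {
    t <- te[i]
    S <- m$alpha0 * exp(-m$r2star0 * t) +
      m$alpha_plus * exp(-(m$r2star0 + a * m$chi_plus) * t) *
        exp(1i * b * m$chi_plus * t) +
      m$alpha_minus * exp(-(m$r2star0 - a * m$chi_minus) * t) *
        exp(1i * b * m$chi_minus * t)
    mag[, , , i] <- Mod(S)
    ph[, , , i] <- Arg(S)
  }
  complex_echo_series(mag, wrap_phase(ph), params)
}

#' Forward-simulate with the nonlocal dipole field and background
#'
#' The bulk susceptibility `chi_bulk = C+ chi+ + C- chi-` is convolved with
#' the unit dipole kernel to give the local frequency offset; a smooth
#' harmonic background polynomial is optionally added (scaled to wrap the
#' late-echo phase); magnitude decays with the three-pool magnitude terms.
#' This exercises the unwrap / V-SHARP / dipole-inversion chain.
#'
#' @inheritParams forward_signal
#' @param add_background Add the stored harmonic background field.
#' @return A noiseless [complex_echo_series()] (phase wrapped).
#' @export
forward_field <- function(truth, params = acq_params(),
                          a = decay_kernel(params$B0, params$gamma)$a,
                          add_background = TRUE) {
  stopifnot(inherits(truth, "phantom_truth"))
  te <- params$echo_times
  m <- truth_maps(truth)
  D <- dipole_kernel(truth$grid_shape, params$voxel_size, params$b0_dir)
  freq <- params$gamma * params$B0 * 1e-6 *
    apply_multiplier(m$chi_bulk, D$values)      # rad/s
  if (add_background) freq <- freq + background_field(truth)
  shp <- c(truth$grid_shape, length(te))
  mag <- array(0, shp); ph <- array(0, shp)
  for (i in seq_along(te)) {
    t <- te[i]
    mag[, , , i] <- m$alpha0 * exp(-m$r2star0 * t) +
      m$alpha_plus * exp(-(m$r2star0 + a * m$chi_plus) * t) +
      m$alpha_minus * exp(-(m$r2star0 - a * m$chi_minus) * t)
    ph[, , , i] <- freq * t
  }
  complex_echo_series(mag, wrap_phase(ph), params)
}

#' Add complex Gaussian noise to an echo series
#'
#' Independent zero-mean Gaussian noise with standard deviation
#' `mean(in-mask TE1 magnitude) / snr` is added to the real and imaginary
#' channels; magnitude and phase are recomputed.
#'
#' @param series A [complex_echo_series()].
#' @param snr Signal-to-noise ratio on the first-echo magnitude; `Inf`
#'   returns the input unchanged.
#' @param seed Integer seed (restores the caller's RNG stream afterwards).
#' @param mask Optional 3D logical array over which the TE1 mean is taken;
#'   defaults to voxels with positive TE1 magnitude.
#' @return A noisy [complex_echo_series()].
#' @export
add_noise <- function(series, snr = 40, seed = 1L, mask = NULL) {
  stopifnot(inherits(series, "complex_echo_series"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0")
  if (!is.finite(snr)) return(series)
  m1 <- series$magnitude[, , , 1]
  if (is.null(mask)) mask <- m1 > 0
  sd <- mean(m1[mask]) / snr
  cplx <- series$magnitude * exp(1i * series$phase)
  n <- length(cplx)
  noise <- with_seed(seed, complex(real = stats::rnorm(n, 0, sd),
                                   imaginary = stats::rnorm(n, 0, sd)))
  cplx <- cplx + array(noise, dim(cplx))
  complex_echo_series(Mod(cplx), wrap_phase(Arg(cplx)), series$params)
}

#' One-call phantom simulation
#'
#' Convenience wrapper: phantom, forward model, optional noise.
#'
#' @inheritParams make_phantom
#' @param params [acq_params()].
#' @param mode `"voxelwise"` ([forward_signal()]) or `"field"`
#'   ([forward_field()]).
#' @param snr Noise level; `Inf` for noiseless.
#' @param add_background Passed to [forward_field()].
#' @return List with `truth` and `series`.
#' @export
simulate_phantom <- function(grid_shape = c(48, 48, 48), layout = "shells",
                             seed = 1L, params = acq_params(),
                             mode = c("field", "voxelwise"), snr = 40,
                             add_background = TRUE, config = list()) {
  mode <- match.arg(mode)
  truth <- make_phantom(grid_shape, layout, seed, config)
  series <- if (mode == "voxelwise") {
    forward_signal(truth, params)
  } else {
    forward_field(truth, params, add_background = add_background)
  }
  if (is.finite(snr)) {
    series <- add_noise(series, snr, seed = truth$seed + 7L,
                        mask = truth$mask$mask)
  }
  list(truth = truth, series = series)
}
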