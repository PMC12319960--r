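# Dipole inversion: local field maps (ppm) -> susceptibility maps (ppm),
# referenced to the whole-brain mean. The inversion is thresholded k-space
# division (TKD) with an optional closed-form Tikhonov variant; both are
# documented stand-ins for iterative streaking-suppression methods, which
# downstream source separation does not require.

#' Unit dipole kernel on the FFT grid
#'
#' `D(k) = 1/3 - (k . b0)^2 / |k|^2`, with `D(0) = 0` by convention. Values
#' lie in `[-2/3, 1/3]`: `-2/3` for k along B0, `1/3` for k perpendicular,
#' and 0 at the magic angle.
#'
#' @param shape Length-3 grid dimensions (each >= 8).
#' @param voxel_size Length-3 voxel size in mm (anisotropy tilts the k grid).
#' @param b0_dir Unit vector of the B0 direction in image axes.
#' @return A `dipole_kernel` object: list with `values` (3D array), `b0_dir`,
#'   `voxel_size`.
#' @export
dipole_kernel <- function(shape, voxel_size = c(1, 1, 1), b0_dir = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("shape must be three integers, each >= 8")
  }
  voxel_size <- as.numeric(voxel_size)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  b0_dir <- as.numeric(b0_dir)
  b0_dir <- b0_dir / sqrt(sum(b0_dir^2))
  kg <- k_grid(shape, voxel_size)
  k2 <- kg$kx^2 + kg$ky^2 + kg$kz^2
  kb <- kg$kx * b0_dir[1] + kg$ky * b0_dir[2] + kg$kz * b0_dir[3]
  D <- array(0, shape)
  nz <- k2 > 0
  D[nz] <- 1 / 3 - (kb[nz]^2) / k2[nz]
  structure(list(values = D, b0_dir = b0_dir, voxel_size = voxel_size),
            class = "dipole_kernel")
}

#' Invert a local field map to susceptibility (TKD)
#'
#' Thresholded k-space division: `chi(k) = F(field)(k) / D(k)` where
#' `|D| >= delta`, and `F(field)(k) sign(D) / delta` where `|D| < delta`.
#' With `tikhonov > 0` the closed-form Tikhonov solution
#' `chi(k) = D F(field) / (D^2 + lambda)` is used instead. The result is
#' referenced to the in-mask mean (whole-brain mean) and zeroed outside the
#' mask.
#'
#' @param field 3D local field in ppm (background-removed).
#' @param kernel A [dipole_kernel()] whose shape matches `field`.
#' @param delta TKD truncation threshold in (0, 1); default 0.2.
#' @param mask 3D logical array; defaults to all voxels.
#' @param tikhonov Tikhonov regularization weight `lambda`; 0 (default)
#'   selects TKD.
#' @return A `susceptibility_map` object: list with `chi` (3D, ppm, in-mask
#'   mean 0), `mask`, `reference = "whole-brain mean"`, `delta`, `tikhonov`.
#' @export
invert_dipole <- function(field, kernel, delta = 0.2, mask = NULL,
                          tikhonov = 0) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  d <- dim(field)
  if (!identical(d, dim(kernel$values))) stop("field/kernel shape mismatch")
  if (!(delta > 0 && delta < 1)) stop("delta must be in (0, 1)")
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- array(as.logical(mask), d)
  if (!any(mask)) stop("mask is empty")
  check_residual_background(field, mask)
  D <- kernel$values
  Fk <- fftnd(field)
  if (tikhonov > 0) {
    chik <- Fk * D / (D^2 + tikhonov)
  } else {
    inv <- ifelse(abs(D) >= delta, 1 / D, sign(D) / delta)
    chik <- Fk * inv
  }
  chi <- Re(ifftnd(chik))
  chi <- reference_to_mask_mean(chi, mask)
  structure(list(chi = chi, mask = mask, reference = "whole-brain mean",
                 delta = delta, tikhonov = tikhonov),
            class = "susceptibility_map")
}

# Reference to in-mask mean and zero outside the mask; idempotent.
reference_to_mask_mean <- function(chi, mask) {
  chi <- chi - mean(chi[mask])
  chi[!mask] <- 0
  chi
}

# Residual (unremoved) background shows up as large field values hugging the
# mask boundary relative to the interior; warn, do not stop.
check_residual_background <- function(field, mask) {
  inner <- erode1(mask)
  boundary <- mask & !inner
  if (!any(boundary) || !any(inner)) return(invisible(FALSE))
  b <- stats::median(abs(field[boundary]))
  i <- stats::median(abs(field[inner]))
  if (b > 5 * i + 1e-12) {
    warning("strong field gradients at the mask boundary; ",
            "background field may not be fully removed")
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

# 6-neighbour binary erosion.
erode1 <- function(mask) {
  d <- dim(mask)
  m <- array(FALSE, d)
  m[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
    mask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
    mask[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
    mask[3:d[1],       2:(d[2] - 1), 2:(d[3] - 1)] &
    mask[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
    mask[2:(d[1] - 1), 3:d[2],       2:(d[3] - 1)] &
    mask[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
    mask[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  m
}

#' Per-echo susceptibility maps
#'
#' Each echo's background-removed phase (radians) is converted to a ppm-scale
#' field via `phase / (gamma B0 TE_i) * 1e6` and inverted independently; each
#' map is referenced to its in-mask mean.
#'
#' @param local A `local_field` object from [vsharp()] with a 4D `field`, or
#'   a 4D array (then `mask` is required).
#' @param params [acq_params()].
#' @param delta TKD threshold.
#' @param mask 3D logical; defaults to the `eroded_mask` of `local`.
#' @param tikhonov Optional Tikhonov weight (see [invert_dipole()]).
#' @return A `susceptibility_series` object: list with `chi_t` (4D, ppm),
#'   `mask`, `params`, `delta`.
#' @export
per_echo_qsm <- function(local, params, delta = 0.2, mask = NULL,
                         tikhonov = 0) {
  if (inherits(local, "local_field")) {
    if (is.null(mask)) mask <- local$eroded_mask
    field <- local$field
  } else {
    field <- local
    if (is.null(mask)) stop("mask is required when `local` is a bare array")
  }
  d <- dim(field)
  if (length(d) != 4L) stop("per-echo inversion needs a 4D field")
  if (d[4] != params$n_echoes) stop("echo count mismatch")
  if (any(params$echo_times == 0)) stop("echo times must be nonzero")
  kernel <- dipole_kernel(d[1:3], params$voxel_size, params$b0_dir)
  chi_t <- array(0, d)
  for (i in seq_len(d[4])) {
    ppm <- field[, , , i] / (params$gamma * params$B0 *
                               params$echo_times[i]) * 1e6
    chi_t[, , , i] <- invert_dipole(ppm, kernel, delta, mask,
                                    tikhonov)$chi
  }
  structure(list(chi_t = chi_t, mask = mask, params = params, delta = delta),
            class = "susceptibility_series")
}

#' Susceptibility map from the combined multi-echo field
#'
#' Inverts the [combine_echoes()] normalized field (already in ppm).
#'
#' @param normalized 3D normalized field in ppm.
#' @param params [acq_params()].
#' @param delta TKD threshold.
#' @param mask 3D logical array.
#' @param tikhonov Optional Tikhonov weight.
#' @return A `susceptibility_map` (see [invert_dipole()]).
#' @export
combined_qsm <- function(normalized, params, delta = 0.2, mask = NULL,
                         tikhonov = 0) {
  kernel <- dipole_kernel(dim(normalized), params$voxel_size, params$b0_dir)
  invert_dipole(normalized, kernel, delta, mask, tikhonov)
}
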