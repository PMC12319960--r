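# Phase processing: Laplacian unwrapping, V-SHARP background removal, and
# multi-echo combination into a normalized (ppm-scale) field.

#' Laplacian-based phase unwrapping
#'
#' Solves the Poisson problem `lap(phi_u) = Im(exp(-i phi) lap(exp(i phi)))`
#' spectrally: the wrapped phase is mirror-padded (even extension, imposing
#' Neumann-like boundaries), the right-hand side is formed as
#' `cos(phi) lap(sin(phi)) - sin(phi) lap(cos(phi))` with the continuous
#' Laplacian symbol `-|2 pi k|^2`, and the same symbol is inverted (DC term
#' set to zero). The result equals the true phase up to an additive harmonic
#' component; the returned volume has zero mean over the padded grid.
#'
#' @param wrapped 3D or 4D array of wrapped phase in radians, values in
#'   (-pi, pi].
#' @param mask Optional 3D logical array (only validated here; unwrapping is
#'   computed on the full grid and masking happens at the V-SHARP stage).
#' @return Array of unwrapped phase, same shape as `wrapped`.
#' @export
laplacian_unwrap <- function(wrapped, mask = NULL) {
  if (!is.null(mask) && !any(mask)) stop("mask is empty")
  d <- dim(wrapped)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("wrapped must be a 3D or 4D array")
  }
  if (length(d) == 4L) {
    out <- array(0, d)
    for (i in seq_len(d[4])) {
      out[, , , i] <- laplacian_unwrap(wrapped[, , , i], mask)
    }
    return(out)
  }
  p <- mirror_pad3(wrapped)
  L <- laplacian_symbol(dim(p), c(1, 1, 1))
  rhs <- cos(p) * apply_multiplier(sin(p), L) -
         sin(p) * apply_multiplier(cos(p), L)
  Linv <- ifelse(abs(L) > 0, 1 / L, 0)
  u <- apply_multiplier(rhs, Linv)
  crop3(u, d)
}

#' V-SHARP background field removal
#'
#' Variable-kernel spherical-mean-value (SMV) filtering. A harmonic field
#' (one generated by sources outside the mask) equals its spherical mean, so
#' subtracting the SMV leaves only the local field. Kernel radii run from
#' `max_radius_vox` down to 1 voxel: each voxel is filtered with the largest
#' sphere that fits entirely inside the mask at that voxel, so that deep
#' tissue gets the most reliable filtering and the usable mask erodes by only
#' one voxel. The residual masked SMV high-pass operator is then inverted to
#' restore the local field:
#' \describe{
#'   \item{`method = "cg"` (default)}{least-squares solve of the masked
#'     variable-radius system by conjugate gradients on the normal
#'     equations (`n_cg` iterations); insensitive to the mask truncation
#'     that limits the k-space division.}
#'   \item{`method = "tsvd"`}{thresholded k-space division by the largest
#'     kernel's high-pass response (`1/(1 - K)` where
#'     `|1 - K| >= svd_thresh`, zero elsewhere).}
#' }
#'
#' @param unwrapped 3D or 4D array of unwrapped phase (radians) or field.
#' @param mask 3D logical array.
#' @param max_radius_vox Largest SMV radius in voxels (default 25); radii
#'   that fit nowhere in the mask (or not in the grid) are skipped
#'   automatically.
#' @param svd_thresh Truncation threshold for the `"tsvd"` deconvolution
#'   (default 0.05).
#' @param method `"cg"` or `"tsvd"`.
#' @param n_cg Conjugate-gradient iterations for `"cg"` (default 10).
#' @return List of class `local_field` with `field` (same shape as input,
#'   zero outside `eroded_mask`), `eroded_mask` (3D logical), `radius_map`
#'   (3D integer, SMV radius used at each voxel), `radii` (radii actually
#'   used).
#' @export
vsharp <- function(unwrapped, mask, max_radius_vox = 25L, svd_thresh = 0.05,
                   method = c("cg", "tsvd"), n_cg = 10L) {
  method <- match.arg(method)
  if (max_radius_vox < 1L) stop("max_radius_vox must be >= 1")
  d <- dim(unwrapped)
  d3 <- if (length(d) == 4L) d[1:3] else d
  mask <- array(as.logical(mask), d3)
  if (!any(mask)) stop("mask is empty")
  mnum <- array(as.numeric(mask), d3)

  # shell geometry: largest fitting sphere per voxel, shared across echoes
  radii <- seq(min(max_radius_vox, (min(d3) - 1L) %/% 2L), 1L)
  Ks <- list()
  rsel <- list()
  assigned <- array(FALSE, d3)
  radius_map <- array(0L, d3)
  used <- integer(0)
  for (r in radii) {
    K <- smv_kernel_fft(d3, r)
    fits <- apply_multiplier(mnum, K) >= 1 - 1e-6
    sel <- fits & mask & !assigned
    if (!any(sel)) next
    Ks[[length(Ks) + 1L]] <- K
    rsel[[length(rsel) + 1L]] <- sel
    radius_map[sel] <- r
    assigned <- assigned | sel
    used <- c(used, r)
  }
  if (!any(assigned)) {
    stop("mask is smaller than the smallest (1-voxel) SMV kernel")
  }
  eroded <- assigned
  enum <- as.numeric(eroded)

  # masked variable-radius SMV high-pass and its adjoint
  Aop <- function(x) {
    X <- fftnd(x)
    out <- array(0, d3)
    for (i in seq_along(Ks)) {
      hp <- x - Re(ifftnd(X * Ks[[i]]))
      out[rsel[[i]]] <- hp[rsel[[i]]]
    }
    out
  }
  Atop <- function(y) {
    out <- array(0, d3)
    for (i in seq_along(Ks)) {
      yr <- array(0, d3)
      yr[rsel[[i]]] <- y[rsel[[i]]]
      out <- out + yr - Re(ifftnd(fftnd(yr) * Ks[[i]]))
    }
    out
  }
  solve_one <- function(phi) {
    h <- Aop(phi * mnum)
    if (method == "tsvd") {
      resid <- 1 - Ks[[1]]
      inv <- ifelse(abs(resid) >= svd_thresh, 1 / resid, 0)
      return(apply_multiplier(h, inv) * enum)
    }
    bvec <- Atop(h)
    x <- array(0, d3)
    r <- bvec
    pp <- r
    rs <- sum(r^2)
    if (rs == 0) return(x)
    for (it in seq_len(n_cg)) {
      Ap <- Atop(Aop(pp))
      denom <- sum(pp * Ap)
      if (denom <= 0) break
      alpha <- rs / denom
      x <- x + alpha * pp
      r <- r - alpha * Ap
      rs2 <- sum(r^2)
      if (rs2 < 1e-12 * rs) break
      pp <- r + (rs2 / rs) * pp
      rs <- rs2
    }
    x * enum
  }

  if (length(d) == 4L) {
    field <- array(0, d)
    for (e in seq_len(d[4])) field[, , , e] <- solve_one(unwrapped[, , , e])
  } else {
    field <- solve_one(unwrapped)
  }
  structure(list(field = field, eroded_mask = eroded,
                 radius_map = radius_map, radii = used,
                 svd_thresh = svd_thresh, method = method),
            class = "local_field")
}

#' Combine multi-echo phase into a normalized field (ppm)
#'
#' The combined field is the plain echo sum normalized by the total phase
#' accrual per unit susceptibility:
#' `phi = sum_i phi_i / (gamma B0 sum_i TE_i)`, reported in ppm (x 1e6).
#'
#' @param unwrapped 4D array of unwrapped (and typically background-removed)
#'   phase, radians, echo axis last.
#' @param params [acq_params()]; echo count must match.
#' @return 3D array, the normalized field in ppm.
#' @examples
#' p <- acq_params(echo_times = 0.004)
#' ph <- array(0.1, c(4, 4, 4, 1))
#' combine_echoes(ph, p)[1, 1, 1]  # ~7.987e-3 ppm
#' @export
combine_echoes <- function(unwrapped, params) {
  d <- dim(unwrapped)
  if (length(d) != 4L) stop("unwrapped must be 4D (echo axis last)")
  if (d[4] != params$n_echoes) stop("echo count mismatch")
  ste <- sum(params$echo_times)
  if (ste <= 0) stop("sum of echo times must be > 0")
  num <- array(0, d[1:3])
  for (i in seq_len(d[4])) num <- num + unwrapped[, , , i]
  num / (params$gamma * params$B0 * ste) * 1e6
}
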