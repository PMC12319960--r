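#' Acquisition parameters for a multi-echo gradient-echo experiment
#'
#' Bundles the physical constants every processing stage consumes: main field
#' strength, proton gyromagnetic ratio, the ordered echo times, voxel geometry
#' and the direction of B0 in image coordinates.
#'
#' The defaults reproduce an 11.7 T ex-vivo mouse protocol: 8 echoes with
#' TE1 = 4 ms and 3.8 ms inter-echo spacing, 70 um isotropic voxels, and the
#' dorsal-ventral axis (third image axis) along B0.
#'
#' @param B0 Main magnetic field strength in tesla. Must be positive.
#' @param gamma Proton gyromagnetic ratio in rad s^-1 T^-1.
#' @param echo_times Strictly increasing vector of echo times in seconds.
#' @param voxel_size Length-3 vector of voxel dimensions in millimetres.
#' @param b0_dir Length-3 unit vector giving the B0 direction in image axes.
#'
#' @return An object of class `acq_params` (a validated list with fields
#'   `B0`, `gamma`, `echo_times`, `voxel_size`, `b0_dir`, `n_echoes`).
#' @examples
#' p <- acq_params()
#' p$n_echoes            # 8
#' round(p$echo_times[8] * 1e3, 1)  # 30.6 ms
#' @export
acq_params <- function(B0 = 11.7,
                       gamma = 2.6752e8,
                       echo_times = 0.004 + 0.0038 * (0:7),
                       voxel_size = c(0.07, 0.07, 0.07),
                       b0_dir = c(0, 0, 1)) {
  stopifnot(is.numeric(B0), length(B0) == 1L, is.finite(B0))
  if (B0 <= 0) stop("B0 must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1L || any(!is.finite(echo_times)) ||
      any(echo_times <= 0)) {
    stop("echo_times must be finite and > 0")
  }
  if (length(echo_times) > 1L && any(diff(echo_times) <= 0)) {
    stop("echo_times must be strictly increasing")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be a positive length-3 vector")
  }
  b0_dir <- as.numeric(b0_dir)
  if (length(b0_dir) != 3L) stop("b0_dir must have length 3")
  nrm <- sqrt(sum(b0_dir^2))
  if (nrm == 0) stop("b0_dir must be nonzero")
  if (abs(nrm - 1) > 1e-9) b0_dir <- b0_dir / nrm
  structure(
    list(B0 = B0, gamma = gamma, echo_times = echo_times,
         voxel_size = voxel_size, b0_dir = b0_dir,
         n_echoes = length(echo_times)),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> B0 = %g T, %d echoes (%.1f..%.1f ms), voxel %s mm\n",
              x$B0, x$n_echoes, min(x$echo_times) * 1e3,
              max(x$echo_times) * 1e3,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Multi-echo complex image series
#'
#' Holds a 4D magnitude array and a 4D wrapped-phase array (radians) on the
#' same grid, with the echo axis last, plus the [acq_params()] they were
#' acquired with. Phase is normalized into (-pi, pi] on construction.
#'
#' @param magnitude 4D numeric array `(x, y, z, echo)`, values >= 0.
#' @param phase 4D numeric array of the same shape, radians.
#' @param params An [acq_params()] object; `n_echoes` must match dim 4.
#' @return A `complex_echo_series` object (list with `magnitude`, `phase`,
#'   `params`).
#' @export
complex_echo_series <- function(magnitude, phase, params) {
  stopifnot(inherits(params, "acq_params"))
  if (length(dim(magnitude)) != 4L || !identical(dim(magnitude), dim(phase))) {
    stop("magnitude and phase must be 4D arrays of identical shape")
  }
  if (dim(magnitude)[4] != params$n_echoes) {
    stop("4th dimension must equal n_echoes")
  }
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  structure(
    list(magnitude = magnitude, phase = wrap_phase(phase), params = params),
    class = "complex_echo_series"
  )
}

#' @export
print.complex_echo_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<complex_echo_series> %dx%dx%d, %d echoes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Wrap phase values into (-pi, pi]
#'
#' @param phi Numeric array of phase values in radians.
#' @return Array of the same shape with every value in (-pi, pi].
#' @examples
#' wrap_phase(c(pi, -pi, 3 * pi / 2))  # pi, pi, -pi/2
#' @export
wrap_phase <- function(phi) {
  out <- phi - 2 * pi * round(phi / (2 * pi))
  # round() maps pi -> wrapped -pi; push the boundary back to +pi
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

#' Brain mask container
#'
#' @param mask 3D logical array; must contain at least one TRUE voxel.
#' @param voxel_size Length-3 voxel dimensions in millimetres.
#' @return A `brain_mask` object.
#' @export
brain_mask <- function(mask, voxel_size = c(0.07, 0.07, 0.07)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty")
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "brain_mask")
}

#' ROI label volume
#'
#' Integer-labelled volume (0 = background) together with a label -> name
#' table. Every nonzero label occurring in the volume must be named.
#'
#' @param labels 3D array of non-negative integers.
#' @param names Named character vector or data.frame with columns
#'   `label`, `name`.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, names) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  labels <- array(as.integer(labels), dim(labels))
  if (is.data.frame(names)) {
    tab <- stats::setNames(as.character(names$name), names$label)
  } else {
    tab <- names
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(present), base::names(tab))
  if (length(missing)) {
    stop("unnamed labels present in volume: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, names = tab), class = "label_volume")
}

#' Convert susceptibility between ppm and ppb
#'
#' Susceptibility is carried in ppm throughout computation; maps are reported
#' in ppb at output boundaries (the conventional reporting unit).
#'
#' @param chi_ppm,chi_ppb Numeric array of susceptibilities.
#' @return The converted array.
#' @examples
#' to_ppb(0.0132)    # 13.2
#' to_ppm(-5.12)     # -0.00512
#' @export
to_ppb <- function(chi_ppm) {
  if (any(!is.finite(chi_ppm))) stop("non-finite susceptibility values")
  chi_ppm * 1000
}

#' @rdname to_ppb
#' @export
to_ppm <- function(chi_ppb) {
  if (any(!is.finite(chi_ppb))) stop("non-finite susceptibility values")
  chi_ppb / 1000
}

#' Read/write acquisition parameters as a JSON sidecar
#'
#' Keys: `B0_T`, `gamma_rad_per_s_per_T`, `echo_times_s`, `voxel_size_mm`,
#' `b0_dir`.
#'
#' @param params An [acq_params()] object.
#' @param path File path for the JSON sidecar.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns an [acq_params()] object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "acq_params"))
  jsonlite::write_json(
    list(B0_T = params$B0,
         gamma_rad_per_s_per_T = params$gamma,
         echo_times_s = params$echo_times,
         voxel_size_mm = params$voxel_size,
         b0_dir = params$b0_dir),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acq_params(B0 = x$B0_T, gamma = x$gamma_rad_per_s_per_T,
             echo_times = x$echo_times_s, voxel_size = x$voxel_size_mm,
             b0_dir = x$b0_dir)
}

#' Read/write a label-name table as TSV
#'
#' Two columns: `label` (integer) and `name`.
#'
#' @param x Named character vector (names are labels) or `label_volume`.
#' @param path TSV path.
#' @return `read_label_table` returns a named character vector.
#' @export
write_label_table <- function(x, path) {
  if (inherits(x, "label_volume")) x <- x$names
  utils::write.table(
    data.frame(label = as.integer(names(x)), name = unname(x)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "character"))
  stats::setNames(d$name, d$label)
}
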