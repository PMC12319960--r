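# Internal spectral helpers shared by the unwrapping, V-SHARP and dipole
# inversion stages. All grids are treated as periodic by stats::fft; callers
# that need non-periodic boundaries mirror-pad first.

fftnd <- function(x) stats::fft(x)

ifftnd <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT sample frequencies (cycles per unit length), numpy fftfreq convention.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# k-space coordinate arrays for a grid, in cycles/mm.
k_grid <- function(shape, voxel_size) {
  kx <- fft_freq(shape[1], voxel_size[1])
  ky <- fft_freq(shape[2], voxel_size[2])
  kz <- fft_freq(shape[3], voxel_size[3])
  list(
    kx = array(rep(kx, times = shape[2] * shape[3]), shape),
    ky = array(rep(rep(ky, each = shape[1]), times = shape[3]), shape),
    kz = array(rep(kz, each = shape[1] * shape[2]), shape)
  )
}

# Even (mirror) extension to twice the size along every axis; together with
# a periodic FFT this imposes Neumann-like boundaries (a DCT in disguise).
mirror_pad3 <- function(x) {
  d <- dim(x)
  x[c(seq_len(d[1]), rev(seq_len(d[1]))),
    c(seq_len(d[2]), rev(seq_len(d[2]))),
    c(seq_len(d[3]), rev(seq_len(d[3])))]
}

crop3 <- function(x, d) x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]

# -|2 pi k|^2 multiplier (continuous Laplacian symbol) for a periodic grid.
laplacian_symbol <- function(shape, voxel_size) {
  kg <- k_grid(shape, voxel_size)
  -(2 * pi)^2 * (kg$kx^2 + kg$ky^2 + kg$kz^2)
}

# FFT of a normalized discrete spherical (SMV) kernel of given radius in
# voxels, centred at the origin of a wrap-around grid. Real and even by
# construction, so its FFT is real.
smv_kernel_fft <- function(shape, radius) {
  ix <- fft_index_coord(shape[1])
  iy <- fft_index_coord(shape[2])
  iz <- fft_index_coord(shape[3])
  r2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
  ker <- array(0, shape)
  ker[r2 <= radius^2 + 1e-9] <- 1
  ker <- ker / sum(ker)
  Re(fftnd(ker))
}

# Signed voxel offsets from the origin on a wrap-around grid.
fft_index_coord <- function(n) {
  c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
}

# Apply a real k-space multiplier to a real array, staying real.
apply_multiplier <- function(x, mult) {
  Re(ifftnd(fftnd(x) * mult))
}
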