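# Shared fixtures and independent oracles.

# default 11.7 T protocol: 8 echoes, TE1 = 4 ms, dTE = 3.8 ms
p8 <- acq_params()

# Brute-force exact Mann-Whitney oracle: enumerate every assignment of the
# pooled *values* (not ranks) to group 1 and recount U each time.
mw_brute <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  u_obs <- sum(outer(x, y, ">"))
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force BH step-up adjustment.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  adj
}

# random in-mask harmonic quadratic on a grid (zero Laplacian by construction)
random_harmonic <- function(shape, seed) {
  co <- chisep:::normalized_coords(shape)
  cf <- chisep:::with_seed(seed, stats::rnorm(8))
  with(co, cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y +
         cf[5] * x * z + cf[6] * y * z + cf[7] * (x^2 - y^2) +
         cf[8] * (y^2 - z^2))
}

# simulate one voxel from the three-pool model with complex Gaussian noise;
# snr on the TE1 magnitude. Returns list(y, truth).
sim_voxel <- function(C_plus, C_minus, chi_plus, chi_minus, r2star0,
                      snr = 40, params = p8,
                      a = decay_kernel(params$B0, params$gamma)$a) {
  truth <- list(alpha0 = 1 - C_plus - C_minus, alpha_plus = C_plus,
                alpha_minus = C_minus, r2star0 = r2star0,
                chi_plus = chi_plus, chi_minus = chi_minus)
  y <- model_signal(truth, a, params$echo_times, params)
  if (is.finite(snr)) {
    sd <- Mod(y[1]) / snr
    y <- y + complex(real = stats::rnorm(length(y), 0, sd),
                     imaginary = stats::rnorm(length(y), 0, sd))
  }
  list(y = y, truth = truth)
}

# Lazily computed, memoized parameter-recovery experiment shared by the
# acceptance criteria 4a and 4c (500 voxels, SNR 40, stated ranges).
.recovery_cache <- new.env(parent = emptyenv())

recovery_experiment <- function(n_voxels = 500L, seed = 20260912L) {
  key <- paste(n_voxels, seed, sep = "_")
  hit <- get0(key, envir = .recovery_cache)
  if (!is.null(hit)) return(hit)
  set.seed(seed)
  a <- decay_kernel(p8$B0, p8$gamma)$a
  rows <- vector("list", n_voxels)
  traces <- vector("list", n_voxels)
  for (i in seq_len(n_voxels)) {
    repeat {
      Cp <- stats::runif(1, 0.2, 0.6)
      Cm <- stats::runif(1, 0.2, 0.6)
      if (Cp + Cm <= 0.9) break
    }
    cp <- stats::runif(1, 0.005, 0.05)
    cm <- -stats::runif(1, 0.005, 0.05)
    R0 <- stats::runif(1, 30, 80)
    sv <- sim_voxel(Cp, Cm, cp, cm, R0)
    f <- fit_three_pool(sv$y, p8, a)
    rows[[i]] <- data.frame(
      C_plus_true = Cp, C_minus_true = Cm,
      chi_plus_true = cp, chi_minus_true = cm,
      chi_plus = f$chi_plus, chi_minus = f$chi_minus,
      pcs = f$pcs, dcs = f$dcs,
      rel_err_plus = abs(f$chi_plus - cp) / cp,
      rel_err_minus = abs(f$chi_minus - cm) / abs(cm))
    traces[[i]] <- f$objective
  }
  out <- list(table = do.call(rbind, rows), traces = traces)
  assign(key, out, envir = .recovery_cache)
  out
}
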