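# ROI summaries and exact nonparametric group statistics: Mann-Whitney U by
# complete enumeration (the n = 5 vs 5 regime has only C(10,5) = 252 group
# assignments) and Benjamini-Hochberg FDR control, both from first
# principles.

#' Per-ROI mean and standard deviation
#'
#' @param map 3D numeric map (typically ppb).
#' @param labels A [label_volume()] aligned with `map`.
#' @param slices Optional integer vector of z-slices to restrict to
#'   (mirrors measuring ROIs across a few consecutive slices).
#' @return data.frame with columns `label`, `name`, `n_voxels`, `mean`,
#'   `sd`.
#' @export
roi_means <- function(map, labels, slices = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  if (!identical(dim(map), dim(lab))) stop("map/labels grid mismatch")
  if (!is.null(slices)) {
    keep <- array(FALSE, dim(lab))
    keep[, , slices] <- TRUE
    lab <- lab * keep
  }
  ids <- as.integer(names(labels$names))
  rows <- lapply(ids, function(id) {
    v <- map[lab == id]
    if (!length(v)) {
      stop("empty ROI after slice restriction: ", labels$names[[as.character(id)]])
    }
    data.frame(label = id, name = labels$names[[as.character(id)]],
               n_voxels = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  do.call(rbind, rows)
}

# Cache of exact U null distributions keyed by "n1,n2".
.mw_cache <- new.env(parent = emptyenv())

# Exact null distribution of U = #{x_i > y_j} over all C(n1+n2, n1)
# assignments of ranks to group 1: a table of counts indexed by U = 0..n1*n2.
mw_null_counts <- function(n1, n2) {
  key <- paste(n1, n2, sep = ",")
  hit <- get0(key, envir = .mw_cache)
  if (!is.null(hit)) return(hit)
  N <- n1 + n2
  combs <- utils::combn(N, n1)
  u <- colSums(combs) - n1 * (n1 + 1) / 2
  counts <- tabulate(u + 1L, nbins = n1 * n2 + 1L)
  assign(key, counts, envir = .mw_cache)
  counts
}

#' Exact two-sided Mann-Whitney U test
#'
#' `U = #{(i, j): x_i > y_j}`; the null distribution is obtained by complete
#' enumeration of all `C(n1 + n2, n1)` assignments of the pooled sample to
#' groups, and the two-sided p-value is `2 min(P(U <= u), P(U >= u))`,
#' capped at 1. Ties across the pooled sample are an error (ROI means of
#' floating-point maps are generically tie-free); small samples only
#' (`n1, n2 <= 12`).
#'
#' @param x,y Numeric vectors of group observations.
#' @return A `mw_test` object: list with `U`, `p`, `n1`, `n2`.
#' @examples
#' mannwhitney_exact(6:10, 1:5)$p  # 2/252 = 0.0079
#' @export
mannwhitney_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  if (n1 > 12L || n2 > 12L) stop("exact enumeration supports n1, n2 <= 12")
  pooled <- c(x, y)
  if (anyDuplicated(pooled)) {
    stop("ties in the pooled sample; exact enumeration requires distinct values")
  }
  U <- sum(outer(x, y, ">"))
  counts <- mw_null_counts(n1, n2)
  total <- sum(counts)
  p_le <- sum(counts[seq_len(U + 1L)]) / total
  p_ge <- sum(counts[(U + 1L):length(counts)]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(U = U, p = p, n1 = n1, n2 = n2), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %d (n = %d vs %d), exact two-sided p = %.4g\n",
              x$U, x$n1, x$n2, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p-values `p~_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1;
#' the rejection set at level `q` is `{p~ <= q}`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` (input order), `reject` (logical), `q`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))$p_adjusted  # all 0.04
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  p_adjusted <- numeric(m)
  p_adjusted[o] <- adj_sorted
  list(p_adjusted = p_adjusted, reject = p_adjusted <= q, q = q)
}

#' Group comparison across ROIs
#'
#' One exact Mann-Whitney test per ROI for the chosen metric, with BH
#' correction across the ROIs of that metric (the multiple-testing family
#' is one metric in one analysis run).
#'
#' @param table ROI table: data.frame with columns `subject`, `group` (two
#'   levels), `roi`, `metric`, `value` (and optionally `n_voxels`), one row
#'   per (subject, ROI, metric).
#' @param metric Which metric to test (e.g. `"PCS"`, `"DCS"`, `"QSM"`).
#' @param q FDR level (default 0.05).
#' @param tie_jitter Add tiny uniform jitter (1e-9 of the value scale,
#'   seeded) to break exact ties in degenerate synthetic inputs.
#' @param jitter_seed Seed for the jitter.
#' @return data.frame with one row per ROI: group means/sds, `U`, `p`,
#'   `p_fdr`, `significant`.
#' @export
compare_groups <- function(table, metric, q = 0.05, tie_jitter = FALSE,
                           jitter_seed = 1L) {
  need <- c("subject", "group", "roi", "metric", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for metric ", metric)
  groups <- sort(unique(as.character(tab$group)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (tie_jitter) {
    scale <- max(abs(tab$value), 1e-12)
    tab$value <- tab$value + with_seed(
      jitter_seed, stats::runif(nrow(tab), -1, 1)) * 1e-9 * scale
  }
  rois <- unique(as.character(tab$roi))
  rows <- lapply(rois, function(rn) {
    x <- tab$value[tab$roi == rn & tab$group == groups[1]]
    y <- tab$value[tab$roi == rn & tab$group == groups[2]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("need >= 2 subjects per group in ROI ", rn)
    }
    tst <- mannwhitney_exact(x, y)
    data.frame(roi = rn,
               mean_1 = mean(x), sd_1 = stats::sd(x),
               mean_2 = mean(y), sd_2 = stats::sd(y),
               n1 = tst$n1, n2 = tst$n2, U = tst$U, p = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "sd_1"] <- paste0("sd_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  names(out)[names(out) == "sd_2"] <- paste0("sd_", groups[2])
  bh <- benjamini_hochberg(out$p, q)
  out$p_fdr <- bh$p_adjusted
  out$significant <- bh$reject
  attr(out, "metric") <- metric
  attr(out, "q") <- q
  out
}

#' Simulate a two-group cohort ROI table
#'
#' Draws `n_per_group` subjects per arm from the `two_group` phantom's
#' parameter distributions (between-subject lognormal variation on every
#' region parameter; the lesion chi+ shifted by `effect_ppm` in group B),
#' computes each region's ground-truth composite PCS/DCS/QSM in ppb, and
#' adds Gaussian ROI-measurement noise. This emulates the between-subject
#' and measurement variability of a small-cohort ROI analysis without
#' rerunning the full imaging chain per subject; the imaging chain itself is
#' validated separately.
#'
#' @param n_per_group Subjects per arm (default 5).
#' @param seed Integer seed.
#' @param effect_ppm Group-B lesion chi+ shift in ppm (default 0.025;
#'   0 gives a null cohort).
#' @param metrics Which metrics to tabulate (subset of PCS/DCS/QSM).
#' @param meas_sd_ppb ROI measurement noise s.d. in ppb (default 0.5).
#' @param subject_cv Between-subject coefficient of variation (default 0.1).
#' @param grid_shape Phantom grid used once for ROI geometry.
#' @return ROI table data.frame (`subject`, `group`, `roi`, `metric`,
#'   `value` in ppb, `n_voxels`).
#' @export
simulate_cohort <- function(n_per_group = 5L, seed = 1L, effect_ppm = 0.025,
                            metrics = c("PCS", "DCS", "QSM"),
                            meas_sd_ppb = 0.5, subject_cv = 0.10,
                            grid_shape = c(24, 24, 24)) {
  geom <- make_phantom(grid_shape, "two_group", seed = 1L)
  counts <- table(geom$labels$labels[geom$labels$labels > 0])
  nvox <- stats::setNames(as.integer(counts),
                          geom$labels$names[names(counts)])
  subj_seeds <- with_seed(seed, sample.int(2^30, 2L * n_per_group))
  noise_seed <- with_seed(seed + 1L, sample.int(2^30, 1L))
  rows <- list()
  k <- 0L
  for (g in c("A", "B")) {
    for (s in seq_len(n_per_group)) {
      k <- k + 1L
      tab <- two_group_param_draw(subj_seeds[k], group = g,
                                  effect_ppm = effect_ppm,
                                  subject_cv = subject_cv)
      tot <- tab$alpha0 + tab$alpha_plus + tab$alpha_minus
      pcs <- tab$alpha_plus / tot * tab$chi_plus * 1000
      dcs <- tab$alpha_minus / tot * tab$chi_minus * 1000
      vals <- list(PCS = pcs, DCS = dcs, QSM = pcs + dcs)
      for (met in metrics) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("%s%02d", g, s), group = g, roi = tab$name,
          metric = met, value = vals[[met]],
          n_voxels = as.integer(nvox[tab$name]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  noise <- with_seed(noise_seed,
                     stats::rnorm(nrow(out), 0, meas_sd_ppb))
  out$value <- out$value + noise
  rownames(out) <- NULL
  out
}
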