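#' Depth-resolved attenuation coefficient map
#'
#' Single-scattering tail-sum estimator applied to every A-line of the
#' repeat-averaged intensity:
#' \deqn{\hat\mu[i] = \frac{I[i]}{2\,\Delta z \sum_{j>i} I[j]}}
#' with \eqn{\Delta z} in millimetres, so \eqn{\hat\mu} is in 1/mm. The
#' estimator is invariant to global intensity scaling and recovers the true
#' attenuation of a single-exponential profile away from the bottom of the
#' range, where the tail sum underflows; the bottom `tail_frac` of depths is
#' therefore masked, as is any voxel with a non-positive tail sum.
#'
#' @param volume An [oct_volume()].
#' @param tail_frac Fraction of the deepest samples to mask, default 0.1.
#' @return A list of class `attenuation_map` with `mu` (3-D array, 1/mm,
#'   `NA` where masked) and `tail_mask` (logical 3-D array, `TRUE` = masked).
#' @export
attenuation_map <- function(volume, tail_frac = 0.1) {
  stopifnot(inherits(volume, "oct_volume"))
  dims <- dim(volume$intensity)
  nz <- dims[1]
  if (nz < 8L) stop("attenuation estimation needs at least 8 depth samples")
  dz_mm <- volume$voxel_pitch[1] / 1000
  avg <- rowMeans(volume$intensity, dims = 3)  # repeat-averaged (z, x, y)

  flat <- matrix(avg, nrow = nz)               # columns are A-lines
  csum <- apply(flat, 2, cumsum)
  tail_sum <- sweep(-csum, 2, csum[nz, ], "+") # sum over j > i
  mu <- flat / (2 * dz_mm * tail_sum)

  n_tail <- max(1L, ceiling(tail_frac * nz))
  masked <- matrix(FALSE, nz, ncol(flat))
  masked[(nz - n_tail + 1L):nz, ] <- TRUE
  masked[tail_sum <= 0] <- TRUE
  mu[masked] <- NA_real_

  structure(
    list(mu = array(mu, dims[1:3]), tail_mask = array(masked, dims[1:3]),
         dz_mm = dz_mm),
    class = "attenuation_map"
  )
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf(
    "Attenuation map: %s voxels, %.0f%% masked, median %.3g 1/mm\n",
    paste(dim(x$mu), collapse = "x"), 100 * mean(x$tail_mask),
    stats::median(x$mu, na.rm = TRUE)
  ))
  invisible(x)
}

# quantize window values to 1..levels over the window min-max range
quantize_levels <- function(x, levels) {
  rng <- range(x)
  if (diff(rng) <= 0) return(array(1L, dim(x)))
  q <- floor((x - rng[1]) / diff(rng) * levels) + 1L
  q[q > levels] <- levels
  array(as.integer(q), dim(x))
}

# symmetric, normalised co-occurrence matrix of a quantized 2-D window
glcm_matrix <- function(q, offset, levels) {
  nr <- nrow(q); nc <- ncol(q)
  dz <- offset[1]; dx <- offset[2]
  i1 <- seq_len(nr - abs(dz)); j1 <- seq_len(nc - abs(dx))
  i2 <- i1 + abs(dz); j2 <- j1 + abs(dx)
  if (dz < 0 || dx < 0) {            # negative components flip one axis
    if (dz < 0) { tmp <- i1; i1 <- i2; i2 <- tmp }
    if (dx < 0) { tmp <- j1; j1 <- j2; j2 <- tmp }
  }
  a <- q[i1, j1, drop = FALSE]
  b <- q[i2, j2, drop = FALSE]
  counts <- table(
    factor(as.vector(a), levels = seq_len(levels)),
    factor(as.vector(b), levels = seq_len(levels))
  )
  m <- counts + t(counts)            # symmetric accumulation
  m / sum(m)
}

haralick_features <- function(P) {
  levels <- nrow(P)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  correlation <- if (var_i <= 0 || var_j <= 0) {
    0  # zero-variance convention: constant window
  } else {
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  }
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' Grey-level co-occurrence texture features for one window
#'
#' Quantizes a 2-D window of the repeat-averaged B-scan plane (depth x fast)
#' to `levels` grey levels over the window's min-max range, accumulates a
#' symmetric normalised co-occurrence matrix per offset, computes the four
#' Haralick features (contrast, correlation, energy, homogeneity), and
#' averages them over the offsets. A constant window yields contrast 0,
#' energy 1, homogeneity 1 and correlation 0 by convention.
#'
#' @param window_vals 2-D numeric matrix (depth x fast).
#' @param levels Number of grey levels, default 32.
#' @param offsets List of integer `(d_depth, d_fast)` pairs; default the
#'   four distance-1 directions.
#' @return A one-row tibble with the four features.
#' @export
glcm_window_features <- function(window_vals, levels = 32L,
                                 offsets = list(c(0L, 1L), c(1L, 0L),
                                                c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.matrix(window_vals), levels >= 2L)
  for (off in offsets) {
    if (abs(off[1]) >= nrow(window_vals) || abs(off[2]) >= ncol(window_vals)) {
      stop("window smaller than the co-occurrence offset extent")
    }
  }
  q <- quantize_levels(window_vals, levels)
  feats <- vapply(offsets, function(off) {
    haralick_features(glcm_matrix(q, off, levels))
  }, numeric(4))
  tibble::tibble(
    contrast = mean(feats["contrast", ]),
    correlation = mean(feats["correlation", ]),
    energy = mean(feats["energy", ]),
    homogeneity = mean(feats["homogeneity", ])
  )
}

#' GLCM texture features at chosen voxel centres
#'
#' Computes [glcm_window_features()] in a `(depth, fast)` window of the
#' repeat-averaged volume around each 0-based voxel centre. Centres whose
#' window crosses the volume edge get `NA` features.
#'
#' @param volume An [oct_volume()].
#' @param centers Integer matrix (n x 3) of 0-based `(depth, fast, slow)`
#'   voxel indices.
#' @param window Integer pair `(depth, fast)` of window extents, default
#'   `c(6, 6)` matching the Rayleigh window footprint.
#' @param levels Grey levels, default 32.
#' @param offsets Offset list, see [glcm_window_features()].
#' @return A tibble with one row per centre: the indices plus the four
#'   feature columns.
#' @export
glcm_features_at <- function(volume, centers, window = c(6L, 6L),
                             levels = 32L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(volume, "oct_volume"))
  centers <- matrix(as.integer(centers), ncol = 3)
  avg <- rowMeans(volume$intensity, dims = 3)
  dims <- dim(avg)
  half <- as.integer(window) %/% 2L
  out <- purrr::map_dfr(seq_len(nrow(centers)), function(r) {
    ctr <- centers[r, ]
    o <- ctr[1:2] - half
    if (any(o < 0L) || any(o + window > dims[1:2])) {
      return(tibble::tibble(depth = ctr[1], fast = ctr[2], slow = ctr[3],
                            contrast = NA_real_, correlation = NA_real_,
                            energy = NA_real_, homogeneity = NA_real_))
    }
    w <- avg[(o[1] + 1L):(o[1] + window[1]),
             (o[2] + 1L):(o[2] + window[2]), ctr[3] + 1L]
    dplyr::bind_cols(
      tibble::tibble(depth = ctr[1], fast = ctr[2], slow = ctr[3]),
      glcm_window_features(w, levels, offsets)
    )
  })
  out
}
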