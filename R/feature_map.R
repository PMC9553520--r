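#' Rayleigh-fit features for one window centred at a voxel
#'
#' Pools the window around `center` (0-based voxel index triple) across all
#' repeats, fits the three-parameter Rayleigh density, and returns the
#' `(r_squared, a, c)` feature triple the classifier consumes. Windows are
#' anchored so that `center` is the window's central voxel (extent halves
#' rounded down); a window that would cross the volume edge is invalid.
#'
#' @param volume An [oct_volume()].
#' @param center Integer triple `(depth, fast, slow)`, 0-based.
#' @param window Integer triple of window extents, default `c(6, 6, 10)`.
#' @param n_bins Histogram bin count.
#' @return A one-row tibble with columns `r_squared`, `a_coeff`, `c_coeff`,
#'   `converged`, or `NULL` if the window does not fit inside the volume.
#' @export
window_features <- function(volume, center, window = c(6L, 6L, 10L),
                            n_bins = 64L) {
  origin <- as.integer(center) - as.integer(window) %/% 2L
  dims <- dim(volume$intensity)[1:3]
  if (any(origin < 0L) || any(origin + window > dims)) return(NULL)
  fit <- fit_rayleigh(pool_roi(volume, origin, window), n_bins = n_bins)
  tibble::tibble(
    r_squared = fit$r_squared, a_coeff = fit$a, c_coeff = fit$c,
    converged = fit$converged
  )
}

#' Sliding-window Rayleigh feature maps
#'
#' Fits the three-parameter Rayleigh density in a window around every voxel
#' centre on a stride lattice, pooling across all repeat frames, and returns
#' per-voxel maps of the goodness of fit and the `a` and `c` coefficients.
#' Edge voxels whose window would leave the volume are masked (no padding).
#'
#' @param volume An [oct_volume()].
#' @param window Integer triple `(depth, fast, slow)` of window extents;
#'   default matches the ROI footprint `c(6, 6, 10)`.
#' @param stride Integer triple of lattice strides, default `c(1, 1, 1)`.
#' @param n_bins Histogram bin count per window.
#' @return A list of class `feature_map` with 3-D arrays `r_squared`,
#'   `a_coeff`, `c_coeff`, a logical `valid` mask, and the `window`/`stride`
#'   used. Masked voxels are `NA`.
#' @export
feature_map <- function(volume, window = c(6L, 6L, 10L),
                        stride = c(1L, 1L, 1L), n_bins = 64L) {
  stopifnot(inherits(volume, "oct_volume"))
  window <- as.integer(window)
  stride <- as.integer(stride)
  dims <- dim(volume$intensity)[1:3]
  if (any(window > dims)) stop("window larger than the volume")
  if (any(stride < 1L)) stop("stride must be >= 1")

  half <- window %/% 2L
  # valid centre range per axis: origin = centre - half must satisfy bounds
  centers <- lapply(1:3, function(ax) {
    seq(half[ax], dims[ax] - (window[ax] - half[ax]), by = stride[ax])
  })
  shape <- dims
  r2 <- array(NA_real_, shape)
  am <- array(NA_real_, shape)
  cm <- array(NA_real_, shape)
  valid <- array(FALSE, shape)

  for (iz in centers[[1]]) for (ix in centers[[2]]) for (iy in centers[[3]]) {
    f <- window_features(volume, c(iz, ix, iy), window, n_bins)
    if (is.null(f)) next
    r2[iz + 1L, ix + 1L, iy + 1L] <- f$r_squared
    am[iz + 1L, ix + 1L, iy + 1L] <- f$a_coeff
    cm[iz + 1L, ix + 1L, iy + 1L] <- f$c_coeff
    valid[iz + 1L, ix + 1L, iy + 1L] <- TRUE
  }
  structure(
    list(r_squared = r2, a_coeff = am, c_coeff = cm, valid = valid,
         window = window, stride = stride),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf(
    "Rayleigh feature map: %s voxels, window %s, stride %s, %d valid centres\n",
    paste(dim(x$r_squared), collapse = "x"),
    paste(x$window, collapse = "x"), paste(x$stride, collapse = "x"),
    sum(x$valid)
  ))
  invisible(x)
}

#' Tidy a feature map into a per-voxel tibble
#'
#' @param x A `feature_map`.
#' @param ... Unused.
#' @return A tibble with 0-based voxel indices `depth`, `fast`, `slow` and
#'   the three feature columns, one row per valid centre.
#' @method tidy feature_map
#' @export
tidy.feature_map <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  tibble::tibble(
    depth = idx[, 1] - 1L, fast = idx[, 2] - 1L, slow = idx[, 3] - 1L,
    r_squared = x$r_squared[x$valid],
    a_coeff = x$a_coeff[x$valid],
    c_coeff = x$c_coeff[x$valid]
  )
}

#' Plot one slow-axis slice of a feature map
#'
#' @param object A `feature_map`.
#' @param feature Which map to show: `"r_squared"`, `"a_coeff"` or `"c_coeff"`.
#' @param slow 0-based slow-axis slice index.
#' @param ... Unused.
#' @return A ggplot raster of the selected feature over the B-scan plane.
#' @method autoplot feature_map
#' @export
autoplot.feature_map <- function(object, feature = "r_squared", slow = NULL,
                                 ...) {
  feature <- match.arg(feature, c("r_squared", "a_coeff", "c_coeff"))
  if (is.null(slow)) slow <- dim(object$r_squared)[3] %/% 2L
  df <- tidy(object)
  df <- df[df$slow == slow, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fast, y = .data$depth,
                                   fill = .data[[feature]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fast (voxel)", y = "depth (voxel)", fill = feature,
                  title = sprintf("slow slice %d", slow)) +
    ggplot2::theme_minimal()
}
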