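#' Three-parameter Rayleigh probability density
#'
#' Evaluates the shifted, amplitude-scaled Rayleigh density
#' \deqn{P(x; a, b, c) = a \frac{x - c}{b^2} \exp\!\left(-\frac{(x-c)^2}{2b^2}\right)}
#' used to model OCT speckle intensity histograms. `a` is the amplitude
#' normalisation coefficient, `b` the scale, and `c` the shift. For `x < c`
#' the density is 0 (piecewise extension: the analytic form would go negative
#' there, which a density cannot). With `a = 1` the function integrates to 1
#' over `[c, Inf)` for any `b > 0`.
#'
#' @param x Numeric vector of intensities (arbitrary linear units).
#' @param a Amplitude normalisation coefficient, `a >= 0`.
#' @param b Scale coefficient, strictly positive.
#' @param c Shift coefficient (may be negative).
#' @return Numeric vector of density values, same length as `x`.
#' @examples
#' rayleigh_pdf(1, a = 1, b = 1, c = 0)  # exp(-1/2) at the mode
#' @export
rayleigh_pdf <- function(x, a, b, c) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single positive number, got ", format(b))
  }
  u <- x - c
  out <- a * u / b^2 * exp(-u^2 / (2 * b^2))
  out[u < 0] <- 0
  out
}

#' Pool the pixels of a region of interest across repeated B-scans
#'
#' Flattens all voxel intensities inside a rectangular ROI, over a half-open
#' range of repeat frames, into one numeric sample. With the default ROI
#' extent of 6 (depth) x 6 (fast) x 10 (slow) voxels and 24 repeats this
#' yields the 8640-pixel sample the speckle histogram is built from.
#'
#' @param volume An [oct_volume()].
#' @param origin Integer triple `(depth, fast, slow)`, 0-based voxel indices
#'   of the ROI corner nearest the volume origin.
#' @param extent Integer triple `(depth, fast, slow)` of ROI size in voxels.
#' @param repeats Half-open 0-based repeat index interval `c(from, to)`;
#'   default covers all repeats.
#' @return Numeric vector of length `prod(extent) * (to - from)`.
#' @export
pool_roi <- function(volume, origin, extent = c(6L, 6L, 10L), repeats = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  dims <- dim(volume$intensity)
  origin <- as.integer(origin)
  extent <- as.integer(extent)
  if (length(origin) != 3L || length(extent) != 3L || any(extent < 1L)) {
    stop("`origin` and `extent` must be integer triples with positive extents")
  }
  if (is.null(repeats)) repeats <- c(0L, dims[4])
  repeats <- as.integer(repeats)
  if (any(origin < 0L) || any(origin + extent > dims[1:3])) {
    stop(
      "ROI out of bounds: origin (", paste(origin, collapse = ","),
      ") + extent (", paste(extent, collapse = ","),
      ") exceeds volume dimensions (", paste(dims[1:3], collapse = ","), ")"
    )
  }
  if (repeats[1] < 0L || repeats[2] > dims[4] || repeats[1] >= repeats[2]) {
    stop("repeat range [", repeats[1], ",", repeats[2], ") invalid for ",
         dims[4], " repeats")
  }
  as.vector(volume$intensity[
    (origin[1] + 1L):(origin[1] + extent[1]),
    (origin[2] + 1L):(origin[2] + extent[2]),
    (origin[3] + 1L):(origin[3] + extent[3]),
    (repeats[1] + 1L):repeats[2],
    drop = FALSE
  ])
}

#' Build a density-normalised intensity histogram
#'
#' Equal-width bins spanning the sample range, with heights normalised so
#' that `sum(density * bin_width) == 1`. The Rayleigh fit operates on the
#' `(bin_center, density)` pairs of this histogram.
#'
#' @param sample Numeric vector of pooled pixel intensities.
#' @param n_bins Number of bins (>= 4). Default 64.
#' @return A tibble of class `intensity_histogram` with columns `bin_left`,
#'   `bin_right`, `bin_center`, `count`, `density`, and attributes `n_pixels`,
#'   `raw_min`, `raw_max`, `bin_width`.
#' @export
make_histogram <- function(sample, n_bins = 64L) {
  sample <- as.numeric(sample)
  if (length(sample) == 0L || anyNA(sample) || any(!is.finite(sample))) {
    stop("sample must be non-empty and finite")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("`n_bins` must be at least 4")
  rng <- range(sample)
  if (diff(rng) <= 0) {
    stop("degenerate histogram: sample has zero intensity range")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(sample, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  width <- diff(edges)[1]
  out <- tibble::tibble(
    bin_left = edges[-(n_bins + 1L)],
    bin_right = edges[-1L],
    bin_center = h$mids,
    count = h$counts,
    density = h$counts / (length(sample) * width)
  )
  attr(out, "n_pixels") <- length(sample)
  attr(out, "raw_min") <- rng[1]
  attr(out, "raw_max") <- rng[2]
  attr(out, "bin_width") <- width
  class(out) <- c("intensity_histogram", class(out))
  out
}

#' Fit the three-parameter Rayleigh density to an intensity histogram
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of [rayleigh_pdf()]
#' against the histogram's `(bin_center, density)` pairs. The goodness of fit
#' `r_squared = 1 - SSE / SS_tot` is computed on the bin heights, with
#' `SS_tot` taken about the mean density. Starting values are derived from
#' the histogram (`c0` below the sample minimum, `b0` the distance from `c0`
#' to the mode bin, `a0` matching the peak density), with progressively
#' deeper shift starts tried when a solution ends on a bound; every
#' Levenberg-Marquardt solution is polished by a projected quasi-Newton pass
#' so a spuriously pinned bound is released. Bounds keep `b` positive and
#' `c` at or below the sample minimum. A fit that fails or genuinely ends
#' pinned at a bound is reported with `converged = FALSE`; coefficients are
#' still returned.
#'
#' @param hist An `intensity_histogram` from [make_histogram()], or a numeric
#'   sample (which is histogrammed first with `n_bins` bins).
#' @param n_bins Bin count used only when `hist` is a raw sample.
#' @return An object of class `rayleigh_fit`: a list with elements `a`, `b`,
#'   `c`, `r_squared`, `sse`, `converged`, `n_pixels`, `n_bins`, and the
#'   histogram augmented with a `fitted` column.
#' @seealso [tidy.rayleigh_fit()], [glance.rayleigh_fit()],
#'   [autoplot.rayleigh_fit()]
#' @export
fit_rayleigh <- function(hist, n_bins = 64L) {
  if (is.numeric(hist)) hist <- make_histogram(hist, n_bins = n_bins)
  stopifnot(inherits(hist, "intensity_histogram"))
  if (sum(hist$count > 0) < 4L) {
    stop("histogram must have at least 4 non-empty bins")
  }
  x <- hist$bin_center
  y <- hist$density
  if (stats::var(y) == 0) stop("degenerate histogram: flat density")

  raw_min <- unname(attr(hist, "raw_min"))
  raw_max <- unname(attr(hist, "raw_max"))
  rng <- raw_max - raw_min
  b0 <- x[which.max(y)] - (raw_min - 0.05 * rng)
  a0 <- max(y) * b0 * exp(0.5)
  lower <- c(a = 0, b = 1e-12, c = raw_min - rng)
  upper <- c(a = Inf, b = 10 * rng, c = raw_min)

  resid_fn <- function(p) y - rayleigh_pdf(x, p[1], max(p[2], 1e-12), p[3])
  sse_fn <- function(p) sum(resid_fn(p)^2)
  lm_pass <- function(start) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 500, maxfev = 2000
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(par = start, ok = FALSE))
    # polish: projected LM steps can stall on the box; a quasi-Newton pass
    # from the LM solution leaves a spuriously pinned bound
    pol <- tryCatch(
      stats::optim(fit$par, sse_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL
    )
    par <- fit$par
    ok <- fit$info %in% 1:4
    if (!is.null(pol) && pol$value < sse_fn(par)) {
      # re-entering LM from the interior point regains quadratic convergence
      refit <- tryCatch(
        minpack.lm::nls.lm(
          par = pol$par, fn = resid_fn, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(
            ftol = 1e-14, ptol = 1e-14, maxiter = 200, maxfev = 1000
          )
        ),
        error = function(e) NULL
      )
      if (!is.null(refit) && sse_fn(refit$par) <= pol$value) {
        par <- refit$par
        ok <- refit$info %in% 1:4
      } else {
        par <- pol$par
        ok <- pol$convergence == 0
      }
    }
    list(par = par, ok = ok)
  }
  at_bound <- function(par) {
    tol <- 1e-9 * pmax(1, abs(par))
    lo <- is.finite(lower) & (par - lower) <= tol
    hi <- is.finite(upper) & (upper - par) <= tol
    any((lo | hi)[c("b", "c")])
  }

  # shallow, default and deep shift starts; stop early once a start lands
  # on an interior optimum
  best <- NULL
  for (c0 in raw_min - c(0.05, 0.15, 0.4) * rng) {
    b_start <- x[which.max(y)] - c0
    cand <- lm_pass(c(a = max(y) * b_start * exp(0.5), b = b_start, c = c0))
    if (is.null(best) || sse_fn(cand$par) < sse_fn(best$par)) best <- cand
    if (best$ok && !at_bound(best$par)) break
  }
  est <- best$par
  ok <- best$ok && !at_bound(est)  # pinned bounds are flagged, not errored

  fitted <- rayleigh_pdf(x, est["a"], est["b"], est["c"])
  sse <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  hist$fitted <- fitted

  structure(
    list(
      a = unname(est["a"]), b = unname(est["b"]), c = unname(est["c"]),
      r_squared = 1 - sse / ss_tot, sse = sse,
      converged = isTRUE(ok),
      n_pixels = attr(hist, "n_pixels"), n_bins = nrow(hist),
      histogram = hist
    ),
    class = "rayleigh_fit"
  )
}

#' Coefficient of determination of a Rayleigh fit on histogram heights
#'
#' `1 - SS_res / SS_tot` where residuals compare the model evaluated at the
#' bin centres against the observed densities, and `SS_tot` is about the mean
#' density. Equals 1 for a perfect fit and 0 for a model identical to the
#' mean density; always `<= 1`.
#'
#' @param hist An `intensity_histogram`.
#' @param fit Either a `rayleigh_fit` or a numeric vector of model densities
#'   evaluated at `hist$bin_center`.
#' @return A single numeric value.
#' @export
r_squared <- function(hist, fit) {
  stopifnot(inherits(hist, "intensity_histogram"))
  model <- if (inherits(fit, "rayleigh_fit")) {
    rayleigh_pdf(hist$bin_center, fit$a, fit$b, fit$c)
  } else {
    as.numeric(fit)
  }
  if (length(model) != nrow(hist)) {
    stop("model densities must match the histogram's bins")
  }
  y <- hist$density
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("flat histogram: SS_tot is zero")
  1 - sum((y - model)^2) / ss_tot
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat("Three-parameter Rayleigh fit\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  R^2 = %.4f  (SSE %.3g, %d pixels, %d bins)%s\n",
              x$r_squared, x$sse, x$n_pixels, x$n_bins,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Tidy a Rayleigh fit into a coefficient table
#'
#' @param x A `rayleigh_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy rayleigh_fit
#' @export
tidy.rayleigh_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' One-row summary of a Rayleigh fit
#'
#' @param x A `rayleigh_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `sse`, `converged`, `n_pixels`, `n_bins`.
#' @method glance rayleigh_fit
#' @export
glance.rayleigh_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sse = x$sse, converged = x$converged,
    n_pixels = x$n_pixels, n_bins = x$n_bins
  )
}

#' Plot an intensity histogram with its Rayleigh fit
#'
#' @param object A `rayleigh_fit`.
#' @param ... Unused.
#' @return A ggplot object: histogram bars with the fitted density overlaid.
#' @method autoplot rayleigh_fit
#' @export
autoplot.rayleigh_fit <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_center)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density),
                      width = attr(h, "bin_width"),
                      fill = "darkseagreen3", colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "intensity (a.u.)", y = "density",
      title = sprintf("Rayleigh fit: R² = %.3f, a = %.2f, b = %.2f, c = %.2f",
                      object$r_squared, object$a, object$b, object$c)
    ) +
    ggplot2::theme_minimal()
}
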