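# Shared fixtures, built in code at test time.

# shifted Rayleigh sample via the closed-form quantile transform
r_shifted_rayleigh <- function(n, b, c = 0) {
  c + b * sqrt(-2 * log(stats::runif(n)))
}

# closed-form CDF of the shifted Rayleigh, for KS oracles
p_shifted_rayleigh <- function(q, b, c = 0) {
  ifelse(q < c, 0, 1 - exp(-(q - c)^2 / (2 * b^2)))
}

# a small volume holding iid draws from one generator function
toy_volume <- function(dims = c(6L, 6L, 10L, 4L), gen = stats::rnorm,
                       pitch = c(7.5, 7.5, 3.75), seed = 1L) {
  set.seed(seed)
  oct_volume(array(abs(gen(prod(dims))) + 0.01, dim = dims), pitch)
}

# compact phantom used where full default geometry would be overkill
small_phantom_config <- function(seed = 0L, ...) {
  phantom_config(
    volume_shape = c(100L, 100L, 12L, 8L),
    surface_depth = 90,
    noise_band_start = 570,
    tube = list(center_depth = 280, center_fast = 260,
                inner_diameter = 160, outer_diameter = 380),
    rod = list(center_depth = 280, center_fast = 560, diameter = 200),
    seed = seed,
    ...
  )
}

# exact histogram whose densities are generated from the model itself;
# raw_min sits above c so the shift bound is not pinned
model_histogram <- function(a, b, c, n_bins = 64L, span = 4) {
  lo <- c + 0.02 * b
  hi <- c + span * b
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  h <- tibble::tibble(
    bin_left = edges[-(n_bins + 1L)],
    bin_right = edges[-1],
    bin_center = centers,
    count = 100L,
    density = rayleigh_pdf(centers, a, b, c)
  )
  attr(h, "n_pixels") <- 100L * n_bins
  attr(h, "raw_min") <- lo
  attr(h, "raw_max") <- hi
  attr(h, "bin_width") <- diff(edges)[1]
  class(h) <- c("intensity_histogram", class(h))
  h
}

# exhaustive SSE evaluation over a full (a, b, c) grid: the brute-force
# oracle the optimizer is checked against
grid_search_sse <- function(hist, a_grid, b_grid, c_grid) {
  x <- hist$bin_center
  y <- hist$density
  best <- Inf
  for (b in b_grid) for (cc in c_grid) {
    m <- rayleigh_pdf(x, 1, b, cc)
    # SSE(a) = yy - 2 a (m.y) + a^2 (m.m), evaluated at every grid a
    sse <- sum(y^2) - 2 * a_grid * sum(m * y) + a_grid^2 * sum(m^2)
    best <- min(best, min(sse))
  }
  best
}
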