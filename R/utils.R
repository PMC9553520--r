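# Seeding discipline: every stochastic operation evaluates under an explicit
# seed with a fixed RNG configuration (Mersenne-Twister, inversion normals,
# rejection sampling), restoring the caller's RNG state afterwards.
with_rng <- function(seed, code) {
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Rayleigh(sigma) amplitudes via the circular-Gaussian quadratures
rrayleigh <- function(n, sigma = 1) {
  sigma * sqrt(stats::rnorm(n)^2 + stats::rnorm(n)^2)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
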