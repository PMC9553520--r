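#' Region labels used by the phantom simulator
#'
#' The six material classes of the tissue-mimicking phantom: air above the
#' sample surface, the deep low-signal noise band, dyed water in the tube
#' lumen (lymph analogue), the transparent solid rod (nerve analogue), the
#' semi-transparent tube wall, and the Intralipid-gelatin scattering
#' background (tissue analogue).
#'
#' @return Character vector of the six region labels, in canonical order.
#' @export
region_labels <- function() {
  c("air", "noise", "dyed_water", "transparent_solid",
    "semi_transparent_solid", "intralipid")
}

#' Speckle model for one phantom region
#'
#' Describes the generative intensity statistics of one material class.
#' Amplitudes are built as `shift + R1 + R2` where `R1` is Rayleigh speckle
#' with scale `base_scale` (decaying as `exp(-depth_attenuation * dz)` with
#' depth below the region top) and `R2` is an additive Rayleigh detector
#' noise floor with scale `noise_floor_scale`. With probability
#' `1 - rayleigh_purity` a voxel's speckle is drawn instead from a
#' depth-graded contaminating Rayleigh component whose scale sweeps linearly
#' across successive ROI-sized depth blocks, degrading the single-Rayleigh
#' fit the way strong local attenuation gradients do in dense scatterers.
#' `decorrelation` interpolates the underlying circular-Gaussian speckle
#' field between a frozen realisation (0, solids) and an independent draw
#' per repeat frame (1, fluids and noise), preserving the Rayleigh marginal
#' at every setting.
#'
#' @param label One of [region_labels()].
#' @param base_scale Rayleigh scale of the signal amplitude (a.u.), > 0.
#' @param shift Additive intensity offset (a.u.); may be negative.
#' @param noise_floor_scale Rayleigh scale of the additive noise floor, >= 0.
#' @param depth_attenuation Exponential decay of `base_scale` per micrometre
#'   of depth below the region top, >= 0.
#' @param rayleigh_purity Fraction of voxels carrying a single-component
#'   Rayleigh signal, in `[0, 1]`.
#' @param decorrelation Speckle decorrelation between repeat frames, in
#'   `[0, 1]`.
#' @return A list of class `region_speckle_model`.
#' @export
region_speckle_model <- function(label, base_scale, shift = 0,
                                 noise_floor_scale = 0,
                                 depth_attenuation = 0,
                                 rayleigh_purity = 1,
                                 decorrelation = 1) {
  label <- match.arg(label, region_labels())
  stopifnot(
    is.numeric(base_scale), base_scale > 0,
    noise_floor_scale >= 0, depth_attenuation >= 0,
    rayleigh_purity >= 0, rayleigh_purity <= 1,
    decorrelation >= 0, decorrelation <= 1
  )
  structure(
    list(label = label, base_scale = base_scale, shift = shift,
         noise_floor_scale = noise_floor_scale,
         depth_attenuation = depth_attenuation,
         rayleigh_purity = rayleigh_purity,
         decorrelation = decorrelation),
    class = "region_speckle_model"
  )
}

#' Default region speckle models
#'
#' One [region_speckle_model()] per material class, chosen so the generated
#' phantom reproduces the qualitative fitting regimes seen on real material
#' classes: near-perfect Rayleigh histograms in air and noise, slightly
#' degraded fits in the clear fluid and transparent solid, a visibly
#' non-Rayleigh semi-transparent wall, and a poor single-Rayleigh fit in the
#' dense Intralipid scatterer.
#'
#' @return Named list of `region_speckle_model` objects.
#' @export
default_region_models <- function() {
  list(
    air = region_speckle_model(
      "air", base_scale = 1.0, shift = -0.2,
      noise_floor_scale = 0, decorrelation = 1
    ),
    noise = region_speckle_model(
      "noise", base_scale = 1.3, shift = -0.2,
      noise_floor_scale = 0, decorrelation = 1
    ),
    dyed_water = region_speckle_model(
      "dyed_water", base_scale = 2.2, shift = -0.22,
      noise_floor_scale = 0.3, rayleigh_purity = 1,
      decorrelation = 1
    ),
    transparent_solid = region_speckle_model(
      "transparent_solid", base_scale = 2.8, shift = -0.26,
      noise_floor_scale = 0.15, depth_attenuation = 2e-4,
      rayleigh_purity = 0.92, decorrelation = 0.9
    ),
    semi_transparent_solid = region_speckle_model(
      "semi_transparent_solid", base_scale = 5, shift = -0.2,
      noise_floor_scale = 0.15, depth_attenuation = 1e-3,
      rayleigh_purity = 0.85, decorrelation = 0.9
    ),
    intralipid = region_speckle_model(
      "intralipid", base_scale = 8, shift = -0.3,
      noise_floor_scale = 0.15, depth_attenuation = 2e-3,
      rayleigh_purity = 0.6, decorrelation = 0.9
    )
  )
}

#' Phantom configuration
#'
#' Geometry and per-region speckle models for the synthetic phantom: a
#' semi-transparent tube (lumen filled with dyed water) and a transparent
#' rod, both running along the slow axis, embedded in an Intralipid-gelatin
#' background under an air gap, with a low-signal noise band at depth. The
#' default geometry uses a 305/762 um inner/outer tube diameter and a 400 um
#' rod, at voxel pitches of 7.5 um (depth), 7.5 um (fast) and 3.75 um (slow).
#'
#' @param volume_shape Integer 4-vector `(n_depth, n_fast, n_slow, n_repeat)`.
#' @param voxel_pitch Numeric triple `(dz, dx, dy)` in micrometres.
#' @param surface_depth Depth of the air/medium interface in micrometres.
#' @param noise_band_start Depth (um) below which the background is the
#'   low-signal noise band.
#' @param tube List with `center_depth`, `center_fast` (um, voxel-centre
#'   coordinates), `inner_diameter`, `outer_diameter` (um); axis is slow.
#' @param rod List with `center_depth`, `center_fast`, `diameter` (um).
#' @param region_models Named list with one [region_speckle_model()] per
#'   label in [region_labels()].
#' @param seed Integer RNG seed used by [generate_phantom()].
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(200L, 187L, 16L, 24L),
                           voxel_pitch = c(7.5, 7.5, 3.75),
                           surface_depth = 150,
                           noise_band_start = 1200,
                           tube = list(center_depth = 600, center_fast = 500,
                                       inner_diameter = 305,
                                       outer_diameter = 762),
                           rod = list(center_depth = 600, center_fast = 1100,
                                      diameter = 400),
                           region_models = default_region_models(),
                           seed = 0L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(
    length(volume_shape) == 4L, all(volume_shape >= 1L),
    length(voxel_pitch) == 3L, all(voxel_pitch > 0),
    surface_depth >= 0, noise_band_start > surface_depth
  )
  if (tube$inner_diameter >= tube$outer_diameter) {
    stop("tube inner diameter must be smaller than its outer diameter")
  }
  if (tube$inner_diameter <= 0 || rod$diameter <= 0) {
    stop("tube and rod diameters must be positive")
  }
  depth_um <- volume_shape[1] * voxel_pitch[1]
  fast_um <- volume_shape[2] * voxel_pitch[2]
  check_inside <- function(cz, cx, radius, what) {
    if (cz - radius < 0 || cz + radius > depth_um ||
        cx - radius < 0 || cx + radius > fast_um) {
      stop(what, " does not fit inside the volume (",
           round(depth_um), " x ", round(fast_um), " um)")
    }
  }
  check_inside(tube$center_depth, tube$center_fast,
               tube$outer_diameter / 2, "tube")
  check_inside(rod$center_depth, rod$center_fast, rod$diameter / 2, "rod")
  missing <- setdiff(region_labels(), names(region_models))
  if (length(missing)) {
    stop("region_models missing: ", paste(missing, collapse = ", "))
  }
  for (m in region_models) stopifnot(inherits(m, "region_speckle_model"))
  structure(
    list(volume_shape = volume_shape, voxel_pitch = voxel_pitch,
         surface_depth = surface_depth, noise_band_start = noise_band_start,
         tube = tube, rod = rod, region_models = region_models,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' OCT intensity volume
#'
#' A 4-D array of linear intensities indexed `(depth, fast, slow, repeat)`
#' with voxel pitch metadata. Depth index 1 is the top of the volume;
#' micrometre positions refer to voxel centres.
#'
#' @param intensity 4-D numeric array.
#' @param voxel_pitch Numeric triple `(dz, dx, dy)` in micrometres.
#' @return A list of class `oct_volume`.
#' @export
oct_volume <- function(intensity, voxel_pitch) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 4L,
            all(dim(intensity) >= 1L),
            length(voxel_pitch) == 3L, all(voxel_pitch > 0))
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(
    list(intensity = intensity, voxel_pitch = as.numeric(voxel_pitch),
         n_repeat = dim(intensity)[4]),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "OCT volume: %d x %d x %d voxels, %d repeats (pitch %.3g/%.3g/%.3g um)\n",
    d[1], d[2], d[3], d[4],
    x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3]
  ))
  invisible(x)
}

#' Ground-truth label map
#'
#' 3-D integer array over the spatial voxel grid; values index
#' [region_labels()], 0 means unassigned.
#'
#' @param labels 3-D integer array.
#' @return A list of class `label_map` with elements `labels` and `levels`.
#' @export
label_map <- function(labels) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 6L)) stop("labels must be in 0..6")
  structure(list(labels = labels, levels = region_labels()),
            class = "label_map")
}

# voxel-centre coordinates (um) along one axis, depth index 0 at the top
voxel_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# integer label grid over (depth, fast); constant along slow (tube/rod axis)
phantom_label_grid <- function(config) {
  nz <- config$volume_shape[1]
  nx <- config$volume_shape[2]
  z <- voxel_centers(nz, config$voxel_pitch[1])
  x <- voxel_centers(nx, config$voxel_pitch[2])
  zz <- matrix(z, nz, nx)
  xx <- matrix(x, nz, nx, byrow = TRUE)
  lv <- region_labels()
  grid <- matrix(match("intralipid", lv), nz, nx)
  grid[zz >= config$noise_band_start] <- match("noise", lv)
  r_tube <- sqrt((zz - config$tube$center_depth)^2 +
                 (xx - config$tube$center_fast)^2)
  grid[r_tube < config$tube$outer_diameter / 2] <-
    match("semi_transparent_solid", lv)
  grid[r_tube < config$tube$inner_diameter / 2] <- match("dyed_water", lv)
  r_rod <- sqrt((zz - config$rod$center_depth)^2 +
                (xx - config$rod$center_fast)^2)
  grid[r_rod < config$rod$diameter / 2] <- match("transparent_solid", lv)
  grid[zz < config$surface_depth] <- match("air", lv)
  grid
}

# fractional position of a depth index within successive blocks of
# `block` voxels; drives the depth-graded contaminating component
depth_grade_fraction <- function(depth_index, block = 6L) {
  ((depth_index - 1L) %% block) / (block - 1L)
}

# scale multipliers spanned by the contaminating component: dim, partially
# shadowed speckle down to 5% of the local scale, swept linearly over each
# ROI-depth block
contaminant_grade_span <- c(0.05, 0.30)

#' Generate a synthetic OCT phantom volume with ground truth
#'
#' Draws a 4-D intensity volume from the per-region speckle models of a
#' [phantom_config()] and returns it together with the voxel-wise label map.
#' Speckle amplitudes are generated through an underlying circular-Gaussian
#' field: repeat frame r uses the field
#' `rho * frozen + sqrt(1 - rho^2) * fresh` with `rho = 1 - decorrelation`,
#' so the Rayleigh amplitude marginal is exact at every decorrelation
#' setting. Contaminated voxels (probability `1 - rayleigh_purity`, frozen
#' per spatial voxel) take their scale from a dim linear depth grade spanning
#' 0.05x to 0.30x the local scale over 6-voxel (ROI-depth) blocks, emulating
#' partially shadowed speckle in dense scatterers. The detector
#' noise floor is redrawn independently for every repeat. Deterministic
#' given `config$seed` (Mersenne-Twister, inversion normals, one stream).
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` ([oct_volume()]) and `labels`
#'   ([label_map()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$volume_shape
  nz <- shp[1]; nx <- shp[2]; ny <- shp[3]; nrep <- shp[4]
  grid <- phantom_label_grid(config)
  nvox <- nz * nx * ny
  lab3 <- array(rep(grid, ny), dim = c(nz, nx, ny))

  z_um <- voxel_centers(nz, config$voxel_pitch[1])
  z3 <- array(rep(z_um, nx * ny), dim = c(nz, nx, ny))
  grade <- depth_grade_fraction(array(rep(seq_len(nz), nx * ny),
                                      dim = c(nz, nx, ny)))

  scale_vox <- array(0, dim = c(nz, nx, ny))
  shift_vox <- array(0, dim = c(nz, nx, ny))
  noise_vox <- array(0, dim = c(nz, nx, ny))
  rho_vox <- array(0, dim = c(nz, nx, ny))

  with_rng(config$seed, {
    for (k in seq_along(region_labels())) {
      mask <- lab3 == k
      if (!any(mask)) next
      m <- config$region_models[[region_labels()[k]]]
      top_z <- min(z3[mask])
      s <- m$base_scale * exp(-m$depth_attenuation * (z3[mask] - top_z))
      if (m$rayleigh_purity < 1) {
        contaminated <- stats::runif(sum(mask)) > m$rayleigh_purity
        g <- contaminant_grade_span[1] +
          diff(contaminant_grade_span) * grade[mask]
        s[contaminated] <- s[contaminated] * g[contaminated]
      }
      scale_vox[mask] <- s
      shift_vox[mask] <- m$shift
      noise_vox[mask] <- m$noise_floor_scale
      rho_vox[mask] <- 1 - m$decorrelation
    }

    intensity <- array(0, dim = c(nz, nx, ny, nrep))
    x0 <- stats::rnorm(nvox)
    y0 <- stats::rnorm(nvox)
    rho <- as.vector(rho_vox)
    mix <- sqrt(1 - rho^2)
    for (r in seq_len(nrep)) {
      xr <- rho * x0 + mix * stats::rnorm(nvox)
      yr <- rho * y0 + mix * stats::rnorm(nvox)
      amp <- as.vector(scale_vox) * sqrt(xr^2 + yr^2)
      noise <- as.vector(noise_vox) *
        sqrt(stats::rnorm(nvox)^2 + stats::rnorm(nvox)^2)
      intensity[, , , r] <- as.vector(shift_vox) + amp + noise
    }
  })

  list(
    volume = oct_volume(intensity, config$voxel_pitch),
    labels = label_map(lab3)
  )
}
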