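#' Generate a single-region volume from one speckle model
#'
#' Convenience generator for fixtures and for the flow study: every voxel
#' follows the same [region_speckle_model()], with the same speckle field
#' construction as [generate_phantom()] (frozen circular-Gaussian field,
#' per-repeat decorrelation, dim depth-graded contaminant, additive noise
#' floor).
#'
#' @param model A [region_speckle_model()].
#' @param shape Integer 4-vector `(n_depth, n_fast, n_slow, n_repeat)`.
#' @param voxel_pitch Numeric triple `(dz, dx, dy)` in micrometres.
#' @param seed RNG seed.
#' @return An [oct_volume()].
#' @export
generate_region_volume <- function(model, shape = c(24L, 24L, 16L, 24L),
                                   voxel_pitch = c(7.5, 7.5, 3.75),
                                   seed = 0L) {
  stopifnot(inherits(model, "region_speckle_model"))
  shape <- as.integer(shape)
  nz <- shape[1]; nvox <- prod(shape[1:3]); nrep <- shape[4]
  z_um <- voxel_centers(nz, voxel_pitch[1])
  z3 <- rep(z_um, length.out = nvox)  # depth varies fastest
  grade <- depth_grade_fraction(rep(seq_len(nz), length.out = nvox))

  with_rng(seed, {
    s <- model$base_scale * exp(-model$depth_attenuation * (z3 - z_um[1]))
    if (model$rayleigh_purity < 1) {
      contaminated <- stats::runif(nvox) > model$rayleigh_purity
      g <- contaminant_grade_span[1] + diff(contaminant_grade_span) * grade
      s[contaminated] <- s[contaminated] * g[contaminated]
    }
    rho <- 1 - model$decorrelation
    mix <- sqrt(1 - rho^2)
    x0 <- stats::rnorm(nvox); y0 <- stats::rnorm(nvox)
    intensity <- array(0, dim = shape)
    for (r in seq_len(nrep)) {
      xr <- rho * x0 + mix * stats::rnorm(nvox)
      yr <- rho * y0 + mix * stats::rnorm(nvox)
      amp <- s * sqrt(xr^2 + yr^2)
      noise <- rrayleigh(nvox, model$noise_floor_scale)
      intensity[, , , r] <- model$shift + amp + noise
    }
    oct_volume(intensity, voxel_pitch)
  })
}

#' Auto-place non-overlapping single-region ROIs
#'
#' Rejection-samples ROI origins whose full extent lies inside one region of
#' the label map, keeping at least `min_separation` voxels between accepted
#' ROIs.
#'
#' @param labels A [label_map()].
#' @param region Region label (see [region_labels()]).
#' @param n Number of ROIs requested.
#' @param extent ROI extent triple, default `c(6, 6, 10)`.
#' @param seed RNG seed.
#' @param min_separation Minimum voxel gap between ROIs, default 1.
#' @param max_attempts Sampling attempts before giving up.
#' @return A tibble with 0-based origin columns `depth`, `fast`, `slow`.
#' @export
place_rois <- function(labels, region, n, extent = c(6L, 6L, 10L), seed = 0L,
                       min_separation = 1L, max_attempts = 20000L) {
  stopifnot(inherits(labels, "label_map"))
  k <- match(match.arg(region, region_labels()), region_labels())
  extent <- as.integer(extent)
  dims <- dim(labels$labels)
  if (n == 0L) {
    return(tibble::tibble(depth = integer(), fast = integer(),
                          slow = integer()))
  }
  candidates <- which(labels$labels == k, arr.ind = TRUE) - 1L
  candidates <- candidates[
    candidates[, 1] + extent[1] <= dims[1] &
    candidates[, 2] + extent[2] <= dims[2] &
    candidates[, 3] + extent[3] <= dims[3], , drop = FALSE]
  if (nrow(candidates) == 0L) {
    stop("region '", region_labels()[k], "' too small for a ",
         paste(extent, collapse = "x"), " ROI")
  }
  accepted <- matrix(integer(0), 0, 3)
  with_rng(seed, {
    order_idx <- sample(nrow(candidates))
    tried <- 0L
    for (i in order_idx) {
      if (nrow(accepted) >= n || tried >= max_attempts) break
      tried <- tried + 1L
      o <- candidates[i, ]
      block <- labels$labels[(o[1] + 1L):(o[1] + extent[1]),
                             (o[2] + 1L):(o[2] + extent[2]),
                             (o[3] + 1L):(o[3] + extent[3])]
      if (!all(block == k)) next
      if (nrow(accepted) > 0) {
        sep <- min_separation
        overlap <- any(
          abs(accepted[, 1] - o[1]) < extent[1] + sep &
          abs(accepted[, 2] - o[2]) < extent[2] + sep &
          abs(accepted[, 3] - o[3]) < extent[3] + sep
        )
        if (overlap) next
      }
      accepted <- rbind(accepted, o)
    }
  })
  if (nrow(accepted) < n) {
    stop("could only place ", nrow(accepted), " of ", n, " ROIs in region '",
         region_labels()[k], "'")
  }
  tibble::tibble(depth = accepted[, 1], fast = accepted[, 2],
                 slow = accepted[, 3])
}

#' Region-wise Rayleigh fitting study over phantoms
#'
#' Generates one phantom per seed, auto-places `rois_per_region`
#' non-overlapping ROIs inside every region, pools and fits each ROI, and
#' returns one row per fit. With the defaults (2 phantoms x 10 ROIs) each
#' region contributes n = 20 observations.
#'
#' @param config A [phantom_config()]; its `seed` is replaced per phantom.
#' @param phantom_seeds Integer vector, one seed per phantom; default
#'   `c(seed, seed + 1)`.
#' @param rois_per_region ROIs per region per phantom, default 10.
#' @param extent ROI extent, default `c(6, 6, 10)`.
#' @param n_bins Histogram bins, default 64.
#' @param seed Base seed (phantom seeds and ROI placement derive from it).
#' @return A tibble with columns `phantom`, `region`, `roi`, the ROI origin,
#'   `a`, `b`, `c`, `r_squared`, `sse`, `converged`, `n_pixels`.
#' @export
run_roi_study <- function(config = phantom_config(), phantom_seeds = NULL,
                          rois_per_region = 10L, extent = c(6L, 6L, 10L),
                          n_bins = 64L, seed = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(phantom_seeds)) phantom_seeds <- seed + c(0L, 1L)
  purrr::map_dfr(seq_along(phantom_seeds), function(p) {
    cfg <- config
    cfg$seed <- as.integer(phantom_seeds[p])
    ph <- generate_phantom(cfg)
    purrr::map_dfr(region_labels(), function(reg) {
      origins <- place_rois(ph$labels, reg, rois_per_region, extent,
                            seed = seed + 1000L * p)
      purrr::map_dfr(seq_len(nrow(origins)), function(i) {
        o <- c(origins$depth[i], origins$fast[i], origins$slow[i])
        fit <- fit_rayleigh(pool_roi(ph$volume, o, extent), n_bins = n_bins)
        tibble::tibble(
          phantom = p, region = factor(reg, levels = region_labels()),
          roi = i, depth = o[1], fast = o[2], slow = o[3],
          a = fit$a, b = fit$b, c = fit$c, r_squared = fit$r_squared,
          sse = fit$sse, converged = fit$converged, n_pixels = fit$n_pixels
        )
      })
    })
  })
}

#' Summarise a ROI study per region
#'
#' @param study Output of [run_roi_study()].
#' @return A tibble with per-region mean and sd of `r_squared`, `a`, `b`, `c`
#'   and the observation count.
#' @export
summarise_roi_study <- function(study) {
  dplyr::group_by(study, .data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      r_squared_mean = mean(.data$r_squared),
      r_squared_sd = stats::sd(.data$r_squared),
      a_mean = mean(.data$a), a_sd = stats::sd(.data$a),
      b_mean = mean(.data$b), b_sd = stats::sd(.data$b),
      c_mean = mean(.data$c), c_sd = stats::sd(.data$c),
      .groups = "drop"
    )
}

#' Flow-condition insensitivity study on the lumen
#'
#' Simulates the tube lumen under three conditions -- dyed water flowing,
#' dyed water static, and clear water static -- fits `rois_per_condition`
#' ROIs per condition, and permutation-tests every condition pair for a
#' difference in mean `r_squared` and mean `a`. Flow does not alter the
#' pooled spatial speckle statistics; dye is modelled as a 0.98 intensity
#' scale factor (absorption only) and Brownian motion keeps water speckle
#' nearly fully decorrelated between repeats whether flowing or not, so the
#' comparison is a designed null.
#'
#' @param lumen_model The dyed-water [region_speckle_model()]; default from
#'   [default_region_models()].
#' @param rois_per_condition ROIs per condition, default 10.
#' @param shape Single-region volume shape, default `c(36, 36, 16, 24)`
#'   (room for up to 16 separated lumen ROIs).
#' @param n_bins Histogram bins.
#' @param n_permutations Permutations per test, default 1000.
#' @param alpha Significance level for flagging, default 0.05.
#' @param seed Base RNG seed.
#' @return A list with `fits` (per-ROI tibble with `condition`), `tests`
#'   (tibble: `metric`, `condition_a`, `condition_b`, `p_value`, `flagged`)
#'   and `alpha`.
#' @export
run_flow_study <- function(lumen_model = default_region_models()$dyed_water,
                           rois_per_condition = 10L,
                           shape = c(36L, 36L, 16L, 24L), n_bins = 64L,
                           n_permutations = 1000L, alpha = 0.05,
                           seed = 0L) {
  dye_factor <- 0.98
  conditions <- list(
    flowing_dyed = list(decorrelation = 1.0, scale_factor = dye_factor),
    static_dyed = list(decorrelation = 0.97, scale_factor = dye_factor),
    static_clear = list(decorrelation = 0.97, scale_factor = 1.0)
  )
  fits <- purrr::imap_dfr(conditions, function(cnd, name) {
    m <- lumen_model
    m$decorrelation <- cnd$decorrelation
    m$base_scale <- m$base_scale * cnd$scale_factor
    m$shift <- m$shift * cnd$scale_factor
    vol <- generate_region_volume(m, shape,
                                  seed = seed + match(name, names(conditions)))
    lab <- label_map(array(match("dyed_water", region_labels()),
                           dim = shape[1:3]))
    origins <- place_rois(lab, "dyed_water", rois_per_condition,
                          seed = seed + 100L)
    purrr::map_dfr(seq_len(nrow(origins)), function(i) {
      o <- c(origins$depth[i], origins$fast[i], origins$slow[i])
      fit <- fit_rayleigh(pool_roi(vol, o), n_bins = n_bins)
      tibble::tibble(condition = name, roi = i, a = fit$a, b = fit$b,
                     c = fit$c, r_squared = fit$r_squared)
    })
  })
  pairs <- utils::combn(names(conditions), 2, simplify = FALSE)
  tests <- purrr::map_dfr(c("r_squared", "a"), function(metric) {
    purrr::imap_dfr(pairs, function(pr, i) {
      xa <- fits[[metric]][fits$condition == pr[1]]
      xb <- fits[[metric]][fits$condition == pr[2]]
      p <- permutation_test(xa, xb, n_permutations,
                            seed = seed + 7L * i +
                              37L * match(metric, c("r_squared", "a")))
      tibble::tibble(metric = metric, condition_a = pr[1],
                     condition_b = pr[2], p_value = p)
    })
  })
  # family-wise control over the 6 pairwise comparisons, matching the
  # multiple-comparison ANOVA treatment such condition contrasts get
  tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "holm")
  tests$flagged <- tests$p_adjusted < alpha
  list(fits = fits, tests = tests, alpha = alpha)
}

#' Two-sided permutation test for a difference in means
#'
#' Monte-Carlo permutation p-value for `|mean(x) - mean(y)|` under random
#' relabelling, with the +1 correction so p is never exactly 0.
#'
#' @param x,y Numeric samples.
#' @param n_permutations Number of relabellings, default 1000.
#' @param seed RNG seed.
#' @return A p-value in (0, 1].
#' @export
permutation_test <- function(x, y, n_permutations = 1000L, seed = 0L) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  with_rng(seed, {
    exceed <- sum(vapply(seq_len(n_permutations), function(i) {
      idx <- sample(length(pooled), nx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs
    }, logical(1)))
    (exceed + 1) / (n_permutations + 1)
  })
}

#' Compare classifier feature sets on a labelled volume
#'
#' Runs the full classification protocol -- draw `per_class` training pixels
#' per region, compute features, train an RBF SVM with stratified k-fold
#' cross-validation -- once per dataset randomization and once per feature
#' set, re-using the same sampled pixels across feature sets so the
#' comparison is paired. Feature sets: `"rayleigh"` (R^2, a, c from the
#' windowed Rayleigh fit), `"attenuation"` (window-averaged depth-resolved
#' attenuation coefficient), `"glcm"` (four Haralick features of the B-scan
#' plane window).
#'
#' @param volume An [oct_volume()].
#' @param labels A [label_map()].
#' @param feature_sets Character vector among `"rayleigh"`, `"attenuation"`,
#'   `"glcm"`.
#' @param per_class Training pixels per region per randomization, default 30.
#' @param folds Cross-validation folds, default 5.
#' @param n_randomizations Dataset randomizations, default 10.
#' @param window Rayleigh window extent, default `c(6, 6, 10)`.
#' @param n_bins Histogram bins.
#' @param seed Base seed; randomization r uses `seed + r`.
#' @return A named list of [build_report()] results, one per feature set,
#'   with a `comparison` tibble attribute (`feature_set`, `accuracy_mean`,
#'   `accuracy_sd`).
#' @export
classifier_study <- function(volume, labels,
                             feature_sets = c("rayleigh", "attenuation",
                                              "glcm"),
                             per_class = 30L, folds = 5L,
                             n_randomizations = 10L,
                             window = c(6L, 6L, 10L), n_bins = 64L,
                             seed = 0L) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  att <- if ("attenuation" %in% feature_sets) attenuation_map(volume)
  runs <- stats::setNames(
    lapply(feature_sets, function(fs) vector("list", n_randomizations)),
    feature_sets
  )
  for (r in seq_len(n_randomizations)) {
    rseed <- seed + r
    centers <- sample_region_centers(volume, labels, per_class, rseed, window)
    for (fs in feature_sets) {
      tbl <- switch(fs,
        rayleigh = {
          feats <- purrr::map_dfr(seq_len(nrow(centers)), function(i) {
            window_features(volume, c(centers$depth[i], centers$fast[i],
                                      centers$slow[i]), window, n_bins)
          })
          dplyr::bind_cols(centers, feats[, c("r_squared", "a_coeff",
                                              "c_coeff")])
        },
        attenuation = {
          mu <- vapply(seq_len(nrow(centers)), function(i) {
            window_mean_mu(att, c(centers$depth[i], centers$fast[i],
                                  centers$slow[i]), window)
          }, numeric(1))
          dplyr::bind_cols(centers, tibble::tibble(mu = mu))
        },
        glcm = {
          g <- glcm_features_at(volume,
                                as.matrix(centers[, c("depth", "fast",
                                                      "slow")]),
                                window = window[1:2])
          dplyr::bind_cols(centers,
                           g[, c("contrast", "correlation", "energy",
                                 "homogeneity")])
        }
      )
      runs[[fs]][[r]] <- train_svm_cv(tbl, folds = folds, seed = rseed)
    }
  }
  reports <- lapply(runs, build_report)
  comparison <- purrr::imap_dfr(reports, function(rep, fs) {
    tibble::tibble(feature_set = fs,
                   accuracy_mean = rep$overall_accuracy_mean,
                   accuracy_sd = rep$overall_accuracy_sd)
  })
  attr(reports, "comparison") <- comparison
  reports
}

# mean attenuation over the window footprint, ignoring masked voxels
window_mean_mu <- function(att, center, window) {
  dims <- dim(att$mu)
  o <- as.integer(center) - as.integer(window) %/% 2L
  if (any(o < 0L) || any(o + window > dims)) return(NA_real_)
  vals <- att$mu[(o[1] + 1L):(o[1] + window[1]),
                 (o[2] + 1L):(o[2] + window[2]),
                 (o[3] + 1L):(o[3] + window[3])]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}
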