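#' Sample labelled training pixels and their Rayleigh-fit features
#'
#' Draws `per_class` voxels uniformly without replacement from each region
#' of a label map and returns their `(R^2, a, c)` features. Given a
#' [feature_map()], features are looked up at valid map voxels; given an
#' [oct_volume()], features are fitted on demand in a window around each
#' sampled voxel, which avoids fitting the full volume when only a training
#' sample is needed. Candidate voxels are those whose feature window lies
#' fully inside the volume and carries a single region label throughout:
#' supervised training pixels must have an unambiguous ground-truth label
#' for the pooled sample their features are computed from.
#'
#' @param x A [feature_map()] or an [oct_volume()].
#' @param labels A [label_map()].
#' @param per_class Number of pixels per region, default 30.
#' @param seed RNG seed for the draw.
#' @param window,n_bins Window extents and histogram bins (volume input).
#' @return A tibble of class `feature_table`: columns `region` (factor over
#'   [region_labels()]), 0-based `depth`, `fast`, `slow`, the feature
#'   columns `r_squared`, `a_coeff`, `c_coeff`, and `seed`.
#' @export
sample_training_pixels <- function(x, labels, per_class = 30L, seed = 0L,
                                   window = c(6L, 6L, 10L), n_bins = 64L) {
  stopifnot(inherits(labels, "label_map"))
  centers <- sample_region_centers(x, labels, per_class, seed, window)
  feats <- if (inherits(x, "feature_map")) {
    purrr::map_dfr(seq_len(nrow(centers)), function(r) {
      i <- centers$depth[r] + 1L; j <- centers$fast[r] + 1L
      k <- centers$slow[r] + 1L
      tibble::tibble(r_squared = x$r_squared[i, j, k],
                     a_coeff = x$a_coeff[i, j, k],
                     c_coeff = x$c_coeff[i, j, k])
    })
  } else {
    purrr::map_dfr(seq_len(nrow(centers)), function(r) {
      f <- window_features(x, c(centers$depth[r], centers$fast[r],
                                centers$slow[r]), window, n_bins)
      f[, c("r_squared", "a_coeff", "c_coeff")]
    })
  }
  out <- dplyr::bind_cols(centers, feats)
  out$seed <- as.integer(seed)
  class(out) <- c("feature_table", class(out))
  out
}

# 3-D box-filter sum via integral image; returns the window sum anchored at
# each valid window origin, NA elsewhere
box_sum <- function(arr, window) {
  dims <- dim(arr)
  cs <- apply(arr, c(2, 3), cumsum)                    # along depth
  cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))  # along fast
  cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))  # along slow
  pad <- array(0, dims + 1L)
  pad[-1, -1, -1] <- cs
  w <- window
  n <- dims - w + 1L
  i <- seq_len(n[1]); j <- seq_len(n[2]); k <- seq_len(n[3])
  pad[i + w[1], j + w[2], k + w[3], drop = FALSE] -
    pad[i, j + w[2], k + w[3], drop = FALSE] -
    pad[i + w[1], j, k + w[3], drop = FALSE] -
    pad[i + w[1], j + w[2], k, drop = FALSE] +
    pad[i, j, k + w[3], drop = FALSE] +
    pad[i, j + w[2], k, drop = FALSE] +
    pad[i + w[1], j, k, drop = FALSE] -
    pad[i, j, k, drop = FALSE]
}

# centres whose full window footprint carries one region label: supervised
# training pixels must have an unambiguous label for the pooled sample
window_pure_mask <- function(labels, k, window) {
  dims <- dim(labels)
  half <- as.integer(window) %/% 2L
  m <- array(as.numeric(labels == k), dims)
  pure_origin <- box_sum(m, window) >= prod(window) - 0.5
  out <- array(FALSE, dims)
  n <- dims - window + 1L
  out[(half[1] + 1L):(half[1] + n[1]),
      (half[2] + 1L):(half[2] + n[2]),
      (half[3] + 1L):(half[3] + n[3])] <- pure_origin
  out
}

# uniform per-class draw of window-pure centres; errors name the region
sample_region_centers <- function(x, labels, per_class, seed, window) {
  dims <- dim(labels$labels)
  if (inherits(x, "feature_map")) {
    valid <- x$valid
  } else if (inherits(x, "oct_volume")) {
    stopifnot(identical(dim(x$intensity)[1:3], dims))
    valid <- array(TRUE, dims)
  } else {
    stop("`x` must be a feature_map or an oct_volume")
  }
  with_rng(seed, {
    purrr::map_dfr(seq_along(region_labels()), function(k) {
      ok <- which(window_pure_mask(labels$labels, k, window) & valid)
      if (length(ok) < per_class) {
        stop("region '", region_labels()[k], "' has only ", length(ok),
             " valid voxels; ", per_class, " requested")
      }
      picked <- if (per_class > 0L) sample(ok, per_class) else integer(0)
      idx <- arrayInd(picked, dims)
      tibble::tibble(
        region = factor(region_labels()[k], levels = region_labels()),
        depth = idx[, 1] - 1L, fast = idx[, 2] - 1L, slow = idx[, 3] - 1L
      )
    })
  })
}

feature_columns <- function(table) {
  setdiff(names(table), c("region", "depth", "fast", "slow", "seed"))
}

#' Cross-validated RBF-kernel support vector machine
#'
#' Trains a Gaussian-kernel SVM on a labelled feature table with stratified
#' k-fold cross-validation and returns the out-of-fold predictions and
#' per-class decision scores. Features are standardised (z-score) with
#' parameters estimated from the training folds only. The kernel scale
#' defaults to the "fine" preset `sqrt(d)/4` for `d` features (passed to the
#' underlying fit as `gamma = 1/scale^2`), box constraint 1, one-vs-one
#' multiclass with summed pairwise decision values as one-vs-rest scores.
#'
#' @param table A `feature_table` (or any tibble with a `region` factor and
#'   numeric feature columns).
#' @param folds Number of cross-validation folds, default 5.
#' @param seed RNG seed for the fold assignment.
#' @param kernel_scale Gaussian kernel scale; default `sqrt(d)/4`.
#' @param cost Box constraint, default 1.
#' @return A list of class `svm_cv`: `predictions` (tibble with `row`,
#'   `fold`, `truth`, `pred` and one `score_*` column per class),
#'   `scaling` (per-fold standardisation parameters), `accuracy`
#'   (out-of-fold mean of per-class true-positive rates), and the settings.
#' @export
train_svm_cv <- function(table, folds = 5L, seed = 0L, kernel_scale = NULL,
                         cost = 1) {
  stopifnot(is.data.frame(table), "region" %in% names(table), folds >= 2L)
  fcols <- feature_columns(table)
  keep <- stats::complete.cases(table[, fcols])
  table <- table[keep, ]
  y <- droplevels(factor(table$region))
  if (nlevels(y) < 2L) stop("need at least two classes to train")
  counts <- table(y)
  if (any(counts < folds)) {
    stop("cannot stratify: class '", names(counts)[which.min(counts)],
         "' has fewer rows (", min(counts), ") than folds (", folds, ")")
  }
  X <- as.matrix(table[, fcols])
  d <- ncol(X)
  if (is.null(kernel_scale)) kernel_scale <- sqrt(d) / 4
  gamma <- 1 / kernel_scale^2

  fold_id <- integer(nrow(X))
  with_rng(seed, {
    for (lv in levels(y)) {
      rows <- which(y == lv)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })

  all_levels <- levels(y)
  preds <- vector("list", folds)
  scalings <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    scalings[[f]] <- list(center = mu, scale = sdv)
    Ztr <- scale(X[tr, , drop = FALSE], mu, sdv)
    Zva <- scale(X[!tr, , drop = FALSE], mu, sdv)
    fit <- e1071::svm(Ztr, y[tr], kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE)
    pr <- stats::predict(fit, Zva, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    scores <- ovr_scores(dv, all_levels)
    preds[[f]] <- dplyr::bind_cols(
      tibble::tibble(row = which(!tr), fold = f,
                     truth = y[!tr], pred = factor(pr, levels = all_levels)),
      scores
    )
  }
  predictions <- dplyr::arrange(dplyr::bind_rows(preds), .data$row)
  acc <- mean(diag(prop.table(table(predictions$truth, predictions$pred),
                              margin = 1)), na.rm = TRUE)
  structure(
    list(predictions = predictions, scaling = scalings, accuracy = acc,
         folds = folds, seed = as.integer(seed),
         kernel_scale = kernel_scale, cost = cost, features = fcols,
         levels = all_levels),
    class = "svm_cv"
  )
}

# one-vs-rest scores from pairwise (one-vs-one) decision values
ovr_scores <- function(dv, levels) {
  out <- matrix(0, nrow(dv), length(levels),
                dimnames = list(NULL, levels))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (p in seq_along(pairs)) {
    out[, pairs[[p]][1]] <- out[, pairs[[p]][1]] + dv[, p]
    out[, pairs[[p]][2]] <- out[, pairs[[p]][2]] - dv[, p]
  }
  colnames(out) <- paste0("score_", colnames(out))
  tibble::as_tibble(out)
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV RBF SVM on (%s): out-of-fold accuracy %.1f%%\n",
    x$folds, paste(x$features, collapse = ", "), 100 * x$accuracy
  ))
  invisible(x)
}

#' One-vs-rest ROC curves with optimal operating points
#'
#' Builds the ROC curve of each class from per-class decision scores,
#' computes the area under the curve by the trapezoid rule, and marks the
#' operating point maximising Youden's J = TPR - FPR (ties broken toward
#' higher TPR).
#'
#' @param scores Numeric matrix or data frame, one column per class (the
#'   `score_*` columns of [train_svm_cv()] predictions are accepted).
#' @param labels Factor (or character) of true class labels.
#' @return A tibble with one row per class: `class`, `auc`, `optimal_fpr`,
#'   `optimal_tpr`, `optimal_threshold`, and a `roc` list-column of
#'   `(threshold, fpr, tpr)` tibbles.
#' @export
roc_analysis <- function(scores, labels) {
  scores <- as.data.frame(scores)
  names(scores) <- sub("^score_", "", names(scores))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("ROC undefined: labels contain a single class")
  }
  purrr::map_dfr(names(scores), function(cls) {
    s <- scores[[cls]]
    y <- labels == cls
    if (!any(y) || all(y)) {
      stop("ROC undefined for class '", cls, "': one-sided labels")
    }
    ord <- order(s, decreasing = TRUE)
    s_ord <- s[ord]; y_ord <- y[ord]
    # step through descending unique thresholds
    uniq <- !duplicated(s_ord)
    tp <- cumsum(y_ord); fp <- cumsum(!y_ord)
    idx <- c(which(uniq)[-1] - 1L, length(s_ord))
    tpr <- c(0, tp[idx] / sum(y))
    fpr <- c(0, fp[idx] / sum(!y))
    thr <- c(Inf, s_ord[uniq])
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    j <- tpr - fpr
    best <- which(j == max(j))
    best <- best[which.max(tpr[best])]
    tibble::tibble(
      class = cls, auc = auc,
      optimal_fpr = fpr[best], optimal_tpr = tpr[best],
      optimal_threshold = thr[best],
      roc = list(tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr))
    )
  })
}

#' Aggregate cross-validated runs into a classifier report
#'
#' Averages row-normalised confusion matrices over dataset randomizations,
#' summarises overall accuracy (the mean of the per-class true-positive
#' rates, i.e. the mean confusion diagonal) as mean +/- sd across
#' randomizations, and averages per-class ROC summaries.
#'
#' @param runs A list of [train_svm_cv()] results (one per randomization).
#' @return An object of class `classifier_report`: `confusion` (row-
#'   normalised, true x predicted), `overall_accuracy_mean` and
#'   `overall_accuracy_sd` (percent), `per_class` (tibble with mean AUC,
#'   TPR, FNR and optimal points), `n_randomizations`, `seeds`.
#' @export
build_report <- function(runs) {
  stopifnot(length(runs) >= 1L)
  lv <- runs[[1]]$levels
  confusions <- lapply(runs, function(r) {
    tab <- table(factor(r$predictions$truth, lv),
                 factor(r$predictions$pred, lv))
    prop.table(tab, margin = 1)
  })
  accs <- vapply(confusions, function(m) mean(diag(m)), numeric(1))
  conf_mean <- Reduce(`+`, confusions) / length(confusions)

  rocs <- lapply(runs, function(r) {
    roc_analysis(r$predictions[paste0("score_", lv)], r$predictions$truth)
  })
  per_class <- dplyr::bind_rows(rocs) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      auc = mean(.data$auc),
      optimal_fpr = mean(.data$optimal_fpr),
      optimal_tpr = mean(.data$optimal_tpr),
      .groups = "drop"
    )
  tpr <- diag(conf_mean)
  per_class <- dplyr::left_join(
    per_class,
    tibble::tibble(class = lv, tpr = tpr, fnr = 1 - tpr),
    by = "class"
  )
  structure(
    list(
      confusion = conf_mean,
      overall_accuracy_mean = 100 * mean(accs),
      overall_accuracy_sd = if (length(accs) == 1L) 0
                            else 100 * stats::sd(accs),
      accuracies = 100 * accs,
      per_class = per_class,
      roc_curves = rocs,
      n_randomizations = length(runs),
      seeds = vapply(runs, function(r) r$seed, integer(1))
    ),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "Classifier report: overall accuracy %.1f%% +/- %.1f%% (%d randomizations)\n",
    x$overall_accuracy_mean,
    if (is.na(x$overall_accuracy_sd)) 0 else x$overall_accuracy_sd,
    x$n_randomizations
  ))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Tidy the averaged confusion matrix of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A long tibble with `truth`, `pred` and the row-normalised `rate`.
#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) {
  m <- as.data.frame.table(x$confusion, responseName = "rate")
  tibble::tibble(truth = m[[1]], pred = m[[2]], rate = m$rate)
}

#' One-row summary of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with the overall accuracy mean/sd (percent), the mean
#'   per-class AUC and the number of randomizations.
#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(
    accuracy_mean = x$overall_accuracy_mean,
    accuracy_sd = x$overall_accuracy_sd,
    mean_auc = mean(x$per_class$auc),
    n_randomizations = x$n_randomizations
  )
}

#' Plot a classifier report
#'
#' @param object A `classifier_report`.
#' @param type `"confusion"` (heatmap of the averaged row-normalised
#'   confusion matrix) or `"roc"` (per-class ROC curves of the first
#'   randomization with optimal points marked).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, type = c("confusion", "roc"),
                                       ...) {
  type <- match.arg(type)
  if (type == "confusion") {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                     fill = .data$rate)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)),
                         size = 3) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                   limits = c(0, 1)) +
      ggplot2::scale_y_discrete(limits = rev) +
      ggplot2::labs(x = "predicted", y = "true",
                    title = sprintf("Overall accuracy %.1f%% +/- %.1f%%",
                                    object$overall_accuracy_mean,
                                    object$overall_accuracy_sd)) +
      ggplot2::theme_minimal()
  } else {
    roc1 <- object$roc_curves[[1]]
    curves <- tidyr::unnest(roc1[, c("class", "roc")], "roc")
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                         colour = .data$class)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(
        data = roc1,
        ggplot2::aes(x = .data$optimal_fpr, y = .data$optimal_tpr,
                     colour = .data$class),
        shape = 19, size = 2, colour = "red", show.legend = FALSE
      ) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate") +
      ggplot2::theme_minimal()
  }
}
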