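# six well-separated Gaussian clusters in 3-D feature space
separable_table <- function(n_per_class = 30L, sep = 50, sd = 1, seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(seq_along(region_labels()), function(k) {
    tibble::tibble(
      region = factor(region_labels()[k], levels = region_labels()),
      f1 = rnorm(n_per_class, sep * k, sd),
      f2 = rnorm(n_per_class, sep * (k %% 3), sd),
      f3 = rnorm(n_per_class, -sep * k, sd)
    )
  })
}

test_that("training pixels are sampled per class, deterministically per seed", {
  ph <- generate_phantom(small_phantom_config(seed = 2))
  t30 <- sample_training_pixels(ph$volume, ph$labels, per_class = 30,
                                seed = 1, window = c(6L, 6L, 6L))
  expect_equal(nrow(t30), 180)
  expect_equal(unname(table(t30$region)), rep(30L, 6), ignore_attr = TRUE)
  expect_true(all(is.finite(t30$r_squared)))

  t1 <- sample_training_pixels(ph$volume, ph$labels, per_class = 1,
                               seed = 1, window = c(6L, 6L, 6L))
  expect_equal(nrow(t1), 6)

  # same seed reproduces the draw; a new seed moves the pixels but not the
  # class counts
  t30b <- sample_training_pixels(ph$volume, ph$labels, per_class = 30,
                                 seed = 1, window = c(6L, 6L, 6L))
  expect_identical(t30$depth, t30b$depth)
  t30c <- sample_training_pixels(ph$volume, ph$labels, per_class = 30,
                                 seed = 2, window = c(6L, 6L, 6L))
  expect_false(identical(t30$depth, t30c$depth))
  expect_equal(table(t30c$region), table(t30$region))
})

test_that("sampling errors name the starved region", {
  ph <- generate_phantom(small_phantom_config(seed = 2))
  expect_error(
    sample_training_pixels(ph$volume, ph$labels, per_class = 1e6, seed = 1),
    "air"
  )
})

test_that("sampling from a feature map uses only valid map voxels", {
  ph <- generate_phantom(small_phantom_config(seed = 6))
  fm <- feature_map(ph$volume, window = c(6L, 6L, 6L), stride = c(8L, 8L, 3L))
  tb <- sample_training_pixels(fm, ph$labels, per_class = 2, seed = 3,
                               window = c(6L, 6L, 6L))
  expect_equal(nrow(tb), 12)
  expect_true(all(is.finite(tb$r_squared)))
  for (i in seq_len(nrow(tb))) {
    expect_true(fm$valid[tb$depth[i] + 1, tb$fast[i] + 1, tb$slow[i] + 1])
  }
})

test_that("perfectly separated clusters are classified perfectly", {
  tbl <- separable_table()
  cv <- train_svm_cv(tbl, folds = 5, seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_equal(as.character(cv$predictions$pred),
               as.character(cv$predictions$truth))
})

test_that("permuted labels score at chance", {
  tbl <- separable_table()
  accs <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    perm <- tbl
    perm$region <- sample(perm$region)
    train_svm_cv(perm, folds = 5, seed = seed)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 6), 0.08)
})

test_that("standardisation parameters come from training folds only", {
  tbl <- separable_table()
  cv1 <- train_svm_cv(tbl, folds = 5, seed = 9)
  # corrupt rows of fold 1 (its validation rows): training-fold scaling of
  # fold 1 must not change
  val_rows <- cv1$predictions$row[cv1$predictions$fold == 1]
  tbl2 <- tbl
  tbl2[val_rows, c("f1", "f2", "f3")] <-
    tbl2[val_rows, c("f1", "f2", "f3")] + 1e4
  cv2 <- train_svm_cv(tbl2, folds = 5, seed = 9)
  expect_equal(cv2$scaling[[1]], cv1$scaling[[1]], tolerance = 1e-12)
})

test_that("stratification failures are explicit", {
  tbl <- separable_table(n_per_class = 3L)
  expect_error(train_svm_cv(tbl, folds = 5, seed = 1), "stratify")
})

test_that("ROC analysis matches trivial and hand-enumerated cases", {
  # scores identical to the labels: perfect separation
  lab <- factor(c(rep("air", 5), rep("noise", 5)))
  sc <- tibble::tibble(air = as.numeric(lab == "air"),
                       noise = as.numeric(lab == "noise"))
  roc <- roc_analysis(sc, lab)
  expect_equal(roc$auc, c(1, 1))
  expect_equal(roc$optimal_fpr, c(0, 0))
  expect_equal(roc$optimal_tpr, c(1, 1))

  # hand enumeration: scores (.9,.8,.3,.1) vs labels (1,1,0,0)
  roc2 <- roc_analysis(tibble::tibble(pos = c(0.9, 0.8, 0.3, 0.1)),
                       factor(c("pos", "pos", "neg", "neg")))
  pts <- roc2$roc[[1]]
  expect_equal(pts$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(pts$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(roc2$auc, 1)

  expect_error(roc_analysis(tibble::tibble(a = 1:3),
                            factor(c("a", "a", "a"))),
               "single class")
})

test_that("label-independent scores give AUC near one half", {
  set.seed(31)
  lab <- factor(sample(c("a", "b"), 300, replace = TRUE))
  sc <- tibble::tibble(a = rnorm(300), b = rnorm(300))
  roc <- roc_analysis(sc, lab)
  expect_equal(roc$auc, c(0.5, 0.5), tolerance = 0.12)
})

test_that("trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(120)
  labels <- factor(ifelse(scores + rnorm(120) > 0, "hit", "miss"))
  ours <- roc_analysis(tibble::tibble(hit = scores), labels)
  ref <- pROC::roc(response = labels == "hit", predictor = scores,
                   quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("reports satisfy their accounting identities", {
  tbl <- separable_table()
  cv <- train_svm_cv(tbl, folds = 5, seed = 1)
  rep1 <- build_report(list(cv))
  # a single randomization has zero spread
  expect_equal(rep1$overall_accuracy_sd, 0)
  # all-correct predictor: identity confusion
  expect_equal(unname(as.matrix(rep1$confusion)), diag(6), ignore_attr = TRUE)

  cvs <- lapply(1:3, function(s) train_svm_cv(tbl, folds = 5, seed = s))
  rep3 <- build_report(cvs)
  expect_equal(unname(rowSums(rep3$confusion)), rep(1, 6), tolerance = 1e-9)
  # overall accuracy is the mean diagonal of the averaged confusion
  expect_equal(rep3$overall_accuracy_mean,
               100 * mean(diag(rep3$confusion)), tolerance = 1e-9)
  expect_equal(rep3$n_randomizations, 3)
  expect_s3_class(autoplot(rep3), "ggplot")
  expect_s3_class(autoplot(rep3, type = "roc"), "ggplot")
  gl <- glance(rep3)
  expect_true(all(gl$mean_auc >= 0 & gl$mean_auc <= 1))
})
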