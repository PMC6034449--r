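# synthetic feature clusters: well-separated crop/weed shape statistics
make_cluster_regions <- function(n_images = 20L, per_image = 6L, seed = 1L,
                                 sep = 6, mixed_per_image = 0L) {
  withr_seed <- function(code) vegmorph:::with_seed(seed, code)
  withr_seed({
    rows <- list()
    for (img in seq_len(n_images)) {
      lab <- rep(c("crop", "weed"), length.out = per_image)
      lab <- c(lab, rep("mixed", mixed_per_image))
      mu <- ifelse(lab == "weed", sep * 0.1, 0)
      mu[lab == "mixed"] <- sep * 0.05
      f <- sapply(1:5, function(j) rnorm(length(lab), mu, 0.1))
      colnames(f) <- c("solidity", "eccentricity", "circularity",
                       "non_compactness", "grey_range")
      rows[[img]] <- cbind(data.frame(image = img, label = lab),
                           as.data.frame(f))
    }
    do.call(rbind, rows)
  })
}

test_that("image folds partition without leakage and deterministically", {
  ids <- rep(1:20, each = 3)
  folds <- split_by_image(ids, 10, seed = 5)
  expect_length(folds, 10L)
  expect_setequal(unlist(folds), 1:20)
  expect_true(all(lengths(folds) == 2L))
  expect_identical(folds, split_by_image(ids, 10, seed = 5))
  expect_false(identical(folds, split_by_image(ids, 10, seed = 6)))
  expect_error(split_by_image(1:5, 10), "fewer images")
})

test_that("training preparation duplicates mixed and balances classes", {
  df <- data.frame(label = c(rep("crop", 10), rep("weed", 4)), x = 1:14)
  out <- prepare_training(df, seed = 1)
  expect_equal(sum(out$label == "crop"), 10L)
  expect_equal(sum(out$label == "weed"), 10L)

  df2 <- data.frame(label = c(rep("crop", 5), rep("weed", 5),
                              rep("mixed", 3)), x = 1:13)
  out2 <- prepare_training(df2, seed = 1)
  expect_equal(sum(out2$label == "crop"), 8L)  # 5 + 3 mixed copies
  expect_equal(sum(out2$label == "weed"), 8L)
  expect_false(any(out2$label == "mixed"))

  expect_error(prepare_training(data.frame(label = rep("crop", 4))),
               "empty")
})

test_that("grid search finds a separating model on separable clusters", {
  reg <- make_cluster_regions(seed = 3)
  samples <- prepare_training(reg, seed = 2)
  model <- grid_search_train(samples, classifier_config(), seed = 2)
  expect_s3_class(model, "vm_svm")
  expect_equal(model$val_f1, 1)
  # deterministic given the seed
  model2 <- grid_search_train(samples, classifier_config(), seed = 2)
  expect_identical(model$grid_row, model2$grid_row)
  expect_identical(model$platt, model2$platt)
})

test_that("label-permuted features score near chance", {
  reg <- make_cluster_regions(n_images = 10L, per_image = 6L, seed = 4)
  f1s <- vapply(1:20, function(r) {
    perm <- reg
    perm$label <- vegmorph:::with_seed(100 + r, sample(perm$label))
    samples <- prepare_training(perm, seed = r)
    grid_search_train(samples, classifier_config(), seed = r)$val_f1
  }, 0)
  expect_lt(abs(mean(f1s) - 0.5), 0.15)
})

test_that("rejection respects the confidence threshold", {
  reg <- make_cluster_regions(seed = 6)
  samples <- prepare_training(reg, seed = 1)
  model <- grid_search_train(samples, classifier_config(), seed = 1)
  x <- as.matrix(reg[, vegmorph:::feature_names])

  pr <- predict_with_rejection(model, x, confidence = 0.5)
  expect_false(any(pr$decision == "rejected"))  # max prob is always >= 0.5
  expect_equal(pr$p_crop + pr$p_weed, rep(1, nrow(pr)))

  # monotonicity: raising c never classifies more samples
  classified <- vapply(seq(0.5, 0.99, by = 0.07), function(cc) {
    sum(predict_with_rejection(model, x, cc)$decision != "rejected")
  }, 0)
  expect_true(all(diff(classified) <= 0))

  # a manufactured borderline probability is rejected at c = 0.6
  mid <- model
  mid$platt <- c(stats::qlogis(0.55), 0)  # constant p_crop = 0.55
  pr_mid <- predict_with_rejection(mid, x[1:3, ], confidence = 0.6)
  expect_true(all(pr_mid$decision == "rejected"))
  pr_lo <- predict_with_rejection(mid, x[1:3, ], confidence = 0.5)
  expect_true(all(pr_lo$decision == "crop"))
})

test_that("cross-validation recovers separable classes and handles mixed", {
  reg <- make_cluster_regions(n_images = 20L, seed = 8, mixed_per_image = 1L)
  cv <- cross_validate(reg, classifier_config(folds = 10, seed = 3))
  expect_length(cv$folds, 10L)
  expect_gte(cv$pooled$crop$f1, 0.95)
  expect_gte(cv$pooled$weed$f1, 0.95)
  expect_equal(nrow(cv$predictions), nrow(reg))

  # mixed handling is additive: crop/weed rows score identically without it
  reg_pure <- reg[reg$label != "mixed", ]
  cv_pure <- cross_validate(reg_pure, classifier_config(folds = 10, seed = 3))
  p1 <- cv$predictions[cv$predictions$label != "mixed", ]
  p1 <- p1[order(p1$image, p1$p_crop), ]
  p2 <- cv_pure$predictions[order(cv_pure$predictions$image,
                                  cv_pure$predictions$p_crop), ]
  expect_equal(nrow(p1), nrow(p2))

  # determinism
  cv2 <- cross_validate(reg, classifier_config(folds = 10, seed = 3))
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("confidence sweep yields a valid interpolated PR curve", {
  reg <- make_cluster_regions(n_images = 12L, seed = 9, sep = 2)
  cv <- cross_validate(reg, classifier_config(folds = 6, seed = 2))
  pr <- pr_over_confidence(cv, confidences = seq(0.5, 0.9, by = 0.1))
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  o <- order(pr$recall)
  expect_true(all(diff(pr$precision[o]) <= 1e-12))
})
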