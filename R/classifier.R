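#' Classifier configuration
#'
#' Kernel grid and protocol parameters for the crop/weed maximum-margin
#' classifier: a linear kernel with cost `C` in \{1, 10, 100, 1000\}, a
#' radial-basis kernel over the same costs crossed with
#' `gamma` in \{0.001, 0.0001\}, and polynomial kernels of degree 2-4
#' (at cost 1). Model selection uses a stratified 70/30 train/validation
#' split inside each training fold; evaluation uses image-level k = 10
#' cross-validation so that no region of a test image is ever seen in
#' training.
#'
#' @param confidence rejection confidence `c` in `[0.5, 1]`: a region is
#'   left unclassified when the winning class probability falls below it.
#' @param train_fraction fraction of training samples used for fitting
#'   (the remainder scores the grid).
#' @param folds number of image-level cross-validation folds.
#' @param seed RNG seed for folds, splits and oversampling.
#' @param grid data.frame of kernel configurations (columns `kernel`,
#'   `cost`, `gamma`, `degree`); defaults to the grid above.
#' @param strict_mixed if `TRUE`, mixed regions in the test fold are
#'   scored strictly (always counted as errors) instead of being accepted
#'   under either decision.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(confidence = 0.5, train_fraction = 0.7,
                              folds = 10L, seed = 1L, grid = svm_grid(),
                              strict_mixed = FALSE) {
  stopifnot(confidence >= 0.5, confidence <= 1,
            train_fraction > 0, train_fraction < 1, folds >= 2)
  structure(
    list(confidence = confidence, train_fraction = train_fraction,
         folds = as.integer(folds), seed = as.integer(seed), grid = grid,
         strict_mixed = isTRUE(strict_mixed)),
    class = "classifier_config"
  )
}

#' The kernel/parameter grid
#'
#' @return data.frame with one row per grid point.
#' @export
svm_grid <- function() {
  rbind(
    data.frame(kernel = "linear", cost = c(1, 10, 100, 1000),
               gamma = NA_real_, degree = NA_integer_),
    expand.grid(kernel = "radial", cost = c(1, 10, 100, 1000),
                gamma = c(0.001, 0.0001), degree = NA_integer_,
                stringsAsFactors = FALSE),
    data.frame(kernel = "polynomial", cost = 1, gamma = NA_real_,
               degree = 2:4)
  )
}

#' Partition images into cross-validation folds
#'
#' All regions of an image fall into the same fold, so testing is free of
#' image-level leakage. Fold sizes differ by at most one.
#'
#' @param image_ids vector of image identifiers (one per region, or the
#'   unique set).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` vectors of image ids.
#' @export
split_by_image <- function(image_ids, k, seed = 1L) {
  imgs <- unique(image_ids)
  if (length(imgs) < k) stop("fewer images than folds")
  shuffled <- with_seed(seed, sample(imgs))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Prepare balanced training samples
#'
#' Every mixed region contributes one crop-labelled and one weed-labelled
#' copy (the region genuinely contains both), then the minority class is
#' oversampled with replacement to the majority class size so that the
#' classifier sees exactly balanced classes.
#'
#' @param regions data.frame with a `label` column in
#'   \{crop, weed, mixed\} plus feature columns.
#' @param seed RNG seed for the oversampling draw.
#' @return data.frame with `label` in \{crop, weed\} and equal class
#'   counts.
#' @export
prepare_training <- function(regions, seed = 1L) {
  stopifnot(all(regions$label %in% c("crop", "weed", "mixed")))
  mixed <- regions[regions$label == "mixed", , drop = FALSE]
  out <- regions[regions$label != "mixed", , drop = FALSE]
  if (nrow(mixed) > 0) {
    as_crop <- mixed; as_crop$label <- "crop"
    as_weed <- mixed; as_weed$label <- "weed"
    out <- rbind(out, as_crop, as_weed)
  }
  n_crop <- sum(out$label == "crop")
  n_weed <- sum(out$label == "weed")
  if (n_crop == 0 || n_weed == 0)
    stop("a class is empty after mixed-class duplication")
  if (n_crop != n_weed) {
    minor <- if (n_crop < n_weed) "crop" else "weed"
    need <- abs(n_crop - n_weed)
    pool <- which(out$label == minor)
    extra <- with_seed(seed, sample(pool, need, replace = TRUE))
    out <- rbind(out, out[extra, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Grid-search an SVM on a balanced training set
#'
#' Splits the samples into a stratified 70/30 train/validation split,
#' fits every kernel/parameter combination of the grid on the 70% and
#' scores it by crop-class F1 on the 30%; the best-scoring fitted model
#' is returned. Probability outputs come from a Platt sigmoid fitted on
#' the training decision values, so `p_crop = 1 - p_weed` always holds
#' and the whole procedure is deterministic given the seed.
#'
#' @param samples balanced data.frame from [prepare_training()] with the
#'   five (normalized) feature columns and a `label` column.
#' @param config a [classifier_config()].
#' @param seed RNG seed for the stratified split.
#' @return object of class `vm_svm`: list with the fitted `e1071::svm`
#'   model, Platt coefficients, the chosen grid row and its validation F1.
#' @export
grid_search_train <- function(samples, config = classifier_config(),
                              seed = config$seed) {
  grid <- config$grid
  if (nrow(grid) == 0L) stop("empty parameter grid")
  x <- as.matrix(samples[, feature_names])
  y <- factor(samples$label, levels = c("crop", "weed"))

  idx_tr <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      n_tr <- max(1L, round(config$train_fraction * length(ix)))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  idx_va <- setdiff(seq_along(y), idx_tr)
  if (length(idx_va) == 0L) stop("validation split is empty")

  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- fit_svm(x[idx_tr, , drop = FALSE], y[idx_tr], grid[i, ])
    pred <- predict(fit, x[idx_va, , drop = FALSE])
    f1 <- class_f1(pred, y[idx_va], positive = "crop")
    if (is.null(best) || f1 > best$val_f1) {
      best <- list(svm = fit, grid_row = grid[i, ], val_f1 = f1)
    }
  }
  platt <- fit_platt(best$svm, x[idx_tr, , drop = FALSE], y[idx_tr])
  structure(
    list(svm = best$svm, platt = platt, grid_row = best$grid_row,
         val_f1 = best$val_f1, levels = c("crop", "weed")),
    class = "vm_svm"
  )
}

fit_svm <- function(x, y, row) {
  args <- list(x = x, y = y, kernel = row$kernel, cost = row$cost,
               scale = FALSE)
  if (!is.na(row$gamma)) args$gamma <- row$gamma
  if (!is.na(row$degree)) args$degree <- row$degree
  do.call(e1071::svm, args)
}

# Platt scaling: logistic fit of P(crop) on the training decision values.
# Perfectly separated training data makes glm non-converged; the fitted
# monotone sigmoid is still a valid calibration, so warnings are muted.
fit_platt <- function(fit, x, y) {
  d <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                       "decision.values"))
  z <- as.integer(y == "crop")
  co <- suppressWarnings(stats::coef(glm(z ~ d, family = binomial())))
  if (anyNA(co)) co <- c(0, 0)  # constant decision values: p = 0.5
  co
}

class_f1 <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  res <- eval_result(tp, fp, fn)
  res$f1
}

#' Predict with confidence rejection
#'
#' Classifies each region as the more probable class, unless the winning
#' probability falls below the rejection confidence `c`, in which case
#' the region is rejected (left to downstream pixel-level treatment).
#' With `c = 0.5` nothing is ever rejected.
#'
#' @param model a `vm_svm` from [grid_search_train()].
#' @param x feature matrix (normalized like the training data).
#' @param confidence rejection threshold in `[0.5, 1]`.
#' @return data.frame with `p_crop`, `p_weed` and `decision` in
#'   \{crop, weed, rejected\}.
#' @export
predict_with_rejection <- function(model, x, confidence = 0.5) {
  stopifnot(inherits(model, "vm_svm"))
  d <- as.numeric(attr(predict(model$svm, x, decision.values = TRUE),
                       "decision.values"))
  p_crop <- plogis(model$platt[1] + model$platt[2] * d)
  decision <- ifelse(p_crop >= 0.5, "crop", "weed")
  decision[pmax(p_crop, 1 - p_crop) < confidence] <- "rejected"
  data.frame(p_crop = p_crop, p_weed = 1 - p_crop, decision = decision)
}

#' Persist a fitted classifier to a single file
#'
#' @param model a `vm_svm` from [grid_search_train()].
#' @param path output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vm_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a persisted classifier
#'
#' @param path file written by [save_model()].
#' @return the `vm_svm` model.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vm_svm")) stop("not a saved vegmorph classifier")
  model
}

#' Image-level cross-validation of the crop/weed classifier
#'
#' For each of the `k` folds: regions of the other `k - 1` folds form the
#' training set; feature normalization statistics are estimated on it,
#' mixed regions are duplicated and classes balanced
#' ([prepare_training()]), the kernel grid is searched
#' ([grid_search_train()]), and the held-out fold is scored with
#' rejection at the configured confidence. Mixed ground truth counts as
#' correct under either decision (unless `strict_mixed`). Pooled
#' confusion counts are reported with crop as the positive class, plus
#' the weed-positive counterpart.
#'
#' @param regions data.frame with columns `image`, `label` and the five
#'   feature columns (raw, un-normalized).
#' @param config a [classifier_config()].
#' @return list of class `vm_cv`: per-fold results, pooled `eval_result`s
#'   for crop and weed, and the full prediction table.
#' @export
cross_validate <- function(regions, config = classifier_config()) {
  folds <- split_by_image(regions$image, config$folds, config$seed)
  fold_res <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_sel <- regions$image %in% folds[[f]]
    train <- regions[!test_sel, , drop = FALSE]
    test <- regions[test_sel, , drop = FALSE]
    norm <- normalize_features(as.matrix(train[, feature_names]))
    train_n <- train
    train_n[, feature_names] <- norm$matrix
    balanced <- prepare_training(train_n, seed = config$seed + f)
    model <- grid_search_train(balanced, config, seed = config$seed + f)
    x_te <- normalize_features(as.matrix(test[, feature_names]),
                               norm$stats)$matrix
    pr <- predict_with_rejection(model, x_te, config$confidence)
    pr$label <- test$label
    pr$image <- test$image
    pr$fold <- f
    preds[[f]] <- pr
    fold_res[[f]] <- list(
      model_kernel = model$grid_row$kernel, val_f1 = model$val_f1,
      crop = score_predictions(pr, "crop", config$strict_mixed),
      weed = score_predictions(pr, "weed", config$strict_mixed)
    )
  }
  all_pred <- do.call(rbind, preds)
  structure(
    list(
      folds = fold_res,
      pooled = list(
        crop = score_predictions(all_pred, "crop", config$strict_mixed),
        weed = score_predictions(all_pred, "weed", config$strict_mixed)
      ),
      predictions = all_pred,
      config = config
    ),
    class = "vm_cv"
  )
}

# Confusion counts with `positive` as the positive class. Mixed truth is
# correct under either decision: it counts as a true positive when the
# decision is the positive class and is otherwise ignored (it is a true
# negative of this binary view, never an error) unless strict scoring is
# requested, in which case mixed is an error for both decisions.
score_predictions <- function(pr, positive, strict_mixed = FALSE) {
  negative <- setdiff(c("crop", "weed"), positive)
  dec <- pr$decision
  truth <- pr$label
  if (strict_mixed) {
    tp <- sum(dec == positive & truth == positive)
    fp <- sum(dec == positive & truth != positive)
    fn <- sum(dec != positive & truth == positive)
  } else {
    tp <- sum(dec == positive & truth %in% c(positive, "mixed"))
    fp <- sum(dec == positive & truth == negative)
    fn <- sum(dec != positive & truth == positive)
  }
  eval_result(tp, fp, fn)
}

#' @export
print.vm_cv <- function(x, ...) {
  cat(sprintf("image-level %d-fold cross-validation, %d regions\n",
              length(x$folds), nrow(x$predictions)))
  cat("pooled crop: "); print(x$pooled$crop)
  cat("pooled weed: "); print(x$pooled$weed)
  invisible(x)
}

#' Precision-recall curve over the rejection confidence
#'
#' Re-scores an existing prediction table while sweeping the rejection
#' confidence `c`; raising `c` converts low-confidence decisions into
#' rejections, trading recall for precision.
#'
#' @param cv a `vm_cv` from [cross_validate()].
#' @param confidences vector of rejection thresholds to sweep.
#' @param positive positive class.
#' @return data.frame `(confidence, recall, precision)` with interpolated
#'   precision.
#' @export
pr_over_confidence <- function(cv, confidences = seq(0.5, 0.95, by = 0.05),
                               positive = "crop") {
  pr <- cv$predictions
  rows <- lapply(confidences, function(cc) {
    dec <- ifelse(pr$p_crop >= 0.5, "crop", "weed")
    dec[pmax(pr$p_crop, 1 - pr$p_crop) < cc] <- "rejected"
    res <- score_predictions(
      data.frame(decision = dec, label = pr$label), positive,
      cv$config$strict_mixed
    )
    data.frame(confidence = cc, recall = res$recall,
               precision = res$precision)
  })
  raw <- do.call(rbind, rows)
  interp <- interpolated_pr(raw$recall, raw$precision)
  merge(raw[, c("confidence", "recall")], interp, by = "recall")[
    , c("confidence", "recall", "precision")
  ]
}
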