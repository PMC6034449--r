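#' Pipeline configuration
#'
#' Single configuration object covering segmentation, baseline and
#' classifier parameters; round-trips losslessly through YAML and rejects
#' unknown keys, so a run is fully described by one file plus a seed.
#'
#' @param ... overrides for any of the default fields (see
#'   [seg_params()], [rats_params()], [classifier_config()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    delta = 30, g_min = 10, k_factor = 15, e_area = 0.15, l_similar = 6,
    t_area = 0, min_extinction = 10, connectivity = 4L,
    lambda = 3, eta = 0,
    confidence = 0.5, train_fraction = 0.7, folds = 10L, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the [pipeline_config()] keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

config_seg_params <- function(config) {
  seg_params(delta = config$delta, g_min = config$g_min,
             k_factor = config$k_factor, e_area = config$e_area,
             l_similar = config$l_similar, t_area = config$t_area,
             min_extinction = config$min_extinction)
}

log_lines <- function(lines, log_file = NULL) {
  for (l in lines) message(l)
  if (!is.null(log_file)) cat(lines, file = log_file, sep = "\n", append = TRUE)
  invisible(NULL)
}

config_log <- function(config) {
  c(sprintf("vegmorph %s", as.character(packageVersion("vegmorph"))),
    sprintf("config: %s",
            paste(sprintf("%s=%s", names(config),
                          vapply(config, format, "")), collapse = " ")))
}

#' Segment one or more NDVI images (pipeline entry point)
#'
#' Runs max-tree segmentation (or a global-threshold baseline) on each
#' input image, writes the segmentation mask, label image and region CSV
#' next to each input's base name under `out_dir`, and, when a matching
#' ground-truth mask is supplied, reports pixel precision/recall/F1.
#'
#' @param inputs character vector of image paths, or a list of integer
#'   matrices (named, for output naming).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param method `"maxtree"` (default), `"otsu"` or `"rats"`.
#' @param truths optional vector of ground-truth mask paths (or list of
#'   logical matrices) matching `inputs`.
#' @return invisibly, a data.frame of per-image results.
#' @export
run_segment <- function(inputs, out_dir, config = pipeline_config(),
                        method = c("maxtree", "otsu", "rats"),
                        truths = NULL) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  log_lines(c(config_log(config), sprintf("method: %s", method)), log_file)
  rows <- list()
  for (i in seq_along(inputs)) {
    if (is.character(inputs)) {
      img <- read_image(inputs[[i]])
      name <- tools::file_path_sans_ext(basename(inputs[[i]]))
    } else {
      img <- inputs[[i]]
      name <- if (!is.null(names(inputs))) names(inputs)[i] else sprintf("image%03d", i)
    }
    if (inherits(img, "rgbn_image"))
      img <- quantize_ndvi(compute_ndvi(img$nir, img$red))
    if (method == "maxtree") {
      seg <- segment_vegetation(img, config_seg_params(config),
                                config$connectivity)
      mask <- segmentation_mask(seg)
      write_labels(label_image(seg), file.path(out_dir, paste0(name, "_labels.tif")))
      write_regions(seg, file.path(out_dir, paste0(name, "_regions.csv")))
      n_regions <- nrow(seg$regions)
    } else {
      t <- if (method == "otsu") otsu_threshold(img)
           else rats_threshold(img, rats_params(config$lambda, config$eta))
      mask <- apply_threshold(img, t)
      log_lines(sprintf("%s: %s threshold %.2f", name, method, t), log_file)
      n_regions <- NA_integer_
    }
    write_mask(mask, file.path(out_dir, paste0(name, "_mask.png")))
    row <- data.frame(image = name, regions = n_regions,
                      foreground = sum(mask))
    if (!is.null(truths)) {
      truth <- if (is.character(truths)) read_mask(truths[[i]]) else truths[[i]]
      m <- pixel_metrics(mask, truth)
      row$precision <- m$precision; row$recall <- m$recall; row$f1 <- m$f1
      log_lines(sprintf("%s: F1 = %.4f (precision %.4f, recall %.4f)",
                        name, m$f1, m$precision, m$recall), log_file)
    } else {
      log_lines(sprintf("%s: %d foreground px, %s regions", name,
                        sum(mask), format(n_regions)), log_file)
    }
    rows[[i]] <- row
  }
  invisible(do.call(rbind, rows))
}

#' Label segmented regions against ground truth
#'
#' Matches every accepted region of a segmentation to the ground-truth
#' label map of a synthetic field sample and attaches the five region
#' features, producing one row per region for classifier training and
#' evaluation. A region takes the class of the ground-truth region it
#' overlaps most; regions overlapping less than `min_overlap` of their
#' pixels with any vegetation (spurious detections) are dropped.
#'
#' @param sample a `field_sample` from [generate_field()].
#' @param seg an `mt_segmentation` of the sample's image.
#' @param image_id identifier stored in the `image` column.
#' @param min_overlap minimal fraction of region pixels on vegetation.
#' @return data.frame with `image`, `label` and the five feature columns.
#' @export
extract_labelled_regions <- function(sample, seg, image_id = 1L,
                                     min_overlap = 0.5) {
  stopifnot(inherits(sample, "field_sample"), inherits(seg, "mt_segmentation"))
  reg <- seg$regions
  if (nrow(reg) == 0L) {
    return(cbind(data.frame(image = character(0), label = character(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0, 5)),
                                 feature_names)))
  }
  feats <- region_features(seg$tree, reg$node)
  labels <- character(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    m <- nodes_mask(seg$tree, reg$node[i])
    hit <- sample$labels[m]
    frac <- mean(hit > 0)
    if (is.na(frac) || frac < min_overlap) {
      labels[i] <- NA_character_
    } else {
      best <- as.integer(names(which.max(table(hit[hit > 0]))))
      labels[i] <- sample$table$class[sample$table$region == best]
    }
  }
  keep <- !is.na(labels)
  out <- cbind(data.frame(image = image_id, label = labels[keep]),
               feats[keep, feature_names, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Cross-validate the classifier on a labelled region table
#'
#' @param regions data.frame (or CSV path) with columns `image`, `label`
#'   and the five feature columns.
#' @param out_dir output directory for metrics and prediction CSVs.
#' @param config a [pipeline_config()].
#' @return invisibly, the `vm_cv` result.
#' @export
run_classify <- function(regions, out_dir, config = pipeline_config()) {
  if (is.character(regions)) regions <- read.csv(regions)
  if (is.null(regions$label)) stop("regions table has no 'label' column")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  log_lines(config_log(config), log_file)
  cc <- classifier_config(confidence = config$confidence,
                          train_fraction = config$train_fraction,
                          folds = config$folds, seed = config$seed)
  cv <- cross_validate(regions, cc)
  per_fold <- do.call(rbind, lapply(seq_along(cv$folds), function(f) {
    fr <- cv$folds[[f]]
    data.frame(fold = f, kernel = fr$model_kernel, val_f1 = fr$val_f1,
               crop_f1 = fr$crop$f1, weed_f1 = fr$weed$f1)
  }))
  write.csv(per_fold, file.path(out_dir, "fold_metrics.csv"), row.names = FALSE)
  write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(pr_over_confidence(cv), file.path(out_dir, "pr_confidence.csv"),
            row.names = FALSE)
  log_lines(sprintf("pooled crop F1 = %.4f, weed F1 = %.4f",
                    cv$pooled$crop$f1, cv$pooled$weed$f1), log_file)
  invisible(cv)
}

#' Generate synthetic field bundles
#'
#' @param spec a [field_spec()], or a YAML file of spec fields.
#' @param out_dir output directory; one bundle subdirectory per sample.
#' @param n number of samples (seeds `seed, seed+1, ...`).
#' @return invisibly, the bundle directories.
#' @export
run_synth <- function(spec, out_dir, n = 1L) {
  if (is.character(spec)) spec <- do.call(field_spec, yaml::read_yaml(spec))
  dirs <- character(n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    sample <- generate_field(sp)
    dirs[i] <- file.path(out_dir, sprintf("field_%03d", i))
    write_field_sample(sample, dirs[i])
  }
  invisible(dirs)
}

#' Evaluate a predicted mask against ground truth
#'
#' @param predicted mask path or logical matrix.
#' @param truth mask path or logical matrix.
#' @return the `eval_result`, printed.
#' @export
run_eval <- function(predicted, truth) {
  if (is.character(predicted)) predicted <- read_mask(predicted)
  if (is.character(truth)) truth <- read_mask(truth)
  res <- pixel_metrics(predicted, truth)
  print(res)
  invisible(res)
}
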