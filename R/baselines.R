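#' Otsu's global threshold
#'
#' Examines every threshold and proposes the one with the greatest
#' inter-class variance between the background (values `<= t`) and
#' foreground (values `> t`) classes, computed from the image histogram.
#' Ties resolve to the lowest threshold.
#'
#' @param image integer matrix in `[0, 255]`.
#' @return threshold `t` (grey level); foreground is `image > t`.
#' @export
otsu_threshold <- function(image) {
  image <- as_grey_image(image)
  if (length(unique(as.vector(image))) < 2L)
    stop("Otsu threshold undefined for a constant image")
  h <- tabulate(as.vector(image) + 1L, nbins = 256L)
  p <- h / sum(h)
  v <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * v)
  mt <- m0[256]
  # between-class variance for t = 0..254 (split <= t vs > t); thresholds
  # inside a histogram gap give the identical split as the gap's lowest
  # occupied level, so only occupied levels are scored (this also makes
  # the tie-to-lowest rule robust to floating-point noise)
  w0t <- w0[1:255]
  m0t <- m0[1:255]
  valid <- w0t > 0 & w0t < 1 & h[1:255] > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mt * w0t[valid] - m0t[valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  top <- max(bcv)
  which(bcv >= top - abs(top) * 1e-12)[1] - 1L
}

#' RATS parameters
#'
#' @param lambda gradient-dependent sensitivity (default 3, for the Sobel
#'   operator).
#' @param eta background-noise control, `>= 0`; only pixels with gradient
#'   magnitude above `eta * lambda` contribute.
#' @return list of class `rats_params`.
#' @export
rats_params <- function(lambda = 3, eta = 0) {
  stopifnot(lambda > 0, eta >= 0)
  structure(list(lambda = lambda, eta = eta), class = "rats_params")
}

#' Robust Automatic Threshold Selection (RATS)
#'
#' The threshold is the average of image intensities weighted by the image
#' gradient: `T = sum(w f) / sum(w)` with `w = G` where the Sobel gradient
#' magnitude `G` exceeds the noise level `eta * lambda` and 0 elsewhere.
#' On low-content images (uniform, or `eta` too large) all weights vanish
#' and the threshold is not well-defined; this raises an error.
#'
#' @param image integer matrix in `[0, 255]`.
#' @param params a [rats_params()] object.
#' @return threshold (numeric grey level, not necessarily integer).
#' @export
rats_threshold <- function(image, params = rats_params()) {
  image <- as_grey_image(image)
  stopifnot(inherits(params, "rats_params"))
  g <- sobel_magnitude(image)
  w <- ifelse(g > params$eta * params$lambda, g, 0)
  sw <- sum(w)
  if (sw == 0) stop("RATS threshold not well-defined (no gradient content)")
  sum(w * image) / sw
}

# Sobel gradient magnitude with replicate borders.
sobel_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[h + 2L, ] <- pad[h + 1L, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2L] <- pad[, w + 1L]
  s <- function(dr, dc) pad[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Apply a global threshold
#'
#' @param image integer matrix.
#' @param t threshold; foreground where `image > t`.
#' @return logical mask.
#' @export
apply_threshold <- function(image, t) {
  image > t
}

#' Pixel-level precision, recall and F1
#'
#' Counts true positives, false positives and false negatives between a
#' predicted and a ground-truth mask and derives precision
#' `p = TP / (TP + FP)`, recall `TP / (TP + FN)` and the harmonic mean
#' `F1 = 2 p r / (p + r)`. An empty prediction has precision 0 by
#' convention so F1 remains defined.
#'
#' @param predicted logical mask.
#' @param truth logical mask of the same shape.
#' @return list of class `eval_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
pixel_metrics <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth))) stop("shape mismatch")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  eval_result(tp, fp, fn)
}

eval_result <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  precision=%.4f recall=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Interpolated precision-recall curve
#'
#' At each recall level `r`, the interpolated precision is the highest
#' precision achieved at any recall `>= r`, which removes the saw-tooth
#' shape of raw precision-recall curves. Duplicate recall levels collapse
#' to their best interpolated precision.
#'
#' @param recall numeric vector of recall values.
#' @param precision matching precision values.
#' @return data.frame `(recall, precision)` sorted by increasing recall
#'   with non-increasing precision.
#' @export
interpolated_pr <- function(recall, precision) {
  stopifnot(length(recall) == length(precision), length(recall) > 0)
  o <- order(recall)
  r <- recall[o]; p <- precision[o]
  ip <- rev(cummax(rev(p)))  # max precision over recall >= r
  keep <- !duplicated(r, fromLast = TRUE)
  data.frame(recall = r[keep], precision = ip[keep])
}
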