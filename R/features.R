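#' Five-feature region descriptors
#'
#' Computes, for each requested node, the five per-region descriptors used
#' for crop/weed discrimination, all derived from the incrementally
#' propagated node attributes so no pixel is revisited:
#'
#' * **solidity**: region area over convex-hull area, the hull taken over
#'   the four corners of every member pixel (a one-pixel region scores 1);
#' * **eccentricity**: of the equivalent ellipse with the same second-order
#'   central moments, `sqrt(1 - b^2/a^2)` from the eigenvalues of the
#'   moment matrix; 0 for a single pixel;
#' * **circularity**: moment-based, perimeter-free:
#'   `A^2 / (2 pi (mu20 + mu02 + A/6))`, equal to 1 for an ideal disk
#'   (the `A/6` term is the discrete per-pixel correction);
#' * **non_compactness**: Hu's first moment invariant with the same
#'   discrete correction, `2 pi ((mu20 + mu02)/A^2 + 1/(6 A))`; 1 for an
#'   ideal disk, larger for elongated shapes, and the exact reciprocal of
#'   circularity;
#' * **grey_range**: span of grey levels inside the region,
#'   `f_max - f_min`, the only grey-dependent feature.
#'
#' @param tree a [max_tree()] object.
#' @param nodes integer vector of node ids (default: all nodes).
#' @return data.frame with columns `node`, `solidity`, `eccentricity`,
#'   `circularity`, `non_compactness`, `grey_range`.
#' @export
region_features <- function(tree, nodes = seq_len(tree$n_nodes)) {
  stopifnot(inherits(tree, "maxtree"))
  nodes <- as.integer(nodes)
  if (any(is.na(nodes) | nodes < 1L | nodes > tree$n_nodes))
    stop("invalid node id")
  a <- tree$area[nodes]
  mu20 <- tree$sxx[nodes] - tree$sx[nodes]^2 / a
  mu02 <- tree$syy[nodes] - tree$sy[nodes]^2 / a
  mu11 <- tree$sxy[nodes] - tree$sx[nodes] * tree$sy[nodes] / a
  hull <- tree$hull_area[nodes]
  if (any(hull <= 0)) stop("degenerate convex hull")

  tr2 <- (mu20 + mu02) / a
  det_disc <- sqrt(pmax(((mu20 - mu02) / a)^2 + 4 * (mu11 / a)^2, 0))
  l1 <- (tr2 + det_disc) / 2
  l2 <- pmax((tr2 - det_disc) / 2, 0)
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / l1, 0)))

  i_r <- mu20 + mu02
  circ <- a^2 / (2 * pi * (i_r + a / 6))
  noncomp <- 2 * pi * (i_r / a^2 + 1 / (6 * a))

  data.frame(
    node = nodes,
    solidity = a / hull,
    eccentricity = ecc,
    circularity = circ,
    non_compactness = noncomp,
    grey_range = tree$fmax[nodes] - tree$fmin[nodes]
  )
}

feature_names <- c("solidity", "eccentricity", "circularity",
                   "non_compactness", "grey_range")

#' Assemble a feature matrix for a set of regions
#'
#' @param features data.frame from [region_features()] (or any data.frame
#'   containing the five feature columns).
#' @return numeric matrix with the five feature columns in canonical order.
#' @export
feature_matrix <- function(features) {
  if (nrow(features) == 0L) stop("no regions")
  as.matrix(features[, feature_names])
}

#' Min-max feature normalization
#'
#' Normalises every feature column to `[0, 1]` across the dataset. When
#' `stats` (from a training set) is supplied, its per-column minima and
#' maxima are applied and out-of-range values are clipped to `[0, 1]`, so
#' that no test-set information leaks into the normalization. A constant
#' column maps to 0.5.
#'
#' @param m numeric feature matrix.
#' @param stats optional list with `min` and `max` vectors from a previous
#'   call (training data).
#' @return list with `matrix` (normalized) and `stats`.
#' @export
normalize_features <- function(m, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(min = apply(m, 2, min), max = apply(m, 2, max))
  }
  rng <- stats$max - stats$min
  out <- sweep(m, 2, stats$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0.5
  out[out < 0] <- 0
  out[out > 1] <- 1
  list(matrix = out, stats = stats)
}

#' Export a feature matrix as CSV
#'
#' @param features data.frame of region features (optionally with labels).
#' @param path output file.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
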