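#' Segmentation parameters
#'
#' Parameters of the stability-based region selection. The defaults are the
#' empirically determined values reported for field imagery: minimal allowed
#' growth `g_min = 10`, size difference factor `k_factor = 15`, relative area
#' tolerance `e_area = 0.15`, minimal run of similar consecutive regions
#' `l_similar = 6`, and an extinction cutoff of 10 grey levels for marker
#' selection. The grey-level span `delta = 30` controls over how many levels
#' region growth is measured. `t_area = 0` disables the minimal-region-area
#' filter; set it to the smallest plant size (in pixels) worth keeping.
#'
#' @param delta grey-level span for the growth factor (>= 1).
#' @param g_min minimal allowed growth (dimensionless, >= 0).
#' @param k_factor size difference factor for candidate adjustment (>= 1).
#' @param e_area relative area tolerance in `[0, 1)`.
#' @param l_similar minimal number of similar consecutive regions (>= 1).
#' @param t_area minimal accepted region area in pixels (0 = disabled).
#' @param min_extinction extinction cutoff in grey levels for markers.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(delta = 30, g_min = 10, k_factor = 15, e_area = 0.15,
                       l_similar = 6, t_area = 0, min_extinction = 10) {
  stopifnot(delta >= 1, g_min >= 0, k_factor >= 1,
            e_area >= 0, e_area < 1, l_similar >= 1, t_area >= 0)
  structure(
    list(delta = delta, g_min = g_min, k_factor = k_factor, e_area = e_area,
         l_similar = l_similar, t_area = t_area,
         min_extinction = min_extinction),
    class = "seg_params"
  )
}

#' Threshold decomposition along one branch
#'
#' Walking a max-tree branch from a leaf to the root enumerates all the
#' regions obtained by thresholding the image around that regional maximum
#' with a decreasing threshold.
#'
#' @param tree a [max_tree()] object.
#' @param leaf a leaf node id.
#' @return data.frame of region candidates ordered leaf to root, columns
#'   `node`, `level` (strictly decreasing) and `area` (non-decreasing).
#' @export
branch_candidates <- function(tree, leaf) {
  stopifnot(inherits(tree, "maxtree"))
  leaf <- as.integer(leaf)
  if (length(leaf) != 1L || is.na(leaf) || leaf < 1L || leaf > tree$n_nodes)
    stop("invalid node id")
  if (!tree$is_leaf[leaf]) stop("node is not a leaf")
  chain <- integer(256L)
  n <- 0L
  cur <- leaf
  repeat {
    n <- n + 1L
    chain[n] <- cur
    nxt <- tree$parent[cur]
    if (nxt == cur) break
    cur <- nxt
  }
  chain <- chain[seq_len(n)]
  data.frame(node = chain, level = tree$level[chain], area = tree$area[chain])
}

#' Growth factors along a branch
#'
#' For the candidate at grey level `k`, the growth factor over a span of
#' `delta` grey levels is `G = (A(R') - A(R_k)) / A(R_k)`, where `R'` is the
#' component on the branch at threshold `k - delta`: the candidate with the
#' largest level `<= k - delta`, falling back to the root when the branch
#' ends. A spike in `G` signals the merging of a contrasted object into its
#' background.
#'
#' @param branch output of [branch_candidates()].
#' @param delta grey-level span.
#' @return numeric vector of growth factors, one per candidate.
#' @export
growth_factors <- function(branch, delta) {
  lv <- branch$level
  a <- branch$area
  n <- length(lv)
  # levels are strictly decreasing; for each k find first index with
  # level <= k - delta (the component just below the span), else the root
  tgt <- lv - delta
  # count of levels > tgt, via findInterval on the negated (increasing) levels
  j <- findInterval(-tgt, -lv, left.open = TRUE) + 1L
  j <- pmin(j, n)
  (a[j] - a) / a
}

#' Select the most stable fast-growing region on a branch
#'
#' Starts from the candidate `B` with the largest growth factor and applies
#' the four-step adjustment that favours slightly larger, repeated regions:
#' (1) examine candidates `R` with `g_min < G(R) < G(B)` in order of
#' descending growth; (2) take the first with area `A(R) > k_factor * A(B)`;
#' (3) count the consecutive following candidates whose area lies within
#' `(1 +/- e_area) * A(R)`; (4) if at least `l_similar` such regions exist,
#' set `B <- R` and restart from (1); otherwise stop.
#'
#' @param branch output of [branch_candidates()].
#' @param params a [seg_params()] object.
#' @param growth optional precomputed [growth_factors()].
#' @return one-row data.frame (`node`, `level`, `area`, `growth`), or `NULL`
#'   when no candidate exceeds `g_min`.
#' @export
select_region <- function(branch, params, growth = NULL) {
  stopifnot(inherits(params, "seg_params"))
  if (nrow(branch) == 0L) return(NULL)
  g <- if (is.null(growth)) growth_factors(branch, params$delta) else growth
  # argmax growth; ties prefer the higher-level (smaller, more contrasted)
  # candidate, i.e. the earliest in leaf-to-root order
  b <- which.max(g)
  if (g[b] <= params$g_min) return(NULL)
  repeat {
    cand <- which(g > params$g_min & g < g[b])
    if (length(cand) == 0L) break
    # descending growth, ties by descending level (= ascending index)
    cand <- cand[order(-g[cand], cand)]
    ok <- branch$area[cand] > params$k_factor * branch$area[b]
    pos <- which(ok)[1]
    if (is.na(pos)) break
    r <- cand[pos]
    a_r <- branch$area[r]
    run <- 0L
    for (q in cand[seq_len(length(cand) - pos) + pos]) {
      if (branch$area[q] >= (1 - params$e_area) * a_r &&
          branch$area[q] <= (1 + params$e_area) * a_r) {
        run <- run + 1L
        if (run >= params$l_similar) break
      } else {
        break
      }
    }
    if (run >= params$l_similar) {
      b <- r
    } else {
      break
    }
  }
  data.frame(node = branch$node[b], level = branch$level[b],
             area = branch$area[b], growth = g[b])
}

#' Segment a prebuilt max-tree
#'
#' Runs marker selection and per-branch region selection on an existing
#' tree. Useful when sweeping `delta` or other parameters, since the tree
#' and the extinction values do not depend on them.
#'
#' @param tree a [max_tree()] object.
#' @param params a [seg_params()] object.
#' @param extinctions optional precomputed [extinction_values()].
#' @return object of class `mt_segmentation`; see [segment_vegetation()].
#' @export
segment_tree <- function(tree, params = seg_params(), extinctions = NULL) {
  stopifnot(inherits(tree, "maxtree"), inherits(params, "seg_params"))
  if (is.null(extinctions)) extinctions <- extinction_values(tree)
  markers <- select_markers(extinctions, params$min_extinction)
  rows <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    br <- branch_candidates(tree, markers$node[i])
    sel <- select_region(br, params)
    if (!is.null(sel)) {
      sel$marker <- markers$node[i]
      rows[[i]] <- sel
    }
  }
  regions <- do.call(rbind, rows)
  if (is.null(regions)) {
    regions <- data.frame(node = integer(), level = integer(),
                          area = numeric(), growth = numeric(),
                          marker = integer())
  }
  if (params$t_area > 0) regions <- regions[regions$area >= params$t_area, ]
  # exact duplicates resolve to the same canonical node
  regions <- regions[!duplicated(regions$node), ]
  rownames(regions) <- NULL
  structure(
    list(regions = regions, tree = tree, params = params,
         markers = markers, dim = tree$dim),
    class = "mt_segmentation"
  )
}

#' Max-tree vegetation segmentation
#'
#' The full segmentation step: build the max-tree of the NDVI image, compute
#' grey-range extinction values, keep the contrasted regional maxima as
#' markers, and for each marker select the most stable fast-growing region
#' along its branch ([select_region()]). Regions smaller than `t_area` are
#' discarded regardless of their growth, exact duplicates (identical
#' canonical nodes) are removed, and nested non-identical regions are kept.
#'
#' @param image integer NDVI image in `[0, 255]`.
#' @param params a [seg_params()] object.
#' @param connectivity pixel adjacency, 4 (default) or 8.
#' @return object of class `mt_segmentation`: list with `regions`
#'   (data.frame of `node`, `level`, `area`, `growth`, `marker`), the
#'   `tree`, the `params` used and the marker table.
#' @examples
#' img <- matrix(40L, 64, 64)
#' img[20:40, 20:40] <- 160L
#' seg <- segment_vegetation(img)
#' seg$regions
#' @export
segment_vegetation <- function(image, params = seg_params(),
                               connectivity = 4L) {
  tree <- max_tree(image, connectivity)
  segment_tree(tree, params)
}

#' @export
print.mt_segmentation <- function(x, ...) {
  cat(sprintf("mt_segmentation: %d region(s) from %d marker(s), %d x %d image\n",
              nrow(x$regions), nrow(x$markers), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Binary mask of a segmentation result
#'
#' Union of the pixel sets of all accepted regions.
#'
#' @param result an `mt_segmentation` object.
#' @return logical matrix (TRUE = vegetation).
#' @export
segmentation_mask <- function(result) {
  stopifnot(inherits(result, "mt_segmentation"))
  nodes_mask(result$tree, result$regions$node)
}

#' Label image of a segmentation result
#'
#' Regions are numbered in acceptance order; background is 0. Nested regions
#' overwrite the regions that contain them, so each pixel carries the label
#' of the innermost accepted region covering it.
#'
#' @param result an `mt_segmentation` object.
#' @return integer matrix of region labels.
#' @export
label_image <- function(result) {
  stopifnot(inherits(result, "mt_segmentation"))
  lab <- matrix(0L, result$dim[1], result$dim[2])
  reg <- result$regions
  for (i in order(-reg$area)) {  # outer regions first, inner overwrite
    m <- nodes_mask(result$tree, reg$node[i])
    lab[m] <- i
  }
  lab
}

#' Export segmentation regions as CSV
#'
#' Columns: region id, marker pixel (row, col), level, area and growth.
#'
#' @param result an `mt_segmentation` object.
#' @param path output file.
#' @export
write_regions <- function(result, path) {
  reg <- result$regions
  h <- result$dim[1]
  p <- result$tree$min_pixel[reg$marker]
  out <- data.frame(
    region = seq_len(nrow(reg)),
    marker_row = (p - 1L) %% h + 1L,
    marker_col = (p - 1L) %/% h + 1L,
    level = reg$level, area = reg$area, growth = reg$growth
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
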