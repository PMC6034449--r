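#' Build the max-tree of an 8-bit image
#'
#' The max-tree is the hierarchy of connected components of all upper level
#' sets \eqn{L_k = \{f \ge k\}} of a grey-level image, nested by decreasing
#' threshold. Leaves correspond one-to-one to the regional maxima of the
#' image. The tree is canonical: components that are identical across
#' consecutive grey levels are stored once, at the highest such level.
#'
#' Node attributes (area, raw moment sums up to order two, grey extrema and
#' convex-hull area over pixel corners) are propagated incrementally from the
#' leaves towards the root during construction, so that every pixel's
#' coordinates are visited exactly once.
#'
#' Node ids are ordered so that every child has a smaller id than its parent;
#' the root is the last node.
#'
#' @param image integer matrix with values in `[0, 255]`.
#' @param connectivity pixel adjacency, 4 (default) or 8.
#' @param hull_points if `TRUE`, keep the per-node convex-hull vertices
#'   (pixel-corner coordinates); memory-heavy, intended for small images.
#' @return An object of class `maxtree`: a list with per-node vectors
#'   `parent`, `level`, `area`, attribute sums, and `node_of_pixel` mapping
#'   every pixel (column-major) to its owning node.
#' @seealso [min_tree()], [node_attributes()], [node_pixels()],
#'   [area_opening()], [extinction_values()]
#' @examples
#' img <- matrix(0L, 6, 6)
#' img[2:3, 2:3] <- 100L
#' img[5, 5] <- 200L
#' tr <- max_tree(img)
#' tr$level
#' @export
max_tree <- function(image, connectivity = 4L, hull_points = FALSE) {
  image <- as_grey_image(image)
  raw <- .mt_build(image, as.integer(connectivity), isTRUE(hull_points))
  new_maxtree(raw, image, as.integer(connectivity), type = "max")
}

#' Build the min-tree of an 8-bit image
#'
#' The dual of the max-tree, built from lower level sets; leaves are regional
#' minima. Implemented as the max-tree of the inverted image `255 - f`, with
#' levels and grey extrema reported on the original scale.
#'
#' @inheritParams max_tree
#' @return An object of class `maxtree` with `type = "min"`; along any
#'   leaf-to-root path the level is increasing.
#' @export
min_tree <- function(image, connectivity = 4L, hull_points = FALSE) {
  image <- as_grey_image(image)
  inv <- 255L - image
  raw <- .mt_build(inv, as.integer(connectivity), isTRUE(hull_points))
  tr <- new_maxtree(raw, inv, as.integer(connectivity), type = "min")
  tr$level <- 255L - tr$level
  fmin <- 255L - tr$fmax
  fmax <- 255L - tr$fmin
  tr$fmin <- fmin
  tr$fmax <- fmax
  tr$image <- image
  tr
}

new_maxtree <- function(raw, image, connectivity, type) {
  n <- length(raw$parent)
  has_child <- logical(n)
  has_child[raw$parent[raw$parent != seq_len(n)]] <- TRUE
  structure(
    list(
      parent = raw$parent, level = raw$level, area = raw$area,
      sx = raw$sx, sy = raw$sy, sxx = raw$sxx, syy = raw$syy, sxy = raw$sxy,
      fmin = raw$fmin, fmax = raw$fmax, hull_area = raw$hull_area,
      min_pixel = raw$min_pixel + 1L,
      hull_points = raw$hull_points,
      node_of_pixel = raw$node_of_pixel,
      is_leaf = !has_child,
      root = raw$root,
      n_nodes = n,
      dim = dim(image),
      connectivity = connectivity,
      type = type,
      image = image
    ),
    class = "maxtree"
  )
}

as_grey_image <- function(image) {
  if (is.logical(image)) image <- image * 255L
  if (!is.matrix(image)) stop("image must be a matrix")
  if (length(image) == 0L) stop("empty image")
  if (is.double(image)) {
    if (any(abs(image - round(image)) > 1e-9, na.rm = TRUE))
      stop("image values must be integers in [0, 255]")
    image <- matrix(as.integer(round(image)), nrow(image), ncol(image))
  }
  if (anyNA(image) || any(image < 0L) || any(image > 255L))
    stop("image values must be integers in [0, 255]")
  image
}

#' @export
print.maxtree <- function(x, ...) {
  cat(sprintf(
    "%s-tree: %d nodes (%d leaves), %d x %d image, %d-connectivity\n",
    x$type, x$n_nodes, sum(x$is_leaf), x$dim[1], x$dim[2], x$connectivity
  ))
  invisible(x)
}

#' Per-node attribute table
#'
#' Central moments are derived from the propagated raw sums using
#' pixel-centre coordinates (`x` = 0-based column, `y` = 0-based row);
#' discrete corrections belong to the feature formulas, not to the stored
#' sums. The table is suitable for CSV export.
#'
#' @param tree a [max_tree()] object.
#' @return data.frame with one row per node: `node`, `parent`, `level`,
#'   `area`, central moments `mu20`, `mu02`, `mu11`, grey extrema `fmin`,
#'   `fmax`, `grey_range`, `hull_area` and `is_leaf`.
#' @export
node_attributes <- function(tree) {
  stopifnot(inherits(tree, "maxtree"))
  a <- tree$area
  data.frame(
    node = seq_len(tree$n_nodes),
    parent = tree$parent,
    level = tree$level,
    area = a,
    mu20 = tree$sxx - tree$sx^2 / a,
    mu02 = tree$syy - tree$sy^2 / a,
    mu11 = tree$sxy - tree$sx * tree$sy / a,
    fmin = tree$fmin,
    fmax = tree$fmax,
    grey_range = tree$fmax - tree$fmin,
    hull_area = tree$hull_area,
    is_leaf = tree$is_leaf
  )
}

#' Pixel set of a node
#'
#' Materialises the component represented by a node: its proper pixels plus
#' the pixels of all descendants. The set is connected under the tree's
#' connectivity.
#'
#' @param tree a [max_tree()] object.
#' @param node node id.
#' @return two-column integer matrix of (row, col), 1-based.
#' @export
node_pixels <- function(tree, node) {
  stopifnot(inherits(tree, "maxtree"))
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > tree$n_nodes)
    stop("invalid node id")
  mask <- .mt_mask_nodes(tree$node_of_pixel, tree$parent, node)
  idx <- which(mask)
  h <- tree$dim[1]
  cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
}

#' Binary mask of the union of node subtrees
#'
#' @param tree a [max_tree()] object.
#' @param nodes integer vector of node ids.
#' @return logical matrix of the image dimensions.
#' @export
nodes_mask <- function(tree, nodes) {
  stopifnot(inherits(tree, "maxtree"))
  if (length(nodes) == 0L) {
    return(matrix(FALSE, tree$dim[1], tree$dim[2]))
  }
  mask <- .mt_mask_nodes(tree$node_of_pixel, tree$parent, as.integer(nodes))
  matrix(mask, tree$dim[1], tree$dim[2])
}

#' Reconstruct the image from the tree
#'
#' Each pixel takes the level of its owning node; for a valid tree this
#' reproduces the input image exactly.
#'
#' @param tree a [max_tree()] object.
#' @return integer matrix.
#' @export
reconstruct <- function(tree) {
  stopifnot(inherits(tree, "maxtree"))
  lev <- tree$level
  if (tree$type == "min") lev <- 255L - lev
  out <- .mt_reconstruct(tree$node_of_pixel, lev, tree$dim[1], tree$dim[2])
  if (tree$type == "min") out <- 255L - out
  out
}

#' Area opening
#'
#' Connected filter: each output pixel takes the highest level `k` such that
#' the pixel lies in a connected component of the upper level set `L_k` with
#' area at least `t_area`. Components that are too small are merged into
#' their nearest surviving ancestor; all other region boundaries are left
#' intact. Anti-extensive and idempotent.
#'
#' @param image integer matrix in `[0, 255]`, or a [max_tree()] object.
#' @param t_area minimal component area in pixels (>= 1).
#' @param connectivity pixel adjacency (ignored when `image` is a tree).
#' @return filtered integer matrix.
#' @export
area_opening <- function(image, t_area, connectivity = 4L) {
  if (t_area < 1) stop("t_area must be >= 1")
  tree <- if (inherits(image, "maxtree")) image else max_tree(image, connectivity)
  if (tree$type != "max") stop("area opening requires a max-tree")
  .mt_area_opening(
    tree$node_of_pixel, tree$parent, tree$level, tree$area,
    as.numeric(t_area), tree$dim[1], tree$dim[2]
  )
}

#' Export the node table as CSV
#'
#' @param tree a [max_tree()] object.
#' @param path output file.
#' @export
write_node_table <- function(tree, path) {
  write.csv(node_attributes(tree), path, row.names = FALSE)
  invisible(path)
}
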