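#' Grey-range extinction values of the regional maxima
#'
#' For every leaf of the max-tree (regional maximum), the extinction value is
#' the largest grey-range filter size that the maximum survives: the contrast
#' between the maximum and the level at which its component merges with a
#' component holding a more dominant maximum. The globally dominant maximum
#' receives the full image grey range. Dominance between equal-valued maxima
#' is broken deterministically towards the leaf containing the smallest
#' (column-major) pixel index.
#'
#' Extinction values are a noise-robust contrast measure: a maximum sitting
#' on low-amplitude texture is extinguished quickly, while a well-contrasted
#' plant region survives large filter sizes.
#'
#' @param tree a [max_tree()] object.
#' @return numeric vector over all nodes; extinction value for leaves,
#'   `NA` for internal nodes.
#' @seealso [select_markers()]
#' @export
extinction_values <- function(tree) {
  stopifnot(inherits(tree, "maxtree"))
  .mt_extinction(tree$parent, tree$level, tree$min_pixel, tree$is_leaf)
}

#' Select marker leaves by extinction value
#'
#' Keeps exactly the regional maxima whose extinction value is at least
#' `min_extinction`; maxima with strictly smaller values are discarded.
#' The default cutoff of 10 grey levels (out of 1-255) removes maxima due to
#' sensor noise and soil texture while keeping contrasted vegetation.
#'
#' @param extinctions output of [extinction_values()].
#' @param min_extinction minimal extinction value in grey levels.
#' @return data.frame with columns `node` (leaf id) and `extinction`,
#'   ordered by decreasing extinction (ties by node id).
#' @export
select_markers <- function(extinctions, min_extinction = 10) {
  keep <- which(!is.na(extinctions) & extinctions >= min_extinction)
  keep <- keep[order(-extinctions[keep], keep)]
  data.frame(node = keep, extinction = extinctions[keep])
}

#' Export a marker set as CSV
#'
#' @param tree a [max_tree()] object.
#' @param markers output of [select_markers()].
#' @param path output file.
#' @export
write_markers <- function(tree, markers, path) {
  h <- tree$dim[1]
  p <- tree$min_pixel[markers$node]
  out <- data.frame(
    node = markers$node,
    row = (p - 1L) %% h + 1L,
    col = (p - 1L) %/% h + 1L,
    extinction = markers$extinction
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
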