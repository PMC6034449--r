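# Brute-force oracles, independent of the package's max-tree code paths.
# Everything here works directly on upper level sets by flood fill, at the
# small image sizes the oracle tests use.

# 4- or 8-connected components of a logical matrix; returns a list of
# sorted column-major linear index vectors, ordered by smallest member.
bf_components <- function(bin, connectivity = 4) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nl <- 0L
  nb <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  for (p in which(bin)) {
    if (lab[p] > 0L) next
    nl <- nl + 1L
    queue <- p
    lab[p] <- nl
    while (length(queue) > 0L) {
      q <- queue[[1]]
      queue <- queue[-1]
      r <- (q - 1L) %% h + 1L
      cc <- (q - 1L) %/% h + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1]
        c2 <- cc + nb[k, 2]
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w) {
          qq <- rr + (c2 - 1L) * h
          if (bin[qq] && lab[qq] == 0L) {
            lab[qq] <- nl
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  if (nl == 0L) return(list())
  unname(split(which(lab > 0L), lab[lab > 0L]))
}

# Canonical (level, pixel-set) pairs of all upper-level-set components,
# deduplicated by pixel-set equality keeping the highest level.
bf_canonical_nodes <- function(img, connectivity = 4) {
  sets <- list()
  keys <- character()
  for (k in sort(unique(as.vector(img)))) {
    for (comp in bf_components(img >= k, connectivity)) {
      key <- paste(comp, collapse = ",")
      i <- match(key, keys)
      if (is.na(i)) {
        keys <- c(keys, key)
        sets[[length(sets) + 1L]] <- list(level = k, pixels = comp)
      } else {
        sets[[i]]$level <- k  # ascending scan: last write is the highest
      }
    }
  }
  sets
}

# node signature strings "level|p1,p2,..." for set comparison
node_signature <- function(level, pixels) {
  paste0(level, "|", paste(sort(pixels), collapse = ","))
}

tree_signatures <- function(tree) {
  h <- tree$dim[1]
  vapply(seq_len(tree$n_nodes), function(n) {
    px <- node_pixels(tree, n)
    node_signature(tree$level[n], px[, 1] + (px[, 2] - 1L) * h)
  }, "")
}

bf_signatures <- function(img, connectivity = 4) {
  vapply(bf_canonical_nodes(img, connectivity),
         function(s) node_signature(s$level, s$pixels), "")
}

# direct attribute computation from an explicit pixel set
bf_attributes <- function(img, pixels) {
  h <- nrow(img)
  x <- (pixels - 1L) %/% h       # 0-based column = x
  y <- (pixels - 1L) %% h        # 0-based row = y
  a <- length(pixels)
  px <- c(x - 0.5, x - 0.5, x + 0.5, x + 0.5)
  py <- c(y - 0.5, y + 0.5, y - 0.5, y + 0.5)
  hi <- grDevices::chull(px, py)
  xx <- px[hi]; yy <- py[hi]
  hull <- abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  list(
    area = a,
    mu20 = sum(x^2) - sum(x)^2 / a,
    mu02 = sum(y^2) - sum(y)^2 / a,
    mu11 = sum(x * y) - sum(x) * sum(y) / a,
    fmin = min(img[pixels]),
    fmax = max(img[pixels]),
    hull_area = hull
  )
}

# regional maxima as (pixel set, value, tie key = smallest pixel index)
bf_maxima <- function(img, connectivity = 4) {
  h <- nrow(img); w <- ncol(img)
  out <- list()
  for (v in unique(sort(as.vector(img)))) {
    for (comp in bf_components(img == v, connectivity)) {
      r <- (comp - 1L) %% h + 1L
      cc <- (comp - 1L) %/% h + 1L
      nbv <- integer(0)
      drs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
             else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                       c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
      is_max <- TRUE
      for (d in drs) {
        rr <- r + d[1]; c2 <- cc + d[2]
        ok <- rr >= 1 & rr <= h & c2 >= 1 & c2 <= w
        if (any(ok)) {
          qq <- rr[ok] + (c2[ok] - 1L) * h
          qq <- setdiff(qq, comp)
          if (any(img[qq] > v)) { is_max <- FALSE; break }
        }
      }
      if (is_max) out[[length(out) + 1L]] <-
        list(pixels = comp, value = v, key = min(comp))
    }
  }
  out
}

# grey-range extinction by its filtering definition: the contrast down to
# the highest threshold at which the maximum shares a component with a
# dominant competitor (higher value, or equal value and smaller tie key);
# the overall winner gets the full image range
bf_extinction <- function(img, connectivity = 4) {
  maxima <- bf_maxima(img, connectivity)
  lo <- min(img)
  res <- vapply(maxima, function(m) {
    rivals <- Filter(function(o) {
      o$value > m$value || (o$value == m$value && o$key < m$key)
    }, maxima)
    if (length(rivals) == 0L) return(m$value - lo)
    for (k in seq(m$value, lo, by = -1)) {
      comps <- bf_components(img >= k, connectivity)
      mine <- comps[[which(vapply(comps, function(s) m$key %in% s, TRUE))]]
      if (any(vapply(rivals, function(o) o$key %in% mine, TRUE)))
        return(m$value - k)
    }
    m$value - lo
  }, 0)
  names(res) <- vapply(maxima, function(m) as.character(m$key), "")
  res
}

# stacked binary area opening
bf_area_opening <- function(img, t_area, connectivity = 4) {
  out <- matrix(min(img), nrow(img), ncol(img))
  for (k in sort(unique(as.vector(img)))) {
    for (comp in bf_components(img >= k, connectivity)) {
      if (length(comp) >= t_area) out[comp] <- pmax(out[comp], k)
    }
  }
  out
}

rand_img <- function(h, w, levels) {
  matrix(sample(0:(levels - 1L), h * w, replace = TRUE), h, w)
}

# extinction values of the package, named by each leaf's smallest pixel index
pkg_extinction_by_key <- function(tree) {
  ext <- extinction_values(tree)
  leaves <- which(tree$is_leaf)
  res <- ext[leaves]
  names(res) <- as.character(tree$min_pixel[leaves])
  res
}
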