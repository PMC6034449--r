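#' Specification of a synthetic NDVI field
#'
#' Describes an NDVI-like test image: a darker, textured, noisy soil
#' background carrying bright plant regions of controllable contrast, with
#' per-pixel ground truth and per-region crop/weed/mixed labels. Crops are
#' rendered as compact rosettes (overlapping rasterized ellipses around a
#' core), weeds as thin elongated blades (high-aspect rotated ellipses),
#' which gives the two classes clearly different shape statistics. Sparse
#' bright speckle emulates the spurious local maxima that sensor noise and
#' registration errors produce in real imagery, and a 1-pixel edge ramp at
#' a quarter of the plant contrast models the imprecise, fading plant
#' borders responsible for boundary errors in real data.
#'
#' @param width,height image size in pixels.
#' @param soil_level soil base grey level.
#' @param soil_texture half-amplitude of the smoothed soil texture noise
#'   (grey levels).
#' @param texture_kernel box-blur kernel width (odd) for the soil texture.
#' @param speckle_rate fraction of soil pixels receiving bright speckle.
#' @param speckle_amplitude speckle brightness over the soil level.
#' @param n_plants number of plants.
#' @param crop_fraction expected fraction of crop plants.
#' @param contrast plant grey-level contrast over the soil level; scalar or
#'   length-2 range sampled per plant.
#' @param plant_area target plant area in pixels; scalar or length-2 range.
#' @param overlap_prob probability that a weed is planted overlapping a
#'   crop, creating a mixed region.
#' @param illumination amplitude of a linear left-to-right illumination
#'   gradient (grey levels; 0 disables).
#' @param edge_ramp render a 1-pixel half-contrast ramp at plant borders.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return list of class `field_spec`.
#' @export
field_spec <- function(width = 512L, height = 512L, soil_level = 70,
                       soil_texture = 6, texture_kernel = 5L,
                       speckle_rate = 0.002, speckle_amplitude = 12,
                       n_plants = 8L, crop_fraction = 0.5,
                       contrast = 60, plant_area = c(250, 900),
                       overlap_prob = 0, illumination = 0,
                       edge_ramp = TRUE, seed = 1L) {
  stopifnot(width >= 16, height >= 16, n_plants >= 0,
            all(plant_area >= 1), max(contrast) + soil_level <= 255,
            overlap_prob >= 0, overlap_prob <= 1)
  structure(as.list(environment()), class = "field_spec")
}

#' Generate a synthetic field sample
#'
#' Renders the field described by a [field_spec()]: soil (base level plus
#' smoothed uniform texture plus optional linear illumination gradient plus
#' sparse bright speckle), then the plants at `soil_level + contrast` with
#' an optional soft edge ramp. Overlapping crop and weed plants produce
#' regions labelled `mixed`. Fully reproducible from the spec seed.
#'
#' @param spec a [field_spec()] object.
#' @return list of class `field_sample`: `image` (integer NDVI matrix),
#'   `truth` (logical mask), `labels` (integer region label map),
#'   `table` (data.frame: `region`, `class`, `area`), and the `spec`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, render_field(spec))
}

render_field <- function(spec) {
  h <- spec$height; w <- spec$width
  img <- matrix(spec$soil_level, h, w)
  if (spec$soil_texture > 0) {
    noise <- matrix(runif(h * w, -spec$soil_texture, spec$soil_texture), h, w)
    img <- img + box_blur(noise, spec$texture_kernel)
  }
  if (spec$illumination > 0) {
    img <- img + matrix(seq(0, spec$illumination, length.out = w),
                        h, w, byrow = TRUE)
  }

  # plants: class, contrast and area sampled per plant, then placed
  classes <- ifelse(runif(spec$n_plants) < spec$crop_fraction, "crop", "weed")
  contr <- sample_range(spec$contrast, spec$n_plants)
  areas <- sample_range(spec$plant_area, spec$n_plants)

  crop_mask <- matrix(FALSE, h, w)
  weed_mask <- matrix(FALSE, h, w)
  occupied <- matrix(FALSE, h, w)
  levels_img <- matrix(0, h, w)  # plant level over soil, 0 = no plant
  placed <- 0L

  for (i in seq_len(spec$n_plants)) {
    m <- if (classes[i] == "crop") raster_rosette(areas[i])
         else raster_blade(areas[i])
    ph <- nrow(m); pw <- ncol(m)
    if (ph > h - 2 || pw > w - 2) stop("plants cannot be placed without exceeding the image")
    want_overlap <- classes[i] == "weed" && placed > 0L &&
      any(crop_mask) && runif(1) < spec$overlap_prob
    pos <- NULL
    for (try in 1:200) {
      r0 <- sample.int(h - ph - 1L, 1L)
      c0 <- sample.int(w - pw - 1L, 1L)
      if (want_overlap) {
        hit <- any(crop_mask[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)] & m)
        if (hit) { pos <- c(r0, c0); break }
      } else {
        # expanded window must be completely free: a 1-px guard band keeps
        # disjoint plants from touching even diagonally
        r1 <- max(r0 - 1L, 1L); r2 <- min(r0 + ph, h)
        c1 <- max(c0 - 1L, 1L); c2 <- min(c0 + pw, w)
        if (!any(occupied[r1:r2, c1:c2])) { pos <- c(r0, c0); break }
      }
    }
    if (is.null(pos)) {
      if (want_overlap) next  # fall back: skip the overlap plant
      stop("plants cannot be placed without exceeding the image")
    }
    rows <- pos[1]:(pos[1] + ph - 1L)
    cols <- pos[2]:(pos[2] + pw - 1L)
    tgt <- if (classes[i] == "crop") "crop" else "weed"
    sl <- levels_img[rows, cols]
    sl[m] <- pmax(sl[m], contr[i])
    levels_img[rows, cols] <- sl
    occupied[rows, cols] <- occupied[rows, cols] | m
    if (tgt == "crop") crop_mask[rows, cols] <- crop_mask[rows, cols] | m
    else weed_mask[rows, cols] <- weed_mask[rows, cols] | m
    placed <- placed + 1L
  }

  truth <- levels_img > 0
  if (isTRUE(spec$edge_ramp)) {
    # border pixels at a quarter of the plant contrast: leaf edges fade
    # nearly to soil level, as real plant borders do
    interior <- erode4(truth)
    border <- truth & !interior
    levels_img[border] <- levels_img[border] / 4
  }
  img[truth] <- spec$soil_level + levels_img[truth] +
    (if (spec$illumination > 0)
      matrix(seq(0, spec$illumination, length.out = w), h, w, byrow = TRUE)[truth]
     else 0)

  # sparse bright speckle on the soil: spurious regional maxima
  soil_idx <- which(!truth)
  n_spk <- round(spec$speckle_rate * length(soil_idx))
  if (n_spk > 0) {
    at <- sample(soil_idx, n_spk)
    img[at] <- img[at] + spec$speckle_amplitude
  }

  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)

  labels <- label_components(truth)
  n_reg <- max(labels)
  cls <- character(n_reg)
  for (r in seq_len(n_reg)) {
    sel <- labels == r
    has_c <- any(sel & crop_mask)
    has_w <- any(sel & weed_mask)
    cls[r] <- if (has_c && has_w) "mixed" else if (has_c) "crop" else "weed"
  }
  tab <- data.frame(region = seq_len(n_reg), class = cls,
                    area = as.vector(table(factor(labels[labels > 0],
                                                  levels = seq_len(n_reg)))))
  structure(list(image = img, truth = truth, labels = labels,
                 table = tab, spec = spec),
            class = "field_sample")
}

sample_range <- function(x, n) {
  if (n == 0L) return(numeric(0))
  if (length(x) == 1L) rep(x, n) else runif(n, min(x), max(x))
}

raster_ellipse <- function(a, b, theta, cx = 0, cy = 0, r = NULL) {
  if (is.null(r)) r <- ceiling(max(a, b) + max(abs(cx), abs(cy))) + 1L
  xs <- seq(-r, r)
  x <- matrix(xs, 2 * r + 1L, 2 * r + 1L, byrow = TRUE) - cx
  y <- matrix(xs, 2 * r + 1L, 2 * r + 1L) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# compact rosette: central disk plus overlapping elliptical leaves
raster_rosette <- function(area) {
  rad <- sqrt(area / (0.75 * pi))
  n_leaf <- sample(5:7, 1L)
  phi <- runif(1, 0, 2 * pi)
  r <- ceiling(1.2 * rad) + 1L  # common grid for core and leaves
  m <- raster_ellipse(0.55 * rad, 0.55 * rad, 0, r = r)
  for (k in seq_len(n_leaf)) {
    th <- phi + 2 * pi * k / n_leaf
    leaf <- raster_ellipse(0.55 * rad, 0.30 * rad, th,
                           cx = 0.55 * rad * cos(th),
                           cy = 0.55 * rad * sin(th), r = r)
    m <- m | leaf
  }
  trim_mask(m)
}

# thin elongated blade: high-aspect rotated ellipse
raster_blade <- function(area, aspect = NULL) {
  if (is.null(aspect)) aspect <- runif(1, 9, 14)
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  th <- runif(1, 0, pi)
  trim_mask(raster_ellipse(a, b, th))
}

trim_mask <- function(m) {
  rs <- which(rowSums(m) > 0); cs <- which(colSums(m) > 0)
  m[rs[1]:rs[length(rs)], cs[1]:cs[length(cs)], drop = FALSE]
}

erode4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  m & p[1:h, 2:(w + 1)] & p[3:(h + 2), 2:(w + 1)] &
    p[2:(h + 1), 1:w] & p[2:(h + 1), 3:(w + 2)]
}

box_blur <- function(m, k) {
  if (k <= 1L) return(m)
  kern <- rep(1 / k, k)
  pad <- (k - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  big <- m[c(rep(1L, pad), 1:h, rep(h, pad + 1L)),
           c(rep(1L, pad), 1:w, rep(w, pad + 1L))]
  sm <- apply(big, 2, function(col) stats::filter(col, kern, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, kern, sides = 2)))
  sm[pad + (1:h), pad + (1:w)]
}

#' Connected-component labelling of a binary mask
#'
#' Labels the 4-connected foreground components of a binary mask using the
#' max-tree of the 0/1 image (the components are exactly the level-1
#' nodes' pixel sets).
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background), numbered
#'   in order of their smallest column-major pixel index.
#' @export
label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  tr <- max_tree(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  comp <- which(tr$level == 1L & tr$level[tr$parent] == 0L)
  if (length(comp) == 0L) comp <- tr$root  # all-foreground mask
  comp <- comp[order(tr$min_pixel[comp])]
  lab <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(comp)) {
    lab[nodes_mask(tr, comp[i])] <- i
  }
  lab
}

#' Generate a low-vegetation field
#'
#' As [generate_field()], constrained to at most 0.5% foreground
#' fraction: a few small plants in an otherwise plain textured field, the
#' regime in which global thresholding methods break down.
#'
#' @param spec a [field_spec()]; defaults to 4 plants of about 220 px in
#'   close proximity on a 512 x 512 field under a 40-grey-level linear
#'   illumination gradient, the uneven-lighting regime where a single
#'   global threshold cannot separate dark-side vegetation from
#'   bright-side soil.
#' @return a `field_sample`; errors if the rendered foreground exceeds
#'   0.5% of the pixels.
#' @export
generate_lowveg <- function(spec = field_spec(n_plants = 4L,
                                              plant_area = c(180, 260),
                                              illumination = 40,
                                              overlap_prob = 0)) {
  out <- generate_field(spec)
  frac <- mean(out$truth)
  if (frac > 0.005)
    stop(sprintf("foreground fraction %.4f exceeds the 0.5%% low-vegetation bound", frac))
  out
}

#' Toy binary images for morphology oracles
#'
#' A small binary image holding exactly three 4-connected components: a
#' large blocky object with fine boundary detail, a thin elongated object
#' (both of area >= 9), and one object smaller than 9 pixels. An area
#' opening with threshold 9 removes exactly the smallest object while
#' preserving the thin elongated one intact.
#'
#' @return list with `image` (0/1 integer matrix) and `areas` (component
#'   areas in label order).
#' @export
generate_toy_binary <- function() {
  m <- matrix(0L, 16L, 16L)
  m[3:8, 3:8] <- 1L          # blocky object ...
  m[3, 3] <- 0L; m[8, 3] <- 0L; m[5:6, 8] <- 0L  # ... with boundary detail
  m[2, 5:6] <- 1L
  m[12, 2:13] <- 1L          # thin elongated object, 1 px wide
  m[14:15, 15:16] <- 1L      # sub-9-px object
  lab <- label_components(m == 1L)
  areas <- as.vector(table(lab[lab > 0]))
  list(image = m, areas = areas)
}

#' Write a field sample bundle
#'
#' Writes `ndvi.png`, `truth.png`, `labels.tif` (16-bit), `labels.csv` and
#' `spec.yaml` into a directory.
#'
#' @param sample a `field_sample`.
#' @param dir output directory (created if missing).
#' @export
write_field_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "field_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(sample$image, file.path(dir, "ndvi.png"))
  write_mask(sample$truth, file.path(dir, "truth.png"))
  write_labels(sample$labels, file.path(dir, "labels.tif"))
  write.csv(sample$table, file.path(dir, "labels.csv"), row.names = FALSE)
  sp <- sample$spec
  class(sp) <- NULL
  yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  invisible(dir)
}
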