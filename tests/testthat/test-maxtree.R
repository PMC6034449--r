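test_that("canonical structure matches the spec examples", {
  # constant image: a single node
  tc <- max_tree(matrix(5L, 5, 5))
  expect_equal(tc$n_nodes, 1L)
  expect_equal(tc$area, 25)
  expect_equal(tc$level, 5L)

  # zeros with a 2x2 patch at 100 and an isolated pixel at 200
  img <- matrix(0L, 6, 6)
  img[2:3, 2:3] <- 100L
  img[5, 5] <- 200L
  tr <- max_tree(img)
  expect_equal(tr$n_nodes, 3L)
  expect_setequal(paste(tr$level, tr$area), c("0 36", "100 4", "200 1"))
  expect_equal(sum(tr$parent == seq_len(3)), 1L)  # exactly one root
  expect_true(all(tr$level[tr$parent] <= tr$level))

  # 1x4 ramp: chain of four nodes
  tb <- max_tree(matrix(0:3, 1, 4))
  expect_equal(sort(tb$area), c(1, 2, 3, 4))
  expect_equal(sort(tb$level), 0:3)

  expect_error(max_tree(matrix(integer(0), 0, 0)), "empty")
  expect_error(max_tree(matrix(300L, 2, 2)), "\\[0, 255\\]")
})

test_that("node (level, pixel-set) pairs equal brute-force level-set components", {
  set.seed(101)
  for (i in 1:8) {
    img <- rand_img(12, 12, 8)
    for (conn in c(4L, 8L)) {
      tr <- max_tree(img, conn)
      expect_setequal(tree_signatures(tr), bf_signatures(img, conn))
    }
  }
})

test_that("reconstruction reproduces the input exactly", {
  set.seed(5)
  for (i in 1:5) {
    img <- rand_img(15, 11, 16)
    expect_identical(reconstruct(max_tree(img)), img)
    expect_identical(reconstruct(min_tree(img)), img)
  }
})

test_that("area and grey range are non-decreasing from leaf to root", {
  set.seed(9)
  img <- rand_img(16, 16, 8)
  tr <- max_tree(img)
  rng <- tr$fmax - tr$fmin
  for (leaf in which(tr$is_leaf)) {
    br <- branch_candidates(tr, leaf)
    expect_true(all(diff(br$area) >= 0))
    expect_true(all(diff(rng[br$node]) >= 0))
    expect_true(all(diff(br$level) < 0))
  }
})

test_that("min-tree is the max-tree of the inverted image", {
  set.seed(13)
  img <- rand_img(10, 10, 6)
  mn <- min_tree(img)
  mx <- max_tree(255L - img)
  expect_identical(mn$parent, mx$parent)
  expect_identical(mn$level, 255L - mx$level)
  expect_identical(mn$node_of_pixel, mx$node_of_pixel)

  # one dark pit: a min-tree leaf exactly there
  flat <- matrix(9L, 7, 7)
  flat[4, 4] <- 2L
  mnp <- min_tree(flat)
  expect_equal(mnp$n_nodes, 2L)
  leaf <- which(mnp$is_leaf)
  expect_equal(mnp$area[leaf], 1)
  expect_equal(mnp$level[leaf], 2L)
  expect_equal(min_tree(matrix(3L, 4, 4))$n_nodes, 1L)
})

test_that("incremental attributes equal direct computation on every node", {
  set.seed(23)
  for (i in 1:5) {
    img <- rand_img(12, 12, 8)
    tr <- max_tree(img)
    at <- node_attributes(tr)
    h <- tr$dim[1]
    for (n in seq_len(tr$n_nodes)) {
      px <- node_pixels(tr, n)
      lin <- px[, 1] + (px[, 2] - 1L) * h
      d <- bf_attributes(img, lin)
      expect_equal(at$area[n], d$area)
      expect_equal(at$mu20[n], d$mu20, tolerance = 1e-9)
      expect_equal(at$mu02[n], d$mu02, tolerance = 1e-9)
      expect_equal(at$mu11[n], d$mu11, tolerance = 1e-9)
      expect_identical(at$fmin[n], d$fmin)
      expect_identical(at$fmax[n], d$fmax)
      expect_equal(at$hull_area[n], d$hull_area, tolerance = 1e-9)
    }
  }
})

test_that("central moments of a 2x2 block come from pixel centres", {
  img <- matrix(0L, 4, 4)
  img[2:3, 2:3] <- 7L
  tr <- max_tree(img)
  at <- node_attributes(tr)
  blk <- which(at$level == 7L)
  expect_equal(at$area[blk], 4)
  expect_equal(at$mu20[blk], 1)
  expect_equal(at$mu02[blk], 1)
  expect_equal(at$mu11[blk], 0)
  expect_equal(at$grey_range[blk], 0)  # flat leaf
  root <- tr$root
  expect_equal(at$area[root], 16)      # root covers the whole image
})

test_that("node pixel sets are nested, disjoint across siblings, connected", {
  set.seed(31)
  img <- rand_img(10, 10, 6)
  tr <- max_tree(img)
  h <- tr$dim[1]
  px_root <- node_pixels(tr, tr$root)
  expect_equal(nrow(px_root), 100L)
  for (n in seq_len(tr$n_nodes)) {
    px <- node_pixels(tr, n)
    lin <- sort(px[, 1] + (px[, 2] - 1L) * h)
    bin <- matrix(FALSE, 10, 10)
    bin[lin] <- TRUE
    expect_length(bf_components(bin, tr$connectivity), 1L)
  }
  kids <- split(seq_len(tr$n_nodes)[-tr$root], tr$parent[-tr$root])
  for (sib in kids) {
    if (length(sib) < 2) next
    sets <- lapply(sib, function(n) {
      px <- node_pixels(tr, n)
      px[, 1] + (px[, 2] - 1L) * h
    })
    expect_equal(anyDuplicated(unlist(sets)), 0L)
  }
  expect_error(node_pixels(tr, tr$n_nodes + 5L), "invalid node")
})

test_that("tree area opening equals the stacked binary opening", {
  set.seed(47)
  for (i in 1:5) {
    img <- rand_img(12, 12, 6)
    for (t_area in c(1, 3, 9, 30, 200)) {
      got <- area_opening(img, t_area)
      expect_identical(got, bf_area_opening(img, t_area))
      expect_true(all(got <= img))                       # anti-extensive
      expect_identical(area_opening(got, t_area), got)   # idempotent
    }
    expect_identical(area_opening(img, 1), img)
    expect_true(all(area_opening(img, 1e5) == min(img)))
  }
  expect_error(area_opening(rand_img(5, 5, 4), 0), "t_area")
})

test_that("area opening keeps large and thin objects, removes small ones", {
  toy <- generate_toy_binary()
  img <- toy$image * 100L
  out <- area_opening(img, 9)
  kept <- label_components(out > 0)
  expect_equal(max(kept), 2L)                # the sub-9-px object is gone
  big <- toy$areas[toy$areas >= 9]
  expect_equal(sort(as.vector(table(kept[kept > 0]))), sort(big))
  expect_identical(out, bf_area_opening(img, 9))
})
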