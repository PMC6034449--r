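test_that("branch candidates enumerate the threshold decomposition", {
  tr <- max_tree(matrix(0:3, 1, 4))
  leaf <- which(tr$is_leaf)
  br <- branch_candidates(tr, leaf)
  expect_equal(br$area, c(1, 2, 3, 4))
  expect_equal(br$level, 3:0)

  tc <- max_tree(matrix(4L, 3, 3))
  expect_equal(nrow(branch_candidates(tc, 1L)), 1L)

  img <- matrix(0L, 6, 6)
  img[2:3, 2:3] <- 100L
  trn <- max_tree(img)
  expect_error(branch_candidates(trn, trn$root), "not a leaf")
})

test_that("growth factor follows the span-below-the-level convention", {
  # ramp 1x10 with values 9..0, delta = 3: level 9 (area 1) vs level 6 (area 4)
  tr <- max_tree(matrix(9:0, 1, 10))
  br <- branch_candidates(tr, which(tr$is_leaf))
  g <- growth_factors(br, 3)
  expect_equal(g[1], 3)
  # level k has area 10-k and compares against level k-3 (area 13-k),
  # clamped at the root: G = min(3, k) / (10 - k)
  expect_equal(g, pmin(3, br$level) / br$area, tolerance = 1e-12)

  # constant area across >= delta levels: zero growth
  br2 <- data.frame(node = 1:3, level = c(100L, 60L, 0L), area = c(50, 50, 5000))
  expect_equal(growth_factors(br2, 30)[1], 0)

  # direct arithmetic: A=100 vs 300 over the span
  br3 <- data.frame(node = 1:2, level = c(50L, 20L), area = c(100, 300))
  expect_equal(growth_factors(br3, 30)[1], 2)

  # branch ends: the root area is used
  expect_equal(growth_factors(br3, 200)[1], 2)
})

test_that("candidate adjustment promotes larger repeated regions", {
  p <- seg_params(delta = 30, g_min = 10, k_factor = 15, e_area = 0.15,
                  l_similar = 6)

  # flat branch: nothing exceeds g_min
  br <- data.frame(node = 1:3, level = c(90L, 60L, 30L), area = c(10, 10, 10))
  expect_null(select_region(br, p, growth = c(0, 0, 0)))

  # no competitor is k_factor times larger: argmax growth unchanged
  br2 <- data.frame(node = 1:4, level = c(90L, 70L, 50L, 30L),
                    area = c(10, 20, 40, 80))
  sel2 <- select_region(br2, p, growth = c(50, 20, 15, 12))
  expect_equal(sel2$node, 1L)
  expect_equal(sel2$growth, 50)

  # hand-traced adjustment: B0 (G=50, A=10); R (G=20, A=200 > 15*10)
  # followed by six consecutive candidates within +/-15% of 200 and
  # descending growth above 10 -> R is promoted
  br3 <- data.frame(node = 1:9,
                    level = as.integer(seq(120, 40, by = -10)),
                    area = c(10, 200, 202, 206, 210, 214, 220, 226, 5000))
  g3 <- c(50, 20, 19, 18, 17, 16, 15, 14, 1)
  sel3 <- select_region(br3, p, growth = g3)
  expect_equal(sel3$node, 2L)
  expect_equal(sel3$area, 200)

  # with a too-short similar run the adjustment does not fire
  sel4 <- select_region(br3[c(1:4, 9), ], p, growth = g3[c(1:4, 9)])
  expect_equal(sel4$node, 1L)
})

test_that("a contrasted disk is segmented exactly", {
  img <- matrix(40L, 128, 128)
  xs <- matrix(1:128, 128, 128, byrow = TRUE)
  ys <- matrix(1:128, 128, 128)
  disk <- (xs - 64)^2 + (ys - 64)^2 <= 20^2
  img[disk] <- 160L
  seg <- segment_vegetation(img)
  expect_equal(nrow(seg$regions), 1L)
  expect_identical(segmentation_mask(seg), disk)

  # constant image: no markers, empty result
  seg0 <- segment_vegetation(matrix(50L, 64, 64))
  expect_equal(nrow(seg0$regions), 0L)
  expect_false(any(segmentation_mask(seg0)))
})

test_that("markers converging to one node are deduplicated", {
  img <- matrix(40L, 150, 150)
  xs <- matrix(1:150, 150, 150, byrow = TRUE)
  ys <- matrix(1:150, 150, 150)
  plateau <- (xs - 75)^2 + (ys - 75)^2 <= 20^2
  img[plateau] <- 150L
  img[(xs - 66)^2 + (ys - 75)^2 <= 8^2] <- 165L
  img[(xs - 84)^2 + (ys - 75)^2 <= 8^2] <- 175L
  tr <- max_tree(img)
  expect_equal(sum(tr$is_leaf), 2L)
  # both bump windows land on the plateau, whose own growth dominates:
  # both branches select the same plateau node
  seg <- segment_tree(tr, seg_params(delta = 15))
  expect_equal(nrow(seg$regions), 1L)
  expect_identical(segmentation_mask(seg), plateau)
})

test_that("region area filtering discards small regions regardless of growth", {
  img <- matrix(40L, 96, 96)
  img[20:40, 20:40] <- 160L   # area 441
  img[5, 5] <- 160L           # area 1, same contrast
  seg_all <- segment_vegetation(img, seg_params(t_area = 0))
  expect_equal(nrow(seg_all$regions), 2L)
  seg_t <- segment_vegetation(img, seg_params(t_area = 50))
  expect_equal(nrow(seg_t$regions), 1L)
  expect_equal(seg_t$regions$area, 441)
})

test_that("segmentation is grey-shift invariant and deterministic", {
  f <- generate_field(field_spec(width = 160L, height = 160L, n_plants = 3L,
                                 seed = 3L))
  p <- seg_params(t_area = 50)
  seg1 <- segment_vegetation(f$image, p)
  seg2 <- segment_vegetation(f$image + 40L, p)
  expect_identical(segmentation_mask(seg1), segmentation_mask(seg2))
  seg3 <- segment_vegetation(f$image, p)
  expect_identical(seg1$regions, seg3$regions)
})

test_that("an added distant blob does not disturb other regions", {
  f <- generate_field(field_spec(width = 200L, height = 200L, n_plants = 3L,
                                 seed = 8L))
  p <- seg_params(t_area = 50)
  base_mask <- segmentation_mask(segment_vegetation(f$image, p))
  img2 <- f$image
  img2[3:12, 3:12] <- 150L   # far corner blob
  mask2 <- segmentation_mask(segment_vegetation(img2, p))
  # the blob's own region may include its merge fringe; everything outside
  # a guard window around it must be untouched
  far <- matrix(TRUE, 200, 200)
  far[1:14, 1:14] <- FALSE
  expect_identical(mask2 & far, base_mask & far)
  blob <- matrix(FALSE, 200, 200)
  blob[3:12, 3:12] <- TRUE
  expect_true(all(mask2[blob]))
})

test_that("nested regions are kept; masks and labels stay consistent", {
  img <- matrix(30L, 96, 96)
  img[10:30, 10:30] <- 150L           # outer bright square, area 441
  img[15:17, 15:17] <- 200L           # small very contrasted core, area 9
  img[24:29, 24:29] <- 170L           # second bump, area 36
  seg <- segment_tree(max_tree(img), seg_params(delta = 20))
  # the core's branch keeps the core (its growth dominates); the second
  # bump's branch selects the outer square: a nested pair
  expect_equal(nrow(seg$regions), 2L)
  expect_setequal(seg$regions$area, c(9, 441))
  m <- segmentation_mask(seg)
  outer <- matrix(FALSE, 96, 96)
  outer[10:30, 10:30] <- TRUE
  expect_identical(m, outer)           # nested union equals the outermost
  lab <- label_image(seg)
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), 1:2)
  inner_id <- seg$regions$node[which.min(seg$regions$area)]
  expect_true(all(lab[15:17, 15:17] ==
                    which(seg$regions$node == inner_id)))
})
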