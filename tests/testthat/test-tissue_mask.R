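test_that("saturation channel matches hand HSV conversion", {
  expect_equal(saturation_channel(solid_rgb(4, 4, c(77, 77, 77))),
               matrix(0, 4, 4))
  expect_equal(saturation_channel(solid_rgb(4, 4, c(255, 0, 0))),
               matrix(1, 4, 4))
  expect_equal(saturation_channel(solid_rgb(2, 2, c(128, 64, 64))),
               matrix((128 - 64) / 128, 2, 2))
  expect_equal(saturation_channel(solid_rgb(2, 2, c(0, 0, 0))),
               matrix(0, 2, 2))
})

test_that("a saturated square on white is recovered with high IoU", {
  px <- solid_rgb(512, 512, c(245, 245, 245))
  truth <- matrix(FALSE, 512, 512)
  truth[150:349, 200:399] <- TRUE
  for (ch in 1:3) {
    p <- px[, , ch]
    p[truth] <- c(186, 85, 150)[ch]
    px[, , ch] <- p
  }
  tm <- compute_tissue_mask(raster_image(px, 5))
  iou <- sum(tm$mask & truth) / sum(tm$mask | truth)
  expect_gte(iou, 0.98)
})

test_that("specks below the area threshold are removed", {
  px <- solid_rgb(512, 512, c(245, 245, 245))
  truth <- matrix(FALSE, 512, 512)
  truth[150:349, 200:399] <- TRUE
  set.seed(4)
  speck_anchor <- cbind(sample(c(5:120, 380:490), 10), sample(5:490, 10))
  stain <- truth
  for (s in seq_len(10)) {
    stain[speck_anchor[s, 1] + 0:4, speck_anchor[s, 2] + 0:4] <- TRUE
  }
  for (ch in 1:3) {
    p <- px[, , ch]
    p[stain] <- c(186, 85, 150)[ch]
    px[, , ch] <- p
  }
  tm <- compute_tissue_mask(raster_image(px, 5))
  # all specks (area 25 < 100) removed, square kept
  for (s in seq_len(10)) {
    expect_false(any(tm$mask[speck_anchor[s, 1] + 0:4, speck_anchor[s, 2] + 0:4]))
  }
  expect_gte(sum(tm$mask & truth) / sum(truth), 0.97)
})

test_that("holes are filled or preserved by the area rule", {
  px <- solid_rgb(400, 400, c(245, 245, 245))
  tissue <- matrix(FALSE, 400, 400)
  tissue[100:299, 100:299] <- TRUE
  tissue[150:159, 150:159] <- FALSE    # 10x10 hole, area 100 > 16: kept
  tissue[250:252, 250:252] <- FALSE    # 3x3 hole, area 9 <= 16: filled
  for (ch in 1:3) {
    p <- px[, , ch]
    p[tissue] <- c(186, 85, 150)[ch]
    px[, , ch] <- p
  }
  tm <- compute_tissue_mask(raster_image(px, 5))
  expect_false(any(tm$mask[152:157, 152:157]))   # large hole interior stays open
  expect_true(all(tm$mask[250:252, 250:252]))    # small hole filled
})

test_that("at most max_holes holes are preserved, largest first", {
  mask <- matrix(FALSE, 200, 260)
  mask[20:180, 20:240] <- TRUE
  sides <- c(12, 11, 10, 9, 8, 7)                # areas 144..49, all > 16
  anchors <- cbind(40, c(30, 60, 90, 120, 150, 180))
  for (i in seq_along(sides)) {
    mask[anchors[i, 1] + seq_len(sides[i]) - 1,
         anchors[i, 2] + seq_len(sides[i]) - 1] <- FALSE
  }
  cleaned <- gnnsurv:::clean_mask(mask, min_area = 100, min_hole = 16, max_holes = 4)
  # the 4 largest holes survive, the 2 smallest are filled
  for (i in 1:4) {
    expect_false(any(cleaned[anchors[i, 1] + seq_len(sides[i]) - 1,
                             anchors[i, 2] + seq_len(sides[i]) - 1]))
  }
  for (i in 5:6) {
    expect_true(all(cleaned[anchors[i, 1] + seq_len(sides[i]) - 1,
                            anchors[i, 2] + seq_len(sides[i]) - 1]))
  }
})

test_that("component/hole cleanup is idempotent and monotone in min_area", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(64 * 64) < 0.45, 64, 64)
    once <- gnnsurv:::clean_mask(m, 30, 16, 8)
    twice <- gnnsurv:::clean_mask(once, 30, 16, 8)
    expect_identical(once, twice)
    larger <- gnnsurv:::clean_mask(m, 60, 16, 8)
    expect_true(all(!larger | once))     # raising min_area never adds pixels
  }
})

test_that("compiled component labelling agrees with a flood-fill oracle", {
  set.seed(21)
  for (rep in 1:6) {
    m <- matrix(runif(40 * 40) < 0.4, 40, 40)
    for (conn in c(4, 8)) {
      fast <- label_components(m, conn)
      slow <- flood_fill_label(m, conn)
      # identical partitions and identical numbering (both scanline-ordered)
      expect_identical(fast, slow)
    }
  }
})

test_that("an unstained image yields an empty mask with a warning", {
  px <- solid_rgb(300, 300, c(245, 245, 245))
  set.seed(2)
  px <- px + array(as.integer(sample(-2:2, length(px), TRUE)), dim(px))
  expect_warning(tm <- compute_tissue_mask(raster_image(px, 5)),
                 "empty")
  expect_false(any(tm$mask))
})
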