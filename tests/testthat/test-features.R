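test_that("labelling partitions the foreground exactly (flood-fill oracle)", {
  set.seed(41)
  for (rep in 1:20) {
    mask <- matrix(rbinom(16 * 16, 1, 0.35), 16, 16)
    for (conn in c(4, 8)) {
      regions <- label_regions(mask, connectivity = conn)
      ref <- flood_fill_labels(mask, connectivity = conn)
      # same number of components
      expect_equal(length(regions), max(ref))
      # identical partition: each region's pixels carry one oracle label,
      # and all foreground pixels are covered exactly once
      seen <- matrix(0L, 16, 16)
      for (r in regions) {
        labs <- ref[r$pixels]
        expect_equal(length(unique(labs)), 1L)
        expect_equal(r$area, sum(ref == labs[1]))
        seen[r$pixels] <- seen[r$pixels] + 1L
      }
      expect_equal(seen, (ref > 0) + 0L, ignore_attr = TRUE)
    }
  }
})

test_that("diagonal neighbours merge under 8- but not 4-connectivity", {
  mask <- matrix(0, 4, 4)
  mask[2, 2] <- 1
  mask[3, 3] <- 1
  expect_length(label_regions(mask, 8), 1L)
  expect_length(label_regions(mask, 4), 2L)
  expect_length(label_regions(matrix(0, 4, 4)), 0L)
})

test_that("border filtering removes exactly the regions in the band", {
  mask <- matrix(0, 8, 10)
  mask[1, 6] <- 1          # touches the top edge
  mask[4:5, 4:5] <- 1      # fully interior
  regions <- label_regions(mask)
  expect_length(regions, 2L)
  kept <- filter_border(regions, dim(mask), margin = 1)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$area, 4L)
  # margin 0 removes nothing
  expect_length(filter_border(regions, dim(mask), margin = 0), 2L)
  # idempotent
  expect_identical(filter_border(kept, dim(mask), margin = 1), kept)
  # touches_border flag agrees with a margin-1 filter
  expect_true(regions[[which(vapply(regions, function(r) r$pixels[1, 1] == 1,
                                    logical(1)))]]$touches_border)
})

test_that("centroids are pixel-coordinate means", {
  mask <- matrix(0, 10, 10)
  mask[2:3, 3:4] <- 1                      # 2x2 block
  mask[7, 9] <- 1                          # single pixel
  mask[5, 1] <- 1; mask[6, 1] <- 1; mask[6, 2] <- 1  # L-tromino
  regions <- label_regions(mask)
  cents <- centroids(regions)
  expect_equal(nrow(cents), 3L)
  rows <- cents[order(cents[, "col"]), , drop = FALSE]
  expect_equal(unname(rows[1, ]), c(5 + 2 / 3, 1 + 1 / 3))  # tromino
  expect_equal(unname(rows[2, ]), c(2.5, 3.5))              # block
  expect_equal(unname(rows[3, ]), c(7, 9))                  # singleton
  expect_equal(nrow(centroids(list())), 0L)
})

test_that("centroids lie within their region's bounding box", {
  set.seed(44)
  mask <- matrix(rbinom(400, 1, 0.3), 20, 20)
  for (r in label_regions(mask)) {
    expect_gte(r$centroid[1], min(r$pixels[, 1]))
    expect_lte(r$centroid[1], max(r$pixels[, 1]))
    expect_gte(r$centroid[2], min(r$pixels[, 2]))
    expect_lte(r$centroid[2], max(r$pixels[, 2]))
  }
})

test_that("minimum-area filtering is off by default and works when set", {
  mask <- matrix(0, 6, 6)
  mask[2, 2] <- 1
  mask[4:5, 4:5] <- 1
  regions <- label_regions(mask)
  expect_length(filter_min_area(regions, 0), 2L)
  expect_length(filter_min_area(regions, 2), 1L)
})

test_that("dark-core filtering separates heads from debris by intensity", {
  img <- matrix(0.75, 20, 20)
  mask <- matrix(0, 20, 20)
  img[4:6, 4:6] <- 0.35; mask[4:6, 4:6] <- 1      # head-dark region
  img[12:13, 12:13] <- 0.55; mask[12:13, 12:13] <- 1  # debris-bright region
  regions <- label_regions(mask)
  kept <- filter_dark_regions(regions, img)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$centroid, c(row = 5, col = 5))
})

test_that("refine_mask drops border, bright and small regions, keeps heads", {
  img <- matrix(0.8, 24, 24)
  mask <- matrix(0, 24, 24)
  img[10:12, 10:12] <- 0.3; mask[10:12, 10:12] <- 1  # head: kept
  img[18:19, 18:19] <- 0.6; mask[18:19, 18:19] <- 1  # bright: dropped
  mask[1, 5] <- 1; img[1, 5] <- 0.2                  # border: dropped
  out <- refine_mask(mask, img)
  expected <- matrix(0, 24, 24)
  expected[10:12, 10:12] <- 1
  expect_equal(out, expected)
  # the compiled fast path agrees with the region-list route
  regions <- label_regions(mask)
  regions <- filter_border(regions, dim(mask), 1)
  regions <- filter_dark_regions(regions, img)
  rebuilt <- matrix(0, 24, 24)
  for (r in regions) rebuilt[r$pixels] <- 1
  expect_equal(out, rebuilt)
  # min_area applies after the other filters
  expect_equal(sum(refine_mask(mask, img, min_area = 10)), 0)
})

test_that("greedy matching obeys its counting identities and tie-break", {
  pts <- cbind(c(2, 8, 14), c(3, 9, 2))
  res <- match_detections(pts, pts, radius = 1)
  expect_equal(res$matched, 3L)
  expect_equal(res$missed, 0L)
  expect_equal(res$spurious, 0L)

  res2 <- match_detections(matrix(numeric(0), ncol = 2), pts, radius = 2)
  expect_equal(res2$matched, 0L)
  expect_equal(res2$missed, 3L)

  # one prediction equidistant from two truths: matches the truth that
  # comes first in row-major order
  truth <- cbind(c(5, 7), c(5, 5))
  pred <- cbind(6, 5)
  res3 <- match_detections(pred, truth, radius = 2)
  expect_equal(res3$matched, 1L)
  expect_equal(unname(res3$pairs[1, 2]), 1L)

  # counting identities on random scatters
  set.seed(50)
  for (rep in 1:10) {
    p <- cbind(runif(12, 0, 30), runif(12, 0, 30))
    t <- cbind(runif(9, 0, 30), runif(9, 0, 30))
    m <- match_detections(p, t, radius = 4)
    expect_equal(m$matched + m$missed, 9L)
    expect_equal(m$matched + m$spurious, 12L)
  }
})
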