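test_that("normalization uses the bounding-box midpoint and half the largest edge", {
  nc <- normalizeCloud(rbind(c(0, 0, 0), c(10, 0, 0), c(5, 1, 0), c(5, 0, 1)))
  tr <- normTransform(nc)
  expect_equal(tr@scale, 5)
  expect_equal(tr@translation, c(5, 0.5, 0.5))
  expect_equal(cloudPoints(nc)[1:2, 1], c(-1, 1))
  expect_error(normalizeCloud(matrix(1, 4, 3)), "identical")
})

test_that("normalization round-trips and is shift/scale equivariant", {
  set.seed(10)
  p <- matrix(rnorm(300, sd = 40), 100, 3)
  nc <- normalizeCloud(p)
  back <- toMm(cloudPoints(nc), normTransform(nc))
  expect_lt(max(abs(back - p)) / max(abs(p)), 1e-9)
  # uniform scale + rigid shift leaves the normalized cloud unchanged
  nc2 <- normalizeCloud(3 * p + matrix(7, 100, 3, byrow = TRUE))
  expect_equal(cloudPoints(nc2), cloudPoints(nc), tolerance = 1e-12)
  expect_equal(normTransform(nc2)@scale, 3 * normTransform(nc)@scale)
})

test_that("voxelization maps boundary points into the grid and respects 2S/M accuracy", {
  g <- voxelize(rbind(c(-1, -1, -1), c(1, 1, 1), c(0.1, 0.1, 0.1), c(-0.2, 0, 0)), 2)
  occ <- occupancy(g)
  expect_equal(occ[1, 1, 1], 1)  # corner (-1,-1,-1)
  expect_equal(occ[2, 2, 2], 1)  # +1 boundary clamps to the last cell
  # accuracy bound: per-axis mm displacement point <-> voxel center <= 2S/M
  set.seed(11)
  for (M in c(2, 8, 32)) {
    p <- matrix(rnorm(150, sd = 30), 50, 3)
    nc <- normalizeCloud(p)
    S <- normTransform(nc)@scale
    idx0 <- floor((cloudPoints(nc) + 1) / 2 * M)
    idx0[idx0 > M - 1] <- M - 1
    ctr <- (idx0 + 0.5) * 2 / M - 1
    expect_true(all(abs(ctr - cloudPoints(nc)) * S <= 2 * S / M + 1e-12))
  }
})

test_that("occupied-voxel count is invariant under point order", {
  set.seed(12)
  p <- matrix(runif(600, -1, 1), 200, 3)
  g1 <- voxelize(p, 16)
  g2 <- voxelize(p[sample.int(200), ], 16)
  expect_identical(occupancy(g1), occupancy(g2))
})

test_that("voxelCenter inverts the index mapping", {
  expect_equal(voxelCenter(1, 1, 1, 2), c(-0.5, -0.5, -0.5))
  # exhaustive round trip at M = 4: center of each cell voxelizes to that cell
  M <- 4
  for (i in 1:M) for (j in 1:M) for (k in 1:M) {
    ctr <- voxelCenter(i, j, k, M)
    idx <- floor((ctr + 1) / 2 * M) + 1
    expect_equal(idx, c(i, j, k))
  }
  # mirror symmetry: idx -> M + 1 - idx flips the sign
  expect_equal(voxelCenter(1, 2, 3, 4), -voxelCenter(4, 3, 2, 4))
  expect_error(voxelCenter(0, 1, 1, 4), "indices")
})

test_that("outlier filter removes a far point and honors its guards", {
  set.seed(13)
  th <- runif(200, 0, 2 * pi); ph <- acos(runif(200, -1, 1))
  sph <- 50 * cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  cloud <- faceCloud(rbind(sph, c(500, 0, 0)))
  filt <- outlierFilter(cloud, kNeighbors = 5, sigmaMult = 2)
  expect_equal(nrow(cloudPoints(filt)), 200)
  expect_false(any(cloudPoints(filt)[, 1] == 500))
  # brute-force kNN oracle agrees on which point is extreme
  d2 <- as.matrix(dist(cloudPoints(cloud)))
  diag(d2) <- Inf
  md <- apply(d2, 1, function(r) mean(sort(r)[1:5]))
  expect_equal(unname(which.max(md)), 201L)
  # sigmaMult = Inf is the identity
  expect_identical(cloudPoints(outlierFilter(cloud, 5, Inf)), cloudPoints(cloud))
  # output is always a sub-multiset of the input
  expect_true(all(cloudPoints(filt) %in% cloudPoints(cloud)))
  # never removes more than 20% of points
  spread <- faceCloud(matrix(rnorm(120, sd = 30), 40, 3))
  kept <- nrow(cloudPoints(outlierFilter(spread, 3, sigmaMult = -1)))
  expect_gte(kept, ceiling(0.8 * 40))
})

test_that("cropOrgan selects box points, composes transforms, and is monotone in margin", {
  corners <- as.matrix(expand.grid(x = c(-40, 40), y = c(-40, 40), z = c(-40, 40)))
  nc <- normalizeCloud(corners)
  # box around the 4 corners with x < 0 (normalized x = -1)
  box <- c(-1, 0, 0, 0.2, 1.2, 1.2)
  crop <- cropOrgan(nc, box, margin = 1, MOrgan = 4)
  expect_equal(nrow(crop$points), 4L)
  # composed transform: region-frame origin -> mm midpoint of the selection
  expect_equal(toMm(c(0, 0, 0), crop$transform), c(-40, 0, 0))
  # region-frame corners map back to the original mm corners
  mmBack <- toMm(crop$points, crop$transform)
  expect_equal(sort(mmBack[, 2]), sort(corners[corners[, 1] < 0, 2]), tolerance = 1e-9)
  # growing the margin can only add points
  set.seed(14)
  p <- matrix(runif(900, -1, 1), 300, 3)
  nc2 <- normalizeCloud(p * 50)
  b2 <- c(0.2, -0.1, 0, 0.3, 0.3, 0.3)
  inBox <- function(margin) {
    sel <- abs(sweep(cloudPoints(nc2), 2, b2[1:3])) <=
      rep(margin * b2[4:6], each = 300)
    which(rowSums(sel) == 3)
  }
  expect_true(all(inBox(1) %in% inBox(1.2)))
  expect_error(cropOrgan(nc2, c(5, 5, 5, 0.01, 0.01, 0.01), 1, 4),
               "empty organ crop")
})

test_that("a whole-domain crop reproduces the face-level voxelization", {
  # cloud whose bounding box is exactly symmetric, so re-normalization is identity
  set.seed(15)
  p <- rbind(matrix(runif(300, -0.9, 0.9), 100, 3),
             c(-1, -1, -1), c(1, 1, 1))
  nc <- normalizeCloud(p * 30)
  crop <- cropOrgan(nc, c(0, 0, 0, 1, 1, 1), margin = 1, MOrgan = 8)
  expect_identical(occupancy(crop$grid), occupancy(voxelize(nc, 8)))
  expect_equal(crop$transform@scale, normTransform(nc)@scale)
})
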