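test_that("orthogonal reslicing permutes axes, spacing, and is an involution", {
  v <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  s <- imageStack(v, spacing = c(1, 2, 3))

  rx <- resliceOrthogonal(s, "X")
  expect_equal(dim(voxels(rx))[1], 5)          # slices stacked along Y
  expect_equal(spacing(rx), c(2, 1, 3))
  ry <- resliceOrthogonal(s, "Y")
  expect_equal(dim(voxels(ry))[1], 6)          # slices stacked along X
  expect_equal(spacing(ry), c(3, 2, 1))

  expect_identical(voxels(resliceOrthogonal(rx, "X")), v)
  expect_identical(voxels(resliceOrthogonal(ry, "Y")), v)
  expect_error(resliceOrthogonal(s, "Z"))
})

test_that("reslice index mapping is exactly (z,y,x)->(y,z,x) and (x,y,z)", {
  v <- array(seq_len(27), c(3, 3, 3))
  s <- imageStack(v)
  vx <- voxels(resliceOrthogonal(s, "X"))
  vy <- voxels(resliceOrthogonal(s, "Y"))
  for (z in 1:3) for (y in 1:3) for (x in 1:3) {
    expect_identical(vx[y, z, x], v[z, y, x])
    expect_identical(vy[x, y, z], v[z, y, x])
  }
})

test_that("slice maxima: empty slice, single spot, plateau centroid", {
  expect_true(all(sliceLocalMaxima(matrix(0, 8, 8)) == 0))

  spot <- exp(-(outer((1:16 - 6)^2, (1:16 - 11)^2, "+")) / 8)
  m <- sliceLocalMaxima(spot, prominence = 0.1)
  expect_equal(sum(m), 1)
  expect_equal(which(m == 1, arr.ind = TRUE)[1, ], c(row = 6, col = 11))

  ridge <- matrix(0, 9, 9)
  ridge[5, 2:8] <- 1            # flat plateau: only its centroid is marked
  m <- sliceLocalMaxima(ridge, prominence = 0.1)
  expect_equal(which(m == 1, arr.ind = TRUE)[1, ], c(row = 5, col = 5))
  expect_equal(sum(m), 1)
})

test_that("prominence filtering matches the flood-based oracle", {
  # two equal spots with a connecting valley at half height
  twin <- matrix(0, 16, 16)
  twin[8, 4] <- 100
  twin[8, 12] <- 100
  twin[8, 5:11] <- 50
  for (pr in c(0.2, 0.6)) {
    expect_identical(unname(sliceLocalMaxima(twin, pr)),
                     unname(brutePromMaxima(twin, pr)))
  }
  # equal peaks are tied: neither is connected to a higher maximum, so both
  # carry full prominence and survive either threshold
  expect_equal(sum(sliceLocalMaxima(twin, 0.6)), 2)

  # unequal peaks: the lower one dies at a strict threshold
  twin2 <- twin
  twin2[8, 12] <- 80
  expect_equal(sum(sliceLocalMaxima(twin2, 0.6)), 1)
  expect_identical(unname(sliceLocalMaxima(twin2, 0.6)),
                   unname(brutePromMaxima(twin2, 0.6)))

  # randomized smooth fields
  set.seed(42)
  for (rep in 1:8) {
    base <- matrix(runif(36), 6, 6)
    big <- base[rep(1:6, each = 2), rep(1:6, each = 2)]  # 12x12 with plateaus
    sm <- (big + big[c(1, 1:11), ] + big[, c(1, 1:11)]) / 3
    expect_identical(unname(sliceLocalMaxima(sm, 0.15)),
                     unname(brutePromMaxima(sm, 0.15)))
  }
})

test_that("skeletonization recovers tube centerlines via both reslices", {
  stack <- makePhantomStack("tube", dims = c(12L, 48L, 48L))
  pre <- preprocessStack(stack)
  mask <- skeletonizeStack(pre)
  expect_equal(dim(pixels(mask)), c(48L, 48L))
  ctr <- phantomCenterline("tube", c(12L, 48L, 48L))
  hits <- which(pixels(mask) == 1, arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  expect_true(all(abs(hits[, "row"] - ctr$y[1]) <= 1))
  # every column along the tube is segmented
  expect_true(all(seq_len(48) %in% hits[, "col"]))

  # a tube along Y (aligned with the other reslice axis) still segments fully
  vy <- aperm(voxels(stack), c(1, 3, 2))
  masky <- skeletonizeStack(preprocessStack(imageStack(vy)))
  hitsy <- which(pixels(masky) == 1, arr.ind = TRUE)
  expect_true(all(abs(hitsy[, "col"] - ctr$y[1]) <= 1))
  expect_true(all(seq_len(48) %in% hitsy[, "row"]))
})

test_that("the skeleton is intensity-scale-free and thickness-normalized", {
  stack <- makePhantomStack("tube", dims = c(12L, 48L, 48L))
  pre <- preprocessStack(stack)
  m1 <- pixels(skeletonizeStack(pre))
  m2 <- pixels(skeletonizeStack(imageStack(voxels(pre) * 37.5, spacing(pre))))
  expect_identical(m1, m2)

  counts <- vapply(c(1, 2, 3, 4), function(sg) {
    st <- makePhantomStack("tube", dims = c(24L, 48L, 48L), sigma = sg)
    sum(pixels(skeletonizeStack(preprocessStack(st))))
  }, numeric(1))
  expect_lt(diff(range(counts)) / mean(counts), 0.2)
})
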