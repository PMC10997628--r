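test_that("voxel ranking is descending with index tie-breaks", {
  tm <- array(c(0.1, 0.9, 0.5), c(3, 1, 1))
  expect_identical(rank_voxels(tm), c(2L, 3L, 1L))

  # all-equal statistics: identity order by voxel index
  expect_identical(rank_voxels(array(1, c(4, 1, 1))), 1:4)

  # permutation equivariance
  set.seed(1)
  v <- array(rnorm(24), c(4, 3, 2))
  r <- rank_voxels(v)
  perm <- sample(24)
  v2 <- array(as.numeric(v)[perm], c(4, 3, 2))
  expect_identical(as.numeric(v2)[rank_voxels(v2)], as.numeric(v)[r])

  expect_error(rank_voxels(v, array(FALSE, c(4, 3, 2))), "empty")
})

test_that("the enrichment curve reproduces the hand enumeration", {
  # N = 10, region occupies ranks 1, 2 and 5 (V = 3)
  tm <- array(seq(10, 1), c(10, 1, 1))  # ranking = voxel order
  atlas <- array(0L, c(10, 1, 1))
  atlas[c(1, 2, 5)] <- 1L
  ec <- enrichment_curve(rank_voxels(tm), atlas, 1L)
  expect_equal(ec$curve[1:5],
               c(1/3 - 0.1, 2/3 - 0.2, 2/3 - 0.3, 2/3 - 0.4, 1 - 0.5),
               tolerance = 1e-12)
  expect_equal(round(ec$curve[1:5], 4),
               c(0.2333, 0.4667, 0.3667, 0.2667, 0.5000))
  expect_equal(ec$ks_stat, 0.5)
  expect_identical(ec$argmax_n, 5L)
  expect_equal(ec$curve[10], 0)
  expect_equal(ec$r, 0.3)

  # region exactly the top V ranks: ks = 1 - V/N
  atlas2 <- array(0L, c(10, 1, 1)); atlas2[1:3] <- 1L
  ec2 <- enrichment_curve(rank_voxels(tm), atlas2, 1L)
  expect_equal(ec2$ks_stat, 1 - 3 / 10)

  # region exactly the bottom V ranks: curve <= 0 until the region starts,
  # maximum 0 reached once every voxel is ranked (N = 6, V = 2)
  tm6 <- array(seq(6, 1), c(6, 1, 1))
  atlas3 <- array(0L, c(6, 1, 1)); atlas3[5:6] <- 1L
  ec3 <- enrichment_curve(rank_voxels(tm6), atlas3, 1L)
  expect_equal(ec3$ks_stat, 0)
  expect_true(all(ec3$curve[1:4] < 0))

  expect_error(enrichment_curve(rank_voxels(tm), atlas, 9L), "absent")
})

test_that("curve bounds and monotone response hold on random instances", {
  set.seed(7)
  for (k in 1:20) {
    N <- sample(20:60, 1)
    V <- sample(2:(N %/% 2), 1)
    tm <- array(rnorm(N), c(N, 1, 1))
    atlas <- array(0L, c(N, 1, 1))
    reg <- sample(N, V)
    atlas[reg] <- 1L
    ec <- enrichment_curve(rank_voxels(tm), atlas, 1L)
    expect_true(all(ec$curve <= 1 - V / N + 1e-12))
    expect_true(all(ec$curve >= -(1 - V / N) - 1e-12))
    expect_gte(ec$ks_stat, 0)
    expect_lte(ec$ks_stat, 1 - V / N + 1e-12)
    # brute-force prefix scan agrees with the vectorised curve
    ranked <- rank_voxels(tm)
    brute <- vapply(seq_len(N), function(n)
      sum(ranked[seq_len(n)] %in% reg) / V - n / N, numeric(1))
    expect_equal(ec$curve, brute, tolerance = 1e-12)

    # raising region voxels never decreases the statistic
    tm2 <- tm
    tm2[reg] <- tm2[reg] + runif(1, 0, 2)
    ec2 <- enrichment_curve(rank_voxels(tm2), atlas, 1L)
    expect_gte(ec2$ks_stat + 1e-12, ec$ks_stat)
  }
})

test_that("region profiles cover all labels and degenerate cases", {
  # single region covering every scoped voxel: k/V = n/N exactly, ks = 0
  tm <- array(rnorm(60), c(5, 4, 3))
  whole <- array(1L, c(5, 4, 3))
  prof <- region_profile(tm, whole)
  expect_identical(nrow(prof), 1L)
  expect_equal(prof$ks_stat, 0)

  # a uniform-random t-map is enriched nowhere: null calibration
  set.seed(11)
  atlas <- array(0L, c(12, 10, 10))
  atlas[1:200] <- 1L           # V = 200
  atlas[atlas == 0L] <- 2L
  ks_null <- vapply(1:200, function(i) {
    tmr <- array(runif(1200), c(12, 10, 10))
    enrichment_curve(rank_voxels(tmr), atlas, 1L)$ks_stat
  }, numeric(1))
  expect_lt(quantile(ks_null, 0.95), 0.15)

  expect_error(region_profile(tm, array(1L, c(2, 2, 2))), "does not match")
})
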