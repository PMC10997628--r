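test_that("latent sd is the sample sd and survives row permutation", {
  z <- cbind(a = c(0, 2), b = c(1, 1))
  s <- latent_sd(z)
  expect_equal(unname(s), c(sqrt(2), 0))
  z2 <- matrix(rnorm(50), 10, 5)
  expect_equal(latent_sd(z2), latent_sd(z2[sample(10), ]))
  expect_error(latent_sd(matrix(1, 1, 3)), "at least 2")
})

test_that("latent perturbation changes exactly one coordinate", {
  z <- c(1, 2, 3)
  expect_identical(perturb_latent(z, 2, 0), z)
  p <- perturb_latent(z, 2, 0.5)
  expect_equal(p - z, c(0, 0.5, 0))
  expect_equal(perturb_latent(perturb_latent(z, 3, 1.2), 3, -1.2), z)
  expect_error(perturb_latent(z, 4, 1), "out of range")
})

test_that("Gaussian smoothing behaves at its boundary cases", {
  a <- array(rnorm(16 * 20 * 16), c(16, 20, 16))
  expect_identical(smooth_volume(a, 0), a)
  expect_error(smooth_volume(a, -1), "non-negative")

  # impulse: symmetric kernel keeps the maximum at the impulse voxel
  imp <- array(0, c(25, 25, 25))
  imp[13, 13, 13] <- 1
  sm <- smooth_volume(imp, 3)
  expect_identical(which.max(sm), which.max(imp))

  # constant input stays constant in the interior (kernel sums to 1)
  con <- smooth_volume(array(1, c(30, 30, 30)), 2)
  expect_lt(max(abs(con[10:20, 10:20, 10:20] - 1)), 1e-12)
})

test_that("a linear decoder reproduces the closed-form perturbation map", {
  set.seed(31)
  shape <- c(5L, 4L, 3L)
  nv <- prod(shape)
  A <- matrix(rnorm(nv * 4), nv, 4)
  dec <- linear_decoder(A, shape)
  z <- matrix(rnorm(40 * 4), 40, 4)

  tm <- perdi_tmap(dec, z, dim_index = 2, multiplier = 1, n_subjects = 20,
                   smooth_sigma = 0, seed = 5)
  delta <- sd(z[, 2])
  # differences are exactly delta * A[, 2] for every subject
  expect_equal(as.numeric(tm$mean_abs_diff), abs(delta * A[, 2]),
               tolerance = 1e-12)
  # voxel ranking of the map equals the ranking of |A[, 2]|
  expect_identical(order(-as.numeric(tm$raw), seq_len(nv)),
                   order(-abs(A[, 2]), seq_len(nv)))
  # sign symmetry: +1 and -1 multipliers give the same map
  tm_neg <- perdi_tmap(dec, z, dim_index = 2, multiplier = -1,
                       n_subjects = 20, smooth_sigma = 0, seed = 5)
  expect_equal(tm$raw, tm_neg$raw, tolerance = 1e-12)
  # every voxel is degenerate (zero variance of paired differences)
  expect_identical(tm$degenerate, sum(A[, 2] != 0))

  # zero multiplier: all differences vanish, t-map identically zero
  tm0 <- perdi_tmap(dec, z, dim_index = 2, multiplier = 0, n_subjects = 20,
                    smooth_sigma = 0, seed = 5)
  expect_true(all(tm0$values == 0))
})

test_that("voxel-wise paired t matches the textbook formula", {
  m <- tiny_model(latent = 5, seed = 41)
  set.seed(42)
  z <- matrix(rnorm(30 * 5), 30, 5)
  tm <- perdi_tmap(m, z, dim_index = 3, n_subjects = 20, smooth_sigma = 0,
                   seed = 6)
  # recompute the paired series independently and use stats::t.test
  idx <- withr::with_seed(6, sample.int(30, 20))
  z0 <- z[idx, ]
  z1 <- z0
  z1[, 3] <- z1[, 3] + sd(z[, 3])
  d <- decode_latents(m, z1) - decode_latents(m, z0)
  probe <- withr::with_seed(43, sample.int(nrow(d), 20))
  for (v in probe) {
    tv <- t.test(d[v, ])$statistic
    expect_equal(as.numeric(tm$raw)[v], abs(unname(tv)), tolerance = 1e-10)
  }
})

test_that("perturbation preconditions are enforced", {
  m <- tiny_model(latent = 3)
  z <- matrix(rnorm(30), 10, 3)
  expect_error(perdi_tmap(m, z, 1, n_subjects = 11), "exceeds")
  expect_error(perdi_tmap(m, z, 1, n_subjects = 1), "at least 2")
  z[, 2] <- 7
  expect_error(perdi_tmap(m, z, 2, n_subjects = 5), "degenerate")
})
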