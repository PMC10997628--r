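test_that("masked MSE evaluates the step-function loss exactly", {
  # two voxels, only the first masked: O = (1,5), R = (3,9) -> (3-1)^2 = 4
  orig <- vol_from_values(c(1, 5), mask_pattern = c(TRUE, FALSE))
  recon <- array(c(3, 9), c(2, 1, 1))
  expect_identical(masked_mse(recon, orig), 4)
  expect_identical(masked_mse(recon, orig, reduction = "sum"), 4)

  # identity
  expect_identical(masked_mse(orig$intensities, orig), 0)

  # arbitrary background edits never change the loss
  co <- tiny_cohort(n = 1)
  v <- cohort_volume(co, 1)
  r <- v$intensities + 0.1
  base <- masked_mse(r, v)
  for (k in 1:5) {
    r2 <- r
    r2[!v$mask] <- rnorm(sum(!v$mask), sd = 10^k)
    expect_identical(masked_mse(r2, v), base)
  }

  expect_error(masked_mse(array(0, c(3, 3, 3)), v), "shape mismatch")
  empty <- masked_volume(array(1, c(2, 2, 2)), mask = array(FALSE, c(2, 2, 2)))
  expect_error(masked_mse(array(0, c(2, 2, 2)), empty), "empty mask")
})

test_that("the autoencoder reproduces the input shape, including full scale", {
  m <- tiny_model()
  co <- tiny_cohort(n = 3)
  z <- encode_volumes(m, co)
  expect_identical(dim(z), c(3L, 6L))
  r <- decode_latents(m, z)
  expect_identical(nrow(r), as.integer(prod(co$shape)))
  expect_identical(attr(r, "shape"), m$config$input_shape)

  # full-resolution brain grid: 182 x 218 x 182 in, identical shape out
  cfg <- ae_config(c(182L, 218L, 182L), latent_dim = 2L, n_blocks = 4L,
                   channel_widths = c(1L, 1L, 1L, 1L, 1L), seed = 1)
  expect_identical(cfg$padded_shape, c(192L, 224L, 192L))
  big <- build_autoencoder(cfg)
  x <- array(0, c(182, 218, 182))
  x[60:120, 80:140, 60:120] <- rnorm(61^3)
  v <- masked_volume(x)
  z <- encode_volumes(big, list(v))
  expect_identical(dim(z), c(1L, 2L))
  r <- decode_latents(big, z)
  expect_identical(nrow(r), as.integer(prod(c(182L, 218L, 182L))))
})

test_that("parameter count grows with the bottleneck and shapes are validated", {
  n16 <- n_parameters(tiny_model(latent = 6))
  n32 <- n_parameters(tiny_model(latent = 12))
  expect_gt(n32, n16)

  expect_error(ae_config(c(8, 8, 8), n_blocks = 4), "at least 16")
  expect_error(ae_config(c(16, 16, 16), n_blocks = 2,
                         channel_widths = c(2, 4)), "length")
})

test_that("training reduces validation loss, checkpoints, and is seeded", {
  co <- znormalize_cohort(tiny_cohort(n = 30, seed = 9))
  m <- tiny_model(latent = 4, seed = 11)
  tr1 <- ae_train(m, co, epochs = 8, val_fraction = 0.25, batch_size = 8,
                  seed = 11)
  expect_lt(tail(tr1$history$val_loss, 1), tr1$history$val_loss[1])
  expect_identical(tr1$best_epoch,
                   which.min(tr1$history$val_loss))
  # determinism under the seed
  tr2 <- ae_train(m, co, epochs = 8, val_fraction = 0.25, batch_size = 8,
                  seed = 11)
  expect_identical(tr1$params, tr2$params)
  expect_identical(tr1$history, tr2$history)

  expect_error(ae_train(m, co, epochs = 8, val_fraction = 1.2), "val_fraction")
})

test_that("identical inputs encode identically (inference is deterministic)", {
  co <- tiny_cohort(n = 2)
  co$intensities[, 2] <- co$intensities[, 1]
  m <- tiny_model()
  z <- encode_volumes(m, co)
  expect_identical(z[1, ], z[2, ])
})

test_that("reconstruction gap separates informative models from collapsed ones", {
  co <- znormalize_cohort(tiny_cohort(n = 16, seed = 21))
  # collapsed model: all weights zero -> constant output for every subject
  m0 <- tiny_model()
  m0$params <- lapply(m0$params, function(p) p * 0)
  g0 <- reconstruction_gap(m0, co, seed = 2)
  expect_equal(g0$matched, g0$random_pair, tolerance = 1e-6)
  # derangement: nobody is paired with themselves
  expect_true(all(g0$permutation != seq_along(g0$permutation)))

  # briefly trained model: matched below random pairs
  m <- ae_train(tiny_model(latent = 4, seed = 13), co, epochs = 10,
                val_fraction = 0.25, batch_size = 8, seed = 13)
  g <- reconstruction_gap(m, co, seed = 2)
  expect_lt(g$matched, g$random_pair)

  expect_error(reconstruction_gap(m, list(cohort_volume(co, 1))), "at least 2")
})
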