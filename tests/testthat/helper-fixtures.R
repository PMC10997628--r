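# Shared lightweight fixtures. Everything is generated in code; the heavier
# end-to-end cohort lives only in test-acceptance.R.

tiny_spec <- function() phantom_spec(grid_shape = c(16L, 20L, 16L))

tiny_cohort <- function(n = 24, seed = 42) {
  fac <- sample_cohort_factors(n, 2L, seed = seed)
  suppressWarnings(render_cohort(fac, tiny_spec(), seed = seed + 1L))
}

# a small untrained (random-weight) model on the tiny grid
tiny_model <- function(latent = 6L, seed = 3L) {
  cfg <- ae_config(c(16L, 20L, 16L), latent_dim = latent, n_blocks = 2L,
                   channel_widths = c(2L, 3L, 4L), learning_rate = 1e-3,
                   seed = seed)
  build_autoencoder(cfg)
}

# construct a masked_volume directly from a vector of masked values
vol_from_values <- function(values, mask_pattern = NULL, shape = NULL) {
  n <- length(values)
  if (is.null(shape)) shape <- c(n, 1L, 1L)
  arr <- array(0, shape)
  if (is.null(mask_pattern)) mask_pattern <- rep(TRUE, n)
  arr[seq_len(n)][mask_pattern] <- values[mask_pattern]
  masked_volume(arr, mask = array(seq_len(prod(shape)) %in% which(mask_pattern),
                                  shape))
}

# dosage triple with controlled LD: B is A with enough entries resampled to
# land near the requested r2; C independent
ld_toy_genotypes <- function(n = 4000, r2_ab = 0.7, seed = 9,
                             positions = c(1000000L, 1100000L, 2000000L)) {
  withr::with_seed(seed, {
    a <- rbinom(n, 2, 0.4)
    b <- a
    flip <- runif(n) < (1 - sqrt(r2_ab))
    b[flip] <- rbinom(sum(flip), 2, 0.4)
    cc <- rbinom(n, 2, 0.4)
    genotype_set(cbind(a, b, cc),
                 data.frame(id = c("A", "B", "C"), chrom = 1L,
                            pos = positions, a1 = "A", a2 = "B",
                            stringsAsFactors = FALSE))
  })
}
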