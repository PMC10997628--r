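test_that("cohort factors are seeded, standardised and validated", {
  a <- sample_cohort_factors(4, 2, seed = 7)
  b <- sample_cohort_factors(4, 2, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort_factors(4, 2, seed = 8)))

  big <- sample_cohort_factors(10000, 2, seed = 1)
  expect_lt(abs(mean(big$factor1)), 0.05)
  expect_lt(abs(mean(big$factor2)), 0.05)
  expect_lt(abs(var(big$factor1) - 1), 0.1)

  expect_error(sample_cohort_factors(0, 2), "positive")
  expect_error(sample_cohort_factors(5, 1), "at least 2")
})

test_that("rendering is deterministic and background is exactly zero", {
  fac <- sample_cohort_factors(3, 2, seed = 1)
  spec <- tiny_spec()
  a <- render_cohort(fac, spec, seed = 5)
  b <- render_cohort(fac, spec, seed = 5)
  expect_identical(a$intensities, b$intensities)
  expect_true(all(a$intensities[!a$mask, ] == 0))

  # zero factors, zero noise: template; identical factors -> identical voxels
  spec0 <- phantom_spec(grid_shape = c(16, 20, 16), noise_sd = 0,
                        centre_jitter_sd = 0, radius_jitter = 0,
                        intensity_jitter = 0, texture_amplitude = 0)
  f0 <- fac[c(1, 1), ]
  f0[paste0("factor", 1:2)] <- 0
  t0 <- render_cohort(f0, spec0, seed = 1)
  expect_identical(t0$intensities[, 1], t0$intensities[, 2])
})

test_that("ventricle voxel count grows monotonically with its factor", {
  spec <- phantom_spec(grid_shape = c(16, 20, 16), noise_sd = 0,
                       centre_jitter_sd = 0, radius_jitter = 0,
                       intensity_jitter = 0, texture_amplitude = 0)
  fac <- sample_cohort_factors(5, 2, seed = 1)
  fac$factor2[] <- 0
  fac$factor1 <- c(-2, -1, 0, 1, 2)
  co <- render_cohort(fac, spec, seed = 1)
  other <- c(0, spec$intensities$cortex, spec$intensities$subcortical)
  counts <- colSums(!matrix(co$intensities %in% other,
                            nrow(co$intensities)))
  expect_true(all(diff(counts) >= 0))   # voxelisation is discrete
  expect_gt(counts[5], counts[1])       # +2 strictly larger than -2
})

test_that("out-of-range factors are clamped with a warning", {
  spec <- phantom_spec(grid_shape = c(16, 20, 16), noise_sd = 0,
                       centre_jitter_sd = 0, radius_jitter = 0,
                       intensity_jitter = 0, texture_amplitude = 0)
  fac <- sample_cohort_factors(2, 2, seed = 1)
  fac$factor1 <- c(5, 2)   # 5 is beyond the clamp, 2 is at it
  fac$factor2[] <- 0
  expect_warning(co <- render_cohort(fac, spec, seed = 1), "clamped")
  expect_identical(co$intensities[, 1], co$intensities[, 2])
})

test_that("background voxel count matches brute-force ellipsoid voxelisation", {
  spec <- phantom_spec(grid_shape = c(16, 20, 16), noise_sd = 0,
                       centre_jitter_sd = 0, radius_jitter = 0,
                       intensity_jitter = 0, texture_amplitude = 0)
  fac <- sample_cohort_factors(1, 2, seed = 2)
  co <- render_cohort(fac, spec, seed = 2)
  # independent enumeration: test every voxel centre against the ellipsoid
  g <- spec$grid_shape
  cen <- spec$centre
  rad <- spec$brain_radii
  inside <- 0L
  for (z in seq_len(g[3])) for (y in seq_len(g[2])) for (x in seq_len(g[1]))
    if (((x - cen[1]) / rad[1])^2 + ((y - cen[2]) / rad[2])^2 +
        ((z - cen[3]) / rad[3])^2 <= 1) inside <- inside + 1L
  expect_equal(sum(co$intensities[, 1] == 0), prod(g) - inside)
  expect_identical(sum(co$mask), inside)
})

test_that("atlas labels the template and rejects overlapping regions", {
  spec <- tiny_spec()
  atl <- phantom_atlas(spec)
  counts <- table(atl$labels[atl$labels > 0])
  expect_length(counts, length(spec$region_defs) + 1L)  # + cortex
  expect_true(all(counts > 0))

  # containment: no label where the template is background
  co <- render_cohort(transform(sample_cohort_factors(1, 2, seed = 1),
                                factor1 = 0, factor2 = 0),
                      phantom_spec(grid_shape = spec$grid_shape, noise_sd = 0,
                                   centre_jitter_sd = 0, radius_jitter = 0,
                                   intensity_jitter = 0,
                                   texture_amplitude = 0),
                      seed = 1)
  expect_true(all(atl$labels[!co$mask] == 0))

  # region counts match direct geometric enumeration
  r <- spec$region_defs[[1]]  # ventricle ellipsoid
  g <- spec$grid_shape
  inside <- 0L
  for (z in seq_len(g[3])) for (y in seq_len(g[2])) for (x in seq_len(g[1]))
    if (((x - r$centre[1]) / r$radii[1])^2 + ((y - r$centre[2]) / r$radii[2])^2 +
        ((z - r$centre[3]) / r$radii[3])^2 <= 1) inside <- inside + 1L
  expect_identical(unname(counts["1"]), inside)

  # overlapping definitions are rejected by name
  bad <- spec
  bad$region_defs[[2]]$centre <- bad$region_defs[[1]]$centre
  expect_error(phantom_atlas(bad), "ventricle")
})

test_that("simulated genotypes hit the LD target and are seeded", {
  sim1 <- simulate_genotypes(2500, 20, block_size = 5, within_block_r2 = 0.5,
                             seed = 3)
  sim2 <- simulate_genotypes(2500, 20, block_size = 5, within_block_r2 = 0.5,
                             seed = 3)
  expect_identical(sim1$genotypes$dosages, sim2$genotypes$dosages)

  r2m <- cor(sim1$genotypes$dosages)^2
  blk <- sim1$genotypes$variants$block
  same <- outer(blk, blk, "==") & upper.tri(r2m)
  expect_lt(abs(mean(r2m[same]) - 0.5), 0.1)
  expect_lt(mean(r2m[outer(blk, blk, "!=") & upper.tri(r2m)]), 0.01)

  # r2 = 0: independent variants
  sim0 <- simulate_genotypes(5000, 10, block_size = 5, within_block_r2 = 0,
                             seed = 4)
  r20 <- cor(sim0$genotypes$dosages)^2
  expect_lt(mean(r20[upper.tri(r20)]), 0.01)

  expect_error(simulate_genotypes(100, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(100, 10, maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("planted causal effects act on the named factor", {
  fac <- sample_cohort_factors(500, 2, seed = 5)
  # no causal map: factors independent of dosages
  sim <- simulate_genotypes(500, 50, factors = fac, seed = 6)
  rmax <- max(abs(cor(fac$factor1, sim$genotypes$dosages)))
  expect_lt(rmax, 4.5 / sqrt(500))  # consistent with the null at this n

  # noiseless identity: zero base factor + beta 1 -> correlation 1
  fac0 <- fac
  fac0$factor1[] <- 0
  simc <- simulate_genotypes(500, 50, factors = fac0,
                             causal_map = data.frame(variant = 7L,
                                                     factor = 1L, beta = 1),
                             seed = 6)
  expect_equal(cor(simc$factors$factor1,
                   attr(simc$genotypes, "complete_dosages")[, 7]), 1)
  expect_error(simulate_genotypes(100, 10, factors = fac[1:100, ],
                                  causal_map = data.frame(variant = 99L,
                                                          factor = 1L,
                                                          beta = 1)),
               "exceeds m")
})

test_that("genotype containers validate and round-trip through TSV and VCF", {
  sim <- simulate_genotypes(30, 12, missing_rate = 0.1, seed = 8)
  g <- sim$genotypes
  expect_gt(sum(is.na(g$dosages)), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, tsv)
  g2 <- read_genotypes_tsv(tsv)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$variants$pos, g$variants$pos)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, vcf)
  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  expect_equal(unname(t(ds)), unname(g$dosages))

  expect_error(genotype_set(matrix(3, 2, 1),
                            data.frame(id = "v", chrom = 1, pos = 1,
                                       a1 = "A", a2 = "B")),
               "\\[0, 2\\]")
  expect_error(genotype_set(matrix(1, 2, 2),
                            data.frame(id = c("a", "b"), chrom = 1,
                                       pos = c(5, 5), a1 = "A", a2 = "B")),
               "strictly increasing")
})
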