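test_that("variant QC applies the stage thresholds exactly", {
  # hand-built set: v1 clean; v2 missing 6%; v3 monomorphic; v4 missing 12%;
  # v5 rare but above the MAF floor
  set.seed(6)
  n <- 100
  dd <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.3),
              v3 = 0L, v4 = rbinom(n, 2, 0.4), v5 = rbinom(n, 2, 0.3))
  dd[1:6, "v2"] <- NA
  dd[1:12, "v4"] <- NA
  dd[, "v5"] <- 0L; dd[1, "v5"] <- 1L  # maf 0.005 > 1e-4
  g <- genotype_set(dd, data.frame(id = colnames(dd), chrom = 1L,
                                   pos = (1:5) * 1000L, a1 = "A", a2 = "B"))
  q1 <- qc_genotypes(g, assoc_config(), "qc")
  expect_identical(q1$genotypes$variants$id, c("v1", "v5"))
  expect_identical(q1$report$n_fail_maf, 1L)      # v3
  expect_identical(q1$report$n_fail_missing, 2L)  # v2, v4

  # cohort stage relaxes missingness to < 0.1: v2 returns, v4 stays out
  q2 <- qc_genotypes(g, assoc_config(), "cohort")
  expect_identical(q2$genotypes$variants$id, c("v1", "v2", "v5"))

  gbad <- genotype_set(matrix(0L, 10, 1),
                       data.frame(id = "x", chrom = 1, pos = 1,
                                  a1 = "A", a2 = "B"))
  expect_error(qc_genotypes(gbad, assoc_config(), "qc"), "no variants survive")
})

test_that("kinship exclusion removes cross-cohort relatives", {
  kin <- data.frame(id1 = c("r1", "r2"), id2 = c("d1", "d2"),
                    coefficient = c(0.05, 0.02))
  kept <- exclude_related(c("r1", "r2", "r3"), kin, c("d1", "d2"))
  expect_identical(kept, c("r2", "r3"))  # 0.05 > 0.0442 out, 0.02 in
  expect_identical(exclude_related(c("r1", "r2"), NULL, c("d1")),
                   c("r1", "r2"))
  expect_error(exclude_related(c("x", "r1"), kin, c("x", "d1")), "leakage")
})

test_that("the association scan matches closed forms", {
  # noiseless y = dosage: beta 1, p at the floor
  set.seed(11)
  n <- 60
  dos <- matrix(rbinom(n, 2, 0.4), n, 1)
  g1 <- genotype_set(dos, data.frame(id = "v1", chrom = 1L, pos = 10L,
                                     a1 = "A", a2 = "B"))
  sc <- assoc_scan(as.numeric(dos), g1)
  expect_equal(sc$beta, 1, tolerance = 1e-10)
  expect_lte(sc$p, 1e-300)

  # simple-regression t equals r * sqrt((n-2) / (1-r^2)) on 20 random draws
  for (k in 1:20) {
    d <- rbinom(n, 2, runif(1, 0.2, 0.5))
    y <- 0.2 * d + rnorm(n)
    g <- genotype_set(matrix(d, n, 1),
                      data.frame(id = "v", chrom = 1L, pos = 10L,
                                 a1 = "A", a2 = "B"))
    t_scan <- assoc_scan(y, g)$t
    r <- cor(y, d)
    expect_equal(t_scan, r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
  }

  # collinear covariates are named
  covs <- build_covariates(rnorm(n), rbinom(n, 1, 0.5))
  covs <- cbind(covs, age_copy = covs[, "age"])
  expect_error(assoc_scan(rnorm(n), g1, covs), "age_copy")
})

test_that("missing dosages are dropped casewise", {
  set.seed(12)
  n <- 80
  d <- rbinom(n, 2, 0.4)
  dm <- d; dm[1:10] <- NA
  y <- 0.5 * d + rnorm(n)
  g <- genotype_set(matrix(dm, n, 1),
                    data.frame(id = "v", chrom = 1L, pos = 1L,
                               a1 = "A", a2 = "B"))
  sc <- assoc_scan(y, g)
  expect_identical(sc$n, 70L)
  fit <- summary(lm(y[-(1:10)] ~ d[-(1:10)]))
  expect_equal(sc$beta, unname(fit$coefficients[2, 1]), tolerance = 1e-10)
  expect_equal(sc$se, unname(fit$coefficients[2, 2]), tolerance = 1e-10)
})

test_that("genomic inflation matches its closed forms", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1)
  # chi-square of 1: p = 0.317311 -> lambda = 1 / 0.4549364
  expect_equal(genomic_inflation(rep(0.317311, 3)), 1 / qchisq(0.5, 1),
               tolerance = 1e-4)
  expect_equal(round(genomic_inflation(rep(0.317311, 3)), 4), 2.1981)
  withr::with_seed(77, {
    expect_lt(abs(genomic_inflation(runif(1e5)) - 1), 0.02)
  })
  expect_error(genomic_inflation(numeric(0)), "no p values")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("minP aggregation takes the per-variant minimum across dimensions", {
  tab <- data.frame(variant = rep(c("v1", "v2"), each = 2),
                    chrom = 1L, pos = rep(c(100L, 200L), each = 2),
                    dim = rep(c("D1", "D2"), 2),
                    p = c(0.3, 0.01, 0.2, 0.5))
  mp <- minp_aggregate(tab)
  expect_equal(mp$min_p, c(0.01, 0.2))
  expect_equal(mp$dim, c("D2", "D1"))
  # invariant to dimension order
  mp2 <- minp_aggregate(tab[order(tab$dim, decreasing = TRUE), ])
  expect_equal(mp$min_p, mp2$min_p)
  # single dimension: identity
  one <- tab[tab$dim == "D1", ]
  expect_equal(minp_aggregate(one)$min_p, one$p)
  # mismatched variant sets are rejected
  expect_error(minp_aggregate(tab[-1, ]), "differ")
})

test_that("two-step clumping reproduces the three-variant enumeration", {
  g <- ld_toy_genotypes()
  r2 <- cor(g$dosages)^2
  expect_gt(r2["a", "b"], 0.6)
  expect_lt(r2["a", "cc"], 0.1)
  minp <- data.frame(variant = c("A", "B", "C"), chrom = 1L,
                     pos = g$variants$pos, min_p = c(1e-12, 1e-10, 1e-11),
                     dim = c("D1", "D1", "D2"))
  cfg <- assoc_config(discovery_alpha = 1e-8)
  loci <- clump_loci(minp, g, cfg)
  # step 1 keeps {A, C}; step 2 keeps both as leads; 0.9 Mb gap -> 2 loci
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$leads, c("A", "C"))
  expect_identical(loci$start[1], 1000000L)
  expect_identical(loci$end[1], 1100000L)   # locus 1 spans B through LD
  expect_identical(loci$start[2], 2000000L)
  expect_identical(loci$peak_variant[1], "A")

  # moving C to 1.3 Mb closes the gap below 250 kb: one locus, two leads
  g2 <- ld_toy_genotypes(positions = c(1000000L, 1100000L, 1300000L))
  minp2 <- minp; minp2$pos <- g2$variants$pos
  loci2 <- clump_loci(minp2, g2, cfg)
  expect_identical(nrow(loci2), 1L)
  expect_identical(loci2$n_leads, 2L)

  # a single significant variant: one locus, led by A, spanning B through LD
  minp3 <- minp; minp3$min_p <- c(1e-12, 1, 1)
  loci3 <- clump_loci(minp3, g, cfg)
  expect_identical(nrow(loci3), 1L)
  expect_identical(loci3$leads, "A")
  expect_identical(loci3$end, 1100000L)

  # no significant variants: empty result, not an error
  minp4 <- minp; minp4$min_p <- rep(0.5, 3)
  expect_message(loci4 <- clump_loci(minp4, g, cfg), "no variants")
  expect_identical(nrow(loci4), 0L)
})

test_that("clumping the members of clumped loci is idempotent", {
  withr::with_seed(21, {
    sim <- simulate_genotypes(1500, 60, block_size = 6, within_block_r2 = 0.6,
                              seed = 31)
    g <- sim$genotypes
    p <- runif(60)
    p[c(8, 9, 40)] <- c(1e-12, 1e-11, 1e-13)
    minp <- data.frame(variant = g$variants$id, chrom = g$variants$chrom,
                       pos = g$variants$pos, min_p = p, dim = "D1")
    cfg <- assoc_config(discovery_alpha = 1e-8)
    l1 <- clump_loci(minp, g, cfg)
    members <- unique(unlist(l1$members))
    keep <- g$variants$id %in% members
    l2 <- clump_loci(minp[minp$variant %in% members, ],
                     subset_variants(g, keep), cfg)
    expect_equal(l1[c("chrom", "start", "end", "leads", "n_leads")],
                 l2[c("chrom", "start", "end", "leads", "n_leads")])
  })
})

test_that("replication thresholds follow the lead count", {
  # threshold arithmetic at a typical lead count: 126 leads -> 0.05/126
  expect_equal(0.05 / 126, 3.968254e-4, tolerance = 1e-6)

  g <- ld_toy_genotypes()
  minp <- data.frame(variant = c("A", "B", "C"), chrom = 1L,
                     pos = g$variants$pos, min_p = c(1e-12, 1e-10, 1e-11),
                     dim = c("D1", "D1", "D2"))
  loci <- clump_loci(minp, g, assoc_config(discovery_alpha = 1e-8))
  mk_rep <- function(pA, pC) data.frame(
    variant = c("A", "C"), chrom = 1L, pos = c(1, 3), dim = c("D1", "D2"),
    a1 = "A", a2 = "B", beta = 1, se = 1, t = 1, p = c(pA, pC), n = 100L)
  # 2 leads -> threshold 0.025: p = 0.03 fails, p = 0.01 passes
  r <- test_replication(loci, mk_rep(0.03, 0.01))
  expect_identical(r$replicated, c(FALSE, TRUE))
  expect_equal(attr(r, "rep_threshold"), 0.025)
  # missing lead: warning, unreplicated
  expect_warning(r2 <- test_replication(loci, mk_rep(0.01, 0.01)[1, ]),
                 "missing")
  expect_identical(r2$replicated, c(TRUE, FALSE))
})

test_that("meta-analysis combines z scores with sqrt(n) weights", {
  base <- data.frame(variant = "v", chrom = 1L, pos = 1L, dim = "D1",
                     a1 = "A", a2 = "B", beta = 1, se = 1, t = 2,
                     p = 2 * pnorm(-2), n = 400L)
  m <- meta_combine(base, base)
  expect_equal(m$z_meta, sqrt(2) * 2, tolerance = 1e-10)

  b2 <- base; b2$p <- 1; b2$beta <- 0.0
  m2 <- meta_combine(transform(base, p = 2 * pnorm(-2)), b2)
  expect_equal(m2$z_meta, 2 / sqrt(2), tolerance = 1e-6)
  expect_equal(round(m2$z_meta, 5), 1.41421)

  # allele flip in cohort 2 is corrected before combination
  flip <- base; flip$a1 <- "B"; flip$a2 <- "A"; flip$beta <- -1
  m3 <- meta_combine(base, flip)
  expect_equal(m3$z_meta, m$z_meta, tolerance = 1e-12)

  # unalignable alleles are dropped with a warning
  bad <- base; bad$a1 <- "X"; bad$a2 <- "Y"
  expect_warning(m4 <- meta_combine(base, bad), "unalignable")
  expect_identical(nrow(m4), 0L)
})

test_that("locus overlap respects chromosome and padding", {
  a <- data.frame(chrom = c(1L, 1L, 2L), start = c(100e3, 900e3, 100e3),
                  end = c(200e3, 950e3, 200e3))
  b <- data.frame(chrom = 1L, start = 400e3, end = 500e3)
  ov <- loci_overlap(a, b, pad_kb = 125)
  expect_identical(ov, c(FALSE, FALSE, FALSE))
  ov2 <- loci_overlap(a, b, pad_kb = 425)
  expect_identical(ov2, c(TRUE, TRUE, FALSE))
})
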