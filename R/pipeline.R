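#' Demo pipeline configuration
#'
#' Desk-scale study conditions for the end-to-end demonstration: a model
#' development cohort of phantoms for autoencoder training, a disjoint GWAS
#' cohort split 65/35 into discovery and replication, LD-structured
#' genotypes with one planted causal variant acting on the ventricle factor,
#' and the interpretation / association post-processing stages. All stage
#' seeds derive from the single run seed.
#'
#' @param seed Run seed.
#' @param out_dir Output directory for artifacts (created if needed).
#' @param n_train Model-development subjects.
#' @param n_gwas GWAS subjects (split into discovery and replication).
#' @param grid_shape Phantom grid.
#' @param latent_dim,n_blocks,channel_widths,epochs,batch_size,learning_rate
#'   Autoencoder settings (see [ae_config()]).
#' @param m_variants,block_size,within_block_r2,maf_range,missing_rate
#'   Genotype simulation settings (see [simulate_genotypes()]).
#' @param causal_variant Index of the planted causal variant.
#' @param causal_factor Generative factor it acts on.
#' @param causal_frac_var Fraction of the factor's variance explained by the
#'   causal variant.
#' @param discovery_frac Fraction of the GWAS cohort used for discovery.
#' @param alpha Desk-scale significance threshold for clumping.
#' @param perdi_n,smooth_sigma PerDI settings.
#' @return A list of class `demo_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = file.path(tempdir(), "udip_demo"),
                        n_train = 800L, n_gwas = 2000L,
                        grid_shape = c(32L, 38L, 32L), latent_dim = 16L,
                        n_blocks = 3L, channel_widths = c(2L, 6L, 12L, 16L),
                        epochs = 40L, batch_size = 16L, learning_rate = 1e-3,
                        m_variants = 300L, block_size = 10L,
                        within_block_r2 = 0.5, maf_range = c(0.05, 0.5),
                        missing_rate = 0.02, causal_variant = 155L,
                        causal_factor = 1L, causal_frac_var = 0.05,
                        discovery_frac = 0.65, alpha = 1e-5,
                        perdi_n = 500L, smooth_sigma = 3) {
  structure(as.list(environment()), class = "demo_config")
}

# beta such that beta^2 * var(dosage) is `frac` of the resulting factor
# variance, the base factor having unit variance
causal_beta <- function(dosage_var, frac) sqrt(frac / ((1 - frac) * dosage_var))

#' Run the end-to-end demonstration pipeline
#'
#' simulate -> normalise -> train -> encode -> interpret (PerDI + atlas
#' enrichment for the factor-linked dimensions) -> associate (discovery /
#' replication) -> minP -> clump -> replicate -> meta-analyse. Writes TSV /
#' NIfTI artifacts and a JSON manifest to `config$out_dir` and returns all
#' intermediate objects.
#'
#' @param config A [demo_config()].
#' @param progress Print stage messages.
#' @return A list with the cohorts, model, latents, interpretation tables,
#'   association tables, loci and manifest (invisibly).
#' @export
run_demo <- function(config = demo_config(), progress = TRUE) {
  stopifnot(inherits(config, "demo_config"))
  say <- function(...) if (progress) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  t0 <- proc.time()[3]

  ## 1. cohorts -------------------------------------------------------------
  n_total <- config$n_train + config$n_gwas
  say("[1/7] simulating %d subjects (%d train, %d GWAS)", n_total,
      config$n_train, config$n_gwas)
  fac <- sample_cohort_factors(n_total, f = 2L, seed = seed)
  idx_train <- seq_len(config$n_train)
  idx_gwas <- config$n_train + seq_len(config$n_gwas)

  sim <- simulate_genotypes(config$n_gwas, config$m_variants,
                            block_size = config$block_size,
                            within_block_r2 = config$within_block_r2,
                            maf_range = config$maf_range,
                            missing_rate = config$missing_rate,
                            factors = fac[idx_gwas, ], seed = seed + 1L)
  geno <- sim$genotypes
  dvar <- var(attr(geno, "complete_dosages")[, config$causal_variant])
  beta <- causal_beta(dvar, config$causal_frac_var)
  fcol <- sprintf("factor%d", config$causal_factor)
  fac[idx_gwas, fcol] <- sim$factors[[fcol]] +
    beta * attr(geno, "complete_dosages")[, config$causal_variant]

  spec <- phantom_spec(grid_shape = config$grid_shape)
  cohort <- suppressWarnings(render_cohort(fac, spec, seed = seed + 2L))
  cohort <- znormalize_cohort(cohort)
  atlas <- phantom_atlas(spec)
  sub_cohort <- function(ix) {
    co <- cohort
    co$intensities <- co$intensities[, ix, drop = FALSE]
    co$subject_ids <- co$subject_ids[ix]
    co
  }
  train_cohort <- sub_cohort(idx_train)
  gwas_cohort <- sub_cohort(idx_gwas)

  ## 2. autoencoder ---------------------------------------------------------
  say("[2/7] training autoencoder (%d epochs, latent %d)", config$epochs,
      config$latent_dim)
  acfg <- ae_config(config$grid_shape, latent_dim = config$latent_dim,
                    n_blocks = config$n_blocks,
                    channel_widths = config$channel_widths,
                    learning_rate = config$learning_rate, seed = seed + 3L)
  model <- build_autoencoder(acfg)
  model <- ae_train(model, train_cohort, epochs = config$epochs,
                    val_fraction = 0.25, batch_size = config$batch_size,
                    seed = seed + 3L)

  ## 3. encode + reconstruction check ---------------------------------------
  say("[3/7] encoding cohorts")
  z_gwas <- encode_volumes(model, gwas_cohort)
  gap_n <- min(200L, config$n_gwas)
  gap_ix <- with_seed(seed + 4L, sample.int(config$n_gwas, gap_n))
  gap <- reconstruction_gap(model, sub_cohort(idx_gwas[gap_ix]),
                            seed = seed + 4L)

  ## 4. interpretation ------------------------------------------------------
  say("[4/7] decoder interpretation (PerDI + enrichment)")
  fac_gwas <- fac[idx_gwas, ]
  cors <- cbind(factor1 = as.numeric(abs(cor(z_gwas, fac_gwas$factor1))),
                factor2 = as.numeric(abs(cor(z_gwas, fac_gwas$factor2))))
  key_dims <- apply(cors, 2, which.max)
  tmaps <- list()
  profiles <- list()
  for (f in seq_along(key_dims)) {
    d <- key_dims[f]
    tm <- perdi_tmap(model, z_gwas, d, n_subjects = config$perdi_n,
                     smooth_sigma = config$smooth_sigma, seed = seed + 5L,
                     mask = cohort$mask)
    tmaps[[f]] <- tm
    profiles[[f]] <- region_profile(tm, atlas)
  }
  names(tmaps) <- names(profiles) <- names(key_dims)

  ## 5. association ---------------------------------------------------------
  say("[5/7] association scans")
  acfg2 <- assoc_config(d_total = config$latent_dim,
                        discovery_alpha = config$alpha)
  geno <- qc_genotypes(geno, acfg2, stage = "qc")$genotypes
  n_disc <- round(config$discovery_frac * config$n_gwas)
  disc_ix <- with_seed(seed + 6L, sample.int(config$n_gwas, n_disc))
  rep_ix <- setdiff(seq_len(config$n_gwas), disc_ix)
  # phantom subjects are unrelated; the kinship exclusion still runs so the
  # cohort-independence path is exercised
  rep_ids <- exclude_related(gwas_cohort$subject_ids[rep_ix],
                             kinship = NULL,
                             gwas_cohort$subject_ids[disc_ix],
                             kinship_max = acfg2$kinship_max)
  rep_ix <- rep_ix[gwas_cohort$subject_ids[rep_ix] %in% rep_ids]
  covs <- build_covariates(fac_gwas$age_like, fac_gwas$sex_like)
  scan_cohort <- function(ix) {
    g <- qc_genotypes(subset_subjects(geno, ix), acfg2,
                      stage = "cohort")$genotypes
    assoc_scan(z_gwas[ix, , drop = FALSE], g, covs[ix, , drop = FALSE], acfg2)
  }
  disc <- scan_cohort(disc_ix)
  repl <- scan_cohort(rep_ix)
  lambda_by_dim <- vapply(split(disc$p, disc$dim), genomic_inflation,
                          numeric(1))

  ## 6. loci ----------------------------------------------------------------
  say("[6/7] minP aggregation, clumping, replication, meta-analysis")
  minp <- minp_aggregate(disc)
  loci <- clump_loci(minp, subset_subjects(geno, disc_ix), acfg2)
  if (nrow(loci) > 0) loci <- test_replication(loci, repl)
  meta <- meta_combine(disc, repl)

  ## 7. artifacts -----------------------------------------------------------
  say("[7/7] writing artifacts to %s", config$out_dir)
  out <- function(...) file.path(config$out_dir, ...)
  write.table(fac, out("factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(subject_id = rownames(z_gwas), z_gwas),
              out("latents.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotypes_tsv(geno, out("genotypes.tsv"))
  write_genotypes_vcf(geno, out("genotypes.vcf"))
  write_atlas(atlas, out("atlas.nii.gz"), out("atlas_labels.tsv"))
  write_volume(cohort_volume(cohort, 1L), out("example_volume.nii.gz"))
  for (f in names(tmaps))
    write_tmap(tmaps[[f]], out(sprintf("tmap_dim%d_%s.nii.gz",
                                       key_dims[[f]], f)))
  for (f in names(profiles))
    write.table(profiles[[f]], out(sprintf("enrichment_%s.tsv", f)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("disc", "repl")) {
    tb <- get(nm)
    write.table(tb[setdiff(names(tb), "members")],
                out(sprintf("assoc_%s.tsv",
                            c(disc = "discovery", repl = "replication")[nm])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(loci) > 0)
    write.table(loci[setdiff(names(loci), "members")], out("loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, out("meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("udip")),
    seed = seed,
    stages = list(
      simulate = list(n_total = n_total, n_train = config$n_train,
                      n_gwas = config$n_gwas, m_variants = config$m_variants,
                      causal_variant = config$causal_variant,
                      causal_beta = beta),
      train = list(epochs = config$epochs, latent_dim = config$latent_dim,
                   best_epoch = model$best_epoch,
                   best_val_loss = min(model$history$val_loss),
                   first_val_loss = model$history$val_loss[1]),
      reconstruction = list(matched = gap$matched,
                            random_pair = gap$random_pair),
      interpretation = list(key_dims = as.list(key_dims),
                            max_abs_cor = as.list(apply(cors, 2, max)),
                            top_region = lapply(profiles,
                                                function(p) p$region[1])),
      association = list(n_discovery = length(disc_ix),
                         n_replication = length(rep_ix),
                         alpha = config$alpha,
                         lambda_by_dim = as.list(lambda_by_dim),
                         n_significant_pairs = sum(disc$p < config$alpha,
                                                   na.rm = TRUE),
                         n_loci = nrow(loci),
                         n_replicated = if (nrow(loci)) sum(loci$replicated)
                                        else 0L)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done in %.1f min", (proc.time()[3] - t0) / 60)
  invisible(list(config = config, factors = fac, spec = spec, atlas = atlas,
                 genotypes = geno, model = model, latents = z_gwas,
                 gap = gap, factor_cors = cors, key_dims = key_dims,
                 tmaps = tmaps, profiles = profiles,
                 discovery = disc, replication = repl,
                 lambda_by_dim = lambda_by_dim, minp = minp, loci = loci,
                 meta = meta, causal_beta = beta,
                 discovery_idx = disc_ix, replication_idx = rep_ix,
                 manifest = manifest))
}

#' Planted-variant recovery simulation
#'
#' Repeats, under different seeds, the association half of the pipeline on
#' the generative factor itself: simulate an LD-structured cohort with one
#' causal variant explaining `frac_var` of the factor's variance, scan
#' discovery and replication cohorts, clump, and check that the causal
#' variant is significant, that its clumped locus covers the causal
#' position, and that the locus replicates.
#'
#' @param n_runs Number of seeded repetitions.
#' @param n Subjects per run.
#' @param m Variants per run.
#' @param frac_var Causal fraction of factor variance.
#' @param alpha Scaled significance threshold.
#' @param seed Base seed; run k uses `seed + k`.
#' @param ... Passed to [simulate_genotypes()].
#' @return Data.frame with one row per run: `significant`, `locus_covers`,
#'   `replicated`.
#' @export
recovery_runs <- function(n_runs = 20L, n = 2000L, m = 200L,
                          frac_var = 0.05, alpha = 1e-5, seed = 1000L, ...) {
  res <- lapply(seq_len(n_runs), function(k) {
    s <- seed + k
    fac <- sample_cohort_factors(n, 2L, seed = s)
    causal <- with_seed(s * 7L, sample.int(m, 1L))
    sim <- simulate_genotypes(n, m, factors = fac, seed = s, ...)
    geno <- sim$genotypes
    dvar <- var(attr(geno, "complete_dosages")[, causal])
    beta <- causal_beta(dvar, frac_var)
    y <- fac$factor1 + beta * attr(geno, "complete_dosages")[, causal]
    cfg <- assoc_config(discovery_alpha = alpha)
    geno <- qc_genotypes(geno, cfg, stage = "qc")$genotypes
    disc_ix <- with_seed(s + 1L, sample.int(n, round(0.65 * n)))
    rep_ix <- setdiff(seq_len(n), disc_ix)
    covs <- build_covariates(fac$age_like, fac$sex_like)
    disc <- assoc_scan(y[disc_ix], subset_subjects(geno, disc_ix),
                       covs[disc_ix, ], cfg)
    repl <- assoc_scan(y[rep_ix], subset_subjects(geno, rep_ix),
                       covs[rep_ix, ], cfg)
    causal_id <- sprintf("var%05d", causal)
    causal_pos <- geno$variants$pos[match(causal_id, geno$variants$id)]
    sig <- isTRUE(disc$p[disc$variant == causal_id] < alpha)
    minp <- minp_aggregate(disc)
    loci <- suppressMessages(clump_loci(minp, subset_subjects(geno, disc_ix),
                                        cfg))
    covers <- FALSE
    replicated <- FALSE
    if (nrow(loci) > 0) {
      hit <- which(loci$start <= causal_pos & loci$end >= causal_pos)
      covers <- length(hit) > 0
      loci <- test_replication(loci, repl)
      if (covers) replicated <- isTRUE(loci$replicated[hit[1]])
    }
    data.frame(run = k, significant = sig, locus_covers = covers,
               replicated = replicated)
  })
  do.call(rbind, res)
}
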