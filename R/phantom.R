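#' Phantom cohort specification
#'
#' Describes the synthetic brain-like phantom: a brain ellipsoid ("cortex")
#' containing an interior ellipsoid ("ventricle") and two fixed lateral
#' spheres ("subcortical" nuclei). Two generative factors drive anatomy:
#' factor 1 enlarges the ventricle and darkens its interior (larger
#' ventricles carry purer, darker CSF - the dominant dark-region signal a
#' reconstruction loss captures), and factor 2 scales the subcortical
#' nuclei's size (their T1 intensity contrast against cortex is subtle, so
#' their baseline intensity sits only moderately above cortex and stays
#' fixed). Per-subject nuisance
#' jitter of region centres, radii and intensities supplies the anatomical
#' variability of a real cohort. Background voxels are exactly 0; Gaussian
#' noise is added inside the brain mask only. The geometry mirrors the
#' targets of atlas enrichment: ventricular, subcortical and cortical
#' compartments at desk scale.
#'
#' @param grid_shape Voxel grid dimensions (3 integers).
#' @param brain_radii Semi-axes of the brain ellipsoid in voxels; default
#'   `grid_shape/2 - 3`.
#' @param noise_sd Standard deviation of additive Gaussian noise inside the
#'   mask, in raw intensity units (tissue intensities are 0.03-0.8).
#' @param intensities Named list of tissue intensities (`cortex`,
#'   `ventricle`, `subcortical`).
#' @param size_scale Fractional change of the ventricle semi-axes per unit
#'   of its driving factor.
#' @param ventricle_intensity_scale Fractional darkening of the ventricle
#'   interior per unit of the same factor (intensity is the dominant
#'   voxel-wise signature, extent the secondary one).
#' @param subcort_size_scale Fractional change of the subcortical sphere
#'   radii per unit of the second factor.
#' @param factor_clamp Factors driving geometry/intensity are clamped to
#'   `[-factor_clamp, factor_clamp]` (with a warning) so regions can neither
#'   vanish nor breach the brain boundary.
#' @param centre_jitter_sd Per-subject random displacement (sd, voxels) of
#'   each region centre - anatomical nuisance variation beyond the factors.
#' @param radius_jitter Per-subject relative sd of region radii.
#' @param intensity_jitter Per-subject relative sd of tissue intensities
#'   (cortex included).
#' @param texture_amplitude Amplitude (intensity units) of a smooth
#'   per-subject random texture field added inside the brain - the
#'   irreducible anatomical variability of a real population. Together with
#'   the centre/radius jitters this gives every voxel genuine
#'   between-subject variability; without it the paired statistics of
#'   decoder interpretation face degenerate near-zero-variance denominators
#'   that no real cohort shows.
#' @param texture_scale Gaussian correlation length (voxels) of the texture
#'   field.
#' @return Object of class `phantom_spec` with a `region_defs` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 38L, 32L), brain_radii = NULL,
                         noise_sd = 0.05,
                         intensities = list(cortex = 0.6, ventricle = 0.3,
                                            subcortical = 0.75),
                         size_scale = 0.05, ventricle_intensity_scale = -0.45,
                         subcort_size_scale = 0.2,
                         factor_clamp = 2, centre_jitter_sd = 0.3,
                         radius_jitter = 0.03, intensity_jitter = 0.02,
                         texture_amplitude = 0, texture_scale = 2.5) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 12L), noise_sd >= 0,
            size_scale > 0, ventricle_intensity_scale < 0,
            subcort_size_scale > 0, factor_clamp > 0,
            centre_jitter_sd >= 0, radius_jitter >= 0, intensity_jitter >= 0,
            texture_amplitude >= 0, texture_scale > 0)
  if (is.null(brain_radii)) brain_radii <- grid_shape / 2 - 3
  brain_radii <- as.numeric(brain_radii)
  stopifnot(all(brain_radii >= 3), all(brain_radii <= grid_shape / 2))
  centre <- (grid_shape + 1) / 2
  rx <- brain_radii[1]
  region_defs <- list(
    # the ventricle factor moves both extent and darkness: larger ventricles
    # carry purer CSF, so the interior also darkens as they grow
    list(name = "ventricle", type = "ellipsoid", centre = centre,
         radii = 0.33 * brain_radii, intensity = intensities$ventricle,
         size_factor = 1L, size_scale = size_scale,
         intensity_factor = 1L, intensity_scale = ventricle_intensity_scale),
    list(name = "subcort_l", type = "sphere",
         centre = centre + c(-0.64 * rx, 0, 0), radii = rep(0.22 * rx, 3),
         intensity = intensities$subcortical, size_factor = 2L,
         size_scale = subcort_size_scale, intensity_factor = NA_integer_),
    list(name = "subcort_r", type = "sphere",
         centre = centre + c(0.64 * rx, 0, 0), radii = rep(0.22 * rx, 3),
         intensity = intensities$subcortical, size_factor = 2L,
         size_scale = subcort_size_scale, intensity_factor = NA_integer_))
  structure(list(grid_shape = grid_shape, brain_radii = brain_radii,
                 centre = centre, noise_sd = noise_sd,
                 intensities = intensities, region_defs = region_defs,
                 factor_clamp = factor_clamp,
                 centre_jitter_sd = centre_jitter_sd,
                 radius_jitter = radius_jitter,
                 intensity_jitter = intensity_jitter,
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale),
            class = "phantom_spec")
}

#' Sample cohort generative factors and covariates
#'
#' Draws `f` independent standard-normal anatomical factors per subject,
#' plus an age-like continuous covariate and a binary sex-like covariate.
#'
#' @param n Number of subjects (>= 1).
#' @param f Number of generative factors (>= 2).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A data.frame with columns `subject_id`, `factor1..factorf`,
#'   `age_like`, `sex_like`.
#' @export
sample_cohort_factors <- function(n, f = 2L, seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  if (length(f) != 1L || is.na(f) || f < 2) stop("f must be at least 2")
  n <- as.integer(n); f <- as.integer(f)
  with_seed(seed, {
    fac <- matrix(rnorm(n * f), n, f,
                  dimnames = list(NULL, sprintf("factor%d", seq_len(f))))
    data.frame(subject_id = sprintf("S%05d", seq_len(n)), fac,
               age_like = rnorm(n, mean = 60, sd = 7.5),
               sex_like = rbinom(n, 1L, 0.5),
               stringsAsFactors = FALSE)
  })
}

# squared normalised ellipsoid distance field: value <= s^2 means inside the
# region scaled by s. Returned as a vector over the flattened grid.
region_distance2 <- function(spec, centre, radii) {
  g <- spec$grid_shape
  x <- (seq_len(g[1]) - centre[1]) / radii[1]
  y <- (seq_len(g[2]) - centre[2]) / radii[2]
  z <- (seq_len(g[3]) - centre[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  as.numeric(d2)
}

phantom_fields <- function(spec) {
  brain <- region_distance2(spec, spec$centre, spec$brain_radii) <= 1
  fields <- lapply(spec$region_defs, function(r)
    region_distance2(spec, r$centre, r$radii))
  list(brain = brain, fields = fields)
}

# clamp a factor value, counting events in `counter` (an environment) so the
# caller can emit one summary warning per cohort
clamp_factor <- function(value, clamp, counter = NULL) {
  if (any(abs(value) > clamp) && !is.null(counter))
    counter$n <- counter$n + sum(abs(value) > clamp)
  pmin(pmax(value, -clamp), clamp)
}

#' Render a cohort of phantom volumes
#'
#' Produces one 3D volume per subject. The ventricle's semi-axes scale as
#' `1 + size_scale * factor1` (so its voxel count grows monotonically with
#' the factor over the clamp-free range) while its interior darkens with the
#' same factor; the subcortical sphere radii scale as
#' `1 + subcort_size_scale * factor2`. Voxels outside the brain
#' ellipsoid are exactly 0.
#'
#' @param factors Data.frame from [sample_cohort_factors()] (or any
#'   data.frame with `factor1`, `factor2`, `subject_id` columns).
#' @param spec A [phantom_spec()].
#' @param seed Seed for the rendering noise.
#' @return An object of class `phantom_cohort`: list with `intensities`
#'   (`nvox x N` matrix), shared logical `mask` array, `shape`,
#'   `subject_ids` and the `spec`.
#' @export
render_cohort <- function(factors, spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), is.data.frame(factors))
  fcols <- grep("^factor[0-9]+$", names(factors), value = TRUE)
  if (length(fcols) < 2L) stop("factors table needs at least factor1, factor2")
  pf <- phantom_fields(spec)
  jitterless <- spec$centre_jitter_sd == 0 && spec$radius_jitter == 0
  n <- nrow(factors)
  nvox <- prod(spec$grid_shape)
  xmat <- matrix(0, nvox, n)
  clamped <- new.env()
  clamped$n <- 0L
  with_seed(seed, {
    for (i in seq_len(n)) {
      v <- rep(0, nvox)
      cortex_i <- spec$intensities$cortex *
        (1 + rnorm(1, sd = spec$intensity_jitter))
      v[pf$brain] <- cortex_i
      for (k in seq_along(spec$region_defs)) {
        r <- spec$region_defs[[k]]
        s <- 1
        if (!is.na(r$size_factor)) {
          fv <- clamp_factor(factors[[fcols[r$size_factor]]][i],
                             spec$factor_clamp, clamped)
          s <- 1 + r$size_scale * fv
        }
        inten <- r$intensity
        if (!is.na(r$intensity_factor)) {
          fv <- clamp_factor(factors[[fcols[r$intensity_factor]]][i],
                             spec$factor_clamp, clamped)
          inten <- r$intensity * (1 + r$intensity_scale * fv)
        }
        inten <- inten * (1 + rnorm(1, sd = spec$intensity_jitter))
        if (jitterless) {
          field <- pf$fields[[k]]
        } else {
          field <- region_distance2(
            spec, r$centre + rnorm(3, sd = spec$centre_jitter_sd),
            r$radii * (1 + rnorm(1, sd = spec$radius_jitter)))
        }
        v[field <= s^2 & pf$brain] <- inten
      }
      if (spec$texture_amplitude > 0) {
        tex <- smooth_volume(array(rnorm(nvox), spec$grid_shape),
                             spec$texture_scale)
        tex <- as.numeric(tex)[pf$brain]
        v[pf$brain] <- v[pf$brain] +
          spec$texture_amplitude * tex / sd(tex)
      }
      if (spec$noise_sd > 0)
        v[pf$brain] <- v[pf$brain] + rnorm(sum(pf$brain), sd = spec$noise_sd)
      xmat[, i] <- v
    }
  })
  if (clamped$n > 0)
    warning(sprintf("%d factor value(s) beyond +/-%g clamped (region size/intensity kept within bounds)",
                    clamped$n, spec$factor_clamp), call. = FALSE)
  structure(list(intensities = xmat,
                 mask = array(pf$brain, spec$grid_shape),
                 shape = spec$grid_shape,
                 subject_ids = as.character(factors$subject_id),
                 spec = spec),
            class = "phantom_cohort")
}

#' Render a single phantom
#'
#' @param factors One-row data.frame (or the full table plus `row`).
#' @param spec A [phantom_spec()].
#' @param seed Noise seed.
#' @param row Which row of `factors` to render.
#' @return A [masked_volume].
#' @export
render_phantom <- function(factors, spec = phantom_spec(), seed = 1L, row = 1L) {
  co <- render_cohort(factors[row, , drop = FALSE], spec, seed)
  cohort_volume(co, 1L)
}

#' Extract one subject from a phantom cohort as a masked volume
#' @param cohort A `phantom_cohort`.
#' @param i Subject index.
#' @return A [masked_volume].
#' @export
cohort_volume <- function(cohort, i) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  masked_volume(array(cohort$intensities[, i], cohort$shape),
                mask = cohort$mask)
}

#' Z-normalise every volume of a cohort
#'
#' Applies the background-excluded z-score normalisation (see
#' [znormalize()]) column-wise, keeping the compact matrix representation.
#'
#' @param cohort A `phantom_cohort`.
#' @return The cohort with normalised intensities.
#' @export
znormalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  m <- as.logical(cohort$mask)
  x <- cohort$intensities
  for (i in seq_len(ncol(x))) {
    v <- x[m, i]
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s < 1e-12) stop("constant masked intensities in volume ", i)
    x[m, i] <- (v - mu) / s
  }
  cohort$intensities <- x
  cohort
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d subjects, grid %s, %d brain voxels\n",
              ncol(x$intensities), paste(x$shape, collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Region atlas matching the phantom template
#'
#' Labels the zero-factor template geometry: each explicit region gets its
#' own integer label (in `region_defs` order, starting at 1) and the
#' remaining brain tissue is labelled as cortex. 0 is background. Region
#' definitions that overlap at template scale are rejected.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_atlas`: list with integer `labels`
#'   array and `names` (named integer vector label -> region name).
#' @export
phantom_atlas <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  pf <- phantom_fields(spec)
  nvox <- prod(spec$grid_shape)
  lab <- integer(nvox)
  for (k in seq_along(spec$region_defs)) {
    inside <- pf$fields[[k]] <= 1
    hit <- inside & lab > 0L
    if (any(hit)) {
      other <- spec$region_defs[[unique(lab[hit])[1]]]$name
      stop("overlapping region definitions: ",
           spec$region_defs[[k]]$name, " and ", other)
    }
    lab[inside] <- k
  }
  cortex_label <- length(spec$region_defs) + 1L
  lab[pf$brain & lab == 0L] <- cortex_label
  lab[!pf$brain] <- 0L
  nm <- c(vapply(spec$region_defs, `[[`, "", "name"), "cortex")
  names(nm) <- as.character(seq_along(nm))
  structure(list(labels = array(lab, spec$grid_shape), names = nm,
                 shape = spec$grid_shape),
            class = "phantom_atlas")
}

#' Simulate genotypes with block LD structure
#'
#' Variants are organised in consecutive blocks. Within a block all variants
#' share an allele frequency and are generated by copying a latent block
#' haplotype with a resampling probability tuned so that the expected
#' pairwise dosage r-squared equals `within_block_r2`; across blocks variants
#' are independent. Optional planted effects add `beta * dosage` of a causal
#' variant to a named generative factor (before any missingness is applied),
#' and uniform missingness exercises the downstream quality-control filters.
#'
#' @param n Subjects.
#' @param m Variants.
#' @param block_size Variants per LD block.
#' @param within_block_r2 Target pairwise dosage r-squared within a block,
#'   in `[0, 1)`.
#' @param maf_range Allele-frequency range (each block draws one frequency
#'   uniformly from it); must lie in (0, 0.5].
#' @param causal_map Optional data.frame with columns `variant`, `factor`,
#'   `beta`.
#' @param missing_rate Per-genotype probability of a missing dosage.
#' @param factors Optional factors table to receive the planted effects.
#' @param chrom Chromosome id for all variants.
#' @param spacing_bp Base-pair spacing between adjacent variants.
#' @param seed Integer seed.
#' @return List with `genotypes` (a `genotype_set`) and `factors` (updated
#'   table, or `NULL` if none given).
#' @export
simulate_genotypes <- function(n, m, block_size = 10L, within_block_r2 = 0.5,
                               maf_range = c(0.05, 0.5), causal_map = NULL,
                               missing_rate = 0, factors = NULL,
                               chrom = 1L, spacing_bp = 20000L, seed = 1L) {
  stopifnot(n >= 2, m >= 1, block_size >= 1,
            within_block_r2 >= 0, within_block_r2 < 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie in (0, 0.5]")
  if (!is.null(causal_map)) {
    stopifnot(all(c("variant", "factor", "beta") %in% names(causal_map)))
    if (any(causal_map$variant > m)) stop("causal variant index exceeds m")
  }
  block <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  # per-haplotype copy fidelity: dosage correlation between two variants of
  # one block is (1-eps)^2 per haplotype, so r2 = (1-eps)^4
  eps <- 1 - within_block_r2^(1 / 4)
  dose <- with_seed(seed, {
    d <- matrix(0L, n, m)
    for (b in unique(block)) {
      js <- which(block == b)
      p <- runif(1, maf_range[1], maf_range[2])
      for (h in 1:2) {
        z <- rbinom(n, 1L, p)
        for (j in js) {
          keep <- runif(n) >= eps
          a <- ifelse(keep, z, rbinom(n, 1L, p))
          d[, j] <- d[, j] + a
        }
      }
    }
    d
  })
  if (!is.null(factors) && !is.null(causal_map)) {
    for (k in seq_len(nrow(causal_map))) {
      fc <- sprintf("factor%d", causal_map$factor[k])
      if (!fc %in% names(factors)) stop("no such factor column: ", fc)
      factors[[fc]] <- factors[[fc]] +
        causal_map$beta[k] * dose[, causal_map$variant[k]]
    }
  }
  observed <- dose
  if (missing_rate > 0) {
    miss <- with_seed(seed + 1L, matrix(runif(n * m) < missing_rate, n, m))
    observed[miss] <- NA_integer_
  }
  geno <- genotype_set(
    dosages = observed,
    variants = data.frame(
      id = sprintf("var%05d", seq_len(m)), chrom = as.integer(chrom),
      pos = as.integer(spacing_bp) * seq_len(m),
      a1 = "A", a2 = "B", block = block, stringsAsFactors = FALSE),
    subject_ids = if (!is.null(factors)) as.character(factors$subject_id)
                  else sprintf("S%05d", seq_len(n)))
  attr(geno, "complete_dosages") <- dose
  list(genotypes = geno, factors = factors)
}

#' Genotype dosage container
#'
#' @param dosages `N x M` dosage matrix, values in `[0, 2]` or `NA`.
#' @param variants Data.frame with `id`, `chrom`, `pos`, `a1`, `a2` (and any
#'   extra columns); positions must be strictly increasing within a
#'   chromosome.
#' @param subject_ids Character vector of length `N`.
#' @return Object of class `genotype_set`. Observed minor-allele frequency
#'   and missing rate are computed and stored per variant.
#' @export
genotype_set <- function(dosages, variants, subject_ids = NULL) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages),
            all(c("id", "chrom", "pos", "a1", "a2") %in% names(variants)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%05d", seq_len(nrow(dosages)))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  variants$missing_rate <- colMeans(is.na(dosages))
  structure(list(dosages = dosages, variants = variants,
                 subject_ids = as.character(subject_ids)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d subjects x %d variants (%d chromosome(s))\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))))
  invisible(x)
}

#' Subset a genotype set by variant index
#' @param geno A `genotype_set`.
#' @param keep Integer or logical index over variants.
#' @return A `genotype_set` with the selected variants.
#' @export
subset_variants <- function(geno, keep) {
  stopifnot(inherits(geno, "genotype_set"))
  genotype_set(geno$dosages[, keep, drop = FALSE],
               geno$variants[keep, setdiff(names(geno$variants),
                                           c("maf", "missing_rate")),
                             drop = FALSE],
               geno$subject_ids)
}

#' Subset a genotype set by subject index
#' @param geno A `genotype_set`.
#' @param keep Integer or logical index over subjects.
#' @return A `genotype_set` with the selected subjects (per-variant MAF and
#'   missing rate are recomputed).
#' @export
subset_subjects <- function(geno, keep) {
  stopifnot(inherits(geno, "genotype_set"))
  genotype_set(geno$dosages[keep, , drop = FALSE],
               geno$variants[, setdiff(names(geno$variants),
                                       c("maf", "missing_rate")),
                             drop = FALSE],
               geno$subject_ids[keep])
}

#' Write genotypes as a minimal dosage VCF
#'
#' One `DS`-format field per subject; missing dosages become `.`. The
#' companion reader for analysis is any standard VCF tool; the file is also
#' round-tripped with vcfR in the package tests.
#'
#' @param geno A `genotype_set`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$subject_ids), collapse = "\t")),
             con)
  v <- geno$variants
  ds <- t(geno$dosages)
  body <- vapply(seq_len(nrow(v)), function(j) {
    val <- ifelse(is.na(ds[j, ]), ".", format(ds[j, ], trim = TRUE))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS",
            ".", "DS", val), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write genotypes as a variant-by-subject TSV
#' @param geno A `genotype_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_set"))
  df <- cbind(geno$variants[c("id", "chrom", "pos", "a1", "a2")],
              as.data.frame(t(geno$dosages)))
  names(df) <- c("id", "chrom", "pos", "a1", "a2", geno$subject_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from the variant-by-subject TSV written by
#' [write_genotypes_tsv()]
#' @param path TSV path.
#' @return A `genotype_set`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("id", "chrom", "pos", "a1", "a2")
  stopifnot(all(meta %in% names(df)))
  ids <- setdiff(names(df), meta)
  genotype_set(t(as.matrix(df[ids])), df[meta], subject_ids = ids)
}

#' Write an atlas as NIfTI plus a label table
#' @param atlas A `phantom_atlas`.
#' @param nii_path NIfTI output path.
#' @param labels_path TSV output path for (label, name).
#' @return `nii_path`, invisibly.
#' @export
write_atlas <- function(atlas, nii_path, labels_path) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  RNifti::writeNifti(RNifti::asNifti(atlas$labels * 1.0), nii_path)
  write.table(data.frame(label = as.integer(names(atlas$names)),
                         name = unname(atlas$names)),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nii_path)
}
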