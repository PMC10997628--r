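#' Association-scan configuration
#'
#' Bundles the thresholds of the genetic-association post-processing:
#' genome-wide significance Bonferroni-corrected for the number of latent
#' dimensions tested, the two LD pruning levels of locus clumping, the
#' locus merging distance, the variant QC filters and the cross-cohort
#' kinship exclusion threshold.
#'
#' @param d_total Total number of latent dimensions tested (sets the default
#'   discovery threshold `5e-8 / d_total`).
#' @param discovery_alpha Significance threshold for calling a (variant,
#'   dimension) pair; overrides the `d_total` default when given. Desk-scale
#'   cohorts use a proportionally scaled threshold.
#' @param prune_r2_independent r-squared level of the first pruning step
#'   (independent significant variants).
#' @param prune_r2_lead r-squared level of the second pruning step (lead
#'   variants) and of locus membership.
#' @param merge_kb Adjacent loci closer than this many kilobases are merged.
#' @param maf_min Variants must have minor-allele frequency strictly above
#'   this value.
#' @param missing_max_qc Maximum missing rate at the initial QC stage
#'   (strictly below).
#' @param missing_max_cohort Maximum missing rate at the per-cohort stage.
#' @param kinship_max Kinship coefficient above which a replication subject
#'   related to a discovery subject is excluded (`2^-4.5 ~ 0.0442`).
#' @return Object of class `assoc_config`.
#' @export
assoc_config <- function(d_total = 256L, discovery_alpha = NULL,
                         prune_r2_independent = 0.6, prune_r2_lead = 0.1,
                         merge_kb = 250L, maf_min = 1e-4,
                         missing_max_qc = 0.05, missing_max_cohort = 0.1,
                         kinship_max = 2^(-4.5)) {
  if (is.null(discovery_alpha)) discovery_alpha <- 5e-8 / d_total
  stopifnot(discovery_alpha > 0, discovery_alpha < 1,
            prune_r2_independent > 0, prune_r2_independent < 1,
            prune_r2_lead > 0, prune_r2_lead < 1, merge_kb > 0,
            maf_min >= 0, missing_max_qc > 0, missing_max_cohort > 0,
            kinship_max > 0)
  structure(list(discovery_alpha = discovery_alpha,
                 prune_r2_independent = prune_r2_independent,
                 prune_r2_lead = prune_r2_lead, merge_kb = as.integer(merge_kb),
                 maf_min = maf_min, missing_max_qc = missing_max_qc,
                 missing_max_cohort = missing_max_cohort,
                 kinship_max = kinship_max),
            class = "assoc_config")
}

#' Variant quality control
#'
#' Removes variants with minor-allele frequency at or below `maf_min` or
#' missing rate at or above the stage threshold (0.05 at the initial `qc`
#' stage, 0.1 at the per-`cohort` stage). Hardy-Weinberg filtering is
#' deliberately not applied: dosages are not hard genotype calls.
#'
#' @param geno A `genotype_set`.
#' @param config An [assoc_config()].
#' @param stage `"qc"` or `"cohort"`.
#' @return List with the filtered `genotypes` and a `report` of per-filter
#'   counts.
#' @export
qc_genotypes <- function(geno, config = assoc_config(),
                         stage = c("qc", "cohort")) {
  stopifnot(inherits(geno, "genotype_set"))
  stage <- match.arg(stage)
  miss_max <- if (stage == "qc") config$missing_max_qc else config$missing_max_cohort
  v <- geno$variants
  fail_maf <- !(v$maf > config$maf_min)
  fail_miss <- !(v$missing_rate < miss_max)
  keep <- !(fail_maf | fail_miss)
  if (!any(keep)) stop("no variants survive QC (", sum(fail_maf),
                       " failed MAF, ", sum(fail_miss), " failed missingness)")
  out <- subset_variants(geno, keep)
  list(genotypes = out,
       report = list(stage = stage, n_input = nrow(v), n_kept = sum(keep),
                     n_fail_maf = sum(fail_maf), n_fail_missing = sum(fail_miss),
                     maf_min = config$maf_min, missing_max = miss_max))
}

#' Exclude replication subjects related to the discovery cohort
#'
#' Drops every replication subject with any kinship coefficient above
#' `kinship_max` to any discovery subject, keeping the two cohorts
#' genetically independent. Overlapping ids are an error (data leakage).
#'
#' @param replication_ids Character vector of replication subject ids.
#' @param kinship Data.frame with columns `id1`, `id2`, `coefficient`
#'   (symmetric pairs; either orientation accepted).
#' @param discovery_ids Character vector of discovery subject ids.
#' @param kinship_max Exclusion threshold.
#' @return The retained replication ids.
#' @export
exclude_related <- function(replication_ids, kinship, discovery_ids,
                            kinship_max = 2^(-4.5)) {
  overlap <- intersect(replication_ids, discovery_ids)
  if (length(overlap) > 0)
    stop("cohort leakage: ", length(overlap),
         " subject(s) present in both discovery and replication (e.g. ",
         overlap[1], ")")
  if (is.null(kinship) || nrow(kinship) == 0) return(replication_ids)
  stopifnot(all(c("id1", "id2", "coefficient") %in% names(kinship)))
  hot <- kinship[kinship$coefficient > kinship_max, , drop = FALSE]
  bad1 <- hot$id1[hot$id2 %in% discovery_ids]
  bad2 <- hot$id2[hot$id1 %in% discovery_ids]
  setdiff(replication_ids, c(bad1, bad2))
}

#' Build the standard covariate design
#'
#' Age, age squared, sex, and the sex-by-age interactions, plus any extra
#' columns supplied.
#'
#' @param age Numeric vector.
#' @param sex Binary (0/1) vector.
#' @param extra Optional data.frame of additional covariates.
#' @return A numeric matrix (no intercept column).
#' @export
build_covariates <- function(age, sex, extra = NULL) {
  stopifnot(length(age) == length(sex))
  m <- cbind(age = age, age2 = age^2, sex = sex,
             sex_age = sex * age, sex_age2 = sex * age^2)
  if (!is.null(extra)) m <- cbind(m, as.matrix(extra))
  m
}

#' Per-variant covariate-adjusted association scan
#'
#' For every (variant, dimension) pair, ordinary least squares of the latent
#' phenotype on dosage plus covariates, with casewise deletion of missing
#' dosages; two-sided p from the t distribution with the residual degrees of
#' freedom. (The full-scale analogue is a mixed-model association scan;
#' phantom cohorts are unrelated by construction, so OLS with the same
#' covariate design is the appropriate desk-scale form.)
#'
#' @param latents N x D matrix (or vector) of phenotypes.
#' @param geno A `genotype_set` with N subjects.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (no intercept column; see [build_covariates()]).
#' @param config An [assoc_config()] (carried into the result).
#' @return Long data.frame of class `assoc_table`: one row per (variant,
#'   dimension) with `beta`, `se`, `t`, `p`, `n` plus variant metadata.
#' @export
assoc_scan <- function(latents, geno, covariates = NULL,
                       config = assoc_config()) {
  stopifnot(inherits(geno, "genotype_set"))
  if (is.null(dim(latents))) latents <- matrix(latents, ncol = 1L,
                                               dimnames = list(NULL, "D1"))
  if (is.null(colnames(latents)))
    colnames(latents) <- sprintf("D%d", seq_len(ncol(latents)))
  n <- nrow(latents)
  if (n != nrow(geno$dosages))
    stop("latents have ", n, " subjects but genotypes have ",
         nrow(geno$dosages))
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (anyNA(cv)) stop("covariates must be complete (no NA)")
    qx <- qr(cbind(1, cv))
    if (qx$rank < ncol(cv) + 1L) {
      cn <- colnames(cv)[qx$pivot[seq(qx$rank + 1L, ncol(cv) + 1L)] - 1L]
      stop("collinear covariates: ", paste(cn, collapse = ", "))
    }
  }
  D <- ncol(latents)
  M <- ncol(geno$dosages)
  res <- vector("list", M)
  for (j in seq_len(M)) {
    dos <- geno$dosages[, j]
    ok <- !is.na(dos)
    nj <- sum(ok)
    X <- cbind(`(Intercept)` = 1, dosage = dos[ok],
               if (!is.null(cv)) cv[ok, , drop = FALSE])
    out <- data.frame(variant = geno$variants$id[j],
                      chrom = geno$variants$chrom[j],
                      pos = geno$variants$pos[j],
                      a1 = geno$variants$a1[j], a2 = geno$variants$a2[j],
                      maf = geno$variants$maf[j],
                      missing_rate = geno$variants$missing_rate[j],
                      dim = colnames(latents), n = nj,
                      beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    qx <- qr(X)
    dfree <- nj - ncol(X)
    if (qx$rank == ncol(X) && dfree > 0) {
      Y <- latents[ok, , drop = FALSE]
      coefs <- qr.coef(qx, Y)
      resid <- qr.resid(qx, Y)
      rinv <- backsolve(qr.R(qx), diag(ncol(X)))
      v_dos <- sum(rinv[2, ]^2)  # (X'X)^-1 [dosage, dosage]
      sig2 <- colSums(resid^2) / dfree
      beta <- coefs[2, ]
      se <- sqrt(sig2 * v_dos)
      tv <- beta / se
      out$beta <- as.numeric(beta)
      out$se <- as.numeric(se)
      out$t <- as.numeric(tv)
      out$p <- pmax(2 * pt(-abs(tv), dfree), 1e-300)
    }
    res[[j]] <- out
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` where each p value is converted
#' to its 1-df chi-square quantile. Well-calibrated tests give lambda close
#' to 1; polygenic signal or confounding inflates it.
#'
#' @param p Vector of p values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p values")
  if (any(p <= 0 | p > 1)) stop("p values must lie in (0, 1]")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Aggregate association tables by the minP rule
#'
#' For each variant, takes the smallest p value across all latent
#' dimensions (and records which dimension attained it), producing the
#' single summary used for significance calls and clumping.
#'
#' @param tab An `assoc_table` (long format across dimensions) or a list of
#'   such tables; every dimension must cover the identical variant set.
#' @return Data.frame with `variant`, `chrom`, `pos`, `min_p`, `dim`.
#' @export
minp_aggregate <- function(tab) {
  if (is.list(tab) && !is.data.frame(tab)) tab <- do.call(rbind, tab)
  stopifnot(all(c("variant", "dim", "p") %in% names(tab)))
  sets <- split(tab$variant, tab$dim)
  ref <- sort(unique(sets[[1]]))
  for (s in sets) if (!identical(sort(unique(s)), ref))
    stop("variant sets differ across dimensions")
  tab <- tab[order(tab$variant, tab$dim), ]
  sp <- split(seq_len(nrow(tab)), tab$variant)
  rows <- vapply(sp, function(ix) ix[which.min(tab$p[ix])], integer(1))
  out <- data.frame(variant = tab$variant[rows], chrom = tab$chrom[rows],
                    pos = tab$pos[rows], min_p = tab$p[rows],
                    dim = tab$dim[rows], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

# squared Pearson correlation of dosages, pairwise-complete
ld_r2 <- function(dosages) {
  suppressWarnings(cor(dosages, use = "pairwise.complete.obs"))^2
}

greedy_prune <- function(ids, p, r2m, thr) {
  ord <- order(p)
  alive <- rep(TRUE, length(ids))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    drop <- which(alive & r2m[i, ] > thr)
    alive[drop] <- FALSE
  }
  sort(kept)
}

#' Clump significant variants into genomic loci
#'
#' Two-step pruning of the minP summary: significant variants are first
#' pruned at LD r-squared 0.6 (ascending p, ties by position) to obtain
#' independent significant variants, which are pruned again at r-squared 0.1
#' to obtain the lead variants. Each locus is the smallest contiguous region
#' containing every genotyped variant with r-squared above 0.1 with one of
#' its leads (LD measured in-sample from dosages), and adjacent loci closer
#' than `merge_kb` kilobases are merged - a merged locus can carry several
#' leads.
#'
#' @param minp Output of [minp_aggregate()].
#' @param geno The `genotype_set` the scan was run on (for in-sample LD).
#' @param config An [assoc_config()]; `discovery_alpha` defines
#'   significance.
#' @return Data.frame of class `udip_loci`: one row per locus with `chrom`,
#'   `start`, `end`, `n_leads`, `leads` / `lead_dims` (comma-joined),
#'   `n_members`, `peak_variant`, `peak_dim`, `peak_p`, and a `members`
#'   list-column.
#' @export
clump_loci <- function(minp, geno, config = assoc_config()) {
  stopifnot(inherits(geno, "genotype_set"),
            all(c("variant", "chrom", "pos", "min_p", "dim") %in% names(minp)))
  sig <- minp[minp$min_p < config$discovery_alpha, , drop = FALSE]
  empty <- data.frame(chrom = integer(0), start = integer(0), end = integer(0),
                      n_leads = integer(0), leads = character(0),
                      lead_dims = character(0), n_members = integer(0),
                      peak_variant = character(0), peak_dim = character(0),
                      peak_p = numeric(0))
  empty$members <- list()
  class(empty) <- c("udip_loci", "data.frame")
  if (nrow(sig) == 0) {
    message("no variants reach the significance threshold ",
            format(config$discovery_alpha))
    return(empty)
  }
  vid <- geno$variants$id
  loci <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$min_p, s$pos), ]
    jall <- which(geno$variants$chrom == ch)
    jsig <- match(s$variant, vid)
    if (anyNA(jsig)) stop("minP table contains variants absent from genotypes")
    r2_sig <- ld_r2(geno$dosages[, jsig, drop = FALSE])
    step1 <- greedy_prune(jsig, s$min_p, r2_sig, config$prune_r2_independent)
    step2 <- greedy_prune(jsig[step1], s$min_p[step1],
                          r2_sig[step1, step1, drop = FALSE],
                          config$prune_r2_lead)
    leads <- jsig[step1][step2]  # column indices into geno
    # locus span: every genotyped variant on this chromosome in LD with a lead
    r2_lead_all <- suppressWarnings(
      cor(geno$dosages[, leads, drop = FALSE],
          geno$dosages[, jall, drop = FALSE],
          use = "pairwise.complete.obs"))^2
    for (k in seq_along(leads)) {
      members <- jall[which(r2_lead_all[k, ] > config$prune_r2_lead)]
      members <- sort(unique(c(members, leads[k])))
      loci[[length(loci) + 1L]] <- list(
        chrom = ch, start = min(geno$variants$pos[members]),
        end = max(geno$variants$pos[members]),
        leads = leads[k], members = members)
    }
  }
  # merge adjacent loci closer than merge_kb (end of left to start of right)
  merged <- list()
  for (ch in unique(vapply(loci, `[[`, numeric(1), "chrom"))) {
    lc <- Filter(function(l) l$chrom == ch, loci)
    lc <- lc[order(vapply(lc, `[[`, numeric(1), "start"))]
    cur <- lc[[1]]
    for (l in lc[-1]) {
      if (l$start - cur$end < config$merge_kb * 1000) {
        cur$end <- max(cur$end, l$end)
        cur$start <- min(cur$start, l$start)
        cur$leads <- c(cur$leads, l$leads)
        cur$members <- sort(unique(c(cur$members, l$members)))
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- l
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  rows <- lapply(merged, function(l) {
    mem_ids <- vid[l$members]
    mp <- minp[match(mem_ids, minp$variant), , drop = FALSE]
    mp <- mp[!is.na(mp$variant), , drop = FALSE]
    peak <- mp[which.min(mp$min_p), ]
    lead_ids <- vid[l$leads]
    lead_dims <- minp$dim[match(lead_ids, minp$variant)]
    df <- data.frame(chrom = l$chrom, start = l$start, end = l$end,
                     n_leads = length(l$leads),
                     leads = paste(lead_ids, collapse = ","),
                     lead_dims = paste(lead_dims, collapse = ","),
                     n_members = length(l$members),
                     peak_variant = peak$variant, peak_dim = peak$dim,
                     peak_p = peak$min_p, stringsAsFactors = FALSE)
    df$members <- list(mem_ids)
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("udip_loci", "data.frame")
  out
}

#' Test locus replication
#'
#' A locus replicates when any of its lead variants, tested at its discovery
#' peak dimension, reaches `alpha / (total number of lead variants)` in the
#' replication scan. Leads missing from the replication table count as not
#' replicated (with a warning).
#'
#' @param loci Output of [clump_loci()].
#' @param replication An `assoc_table` from the replication cohort.
#' @param alpha Family-wise level before dividing by the number of leads.
#' @return `loci` with added columns `replicated`, `best_rep_p`, and the
#'   `rep_threshold` in an attribute.
#' @export
test_replication <- function(loci, replication, alpha = 0.05) {
  stopifnot(inherits(loci, "udip_loci"))
  n_leads_total <- sum(loci$n_leads)
  if (nrow(loci) == 0) return(loci)
  thr <- alpha / n_leads_total
  key <- paste(replication$variant, replication$dim)
  res <- lapply(seq_len(nrow(loci)), function(i) {
    leads <- strsplit(loci$leads[i], ",")[[1]]
    dims <- strsplit(loci$lead_dims[i], ",")[[1]]
    pr <- replication$p[match(paste(leads, dims), key)]
    if (anyNA(pr))
      warning("locus ", i, ": ", sum(is.na(pr)),
              " lead(s) missing from the replication table", call. = FALSE)
    best <- suppressWarnings(min(pr, na.rm = TRUE))
    if (!is.finite(best)) best <- NA_real_
    c(replicated = isTRUE(best < thr), best_rep_p = best)
  })
  loci$replicated <- vapply(res, function(x) as.logical(x[["replicated"]]),
                            logical(1))
  loci$best_rep_p <- vapply(res, function(x) as.numeric(x[["best_rep_p"]]),
                            numeric(1))
  attr(loci, "rep_threshold") <- thr
  loci
}

#' Sample-size-weighted fixed-effect meta-analysis
#'
#' Converts each cohort's two-sided p value and effect direction into a
#' signed z score, aligns effect alleles (swapped alleles flip the sign;
#' unalignable variants are dropped with a warning), and combines with
#' weights sqrt(n): `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))`.
#'
#' @param tab1,tab2 `assoc_table`s sharing (variant, dim) pairs.
#' @return Data.frame with per-pair `z1`, `z2`, `z_meta`, `p_meta`,
#'   `n_total`.
#' @export
meta_combine <- function(tab1, tab2) {
  k1 <- paste(tab1$variant, tab1$dim)
  k2 <- paste(tab2$variant, tab2$dim)
  common <- intersect(k1, k2)
  a <- tab1[match(common, k1), ]
  b <- tab2[match(common, k2), ]
  match_ok <- a$a1 == b$a1 & a$a2 == b$a2
  flipped <- a$a1 == b$a2 & a$a2 == b$a1
  bad <- !(match_ok | flipped)
  if (any(bad)) {
    warning(sum(bad), " variant pair(s) with unalignable alleles dropped",
            call. = FALSE)
    a <- a[!bad, ]; b <- b[!bad, ]; flipped <- flipped[!bad]
  }
  zs <- function(p, beta) sign(beta) * qnorm(pmax(p, 1e-300) / 2,
                                             lower.tail = FALSE)
  z1 <- zs(a$p, a$beta)
  z2 <- zs(b$p, b$beta)
  z2[flipped] <- -z2[flipped]
  w1 <- sqrt(a$n); w2 <- sqrt(b$n)
  zm <- (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
  data.frame(variant = a$variant, chrom = a$chrom, pos = a$pos, dim = a$dim,
             z1 = z1, z2 = z2, z_meta = zm,
             p_meta = pmax(2 * pnorm(-abs(zm)), 1e-300),
             n_total = a$n + b$n, stringsAsFactors = FALSE)
}

#' Overlap two locus tables
#'
#' Flags, for each locus of `loci_a`, whether it overlaps any locus of
#' `loci_b` on the same chromosome after padding the `loci_b` intervals by
#' `pad_kb` kilobases on both sides.
#'
#' @param loci_a,loci_b `udip_loci` data.frames (or any data.frame with
#'   `chrom`, `start`, `end`).
#' @param pad_kb Padding applied to `loci_b`.
#' @return Logical vector over rows of `loci_a`.
#' @export
loci_overlap <- function(loci_a, loci_b, pad_kb = 125) {
  pad <- pad_kb * 1000
  vapply(seq_len(nrow(loci_a)), function(i) {
    b <- loci_b[loci_b$chrom == loci_a$chrom[i], , drop = FALSE]
    any(loci_a$start[i] <= b$end + pad & loci_a$end[i] >= b$start - pad)
  }, logical(1))
}
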