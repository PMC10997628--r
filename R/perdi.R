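#' Per-dimension standard deviation of a latent matrix
#'
#' The perturbation unit for decoder interpretation: one standard deviation
#' of each latent dimension, estimated over the encoded cohort (sample sd,
#' denominator N-1).
#'
#' @param latents N x D latent matrix (N >= 2).
#' @return Numeric vector of length D.
#' @export
latent_sd <- function(latents) {
  if (is.null(dim(latents))) latents <- matrix(latents, ncol = 1L)
  if (nrow(latents) < 2L) stop("need at least 2 subjects to estimate sd")
  apply(latents, 2L, sd)
}

#' Perturb one latent dimension
#'
#' Adds `delta` to entry `dim_index` of a latent vector (or to that column
#' of a latent matrix), keeping all other dimensions constant.
#'
#' @param z Latent vector or N x D matrix.
#' @param dim_index Dimension to perturb (1-based).
#' @param delta Amount added.
#' @return Perturbed copy of `z`.
#' @export
perturb_latent <- function(z, dim_index, delta) {
  d <- if (is.null(dim(z))) length(z) else ncol(z)
  if (dim_index < 1L || dim_index > d)
    stop("dim_index ", dim_index, " out of range [1, ", d, "]")
  if (is.null(dim(z))) z[dim_index] <- z[dim_index] + delta
  else z[, dim_index] <- z[, dim_index] + delta
  z
}

#' Gaussian-smooth a 3D statistic grid
#'
#' Separable Gaussian convolution with kernel truncated at 4 sigma and
#' zero padding outside the grid. `sigma = 0` is the identity. Smoothing
#' compensates for the imperfect voxel correspondence left by linear-only
#' registration.
#'
#' @param arr 3D numeric array.
#' @param sigma Kernel standard deviation in voxels (>= 0).
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(arr, sigma) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(arr)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    n <- dim(a)[axis]
    km <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      km[i, j[ok]] <- k[ok]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    res <- km %*% matrix(ap, n)
    aperm(array(res, dim(a)[perm]), order(perm))
  }
  conv_axis(conv_axis(conv_axis(arr, 1L), 2L), 3L)
}

#' Perturbation-based decoder interpretation (t-map)
#'
#' Maps one latent dimension to voxels: a seeded subject sample is decoded
#' twice, once from the observed latent vectors and once with
#' `multiplier * sigma_d` added to the chosen dimension (all others held
#' constant), and a paired t-test across subjects is run at every voxel on
#' the reconstruction differences. The absolute t-map is then Gaussian
#' smoothed. Voxels whose paired differences have zero variance get t = 0
#' when the mean difference is also 0, and otherwise the maximum finite |t|
#' observed elsewhere (flagged; this keeps the ranking intact without
#' infinities — with a strictly linear decoder, where every voxel is
#' degenerate, the mean absolute difference itself is used as the ranking
#' statistic, scaled to a unit maximum).
#'
#' @param model A trained `udip_model` or [linear_decoder()].
#' @param latents N x D latent matrix of the encoded cohort (also the pool
#'   the subject sample is drawn from).
#' @param dim_index Latent dimension to interpret (1-based).
#' @param multiplier Perturbation size in units of the dimension's sd.
#' @param n_subjects Subjects sampled (without replacement) for the paired
#'   test.
#' @param smooth_sigma Gaussian kernel sd in voxels.
#' @param seed Seed for the subject sample.
#' @param mask Optional logical 3D brain mask. Background reconstructions
#'   are unconstrained by the masked training loss, so their paired
#'   statistics are arbitrary; when a mask is given, t values outside it
#'   are set to 0 before smoothing so they cannot bleed into boundary
#'   regions.
#' @return Object of class `udip_tmap`: smoothed absolute t `values` (3D),
#'   unsmoothed `raw`, `mean_abs_diff`, `dim_index`, `n_used`, and the count
#'   of `degenerate` voxels.
#' @export
perdi_tmap <- function(model, latents, dim_index, multiplier = 1,
                       n_subjects = 500L, smooth_sigma = 3, seed = 1L,
                       mask = NULL) {
  if (is.null(dim(latents))) stop("latents must be a matrix")
  d <- ncol(latents)
  if (dim_index < 1L || dim_index > d) stop("dim_index out of range")
  n_avail <- nrow(latents)
  if (n_subjects < 2L) stop("need at least 2 subjects for a paired t-test")
  if (n_subjects > n_avail)
    stop("n_subjects (", n_subjects, ") exceeds available subjects (",
         n_avail, ")")
  sig <- sd(latents[, dim_index])
  if (!is.finite(sig) || sig == 0)
    stop("degenerate latent dimension ", dim_index, ": zero variance")
  idx <- with_seed(seed, sample.int(n_avail, n_subjects))
  z0 <- latents[idx, , drop = FALSE]
  z1 <- perturb_latent(z0, dim_index, multiplier * sig)
  r0 <- decode_latents(model, z0)
  r1 <- decode_latents(model, z1)
  shape <- attr(r0, "shape")
  diff <- r1 - r0
  n <- n_subjects
  md <- rowMeans(diff)
  sdd <- sqrt(pmax(rowSums((diff - md)^2), 0) / (n - 1))
  tt <- numeric(length(md))
  # "zero variance" at floating precision: paired differences that agree to
  # within 1e-7 of their mean are deterministic, not noisy
  well <- sdd > 1e-7 * abs(md)
  tt[well] <- abs(md[well] / (sdd[well] / sqrt(n)))
  degen <- !well & abs(md) > 0
  n_degen <- sum(degen)
  if (n_degen > 0) {
    finite_max <- if (any(well)) max(tt[well]) else 0
    if (finite_max > 0) {
      tt[degen] <- finite_max
    } else {
      # fully deterministic decoder (e.g. linear): rank by |mean difference|
      tt[degen] <- abs(md[degen]) / max(abs(md[degen]))
    }
  }
  raw <- array(tt, shape)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), as.integer(shape)) ||
              identical(dim(mask), shape))
    raw[!mask] <- 0
  }
  structure(list(values = smooth_volume(raw, smooth_sigma), raw = raw,
                 mean_abs_diff = array(abs(md), shape),
                 dim_index = as.integer(dim_index), n_used = as.integer(n),
                 multiplier = multiplier, degenerate = n_degen),
            class = "udip_tmap")
}

#' @export
print.udip_tmap <- function(x, ...) {
  cat(sprintf("udip_tmap: dim %d, %d subjects, grid %s, max |t| = %.3g\n",
              x$dim_index, x$n_used, paste(dim(x$values), collapse = "x"),
              max(x$values)))
  invisible(x)
}

#' Write a t-map as NIfTI
#' @param tmap A `udip_tmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tmap <- function(tmap, path) {
  stopifnot(inherits(tmap, "udip_tmap"))
  RNifti::writeNifti(RNifti::asNifti(tmap$values), path)
  invisible(path)
}
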