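#' Autoencoder configuration
#'
#' Describes a symmetric 3D convolutional autoencoder: an initial block of
#' two (conv k3 s1 -> batch norm -> leaky ReLU) units, `n_blocks` encoder
#' blocks (max-pool k2 then two conv units), a fully connected map to a
#' `latent_dim`-dimensional bottleneck (so every latent unit sees the whole
#' padded grid), the mirrored decoder whose blocks end in a transposed
#' convolution (k2, stride 2), and a final block closing with a kernel-1
#' convolution and no output activation. Input dimensions are zero-padded up
#' to the next multiple of `2^n_blocks` before the first block and the output
#' is centre-cropped back, so the reconstruction has exactly the input shape.
#'
#' @param input_shape Integer vector of 3 voxel dimensions.
#' @param latent_dim Bottleneck width (number of latent imaging phenotypes).
#' @param n_blocks Number of pooling/upsampling stages.
#' @param channel_widths Integer vector of length `n_blocks + 1`: channels of
#'   the initial block and of each encoder stage. Defaults to
#'   `16 * 2^(0:n_blocks)` capped at 256. These widths (together with
#'   `latent_dim`) set the model capacity and are the main dials when scaling
#'   the model between desk-size phantoms and full-resolution brain images.
#' @param negative_slope Leaky-ReLU slope for negative inputs.
#' @param loss_reduction `"mean"` (per-image mean over masked voxels, then
#'   averaged over the batch; scale-stable across mask sizes) or `"sum"`
#'   (raw sum of masked squared differences).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling weight initialisation, the train/
#'   validation split and shuffling.
#' @return An object of class `ae_config`.
#' @export
ae_config <- function(input_shape, latent_dim = 128L, n_blocks = 4L,
                      channel_widths = NULL, negative_slope = 0.1,
                      loss_reduction = c("mean", "sum"),
                      learning_rate = 1e-4, seed = 1L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L),
            latent_dim >= 1L, n_blocks >= 1L)
  loss_reduction <- match.arg(loss_reduction)
  div <- 2L^n_blocks
  if (min(input_shape) < div)
    stop("input shape too small for ", n_blocks, " halvings: ",
         "every dimension must be at least ", div)
  if (is.null(channel_widths))
    channel_widths <- pmin(16L * 2L^(0:n_blocks), 256L)
  channel_widths <- as.integer(channel_widths)
  if (length(channel_widths) != n_blocks + 1L)
    stop("channel_widths must have length n_blocks + 1 = ", n_blocks + 1L)
  stopifnot(all(channel_widths >= 1L))
  padded <- as.integer(ceiling(input_shape / div) * div)
  structure(list(input_shape = input_shape, padded_shape = padded,
                 latent_dim = as.integer(latent_dim),
                 n_blocks = as.integer(n_blocks),
                 channel_widths = channel_widths,
                 negative_slope = negative_slope,
                 loss_reduction = loss_reduction,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ae_config")
}

#' Build an untrained autoencoder
#'
#' Initialises all weights (He-normal scaled by fan-in, zero biases, unit
#' batch-norm scale) under `config$seed`.
#'
#' @param config An [ae_config].
#' @return An object of class `udip_model` holding the configuration and the
#'   parameter list.
#' @export
build_autoencoder <- function(config) {
  stopifnot(inherits(config, "ae_config"))
  sh <- cpp_ae_param_shapes(unclass(config))
  params <- with_seed(config$seed, {
    lapply(seq_along(sh$shapes), function(i) {
      d <- sh$shapes[[i]]
      nm <- names(sh$shapes)[i]
      if (grepl("_bn_gamma$|_bn_rv$", nm)) {
        matrix(1, d[1], d[2])
      } else if (grepl("_bn_beta$|_bn_rm$|_b$", nm)) {
        matrix(0, d[1], d[2])
      } else {
        matrix(rnorm(d[1] * d[2], sd = sqrt(2 / d[1])), d[1], d[2])
      }
    })
  })
  names(params) <- names(sh$shapes)
  structure(list(config = config, params = params,
                 trainable = sh$trainable, history = NULL,
                 best_epoch = NA_integer_, trained = FALSE),
            class = "udip_model")
}

#' @export
print.udip_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("udip_model: input %s (padded %s), latent %d, %d blocks [%s]\n",
              paste(cfg$input_shape, collapse = "x"),
              paste(cfg$padded_shape, collapse = "x"),
              cfg$latent_dim, cfg$n_blocks,
              paste(cfg$channel_widths, collapse = ",")))
  cat(sprintf("  %s parameters; %s\n", format(n_parameters(x), big.mark = ","),
              if (x$trained)
                sprintf("trained (best epoch %d, val loss %.5g)", x$best_epoch,
                        min(x$history$val_loss))
              else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `udip_model`.
#' @return Integer count of trainable weights.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "udip_model"))
  sum(vapply(model$params[model$trainable], length, integer(1)))
}

# Coerce supported cohort representations to list(x = nvox x N matrix,
# mask = nvox x N matrix, shape, ids).
cohort_matrices <- function(volumes, shape = NULL) {
  if (inherits(volumes, "phantom_cohort")) {
    n <- ncol(volumes$intensities)
    return(list(x = volumes$intensities,
                mask = matrix(as.numeric(volumes$mask), nrow(volumes$intensities), n),
                shape = volumes$shape, ids = volumes$subject_ids))
  }
  if (inherits(volumes, "masked_volume")) volumes <- list(volumes)
  stopifnot(is.list(volumes), length(volumes) >= 1L,
            all(vapply(volumes, inherits, logical(1), "masked_volume")))
  shp <- dim(volumes[[1]]$intensities)
  x <- vapply(volumes, function(v) {
    if (!identical(dim(v$intensities), shp)) stop("volumes differ in shape")
    as.numeric(v$intensities)
  }, numeric(prod(shp)))
  m <- vapply(volumes, function(v) as.numeric(v$mask), numeric(prod(shp)))
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("V%03d", seq_along(volumes))
  list(x = x, mask = m, shape = shp, ids = ids)
}

#' Background-masked mean squared error
#'
#' The reconstruction loss: squared intensity differences summed over the
#' voxels where the original image's brain mask is 1; the step-function mask
#' makes the loss exactly invariant to anything in the background. With
#' `reduction = "mean"` (the default used in training) the sum is divided by
#' the number of masked voxels.
#'
#' @param recon Reconstructed intensities: 3D array, numeric vector, or
#'   [masked_volume].
#' @param orig Original image as a [masked_volume] (its mask defines the
#'   loss support).
#' @param reduction `"mean"` or `"sum"`.
#' @return A non-negative scalar; 0 iff `recon` equals `orig` on the mask.
#' @export
masked_mse <- function(recon, orig, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(orig, "masked_volume"))
  r <- if (inherits(recon, "masked_volume")) recon$intensities else recon
  if (length(r) != length(orig$intensities))
    stop("shape mismatch: reconstruction has ", length(r), " voxels, ",
         "original has ", length(orig$intensities))
  f <- as.numeric(orig$mask)
  nm <- sum(f)
  if (nm == 0) stop("empty mask")
  s <- sum(((as.numeric(r) - as.numeric(orig$intensities))^2) * f)
  if (reduction == "mean") s / nm else s
}

#' Train the autoencoder
#'
#' Splits the cohort into training and validation subsets, minimises the
#' background-masked MSE with Adam, and returns the checkpoint with the
#' lowest validation loss. One seed controls the split and the per-epoch
#' shuffling; batch-norm layers use batch statistics during training and
#' running statistics for validation and all later inference, so encoding is
#' deterministic.
#'
#' @param model A `udip_model` from [build_autoencoder()].
#' @param volumes A `phantom_cohort` or list of [masked_volume]s (already
#'   z-normalised; see [znormalize()]).
#' @param epochs Number of passes over the training set.
#' @param val_fraction Fraction held out for validation/checkpointing.
#' @param batch_size Minibatch size (batches of 1 are skipped: batch norm
#'   needs at least 2 samples).
#' @param seed Seed for the split and shuffling; defaults to the config seed.
#' @param verbose Print per-epoch losses.
#' @return The model with trained parameters, `history` (per-epoch train and
#'   validation loss) and `best_epoch` filled in.
#' @export
ae_train <- function(model, volumes, epochs = 75L, val_fraction = 0.25,
                     batch_size = 16L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "udip_model"), epochs >= 1L,
            val_fraction > 0, val_fraction < 1)
  cm <- cohort_matrices(volumes)
  n <- ncol(cm$x)
  if (n < 2L) stop("need at least 2 volumes to train")
  if (!identical(as.integer(cm$shape), model$config$input_shape))
    stop("volume shape ", paste(cm$shape, collapse = "x"),
         " does not match model input ",
         paste(model$config$input_shape, collapse = "x"))
  if (is.null(seed)) seed <- model$config$seed
  n_val <- max(1L, round(val_fraction * n))
  if (n_val >= n) stop("validation fraction leaves no training volumes")
  val <- with_seed(seed, sample.int(n, n_val))
  tr <- setdiff(seq_len(n), val)
  res <- cpp_ae_train(model$params, cm$x, cm$mask, unclass(model$config),
                      as.integer(tr - 1L), as.integer(val - 1L),
                      as.integer(epochs), as.integer(batch_size),
                      model$config$learning_rate, as.integer(seed %% 2147483647L),
                      isTRUE(verbose))
  model$params <- res$params
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss)
  model$best_epoch <- res$best_epoch
  model$trained <- TRUE
  model
}

#' Encode volumes into the latent space
#'
#' Runs the encoder in inference mode and returns the bottleneck activations
#' (the latent imaging phenotypes), one row per subject in input order.
#'
#' @param model A trained `udip_model`.
#' @param volumes A `phantom_cohort` or list of [masked_volume]s.
#' @param batch_size Inference batch size.
#' @return An N x D numeric matrix with subject ids as row names and
#'   `D1..Dd` column names.
#' @export
encode_volumes <- function(model, volumes, batch_size = 32L) {
  stopifnot(inherits(model, "udip_model"))
  cm <- cohort_matrices(volumes)
  z <- cpp_ae_encode(model$params, cm$x, unclass(model$config),
                     as.integer(batch_size))
  dimnames(z) <- list(cm$ids, sprintf("D%d", seq_len(ncol(z))))
  z
}

#' Decode latent vectors into image space
#'
#' @param model A trained `udip_model`, or a [linear_decoder()] test double.
#' @param latents N x D matrix of latent vectors.
#' @param ... Passed to methods (`batch_size` for `udip_model`).
#' @return An `nvox x N` matrix of reconstructed intensities with the volume
#'   shape in attribute `"shape"`.
#' @export
decode_latents <- function(model, latents, ...) UseMethod("decode_latents")

#' @rdname decode_latents
#' @param batch_size Inference batch size.
#' @export
decode_latents.udip_model <- function(model, latents, batch_size = 32L, ...) {
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1L)
  r <- cpp_ae_decode(model$params, latents, unclass(model$config),
                     as.integer(batch_size))
  attr(r, "shape") <- model$config$input_shape
  r
}

#' Linear decoder test double
#'
#' A stand-in decoder `decode(z) = A z` used to verify perturbation
#' interpretation against closed forms: perturbing latent dimension d by
#' delta changes every reconstruction by exactly `delta * A[, d]`.
#'
#' @param A `nvox x D` weight matrix.
#' @param shape Volume shape (3 integers) with `prod(shape) == nrow(A)`.
#' @return An object of class `udip_linear_decoder`.
#' @export
linear_decoder <- function(A, shape) {
  shape <- as.integer(shape)
  stopifnot(is.matrix(A), length(shape) == 3L, prod(shape) == nrow(A))
  structure(list(A = A, input_shape = shape, latent_dim = ncol(A)),
            class = "udip_linear_decoder")
}

#' @rdname decode_latents
#' @export
decode_latents.udip_linear_decoder <- function(model, latents, ...) {
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1L)
  if (ncol(latents) != ncol(model$A))
    stop("latent width ", ncol(latents), " does not match decoder (",
         ncol(model$A), ")")
  r <- model$A %*% t(latents)
  attr(r, "shape") <- model$input_shape
  r
}

#' Matched versus random-pair reconstruction loss
#'
#' Encodes and decodes each volume, then compares the mean masked MSE of
#' matched (reconstruction_i, original_i) pairs against a seeded derangement
#' (reconstruction_i, original_j), j != i. A trained model that actually
#' encodes subject-specific anatomy gives a matched loss well below the
#' random-pair loss; a collapsed model that outputs a population mean gives
#' roughly equal losses.
#'
#' @param model A trained `udip_model`.
#' @param volumes A `phantom_cohort` or list of at least 2 [masked_volume]s.
#' @param seed Seed for the derangement.
#' @return List with `matched`, `random_pair` mean losses and the permutation
#'   used.
#' @export
reconstruction_gap <- function(model, volumes, seed = 1L) {
  cm <- cohort_matrices(volumes)
  n <- ncol(cm$x)
  if (n < 2L) stop("need at least 2 volumes")
  z <- encode_volumes(model, volumes)
  r <- decode_latents(model, z)
  perm <- with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) break
    }
    p
  })
  loss_vs <- function(j_of_i) {
    mean(vapply(seq_len(n), function(i) {
      j <- j_of_i[i]
      f <- cm$mask[, j]
      sum((r[, i] - cm$x[, j])^2 * f) / sum(f)
    }, numeric(1)))
  }
  list(matched = loss_vs(seq_len(n)), random_pair = loss_vs(perm),
       permutation = perm)
}
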