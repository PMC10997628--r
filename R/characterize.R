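#' CCA variance explained between two latent spaces
#'
#' SVD-based canonical correlation analysis: after demeaning,
#' `X = U1 S1 V1'`, `Y = U2 S2 V2'`, and the canonical correlations are the
#' singular values S of `U1' U2 = U S V'`. The variance of X explained by Y
#' is `||S1 U * S||_F^2 / ||S1||_F^2` (column j of `S1 U` scaled by `S_j`),
#' and symmetrically for Y given X - identically the fraction of X's total
#' demeaned sum of squares captured by orthogonal projection onto Y's
#' column space. Near-zero singular values (below `1e-10` of the largest)
#' are truncated, with a note when the matrices are rank deficient.
#'
#' @param X N x p matrix.
#' @param Y N x q matrix (same N > max(p, q)).
#' @return List with `canonical_correlations` (non-increasing, in `[0,1]`),
#'   `var_x_given_y`, `var_y_given_x`.
#' @export
cca_variance_explained <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) <= max(ncol(X), ncol(Y)))
    stop("need more observations than columns (N > max(p, q))")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (any(apply(Xc, 2, function(c) all(c == 0))) ||
      any(apply(Yc, 2, function(c) all(c == 0))))
    stop("constant columns are not allowed")
  thin <- function(M) {
    s <- svd(M)
    keep <- s$d > 1e-10 * s$d[1]
    if (!all(keep))
      message("rank-deficient matrix: using rank ", sum(keep),
              " of ", length(keep))
    list(u = s$u[, keep, drop = FALSE], d = s$d[keep],
         v = s$v[, keep, drop = FALSE])
  }
  s1 <- thin(Xc)
  s2 <- thin(Yc)
  sm <- svd(crossprod(s1$u, s2$u))
  cc <- pmin(pmax(sm$d, 0), 1)
  vexp <- function(sd_vec, rot) {
    num <- sweep(sweep(rot, 1, sd_vec, `*`), 2, cc, `*`)
    sum(num^2) / sum(sd_vec^2)
  }
  list(canonical_correlations = cc,
       var_x_given_y = vexp(s1$d, sm$u),
       var_y_given_x = vexp(s2$d, sm$v))
}

seeded_folds <- function(n, k, seed, strata = NULL) {
  with_seed(seed, {
    if (is.null(strata)) {
      sample(rep(seq_len(k), length.out = n))
    } else {
      f <- integer(n)
      for (lv in unique(strata)) {
        ix <- which(strata == lv)
        f[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
      }
      f
    }
  })
}

#' Cross-validated prediction of a continuous trait from latents
#'
#' K-fold cross-validation of ordinary least squares; the metric is the
#' out-of-fold coefficient of determination R-squared per fold.
#'
#' @param latents N x D matrix.
#' @param target Numeric vector of length N.
#' @param k_folds Number of folds.
#' @param seed Fold-assignment seed.
#' @return List with `mean_r2`, `sd_r2`, `per_fold`.
#' @export
cv_predict_continuous <- function(latents, target, k_folds = 10L, seed = 1L) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  stopifnot(length(target) == n, k_folds >= 2L)
  if (n < 2L * k_folds) stop("need at least 2 subjects per fold")
  folds <- seeded_folds(n, k_folds, seed)
  r2 <- vapply(seq_len(k_folds), function(k) {
    tr <- folds != k
    fit <- lm.fit(cbind(1, latents[tr, , drop = FALSE]), target[tr])
    pred <- cbind(1, latents[!tr, , drop = FALSE]) %*% fit$coefficients
    y <- target[!tr]
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  list(mean_r2 = mean(r2), sd_r2 = sd(r2), per_fold = r2)
}

#' Cross-validated prediction of a binary trait from latents
#'
#' Stratified K-fold cross-validation of ridge-penalised logistic
#' regression (a small penalty keeps separable problems well-posed); the
#' metric is the out-of-fold area under the ROC curve per fold.
#'
#' @param latents N x D matrix.
#' @param target 0/1 vector of length N with both classes present.
#' @param k_folds Number of folds.
#' @param seed Fold-assignment seed.
#' @param lambda Ridge penalty.
#' @return List with `mean_auroc`, `sd_auroc`, `per_fold`.
#' @export
cv_predict_binary <- function(latents, target, k_folds = 10L, seed = 1L,
                              lambda = 1e-3) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  stopifnot(length(target) == n, k_folds >= 2L)
  target <- as.integer(target)
  if (length(unique(target)) < 2L) stop("target has a single class")
  if (min(table(target)) < k_folds)
    stop("each class needs at least k_folds members for stratified folds")
  folds <- seeded_folds(n, k_folds, seed, strata = target)
  auc <- vapply(seq_len(k_folds), function(k) {
    tr <- folds != k
    fit <- glmnet::glmnet(latents[tr, , drop = FALSE], target[tr],
                          family = "binomial", alpha = 0, lambda = lambda)
    pred <- as.numeric(predict(fit, latents[!tr, , drop = FALSE],
                               type = "response"))
    as.numeric(pROC::auc(response = target[!tr], predictor = pred,
                         levels = c(0L, 1L), direction = "<", quiet = TRUE))
  }, numeric(1))
  list(mean_auroc = mean(auc), sd_auroc = sd(auc), per_fold = auc)
}

#' Correlation structure within and across two latent sets
#'
#' Mean absolute off-diagonal Pearson correlation within each set and mean
#' absolute cross-correlation between the paired sets. Constant columns are
#' excluded with a warning.
#'
#' @param latents_a,latents_b N x Da and N x Db matrices (same subjects,
#'   same order).
#' @return List with `within_a`, `within_b`, `across` and the full
#'   `cross_matrix` of absolute correlations.
#' @export
correlation_summary <- function(latents_a, latents_b) {
  A <- as.matrix(latents_a); B <- as.matrix(latents_b)
  stopifnot(nrow(A) == nrow(B))
  drop_const <- function(M, nm) {
    keep <- apply(M, 2, sd) > 0
    if (!all(keep)) warning(sum(!keep), " constant column(s) excluded from ",
                            nm, call. = FALSE)
    M[, keep, drop = FALSE]
  }
  A <- drop_const(A, "set A"); B <- drop_const(B, "set B")
  offmean <- function(M) {
    ca <- abs(cor(M))
    mean(ca[upper.tri(ca)])
  }
  cross <- abs(cor(A, B))
  list(within_a = offmean(A), within_b = offmean(B),
       across = mean(cross), cross_matrix = cross)
}
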