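#' Rank voxels of a statistic map
#'
#' Orders the voxels inside the ranking scope from highest to lowest
#' statistic; ties are broken by ascending linear voxel index, which makes
#' the ranking fully reproducible.
#'
#' @param tmap A `udip_tmap` or 3D numeric array.
#' @param scope_mask Optional logical array restricting the ranking (e.g.
#'   the brain mask, so background voxels never enter the enrichment).
#'   Default: all voxels.
#' @return Integer vector of linear voxel indices, best first.
#' @export
rank_voxels <- function(tmap, scope_mask = NULL) {
  v <- if (inherits(tmap, "udip_tmap")) tmap$values else tmap
  stopifnot(is.array(v), length(dim(v)) == 3L)
  idx <- if (is.null(scope_mask)) seq_along(v) else {
    stopifnot(identical(dim(scope_mask), dim(v)))
    which(as.logical(scope_mask))
  }
  if (length(idx) == 0L) stop("empty ranking scope")
  idx[order(-v[idx], idx)]
}

#' Ranked-voxel enrichment curve for one atlas region
#'
#' Walks the voxel ranking: after the top n voxels, k of which fall in the
#' region, the curve value is `k/V - n/N` (V region voxels in scope, N total
#' scoped voxels). The enrichment statistic is the maximum of this curve
#' over all cutoffs - a one-sided Kolmogorov-Smirnov statistic comparing the
#' region's rank distribution against uniform. The curve ends at 0, so the
#' statistic lies in `[0, 1 - V/N]`, reaching the upper bound exactly when
#' the region occupies the top V ranks.
#'
#' @param ranked Voxel index ranking from [rank_voxels()].
#' @param atlas A `phantom_atlas` or integer 3D label array.
#' @param region_label Integer label of the region.
#' @return Object of class `enrichment_curve`: `curve` (length N), `ks_stat`,
#'   `argmax_n`, `V`, `N`, `r` (= V/N) and the label.
#' @export
enrichment_curve <- function(ranked, atlas, region_label) {
  lab <- if (inherits(atlas, "phantom_atlas")) atlas$labels else atlas
  ind <- lab[ranked] == region_label
  V <- sum(ind)
  if (V < 1L) stop("region ", region_label, " absent from the ranking scope")
  N <- length(ranked)
  curve <- cumsum(ind) / V - seq_len(N) / N
  ks <- max(curve)
  structure(list(region_label = as.integer(region_label),
                 curve = curve, ks_stat = ks,
                 argmax_n = which.max(curve), V = V, N = N, r = V / N),
            class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment_curve: label %d, V = %d of N = %d, K-S = %.4f at n = %d\n",
              x$region_label, x$V, x$N, x$ks_stat, x$argmax_n))
  invisible(x)
}

#' Enrichment profile of a t-map over all atlas regions
#'
#' Computes the ranked-voxel K-S enrichment statistic for every nonzero
#' atlas label and returns them sorted, best first. The default ranking
#' scope is the labelled brain (`atlas > 0`), excluding background.
#'
#' @param tmap A `udip_tmap` or 3D array.
#' @param atlas A `phantom_atlas` or integer 3D label array.
#' @param scope_mask Optional logical array overriding the ranking scope.
#' @param region_names Optional named vector (label -> name); taken from the
#'   atlas object when available.
#' @return Data.frame with columns `label`, `region`, `V`, `ks_stat`,
#'   `argmax_n`, sorted by decreasing `ks_stat`.
#' @export
region_profile <- function(tmap, atlas, scope_mask = NULL, region_names = NULL) {
  v <- if (inherits(tmap, "udip_tmap")) tmap$values else tmap
  lab <- if (inherits(atlas, "phantom_atlas")) atlas$labels else atlas
  if (is.null(region_names) && inherits(atlas, "phantom_atlas"))
    region_names <- atlas$names
  if (!identical(dim(lab), dim(v)))
    stop("atlas shape ", paste(dim(lab), collapse = "x"),
         " does not match t-map shape ", paste(dim(v), collapse = "x"))
  if (is.null(scope_mask)) scope_mask <- lab > 0L
  ranked <- rank_voxels(v, scope_mask)
  labs <- sort(unique(lab[lab > 0L]))
  rows <- lapply(labs, function(l) {
    ec <- enrichment_curve(ranked, lab, l)
    data.frame(label = l,
               region = if (!is.null(region_names))
                 region_names[[as.character(l)]] else as.character(l),
               V = ec$V, ks_stat = ec$ks_stat, argmax_n = ec$argmax_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ks_stat, out$label), ]
  rownames(out) <- NULL
  out
}
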