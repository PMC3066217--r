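#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the identical distribution: the
#' across-sample mean of order statistics. A matrix-level stand-in for
#' full probe-level preprocessing; within-sample rank order is preserved.
#'
#' @param x Expression matrix (genes x samples).
#' @return An [expression_matrix()] of the same shape.
#' @export
quantile_normalize <- function(x) {
  em <- as_expression_matrix(x)
  m <- em$values
  if (ncol(m) < 2) {
    warning("single-sample matrix returned unchanged")
    return(em)
  }
  sorted <- apply(m, 2, sort)
  target <- rowMeans(sorted)
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average ranks from ties interpolate between target order statistics
    approx(seq_along(target), target, xout = r)$y
  })
  dimnames(out) <- dimnames(m)
  expression_matrix(out, em$batch)
}

#' Relative log expression outlier flags
#'
#' RLE for gene g in sample j is `x[g, j] - median_g(x[g, ])`. A clean
#' array has RLE centered at 0 with small spread; arrays whose RLE median
#' exceeds `median_thresh` in absolute value or whose RLE IQR exceeds
#' `iqr_thresh` are flagged as technical outliers.
#'
#' @param x Expression matrix (at least 3 samples).
#' @param median_thresh Flag threshold on |median RLE| (log2 units).
#' @param iqr_thresh Flag threshold on the RLE inter-quartile range.
#' @return Data frame with per-sample `rle_median`, `rle_iqr` and
#'   `outlier` flag.
#' @export
rle_outlier_flags <- function(x, median_thresh = 0.5, iqr_thresh = 1.0) {
  m <- em_values(as_expression_matrix(x))
  if (ncol(m) < 3) stop("need at least 3 samples for RLE QC")
  med <- apply(m, 1, median)
  rle <- m - med
  rmed <- apply(rle, 2, median)
  riqr <- apply(rle, 2, function(v) diff(quantile(v, c(0.25, 0.75))))
  data.frame(sample_id = colnames(m), rle_median = unname(rmed),
             rle_iqr = unname(riqr),
             outlier = abs(rmed) > median_thresh | riqr > iqr_thresh,
             stringsAsFactors = FALSE)
}

#' Map probe ids to genes and merge cohorts on shared genes
#'
#' Each cohort's rows are translated through the id map (rows with no
#' mapping are dropped), rows mapping to the same gene are collapsed, and
#' cohorts are joined on the intersection of their gene ids. The batch
#' label of the merged matrix is the cohort name.
#'
#' @param cohorts Named list of expression matrices.
#' @param idmap Named character vector (`source -> gene`) as from
#'   [load_id_map()], or `NULL` if rows are already gene ids.
#' @param collapse `"mean"` (average mapped rows) or `"max_var"` (keep the
#'   most variable source row).
#' @return Merged [expression_matrix()] with cohort-of-origin batch
#'   labels.
#' @export
map_and_merge <- function(cohorts, idmap = NULL,
                          collapse = c("mean", "max_var")) {
  collapse <- match.arg(collapse)
  if (!length(cohorts)) stop("need at least one cohort")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  mapped <- lapply(cohorts, function(x) {
    m <- em_values(as_expression_matrix(x))
    ids <- rownames(m)
    if (!is.null(idmap)) {
      tgt <- unname(idmap[ids])
      tgt[is.na(tgt)] <- ids[is.na(tgt)]  # ids without a mapping pass through
    } else tgt <- ids
    if (anyDuplicated(tgt)) {
      if (collapse == "mean") {
        cnt <- table(tgt)
        msum <- rowsum(m, tgt)
        msum <- msum / as.vector(cnt[rownames(msum)])
        m <- msum[unique(tgt), , drop = FALSE]  # first-appearance order
      } else {
        v <- apply(m, 1, var)
        ord <- order(tgt, -v)
        keep <- ord[!duplicated(tgt[ord])]
        keep <- keep[order(match(tgt[keep], unique(tgt)))]
        m <- m[keep, , drop = FALSE]
        rownames(m) <- tgt[keep]
      }
    } else rownames(m) <- tgt
    m
  })
  common <- Reduce(intersect, lapply(mapped, rownames))
  if (!length(common))
    stop("empty gene intersection between cohorts (",
         paste(names(cohorts), collapse = ", "), ")")
  joined <- do.call(cbind, lapply(mapped, function(m)
    m[common, , drop = FALSE]))
  batch <- rep(names(cohorts), vapply(mapped, ncol, 0L))
  expression_matrix(joined, batch)
}

#' RV coefficient between two sample-matched matrices
#'
#' A matrix correlation in `[0, 1]`: the trace inner product of the two
#' sample x sample cross-product matrices of gene-centered data, scaled
#' by the square root of the product of their squared total inertias.
#' Invariant to orthonormal rotation of either gene space.
#'
#' When the number of genes is large relative to the number of samples,
#' the diagonal of each cross-product matrix (the per-sample inertia)
#' dominates the trace and pushes the classical RV of even independent
#' matrices toward 1. `adjusted = TRUE` zeroes the diagonals before
#' taking the traces (the modified RV), which restores a near-zero value
#' for unrelated high-dimensional matrices while keeping
#' `RV(X, X) = 1` and rotation invariance.
#'
#' @param x,y Expression matrices measured on the same samples (columns
#'   aligned by sample id).
#' @param adjusted Use the modified (diagonal-removed) RV.
#' @return The RV coefficient.
#' @export
rv_coefficient <- function(x, y, adjusted = FALSE) {
  mx <- em_values(as_expression_matrix(x))
  my <- em_values(as_expression_matrix(y))
  if (ncol(mx) != ncol(my)) stop("x and y must share samples")
  if (!is.null(colnames(mx)) && !is.null(colnames(my))) {
    if (!setequal(colnames(mx), colnames(my)))
      stop("x and y must share sample ids")
    my <- my[, colnames(mx), drop = FALSE]
  }
  cx <- mx - rowMeans(mx)          # center each gene across samples
  cy <- my - rowMeans(my)
  Sx <- crossprod(cx)              # sample x sample cross-products
  Sy <- crossprod(cy)
  if (adjusted) { diag(Sx) <- 0; diag(Sy) <- 0 }
  den <- sqrt(sum(Sx^2) * sum(Sy^2))
  if (den == 0) stop("RV undefined for a zero-variance matrix")
  sum(Sx * Sy) / den
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' @param x Expression matrix (at least 3 samples).
#' @param distance `"euclidean"` on columns or `"correlation"`
#'   (`1 - Pearson r` between samples).
#' @param k Number of output dimensions.
#' @return Matrix of sample coordinates (samples x k).
#' @export
classical_mds <- function(x, distance = c("euclidean", "correlation"),
                          k = 2) {
  distance <- match.arg(distance)
  m <- em_values(as_expression_matrix(x))
  if (ncol(m) < 3) stop("need at least 3 samples")
  d <- if (distance == "euclidean") dist(t(m)) else
    as.dist(1 - cor(m))
  if (any(!is.finite(d))) stop("non-finite distances")
  coords <- cmdscale(d, k = k)
  rownames(coords) <- colnames(m)
  coords
}

#' Two-cluster survival quality control
#'
#' Average-linkage hierarchical clustering on `1 - Pearson correlation`
#' distance between samples, cut into two clusters, followed by a
#' log-rank test of overall survival between them. Used to check that the
#' dominant expression structure of a cohort is not confounded with
#' outcome.
#'
#' @param x Expression matrix.
#' @param clinical Clinical table covering the samples.
#' @return List with `clusters` (named labels 1/2) and `logrank`
#'   (a [logrank_test()] result, or `NA` p if a cluster has < 2 samples).
#' @export
two_cluster_survival_qc <- function(x, clinical) {
  m <- em_values(as_expression_matrix(x))
  clinical <- clinical_table(clinical)
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) < 10) stop("need at least 10 samples with survival")
  m <- m[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  d <- as.dist(1 - cor(m))
  labs <- cutree(hclust(d, method = "average"), k = 2)
  if (min(table(labs)) < 2) {
    warning("a cluster has fewer than 2 samples; log-rank p undefined")
    return(list(clusters = labs,
                logrank = list(statistic = NA_real_, p = NA_real_, df = 1)))
  }
  lr <- logrank_test(labs, cl$os_months, cl$event)
  list(clusters = labs, logrank = lr)
}
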