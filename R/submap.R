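# Subclass mapping: quantify genome-wide correspondence between
# pre-labeled subclasses of two independent cohorts via mutual
# marker-gene enrichment.

# signal-to-noise ratio of each gene for members of `subclass` vs rest
snr_scores <- function(m, labels, subclass) {
  inn <- labels == subclass
  n1 <- sum(inn); n0 <- sum(!inn)
  x1 <- m[, inn, drop = FALSE]; x0 <- m[, !inn, drop = FALSE]
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  s1 <- sqrt(rowSums((x1 - mu1)^2) / (n1 - 1))
  s0 <- sqrt(rowSums((x0 - mu0)^2) / (n0 - 1))
  den <- s1 + s0
  den[den == 0] <- .Machine$double.eps
  (mu1 - mu0) / den
}

check_occupancy <- function(labels) {
  tb <- table(labels)
  low <- names(tb)[tb < 0.1 * length(labels)]
  if (length(low))
    stop("subclass below 10% occupancy: ", paste(low, collapse = ", "))
  invisible(tb)
}

#' Marker genes of a subclass
#'
#' Genes scored by the signal-to-noise ratio
#' `(mu_in - mu_out) / (sd_in + sd_out)` of the subclass versus all other
#' samples; the top `m` up-regulated genes are returned.
#'
#' @param x Expression matrix.
#' @param labels Per-sample subclass labels (each subclass must hold at
#'   least 10 percent of the samples).
#' @param subclass The subclass whose markers are wanted.
#' @param m Number of markers.
#' @return Character vector of `m` gene ids, best first.
#' @export
subclass_markers <- function(x, labels, subclass, m = 100) {
  mat <- em_values(as_expression_matrix(x))
  labels <- as.character(labels)
  if (length(labels) != ncol(mat)) stop("one label per sample required")
  if (!subclass %in% labels) stop("unknown subclass: ", subclass)
  check_occupancy(labels)
  if (m > nrow(mat)) stop("m exceeds the number of genes")
  s <- snr_scores(mat, labels, subclass)
  names(sort(s, decreasing = TRUE))[seq_len(m)]
}

#' Enrichment score of a marker set in a ranked gene list
#'
#' Classic unweighted Kolmogorov-Smirnov running sum: walking down the
#' ranking, hits step up by `1/m` and misses step down by `1/(N - m)`;
#' the score is the maximum positive deviation, so markers concentrated
#' at the top give a score near 1. The degenerate case `m = N` scores 0.
#' When per-gene `scores` are supplied, hit steps are weighted by the
#' absolute score instead (the later weighted variant); the classic
#' unweighted form is the default used by the mapping procedure.
#'
#' @param markers Character vector of marker genes (subset of the
#'   ranking).
#' @param ranking Character vector: all genes, best-associated first.
#' @param scores Optional numeric scores aligned with `ranking` for the
#'   weighted variant.
#' @return The enrichment score in `[0, 1]`.
#' @export
enrichment_score <- function(markers, ranking, scores = NULL) {
  if (!length(markers)) stop("empty marker set")
  if (anyDuplicated(ranking)) stop("ranking contains duplicates")
  hit <- ranking %in% markers
  m <- sum(hit); N <- length(ranking)
  if (m == 0) stop("no marker present in the ranking")
  if (m == N) return(0)
  if (is.null(scores)) {
    steps <- ifelse(hit, 1 / m, -1 / (N - m))
  } else {
    stopifnot(length(scores) == N)
    w <- abs(scores)
    steps <- ifelse(hit, w / sum(w[hit]), -1 / (N - m))
  }
  max(c(0, cumsum(steps)))
}

# ES of each marker list against the ranking induced by each subclass of
# a cohort; returns matrix markers x subclasses
es_matrix <- function(marker_lists, m_mat, labels, subclasses) {
  vapply(subclasses, function(sc) {
    rk <- names(sort(snr_scores(m_mat, labels, sc), decreasing = TRUE))
    vapply(marker_lists, enrichment_score, 0, ranking = rk)
  }, numeric(length(marker_lists)))
}

#' Subclass mapping between two cohorts
#'
#' For every pair (Ai, Bj) of subclasses the enrichment of marker(Ai) at
#' the top of B's ranking for Bj is scored, its null distribution is
#' built by permuting B's sample labels, and the converse direction is
#' computed with the roles swapped. The two directional p-values combine
#' through the Fisher inverse chi-square statistic
#' `F = -2 (log pAB + log pBA)`, whose null is the exhaustive pairing of
#' the two per-cell ES null distributions; Benjamini-Hochberg adjustment
#' across all cells yields the subclass association (SA) matrix.
#'
#' @param a,b Expression matrices of the two cohorts (gene ids shared).
#' @param labels_a,labels_b Per-sample subclass labels (>= 10 percent
#'   occupancy each).
#' @param m Markers per subclass.
#' @param n_perm Label permutations per direction.
#' @param seed Integer seed; permutations of A and B derive independent
#'   streams so the result is transpose-symmetric under role exchange.
#' @param seed_perm_a,seed_perm_b Explicit per-cohort permutation seeds
#'   (override the derivation from `seed`).
#' @return List of class `SAMatrix`: `sa` (FDR-adjusted combined p per
#'   (Ai, Bj)), `fisher` (F statistics), `p_ab`, `p_ba`, `es_ab`,
#'   `es_ba`.
#' @export
run_submap <- function(a, labels_a, b, labels_b, m = 100, n_perm = 500,
                       seed = 1L, seed_perm_a = NULL, seed_perm_b = NULL) {
  ma <- em_values(as_expression_matrix(a))
  mb <- em_values(as_expression_matrix(b))
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  check_occupancy(labels_a); check_occupancy(labels_b)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) < 2 * m)
    stop("gene universe intersection (", length(common),
         ") smaller than 2m")
  ma <- ma[common, , drop = FALSE]; mb <- mb[common, , drop = FALSE]
  sa_cls <- sort(unique(labels_a)); sb_cls <- sort(unique(labels_b))
  if (is.null(seed_perm_a)) seed_perm_a <- as.integer(seed) + 1L
  if (is.null(seed_perm_b)) seed_perm_b <- as.integer(seed) + 2L

  markers_a <- lapply(sa_cls, function(s) subclass_markers(ma, labels_a, s, m))
  names(markers_a) <- sa_cls
  markers_b <- lapply(sb_cls, function(s) subclass_markers(mb, labels_b, s, m))
  names(markers_b) <- sb_cls

  # direction AB: markers from A, rankings + label permutations in B
  es_ab <- es_matrix(markers_a, mb, labels_b, sb_cls)      # |A| x |B|
  set.seed(seed_perm_b)
  null_ab <- array(NA_real_, c(n_perm, length(sa_cls), length(sb_cls)))
  for (k in seq_len(n_perm)) {
    pl <- sample(labels_b)
    null_ab[k, , ] <- es_matrix(markers_a, mb, pl, sb_cls)
  }
  # direction BA: markers from B, rankings + permutations in A
  es_ba <- es_matrix(markers_b, ma, labels_a, sa_cls)      # |B| x |A|
  set.seed(seed_perm_a)
  null_ba <- array(NA_real_, c(n_perm, length(sb_cls), length(sa_cls)))
  for (k in seq_len(n_perm)) {
    pl <- sample(labels_a)
    null_ba[k, , ] <- es_matrix(markers_b, ma, pl, sa_cls)
  }

  nI <- length(sa_cls); nJ <- length(sb_cls)
  p_ab <- matrix(NA_real_, nI, nJ, dimnames = list(sa_cls, sb_cls))
  p_ba <- matrix(NA_real_, nJ, nI, dimnames = list(sb_cls, sa_cls))
  fisher <- matrix(NA_real_, nI, nJ, dimnames = list(sa_cls, sb_cls))
  p_comb <- matrix(NA_real_, nI, nJ, dimnames = list(sa_cls, sb_cls))
  for (i in seq_len(nI)) for (j in seq_len(nJ)) {
    na_v <- null_ab[, i, j]
    nb_v <- null_ba[, j, i]
    p_ab[i, j] <- (1 + sum(na_v >= es_ab[i, j])) / (n_perm + 1)
    p_ba[j, i] <- (1 + sum(nb_v >= es_ba[j, i])) / (n_perm + 1)
    fisher[i, j] <- -2 * (log(p_ab[i, j]) + log(p_ba[j, i]))
    # null p's of each null ES within its own distribution (add-one)
    pa_null <- (1 + n_perm - rank(na_v, ties.method = "min")) / (n_perm + 1)
    pb_null <- (1 + n_perm - rank(nb_v, ties.method = "min")) / (n_perm + 1)
    f_null <- -2 * outer(log(pa_null), log(pb_null), "+")
    p_comb[i, j] <- (1 + sum(f_null >= fisher[i, j])) /
      (length(f_null) + 1)
  }
  sa <- matrix(bh_fdr(as.vector(p_comb)), nI, nJ,
               dimnames = dimnames(p_comb))
  structure(list(sa = sa, fisher = fisher, p_combined = p_comb,
                 p_ab = p_ab, p_ba = p_ba, es_ab = es_ab, es_ba = es_ba,
                 markers_a = markers_a, markers_b = markers_b,
                 n_perm = n_perm), class = "SAMatrix")
}

#' @export
print.SAMatrix <- function(x, ...) {
  cat("SA matrix (FDR-adjusted combined p-values):\n")
  print(round(x$sa, 4))
  invisible(x)
}
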