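# Risk-phenotype characterization: two-class gene-set analysis with the
# restandardized maxmean statistic, and jackknifed over-representation
# (EASE) scoring of functional categories.

# Welch t statistic per gene (rows) for class1 vs class2
welch_t <- function(m, labels, class1) {
  inn <- labels == class1
  n1 <- sum(inn); n0 <- sum(!inn)
  x1 <- m[, inn, drop = FALSE]; x0 <- m[, !inn, drop = FALSE]
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - mu0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (mu1 - mu0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# maxmean: larger of mean positive part vs mean negative part, signed;
# written with two sums (no pmax) because it runs inside permutation loops
maxmean_stat <- function(scores) {
  sa <- sum(abs(scores))
  ss <- sum(scores)
  n <- length(scores)
  sp <- (sa + ss) / (2 * n)
  sn <- (sa - ss) / (2 * n)
  if (sp >= sn) sp else -sn
}

#' Gene-set analysis with the restandardized maxmean statistic
#'
#' Per-gene Welch t scores are summarized per set by the maxmean
#' statistic (the larger in magnitude of the mean positive part and the
#' mean negative part, signed). Each set's statistic is restandardized
#' by the mean and SD of maxmean over random genome sets of the same
#' size, and significance comes from class-label permutation of the
#' whole procedure.
#'
#' @param x Expression matrix.
#' @param labels Two-class labels per sample (both classes >= 3).
#' @param genesets Named list of gene-id vectors (sets with no overlap
#'   with the matrix's genes are skipped with a warning).
#' @param n_perm Class-label permutations.
#' @param n_random Random same-size gene sets for restandardization.
#' @param seed Integer seed.
#' @return Data frame per set: `set`, `size`, `stat` (restandardized),
#'   `p`, `direction` (`"up_in_<class1>"`/`"down_in_<class1>"`), where
#'   class1 is the first label level.
#' @export
gsa <- function(x, labels, genesets, n_perm = 200, n_random = 200,
                seed = 1L) {
  m <- em_values(as_expression_matrix(x))
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop("one label per sample required")
  cls <- unique(labels)
  if (length(cls) != 2) stop("need exactly 2 classes")
  if (min(table(labels)) < 3) stop("each class needs >= 3 samples")
  universe <- rownames(m)
  idx_sets <- lapply(genesets, function(g) which(universe %in% g))
  empty <- lengths(idx_sets) == 0
  if (any(empty)) {
    warning("set(s) with no genes in the matrix skipped: ",
            paste(names(genesets)[empty], collapse = ", "))
    idx_sets <- idx_sets[!empty]
  }
  if (!length(idx_sets)) stop("no usable gene set")
  sizes <- lengths(idx_sets)
  set.seed(as.integer(seed))
  rand_idx <- lapply(sort(unique(sizes)), function(s)
    replicate(n_random, sample.int(length(universe), s), simplify = FALSE))
  names(rand_idx) <- as.character(sort(unique(sizes)))

  restandardized <- function(tt) {
    raw <- vapply(idx_sets, function(ii) maxmean_stat(tt[ii]), 0)
    vapply(seq_along(raw), function(k) {
      rnd <- vapply(rand_idx[[as.character(sizes[k])]],
                    function(ii) maxmean_stat(tt[ii]), 0)
      s <- sd(rnd)
      # a set spanning (nearly) the whole genome has a degenerate null
      if (!is.finite(s) || s < .Machine$double.eps) return(0)
      (raw[k] - mean(rnd)) / s
    }, 0)
  }
  tt_obs <- welch_t(m, labels, cls[1])$t
  stat_obs <- restandardized(tt_obs)
  exceed <- integer(length(stat_obs))
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    stat_b <- restandardized(welch_t(m, pl, cls[1])$t)
    exceed <- exceed + (abs(stat_b) >= abs(stat_obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(set = names(idx_sets), size = sizes, stat = stat_obs, p = p,
             direction = ifelse(stat_obs >= 0,
                                paste0("up_in_", cls[1]),
                                paste0("down_in_", cls[1])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differentially expressed genes between two classes
#'
#' Welch t-test per gene; genes below the p threshold are split by
#' direction.
#'
#' @param x Expression matrix.
#' @param labels Two-class labels (both classes >= 3 samples).
#' @param p_threshold Selection threshold.
#' @return List with `up` (higher in the first label level), `down`, and
#'   the per-gene `table` (`gene`, `t`, `p`).
#' @export
select_deg <- function(x, labels, p_threshold = 0.01) {
  m <- em_values(as_expression_matrix(x))
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("need exactly 2 classes")
  if (min(table(labels)) < 3) stop("each class needs >= 3 samples")
  wt <- welch_t(m, labels, cls[1])
  tab <- data.frame(gene = rownames(m), t = wt$t, p = wt$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  pass <- tab$p < p_threshold
  list(up = tab$gene[pass & tab$t > 0], down = tab$gene[pass & tab$t < 0],
       table = tab)
}

#' EASE over-representation analysis
#'
#' For each category, the plain over-representation p is the one-sided
#' hypergeometric upper tail of the observed hit count; the EASE score is
#' the same tail computed after removing one hit from the
#' category-by-list cell, a jackknife that penalizes categories supported
#' by very few genes (it is always at least the Fisher p, and equals 1
#' when a category has at most one hit). FDR adjustment is applied
#' within annotation system when a `system` is given, otherwise across
#' all categories.
#'
#' @param hits Character vector of selected genes (subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param categories Named list of gene-id vectors.
#' @param fdr_threshold Rows at or below this FDR are flagged.
#' @param system Optional character vector (one per category) of
#'   annotation systems for within-system FDR.
#' @return Data frame per category: `category`, `size`, `hits`,
#'   `list_total`, `background_total`, `fisher_p`, `ease_score`, `fdr`,
#'   `significant`.
#' @export
ease_analysis <- function(hits, background, categories,
                          fdr_threshold = 0.01, system = NULL) {
  hits <- unique(hits); background <- unique(background)
  if (!length(hits)) stop("empty hit list")
  if (!all(hits %in% background))
    stop("hit list must be a subset of the background")
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], background)
    K <- length(cat_genes)
    k <- length(intersect(cat_genes, hits))
    fisher_p <- if (K == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ease <- if (k <= 1 || K == 0) 1 else
      phyper(k - 2, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, size = K, hits = k, list_total = n,
               background_total = N, fisher_p = fisher_p,
               ease_score = ease, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(system)) {
    stopifnot(length(system) == nrow(out))
    out$system <- system
    out$fdr <- NA_real_
    for (s in unique(system))
      out$fdr[system == s] <- bh_fdr(out$ease_score[system == s])
  } else {
    out$fdr <- bh_fdr(out$ease_score)
  }
  out$significant <- out$fdr <= fdr_threshold
  rownames(out) <- NULL
  out
}
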