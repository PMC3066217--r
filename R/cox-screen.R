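# internal fast path: Xt is the full samples x genes matrix, idx the
# 1-based sample subset of the current fold; no validation, no copies
cox_screen_fast <- function(Xt, idx, time, event, alpha = 1,
                            newton_iter = 4L, standardize = TRUE) {
  sub_t <- time[idx]
  o <- order(sub_t, decreasing = TRUE)
  ts <- sub_t[o]
  ds <- as.integer(event[idx][o])
  grp <- match(ts, unique(ts))
  tie_end <- cumsum(tabulate(grp))[grp] - 1L   # last index of tie group
  cox_screen_cpp(Xt, idx[o] - 1L, ds, tie_end, alpha,
                 as.integer(newton_iter), isTRUE(standardize))
}

#' Univariate Cox screening across all genes
#'
#' For every gene, a univariate Cox model of survival on the
#' (standardized) expression values: the screening p-value is the
#' efficient score (log-rank-type) test at `beta = 0`, and coefficients
#' of genes passing `alpha` are refined to the partial-likelihood
#' maximum by Newton iterations (Breslow tie handling; genes failing the
#' screen keep the one-step estimate). Runs in compiled code; this is
#' the per-fold workhorse of the supervised principal-component
#' pipeline.
#'
#' @param x Expression matrix (genes x samples) or `ExpressionMatrix`.
#' @param os_months,event Survival outcome aligned with the columns.
#' @param alpha Genes with score-test `p < alpha` get Newton refinement
#'   (use `alpha = 1` to refine every gene).
#' @param standardize Standardize each gene to mean 0 / SD 1 first.
#' @param newton_iter Maximum Newton iterations for refined genes.
#' @return Data frame with `gene`, `coef`, `chisq`, `p` in input order.
#' @export
cox_screen <- function(x, os_months, event, alpha = 1,
                       standardize = TRUE, newton_iter = 4L) {
  m <- em_values(as_expression_matrix(x))
  n <- ncol(m)
  stopifnot(length(os_months) == n, length(event) == n)
  if (sum(event) < 1) stop("need at least 1 event")
  res <- cox_screen_fast(t(m), seq_len(n), os_months, event, alpha,
                         newton_iter, standardize)
  data.frame(gene = rownames(m), coef = res$coef, chisq = res$chisq,
             p = res$p, stringsAsFactors = FALSE)
}
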