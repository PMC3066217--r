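# Pathway-activation scoring: a signature trained on experimentally
# controlled on/off perturbation arrays summarizes each sample by a
# rank-1 metagene, and a Bayesian probit regression turns the metagene
# into a posterior probability of pathway activation.

# Albert-Chib Gibbs sampler (thinned, compiled); see src/probit_gibbs.cpp
probit_gibbs <- function(W, y, n_mc, burn_in, thin = 25, prior_var = 100) {
  probit_gibbs_cpp(W, as.integer(y), as.integer(n_mc),
                   as.integer(burn_in), as.integer(thin), prior_var)
}

#' Train a pathway-activation signature
#'
#' Signature genes are the top `n_genes` by absolute Welch t between
#' "on" and "off" training arrays; the metagene is the projection onto
#' the first singular vector of the standardized signature submatrix;
#' and a Bayesian probit regression of the class on the metagene is
#' sampled by the latent-variable Gibbs scheme (zero-mean normal prior).
#'
#' @param x_on,x_off Expression matrices of activated / control arrays
#'   (at least 5 each, same genes).
#' @param n_genes Signature size.
#' @param n_mc Posterior draws kept after burn-in.
#' @param burn_in Discarded initial iterations.
#' @param thin Keep every `thin`-th iteration: the slope chain is
#'   strongly autocorrelated when the classes separate, and thinning
#'   makes the kept draws close to independent.
#' @param seed Integer seed (reproducible posterior).
#' @param prior_var Prior variance of the probit coefficients.
#' @return Object of class `PathwaySignature`: signature genes, training
#'   standardization, unit-norm metagene loadings, posterior draws and
#'   summaries of the probit coefficients.
#' @export
train_signature <- function(x_on, x_off, n_genes = 50, n_mc = 5000,
                            burn_in = 1000, thin = 25, seed = 1L,
                            prior_var = 100) {
  mon <- em_values(as_expression_matrix(x_on))
  moff <- em_values(as_expression_matrix(x_off))
  if (ncol(mon) < 5 || ncol(moff) < 5)
    stop("need at least 5 arrays per class")
  common <- intersect(rownames(mon), rownames(moff))
  mon <- mon[common, , drop = FALSE]; moff <- moff[common, , drop = FALSE]
  m <- cbind(mon, moff)
  y <- rep(c(1, 0), c(ncol(mon), ncol(moff)))
  wt <- welch_t(m, ifelse(y == 1, "on", "off"), "on")
  sig <- rownames(m)[order(-abs(wt$t))][seq_len(min(n_genes, nrow(m)))]
  sub <- m[sig, , drop = FALSE]
  center <- rowMeans(sub)
  scale <- sqrt(rowSums((sub - center)^2) / (ncol(sub) - 1))
  scale[scale == 0] <- 1
  xstd <- (sub - center) / scale
  sv <- svd(xstd, nu = 1, nv = 0)
  loadings <- setNames(as.numeric(sv$u[, 1]), sig)
  meta <- as.numeric(crossprod(loadings, xstd))
  # orient the metagene so "on" arrays score high
  if (mean(meta[y == 1]) < mean(meta[y == 0])) {
    loadings <- -loadings; meta <- -meta
  }
  meta_c <- mean(meta); meta_s <- sd(meta)
  w <- cbind(1, (meta - meta_c) / meta_s)
  if (min(w[y == 1, 2]) > max(w[y == 0, 2]))
    warning("training classes perfectly separated; prior regularizes")
  set.seed(as.integer(seed))
  draws <- probit_gibbs(w, y, n_mc, burn_in, thin, prior_var)
  prob_train <- rowMeans(pnorm(tcrossprod(w, draws)))
  structure(list(genes = sig, center = center, scale = scale,
                 loadings = loadings, meta_center = meta_c,
                 meta_scale = meta_s, draws = draws,
                 posterior = list(mean = colMeans(draws),
                                  sd = apply(draws, 2, sd)),
                 train_prob = setNames(prob_train, colnames(m)),
                 labels = y, seed = as.integer(seed)),
            class = "PathwaySignature")
}

#' @export
print.PathwaySignature <- function(x, ...) {
  cat("PathwaySignature:", length(x$genes), "genes; probit slope",
      signif(x$posterior$mean[2], 3), "+/-", signif(x$posterior$sd[2], 3),
      "\n")
  invisible(x)
}

#' Probability of pathway activation in new samples
#'
#' Projects each sample onto the signature metagene (training
#' standardization) and reports the posterior-mean probit probability;
#' samples above 0.5 are called activated. New samples must be
#' co-batch-adjusted with the training arrays first.
#'
#' @param sig A `PathwaySignature`.
#' @param x Expression matrix of tumors.
#' @return Data frame `sample_id`, `probability`, `call` (logical).
#' @export
predict_activation <- function(sig, x) {
  m <- em_values(as_expression_matrix(x))
  missing <- setdiff(sig$genes, rownames(m))
  if (length(missing))
    stop("signature gene(s) absent: ", paste(missing, collapse = ", "))
  xstd <- (m[sig$genes, , drop = FALSE] - sig$center) / sig$scale
  meta <- as.numeric(crossprod(sig$loadings, xstd))
  w <- cbind(1, (meta - sig$meta_center) / sig$meta_scale)
  prob <- rowMeans(pnorm(tcrossprod(w, sig$draws)))
  data.frame(sample_id = colnames(m), probability = prob,
             call = prob > 0.5, stringsAsFactors = FALSE)
}

#' Association between pathway activation and risk group
#'
#' Cross-tabulates activation calls against high/low risk groups and
#' reports the sample odds ratio with a Woolf (log-normal) 95 percent
#' confidence interval and Fisher's exact p. Zero cells fall back to the
#' Haldane-Anscombe correction with a warning.
#'
#' @param calls Data frame from [predict_activation()].
#' @param risk Data frame from [apply_model()] or
#'   [loocv_risk_groups()]`$assignment`.
#' @return List: `odds_ratio`, `ci` (length 2), `p`, `table`.
#' @export
risk_pathway_association <- function(calls, risk) {
  common <- intersect(calls$sample_id, risk$sample_id)
  if (length(common) < 10) stop("need at least 10 overlapping samples")
  act <- calls$call[match(common, calls$sample_id)]
  grp <- risk$group[match(common, risk$sample_id)]
  tb <- table(factor(act, levels = c(TRUE, FALSE)),
              factor(grp, levels = c("high", "low")))
  tb <- matrix(as.numeric(tb), 2, 2,
               dimnames = list(c("active", "inactive"), c("high", "low")))
  zero <- any(tb == 0)
  tbc <- if (zero) tb + 0.5 else tb
  if (zero) warning("zero cell: Haldane-Anscombe correction applied")
  or <- (tbc[1, 1] * tbc[2, 2]) / (tbc[1, 2] * tbc[2, 1])
  se <- sqrt(sum(1 / tbc))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  p <- if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) NA_real_
       else fisher_exact(tb)$p
  list(odds_ratio = or, ci = ci, p = p, table = tb)
}
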