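# Location/scale empirical-Bayes batch adjustment.
#
# Model: y_ijg = alpha_g + X beta_g + gamma_ig + delta_ig * eps_ijg for
# batch i, sample j, gene g. Gene-wise batch effects are shrunk toward
# common batch-level priors (normal for gamma, inverse-gamma for delta in
# parametric mode; weighted nonparametric posterior means otherwise) and
# removed, returning data on the original scale.

# method-of-moments inverse-gamma hyperparameters for delta.hat
ig_aprior <- function(d) { m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2 }
ig_bprior <- function(d) { m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2 }

# iterative joint solution of the parametric posterior for one batch
it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                   conv = 1e-4) {
  n <- rowSums(!is.na(sdat))
  g_old <- g_hat; d_old <- d_hat
  change <- 1
  while (change > conv) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
    g_old <- g_new; d_old <- d_new
  }
  list(gamma_star = g_old, delta_star = d_old)
}

# nonparametric posterior: each gene's batch effect weighted by the
# likelihood of its standardized data under every other gene's estimates
np_sol <- function(sdat, g_hat, d_hat, mc_genes = NULL, seed = NULL) {
  G <- nrow(sdat)
  n <- ncol(sdat)
  ref <- seq_len(G)
  if (!is.null(mc_genes) && mc_genes < G) {
    if (!is.null(seed)) set.seed(seed)
    ref <- sort(sample.int(G, mc_genes))
  }
  g_star <- numeric(G); d_star <- numeric(G)
  for (g in seq_len(G)) {
    oth <- setdiff(ref, g)
    x <- sdat[g, ]
    sum2 <- vapply(oth, function(k) sum((x - g_hat[k])^2), 0)
    lik <- (1 / (2 * pi * d_hat[oth]))^(n / 2) *
      exp(-sum2 / (2 * d_hat[oth]))
    w <- lik / sum(lik)
    g_star[g] <- sum(g_hat[oth] * w)
    d_star[g] <- sum(d_hat[oth] * w)
  }
  list(gamma_star = g_star, delta_star = d_star)
}

#' Empirical-Bayes batch-effect adjustment
#'
#' Removes additive and multiplicative per-gene batch effects from a
#' merged expression matrix while preserving biological covariate signal.
#' Genes are standardized with a pooled location/scale fit, batch effects
#' are estimated per gene x batch, shrunk across genes via empirical
#' Bayes, and removed; the data are returned on the original scale.
#'
#' @param x Expression matrix (genes x samples).
#' @param batch Per-sample batch labels; defaults to the matrix's own.
#' @param covariates Optional data frame / matrix / vector of biological
#'   covariates to protect (model matrix built without intercept
#'   collinearity against batch).
#' @param mode `"parametric"` (normal / inverse-gamma priors, default) or
#'   `"nonparametric"` (weighted posterior means).
#' @param mc_genes In nonparametric mode, the number of reference genes
#'   sampled for the posterior weights (`NULL` uses all genes).
#' @param seed Seed for the nonparametric gene subsample.
#' @return List with `adjusted` (an [expression_matrix()]) and `model`
#'   (class `BatchAdjustModel`: gamma/delta posterior estimates, grand
#'   locations, covariate effects, pooled variances and batch-level
#'   hyperparameters).
#' @export
combat_adjust <- function(x, batch = NULL, covariates = NULL,
                          mode = c("parametric", "nonparametric"),
                          mc_genes = NULL, seed = NULL) {
  mode <- match.arg(mode)
  em <- as_expression_matrix(x)
  dat <- em$values
  batch <- em_batch(em, batch)
  if (is.null(batch)) stop("batch labels required")
  batch <- factor(batch[colnames(dat)], levels = unique(batch[colnames(dat)]))
  nb <- nlevels(batch)
  n_i <- as.vector(table(batch))
  if (nb == 1) {
    warning("single batch: data returned unchanged")
    return(list(adjusted = em, model = NULL))
  }
  if (any(n_i < 2))
    stop("every batch needs at least 2 samples (offending: ",
         paste(levels(batch)[n_i < 2], collapse = ", "), ")")

  bmat <- model.matrix(~ batch - 1)
  design <- bmat
  if (!is.null(covariates)) {
    cov_mm <- model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                  drop = FALSE]
    design <- cbind(bmat, cov_mm)
    if (qr(design)$rank < ncol(design))
      stop("covariates confounded with batch (design not full rank)")
  }
  n <- ncol(dat); G <- nrow(dat)

  # gene-wise least squares for batch means + covariate effects
  B_hat <- solve(crossprod(design), crossprod(design, t(dat)))  # p x G
  grand_mean <- crossprod(n_i / n, B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- rowMeans((dat - t(design %*% B_hat))^2)  # ML (divide by n)
  stand_mean <- matrix(grand_mean, G, n, byrow = FALSE)
  if (ncol(design) > nb) {
    extra <- design
    extra[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(extra %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(bmat), crossprod(bmat, t(s_data)))) # G x nb
  delta_hat <- sapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1, var))

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  a_prior <- apply(delta_hat, 2, ig_aprior)
  b_prior <- apply(delta_hat, 2, ig_bprior)

  gamma_star <- matrix(0, G, nb)
  delta_star <- matrix(1, G, nb)
  for (i in seq_len(nb)) {
    sdat_i <- s_data[, batch == levels(batch)[i], drop = FALSE]
    if (mode == "parametric") {
      sol <- it_sol(sdat_i, gamma_hat[, i], delta_hat[, i], gamma_bar[i],
                    t2[i], a_prior[i], b_prior[i])
    } else {
      sol <- np_sol(sdat_i, gamma_hat[, i], delta_hat[, i],
                    mc_genes = mc_genes, seed = seed)
    }
    gamma_star[, i] <- sol$gamma_star
    delta_star[, i] <- sol$delta_star
  }

  adj <- s_data
  for (i in seq_len(nb)) {
    j <- batch == levels(batch)[i]
    adj[, j] <- (s_data[, j, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean
  dimnames(adj) <- dimnames(dat)
  dimnames(gamma_star) <- dimnames(delta_star) <-
    dimnames(gamma_hat) <- list(rownames(dat), levels(batch))
  model <- structure(list(
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    alpha = as.numeric(grand_mean), var_pooled = var_pooled,
    beta = if (ncol(design) > nb)
      t(B_hat[-seq_len(nb), , drop = FALSE]) else NULL,
    hyper = list(gamma_bar = gamma_bar, t2 = t2, lambda = a_prior,
                 theta = b_prior),
    batch_levels = levels(batch), mode = mode), class = "BatchAdjustModel")
  list(adjusted = expression_matrix(adj, em_batch(em, batch = batch)),
       model = model)
}

#' Co-adjust a validation cohort with a training set
#'
#' Concatenates the two matrices on shared genes, treats cohort as batch
#' and re-runs [combat_adjust()], so that a trained model can be applied
#' to the validation samples on a common scale.
#'
#' @param train,validation Expression matrices sharing gene ids.
#' @param mode Passed to [combat_adjust()].
#' @return List with re-adjusted `train` and `validation` matrices.
#' @export
coadjust_cohorts <- function(train, validation,
                             mode = c("parametric", "nonparametric")) {
  mode <- match.arg(mode)
  mt <- em_values(as_expression_matrix(train))
  mv <- em_values(as_expression_matrix(validation))
  common <- intersect(rownames(mt), rownames(mv))
  if (!length(common)) stop("no shared genes between cohorts")
  both <- cbind(mt[common, , drop = FALSE], mv[common, , drop = FALSE])
  batch <- rep(c("train", "validation"), c(ncol(mt), ncol(mv)))
  res <- combat_adjust(expression_matrix(both, batch), mode = mode)
  adj <- res$adjusted$values
  list(train = expression_matrix(adj[, seq_len(ncol(mt)), drop = FALSE]),
       validation = expression_matrix(adj[, ncol(mt) + seq_len(ncol(mv)),
                                          drop = FALSE]),
       model = res$model)
}
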