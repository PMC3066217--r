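# Supervised principal-component survival modeling: univariate screening,
# rank by |Cox coefficient|, principal components of the selected genes,
# Cox regression on the leading components, cross-validated risk groups,
# permutation significance and cross-cohort transfer.

align_clinical <- function(x, clinical) {
  m <- em_values(as_expression_matrix(x))
  clinical <- clinical_table(clinical)
  common <- intersect(colnames(m), clinical$sample_id)
  if (!length(common)) stop("no samples shared between matrix and clinical")
  m <- m[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  list(m = m, time = cl$os_months, event = cl$event, ids = common,
       clinical = cl)
}

# order screened genes: |coef| descending, ties by ascending p then gene id
rank_screened <- function(scr) {
  scr[order(-abs(scr$coef), scr$p, scr$gene), , drop = FALSE]
}

# minimal fit used inside every fold/permutation; Xt is the full
# samples x genes matrix, idx the samples of this fold (no copies)
superpc_core <- function(Xt, gene_ids, idx, time, event, alpha, top_k,
                         n_pc, newton_iter = 4L) {
  scr <- cox_screen_fast(Xt, idx, time, event, alpha, newton_iter)
  keep <- which(scr$p < alpha)
  if (length(keep) < n_pc) {
    # degenerate screen (e.g. null data in a fold): fall back to the
    # smallest-p genes so every fold still yields a model
    keep <- order(scr$p, gene_ids)[seq_len(n_pc)]
  }
  # rank kept genes: |coef| descending, ties by ascending p then gene id
  keep <- keep[order(-abs(scr$coef[keep]), scr$p[keep], gene_ids[keep])]
  sel_idx <- head(keep, top_k)
  sel <- gene_ids[sel_idx]
  sub <- t(Xt[idx, sel_idx, drop = FALSE])
  rownames(sub) <- sel
  time <- time[idx]
  event <- event[idx]
  n <- ncol(sub)
  center <- rowMeans(sub)
  scale <- sqrt(rowSums((sub - center)^2) / (n - 1))
  scale[scale == 0] <- 1
  xstd <- (sub - center) / scale
  sv <- svd(xstd, nu = min(n_pc, nrow(xstd)), nv = 0)
  loadings <- sv$u[, seq_len(n_pc), drop = FALSE]
  rownames(loadings) <- sel
  scores <- crossprod(loadings, xstd)            # n_pc x n
  cfit <- survival::coxph.fit(
    t(scores), survival::Surv(time, event), strata = NULL, offset = NULL,
    init = NULL, control = survival::coxph.control(iter.max = 30),
    weights = NULL, method = "efron", rownames = NULL)
  pc_coef <- as.numeric(cfit$coefficients)
  if (any(!is.finite(pc_coef)) || any(abs(pc_coef) > 50))
    stop("Cox fit on principal components diverged")
  risk <- as.numeric(crossprod(scores, pc_coef))
  names(risk) <- rownames(Xt)[idx]
  list(genes = sel, center = center, scale = scale, loadings = loadings,
       pc_coef = pc_coef, risk = risk,
       screen = data.frame(gene = gene_ids[keep], coef = scr$coef[keep],
                           p = scr$p[keep], stringsAsFactors = FALSE))
}

superpc_score_new <- function(core, m) {
  xstd <- (m[core$genes, , drop = FALSE] - core$center) / core$scale
  as.numeric(crossprod(core$pc_coef, crossprod(core$loadings, xstd)))
}

#' Screen genes by univariate survival association and rank them
#'
#' Univariate Cox regression per standardized gene; genes with `p <
#' alpha` are kept and ordered by absolute Cox coefficient (descending),
#' ties broken by ascending p then gene id.
#'
#' @param x Expression matrix.
#' @param clinical Clinical table (matched by sample id).
#' @param alpha Screening significance level.
#' @param newton_iter Newton iterations for coefficient refinement.
#' @return Data frame `gene`, `coef`, `p` (sorted); zero rows (with a
#'   warning) if nothing passes.
#' @export
screen_and_rank <- function(x, clinical, alpha = 0.05, newton_iter = 4L) {
  al <- align_clinical(x, clinical)
  scr <- cox_screen(al$m, al$time, al$event, alpha = alpha,
                    newton_iter = newton_iter)
  keep <- scr[scr$p < alpha, , drop = FALSE]
  if (!nrow(keep)) {
    warning("no gene passed the screen at alpha = ", alpha)
    return(keep[, c("gene", "coef", "p")])
  }
  keep <- rank_screened(keep)
  rownames(keep) <- NULL
  keep[, c("gene", "coef", "p")]
}

#' Fit a supervised principal-component survival model
#'
#' Computes principal components of the standardized top-`top_k` screened
#' genes and fits a Cox model of survival on the first `n_pc` components.
#' The risk score of a sample is the PC-Cox linear predictor; by
#' construction a higher score means a higher hazard.
#'
#' @param x Expression matrix.
#' @param clinical Clinical table.
#' @param top_k Number of top-ranked screened genes used.
#' @param n_pc Number of principal components (1-3 typical).
#' @param alpha Screening level.
#' @param newton_iter Screening Newton iterations.
#' @return Object of class `SuperPCModel`: selected genes, training
#'   standardization, PC loadings, PC Cox coefficients, training risk
#'   scores and the training-median risk threshold. The training data are
#'   retained for nested refits.
#' @export
fit_superpc <- function(x, clinical, top_k = 20, n_pc = 1, alpha = 0.05,
                        newton_iter = 4L) {
  if (top_k < n_pc) stop("top_k must be at least n_pc")
  al <- align_clinical(x, clinical)
  core <- superpc_core(t(al$m), rownames(al$m), seq_len(ncol(al$m)),
                       al$time, al$event, alpha, top_k, n_pc, newton_iter)
  structure(c(core, list(
    n_pc = n_pc, top_k = top_k, alpha = alpha,
    threshold = median(core$risk),
    training = list(m = al$m, time = al$time, event = al$event,
                    ids = al$ids))), class = "SuperPCModel")
}

#' @export
print.SuperPCModel <- function(x, ...) {
  cat("SuperPCModel:", length(x$genes), "genes,", x$n_pc,
      "PC(s); risk threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Apply a fitted model to new samples
#'
#' Scores new samples with the training standardization, loadings and PC
#' Cox coefficients; no parameter is re-estimated. Samples with a score
#' above the threshold are called high risk (ties go to low risk).
#'
#' @param model A `SuperPCModel`.
#' @param x_new Expression matrix, already co-batch-adjusted with the
#'   training data (see [coadjust_cohorts()]).
#' @param threshold_source `"training"` (the transferred training median,
#'   default) or `"cohort_median"` (median of the new cohort's scores).
#' @param impute_mean If `TRUE`, genes missing from `x_new` are imputed
#'   at the training mean (with a warning) instead of erroring.
#' @return Data frame `sample_id`, `score`, `group` (`"high"`/`"low"`).
#' @export
apply_model <- function(model, x_new,
                        threshold_source = c("training", "cohort_median"),
                        impute_mean = FALSE) {
  threshold_source <- match.arg(threshold_source)
  m <- em_values(as_expression_matrix(x_new))
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing)) {
    if (!impute_mean)
      stop("model gene(s) absent from new data: ",
           paste(missing, collapse = ", "))
    warning("imputing training mean for: ", paste(missing, collapse = ", "))
    pad <- matrix(model$center[missing], length(missing), ncol(m),
                  dimnames = list(missing, colnames(m)))
    m <- rbind(m, pad)
  }
  score <- superpc_score_new(model, m)
  thr <- if (threshold_source == "training") model$threshold
         else median(score)
  data.frame(sample_id = colnames(m), score = score,
             group = ifelse(score > thr, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated risk groups
#'
#' For every sample the entire pipeline (screening, ranking, PC fit, Cox
#' fit) is re-run on the remaining samples and the held-out sample is
#' scored by that fold's model, so the resulting risk groups carry no
#' selection-bias optimism. Groups split at the median of the
#' cross-validated scores (ties to low risk) and are compared by the
#' log-rank test.
#'
#' @inheritParams fit_superpc
#' @return List with `assignment` (sample_id, score, group), `logrank`
#'   (a `TestResult`) and `scores`.
#' @export
loocv_risk_groups <- function(x, clinical, alpha = 0.05, top_k = 20,
                              n_pc = 1, newton_iter = 4L) {
  al <- align_clinical(x, clinical)
  n <- ncol(al$m)
  if (n < 20) stop("need at least 20 samples for LOOCV")
  Xt <- t(al$m)
  gid <- rownames(al$m)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (sum(al$event[-i]) < 1) stop("a fold has no events")
    core <- superpc_core(Xt, gid, seq_len(n)[-i], al$time, al$event,
                         alpha, top_k, n_pc, newton_iter)
    xnew <- matrix(Xt[i, match(core$genes, gid)], ncol = 1,
                   dimnames = list(core$genes, al$ids[i]))
    scores[i] <- superpc_score_new(core, xnew)
  }
  thr <- median(scores)
  group <- ifelse(scores > thr, "high", "low")
  lr <- if (length(unique(group)) == 2)
    logrank_test(group, al$time, al$event)
  else structure(list(statistic = 0, p = 1, df = 1), class = "TestResult")
  list(assignment = data.frame(sample_id = al$ids, score = scores,
                               group = group, stringsAsFactors = FALSE),
       logrank = lr, scores = setNames(scores, al$ids), threshold = thr)
}

#' Permutation significance of the cross-validated survival split
#'
#' Survival records (time, event pairs) are randomly reassigned to
#' samples and the complete cross-validated risk-group procedure is
#' repeated for each permutation; the p-value is the add-one fraction of
#' permutations whose log-rank statistic reaches the observed one.
#'
#' @inheritParams loocv_risk_groups
#' @param B Number of permutations (at least 20).
#' @param seed Integer seed.
#' @return List of class `PermutationResult`: `observed`, `permuted`
#'   (length `B`), `p`.
#' @export
permutation_pvalue <- function(x, clinical, alpha = 0.05, top_k = 20,
                               n_pc = 1, B = 100, seed = 1L,
                               newton_iter = 4L) {
  if (B < 20) stop("need at least 20 permutations")
  al <- align_clinical(x, clinical)
  obs <- loocv_risk_groups(x, clinical, alpha, top_k, n_pc, newton_iter)
  set.seed(as.integer(seed))
  perm_stats <- numeric(B)
  cl <- al$clinical
  for (b in seq_len(B)) {
    idx <- sample(length(al$ids))
    cl_b <- cl
    cl_b$os_months <- al$time[idx]
    cl_b$event <- al$event[idx]
    perm_stats[b] <- loocv_risk_groups(
      expression_matrix(al$m), cl_b, alpha, top_k, n_pc,
      newton_iter)$logrank$statistic
  }
  p <- (1 + sum(perm_stats >= obs$logrank$statistic)) / (B + 1)
  structure(list(observed = obs$logrank$statistic, permuted = perm_stats,
                 p = p, loocv = obs), class = "PermutationResult")
}

#' Cross-dataset marker pool
#'
#' Per cohort, supervised PC models are fit over a grid of gene-set sizes
#' and the largest gene set is kept whose cross-validated split is
#' significant in the home cohort and whose transferred model splits
#' every other cohort significantly. The pool is the union of the
#' per-cohort selections, with provenance.
#'
#' @param cohorts Named list of expression matrices.
#' @param clinicals Named list of clinical tables (same names).
#' @param top_k_grid Candidate gene-set sizes.
#' @param alpha Screening level.
#' @param n_pc Principal components per model.
#' @param p_cut Significance level for home and transfer splits.
#' @return List of class `GenePool`: `pool` (gene ids), `provenance`
#'   (cohort -> selected genes), `details` per cohort.
#' @export
cross_dataset_pool <- function(cohorts, clinicals,
                               top_k_grid = c(5, 10, 15, 20, 25),
                               alpha = 0.05, n_pc = 1, p_cut = 0.05) {
  if (length(cohorts) < 1) stop("need at least one cohort")
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  if (is.null(names(clinicals))) names(clinicals) <- names(cohorts)
  selections <- list()
  details <- list()
  for (cn in names(cohorts)) {
    best <- NULL
    tried <- list()
    for (k in sort(top_k_grid)) {
      home <- tryCatch(
        loocv_risk_groups(cohorts[[cn]], clinicals[[cn]], alpha = alpha,
                          top_k = k, n_pc = n_pc),
        error = function(e) NULL)
      if (is.null(home) || is.na(home$logrank$p) ||
          home$logrank$p >= p_cut) next
      model <- fit_superpc(cohorts[[cn]], clinicals[[cn]], top_k = k,
                           n_pc = n_pc, alpha = alpha)
      ok <- TRUE
      transfer_p <- c()
      for (on in setdiff(names(cohorts), cn)) {
        ra <- tryCatch(apply_model(model, cohorts[[on]]),
                       error = function(e) NULL)
        if (is.null(ra) || length(unique(ra$group)) < 2) { ok <- FALSE; break }
        alv <- align_clinical(cohorts[[on]], clinicals[[on]])
        grp <- ra$group[match(alv$ids, ra$sample_id)]
        pv <- logrank_test(grp, alv$time, alv$event)$p
        transfer_p[on] <- pv
        if (is.na(pv) || pv >= p_cut) { ok <- FALSE; break }
      }
      tried[[as.character(k)]] <- list(home_p = home$logrank$p,
                                       transfer_p = transfer_p, valid = ok)
      if (ok) best <- list(k = k, genes = model$genes,
                           home_p = home$logrank$p,
                           transfer_p = transfer_p)
    }
    details[[cn]] <- tried
    if (!is.null(best)) selections[[cn]] <- best
  }
  if (!length(selections)) {
    warning("no cohort yielded a significant transferable model")
    pool <- character(0)
  } else {
    pool <- Reduce(union, lapply(selections, `[[`, "genes"))
  }
  prov <- lapply(selections, `[[`, "genes")
  structure(list(pool = pool, provenance = prov, selections = selections,
                 details = details), class = "GenePool")
}

#' Serialize a fitted model to JSON
#'
#' Writes the transferable part of a `SuperPCModel` (genes, training
#' standardization, loadings, PC Cox coefficients, risk threshold) so a
#' frozen model can be re-applied elsewhere. The retained training data
#' are not serialized, so a deserialized model supports
#' [apply_model()] but not [nested_submodel()].
#'
#' @param model A `SuperPCModel`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_superpc <- function(model, path) {
  obj <- list(genes = model$genes,
              center = unname(model$center),
              scale = unname(model$scale),
              loadings = as.numeric(model$loadings),  # column-major
              pc_coef = model$pc_coef,
              n_pc = model$n_pc, top_k = model$top_k,
              alpha = model$alpha, threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model from JSON
#' @param path JSON file written by [write_superpc()].
#' @return A `SuperPCModel` usable with [apply_model()].
#' @export
read_superpc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(as.numeric(obj$loadings), ncol = obj$n_pc)
  rownames(loadings) <- obj$genes
  structure(list(genes = obj$genes,
                 center = setNames(obj$center, obj$genes),
                 scale = setNames(obj$scale, obj$genes),
                 loadings = loadings, pc_coef = obj$pc_coef,
                 n_pc = obj$n_pc, top_k = obj$top_k, alpha = obj$alpha,
                 threshold = obj$threshold, risk = NULL,
                 training = NULL), class = "SuperPCModel")
}

#' Rank model genes by contribution weight
#'
#' The weight of a gene is the sum over used components of
#' `|loading x PC Cox coefficient|`, i.e. its contribution to the risk
#' score per SD of expression.
#'
#' @param model A `SuperPCModel`.
#' @return Data frame `gene`, `weight`, sorted by decreasing weight.
#' @export
rank_model_genes <- function(model) {
  w <- abs(model$loadings) %*% abs(model$pc_coef)
  out <- data.frame(gene = rownames(model$loadings), weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Nested submodel on the top-m genes
#'
#' Refits the principal components and the PC Cox model on the `m`
#' highest-weight genes of a fitted model, using the retained training
#' data. Screening is not redone: the gene universe is the parent
#' model's, mirroring progressively smaller signatures ranked by model
#' contribution.
#'
#' @param model A `SuperPCModel` (with retained training data).
#' @param m Number of genes to keep (`n_pc <= m <= top_k`).
#' @return A new `SuperPCModel` on the reduced gene set.
#' @export
nested_submodel <- function(model, m) {
  if (m < model$n_pc) stop("m must be at least n_pc")
  if (m > length(model$genes)) stop("m exceeds the model's gene count")
  top <- head(rank_model_genes(model)$gene, m)
  tr <- model$training
  sub <- tr$m[top, , drop = FALSE]
  n <- ncol(sub)
  center <- rowMeans(sub)
  scale <- sqrt(rowSums((sub - center)^2) / (n - 1))
  scale[scale == 0] <- 1
  xstd <- (sub - center) / scale
  sv <- svd(xstd, nu = model$n_pc, nv = 0)
  loadings <- sv$u[, seq_len(model$n_pc), drop = FALSE]
  rownames(loadings) <- top
  scores <- crossprod(loadings, xstd)
  cfit <- survival::coxph.fit(
    t(scores), survival::Surv(tr$time, tr$event), strata = NULL,
    offset = NULL, init = NULL,
    control = survival::coxph.control(iter.max = 30), weights = NULL,
    method = "efron", rownames = NULL)
  pc_coef <- as.numeric(cfit$coefficients)
  risk <- as.numeric(crossprod(scores, pc_coef))
  names(risk) <- colnames(tr$m)
  structure(list(genes = top, center = center, scale = scale,
                 loadings = loadings, pc_coef = pc_coef, risk = risk,
                 screen = model$screen, n_pc = model$n_pc, top_k = m,
                 alpha = model$alpha, threshold = median(risk),
                 training = tr), class = "SuperPCModel")
}
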