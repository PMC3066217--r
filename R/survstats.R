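#' Cox proportional hazards fit
#'
#' Multivariate Cox regression via partial-likelihood maximization, with
#' Efron (default) or Breslow tie handling. Thin, validated wrapper over
#' the standard fitter with the pipeline's error contract: no events,
#' zero-variance covariates and monotone-likelihood divergence are
#' explicit errors.
#'
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @param os_months Follow-up times.
#' @param event Event indicator (1 = death).
#' @param ties `"efron"` or `"breslow"`.
#' @return List of class `SurvivalFit`: per-covariate `coef`, `se`, `hr`,
#'   `hr_lower`, `hr_upper` (Wald 95 percent CI), `p`, plus `loglik`.
#' @export
fit_cox <- function(covariates, os_months, event,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cv <- as.data.frame(covariates)
  if (!nrow(cv)) stop("empty covariate matrix")
  if (sum(event) < 1) stop("no events: Cox model unidentifiable")
  num <- vapply(cv, is.numeric, TRUE)
  if (any(num)) {
    zv <- vapply(cv[num], function(v) var(v, na.rm = TRUE) == 0, TRUE)
    if (any(zv))
      stop("zero-variance covariate(s): ",
           paste(names(cv)[num][zv], collapse = ", "))
  }
  dat <- cbind(data.frame(.time = os_months, .event = event), cv)
  # muffle the fitter's convergence warning: divergence is re-detected
  # below and raised as the monotone-likelihood error
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(.time, .event) ~ ., data = dat, ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- coef(fit)
  if (diverged || any(!is.finite(cf)) || any(abs(cf) > 20))
    stop("monotone likelihood detected (diverging coefficient)")
  se <- sqrt(diag(fit$var))
  structure(list(
    coef = cf, se = se, hr = exp(cf),
    hr_lower = exp(cf - 1.96 * se), hr_upper = exp(cf + 1.96 * se),
    p = 2 * pnorm(-abs(cf / se)),
    loglik = fit$loglik[2], n = fit$n, nevent = fit$nevent),
    class = "SurvivalFit")
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator per group; the median is the smallest observed
#' time with `S(t) <= 0.5` (`NA` = not reached).
#'
#' @param os_months Follow-up times.
#' @param event Event indicator.
#' @param group Optional group labels (single curve if omitted).
#' @return Named list of curves, each with `time`, `surv`, `n_risk`,
#'   `n_event`, `n` and `median`.
#' @export
km_estimate <- function(os_months, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(os_months))
  group <- as.character(group)
  if (any(table(group) == 0)) stop("empty group")
  out <- lapply(split(seq_along(os_months), group), function(idx) {
    fit <- survival::survfit(
      survival::Surv(os_months[idx], event[idx]) ~ 1)
    s <- fit$surv
    med <- if (any(s <= 0.5)) fit$time[which(s <= 0.5)[1]] else NA_real_
    list(time = fit$time, surv = s, n_risk = fit$n.risk,
         n_event = fit$n.event, n = length(idx), median = med)
  })
  out
}

#' Log-rank test between groups
#'
#' Observed-minus-expected chi-square statistic with hypergeometric
#' variance at each event time.
#'
#' @param group Group labels (at least 2 non-empty groups).
#' @param os_months Follow-up times.
#' @param event Event indicator (at least 1 event).
#' @return List of class `TestResult`: `statistic`, `p`, `df`.
#' @export
logrank_test <- function(group, os_months, event) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("need at least 2 groups")
  if (sum(event) < 1) stop("need at least 1 event")
  fit <- survival::survdiff(
    survival::Surv(os_months, event) ~ group)
  df <- length(fit$n) - 1
  structure(list(statistic = fit$chisq,
                 p = pchisq(fit$chisq, df, lower.tail = FALSE), df = df),
            class = "TestResult")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from hypergeometric enumeration: the sum of
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one. The odds ratio is the sample odds
#' ratio `ad / bc`; when a cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied and flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List of class `TestResult`: `odds_ratio`, `p`, `haldane` flag.
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == 2) || any(tb < 0) || any(tb != round(tb)))
    stop("need a 2x2 table of non-negative integers")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("zero margin: Fisher test undefined")
  a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
  m1 <- a + b; n1 <- a + c_; N <- sum(tb)
  support <- max(0, n1 - (N - m1)):min(m1, n1)
  probs <- dhyper(support, m1, N - m1, n1)
  p_obs <- dhyper(a, m1, N - m1, n1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  haldane <- any(tb == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  if (haldane)
    warning("zero cell: odds ratio uses Haldane-Anscombe correction")
  structure(list(odds_ratio = or, p = p, haldane = haldane),
            class = "TestResult")
}

#' Code clinical covariates for multivariate survival adjustment
#'
#' Standard coding for adjusted Cox models: age dichotomized at 65
#' years, grade dichotomized low (grade in `low_grade`) versus high,
#' stage as a number, and debulking as optimal (residual disease at
#' most 1 cm) versus not. Missing values stay `NA`; multivariate fits
#' then use complete cases only (the fitter drops incomplete rows).
#'
#' @param clinical A [clinical_table()] data frame.
#' @param low_grade Grades counted as low (default 1; use `c(1, 2)` to
#'   treat grade 2 as low as well).
#' @return Data frame of numeric covariates aligned with the table's
#'   rows: `age_ge65`, `stage`, `high_grade`, `optimal_debulking`.
#' @export
prognostic_covariates <- function(clinical, low_grade = 1) {
  cl <- clinical_table(clinical)
  get_col <- function(nm) if (nm %in% names(cl)) cl[[nm]] else
    rep(NA, nrow(cl))
  deb <- as.character(get_col("debulking"))
  deb[deb %in% "unknown"] <- NA
  data.frame(
    age_ge65 = as.numeric(get_col("age_years") >= 65),
    stage = as.numeric(get_col("stage")),
    high_grade = as.numeric(!get_col("grade") %in% low_grade &
                              !is.na(get_col("grade"))) +
      ifelse(is.na(get_col("grade")), NA, 0),
    optimal_debulking = as.numeric(deb == "optimal"),
    row.names = cl$sample_id)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values (step-up with monotonicity enforcement).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' @importFrom stats dhyper as.dist
NULL
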