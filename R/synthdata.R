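#' Simulation configuration for multi-batch survival studies
#'
#' Defines the generative model used throughout the test bench: per-gene
#' baseline log2 intensities, a latent prognostic score expressed through
#' a block of prognostic genes, discrete molecular subclasses with marker
#' programs, additive/multiplicative per-gene batch effects, exponential
#' survival driven by the latent score, and uniform administrative
#' censoring calibrated to a target fraction.
#'
#' @param n_batches Number of batches (cohorts).
#' @param samples_per_batch Samples in each batch.
#' @param n_genes Total genes.
#' @param n_prognostic Genes carrying the latent prognostic score.
#' @param beta Log hazard ratio per SD of the latent score.
#' @param gamma_sd SD of the additive per-gene batch shifts (log2 units).
#' @param delta_shape Dispersion (SD of log scale) of the multiplicative
#'   per-gene batch factor applied to the noise; 0 means none.
#' @param baseline_hazard Events per month at latent score 0.
#' @param censor_rate Target marginal censoring fraction in `[0, 1)`.
#' @param n_subclasses Number of molecular subclasses (0 disables).
#' @param subclass_effect Mean log2 shift of subclass marker genes.
#' @param markers_per_subclass Marker genes per subclass program.
#' @param prog_effect Log2 expression change of a prognostic gene per SD
#'   of the latent score.
#' @param noise_sd Range of per-gene residual noise SDs (length 2).
#' @param seed Integer seed; identical configs give identical studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_batches = 4, samples_per_batch = 60,
                       n_genes = 2000, n_prognostic = 20, beta = 0.8,
                       gamma_sd = 2, delta_shape = 0.3,
                       baseline_hazard = 0.02, censor_rate = 0.3,
                       n_subclasses = 2, subclass_effect = 1,
                       markers_per_subclass = 50, prog_effect = 1,
                       noise_sd = c(0.25, 0.75), seed = 1L) {
  cfg <- list(n_batches = as.integer(n_batches),
              samples_per_batch = as.integer(samples_per_batch),
              n_genes = as.integer(n_genes),
              n_prognostic = as.integer(n_prognostic),
              beta = beta, gamma_sd = gamma_sd, delta_shape = delta_shape,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_subclasses = as.integer(n_subclasses),
              subclass_effect = subclass_effect,
              markers_per_subclass = as.integer(markers_per_subclass),
              prog_effect = prog_effect, noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_batches < 1 || samples_per_batch < 1 || n_genes < 1)
      stop("counts must be positive")
    if (n_prognostic > n_genes)
      stop("n_prognostic exceeds n_genes")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("censor_rate must be in [0, 1)")
    if (delta_shape < 0) stop("delta_shape must be >= 0")
    if (n_subclasses > 0 &&
        n_prognostic + n_subclasses * markers_per_subclass > n_genes)
      stop("prognostic + subclass marker genes exceed n_genes")
  })
  class(cfg) <- "sim_config"
  cfg
}

# solve the uniform censoring horizon C so that the average of
# P(T > U) = (1 - exp(-lambda C)) / (lambda C) over samples hits the target
censor_horizon <- function(lambda, target) {
  if (target <= 0) return(Inf)
  f <- function(C) mean((1 - exp(-lambda * C)) / (lambda * C)) - target
  # f is decreasing in C from 1 to 0
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  uniroot(f, c(1e-9, upper), tol = 1e-10)$root
}

#' Simulate a multi-batch integration study with known truth
#'
#' Expression is built as baseline + subclass marker shifts + prognostic
#' signal + batch location effect, with residual noise scaled by a
#' multiplicative batch factor (the location/scale form the batch
#' adjustment model assumes). Survival times are exponential with hazard
#' `baseline_hazard * exp(beta * z)` for the standardized latent score
#' `z`, censored by an independent uniform administrative horizon solved
#' numerically to hit `censor_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with `expression` (an [expression_matrix()] carrying
#'   batch labels), `clinical` (a [clinical_table()] data frame) and
#'   `truth` (prognostic gene ids, latent scores, batch gamma/delta
#'   matrices, subclass labels and marker programs).
#' @export
simulate_integration_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  B <- config$n_batches
  n <- B * config$samples_per_batch
  genes <- sprintf("G%04d", seq_len(G))
  samples <- sprintf("S%03d", seq_len(n))
  batch <- rep(sprintf("batch%d", seq_len(B)), each = config$samples_per_batch)
  names(batch) <- samples

  mu <- rnorm(G, 7, 1)                      # per-gene baseline
  sigma <- runif(G, config$noise_sd[1], config$noise_sd[2])
  X <- matrix(mu, G, n)

  prog <- if (config$n_prognostic > 0) genes[seq_len(config$n_prognostic)]
          else character(0)
  z <- rnorm(n)                             # latent prognostic score
  if (length(prog)) {
    sgn <- rep(c(1, -1), length.out = length(prog))  # mixed directions
    X[seq_along(prog), ] <- X[seq_along(prog), ] +
      config$prog_effect * outer(sgn, z)
  }

  subclass <- NULL
  marker_sets <- NULL
  if (config$n_subclasses > 0) {
    subclass <- sample(rep_len(sprintf("C%d", seq_len(config$n_subclasses)),
                               n))
    names(subclass) <- samples
    marker_sets <- lapply(seq_len(config$n_subclasses), function(k) {
      st <- config$n_prognostic + (k - 1) * config$markers_per_subclass
      genes[st + seq_len(config$markers_per_subclass)]
    })
    names(marker_sets) <- sprintf("C%d", seq_len(config$n_subclasses))
    for (k in seq_len(config$n_subclasses)) {
      idx <- match(marker_sets[[k]], genes)
      on <- subclass == names(marker_sets)[k]
      X[idx, on] <- X[idx, on] + config$subclass_effect
    }
  }

  gamma <- matrix(rnorm(G * B, 0, config$gamma_sd), G, B,
                  dimnames = list(genes, unique(batch)))
  delta <- matrix(exp(rnorm(G * B, 0, config$delta_shape)), G, B,
                  dimnames = list(genes, unique(batch)))
  if (config$gamma_sd == 0) gamma[] <- 0
  if (config$delta_shape == 0) delta[] <- 1

  noise <- matrix(rnorm(G * n), G, n) * sigma
  for (b in seq_len(B)) {
    j <- which(batch == unique(batch)[b])
    X[, j] <- X[, j] + gamma[, b] + noise[, j] * delta[, b]
  }
  dimnames(X) <- list(genes, samples)

  lambda <- config$baseline_hazard * exp(config$beta * as.numeric(scale(z)))
  T_event <- rexp(n, lambda)
  C_horizon <- censor_horizon(lambda, config$censor_rate)
  U <- if (is.finite(C_horizon)) runif(n, 0, C_horizon) else rep(Inf, n)
  os <- pmin(T_event, U)
  event <- as.numeric(T_event <= U)

  clinical <- clinical_table(data.frame(
    sample_id = samples, os_months = os, event = event,
    age_years = round(rnorm(n, 62, 10), 1),
    stage = sample(c(3, 4), n, replace = TRUE, prob = c(0.7, 0.3)),
    grade = sample(1:3, n, replace = TRUE, prob = c(0.1, 0.3, 0.6)),
    debulking = sample(c("optimal", "suboptimal"), n, replace = TRUE),
    histology = "serous",
    subtype = if (is.null(subclass)) NA_character_ else unname(subclass),
    stringsAsFactors = FALSE))

  truth <- list(prognostic_gene_ids = prog,
                latent_score = setNames(as.numeric(scale(z)), samples),
                gamma = gamma, delta = delta,
                subclass = subclass, marker_sets = marker_sets,
                censor_horizon = C_horizon)
  list(expression = expression_matrix(X, batch), clinical = clinical,
       truth = truth)
}

#' Simulate two cohorts sharing subclass signatures
#'
#' Both cohorts plant the same subclass marker programs (identity pairing
#' is the ground truth) on independent noise backgrounds; used to exercise
#' subclass mapping.
#'
#' @param config A [sim_config()]; `n_subclasses` must be at least 2 and
#'   every subclass occupies at least 10 percent of each cohort.
#' @return List with `A`, `B` (each `list(expression, labels)`) and
#'   `truth` (shared marker programs).
#' @export
simulate_subclass_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subclasses < 2) stop("need at least 2 subclasses")
  n <- config$samples_per_batch
  if (floor(n / config$n_subclasses) < ceiling(0.1 * n))
    stop("a subclass would fall below 10% cohort occupancy")
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  marker_sets <- lapply(seq_len(config$n_subclasses), function(k) {
    st <- (k - 1) * config$markers_per_subclass
    genes[st + seq_len(config$markers_per_subclass)]
  })
  names(marker_sets) <- sprintf("C%d", seq_len(config$n_subclasses))
  mu <- rnorm(G, 7, 1)
  sigma <- runif(G, config$noise_sd[1], config$noise_sd[2])
  gen_cohort <- function(tag) {
    labs <- sample(rep_len(names(marker_sets), n))
    X <- matrix(mu, G, n) + matrix(rnorm(G * n), G, n) * sigma
    for (k in names(marker_sets)) {
      idx <- match(marker_sets[[k]], genes)
      X[idx, labs == k] <- X[idx, labs == k] + config$subclass_effect
    }
    samples <- sprintf("%s%03d", tag, seq_len(n))
    dimnames(X) <- list(genes, samples)
    names(labs) <- samples
    list(expression = expression_matrix(X), labels = labs)
  }
  A <- gen_cohort("A")
  B <- gen_cohort("B")
  list(A = A, B = B, truth = list(marker_sets = marker_sets))
}

#' Simulate on/off pathway-activation training arrays
#'
#' Emulates experimentally controlled pathway activation: signature genes
#' are shifted by `separation` noise SDs in the "on" arrays.
#'
#' @param n_on,n_off Arrays per class (each at least 5).
#' @param n_sig_genes Number of planted signature genes.
#' @param separation Shift of signature genes in noise-SD units.
#' @param seed Integer seed.
#' @param n_genes Total genes on the array.
#' @return List with `expression` (an [expression_matrix()]), `labels`
#'   (`"on"`/`"off"` per array) and `signature_genes`.
#' @export
simulate_pathway_training <- function(n_on, n_off, n_sig_genes, separation,
                                      seed = 1L, n_genes = 1000) {
  if (n_on < 5 || n_off < 5) stop("need at least 5 arrays per class")
  if (n_sig_genes > n_genes) stop("n_sig_genes exceeds n_genes")
  set.seed(as.integer(seed))
  n <- n_on + n_off
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("P%03d", seq_len(n))
  labels <- setNames(rep(c("on", "off"), c(n_on, n_off)), samples)
  sigma <- runif(n_genes, 0.5, 1)
  X <- matrix(rnorm(n_genes * n, 7, 1), n_genes, n) +
    matrix(rnorm(n_genes * n), n_genes, n) * sigma
  sig <- genes[seq_len(n_sig_genes)]
  X[seq_len(n_sig_genes), labels == "on"] <-
    X[seq_len(n_sig_genes), labels == "on"] +
    separation * sigma[seq_len(n_sig_genes)]
  dimnames(X) <- list(genes, samples)
  list(expression = expression_matrix(X), labels = labels,
       signature_genes = sig)
}
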