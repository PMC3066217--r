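# shared fixture builders and small independent oracles

# tiny named expression matrix
toy_matrix <- function(n_genes = 3, n_samples = 2, seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(n_genes * n_samples, 7, 1), 4), n_genes, n_samples,
         dimnames = list(sprintf("G%d", seq_len(n_genes)),
                         sprintf("S%d", seq_len(n_samples))))
}

toy_clinical <- function(n = 4, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%d", seq_len(n)),
             os_months = round(rexp(n, 0.02), 2),
             event = rbinom(n, 1, 0.7),
             age_years = round(rnorm(n, 60, 8), 1),
             grade = sample(1:3, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# nearest-centroid batch classifier accuracy with a train/test split;
# the oracle for "how predictable is batch from expression"
centroid_batch_accuracy <- function(m, batch, seed = 99) {
  set.seed(seed)
  n <- ncol(m)
  train <- sort(sample.int(n, floor(n / 2)))
  test <- setdiff(seq_len(n), train)
  cents <- sapply(unique(batch), function(b)
    rowMeans(m[, intersect(train, which(batch == b)), drop = FALSE]))
  pred <- unique(batch)[apply(m[, test, drop = FALSE], 2, function(v)
    which.min(colSums((cents - v)^2)))]
  mean(pred == batch[test])
}

# mean silhouette width of a labeling in a coordinate space
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# adjusted Rand index between two labelings (from the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# naive step-by-step running-sum enrichment score (independent of the
# package implementation)
naive_es <- function(markers, ranking) {
  m <- sum(ranking %in% markers)
  N <- length(ranking)
  run <- 0
  best <- 0
  for (g in ranking) {
    run <- run + if (g %in% markers) 1 / m else -1 / (N - m)
    if (run > best) best <- run
  }
  best
}
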