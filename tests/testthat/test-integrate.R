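test_that("quantile normalization equalizes column distributions", {
  m <- toy_matrix(5, 3)
  same <- matrix(m[, 1], 5, 3, dimnames = dimnames(m))
  expect_equal(quantile_normalize(same)$values, same)
  m2 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  qn <- quantile_normalize(m2)$values
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  set.seed(1)
  m3 <- matrix(rnorm(200), 20, 10,
               dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  qn3 <- quantile_normalize(m3)$values
  sorted <- apply(qn3, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # rank order within each sample preserved
  for (j in 1:10) expect_identical(order(qn3[, j]), order(m3[, j]))
  expect_warning(quantile_normalize(m3[, 1, drop = FALSE]), "single-sample")
})

test_that("RLE flags globally shifted arrays and spares clean ones", {
  set.seed(2)
  m <- matrix(rnorm(2000 * 20, 7, 0.3), 2000, 20,
              dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:20)))
  same <- matrix(m[, 1], 2000, 5,
                 dimnames = list(rownames(m), sprintf("x%d", 1:5)))
  expect_false(any(rle_outlier_flags(same)$outlier))
  m[, 7] <- m[, 7] + 3
  qc <- rle_outlier_flags(m)
  expect_true(qc$outlier[7])
  expect_lt(abs(qc$rle_median[7] - 3), 0.2)
  expect_false(any(qc$outlier[-7]))
  # clean simulated arrays: flag rate at most 5%
  sim <- simulate_integration_study(
    sim_config(n_batches = 1, samples_per_batch = 100, n_genes = 1000,
               gamma_sd = 0, delta_shape = 0, seed = 51))
  expect_lte(mean(rle_outlier_flags(sim$expression)$outlier), 0.05)
})

test_that("map_and_merge joins cohorts on mapped gene intersections", {
  a <- matrix(1:6, 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("a1", "a2")))
  b <- matrix(7:12, 3, 2,
              dimnames = list(c("p1", "p2", "p4"), c("b1", "b2")))
  idmap <- c(p1 = "g1", p2 = "g2", p4 = "g4")
  merged <- map_and_merge(list(A = a, B = b), idmap)
  expect_setequal(rownames(merged), c("g1", "g2"))
  expect_identical(unname(merged$batch), c("A", "A", "B", "B"))
  # identical gene namespaces: intersection is everything
  a2 <- a
  colnames(a2) <- c("a3", "a4")
  m2 <- map_and_merge(list(A = a, B = a2))
  expect_identical(rownames(m2), rownames(a))
  expect_equal(ncol(m2), 4)
  # two probes collapsing to one gene by mean
  c_ <- matrix(c(1, 3, 2, 4), 2, 2,
               dimnames = list(c("q1", "q2"), c("c1", "c2")))
  mc <- map_and_merge(list(C = c_), c(q1 = "g1", q2 = "g1"))
  expect_equal(unname(mc$values["g1", ]), c(2, 3))
  # max_var keeps the most variable probe
  mv <- map_and_merge(list(C = c_), c(q1 = "g1", q2 = "g1"),
                      collapse = "max_var")
  expect_equal(unname(mv$values["g1", ]), c(1, 2))
  expect_error(map_and_merge(list(A = a, B = b)), "intersection")
})

test_that("RV coefficient behaves like a matrix correlation", {
  set.seed(3)
  x <- matrix(rnorm(40 * 15), 40, 15,
              dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:15)))
  expect_equal(rv_coefficient(x, x), 1)
  # orthonormal rotation of gene space leaves sample cross-products alone
  q <- qr.Q(qr(matrix(rnorm(1600), 40, 40)))
  y <- q %*% x
  dimnames(y) <- dimnames(x)
  expect_lt(abs(rv_coefficient(x, y) - 1), 1e-10)
  # symmetry
  z <- matrix(rnorm(40 * 15), 40, 15, dimnames = dimnames(x))
  expect_lt(abs(rv_coefficient(x, z) - rv_coefficient(z, x)), 1e-12)
  expect_error(rv_coefficient(x, matrix(5, 40, 15,
                                        dimnames = dimnames(x))),
               "zero-variance")
})

test_that("independent matrices have a small adjusted RV coefficient", {
  # classical RV is diagonal-dominated when genes >> samples, so the
  # independence check uses the diagonal-removed variant
  set.seed(4)
  rv <- vapply(1:100, function(i) {
    x <- matrix(rnorm(200 * 50), 200, 50)
    y <- matrix(rnorm(200 * 50), 200, 50)
    colnames(x) <- colnames(y) <- sprintf("s%d", 1:50)
    rownames(x) <- rownames(y) <- sprintf("g%d", 1:200)
    rv_coefficient(x, y, adjusted = TRUE)
  }, 0)
  expect_lt(quantile(rv, 0.99), 0.2)
  set.seed(5)
  x <- matrix(rnorm(200 * 50), 200, 50,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:50)))
  expect_equal(rv_coefficient(x, x, adjusted = TRUE), 1)
})

test_that("classical MDS embeds planar configurations exactly", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), 2, 4)  # rectangle corners
  feat <- rbind(pts, matrix(0, 3, 4))             # embed in 5-D
  dimnames(feat) <- list(sprintf("g%d", 1:5), sprintf("s%d", 1:4))
  xy <- classical_mds(feat, "euclidean")
  expect_lt(max(abs(dist(xy) - dist(t(pts)))), 1e-8)
  # duplicated sample lands on identical coordinates
  feat2 <- cbind(feat, s5 = feat[, 1])
  xy2 <- classical_mds(expression_matrix(feat2), "euclidean")
  expect_lt(max(abs(xy2["s5", ] - xy2["s1", ])), 1e-10)
})

test_that("two-cluster QC recovers separated blobs and a null split", {
  set.seed(6)
  n <- 40
  m <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:n)))
  blob <- rep(c(0, 1), each = n / 2)
  m[1:80, blob == 1] <- m[1:80, blob == 1] + 3
  m[81:160, blob == 0] <- m[81:160, blob == 0] + 3  # both blobs coherent
  cl <- toy_clinical(n, seed = 7)
  cl$sample_id <- colnames(m)
  qc <- two_cluster_survival_qc(m, cl)
  expect_equal(adjusted_rand(qc$clusters, blob), 1)
  # identical survival records in the two clusters: statistic 0
  cl2 <- cl
  cl2$os_months <- rep(c(5, 10, 15, 20), 10)
  cl2$event <- rep(1, n)
  qc2 <- two_cluster_survival_qc(m, cl2)
  expect_equal(qc2$logrank$statistic, 0)
})

test_that("cluster-survival QC p-values are calibrated under the null", {
  set.seed(8)
  ps <- vapply(1:100, function(i) {
    n <- 30
    m <- matrix(rnorm(100 * n), 100, n,
                dimnames = list(sprintf("g%d", 1:100),
                                sprintf("s%d", 1:n)))
    m[1:30, 1:15] <- m[1:30, 1:15] + 2   # structure unrelated to survival
    cl <- data.frame(sample_id = colnames(m),
                     os_months = rexp(n, 0.05),
                     event = rbinom(n, 1, 0.8))
    suppressWarnings(two_cluster_survival_qc(m, cl)$logrank$p)
  }, 0)
  expect_lte(mean(ps < 0.05, na.rm = TRUE), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
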