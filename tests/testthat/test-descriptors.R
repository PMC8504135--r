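test_that("kpca_compress matches a brute-force eigendecomposition of the centered rbf kernel", {
  set.seed(42)
  m <- matrix(rnorm(4 * 5), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  gamma <- 1 / 4
  ce <- kpca_compress(m, gamma = gamma)
  expect_identical(colnames(ce$scores), c("fe1", "fe2"))

  # oracle: explicit double-loop kernel, explicit centering matrix, eigen
  x <- t(m); n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- exp(-gamma * sum((x[i, ] - x[j, ])^2))
  }
  J <- diag(n) - matrix(1 / n, n, n)
  Kc <- J %*% K %*% J
  e <- eigen(Kc, symmetric = TRUE)
  ref <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  for (k in 1:2) {
    pivot <- which.max(abs(ref[, k]))
    if (ref[pivot, k] < 0) ref[, k] <- -ref[, k]
  }
  expect_equal(unname(ce$scores), ref, tolerance = 1e-8)
})

test_that("kpca respects its contract: 2 components, duplicate samples coincide, small-n errors", {
  set.seed(7)
  m <- matrix(rnorm(6 * 8), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  m[, 2] <- m[, 1]  # duplicate sample
  ce <- kpca_compress(m)
  expect_equal(ncol(ce$scores), 2L)
  expect_equal(ce$scores[1, ], ce$scores[2, ], tolerance = 1e-10)
  expect_error(kpca_compress(m[, 1:2]), "samples")
  m[1, 1] <- NA
  expect_error(kpca_compress(m), "imputed")
})

test_that("kpca with a linear kernel reproduces PCA scores up to sign", {
  set.seed(9)
  m <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  ce <- kpca_compress(m, kernel = "linear")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)$x[, 1:2]
  for (k in 1:2) {
    expect_equal(abs(stats::cor(ce$scores[, k], pc[, k])), 1,
                 tolerance = 1e-8)
    expect_equal(sd(ce$scores[, k]), sd(pc[, k]), tolerance = 1e-8)
  }
})

test_that("phenotype features match hand computations on uncensored toys", {
  ph <- phenotype_features(make_surv(c(1, 2, 3, 4), rep(1L, 4)))
  expect_equal(ph[["T4"]], 4)
  expect_equal(ph[["SAVE"]], 2.5)
  expect_equal(unname(ph[c("S1", "S2", "S3", "S4")]), rep(0.25, 4))
  expect_equal(ph[["T2"]], 2.5)  # type-7 median
  # KM with no censoring reduces to the empirical survivor function
  ph2 <- phenotype_features(make_surv(c(1, 2, 4, 5), rep(1L, 4)))
  expect_equal(ph2[["Y3"]], 0.5)
  # degenerate: all times equal
  ph3 <- phenotype_features(make_surv(rep(7, 5), rep(1L, 5)))
  expect_equal(ph3[["STD"]], 0)
  expect_equal(unname(ph3[c("T1", "T2", "T3", "T4")]), rep(7, 4))
  expect_equal(ph3[["S4"]], 1)
  expect_error(phenotype_features(make_surv(c(1, 2, 3), c(1L, 1L, 1L))),
               "at least 4")
})

test_that("phenotype features respect censoring, horizons and invariants", {
  # KM at 3y: events at 1 (4 at risk) and 4; censored at 2 -> S(3) = 3/4
  s <- make_surv(c(1, 2, 4, 6), c(1L, 0L, 1L, 1L))
  ph <- phenotype_features(s)
  expect_equal(ph[["Y3"]], 0.75)
  expect_lte(ph[["Y5"]], ph[["Y3"]])
  # naive estimator ignores censoring
  expect_equal(phenotype_features(s, estimator = "naive")[["Y3"]], 0.5)
  # unit_scale: same data in days
  sd_ <- make_surv(c(1, 2, 4, 6) * 365.25, c(1L, 0L, 1L, 1L))
  expect_equal(phenotype_features(sd_, unit_scale = 365.25)[["Y3"]], 0.75)
  expect_warning(phenotype_features(make_surv(1:4, rep(0L, 4))),
                 "censored")
  # properties over random instances: S sums to 1, Y3 >= Y5, order invariance
  set.seed(31)
  for (rep in 1:10) {
    inst <- random_instance(25)
    s1 <- make_surv(inst$time, inst$event)
    p1 <- phenotype_features(s1)
    expect_equal(sum(p1[c("S1", "S2", "S3", "S4")]), 1)
    expect_gte(p1[["Y3"]], p1[["Y5"]])
    perm <- sample(25)
    p2 <- phenotype_features(make_surv(inst$time[perm], inst$event[perm]))
    expect_equal(p1, p2)
  }
})

test_that("genotype features are the moment statistics of the two components", {
  mk_ce <- function(f1, f2) {
    structure(list(sample_ids = paste0("s", seq_along(f1)),
                   scores = cbind(fe1 = f1, fe2 = f2)),
              class = "compressed_expression")
  }
  # symmetric values -> zero skew
  g <- genotype_features(mk_ce(c(-2, -1, 1, 2), c(1, 2, 3, 4)))
  expect_equal(g[["SKEW1"]], 0)
  # oracle: direct sum formulas on an asymmetric vector
  v <- c(1, 2, 3, 4, 10)
  g2 <- genotype_features(mk_ce(v, v))
  mu <- mean(v); m2 <- mean((v - mu)^2)
  expect_equal(g2[["AVE1"]], mu)
  expect_equal(g2[["MID1"]], 3)
  expect_equal(g2[["STD1"]], sqrt(sum((v - mu)^2) / 4))
  expect_equal(g2[["SKEW1"]], mean((v - mu)^3) / m2^1.5)
  expect_equal(g2[["KURT1"]], mean((v - mu)^4) / m2^2 - 3)
  expect_equal(unname(g2[6:10]), unname(g2[1:5]))
  # constant component fallback
  expect_warning(g3 <- genotype_features(mk_ce(rep(2, 5), c(1, 2, 3, 4, 5))),
                 "constant")
  expect_equal(unname(g3[c("STD1", "KURT1", "SKEW1")]), c(0, 0, 0))
  expect_error(genotype_features(mk_ce(1:3, 1:3)), "at least 4")
})

test_that("descriptor matrix stacks 22 features and z-scores columns", {
  st <- simulate_study(simulation_config(n_cohorts = 4, n_samples = 40,
                                         n_genes = 12, censor_rate = 0.3,
                                         seed = 5))
  vecs <- lapply(st, cohort_descriptor)
  d <- build_descriptor_matrix(vecs)
  expect_identical(colnames(d$raw), descriptor_feature_names())
  expect_equal(ncol(d$raw), 22L)
  # normalized columns: mean 0, unit variance (or all-zero when constant)
  for (j in seq_len(22)) {
    col <- d$normalized[, j]
    expect_equal(mean(col), 0, tolerance = 1e-12)
    expect_true(abs(sd(col) - 1) < 1e-12 || all(col == 0))
  }
  # two cohorts: each column is {-x, +x}
  d2 <- build_descriptor_matrix(vecs[1:2])
  expect_equal(d2$normalized[1, ], -d2$normalized[2, ], tolerance = 1e-12)
  # constant feature -> zero column
  vc <- lapply(vecs, function(v) { v$features[["S1"]] <- 0.3; v })
  expect_true(all(build_descriptor_matrix(vc)$normalized[, "S1"] == 0))
  # non-finite entries are named
  vb <- vecs
  vb[[2]]$features[["STD2"]] <- NaN
  expect_error(build_descriptor_matrix(vb), "STD2")
  expect_error(build_descriptor_matrix(vecs[1]), "length")
})

test_that("descriptor matrix TSV round-trips", {
  st <- simulate_study(simulation_config(n_cohorts = 3, n_samples = 30,
                                         n_genes = 10, censor_rate = 0.2,
                                         seed = 6))
  d <- build_descriptor_matrix(lapply(st, cohort_descriptor))
  p <- tempfile(fileext = ".tsv")
  write_descriptor_matrix(d, p)
  back <- utils::read.delim(p, check.names = FALSE)
  expect_identical(back$cohort, d$cohort_names)
  expect_equal(as.matrix(back[, -1]), d$normalized, tolerance = 1e-6,
               ignore_attr = TRUE)
})
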