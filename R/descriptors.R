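#' Feature names of the cohort descriptor
#'
#' Twelve phenotype features summarize the survival distribution (3- and
#' 5-year survival rates, mean/sd/quartiles/max of observed times, and the
#' fraction of patients in each quarter of `[0, T4]`); ten genotype features
#' are moment statistics (mean, median, sd, excess kurtosis, skewness) of the
#' two kernel-PCA components of the expression matrix.
#'
#' @return Character vector of the 22 feature names, in canonical order.
#' @export
descriptor_feature_names <- function() {
  c("Y3", "Y5", "SAVE", "STD", "T1", "T2", "T3", "T4",
    "S1", "S2", "S3", "S4",
    "AVE1", "MID1", "STD1", "KURT1", "SKEW1",
    "AVE2", "MID2", "STD2", "KURT2", "SKEW2")
}

#' Kernel PCA compression of an expression matrix
#'
#' Projects samples onto the top `n_components` kernel principal components of
#' the double-centered kernel matrix over samples. The default kernel is the
#' radial basis function with `gamma = 1/n_genes`; a linear kernel is provided
#' for cross-checking against ordinary PCA.
#'
#' Component signs are fixed deterministically: the entry of largest absolute
#' value in each score vector is made positive, so repeated runs give
#' identical coordinates.
#'
#' @param m Fully imputed numeric genes x samples matrix.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param n_components Number of components, default 2.
#' @param gamma RBF bandwidth; default `1/nrow(m)`.
#' @return A `compressed_expression` list: `sample_ids` and `scores`, an
#'   n_samples x n_components matrix with columns `fe1`, `fe2`, ...
#' @export
kpca_compress <- function(m, kernel = c("rbf", "linear"), n_components = 2L,
                          gamma = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("expression matrix must be fully imputed before KPCA")
  n <- ncol(m)
  if (n < n_components + 1L) {
    stop("need at least n_components + 1 = ", n_components + 1L,
         " samples, got ", n)
  }
  x <- t(m)  # samples x genes
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- 1 / nrow(m)
    sq <- rowSums(x^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    d2[d2 < 0] <- 0
    K <- exp(-gamma * d2)
  } else {
    K <- tcrossprod(x)
  }
  # double centering: Kc = (I - 1/n) K (I - 1/n)
  rm_ <- rowMeans(K)
  Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(K)
  e <- eigen(Kc, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(n_components)], 0)
  scores <- e$vectors[, seq_len(n_components), drop = FALSE] *
    rep(sqrt(lam), each = n)
  for (j in seq_len(n_components)) {
    pivot <- which.max(abs(scores[, j]))
    if (scores[pivot, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("fe", seq_len(n_components))
  rownames(scores) <- colnames(m)
  structure(list(sample_ids = colnames(m), scores = scores),
            class = "compressed_expression")
}

#' Phenotype features of a survival table
#'
#' Computes the 12 survival-distribution summaries: `Y3`/`Y5` are Kaplan-Meier
#' survival probabilities at 3 and 5 years (clamped to the last observed time
#' when follow-up is shorter); `SAVE`/`STD` the mean and standard deviation of
#' observed times; `T1`-`T3` the quartiles and `T4` the maximum of observed
#' times; `S1`-`S4` the fractions of patients whose observed time falls in the
#' four equal subdivisions of `[0, T4]` (intervals right-closed `(lo, hi]`,
#' the first including 0), so every patient lies in exactly one interval and
#' a time equal to a quarter boundary counts toward the lower quarter.
#'
#' @param s A `survival_table`.
#' @param unit_scale Stored time units per year (e.g. 365.25 for days);
#'   default 1 (times already in years).
#' @param estimator `"km"` (Kaplan-Meier, default) or `"naive"` (fraction of
#'   patients with observed time beyond the horizon, ignoring censoring).
#' @param uncensored_only If `TRUE`, `SAVE`/`STD`/quartiles/`S1`-`S4` use only
#'   uncensored patients. Default `FALSE` (all patients).
#' @return Named numeric vector of length 12.
#' @export
phenotype_features <- function(s, unit_scale = 1,
                               estimator = c("km", "naive"),
                               uncensored_only = FALSE) {
  estimator <- match.arg(estimator)
  if (nrow(s) < 4L) stop("phenotype features need at least 4 patients")
  if (sum(s$event) == 0L) {
    warning("all patients censored: survival rates estimated without any event")
  }
  horizon <- function(years) min(years * unit_scale, max(s$time))
  if (estimator == "km") {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = s)
    surv_at <- function(t) summary(fit, times = t, extend = TRUE)$surv
  } else {
    surv_at <- function(t) mean(s$time > t)
  }
  y3 <- surv_at(horizon(3))
  y5 <- surv_at(horizon(5))
  tt <- if (uncensored_only) s$time[s$event == 1L] else s$time
  if (length(tt) < 1L) stop("no observed times available for phenotype features")
  t4 <- max(tt)
  q <- stats::quantile(tt, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  cuts <- c(0.25, 0.5, 0.75) * t4
  # right-closed quarters (lo, hi]: boundary times count toward the lower one
  bin <- findInterval(tt, cuts, left.open = TRUE) + 1L
  sfrac <- tabulate(bin, nbins = 4L) / length(tt)
  c(Y3 = y3, Y5 = y5, SAVE = mean(tt), STD = stats::sd(tt),
    T1 = q[1L], T2 = q[2L], T3 = q[3L], T4 = t4,
    S1 = sfrac[1L], S2 = sfrac[2L], S3 = sfrac[3L], S4 = sfrac[4L])
}

# moment estimators used for the genotype block
.moments <- function(x, prefix) {
  n <- length(x)
  mu <- mean(x)
  ctr <- x - mu
  m2 <- mean(ctr^2)
  s <- stats::sd(x)
  if (m2 < .Machine$double.eps * max(1, mu^2)) {
    warning("constant KPCA component: kurtosis and skewness reported as 0")
    kurt <- 0
    skew <- 0
    s <- 0
  } else {
    skew <- mean(ctr^3) / m2^1.5
    kurt <- mean(ctr^4) / m2^2 - 3  # excess kurtosis: normal -> 0
  }
  out <- c(mu, stats::median(x), s, kurt, skew)
  names(out) <- paste0(c("AVE", "MID", "STD", "KURT", "SKEW"), prefix)
  out
}

#' Genotype features of a compressed expression
#'
#' Mean, median, standard deviation (n-1 denominator), excess kurtosis and
#' skewness (moment estimators) of each of the two KPCA components. A constant
#' component yields `STD = KURT = SKEW = 0` with a warning.
#'
#' @param ce A `compressed_expression` from [kpca_compress()] with 2
#'   components and at least 4 samples.
#' @return Named numeric vector of length 10
#'   (`AVE1`, `MID1`, ..., `SKEW2`).
#' @export
genotype_features <- function(ce) {
  stopifnot(inherits(ce, "compressed_expression"))
  sc <- ce$scores
  if (ncol(sc) != 2L) stop("genotype features expect exactly 2 components")
  if (nrow(sc) < 4L) stop("genotype features need at least 4 samples")
  c(.moments(sc[, 1L], "1"), .moments(sc[, 2L], "2"))
}

#' Full 22-feature descriptor of one cohort
#'
#' Convenience wrapper running [kpca_compress()] on the cohort's expression and
#' combining [phenotype_features()] with [genotype_features()].
#'
#' @param c A `cohort`.
#' @param unit_scale,estimator Passed to [phenotype_features()].
#' @param gamma Passed to [kpca_compress()].
#' @return A `descriptor_vector`: list with `cohort_name` and the named
#'   22-vector `features`.
#' @export
cohort_descriptor <- function(c, unit_scale = 1, estimator = "km",
                              gamma = NULL) {
  ph <- phenotype_features(c$survival, unit_scale = unit_scale,
                           estimator = estimator)
  ge <- genotype_features(kpca_compress(c$expression, gamma = gamma))
  structure(list(cohort_name = c$name, features = c(ph, ge)),
            class = "descriptor_vector")
}

#' Assemble and normalize the cross-cohort descriptor matrix
#'
#' Stacks descriptor vectors into a cohorts x 22 matrix and z-scores each
#' feature column (mean 0, unit variance). Columns constant across cohorts are
#' mapped to all zeros so they carry no clustering weight.
#'
#' @param vectors List of `descriptor_vector` objects (>= 2 cohorts).
#' @return A `descriptor_matrix`: list with `cohort_names`, `raw`,
#'   `normalized` and `normalization_params` (`center`, `scale` per feature).
#' @export
build_descriptor_matrix <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 2L)
  feats <- descriptor_feature_names()
  raw <- t(vapply(vectors, function(v) {
    stopifnot(inherits(v, "descriptor_vector"))
    v$features[feats]
  }, numeric(length(feats))))
  rownames(raw) <- unname(vapply(vectors, function(v) v$cohort_name,
                                 character(1L)))
  colnames(raw) <- feats
  if (!all(is.finite(raw))) {
    bad <- which(!is.finite(raw), arr.ind = TRUE)[1L, ]
    stop("non-finite descriptor entry: cohort '", rownames(raw)[bad[1L]],
         "', feature '", colnames(raw)[bad[2L]], "'")
  }
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, stats::sd)
  normalized <- sweep(raw, 2L, ctr, "-")
  pos <- scl > 0
  normalized[, pos] <- sweep(normalized[, pos, drop = FALSE], 2L,
                             scl[pos], "/")
  normalized[, !pos] <- 0
  structure(list(cohort_names = rownames(raw), raw = raw,
                 normalized = normalized,
                 normalization_params = list(center = ctr, scale = scl)),
            class = "descriptor_matrix")
}

#' Write a descriptor matrix as TSV
#'
#' @param d A `descriptor_matrix`.
#' @param path Output file.
#' @param which `"raw"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(d, path, which = c("normalized", "raw")) {
  which <- match.arg(which)
  df <- data.frame(cohort = d$cohort_names, d[[which]], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
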