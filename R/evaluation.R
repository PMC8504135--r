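#' Harrell's concordance index
#'
#' Fraction of permissible patient pairs whose predicted risks order their
#' survival correctly. A pair (i, j) is permissible when `T_i < T_j` and
#' patient i had the event, or when `T_i == T_j` with i an event and j
#' censored (the event precedes censoring at a shared time). The pair is
#' concordant when the shorter-lived patient has the higher risk score; tied
#' scores count 0.5. A value of 0.5 corresponds to random prediction, 1 to a
#' perfect ordering.
#'
#' @param scores Numeric risk scores (higher = higher predicted hazard).
#' @param s Aligned `survival_table` (or list with `time` and `event`).
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(scores, s) {
  time <- s$time; event <- s$event
  n <- length(time)
  if (length(scores) != n) stop("scores and survival data have different lengths")
  # permissible[i, j]: i fails first and is comparable with j
  ev_i <- matrix(event == 1L, n, n)
  t_i <- matrix(time, n, n)
  t_j <- t(t_i)
  cens_j <- t(matrix(event == 0L, n, n))
  perm <- ev_i & (t_i < t_j | (t_i == t_j & cens_j))
  diag(perm) <- FALSE
  npairs <- sum(perm)
  if (npairs == 0L) stop("no permissible pairs: concordance undefined")
  s_i <- matrix(scores, n, n)
  s_j <- t(s_i)
  conc <- sum(perm & s_i > s_j) + 0.5 * sum(perm & s_i == s_j)
  conc / npairs
}

#' Split patients at the median predicted risk
#'
#' Patients with risk strictly above the median form the high-risk group;
#' those at or below the median (including the median patient for odd n) form
#' the low-risk group, guaranteeing a nonempty high group when scores are not
#' all identical.
#'
#' @param scores Named (or plain) numeric risk scores, n >= 2.
#' @return A `risk_groups` list: `sample_ids`, `group` (factor with levels
#'   `low`, `high`) and `threshold` (the median).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("median split needs at least 2 patients")
  med <- stats::median(scores)
  if (all(scores == scores[1L])) {
    stop("all risk scores identical: no median split possible")
  }
  grp <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  structure(list(sample_ids = ids, group = grp, threshold = med),
            class = "risk_groups")
}

#' Two-group log-rank test
#'
#' Tests whether the survival curves of the high- and low-risk groups differ,
#' via the chi-square statistic (1 degree of freedom) comparing observed and
#' expected event counts across the pooled event times.
#'
#' @param groups A `risk_groups` object (or a 2-level factor).
#' @param s Aligned `survival_table`.
#' @return List with `statistic`, `p_value` and `df = 1`.
#' @export
logrank_test <- function(groups, s) {
  grp <- if (inherits(groups, "risk_groups")) groups$group else as.factor(groups)
  if (length(grp) != nrow(s)) stop("groups and survival table have different lengths")
  if (nlevels(droplevels(grp)) < 2L) stop("both risk groups must be nonempty")
  if (sum(s$event) == 0L) stop("log-rank test needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(s$time, s$event) ~ grp)
  stat <- sd_$chisq
  list(statistic = as.numeric(stat),
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Chi-square association between risk groups and a clinical covariate
#'
#' Pearson chi-square (no continuity correction) on the 2 x L contingency
#' table of risk group against covariate level. Continuous covariates are
#' binned first, by default into quartile intervals; categories with zero
#' margin are dropped with a warning.
#'
#' @param groups A `risk_groups` object (or factor).
#' @param covariate Vector aligned with the samples: factor/character, or
#'   numeric (binned before testing).
#' @param binning For numeric covariates: `"quartile"` (default) or a numeric
#'   vector of cut points.
#' @return List with `statistic`, `p_value`, `df` and the contingency
#'   `table`.
#' @export
chisq_association <- function(groups, covariate, binning = "quartile") {
  grp <- if (inherits(groups, "risk_groups")) groups$group else as.factor(groups)
  if (length(covariate) != length(grp)) {
    stop("covariate and groups have different lengths")
  }
  if (is.numeric(covariate)) {
    breaks <- if (identical(binning, "quartile")) {
      unique(stats::quantile(covariate, probs = c(0, 0.25, 0.5, 0.75, 1),
                             na.rm = TRUE))
    } else {
      unique(c(-Inf, binning, Inf))
    }
    covariate <- cut(covariate, breaks = breaks, include.lowest = TRUE)
  }
  if (!is.factor(covariate)) covariate <- factor(covariate)
  keep <- !is.na(covariate)
  tab <- table(group = grp[keep], level = covariate[keep])
  empty <- colSums(tab) == 0L
  if (any(empty)) {
    warning("dropping empty covariate level(s): ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("fewer than 2 nonempty covariate categories")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = as.numeric(ct$statistic), p_value = ct$p.value,
       df = as.numeric(ct$parameter), table = tab)
}

#' Evaluate risk scores on a cohort
#'
#' Bundles the concordance index, the median risk stratification, the
#' log-rank separation test and chi-square association tests with any
#' clinical covariates into one report.
#'
#' @param scores Risk scores aligned with the cohort's samples.
#' @param s A `survival_table`.
#' @param covariates Character vector of covariate columns of `s` to test;
#'   default all of them.
#' @param per_fold_c Optional numeric vector of cross-validation fold
#'   C-indices to carry in the report.
#' @return An `evaluation_report` list: `c_index`, `logrank_p`,
#'   `logrank_statistic`, `risk_groups`, `per_fold_c`, `covariate_tests`
#'   (data frame of covariate, statistic, df, p_value).
#' @export
evaluate_model <- function(scores, s, covariates = covariate_names(s),
                           per_fold_c = NULL) {
  ci <- concordance_index(scores, s)
  rg <- median_split(scores)
  lr <- logrank_test(rg, s)
  cov_tests <- NULL
  if (length(covariates) > 0L) {
    rows <- lapply(covariates, function(v) {
      res <- tryCatch(chisq_association(rg, s[[v]]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(covariate = v, statistic = res$statistic, df = res$df,
                 p_value = res$p_value)
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows) > 0L) cov_tests <- do.call(rbind, rows)
  }
  structure(list(c_index = ci,
                 logrank_statistic = lr$statistic,
                 logrank_p = lr$p_value,
                 risk_groups = rg,
                 per_fold_c = per_fold_c,
                 covariate_tests = cov_tests),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("C-index: %.3f", x$c_index))
  if (!is.null(x$per_fold_c)) {
    cat(sprintf("  [CV mean %.3f (+/- %.3f) over %d folds]",
                mean(x$per_fold_c), stats::sd(x$per_fold_c),
                length(x$per_fold_c)))
  }
  cat(sprintf("\nlog-rank: chisq = %.3f (df 1), p = %.3g\n",
              x$logrank_statistic, x$logrank_p))
  cat(sprintf("risk groups: %d high / %d low (median threshold %.4f)\n",
              sum(x$risk_groups$group == "high"),
              sum(x$risk_groups$group == "low"),
              x$risk_groups$threshold))
  if (!is.null(x$covariate_tests)) {
    cat("covariate associations:\n")
    print(x$covariate_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Kaplan-Meier curves of the two risk groups
#'
#' Draws the survival curves of the high- and low-risk groups (high in red,
#' low in green), annotated with the log-rank p-value.
#'
#' @param groups A `risk_groups` object.
#' @param s Aligned `survival_table`.
#' @param path Optional file; when given, the plot is written as PDF.
#' @param main Plot title.
#' @return The `survfit` object, invisibly.
#' @export
plot_risk_groups <- function(groups, s, path = NULL,
                             main = "Survival by predicted risk group") {
  grp <- groups$group
  fit <- survival::survfit(survival::Surv(s$time, s$event) ~ grp)
  lr <- logrank_test(groups, s)
  if (!is.null(path)) {
    grDevices::pdf(path, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  plot(fit, col = c("forestgreen", "red2"), lwd = 2,
       xlab = "time", ylab = "survival probability", main = main)
  graphics::legend("topright", lwd = 2, col = c("forestgreen", "red2"),
                   legend = c("low risk", "high risk"), bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", lr$p_value), side = 3,
                  line = 0, cex = 0.8)
  invisible(fit)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    c_index = report$c_index,
    logrank_statistic = report$logrank_statistic,
    logrank_p = report$logrank_p,
    per_fold_c = report$per_fold_c,
    risk_threshold = report$risk_groups$threshold,
    risk_groups = stats::setNames(as.list(as.character(report$risk_groups$group)),
                                  report$risk_groups$sample_ids),
    covariate_tests = report$covariate_tests)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
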