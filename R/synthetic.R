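#' Configuration of a synthetic multi-cohort survival study
#'
#' The generator realizes the proportional-hazards model
#' `lambda(t|x) = lambda0 * exp(h(x))` generatively: each cohort draws latent
#' factors `Z` (samples x latent_rank) from a standard normal, builds
#' expression as `Z %*% loadings + noise` (shifted non-negative so the log2
#' preprocessing is exercisable), sets the true risk `h* = Z %*% beta`, and
#' draws survival times from an exponential baseline with rate
#' `lambda0 * exp(h*)`. Censoring times are uniform on `(0, c)` with `c`
#' calibrated by bisection so the expected censoring fraction matches
#' `censor_rate`.
#'
#' Cohorts belong to latent "families": same-family cohorts share the
#' coefficient vector, loadings, expression scale and baseline hazard up to a
#' small jitter, while families differ by `family_shift`, which scales the
#' coefficient perturbation, the baseline-rate ratio and the overall
#' expression dispersion between families (distinct cancer types differ in
#' both survival and expression distributions, and the genotype block of the
#' cohort descriptor is only informative if the generator reflects the
#' latter). Defaults mimic
#' a liver-cancer-like regime: 370 samples per cohort and a 65.5% censoring
#' rate (34.5% of patients uncensored).
#'
#' @param n_cohorts Number of cohorts, default 6.
#' @param n_families Number of families, default 2 (cohorts are assigned
#'   round-robin unless `family_of` is given).
#' @param family_of Optional integer vector (length `n_cohorts`) of family
#'   ids in `1:n_families`.
#' @param n_samples Samples per cohort (single value or per-cohort vector),
#'   default 370.
#' @param n_genes Number of genes, default 100.
#' @param latent_rank Latent factor dimension, default 5 (<= `n_genes`).
#' @param baseline_rate Family-1 exponential baseline hazard, default 0.1.
#' @param family_shift Between-family multiplier (>= 0) on baseline rate and
#'   coefficient perturbation scale, default 2.
#' @param censor_rate Target censoring proportion in `[0, 1)`, default 0.655.
#' @param within_family_jitter Scale of the within-family perturbation of
#'   coefficients and baseline, default 0.05.
#' @param beta_family Optional list of per-family coefficient vectors
#'   (length `latent_rank`); generated from the seed when `NULL`.
#' @param shared_loadings If `TRUE`, all families share one loading matrix:
#'   families then differ only in their survival structure (baseline hazard
#'   and feature-risk map) and expression scale, not in which gene
#'   combinations carry the latent factors. Default `FALSE`.
#' @param noise_sd Standard deviation of the gene-level measurement noise
#'   added on top of the latent-factor signal (whose per-gene scale is about
#'   1), default 0.5. Larger values make the risk-carrying factors harder to
#'   estimate from few samples.
#' @param seed Integer seed, default 1.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_cohorts = 6L, n_families = 2L,
                              family_of = NULL, n_samples = 370L,
                              n_genes = 100L, latent_rank = 5L,
                              baseline_rate = 0.1, family_shift = 2,
                              censor_rate = 0.655,
                              within_family_jitter = 0.05,
                              beta_family = NULL, shared_loadings = FALSE,
                              noise_sd = 0.5, seed = 1L) {
  stopifnot(n_cohorts >= 1L, n_families >= 1L, latent_rank <= n_genes,
            censor_rate >= 0, censor_rate < 1, all(n_samples >= 4L),
            family_shift >= 0, baseline_rate > 0)
  if (is.null(family_of)) {
    family_of <- rep_len(seq_len(n_families), n_cohorts)
  }
  stopifnot(length(family_of) == n_cohorts,
            all(family_of %in% seq_len(n_families)))
  n_samples <- rep_len(as.integer(n_samples), n_cohorts)
  set.seed(seed)
  r <- as.integer(latent_rank)
  normalize <- function(v) v / sqrt(sum(v^2))
  if (is.null(beta_family)) {
    base_beta <- normalize(stats::rnorm(r))
    beta_family <- vector("list", n_families)
    beta_family[[1L]] <- base_beta
    if (n_families > 1L) {
      for (f in 2L:n_families) {
        beta_family[[f]] <- normalize(base_beta +
                                        family_shift * normalize(stats::rnorm(r)))
      }
    }
  }
  stopifnot(length(beta_family) == n_families,
            all(lengths(beta_family) == r))
  rate_family <- baseline_rate * family_shift^(seq_len(n_families) - 1L)
  if (family_shift == 0) rate_family <- rep(baseline_rate, n_families)
  # expression dispersion differs between families on a sqrt scale
  scale_family <- max(family_shift, 1e-8)^((seq_len(n_families) - 1L) / 2)
  if (family_shift == 0) scale_family <- rep(1, n_families)
  # family loadings map latent factors to genes; shared within a family and,
  # under shared_loadings, across families too
  loadings_family <- lapply(seq_len(n_families), function(f) {
    matrix(stats::rnorm(r * n_genes, sd = 1 / sqrt(r)), nrow = r)
  })
  if (shared_loadings) {
    loadings_family <- rep(loadings_family[1L], n_families)
  }
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_families = as.integer(n_families),
                 family_of = as.integer(family_of),
                 n_samples = n_samples, n_genes = as.integer(n_genes),
                 latent_rank = r, baseline_rate = baseline_rate,
                 rate_family = rate_family, scale_family = scale_family,
                 family_shift = family_shift,
                 censor_rate = censor_rate, noise_sd = noise_sd,
                 within_family_jitter = within_family_jitter,
                 beta_family = beta_family,
                 loadings_family = loadings_family,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# expected censoring fraction when censoring ~ U(0, c) and the event time is
# exponential with the given per-sample rates: mean of (1 - exp(-r c))/(r c)
.expected_censor_frac <- function(cens_upper, rates) {
  mean((1 - exp(-rates * cens_upper)) / (rates * cens_upper))
}

# bisection on the uniform upper bound so the expected censoring fraction
# matches the target; the expectation is monotone decreasing in the bound
.calibrate_censoring <- function(rates, target) {
  if (target <= 0 || target >= 1) {
    stop("censoring calibration failed: target ", target,
         " outside the achievable range (0, 1)")
  }
  lo <- 1e-10; hi <- 1 / stats::median(rates)
  for (i in 1:200) {
    if (.expected_censor_frac(hi, rates) < target) break
    hi <- hi * 2
    if (hi > 1e12) {
      stop("censoring calibration failed: achieved rate ",
           signif(.expected_censor_frac(hi, rates), 3),
           " cannot reach target ", target)
    }
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (.expected_censor_frac(mid, rates) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate one cohort
#'
#' @param cfg A `simulation_config`.
#' @param cohort_index Index in `1:cfg$n_cohorts`.
#' @return A `cohort` carrying extra fields: `family` (planted family id),
#'   `true_risk` (the generating `h*`, named by sample), `true_beta` and
#'   `lambda0`.
#' @export
simulate_cohort <- function(cfg, cohort_index) {
  stopifnot(inherits(cfg, "simulation_config"),
            cohort_index >= 1L, cohort_index <= cfg$n_cohorts)
  fam <- cfg$family_of[cohort_index]
  n <- cfg$n_samples[cohort_index]
  r <- cfg$latent_rank
  set.seed(cfg$seed + 7919L * as.integer(cohort_index))
  jit <- cfg$within_family_jitter
  beta <- cfg$beta_family[[fam]] + jit * stats::rnorm(r)
  beta <- beta / sqrt(sum(beta^2))
  lambda0 <- cfg$rate_family[fam] * exp(jit * stats::rnorm(1L))
  Z <- matrix(stats::rnorm(n * r), nrow = n)
  expr_scale <- cfg$scale_family[fam] * exp(jit * stats::rnorm(1L))
  expr <- expr_scale * (Z %*% cfg$loadings_family[[fam]] +
                          matrix(stats::rnorm(n * cfg$n_genes,
                                              sd = cfg$noise_sd),
                                 nrow = n))
  expr <- expr - min(expr)  # non-negative so log2(v + 1) applies
  h <- drop(Z %*% beta)
  rates <- lambda0 * exp(h)
  t_event <- stats::rexp(n, rate = rates)
  if (cfg$censor_rate == 0) {
    obs <- t_event
    event <- rep(1L, n)
  } else {
    cens_upper <- .calibrate_censoring(rates, cfg$censor_rate)
    t_cens <- stats::runif(n, 0, cens_upper)
    event <- as.integer(t_event <= t_cens)
    obs <- pmin(t_event, t_cens)
  }
  obs <- pmax(obs, .Machine$double.eps)
  name <- sprintf("F%d_C%d", fam, cohort_index)
  sample_ids <- sprintf("%s_s%03d", name, seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  m <- t(expr)
  dimnames(m) <- list(gene_ids, sample_ids)
  surv <- as_survival_table(
    data.frame(sample_id = sample_ids, time = obs, event = event),
    context = name)
  ch <- cohort(name, m, surv)
  ch$family <- fam
  ch$true_risk <- stats::setNames(h, sample_ids)
  ch$true_beta <- beta
  ch$lambda0 <- lambda0
  ch
}

#' Simulate a multi-cohort study
#'
#' Generates every cohort of the configuration independently given the shared
#' family parameters, so same-family cohorts have matching risk structure up
#' to the within-family jitter and families differ by `family_shift`.
#'
#' @param cfg A `simulation_config`.
#' @return Named list of `cohort` objects (see [simulate_cohort()]), with the
#'   planted family labels in the `"families"` attribute.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  cohorts <- lapply(seq_len(cfg$n_cohorts), function(i) simulate_cohort(cfg, i))
  names(cohorts) <- vapply(cohorts, function(c) c$name, character(1L))
  attr(cohorts, "families") <- stats::setNames(cfg$family_of, names(cohorts))
  cohorts
}
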