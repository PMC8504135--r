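#' Transfer-learning plan
#'
#' @param target Target cohort name.
#' @param pretrain_cohorts Character vector of source cohort names (must not
#'   contain the target).
#' @param pretrain_epochs Epochs of source training, default 200.
#' @param finetune_epochs Epochs of target training, default 500.
#' @param freeze_layers Number of leading hidden layers held fixed during
#'   fine-tuning, default 0 (all layers adapt).
#' @return A `transfer_plan` object.
#' @export
transfer_plan <- function(target, pretrain_cohorts, pretrain_epochs = 200L,
                          finetune_epochs = 500L, freeze_layers = 0L) {
  if (target %in% pretrain_cohorts) {
    stop("target cohort must not be in the pre-training set")
  }
  stopifnot(pretrain_epochs >= 1L, finetune_epochs >= 1L, freeze_layers >= 0L)
  structure(list(target = target, pretrain_cohorts = pretrain_cohorts,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 freeze_layers = as.integer(freeze_layers)),
            class = "transfer_plan")
}

#' Training features of a cohort
#'
#' Transposes the expression matrix to samples x genes and standardizes each
#' gene within the cohort (constant genes become zero columns). Per-cohort
#' scaling puts cohorts measured on different scales into a common feature
#' space for cross-cohort pre-training.
#'
#' @param c A `cohort`.
#' @param standardize Z-score genes within the cohort? Default `TRUE`.
#' @return Numeric samples x genes matrix.
#' @export
cohort_features <- function(c, standardize = TRUE) {
  x <- t(c$expression)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    x <- sweep(x, 2L, ctr, "-")
    pos <- scl > 0
    x[, pos] <- sweep(x[, pos, drop = FALSE], 2L, scl[pos], "/")
    x[, !pos] <- 0
  }
  x
}

#' Pre-train a Cox network on pooled source cohorts
#'
#' Trains for `plan$pretrain_epochs` on all source cohorts jointly. The
#' pooled loss is the sum of per-cohort partial likelihoods: risk sets are
#' computed within each cohort (stratified pooling), since survival times are
#' not comparable across cohorts with different baseline hazards.
#'
#' @param cohorts Named list of gene-harmonized `cohort` objects containing
#'   at least the plan's sources.
#' @param spec A `network_spec` whose `input_dim` equals the common gene
#'   count.
#' @param cfg A `training_config`; its `epochs` field is overridden by the
#'   plan.
#' @param plan A `transfer_plan` with a nonempty `pretrain_cohorts`.
#' @return The pre-trained `cox_network` (loss trace in `$loss_trace`).
#' @export
pretrain <- function(cohorts, spec, cfg, plan) {
  stopifnot(inherits(plan, "transfer_plan"))
  if (length(plan$pretrain_cohorts) == 0L) {
    stop("empty pre-training set")
  }
  miss <- setdiff(plan$pretrain_cohorts, names(cohorts))
  if (length(miss) > 0L) {
    stop("pre-training cohort(s) not found: ", paste(miss, collapse = ", "))
  }
  strata <- lapply(cohorts[plan$pretrain_cohorts], function(c) {
    list(x = cohort_features(c), time = c$survival$time,
         event = c$survival$event)
  })
  cfg$epochs <- plan$pretrain_epochs
  net <- init_network(spec, seed = cfg$seed)
  .train_strata(net, strata, cfg)
}

#' Fine-tune a pre-trained network on the target cohort
#'
#' Continues training on the target only, for `plan$finetune_epochs`, holding
#' the first `plan$freeze_layers` hidden layers fixed if requested.
#'
#' @param net A (pre-trained) `cox_network`.
#' @param target A `cohort` whose gene count matches the network input.
#' @param cfg A `training_config`; `epochs` is overridden by the plan.
#' @param plan A `transfer_plan`.
#' @return The fine-tuned `cox_network`.
#' @export
finetune <- function(net, target, cfg, plan) {
  stopifnot(inherits(plan, "transfer_plan"), inherits(target, "cohort"))
  x <- cohort_features(target)
  if (ncol(x) != net$spec$input_dim) {
    stop("target gene count ", ncol(x), " does not match network input_dim ",
         net$spec$input_dim)
  }
  cfg$epochs <- plan$finetune_epochs
  .train_strata(net, list(list(x = x, time = target$survival$time,
                               event = target$survival$event)),
                cfg, freeze_layers = plan$freeze_layers)
}

# defaults for the end-to-end pipeline; user config entries override
.default_fit_config <- function() {
  list(filter_sources = TRUE, min_uncensored = 50L, min_samples = 100L,
       unit_scale = 1, estimator = "km", gamma = NULL,
       hidden_dims = c(50L, 20L, 10L), dropout = 0,
       grid = NULL,  # NULL -> default_grid() when cv, else lr 1e-3
       n_folds = 10L, cv = TRUE,
       pretrain_epochs = 200L, finetune_epochs = 500L, freeze_layers = 0L,
       seed = 1L)
}

#' Fit the adaptive transfer Cox network end-to-end
#'
#' Runs the full pipeline for a target cohort: gene harmonization, the
#' 22-feature descriptor matrix, silhouette-guided k-means clustering,
#' pre-training-set selection (the target's co-cluster members),
#' cross-validated learning-rate choice on the target, pre-training on the
#' selected sources, fine-tuning on the target, and evaluation (concordance,
#' median risk split, log-rank, covariate associations).
#'
#' @param cohorts Named list of `cohort` objects including the target.
#' @param target Name of the target cohort.
#' @param config Named list overriding pipeline defaults: `filter_sources`,
#'   `min_uncensored`, `min_samples` (candidate filter, applied to source
#'   cohorts only), `unit_scale`, `estimator`, `gamma` (descriptors),
#'   `hidden_dims`, `dropout` (architecture), `grid` (list of
#'   `training_config`s), `cv`, `n_folds` (hyperparameter search),
#'   `pretrain_epochs`, `finetune_epochs`, `freeze_layers`, `seed`.
#' @return An `atrcn_fit` list: `network`, `clustering`, `plan`, `report`,
#'   `descriptors`, `cv_summary`, `scores`, `config`.
#' @export
atrcn_fit <- function(cohorts, target, config = list()) {
  cfg <- utils::modifyList(.default_fit_config(), config)
  if (is.null(names(cohorts))) {
    names(cohorts) <- vapply(cohorts, function(c) c$name, character(1L))
  }
  if (!target %in% names(cohorts)) {
    stop("selection stage: target cohort '", target, "' not found")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage: ", conditionMessage(e), call. = FALSE)
    })
  }
  sources <- cohorts[setdiff(names(cohorts), target)]
  if (isTRUE(cfg$filter_sources)) {
    sources <- stage("candidate filter",
                     filter_candidate_cohorts(sources, cfg$min_uncensored,
                                              cfg$min_samples))
  }
  if (length(sources) == 0L) stop("candidate filter stage: no source cohorts remain")
  cohorts <- stage("harmonization",
                   harmonize_genes(c(sources, cohorts[target])))
  names(cohorts) <- vapply(cohorts, function(c) c$name, character(1L))

  vectors <- stage("descriptor", lapply(cohorts, function(c) {
    cohort_descriptor(c, unit_scale = cfg$unit_scale,
                      estimator = cfg$estimator, gamma = cfg$gamma)
  }))
  dmat <- stage("descriptor", build_descriptor_matrix(vectors))
  clustering <- stage("clustering",
                      choose_k_by_silhouette(dmat, seed = cfg$seed))
  pre_set <- stage("selection",
                   pretraining_set_for_target(clustering, target))

  tgt <- cohorts[[target]]
  x_tgt <- cohort_features(tgt)
  spec <- network_spec(ncol(x_tgt), hidden_dims = cfg$hidden_dims,
                       dropout = cfg$dropout)
  grid <- cfg$grid
  if (is.null(grid)) {
    grid <- if (isTRUE(cfg$cv)) {
      default_grid(epochs = cfg$finetune_epochs, seed = cfg$seed)
    } else {
      list(training_config(learning_rate = 1e-3,
                           epochs = cfg$finetune_epochs, seed = cfg$seed))
    }
  }
  cv_summary <- NULL
  per_fold_c <- NULL
  if (isTRUE(cfg$cv) && length(grid) > 1L) {
    cvres <- stage("cross-validation",
                   cross_validate_hyperparams(x_tgt, tgt$survival, spec, grid,
                                              n_folds = cfg$n_folds,
                                              seed = cfg$seed))
    train_cfg <- cvres$best
    cv_summary <- cvres$summary
    best_idx <- which(vapply(grid, identical, logical(1L), y = cvres$best))[1L]
    per_fold_c <- cvres$per_fold_c[[best_idx]]
  } else {
    train_cfg <- grid[[1L]]
  }

  plan <- transfer_plan(target, pre_set,
                        pretrain_epochs = cfg$pretrain_epochs,
                        finetune_epochs = cfg$finetune_epochs,
                        freeze_layers = cfg$freeze_layers)
  net <- stage("pre-training", pretrain(cohorts, spec, train_cfg, plan))
  net <- stage("fine-tuning", finetune(net, tgt, train_cfg, plan))
  scores <- stage("evaluation", forward_risk(net, x_tgt))
  report <- stage("evaluation",
                  evaluate_model(scores, tgt$survival,
                                 per_fold_c = per_fold_c))
  structure(list(network = net, clustering = clustering, plan = plan,
                 report = report, descriptors = dmat,
                 cv_summary = cv_summary, scores = scores,
                 config = cfg),
            class = "atrcn_fit")
}

#' @export
print.atrcn_fit <- function(x, ...) {
  cat(sprintf("adaptive transfer Cox fit for target '%s'\n", x$plan$target))
  cat(sprintf("  pre-training cohorts: %s\n",
              paste(x$plan$pretrain_cohorts, collapse = ", ")))
  cat(sprintf("  clustering: k = %d over %d cohorts\n", x$clustering$k,
              length(x$clustering$assignment)))
  print(x$report)
  invisible(x)
}
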