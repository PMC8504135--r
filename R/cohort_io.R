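#' Read an expression matrix from TSV/CSV
#'
#' Expects genes as rows with the gene identifier in the first column, and a
#' header row of sample identifiers. The tokens `"NA"`, `""`, `"nan"` and
#' `"NaN"` are recorded as missing values, not zeros.
#'
#' @param path Path to a TSV (`.tsv`/`.txt`) or CSV (`.csv`) file.
#' @param sep Field separator. Defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @param missing_tokens Character vector of cell values treated as missing.
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names. May contain `NA` entries until
#'   [preprocess_expression()] is applied.
#' @seealso [read_survival()], [preprocess_expression()]
#' @export
read_expression <- function(path, sep = NULL,
                            missing_tokens = c("NA", "", "nan", "NaN")) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      na.strings = missing_tokens, colClasses = NA,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = ""),
    error = function(e) stop("failed to parse expression file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L) stop("expression file needs a gene id column plus at least one sample column")
  gene_ids <- as.character(df[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    # non-numeric leftovers beyond the declared missing tokens
    suppressWarnings(storage.mode(m) <- "double")
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Read a survival table
#'
#' Requires columns `sample_id`, `time` and `event`; any further columns are
#' retained as clinical covariates. Event values are mapped to 0/1 by a fixed
#' dictionary: `1`, `"TRUE"`, `"true"`, `"dead"`, `"deceased"` mean the event
#' was observed; `0`, `"FALSE"`, `"false"`, `"alive"`, `"living"`,
#' `"censored"` mean censoring.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param sep Field separator, defaulting by file extension as in
#'   [read_expression()].
#' @return A `data.frame` of class `survival_table` with columns `sample_id`
#'   (character), `time` (positive numeric), `event` (integer 0/1) and any
#'   covariate columns.
#' @export
read_survival <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  as_survival_table(df, context = path)
}

# event coding dictionary; anything else is an error
.event_map <- c("1" = 1L, "0" = 0L, "TRUE" = 1L, "FALSE" = 0L,
                "true" = 1L, "false" = 0L, "dead" = 1L, "deceased" = 1L,
                "alive" = 0L, "living" = 0L, "censored" = 0L)

#' Coerce a data frame to a validated survival table
#'
#' @param df Data frame with columns `sample_id`, `time`, `event` and optional
#'   covariates.
#' @param context Label used in error messages (e.g. a file name).
#' @return A validated `survival_table` data frame.
#' @export
as_survival_table <- function(df, context = "survival table") {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop(context, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop(context, ": duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$time <- as.numeric(df$time)
  bad_t <- !is.finite(df$time) | df$time <= 0
  if (any(bad_t)) {
    stop(context, ": nonpositive or missing time for sample(s): ",
         paste(df$sample_id[bad_t], collapse = ", "))
  }
  ev_chr <- as.character(df$event)
  ev <- .event_map[ev_chr]
  if (anyNA(ev)) {
    stop(context, ": unrecognized event value(s): ",
         paste(unique(ev_chr[is.na(ev)]), collapse = ", "),
         " (allowed: ", paste(names(.event_map), collapse = ", "), ")")
  }
  df$event <- as.integer(ev)
  covars <- setdiff(colnames(df), need)
  df <- df[, c(need, covars), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Names of the covariate columns of a survival table
#' @param s A `survival_table`.
#' @return Character vector (possibly empty).
#' @export
covariate_names <- function(s) {
  setdiff(colnames(s), c("sample_id", "time", "event"))
}

#' Preprocess an expression matrix
#'
#' Mirrors the standard RNA-seq preparation for survival modelling: genes with
#' a missing fraction strictly greater than `missing_gene_frac` are dropped,
#' remaining missing entries are imputed with the gene's median over observed
#' samples, and values are optionally transformed to `log2(v + 1)`.
#'
#' The comparison is strict: a gene missing in exactly 20% of samples is kept
#' under the default threshold. The log transform is recorded in the
#' `"log_transformed"` attribute so that preprocessing is idempotent.
#'
#' @param m Numeric genes x samples matrix as from [read_expression()].
#' @param missing_gene_frac Maximum tolerated missing fraction per gene,
#'   default 0.20.
#' @param log_transform Apply `log2(v + 1)`? Default `TRUE`.
#' @return The filtered, fully imputed (and possibly log-transformed) matrix.
#' @export
preprocess_expression <- function(m, missing_gene_frac = 0.20,
                                  log_transform = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (missing_gene_frac < 0 || missing_gene_frac > 1) {
    stop("missing_gene_frac must be in [0, 1]")
  }
  already_logged <- isTRUE(attr(m, "log_transformed"))
  frac_missing <- rowMeans(is.na(m))
  keep <- frac_missing <= missing_gene_frac  # strictly greater -> dropped
  if (!any(keep)) stop("all genes exceed the missing-value threshold")
  m <- m[keep, , drop = FALSE]
  na_rows <- which(rowSums(is.na(m)) > 0L)
  for (i in na_rows) {
    v <- m[i, ]
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    m[i, ] <- v
  }
  if (!all(is.finite(m))) stop("non-finite expression values after imputation")
  if (log_transform && !already_logged) {
    if (any(m < 0)) stop("negative expression values: cannot log2(v + 1) transform")
    m <- log2(m + 1)
  }
  if (log_transform || already_logged) attr(m, "log_transformed") <- TRUE
  m
}

#' Construct a cohort from expression and survival data
#'
#' Samples are aligned to the intersection of expression columns and survival
#' rows, in the expression matrix's order.
#'
#' @param name Cohort label.
#' @param expression Numeric genes x samples matrix.
#' @param survival A `survival_table` (or coercible data frame).
#' @return An object of class `cohort`: a list with elements `name`,
#'   `expression` and `survival`.
#' @export
cohort <- function(name, expression, survival) {
  stopifnot(is.character(name), length(name) == 1L, is.matrix(expression))
  if (!inherits(survival, "survival_table")) {
    survival <- as_survival_table(as.data.frame(survival), context = name)
  }
  common <- intersect(colnames(expression), survival$sample_id)
  if (length(common) < 2L) {
    stop("cohort '", name, "': fewer than 2 samples shared between expression and survival")
  }
  expression <- expression[, common, drop = FALSE]
  survival <- survival[match(common, survival$sample_id), , drop = FALSE]
  rownames(survival) <- NULL
  structure(list(name = name, expression = expression, survival = survival),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d genes x %d samples, %d events (%.1f%% uncensored)\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$survival$event),
              100 * mean(x$survival$event)))
  invisible(x)
}

#' Number of samples / uncensored patients in a cohort
#' @param c A `cohort`.
#' @return Integer count.
#' @export
n_samples <- function(c) ncol(c$expression)

#' @rdname n_samples
#' @export
n_uncensored <- function(c) sum(c$survival$event)

#' Filter candidate source cohorts by size and event count
#'
#' Keeps cohorts with strictly more than `min_uncensored` observed events and
#' strictly more than `min_samples` samples, preserving order. Both
#' inequalities are strict.
#'
#' @param cohorts List of `cohort` objects.
#' @param min_uncensored Event-count threshold, default 50.
#' @param min_samples Sample-size threshold, default 100.
#' @return The retained sublist (possibly empty, with a warning).
#' @export
filter_candidate_cohorts <- function(cohorts, min_uncensored = 50,
                                     min_samples = 100) {
  stopifnot(is.list(cohorts))
  keep <- vapply(cohorts, function(c) {
    n_uncensored(c) > min_uncensored && n_samples(c) > min_samples
  }, logical(1L))
  if (!any(keep)) warning("no cohort passes the candidate filter")
  cohorts[keep]
}

#' Restrict cohorts to their common genes
#'
#' All cohorts are subset to the intersection of their gene ids, in the first
#' cohort's gene order, so that expression features align for cross-cohort
#' training.
#'
#' @param cohorts Nonempty list of `cohort` objects.
#' @return List of cohorts sharing an identical gene id sequence.
#' @export
harmonize_genes <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  genes <- rownames(cohorts[[1L]]$expression)
  for (c in cohorts[-1L]) genes <- intersect(genes, rownames(c$expression))
  if (length(genes) == 0L) stop("no genes shared by all cohorts")
  lapply(cohorts, function(c) {
    c$expression <- c$expression[genes, , drop = FALSE]
    c
  })
}

#' Read a cohort manifest
#'
#' A manifest is a YAML or JSON mapping of cohort name to a list with
#' `expression` and `survival` file paths (relative paths resolved against the
#' manifest's directory). Each cohort is read, preprocessed and assembled.
#'
#' @param path Manifest file (`.yaml`/`.yml` needs the `yaml` package,
#'   `.json` uses jsonlite).
#' @param preprocess Apply [preprocess_expression()] with defaults? Default
#'   `TRUE`.
#' @return Named list of `cohort` objects.
#' @export
read_cohort_manifest <- function(path, preprocess = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML manifests")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  out <- lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    m <- read_expression(resolve(entry$expression))
    if (preprocess) m <- preprocess_expression(m)
    cohort(nm, m, read_survival(resolve(entry$survival)))
  })
  names(out) <- names(spec)
  out
}

#' Write a study of cohorts to disk
#'
#' Writes one expression TSV and one survival CSV per cohort plus a JSON
#' manifest consumable by [read_cohort_manifest()].
#'
#' @param cohorts Named list of `cohort` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(cohorts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (c in cohorts) {
    ep <- file.path(dir, paste0(c$name, "_expression.tsv"))
    sp <- file.path(dir, paste0(c$name, "_survival.csv"))
    df <- data.frame(gene_id = rownames(c$expression), c$expression,
                     check.names = FALSE)
    utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(c$survival, sp, row.names = FALSE)
    manifest[[c$name]] <- list(expression = basename(ep), survival = basename(sp))
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
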