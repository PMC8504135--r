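#' Candidate cluster counts for N cohorts
#'
#' The cluster count k is searched between one quarter and three quarters of
#' the number of cohorts: integers from `ceiling(N/4)` to `floor(3N/4)`, each
#' raised to a minimum of 2. Too small a k pools dissimilar cohorts into the
#' pre-training set; too large a k risks leaving the target alone in its
#' cluster with no pre-training data.
#'
#' @param n_cohorts Number of cohorts, at least 4.
#' @return Integer vector of candidate k values.
#' @export
candidate_k_range <- function(n_cohorts) {
  if (n_cohorts < 4L) stop("candidate k range needs at least 4 cohorts")
  ks <- seq.int(ceiling(n_cohorts / 4), floor(3 * n_cohorts / 4))
  ks <- unique(pmax(ks, 2L))
  ks <- ks[ks < n_cohorts]
  if (length(ks) == 0L) stop("empty candidate k range for N = ", n_cohorts)
  as.integer(ks)
}

# mean silhouette width of a k-means partition on Euclidean distances
.mean_silhouette <- function(assignment, dmat) {
  sil <- cluster::silhouette(assignment, dmat)
  mean(sil[, "sil_width"])
}

#' Cluster cohorts in descriptor space, choosing k by silhouette
#'
#' Runs k-means (10 random restarts, seeded) on the normalized descriptor
#' matrix for every candidate k and returns the partition with the largest
#' mean silhouette coefficient (Euclidean distances, matching the k-means
#' metric). Exact ties are broken toward the smaller k, which yields larger
#' pre-training sets.
#'
#' @param d A `descriptor_matrix`.
#' @param ks Candidate cluster counts; default [candidate_k_range()] of the
#'   number of cohorts. Every k must be smaller than the number of cohorts.
#' @param seed Integer seed making the search deterministic.
#' @param nstart Random restarts per k, default 10.
#' @return A `clustering_result`: list with `k`, `assignment` (named integer
#'   vector cohort -> cluster id in `1:k`), `centroids` (k x 22),
#'   `silhouette_by_k` (named numeric), and `seed`.
#' @export
choose_k_by_silhouette <- function(d, ks = NULL, seed = 1L, nstart = 10L) {
  stopifnot(inherits(d, "descriptor_matrix"))
  x <- d$normalized
  n <- nrow(x)
  if (is.null(ks)) ks <- candidate_k_range(n)
  if (length(ks) == 0L) stop("no candidate k supplied")
  if (any(ks >= n)) stop("every candidate k must be < number of cohorts (", n, ")")
  if (any(ks < 2L)) stop("candidate k must be >= 2")
  dmat <- stats::dist(x)
  ks <- sort(unique(as.integer(ks)))
  sil_by_k <- stats::setNames(numeric(length(ks)), ks)
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed + ks[i])  # per-k seed: result independent of ks ordering
    fits[[i]] <- stats::kmeans(x, centers = ks[i], nstart = nstart,
                               iter.max = 100L)
    sil_by_k[i] <- .mean_silhouette(fits[[i]]$cluster, dmat)
  }
  best <- which.max(sil_by_k)  # first maximum -> smaller k on exact ties
  fit <- fits[[best]]
  structure(list(k = ks[best],
                 assignment = stats::setNames(fit$cluster, rownames(x)),
                 centroids = fit$centers,
                 silhouette_by_k = sil_by_k,
                 seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering of %d cohorts: k = %d (mean silhouette %.3f)\n",
              length(x$assignment), x$k,
              x$silhouette_by_k[as.character(x$k)]))
  for (cl in sort(unique(x$assignment))) {
    cat(sprintf("  cluster %d: %s\n", cl,
                paste(names(x$assignment)[x$assignment == cl], collapse = ", ")))
  }
  invisible(x)
}

#' Pre-training cohorts for a target
#'
#' Returns all cohorts sharing the target's cluster, excluding the target.
#' When the target is alone in its cluster, the members of the nearest other
#' cluster (by centroid Euclidean distance) are returned with a warning, so
#' that small studies still obtain a pre-training set.
#'
#' @param cr A `clustering_result`.
#' @param target Cohort name present in the clustering.
#' @return Character vector of cohort names.
#' @export
pretraining_set_for_target <- function(cr, target) {
  stopifnot(inherits(cr, "clustering_result"))
  if (!target %in% names(cr$assignment)) {
    stop("unknown target cohort: ", target)
  }
  own <- cr$assignment[[target]]
  members <- names(cr$assignment)[cr$assignment == own]
  members <- setdiff(members, target)
  if (length(members) > 0L) return(members)
  warning("target '", target, "' is alone in its cluster; ",
          "falling back to the nearest cluster")
  ranked <- rank_clusters_by_distance(cr, target)
  nearest <- ranked$cluster[2L]
  names(cr$assignment)[cr$assignment == nearest]
}

#' Rank clusters by centroid distance from the target's cluster
#'
#' Euclidean distances from the target's cluster centroid to every cluster
#' centroid, ascending; the target's own cluster comes first with distance 0.
#'
#' @param cr A `clustering_result`.
#' @param target Cohort name present in the clustering.
#' @return Data frame with columns `cluster` and `distance`, ordered
#'   ascending.
#' @export
rank_clusters_by_distance <- function(cr, target) {
  stopifnot(inherits(cr, "clustering_result"))
  if (!target %in% names(cr$assignment)) {
    stop("unknown target cohort: ", target)
  }
  own <- cr$assignment[[target]]
  ctr <- cr$centroids[own, ]
  dd <- sqrt(rowSums(sweep(cr$centroids, 2L, ctr, "-")^2))
  ord <- order(dd)
  data.frame(cluster = as.integer(rownames(cr$centroids))[ord],
             distance = dd[ord], row.names = NULL)
}

#' Serialize a clustering result to JSON
#'
#' @param cr A `clustering_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(cr, path) {
  jsonlite::write_json(
    list(k = cr$k, assignment = as.list(cr$assignment),
         silhouette_by_k = as.list(cr$silhouette_by_k), seed = cr$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
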