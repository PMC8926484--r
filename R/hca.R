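#' Hierarchical cluster analysis of batches
#'
#' Agglomerative clustering of batches on any per-batch variables — most
#' usefully the common-peak areas of a [fingerprint_matrix()], or a single
#' quantitative index such as the SQFM macro-quantitative similarity. The
#' default pairing of squared Euclidean distance with between-groups
#' (average) linkage matches the common default of mainstream statistics
#' suites, so memberships are comparable with routine practice; both choices
#' are configurable.
#'
#' @param data A [fingerprint_matrix()], a data frame with a `batch_id`
#'   column plus numeric variables, or a numeric matrix with row names.
#' @param distance `"sq_euclidean"` (default) or `"euclidean"`.
#' @param linkage `"average"` (between-groups, default), `"ward"` or
#'   `"complete"`.
#' @param standardize Scale each variable to unit variance first
#'   (default FALSE).
#' @return An object of class `batch_hca`: the underlying `hclust` fit plus
#'   `labels`, a `merge_history` tibble (one row per merge: the two merged
#'   clusters as leaf sets, and the height) and the options used.
#' @examples
#' fm <- data.frame(batch_id = c("b1", "b2", "b3"),
#'                  p1 = c(1, 1.1, 5), p2 = c(2, 2.1, 9))
#' cut_batches(cluster_batches(fm), k = 2)
#' @export
cluster_batches <- function(data,
                            distance = c("sq_euclidean", "euclidean"),
                            linkage = c("average", "ward", "complete"),
                            standardize = FALSE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.data.frame(data)) {
    data <- as_tibble(data)
    if ("batch_id" %in% names(data)) {
      labels <- as.character(data$batch_id)
      m <- as.matrix(data[setdiff(names(data), "batch_id")])
    } else {
      labels <- paste0("batch", seq_len(nrow(data)))
      m <- as.matrix(data)
    }
  } else {
    m <- as.matrix(data)
    labels <- rownames(m) %||% paste0("batch", seq_len(nrow(m)))
  }
  if (!is.numeric(m) || anyNA(m)) stop_validation("variables must be numeric with no missing values.")
  if (nrow(m) < 2) stop_validation("need at least 2 batches to cluster.")
  if (standardize) m <- scale(m)

  d <- dist(m)
  if (distance == "sq_euclidean") d <- d^2
  method <- c(average = "average", ward = "ward.D", complete = "complete")[[linkage]]
  hc <- hclust(d, method = method)
  hc$labels <- labels

  leafset_cache <- vector("list", nrow(hc$merge))
  merges <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    la <- if (a < 0) labels[-a] else leafset_cache[[a]]
    lb <- if (b < 0) labels[-b] else leafset_cache[[b]]
    leafset_cache[[i]] <- c(la, lb)
    merges[[i]] <- tibble(step = i, cluster_a = paste(la, collapse = "+"),
                          cluster_b = paste(lb, collapse = "+"),
                          height = hc$height[i])
  }
  structure(list(hclust = hc, labels = labels,
                 merge_history = dplyr::bind_rows(merges),
                 distance = distance, linkage = linkage,
                 standardize = standardize),
            class = "batch_hca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a batch dendrogram into k clusters
#'
#' Clusters are relabelled in order of first appearance over the input
#' batches, so assignments are stable under row permutation up to that
#' canonical relabelling.
#'
#' @param hca A `batch_hca` object from [cluster_batches()].
#' @param k Number of clusters, between 1 and the number of batches.
#' @return A tibble: `batch_id`, `cluster` (integer, 1..k).
#' @export
cut_batches <- function(hca, k) {
  if (!inherits(hca, "batch_hca")) stop_domain("`hca` must come from cluster_batches().")
  n <- length(hca$labels)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k > n) {
    stop_validation(sprintf("`k` must be between 1 and %d.", n))
  }
  raw <- cutree(hca$hclust, k = as.integer(k))
  relabel <- match(raw, unique(raw))
  tibble(batch_id = hca$labels, cluster = relabel)
}

#' @export
print.batch_hca <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d batches (%s distance, %s linkage)\n",
              length(x$labels), x$distance, x$linkage))
  print(x$merge_history)
  invisible(x)
}

#' @export
tidy.batch_hca <- function(x, ...) x$merge_history

#' @export
glance.batch_hca <- function(x, ...) {
  tibble(n_batches = length(x$labels), distance = x$distance,
         linkage = x$linkage, max_height = max(x$hclust$height))
}
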