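## Metabolic subtyping: cluster samples on the enrichment scores of the 50
## metabolism-associated pathways (same k-selection + ordered k-means as the
## m6A pattern clustering), find the most-altered metabolic category by
## centroid distances, and label the three clusters LML / LMI / LMH by their
## mean lipid-pathway enrichment.

#' Cluster samples on metabolic pathway enrichment scores
#'
#' @param scores sets-by-samples enrichment matrix (e.g. [gsva_scores()] on
#'   the 50 metabolic sets).
#' @param k fixed cluster count, or `NULL` to select it.
#' @param k_min,k_max,indices,nstart,gap_B,seed see [select_k()].
#' @return an `m6a_cluster_assignment` (with `selection` when k was chosen).
#' @export
metabolic_clusters <- function(scores, k = NULL, k_min = 2L, k_max = 15L,
                               indices = c("silhouette", "ch", "db", "gap"),
                               nstart = 25L, gap_B = 20L, seed = 1L) {
  assert_that(is.matrix(scores) && nrow(scores) >= 2,
              "need a matrix of at least 2 gene sets")
  x <- t(scores)  # samples x sets
  selection <- NULL
  if (is.null(k)) {
    selection <- select_k(x, k_min = k_min, k_max = k_max, indices = indices,
                          nstart = nstart, gap_B = gap_B, seed = seed)
    k <- selection$k_best
  }
  assign <- kmeans_cluster(x, k = k, nstart = nstart, seed = seed)
  assign$selection <- selection
  assign
}

#' Per-category distance between metabolic clusters
#'
#' For each category, restricts the score matrix to its sets, computes
#' cluster centroids, and reports the mean Euclidean distance over all
#' unordered cluster pairs divided by the square root of the number of sets
#' in the category. The size normalization makes categories with different
#' set counts comparable: duplicating a category's sets leaves its distance
#' unchanged.
#'
#' @param scores sets-by-samples enrichment matrix.
#' @param assignment an `m6a_cluster_assignment` over the same samples.
#' @param categories named character vector (set name -> category).
#' @return data frame (`category`, `n_sets`, `distance`) sorted by
#'   decreasing distance.
#' @export
category_distance <- function(scores, assignment, categories) {
  labels <- assignment$labels[colnames(scores)]
  assert_that(!anyNA(labels), "assignment must cover all score samples")
  k <- assignment$k
  assert_that(k >= 2, "need at least 2 clusters")
  rows <- list()
  for (cat in unique(categories)) {
    sets <- intersect(names(categories)[categories == cat], rownames(scores))
    if (!length(sets)) { warn2("category '%s' has no scored set, skipped", cat); next }
    sub <- scores[sets, , drop = FALSE]
    centroids <- vapply(seq_len(k), function(cl) {
      rowMeans(sub[, labels == cl, drop = FALSE])
    }, numeric(length(sets)))
    ## vapply drops to a plain vector for single-set categories
    centroids <- matrix(centroids, nrow = length(sets))
    pairs <- utils::combn(k, 2)
    d <- mean(apply(pairs, 2, function(pr) {
      sqrt(sum((centroids[, pr[1]] - centroids[, pr[2]])^2))
    }))
    rows[[cat]] <- data.frame(category = cat, n_sets = length(sets),
                              distance = d / sqrt(length(sets)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label metabolic clusters by lipid-pathway enrichment
#'
#' With exactly 3 clusters, ranks them by mean enrichment over the lipid
#' category sets: lowest becomes LML (lipid-metabolism low), middle LMI,
#' highest LMH. Ties in the mean lipid score are broken by cluster size
#' (larger cluster gets the lower label). With k != 3 generic labels
#' L1..Lk (still ordered by lipid score) are used with a warning.
#'
#' @inheritParams category_distance
#' @return list of class `m6a_metabolic`: `labels` (named character vector
#'   per sample), `cluster_label` (cluster index -> label),
#'   `lipid_means`, `assignment`, `category_distance`.
#' @export
lipid_labels <- function(scores, assignment, categories) {
  labels <- assignment$labels[colnames(scores)]
  assert_that(!anyNA(labels), "assignment must cover all score samples")
  k <- assignment$k
  lipid_sets <- intersect(names(categories)[categories == "lipid"],
                          rownames(scores))
  assert_that(length(lipid_sets) > 0, "no lipid-category set in the score matrix")
  lipid_mean <- vapply(seq_len(k), function(cl) {
    mean(scores[lipid_sets, labels == cl, drop = FALSE])
  }, numeric(1))
  sizes <- tabulate(labels, k)
  if (anyDuplicated(lipid_mean)) {
    log_info("tied lipid means broken by cluster size (larger = lower label)")
  }
  ord <- order(lipid_mean, -sizes)  # ties: larger cluster gets lower label
  tags <- if (k == 3) c("LML", "LMI", "LMH") else {
    warn2("expected 3 metabolic clusters, got %d; using generic labels", k)
    paste0("L", seq_len(k))
  }
  cluster_label <- character(k)
  cluster_label[ord] <- tags
  structure(list(labels = setNames(cluster_label[labels], names(labels)),
                 cluster_label = setNames(cluster_label, paste0("cluster", seq_len(k))),
                 lipid_means = setNames(lipid_mean, paste0("cluster", seq_len(k))),
                 assignment = assignment,
                 category_distance = category_distance(scores, assignment,
                                                       categories)),
            class = "m6a_metabolic")
}

#' @export
print.m6a_metabolic <- function(x, ...) {
  cat("metabolic subtypes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                           table(x$labels)), collapse = " "), "\n")
  cat("most altered category:", x$category_distance$category[1], "\n")
  invisible(x)
}
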