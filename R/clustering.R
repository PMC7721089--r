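## Cluster-number selection and k-means assignment.
##
## The cluster count is chosen by a majority vote of four internal validity
## indices evaluated over k = k_min..k_max (mean silhouette width,
## Calinski-Harabasz, Davies-Bouldin, and the gap statistic with B uniform
## reference draws); silhouette/CH/gap vote for their maximizing k, DB for
## its minimizing k, and ties go to the smaller k. K-means itself is Lloyd's
## algorithm (stats::kmeans) with nstart random restarts, and cluster labels
## are renumbered so that cluster 1 has the lowest mean feature value — this
## fixes the C1 = low-expression / C3 = high-expression semantics across runs.

run_kmeans <- function(x, k, nstart, iter_max = 300L) {
  km <- tryCatch(
    suppressWarnings(kmeans(x, centers = k, nstart = nstart,
                            iter.max = iter_max, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km) || anyNA(km$centers)) {
    ## Lloyd can strand an empty cluster on degenerate draws; Hartigan-Wong
    ## re-seeds internally and is used as the documented fallback
    log_info("Lloyd k-means degenerate at k = %d; refitting with Hartigan-Wong", k)
    km <- suppressWarnings(kmeans(x, centers = k, nstart = nstart,
                                  iter.max = iter_max))
  }
  km
}

ch_index <- function(x, labels, centers) {
  n <- nrow(x); k <- nrow(centers)
  grand <- colMeans(x)
  sizes <- tabulate(labels, nbins = k)
  b <- sum(sizes * rowSums((centers - matrix(grand, k, ncol(x), byrow = TRUE))^2))
  w <- sum(rowSums((x - centers[labels, , drop = FALSE])^2))
  (b / (k - 1)) / (w / (n - k))
}

db_index <- function(x, labels, centers) {
  k <- nrow(centers)
  s <- vapply(seq_len(k), function(i) {
    xi <- x[labels == i, , drop = FALSE]
    if (nrow(xi) == 0) return(0)
    mean(sqrt(rowSums((xi - matrix(centers[i, ], nrow(xi), ncol(x),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  d <- as.matrix(dist(centers))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      if (d[i, j] == 0) Inf else (s[i] + s[j]) / d[i, j]
    }, numeric(1)))
  }, numeric(1)))
}

gap_stat <- function(x, k, nstart, B) {
  log_w <- function(m) {
    km <- run_kmeans(m, k, nstart)
    log(max(km$tot.withinss, .Machine$double.xmin))
  }
  obs <- log_w(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  ref <- vapply(seq_len(B), function(b) {
    r <- matrix(runif(length(x), rep(lo, each = nrow(x)),
                      rep(hi, each = nrow(x))),
                nrow = nrow(x))
    log_w(r)
  }, numeric(1))
  mean(ref) - obs
}

#' Select the number of clusters by a multi-index majority vote
#'
#' @param x samples-by-features numeric matrix.
#' @param k_min,k_max candidate range (defaults 2 and 15).
#' @param indices subset of `c("silhouette", "ch", "db", "gap")`.
#' @param nstart k-means restarts per candidate (default 25).
#' @param gap_B reference draws for the gap statistic.
#' @param seed RNG seed (restarts and gap references).
#' @return list with `k_best`, `votes` (named integer vector, one vote per
#'   index), and `report` (data frame of index values per k).
#' @export
select_k <- function(x, k_min = 2L, k_max = 15L,
                     indices = c("silhouette", "ch", "db", "gap"),
                     nstart = 25L, gap_B = 20L, seed = 1L) {
  x <- as.matrix(x)
  indices <- match.arg(indices, several.ok = TRUE)
  assert_that(k_min >= 2 && k_max >= k_min, "need 2 <= k_min <= k_max")
  assert_that(nrow(x) >= k_max + 1, "need more samples than k_max")
  if (all(apply(x, 2, function(c) length(unique(c)) == 1L))) {
    stop2("degenerate data: all rows identical")
  }
  ks <- k_min:k_max
  dmat <- dist(x)
  vals <- matrix(NA_real_, nrow = length(ks), ncol = length(indices),
                 dimnames = list(NULL, indices))
  with_seed(seed, {
    for (i in seq_along(ks)) {
      k <- ks[i]
      km <- run_kmeans(x, k, nstart)
      if ("silhouette" %in% indices) {
        vals[i, "silhouette"] <-
          mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
      }
      if ("ch" %in% indices) vals[i, "ch"] <- ch_index(x, km$cluster, km$centers)
      if ("db" %in% indices) vals[i, "db"] <- db_index(x, km$cluster, km$centers)
      if ("gap" %in% indices) vals[i, "gap"] <- gap_stat(x, k, nstart, gap_B)
    }
  })
  pick <- function(idx) {
    v <- vals[, idx]
    if (idx == "db") ks[which.min(v)] else ks[which.max(v)]
  }
  votes <- vapply(indices, pick, integer(1))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_best <- min(winners)  # ties toward smaller k
  list(k_best = k_best, votes = votes,
       report = data.frame(k = ks, vals, check.names = FALSE))
}

#' K-means clustering with ordered labels
#'
#' Runs Lloyd k-means with `nstart` restarts and renumbers clusters so that
#' cluster 1 has the lowest mean feature value and cluster k the highest.
#'
#' @param x samples-by-features matrix (rownames = sample IDs).
#' @param k number of clusters (>= 2).
#' @param nstart restarts (default 25).
#' @param seed RNG seed.
#' @return list of class `m6a_cluster_assignment`: `sample_ids`, `labels`
#'   (integer 1..k, named), `k`, `centers`, `tot_withinss`, `seed`.
#' @export
kmeans_cluster <- function(x, k, nstart = 25L, seed = 1L) {
  x <- as.matrix(x)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(nrow(x) > k, "need more samples than clusters")
  km <- with_seed(seed, run_kmeans(x, k, nstart))
  ord <- order(rowMeans(km$centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  structure(list(sample_ids = ids, labels = setNames(labels, ids), k = k,
                 centers = km$centers[ord, , drop = FALSE],
                 tot_withinss = km$tot.withinss, seed = seed),
            class = "m6a_cluster_assignment")
}

#' @export
print.m6a_cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means assignment: %d samples in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Assign m6A modification-pattern clusters from regulator expression
#'
#' Restricts the expression matrix to the 20-gene clustering panel (IGF2BPs
#' removed), drops constant-expression genes, standardizes each gene to mean
#' 0 / SD 1, selects the number of clusters over `k_min..k_max` by the
#' multi-index vote, and runs ordered k-means. Cluster C1 is the
#' low-regulator-expression pattern, Ck the highest.
#'
#' @param expr gene-by-sample log2 expression matrix.
#' @param panel regulator panel (default: [clustering_panel()]).
#' @param k fixed cluster count; if `NULL` (default) it is selected.
#' @param k_min,k_max,indices,nstart,gap_B,seed see [select_k()].
#' @return an `m6a_cluster_assignment` with extra elements `selection`
#'   (the [select_k()] output, or NULL if `k` was fixed) and `cluster_means`
#'   (per-cluster mean expression of each panel gene, on the original scale).
#' @export
m6a_clusters <- function(expr, panel = clustering_panel(), k = NULL,
                         k_min = 2L, k_max = 15L,
                         indices = c("silhouette", "ch", "db", "gap"),
                         nstart = 25L, gap_B = 20L, seed = 1L) {
  res <- restrict_panel(panel, expr)
  assert_that(nrow(res$panel) >= 5, "need at least 5 panel genes in the matrix")
  sub <- expr[res$panel$gene, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warn2("dropped %d constant-expression panel gene(s)", sum(sds == 0))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  zs <- t((sub - rowMeans(sub)) / sds)  # samples x genes
  selection <- NULL
  if (is.null(k)) {
    selection <- select_k(zs, k_min = k_min, k_max = k_max, indices = indices,
                          nstart = nstart, gap_B = gap_B, seed = seed)
    k <- selection$k_best
  }
  assign <- kmeans_cluster(zs, k = k, nstart = nstart, seed = seed)
  cm <- vapply(seq_len(k), function(cl) {
    rowMeans(sub[, assign$labels == cl, drop = FALSE])
  }, numeric(nrow(sub)))
  colnames(cm) <- paste0("C", seq_len(k))
  assign$selection <- selection
  assign$cluster_means <- cm
  assign
}

#' Two-component PCA view of a clustering
#'
#' Mean-centered PCA; returns the sample coordinates on the first two
#' components and the ratio of between-cluster to total variance in that
#' plane (a separation summary in \[0, 1\]).
#'
#' @param x samples-by-features matrix.
#' @param labels integer cluster labels, one per row of `x`.
#' @return list with `coordinates` (n x 2) and `separation`.
#' @export
pca_view <- function(x, labels) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 2, "need at least 2 features")
  assert_that(length(labels) == nrow(x), "one label per sample required")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  total <- sum(apply(coords, 2, var)) * (nrow(coords) - 1)
  if (total == 0) return(list(coordinates = coords, separation = 0))
  grand <- colMeans(coords)
  between <- sum(vapply(unique(labels), function(cl) {
    m <- coords[labels == cl, , drop = FALSE]
    nrow(m) * sum((colMeans(m) - grand)^2)
  }, numeric(1)))
  list(coordinates = coords, separation = between / total)
}
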