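## Single-sample gene-set enrichment (GSVA-style).
##
## Three steps: (1) a per-gene density transform mapping each sample's
## expression to its estimated cumulative density across samples (Gaussian
## kernel CDF with bandwidth sd/4, or the empirical CDF); (2) per-sample
## descending ranking of the transformed values, converted to the symmetric
## rank statistic r = |G|/2 - rank + 1/2; (3) a weighted Kolmogorov-Smirnov
## random walk over the ranked gene list, stepping up by |r|^tau (normalized
## over the set) at set members and down by 1/(|G|-|set|) elsewhere. The
## default score is the signed sum of the maximum positive and minimum
## negative walk deviations ("diff_of_maxima"), bounded in [-1, 1].

#' Cumulative-density transform of an expression matrix
#'
#' Per gene, replaces each sample's value by its estimated cumulative density
#' across samples: a Gaussian kernel CDF with bandwidth `sd(gene)/4` (floored
#' at machine epsilon), or the empirical CDF. The transform is strictly
#' monotone within each gene, so per-sample rankings are preserved.
#'
#' @param expr gene-by-sample numeric matrix (>= 3 samples).
#' @param kernel `"gaussian"` or `"ecdf"`.
#' @return matrix of the same shape with values in (0, 1].
#' @export
density_transform <- function(expr, kernel = c("gaussian", "ecdf")) {
  kernel <- match.arg(kernel)
  assert_that(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  if (ncol(expr) < 3) stop2("density transform needs at least 3 samples")
  n <- ncol(expr)
  out <- expr
  if (kernel == "ecdf") {
    for (i in seq_len(nrow(expr))) {
      ## ECDF at x_i = #(x_j <= x_i)/n = max-tie rank / n
      out[i, ] <- rank(expr[i, ], ties.method = "max") / n
    }
  } else {
    for (i in seq_len(nrow(expr))) {
      x <- expr[i, ]
      h <- max(sd(x) / 4, .Machine$double.eps)
      ## column j of outer(x, x, "-")/-h holds (x_j - x_i)/h over i, so the
      ## column mean is the kernel CDF estimate at x_j
      out[i, ] <- colMeans(pnorm(outer(x, x, "-") / -h))
    }
  }
  out
}

#' Per-sample gene ranking of a transformed matrix
#'
#' Ranks genes within each sample in descending order of the transformed
#' value (rank 1 = highest). Ties are broken deterministically by
#' lexicographic gene symbol (the lexicographically smaller symbol gets the
#' better rank); unnamed rows tie-break by row index. The symmetric rank
#' statistic used by the walk is `|G|/2 - rank + 1/2`.
#'
#' @param transformed matrix from [density_transform()].
#' @return integer matrix of ranks, same dimnames.
#' @export
sample_ranks <- function(transformed) {
  assert_that(all(is.finite(transformed)), "transformed matrix must be finite")
  g <- nrow(transformed)
  tie_key <- if (!is.null(rownames(transformed))) {
    order(order(rownames(transformed)))  # lexicographic position of each gene
  } else {
    seq_len(g)
  }
  out <- matrix(0L, nrow = g, ncol = ncol(transformed),
                dimnames = dimnames(transformed))
  for (j in seq_len(ncol(transformed))) {
    ord <- order(-transformed[, j], tie_key)
    out[ord, j] <- seq_len(g)
  }
  out
}

rank_stat <- function(ranks) nrow(as.matrix(ranks)) / 2 - ranks + 0.5

#' Random-walk enrichment statistic for one sample
#'
#' Walks down the sample's ranked gene list: at set members the walk rises by
#' `|r|^tau` normalized by the total over the set; at non-members it falls by
#' `1/(|G| - |set|)`. `mode = "diff_of_maxima"` returns the maximum positive
#' deviation plus the minimum negative deviation (a signed sum in [-1, 1]);
#' `"max_deviation"` returns the single deviation of largest magnitude with
#' its sign.
#'
#' @param ranks named integer vector of a sample's gene ranks (1 = highest).
#' @param gene_set character vector of member symbols.
#' @param tau positive weight exponent on the rank statistic (default 1).
#' @param mode scoring mode.
#' @return scalar score.
#' @export
walk_statistic <- function(ranks, gene_set,
                           tau = 1, mode = c("diff_of_maxima", "max_deviation")) {
  mode <- match.arg(mode)
  assert_that(!is.null(names(ranks)), "ranks must be a named vector")
  in_set <- names(ranks) %in% gene_set
  if (!any(in_set)) stop2("gene set shares no genes with the ranked list")
  if (all(in_set)) stop2("gene set covers every gene; walk undefined")
  g <- length(ranks)
  r <- abs(g / 2 - ranks + 0.5)^tau
  if (sum(r[in_set]) == 0) {
    ## only possible when the whole set sits exactly at the middle rank of an
    ## odd-length list; the normalized in-set step is then 0/0
    stop2("gene set has zero total rank weight; walk undefined")
  }
  ord <- order(ranks)
  in_o <- in_set[ord]
  ## normalize each cumulative sum by its own total so the walk is exactly 0
  ## at the end and the prefix extrema stay within [-1, 1] in floating point
  cum_in <- cumsum(ifelse(in_o, r[ord], 0))
  cum_out <- cumsum(!in_o)
  walk <- cum_in / cum_in[g] - cum_out / cum_out[g]
  v_max <- max(c(0, walk))
  v_min <- min(c(0, walk))
  if (mode == "diff_of_maxima") v_max + v_min
  else if (v_max >= -v_min) v_max else v_min
}

#' Single-sample enrichment scores for a gene-set collection
#'
#' Applies [density_transform()], [sample_ranks()] and [walk_statistic()] for
#' every (set, sample) pair. Sets are first intersected with the matrix genes
#' and filtered to sizes within `[min_size, max_size]`; skipped sets are
#' reported in the `skipped` attribute and a warning. Deterministic given the
#' inputs and parameters.
#'
#' @param expr gene-by-sample log2 expression matrix.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param kernel,tau,mode see [density_transform()] and [walk_statistic()].
#' @param min_size,max_size set-size bounds after intersection (defaults 5
#'   and 500, the conventional GSVA bounds).
#' @return sets-by-samples numeric matrix with attributes `skipped` (data
#'   frame of set, reason) and `params`.
#' @export
gsva_scores <- function(expr, sets, kernel = c("gaussian", "ecdf"), tau = 1,
                        mode = c("diff_of_maxima", "max_deviation"),
                        min_size = 5L, max_size = 500L) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  assert_that(length(sets) > 0 && !is.null(names(sets)), "sets must be a named list")
  assert_that(tau > 0, "tau must be positive")
  z <- density_transform(expr, kernel)
  rk <- sample_ranks(z)
  genes <- rownames(expr)
  kept <- list()
  skipped <- data.frame(set = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) < min_size || length(members) > max_size) {
      skipped <- rbind(skipped, data.frame(
        set = nm,
        reason = sprintf("size %d outside [%d, %d]", length(members),
                         min_size, max_size),
        stringsAsFactors = FALSE))
      next
    }
    kept[[nm]] <- members
  }
  if (nrow(skipped) > 0) {
    warn2("%d gene set(s) skipped by size filtering", nrow(skipped))
  }
  if (!length(kept)) stop2("all gene sets were skipped by size filtering")
  scores <- matrix(NA_real_, nrow = length(kept), ncol = ncol(expr),
                   dimnames = list(names(kept), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    rj <- setNames(rk[, j], genes)
    for (nm in names(kept)) {
      scores[nm, j] <- walk_statistic(rj, kept[[nm]], tau = tau, mode = mode)
    }
  }
  attr(scores, "skipped") <- skipped
  attr(scores, "params") <- list(kernel = kernel, tau = tau, mode = mode,
                                 min_size = min_size, max_size = max_size)
  scores
}

#' Write an enrichment score matrix as TSV
#'
#' @param scores sets-by-samples matrix from [gsva_scores()].
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  d <- data.frame(set = rownames(scores), scores, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
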