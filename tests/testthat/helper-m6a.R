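## Shared helpers: a cross-file cache for the expensive reference cohort and
## pipeline fit, an adjusted-Rand-index oracle, and an independent
## step-by-step random-walk oracle used to verify the enrichment statistic.

.m6a_cache <- new.env(parent = emptyenv())

cache_get <- function(name, expr) {
  if (!exists(name, envir = .m6a_cache)) {
    assign(name, force(expr), envir = .m6a_cache)
  }
  get(name, envir = .m6a_cache)
}

## The reference synthetic cohort (default configuration, seed 1).
default_cohort <- function() {
  cache_get("cohort", simulate_cohort(sim_config(seed = 1)))
}

## One full pipeline fit on the reference cohort, shared across test files.
default_fit <- function() {
  co <- default_cohort()
  cache_get("fit", suppressMessages(suppressWarnings(
    m6a_pipeline(co$expression, co$clinical, co$gene_sets,
                 categories = co$categories))))
}

## A small, fast cohort for I/O and pipeline plumbing tests.
small_cohort <- function() {
  cache_get("small_cohort",
            simulate_cohort(sim_config(n_samples = 60, n_genes = 1300,
                                       seed = 7)))
}

## Adjusted Rand index between two labelings (pair-counting form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## Brute-force random-walk oracle: explicit gene-by-gene loop, independent of
## the vectorized implementation under test. diff_of_maxima mode.
oracle_walk <- function(ranks, gene_set, tau = 1) {
  g <- length(ranks)
  in_set <- names(ranks) %in% gene_set
  stopifnot(any(in_set), !all(in_set))
  wt <- function(nm) abs(g / 2 - ranks[[nm]] + 0.5)^tau
  denom <- 0
  for (nm in names(ranks)[in_set]) denom <- denom + wt(nm)
  running <- 0
  v_max <- 0
  v_min <- 0
  for (nm in names(ranks)[order(unlist(ranks))]) {
    if (nm %in% gene_set) {
      running <- running + wt(nm) / denom
    } else {
      running <- running - 1 / (g - sum(in_set))
    }
    if (running > v_max) v_max <- running
    if (running < v_min) v_min <- running
  }
  v_max + v_min
}

## Build a minimal m6a_cluster_assignment by hand (for label/distance tests).
manual_assignment <- function(labels, k = max(labels)) {
  structure(list(sample_ids = names(labels), labels = labels, k = k,
                 centers = NULL, tot_withinss = NA_real_, seed = NA_integer_),
            class = "m6a_cluster_assignment")
}
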