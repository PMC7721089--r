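## Association reports: chi-square cross-tabulations between stratifications,
## m6Ascore-pathway correlations, treatment-response contrasts, and the
## long-format flow table behind alluvial diagrams.

#' Chi-square cross-tabulation of two label vectors
#'
#' Pearson chi-square without continuity correction by default (Yates
#' correction available for 2x2 tables). A flag marks tables with any
#' expected cell below 5.
#'
#' @param labels_a,labels_b aligned label vectors (>= 2 levels each after
#'   dropping missing values).
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list of class `m6a_crosstab`: `observed`, `expected`, `chi2`,
#'   `df`, `p`, `low_expected` flag.
#' @export
crosstab <- function(labels_a, labels_b, correct = FALSE) {
  assert_that(length(labels_a) == length(labels_b), "label vectors must align")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  tab <- table(as.character(labels_a)[keep], as.character(labels_b)[keep])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2) {
    stop2("cross-tabulation needs at least 2 non-empty levels on each margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(observed = tab, expected = ct$expected,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, low_expected = any(ct$expected < 5)),
            class = "m6a_crosstab")
}

#' @export
print.m6a_crosstab <- function(x, ...) {
  print(x$observed)
  cat(sprintf("chi2 = %.3f, df = %d, p = %.3g%s\n", x$chi2, x$df, x$p,
              if (x$low_expected) " (expected cell < 5)" else ""))
  invisible(x)
}

#' Pearson correlation of the m6Ascore with every pathway score
#'
#' @param scores data frame from [compute_m6ascore()] (needs `sample_id`,
#'   `m6ascore`).
#' @param enrichment sets-by-samples enrichment matrix.
#' @return data frame (`set`, `r`, `p`) sorted by increasing r; sets with
#'   zero variance are skipped with a warning.
#' @export
score_pathway_correlation <- function(scores, enrichment) {
  shared <- intersect(scores$sample_id, colnames(enrichment))
  assert_that(length(shared) >= 3, "need at least 3 aligned samples")
  s <- scores$m6ascore[match(shared, scores$sample_id)]
  rows <- list()
  skipped <- 0L
  for (nm in rownames(enrichment)) {
    y <- enrichment[nm, shared]
    if (sd(y) == 0) { skipped <- skipped + 1L; next }
    ct <- cor.test(s, y, method = "pearson")
    rows[[nm]] <- data.frame(set = nm, r = unname(ct$estimate), p = ct$p.value)
  }
  if (skipped > 0) warn2("%d zero-variance set(s) skipped", skipped)
  assert_that(length(rows) > 0, "no set had usable variance")
  out <- do.call(rbind, rows)
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treatment-response contrast between score groups
#'
#' Response rates (PR/SD) per m6Ascore group plus a 2x2 chi-square. Samples
#' without response data are excluded with a reported count; if all recorded
#' responses are identical the rates are reported and the test skipped with a
#' warning.
#'
#' @param score_group factor/character of score groups (low/high).
#' @param response character vector with values `PD` or `PR/SD` (NA allowed).
#' @return list: `rates` (data frame group, n, n_response, rate), `test`
#'   (an `m6a_crosstab` or NULL).
#' @export
response_contrast <- function(score_group, response) {
  assert_that(length(score_group) == length(response), "inputs must align")
  keep <- !is.na(response) & !is.na(score_group)
  if (sum(!keep) > 0) log_info("excluded %d sample(s) without response data",
                               sum(!keep))
  grp <- as.character(score_group)[keep]
  rsp <- as.character(response)[keep]
  assert_that(length(grp) > 0 && length(unique(grp)) >= 1,
              "no sample with response data")
  rates <- do.call(rbind, lapply(unique(grp), function(g) {
    n <- sum(grp == g)
    nr <- sum(grp == g & rsp == "PR/SD")
    data.frame(group = g, n = n, n_response = nr, rate = nr / n)
  }))
  rownames(rates) <- NULL
  test <- NULL
  if (length(unique(rsp)) < 2 || length(unique(grp)) < 2) {
    warn2("response contrast degenerate; chi-square test skipped")
  } else {
    test <- crosstab(grp, rsp)
  }
  list(rates = rates, test = test)
}

#' Long-format flow table across stratifications
#'
#' Counts every distinct path through the supplied label columns (the table
#' behind an alluvial diagram). Counts sum to the number of samples.
#'
#' @param assignments data frame of aligned label columns (>= 2 columns).
#' @return data frame of the label columns plus `n`.
#' @export
alluvial_table <- function(assignments) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  assert_that(ncol(assignments) >= 2, "need at least 2 label columns")
  ## missing labels become an explicit level so counts still sum to n
  assignments[] <- lapply(assignments, function(col) {
    col <- as.character(col); col[is.na(col)] <- "missing"; col
  })
  out <- aggregate(list(n = rep(1L, nrow(assignments))), by = assignments,
                   FUN = sum)
  out[do.call(order, out[, seq_len(ncol(assignments)), drop = FALSE]), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
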