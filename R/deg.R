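## Moderated differential expression between modification patterns.
##
## A two-group empirical-Bayes moderated t-test: per-gene pooled residual
## variances s_g^2 (d_g df) are shrunk toward a prior variance s0^2 with d0
## prior df, both estimated from the marginal distribution of log s_g^2 by
## moment matching (the scaled-F / log-variance matching used by the standard
## moderated-statistics framework). The moderated t uses the posterior
## variance (d0*s0^2 + d_g*s_g^2)/(d0 + d_g) and d0 + d_g degrees of freedom.

## Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

## Moment-match log s^2 to estimate the prior df d0 and prior variance s0^2.
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_2 = mean(s2[ok]) %||% 1))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    ## no excess spread beyond chi-square sampling noise: infinite prior df;
    ## the pooled mean variance is then the MLE of the shared scale
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated two-group test
#'
#' @param expr_a,expr_b gene-by-sample matrices for the two groups (same gene
#'   rows, each with >= 2 samples). Values are assumed log2 scale, so the
#'   effect is a log2 fold change `mean(A) - mean(B)`.
#' @param prior_df optional fixed prior degrees of freedom `d0`; `NULL`
#'   (default) estimates it from the data, `0` reproduces the ordinary
#'   two-sample pooled t-test, `Inf` fully shares one variance across genes.
#' @return data frame per gene: `gene`, `log2_fc`, `t_mod`, `p`, `s2`,
#'   `s2_post`, `df_total`; attributes `d0` and `s0_2`.
#' @export
moderated_test <- function(expr_a, expr_b, prior_df = NULL) {
  assert_that(is.matrix(expr_a) && is.matrix(expr_b), "inputs must be matrices")
  assert_that(nrow(expr_a) == nrow(expr_b) &&
                identical(rownames(expr_a), rownames(expr_b)),
              "gene rows must be aligned")
  na <- ncol(expr_a); nb <- ncol(expr_b)
  if (na < 2 || nb < 2) stop2("each group needs at least 2 samples")
  fc <- rowMeans(expr_a) - rowMeans(expr_b)
  rss <- rowSums((expr_a - rowMeans(expr_a))^2) +
    rowSums((expr_b - rowMeans(expr_b))^2)
  dg <- na + nb - 2
  s2 <- rss / dg
  if (is.null(prior_df)) {
    pr <- estimate_prior(s2, dg)
  } else {
    assert_that(prior_df >= 0, "prior_df must be >= 0")
    pr <- list(d0 = prior_df,
               s0_2 = if (prior_df > 0) mean(s2[s2 > 0]) else 0)
  }
  d0 <- pr$d0; s0_2 <- pr$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, fc / se, 0)
  ## cap the total df at the pooled residual df over all genes: the prior
  ## cannot carry more information than the data it was estimated from
  df_total <- min(d0 + dg, length(s2) * dg)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[se == 0] <- 1
  out <- data.frame(gene = rownames(expr_a) %||% as.character(seq_along(fc)),
                    log2_fc = fc, t_mod = t_mod, p = p, s2 = s2,
                    s2_post = s2_post, df_total = df_total,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values (monotone in p, capped at 1).
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p > 0 & p <= 1),
              "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Differentially expressed genes between clusters
#'
#' Runs the moderated test for every unordered cluster pair (or each cluster
#' against the rest), adjusts p-values by BH within each contrast, and flags
#' genes passing `p_adj < alpha` and `|log2FC| > fc_min` (strict
#' inequalities). The union gene list collects genes passing in at least one
#' contrast.
#'
#' @param expr gene-by-sample matrix.
#' @param labels integer cluster labels named by sample ID (or aligned with
#'   columns of `expr`).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param fc_min absolute log2 fold-change threshold (default 1).
#' @param mode `"pairwise"` (default) or `"one_vs_rest"`.
#' @return list with `table` (per gene x contrast: log2_fc, t_mod, p, p_adj,
#'   passes) and `genes` (sorted union of passing genes).
#' @export
cluster_degs <- function(expr, labels, alpha = 0.05, fc_min = 1,
                         mode = c("pairwise", "one_vs_rest")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  if (!is.null(names(labels))) {
    assert_that(all(colnames(expr) %in% names(labels)),
                "labels must cover all expression samples")
    labels <- labels[colnames(expr)]
  } else {
    assert_that(length(labels) == ncol(expr), "one label per sample required")
  }
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop2("need at least 2 clusters for DEG analysis")
  contrasts <- if (mode == "pairwise") {
    pairs <- utils::combn(cls, 2, simplify = FALSE)
    lapply(pairs, function(pr) list(
      name = sprintf("C%s_vs_C%s", pr[1], pr[2]),
      a = labels == pr[1], b = labels == pr[2]))
  } else {
    lapply(cls, function(cl) list(
      name = sprintf("C%s_vs_rest", cl),
      a = labels == cl, b = labels != cl))
  }
  out <- list()
  for (ct in contrasts) {
    if (sum(ct$a) < 2 || sum(ct$b) < 2) {
      warn2("contrast %s skipped: a group has fewer than 2 samples", ct$name)
      next
    }
    tt <- moderated_test(expr[, ct$a, drop = FALSE], expr[, ct$b, drop = FALSE])
    tt$p_adj <- bh_adjust(tt$p)
    tt$contrast <- ct$name
    tt$passes <- tt$p_adj < alpha & abs(tt$log2_fc) > fc_min
    out[[ct$name]] <- tt[, c("gene", "contrast", "log2_fc", "t_mod", "p",
                             "p_adj", "passes")]
  }
  if (!length(out)) stop2("no contrast had enough samples")
  table <- do.call(rbind, out)
  rownames(table) <- NULL
  genes <- sort(unique(table$gene[table$passes]))
  list(table = table, genes = genes)
}
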