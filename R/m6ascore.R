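## The m6A gene signature and per-sample m6Ascore.
##
## DEGs between modification patterns are screened one gene at a time with a
## univariate Cox proportional-hazards model on the unscaled log2 expression;
## genes with Wald p < alpha form the signature, split at HR = 1 into risk
## (HR > 1) and protective (HR < 1) genes. Signature expression is then
## min-max scaled per gene to [-1, 1] and the score is
## m6Ascore = sum(risk) - sum(protective). Scaling bounds are frozen in the
## signature so new cohorts can be scored consistently.

#' Univariate Cox screen of candidate genes
#'
#' Fits, per gene, a proportional-hazards model with that gene's (unscaled,
#' log2) expression as the only covariate (Breslow tie handling). Genes whose
#' fit fails or whose expression is constant are flagged and excluded with a
#' report.
#'
#' @param expr gene-by-sample matrix restricted to the candidate genes.
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`
#'   covering the expression samples.
#' @return data frame per converged gene: `gene`, `hr`, `log_hr`, `se`, `p`,
#'   `n_used`; attribute `flagged` lists excluded genes with reasons.
#' @export
cox_screen <- function(expr, clinical) {
  validate_expression(expr)
  al <- align_cohort(expr, clinical)
  expr <- al$expression; clinical <- al$clinical
  n_events <- sum(clinical$os_event)
  if (n_events < 10) {
    warn2("only %d events; univariate Cox estimates will be unstable", n_events)
  }
  surv <- Surv(clinical$os_time, clinical$os_event)
  rows <- vector("list", nrow(expr))
  flagged <- data.frame(gene = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    g <- rownames(expr)[i]
    x <- expr[i, ]
    if (sd(x) == 0) {
      flagged <- rbind(flagged, data.frame(gene = g, reason = "zero variance"))
      next
    }
    fit <- tryCatch(
      suppressWarnings(coxph(surv ~ x, ties = "breslow",
                             control = survival::coxph.control(eps = 1e-8,
                                                               iter.max = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)) ||
        !is.finite(sqrt(fit$var[1, 1]))) {
      flagged <- rbind(flagged, data.frame(gene = g, reason = "non-convergence"))
      next
    }
    beta <- unname(coef(fit)[1])
    se <- sqrt(fit$var[1, 1])
    rows[[i]] <- data.frame(gene = g, hr = exp(beta), log_hr = beta, se = se,
                            p = 2 * pnorm(-abs(beta / se)),
                            n_used = fit$n, stringsAsFactors = FALSE)
  }
  if (nrow(flagged) > 0) {
    log_info("cox_screen: %d gene(s) flagged and excluded", nrow(flagged))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop2("no gene survived the Cox screen")
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Partition a Cox screen into risk and protective signature genes
#'
#' Keeps genes with `p < alpha` and splits them at HR = 1: HR > 1 are risk
#' genes, HR < 1 protective. Genes with HR numerically equal to 1 are
#' excluded with a warning.
#'
#' @param screen output of [cox_screen()].
#' @param alpha significance threshold (default 0.05).
#' @return list of class `m6a_signature`: `risk` and `protective` data frames
#'   (gene, hr, p), `alpha`, and (after [freeze_signature()]) the per-gene
#'   scaling bounds.
#' @export
signature_partition <- function(screen, alpha = 0.05) {
  assert_that(nrow(screen) > 0, "empty Cox screen")
  sig <- screen[screen$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    stop2("no gene passed p < %g; use a larger cohort or looser alpha", alpha)
  }
  unit <- abs(sig$log_hr) < 1e-12
  if (any(unit)) {
    warn2("%d gene(s) with HR exactly 1 excluded from the signature", sum(unit))
    sig <- sig[!unit, , drop = FALSE]
  }
  cols <- c("gene", "hr", "log_hr", "p")
  structure(list(risk = sig[sig$hr > 1, cols, drop = FALSE],
                 protective = sig[sig$hr < 1, cols, drop = FALSE],
                 alpha = alpha, bounds = NULL),
            class = "m6a_signature")
}

#' @export
print.m6a_signature <- function(x, ...) {
  cat(sprintf("m6A gene signature: %d risk (HR > 1), %d protective (HR < 1) genes at p < %g%s\n",
              nrow(x$risk), nrow(x$protective), x$alpha,
              if (is.null(x$bounds)) "" else "; scaling bounds frozen"))
  invisible(x)
}

#' Min-max scale expression per gene to [-1, 1]
#'
#' `x' = 2 * (x - min) / (max - min) - 1` per gene. Constant genes map to 0
#' with a warning. When `bounds` (a data frame with `gene`, `min`, `max`) is
#' supplied — e.g. the frozen bounds of a fitted signature — those bounds are
#' used instead of the observed range, so new samples are scored on the
#' reference scale (values outside the bounds extrapolate beyond [-1, 1]).
#'
#' @param expr gene-by-sample matrix.
#' @param bounds optional frozen bounds.
#' @return scaled matrix with a `bounds` attribute recording the bounds used.
#' @export
minmax_scale <- function(expr, bounds = NULL) {
  assert_that(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  if (is.null(bounds)) {
    lo <- apply(expr, 1, min)
    hi <- apply(expr, 1, max)
  } else {
    idx <- match(rownames(expr), bounds$gene)
    assert_that(!anyNA(idx), "bounds must cover every gene in expr")
    lo <- bounds$min[idx]
    hi <- bounds$max[idx]
  }
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) warn2("%d constant gene(s) scaled to 0", sum(const))
  rng[const] <- 1
  out <- 2 * (expr - lo) / rng - 1
  out[const, ] <- 0
  attr(out, "bounds") <- data.frame(gene = rownames(expr), min = lo, max = hi,
                                    stringsAsFactors = FALSE)
  out
}

#' Freeze per-gene scaling bounds into a signature
#'
#' Records the observed min/max of every signature gene in `expr`, so that
#' [compute_m6ascore()] on later cohorts scores against this reference scale.
#'
#' @param signature an `m6a_signature`.
#' @param expr gene-by-sample matrix (the training cohort).
#' @return the signature with `bounds` filled in.
#' @export
freeze_signature <- function(signature, expr) {
  genes <- intersect(c(signature$risk$gene, signature$protective$gene),
                     rownames(expr))
  if (!length(genes)) stop2("no signature gene present in expr")
  sub <- expr[genes, , drop = FALSE]
  signature$bounds <- data.frame(gene = genes,
                                 min = apply(sub, 1, min),
                                 max = apply(sub, 1, max),
                                 stringsAsFactors = FALSE, row.names = NULL)
  signature
}

#' Compute per-sample m6Ascores
#'
#' Min-max scales signature-gene expression (using frozen bounds when the
#' signature carries them, otherwise the observed range) and returns, per
#' sample, `m6Ascore = sum(scaled risk genes) - sum(scaled protective
#' genes)`. Signature genes absent from the matrix are dropped with a
#' reported count.
#'
#' @param expr gene-by-sample matrix.
#' @param signature an `m6a_signature`.
#' @return data frame `sample_id`, `m6ascore`; the scaled risk/protective
#'   matrices are attached as attributes `scaled_risk`, `scaled_protective`
#'   for audit.
#' @export
compute_m6ascore <- function(expr, signature) {
  validate_expression(expr)
  risk <- intersect(signature$risk$gene, rownames(expr))
  prot <- intersect(signature$protective$gene, rownames(expr))
  n_missing <- nrow(signature$risk) + nrow(signature$protective) -
    length(risk) - length(prot)
  if (n_missing > 0) log_info("%d signature gene(s) absent from matrix, dropped",
                              n_missing)
  if (!length(risk) && !length(prot)) {
    stop2("no signature gene present in the expression matrix")
  }
  genes <- c(risk, prot)
  scaled <- minmax_scale(expr[genes, , drop = FALSE],
                         bounds = signature$bounds)
  sum_rows <- function(g) if (length(g)) colSums(scaled[g, , drop = FALSE]) else 0
  score <- sum_rows(risk) - sum_rows(prot)
  out <- data.frame(sample_id = colnames(expr), m6ascore = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "scaled_risk") <- scaled[risk, , drop = FALSE]
  attr(out, "scaled_protective") <- scaled[prot, , drop = FALSE]
  out
}

#' Split samples into m6Ascore-low and -high groups
#'
#' High means score strictly above the cutoff (the per-cohort median by
#' default); scores equal to the cutoff go to the low group, which keeps the
#' split deterministic.
#'
#' @param scores data frame from [compute_m6ascore()].
#' @param cutoff `"median"` or a numeric value.
#' @return `scores` with an added `score_group` factor (levels low, high).
#' @export
score_groups <- function(scores, cutoff = "median") {
  assert_that(nrow(scores) >= 2, "need at least 2 samples to split")
  cut_val <- if (identical(cutoff, "median")) median(scores$m6ascore)
             else as.numeric(cutoff)
  grp <- ifelse(scores$m6ascore > cut_val, "high", "low")
  if (all(grp == "low")) warn2("all scores at or below the cutoff; every sample is 'low'")
  scores$score_group <- factor(grp, levels = c("low", "high"))
  attr(scores, "cutoff") <- cut_val
  scores
}

#' Write / read a fitted signature as TSV
#'
#' One row per signature gene: `gene`, `side` (risk/protective), `hr`, `p`,
#' `scale_min`, `scale_max`. This file fully determines the scoring of new
#' cohorts.
#'
#' @param signature a frozen `m6a_signature`.
#' @param path file path.
#' @export
write_signature <- function(signature, path) {
  assert_that(!is.null(signature$bounds),
              "freeze the signature before writing (freeze_signature)")
  tab <- rbind(
    data.frame(gene = signature$risk$gene, side = "risk",
               hr = signature$risk$hr, p = signature$risk$p),
    data.frame(gene = signature$protective$gene, side = "protective",
               hr = signature$protective$hr, p = signature$protective$p))
  idx <- match(tab$gene, signature$bounds$gene)
  tab$scale_min <- signature$bounds$min[idx]
  tab$scale_max <- signature$bounds$max[idx]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "side", "hr", "p", "scale_min", "scale_max")
  assert_that(all(req %in% names(d)), "signature file missing columns")
  d$log_hr <- log(d$hr)
  cols <- c("gene", "hr", "log_hr", "p")
  structure(list(risk = d[d$side == "risk", cols, drop = FALSE],
                 protective = d[d$side == "protective", cols, drop = FALSE],
                 alpha = NA_real_,
                 bounds = data.frame(gene = d$gene, min = d$scale_min,
                                     max = d$scale_max,
                                     stringsAsFactors = FALSE)),
            class = "m6a_signature")
}
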