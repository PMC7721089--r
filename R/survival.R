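## Survival analytics: Kaplan-Meier curves, log-rank tests, multivariate Cox,
## a nomogram point system, and time-dependent (IPCW cumulative/dynamic) AUC.

#' Kaplan-Meier estimates per group
#'
#' Product-limit estimator with right censoring; Greenwood standard errors
#' are retained for confidence bands. Empty groups are skipped with a
#' warning.
#'
#' @param time non-negative survival/censoring times.
#' @param event 0/1 event indicators.
#' @param groups optional group labels (default: one pooled group).
#' @return named list of data frames (`time`, `n_risk`, `n_event`, `surv`,
#'   `std_err`), one per group.
#' @export
km_estimate <- function(time, event, groups = NULL) {
  assert_that(all(time >= 0), "times must be non-negative")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(time))
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- groups == g & !is.na(groups)
    if (!sum(sel)) { warn2("group '%s' empty, skipped", g); next }
    fit <- survfit(Surv(time[sel], event[sel]) ~ 1)
    out[[g]] <- data.frame(time = fit$time, n_risk = fit$n.risk,
                           n_event = fit$n.event, surv = fit$surv,
                           std_err = fit$std.err)
  }
  out
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) k-group log-rank statistic, df = k - 1.
#'
#' @inheritParams km_estimate
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  time <- time[keep]; event <- event[keep]; groups <- groups[keep]
  k <- length(unique(groups))
  if (k < 2) stop2("log-rank test needs at least 2 groups")
  fit <- survdiff(Surv(time, event) ~ groups)
  chi2 <- unname(fit$chisq)
  df <- k - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards model
#'
#' Joint fit over the supplied covariate columns (Breslow ties). Character
#' covariates are treated as factors expanded against their first (reference)
#' level; `stage_tnm`/`stage_t` columns are ordered i < ii < iii < iv
#' (t1 < ... < t4) with the lowest stage as reference. Duplicated covariate
#' columns are rejected as collinear. A warning is raised when there are
#' fewer than 10 events per covariate column.
#'
#' @param data data frame containing the covariates plus `os_time`,
#'   `os_event` (or the columns named by `time_col`/`event_col`).
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col survival column names.
#' @return list of class `m6a_cox`: `fit` (the `coxph` object), `table`
#'   (per expanded factor: `hr`, `lo95`, `hi95`, `p`), `covariates`, `data`.
#' @export
cox_multivariate <- function(data, covariates, time_col = "os_time",
                             event_col = "os_event") {
  assert_that(all(c(covariates, time_col, event_col) %in% names(data)),
              "missing column(s) in data")
  d <- data[, c(time_col, event_col, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  for (cv in covariates) {
    if (is.character(d[[cv]]) || is.logical(d[[cv]])) {
      lev <- if (cv %in% c("stage_tnm", "stage_t")) {
        intersect(c("i", "ii", "iii", "iv", paste0("t", 1:4)),
                  unique(d[[cv]]))
      } else if (cv == "score_group") {
        intersect(c("low", "high"), unique(as.character(d[[cv]])))
      } else sort(unique(as.character(d[[cv]])))
      d[[cv]] <- factor(as.character(d[[cv]]), levels = lev)
    }
    vals <- d[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      stop2("covariate '%s' is constant", cv)
    }
  }
  for (i in seq_along(covariates)) {
    for (j in seq_len(i - 1L)) {
      if (identical(as.character(d[[covariates[i]]]),
                    as.character(d[[covariates[j]]]))) {
        stop2("covariates '%s' and '%s' are identical (collinear)",
              covariates[j], covariates[i])
      }
    }
  }
  n_events <- sum(d[[event_col]])
  if (n_events < 10 * length(covariates)) {
    warn2("%d events for %d covariates (< 10 per covariate); estimates may be unstable",
          n_events, length(covariates))
  }
  fml <- stats::as.formula(paste0("Surv(", time_col, ", ", event_col, ") ~ ",
                                  paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    coxph(fml, data = d, ties = "breslow", model = TRUE, x = TRUE),
    error = function(e) stop2("multivariate Cox failed: %s", conditionMessage(e)))
  if (anyNA(coef(fit))) {
    stop2("multivariate Cox did not converge to finite coefficients (%s)",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  table <- data.frame(term = names(beta), hr = exp(beta),
                      lo95 = exp(beta - 1.96 * se),
                      hi95 = exp(beta + 1.96 * se),
                      p = 2 * pnorm(-abs(beta / se)),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = table, covariates = covariates,
                 data = d, time_col = time_col, event_col = event_col),
            class = "m6a_cox")
}

#' @export
print.m6a_cox <- function(x, ...) {
  cat(sprintf("multivariate Cox model (%d samples, %d events)\n",
              nrow(x$data), sum(x$data[[x$event_col]])))
  print(x$table, digits = 3)
  invisible(x)
}

#' Build a nomogram point system from a multivariate Cox model
#'
#' Each covariate's linear-predictor contribution over the observed data is
#' rescaled so that the covariate with the widest contribution range spans
#' exactly 0-100 points; total points are the sum over covariates. Predicted
#' survival at each horizon is `S0(t)^exp(lp)` with the Breslow baseline, and
#' because total points are an affine function of the linear predictor the
#' point-to-survival lookup is exact. Horizons beyond the observed follow-up
#' are refused with a warning.
#'
#' @param model an `m6a_cox` from [cox_multivariate()].
#' @param horizons prediction horizons in the time unit of the data
#'   (default `c(1, 3, 5)` years).
#' @param grid_size number of rows in the total-points lookup table.
#' @return list of class `m6a_nomogram`: `point_range` per covariate,
#'   `lookup` (total points x horizon survival probabilities), `horizons`,
#'   plus internals used by [predict_nomogram()].
#' @export
build_nomogram <- function(model, horizons = c(1, 3, 5), grid_size = 101L) {
  assert_that(inherits(model, "m6a_cox"), "model must come from cox_multivariate()")
  fit <- model$fit
  terms_mat <- predict(fit, type = "terms")  # centered per-covariate lp parts
  t_min <- apply(terms_mat, 2, min)
  t_rng <- apply(terms_mat, 2, max) - t_min
  max_w <- max(t_rng)
  assert_that(max_w > 0, "all covariate contributions are constant")
  ## points for covariate f at term value v: 100 * (v - min_f) / max_w
  bh <- basehaz(fit, centered = TRUE)
  max_fu <- max(model$data[[model$time_col]])
  keep <- horizons <= max_fu
  if (!all(keep)) {
    warn2("horizon(s) %s beyond observed follow-up (%.2f); refused",
          paste(horizons[!keep], collapse = ", "), max_fu)
  }
  horizons <- horizons[keep]
  h0_at <- function(t) {
    idx <- findInterval(t, bh$time)
    if (idx == 0) 0 else bh$hazard[idx]
  }
  ## lp (centered) of a patient with total points P: P * max_w / 100 + sum(min_f)
  lp_offset <- sum(t_min)
  total_max <- sum(t_rng) / max_w * 100
  grid <- seq(0, total_max, length.out = grid_size)
  lookup <- data.frame(total_points = grid)
  for (h in horizons) {
    s0 <- exp(-h0_at(h))
    lookup[[sprintf("surv_%g", h)]] <- s0^exp(grid * max_w / 100 + lp_offset)
  }
  structure(list(model = model,
                 point_range = data.frame(covariate = colnames(terms_mat),
                                          max_points = 100 * t_rng / max_w,
                                          row.names = NULL),
                 term_min = t_min, max_width = max_w, lp_offset = lp_offset,
                 baseline = bh, horizons = horizons, lookup = lookup),
            class = "m6a_nomogram")
}

#' Evaluate a nomogram on patients
#'
#' @param nomogram an `m6a_nomogram`.
#' @param newdata data frame with the model covariates; default: the
#'   training data.
#' @return data frame with per-covariate points, `total_points`, and
#'   predicted survival at each horizon.
#' @export
predict_nomogram <- function(nomogram, newdata = NULL) {
  model <- nomogram$model
  nd <- newdata %||% model$data
  terms_mat <- predict(model$fit, newdata = nd, type = "terms")
  pts <- sweep(terms_mat, 2, nomogram$term_min) / nomogram$max_width * 100
  total <- rowSums(pts)
  out <- data.frame(pts, total_points = total, check.names = FALSE)
  lp <- total * nomogram$max_width / 100 + nomogram$lp_offset
  for (h in nomogram$horizons) {
    idx <- findInterval(h, nomogram$baseline$time)
    s0 <- exp(-if (idx == 0) 0 else nomogram$baseline$hazard[idx])
    out[[sprintf("surv_%g", h)]] <- s0^exp(lp)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.m6a_nomogram <- function(x, ...) {
  cat("nomogram point system\n")
  print(x$point_range, digits = 3)
  cat(sprintf("horizons: %s\n", paste(x$horizons, collapse = ", ")))
  invisible(x)
}

## Left-continuous KM estimate of the censoring distribution G(t-).
censoring_km <- function(time, event) {
  fit <- survfit(Surv(time, 1 - event) ~ 1)
  function(t) {
    ## survival just before t: use event times strictly below t
    idx <- findInterval(t - .Machine$double.eps^0.5, fit$time)
    ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
  }
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each horizon: cases are subjects
#' with an observed event by the horizon, controls those still at risk after
#' it; case contributions are weighted by `1 / G(T_i-)` where G is the
#' Kaplan-Meier estimate of the censoring distribution (the shared control
#' weight cancels). Higher scores are assumed to mean higher risk. Horizons
#' with no cases or no controls are skipped with a warning.
#'
#' @param score numeric risk score per subject.
#' @param time,event survival data.
#' @param horizons evaluation times.
#' @return data frame `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(score, time, event, horizons) {
  assert_that(length(score) == length(time) && length(time) == length(event),
              "score/time/event lengths differ")
  keep <- !is.na(score) & !is.na(time) & !is.na(event)
  score <- score[keep]; time <- time[keep]; event <- event[keep]
  g_minus <- censoring_km(time, event)
  rows <- list()
  for (h in horizons) {
    is_case <- time <= h & event == 1
    is_ctrl <- time > h
    if (!any(is_case) || !any(is_ctrl)) {
      warn2("horizon %g skipped: no cases or no controls", h)
      next
    }
    w <- 1 / pmax(g_minus(time[is_case]), .Machine$double.eps)
    sc <- score[is_case]; st <- score[is_ctrl]
    conc <- vapply(seq_along(sc), function(i) {
      sum(sc[i] > st) + 0.5 * sum(sc[i] == st)
    }, numeric(1))
    auc <- sum(w * conc) / (sum(w) * length(st))
    rows[[length(rows) + 1L]] <- data.frame(horizon = h, auc = auc,
                                            n_cases = sum(is_case),
                                            n_controls = sum(is_ctrl))
  }
  if (!length(rows)) stop2("no horizon could be evaluated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
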