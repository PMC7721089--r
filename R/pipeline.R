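## End-to-end orchestration. `m6a_pipeline()` is the in-memory interface and
## returns a classed fit object; `run_pipeline()` is the file-level driver
## (read inputs, fit, write every intermediate artifact plus a manifest).

#' Pipeline parameters
#'
#' Defaults follow the reference analysis: cluster count selected over
#' k = 2..15 with k-means and nstart = 25; DEG thresholds adjusted p < 0.05
#' and |log2FC| > 1; univariate Cox screen at p < 0.05; median-split score
#' groups; nomogram horizons 1/3/5 years; GSVA defaults (Gaussian kernel,
#' tau = 1, diff-of-maxima scoring, set sizes 5-500).
#'
#' @param k_min,k_max cluster-count search range.
#' @param nstart k-means restarts.
#' @param indices cluster-validity indices for the majority vote.
#' @param gap_B reference draws for the gap statistic.
#' @param kernel,tau,mode,min_set_size,max_set_size enrichment parameters,
#'   see [gsva_scores()].
#' @param deg_alpha,fc_min,deg_mode DEG thresholds and contrast mode.
#' @param cox_alpha univariate Cox screen threshold.
#' @param cutoff score-group cutoff (`"median"` or numeric).
#' @param horizons nomogram/AUC horizons (same unit as `os_time`).
#' @param seed RNG seed for every stochastic step.
#' @return validated list of class `m6a_control`.
#' @export
m6a_control <- function(k_min = 2L, k_max = 15L, nstart = 25L,
                        indices = c("silhouette", "ch", "db", "gap"),
                        gap_B = 20L, kernel = "gaussian", tau = 1,
                        mode = "diff_of_maxima", min_set_size = 5L,
                        max_set_size = 500L, deg_alpha = 0.05, fc_min = 1,
                        deg_mode = "pairwise", cox_alpha = 0.05,
                        cutoff = "median", horizons = c(1, 3, 5), seed = 1L) {
  ctl <- list(k_min = as.integer(k_min), k_max = as.integer(k_max),
              nstart = as.integer(nstart), indices = indices,
              gap_B = as.integer(gap_B), kernel = kernel, tau = tau,
              mode = mode, min_set_size = as.integer(min_set_size),
              max_set_size = as.integer(max_set_size),
              deg_alpha = deg_alpha, fc_min = fc_min, deg_mode = deg_mode,
              cox_alpha = cox_alpha, cutoff = cutoff, horizons = horizons,
              seed = as.integer(seed))
  assert_that(ctl$k_min >= 2 && ctl$k_max >= ctl$k_min, "invalid k range")
  assert_that(ctl$deg_alpha > 0 && ctl$deg_alpha < 1, "invalid deg_alpha")
  assert_that(ctl$cox_alpha > 0 && ctl$cox_alpha < 1, "invalid cox_alpha")
  assert_that(all(ctl$horizons > 0), "horizons must be positive")
  structure(ctl, class = "m6a_control")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full m6A subtyping and scoring analysis
#'
#' Executes, in order: sample alignment; m6A pattern clustering on the
#' 20-gene regulator panel; single-sample enrichment scoring of the supplied
#' gene sets; moderated DEG analysis between patterns; univariate Cox
#' screening of the DEGs; signature partition and per-sample m6Ascore with
#' median-split groups; metabolic subtyping (when a category annotation is
#' supplied); survival analyses (KM + log-rank by score group, multivariate
#' Cox with available clinical covariates, nomogram, time-dependent AUC of
#' the nomogram points); and the association report tables.
#'
#' @param expr gene-by-sample log2 expression matrix.
#' @param clinical clinical data frame (see [read_clinical()]).
#' @param gene_sets named list of gene sets; must contain the pathway sets to
#'   score (e.g. an mRNA-methylation set and the 50 metabolic sets).
#' @param categories optional named character vector mapping metabolic set
#'   names to categories; enables the metabolic subtyping stage.
#' @param panel regulator panel used for clustering (default
#'   [clustering_panel()]).
#' @param control an [m6a_control()].
#' @return object of class `m6a_fit`.
#' @export
m6a_pipeline <- function(expr, clinical, gene_sets, categories = NULL,
                         panel = clustering_panel(), control = m6a_control()) {
  al <- stage("align", align_cohort(expr, clinical))
  expr <- al$expression; clinical <- al$clinical

  clusters <- stage("m6a_clusters", m6a_clusters(
    expr, panel = panel, k_min = control$k_min, k_max = control$k_max,
    indices = control$indices, nstart = control$nstart,
    gap_B = control$gap_B, seed = control$seed))

  enrichment <- stage("gsva", gsva_scores(
    expr, gene_sets, kernel = control$kernel, tau = control$tau,
    mode = control$mode, min_size = control$min_set_size,
    max_size = control$max_set_size))

  degs <- stage("degs", cluster_degs(expr, clusters$labels,
                                     alpha = control$deg_alpha,
                                     fc_min = control$fc_min,
                                     mode = control$deg_mode))
  if (!length(degs$genes)) stop2("pipeline stage 'degs' found no DEG")

  screen <- stage("cox_screen",
                  cox_screen(expr[degs$genes, , drop = FALSE], clinical))
  signature <- stage("signature", {
    sig <- signature_partition(screen, alpha = control$cox_alpha)
    freeze_signature(sig, expr)
  })
  scores <- stage("m6ascore", {
    s <- compute_m6ascore(expr, signature)
    score_groups(s, cutoff = control$cutoff)
  })

  metabolic <- NULL
  if (!is.null(categories)) {
    metabolic <- stage("metabolic", {
      met_sets <- intersect(names(categories), rownames(enrichment))
      assert_that(length(met_sets) >= 2, "need >= 2 scored metabolic sets")
      met_assign <- metabolic_clusters(
        enrichment[met_sets, , drop = FALSE], k_min = control$k_min,
        k_max = control$k_max, indices = control$indices,
        nstart = control$nstart, gap_B = control$gap_B, seed = control$seed)
      lipid_labels(enrichment[met_sets, , drop = FALSE], met_assign,
                   categories[met_sets])
    })
  }

  surv_res <- stage("survival", {
    grp <- setNames(as.character(scores$score_group), scores$sample_id)
    grp <- grp[clinical$sample_id]
    km <- km_estimate(clinical$os_time, clinical$os_event, grp)
    lr <- if (length(unique(grp)) >= 2) {
      logrank_test(clinical$os_time, clinical$os_event, grp)
    } else NULL
    covars <- c("score_group",
                intersect(c("stage_tnm", "age"), names(clinical)))
    cd <- clinical
    cd$score_group <- as.character(grp)
    cox <- nomo <- auc <- NULL
    if (length(unique(na.omit(cd$score_group))) >= 2) {
      cox <- cox_multivariate(cd, covars)
      nomo <- build_nomogram(cox, horizons = control$horizons)
      pts <- predict_nomogram(nomo)
      auc <- time_dependent_auc(pts$total_points,
                                cox$data$os_time, cox$data$os_event,
                                nomo$horizons)
    }
    list(km = km, logrank = lr, cox = cox, nomogram = nomo, auc = auc)
  })

  report <- stage("report", {
    tabs <- list()
    sg <- setNames(as.character(scores$score_group), scores$sample_id)
    ids <- clinical$sample_id
    tabs$score_vs_cluster <- crosstab(sg[ids],
                                      paste0("C", clusters$labels[ids]))
    labels_df <- data.frame(m6Acluster = paste0("C", clusters$labels[ids]),
                            score_group = sg[ids],
                            stringsAsFactors = FALSE)
    if (!is.null(metabolic)) {
      tabs$score_vs_metabolic <- crosstab(sg[ids], metabolic$labels[ids])
      labels_df$metabolic <- metabolic$labels[ids]
    }
    if ("stage_tnm" %in% names(clinical)) {
      tabs$score_vs_stage <- tryCatch(crosstab(sg[ids], clinical$stage_tnm),
                                      error = function(e) NULL)
      labels_df$stage_tnm <- clinical$stage_tnm
    }
    correlations <- score_pathway_correlation(scores, enrichment)
    response <- if ("response" %in% names(clinical) &&
                    any(!is.na(clinical$response))) {
      response_contrast(sg[ids], clinical$response)
    } else NULL
    list(crosstabs = tabs, correlations = correlations, response = response,
         alluvial = alluvial_table(labels_df))
  })

  structure(list(clusters = clusters, enrichment = enrichment, degs = degs,
                 screen = screen, signature = signature, scores = scores,
                 metabolic = metabolic, survival = surv_res, report = report,
                 clinical = clinical, control = control,
                 n_samples = ncol(expr), n_genes = nrow(expr)),
            class = "m6a_fit")
}

#' @export
print.m6a_fit <- function(x, ...) {
  cat(sprintf("m6A pattern analysis: %d samples, %d genes\n",
              x$n_samples, x$n_genes))
  cat(sprintf("  m6A clusters: k = %d (sizes %s)\n", x$clusters$k,
              paste(tabulate(x$clusters$labels, x$clusters$k), collapse = "/")))
  cat(sprintf("  signature: %d risk + %d protective genes (of %d DEGs)\n",
              nrow(x$signature$risk), nrow(x$signature$protective),
              length(x$degs$genes)))
  if (!is.null(x$metabolic)) {
    cat(sprintf("  metabolic subtypes: %s\n",
                paste(sprintf("%s=%d", names(table(x$metabolic$labels)),
                              table(x$metabolic$labels)), collapse = " ")))
  }
  if (!is.null(x$survival$logrank)) {
    cat(sprintf("  score-group log-rank: chi2 = %.2f, p = %.3g\n",
                x$survival$logrank$chi2, x$survival$logrank$p))
  }
  invisible(x)
}

#' @export
summary.m6a_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$survival$auc)) {
    cat("nomogram time-dependent AUC:\n")
    print(object$survival$auc, digits = 3)
  }
  if (!is.null(object$survival$cox)) {
    cat("multivariate Cox:\n")
    print(object$survival$cox$table, digits = 3)
  }
  invisible(object)
}

#' Score a new cohort with a fitted signature
#'
#' Applies the frozen m6A gene signature of a fitted pipeline to a new
#' expression matrix and splits the new cohort at its own median (the
#' per-cohort cutoff convention), or at a supplied numeric cutoff.
#'
#' @param object an `m6a_fit`.
#' @param newdata gene-by-sample log2 expression matrix.
#' @param cutoff `"median"` (default) or numeric.
#' @param ... unused.
#' @return data frame `sample_id`, `m6ascore`, `score_group`.
#' @export
predict.m6a_fit <- function(object, newdata, cutoff = "median", ...) {
  scores <- compute_m6ascore(newdata, object$signature)
  score_groups(scores, cutoff = cutoff)
}

## ---- file-level driver -----------------------------------------------------

.config_keys <- c("expression", "clinical", "gene_sets", "categories",
                  "out_dir", "k_min", "k_max", "nstart", "indices", "gap_B",
                  "kernel", "tau", "mode", "min_set_size", "max_set_size",
                  "deg_alpha", "fc_min", "deg_mode", "cox_alpha", "cutoff",
                  "horizons", "seed")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop2("yaml package required to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  assert_that(is.list(config), "config must be a list or a YAML/JSON path")
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) stop2("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  config
}

#' Run the pipeline from a config and write all artifacts
#'
#' The config (a list, or a path to a YAML/JSON file) names the input files
#' (`expression`, `clinical`, `gene_sets`, optional `categories`), the
#' `out_dir`, and any [m6a_control()] parameter. Unknown keys are rejected.
#' Every intermediate table is written as TSV/JSON under `out_dir` along with
#' a manifest (config, seed, package version); re-running the same config
#' reproduces identical outputs.
#'
#' @param config list or YAML/JSON path.
#' @return invisibly, the `m6a_fit` with attribute `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  for (key in c("expression", "clinical", "gene_sets", "out_dir")) {
    assert_that(!is.null(cfg[[key]]), "config key '%s' is required", key)
  }
  ctl_keys <- intersect(names(cfg), names(formals(m6a_control)))
  control <- do.call(m6a_control, cfg[ctl_keys])
  expr <- read_expression(cfg$expression)
  clinical <- read_clinical(cfg$clinical)
  sets <- read_gmt(cfg$gene_sets)
  categories <- if (!is.null(cfg$categories)) read_categories(cfg$categories)
  fit <- m6a_pipeline(expr, clinical, sets, categories, control = control)
  write_pipeline_outputs(fit, cfg$out_dir, cfg)
  attr(fit, "out_dir") <- cfg$out_dir
  invisible(fit)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(fit, out_dir, cfg = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(data.frame(sample_id = fit$clusters$sample_ids,
                       m6Acluster = paste0("C", fit$clusters$labels)),
            p("m6a_clusters.tsv"))
  if (!is.null(fit$clusters$selection)) {
    write_tsv(fit$clusters$selection$report, p("k_selection.tsv"))
  }
  write_scores(fit$enrichment, p("enrichment_scores.tsv"))
  skipped <- attr(fit$enrichment, "skipped")
  if (!is.null(skipped) && nrow(skipped)) write_tsv(skipped, p("skipped_sets.tsv"))
  write_tsv(fit$degs$table, p("deg_table.tsv"))
  writeLines(fit$degs$genes, p("deg_union.txt"))
  write_tsv(fit$screen, p("cox_screen.tsv"))
  write_signature(fit$signature, p("signature.tsv"))
  write_tsv(as.data.frame(fit$scores), p("m6ascore.tsv"))
  if (!is.null(fit$metabolic)) {
    write_tsv(data.frame(sample_id = names(fit$metabolic$labels),
                         metabolic_subtype = unname(fit$metabolic$labels)),
              p("metabolic_subtypes.tsv"))
    write_tsv(fit$metabolic$category_distance, p("category_distance.tsv"))
  }
  if (!is.null(fit$survival$cox)) {
    write_tsv(fit$survival$cox$table, p("cox_multivariate.tsv"))
  }
  if (!is.null(fit$survival$nomogram)) {
    write_tsv(fit$survival$nomogram$point_range, p("nomogram_points.tsv"))
    write_tsv(fit$survival$nomogram$lookup, p("nomogram_lookup.tsv"))
  }
  if (!is.null(fit$survival$auc)) write_tsv(fit$survival$auc, p("auc.tsv"))
  write_tsv(fit$report$correlations, p("score_pathway_correlation.tsv"))
  write_tsv(fit$report$alluvial, p("alluvial_table.tsv"))
  tests <- list()
  if (!is.null(fit$survival$logrank)) tests$logrank_score_group <- fit$survival$logrank
  for (nm in names(fit$report$crosstabs)) {
    ct <- fit$report$crosstabs[[nm]]
    if (!is.null(ct)) tests[[nm]] <- list(chi2 = ct$chi2, df = ct$df, p = ct$p)
  }
  if (!is.null(fit$report$response)) {
    tests$response <- list(rates = fit$report$response$rates,
                           p = if (!is.null(fit$report$response$test))
                             fit$report$response$test$p else NA)
  }
  writeLines(jsonlite::toJSON(tests, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, dataframe = "rows"),
             p("tests.json"))
  manifest <- list(package = "m6Apattern",
                   version = as.character(utils::packageVersion("m6Apattern")),
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   seed = fit$control$seed,
                   n_samples = fit$n_samples, n_genes = fit$n_genes)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             p("manifest.json"))
  invisible(out_dir)
}
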