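## Synthetic cohort generator.
##
## Emulates the statistical structure the analysis assumes: three latent m6A
## modification patterns with graded regulator expression (readers separating
## pattern 1 from 2, writers separating 1 from 3), pattern-coupled prognostic
## "signature" genes, a metabolic activity axis negatively correlated with the
## pattern index, pattern-linked survival hazard, stage shift and treatment
## response. Expression is generated directly on log2 scale (no count layer),
## matching the log2 FPKM data the pipeline expects. Survival is exponential
## with uniform censoring so that Cox parameter recovery is checkable in
## closed form.

.metabolic_categories <- c(carbohydrate = 12L, lipid = 13L, amino_acid = 13L,
                           other = 12L)
.category_scale <- c(carbohydrate = 1.0, lipid = 1.5, amino_acid = 1.0,
                     other = 0.8)
.pool_per_category <- 280L

#' Configuration for the synthetic cohort generator
#'
#' All defaults together define the reference simulation used throughout the
#' package tests: `n_samples = 300` tumors, `n_genes = 2000` genes, three
#' latent modification patterns of equal size, regulator means stepping by
#' `regulator_shift = 1.5` log2 units between adjacent patterns against
#' `noise_sd = 1` Gaussian noise, 40 risk plus 40 protective pattern-coupled
#' prognostic genes, exponential survival with baseline hazard 0.2 per year
#' and per-pattern log-hazard offsets (0, 0.6, 1.6) under uniform censoring on
#' (0, 10) years, metabolic activity correlated -0.8 with the pattern index,
#' and per-pattern probabilities (0.2, 0.2, 0.6) of treatment response
#' (PR/SD).
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes (>= 200; must be large enough to host the
#'   regulator, signature and metabolic blocks).
#' @param n_clusters number of latent patterns.
#' @param cluster_props probability vector over patterns (sums to 1).
#' @param regulator_shift mean log2 offset between adjacent patterns for
#'   regulator (and signature) genes.
#' @param n_signature_risk,n_signature_protective numbers of planted
#'   prognostic genes correlated positively / negatively with the pattern
#'   index.
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param baseline_hazard exponential hazard per unit time for pattern 1.
#' @param cluster_log_hazard per-pattern log hazard offsets.
#' @param censor_time_max censoring times are Uniform(0, censor_time_max).
#' @param metabolic_coupling correlation (<= 0) between the latent pattern
#'   index and metabolic pathway activity.
#' @param response_probs per-pattern probability of response (PR/SD).
#' @param set_size_min,set_size_max bounds on simulated metabolic set sizes.
#' @param set_overlap maximum sharing fraction between sets of the same
#'   category (0 gives pairwise-disjoint sets within a category).
#' @param seed integer RNG seed; the same seed reproduces the cohort exactly.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 2000L, n_clusters = 3L,
                       cluster_props = NULL, regulator_shift = 1.5,
                       n_signature_risk = 40L, n_signature_protective = 40L,
                       noise_sd = 1, baseline_hazard = 0.2,
                       cluster_log_hazard = c(0, 0.6, 1.6),
                       censor_time_max = 10, metabolic_coupling = -0.8,
                       response_probs = c(0.2, 0.2, 0.6),
                       set_size_min = 10L, set_size_max = 20L,
                       set_overlap = 0.3, seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes, n_clusters = n_clusters,
              cluster_props = cluster_props %||% rep(1 / n_clusters, n_clusters),
              regulator_shift = regulator_shift,
              n_signature_risk = n_signature_risk,
              n_signature_protective = n_signature_protective,
              noise_sd = noise_sd, baseline_hazard = baseline_hazard,
              cluster_log_hazard = cluster_log_hazard,
              censor_time_max = censor_time_max,
              metabolic_coupling = metabolic_coupling,
              response_probs = response_probs,
              set_size_min = as.integer(set_size_min),
              set_size_max = as.integer(set_size_max),
              set_overlap = set_overlap, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop2("invalid sim_config field '%s': %s", field, why)
  }
  chk(is_count(cfg$n_samples), "n_samples", "must be a positive integer")
  chk(is_count(cfg$n_genes) && cfg$n_genes >= 200, "n_genes",
      "must be a positive integer >= 200")
  chk(is_count(cfg$n_clusters), "n_clusters", "must be a positive integer")
  chk(length(cfg$cluster_props) == cfg$n_clusters &&
        all(cfg$cluster_props > 0) &&
        abs(sum(cfg$cluster_props) - 1) < 1e-8,
      "cluster_props", "must be a probability vector of length n_clusters")
  chk(cfg$regulator_shift >= 0, "regulator_shift", "must be non-negative")
  chk(is_count(cfg$n_signature_risk + 1) && cfg$n_signature_risk >= 0,
      "n_signature_risk", "must be a non-negative integer")
  chk(cfg$n_signature_protective >= 0, "n_signature_protective",
      "must be a non-negative integer")
  chk(cfg$noise_sd > 0, "noise_sd", "must be positive")
  chk(cfg$baseline_hazard > 0, "baseline_hazard", "must be positive")
  chk(length(cfg$cluster_log_hazard) == cfg$n_clusters, "cluster_log_hazard",
      "must have one entry per cluster")
  chk(cfg$censor_time_max > 0, "censor_time_max", "must be positive")
  chk(cfg$metabolic_coupling <= 0 && cfg$metabolic_coupling >= -1,
      "metabolic_coupling", "must be in [-1, 0]")
  chk(length(cfg$response_probs) == cfg$n_clusters &&
        all(cfg$response_probs >= 0 & cfg$response_probs <= 1),
      "response_probs", "must be probabilities, one per cluster")
  chk(cfg$set_size_min >= 2 && cfg$set_size_max >= cfg$set_size_min,
      "set_size_min", "set size bounds must satisfy 2 <= min <= max")
  chk(cfg$set_overlap >= 0 && cfg$set_overlap < 1, "set_overlap",
      "must be in [0, 1)")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

## Deterministic gene-universe layout: regulators, signature blocks, metabolic
## category pools, then noise genes. Pure function of the config (no RNG).
gene_layout <- function(cfg) {
  panel <- m6a_regulators()
  reg <- panel$gene
  risk <- if (cfg$n_signature_risk > 0)
    sprintf("SIGR%03d", seq_len(cfg$n_signature_risk)) else character(0)
  prot <- if (cfg$n_signature_protective > 0)
    sprintf("SIGP%03d", seq_len(cfg$n_signature_protective)) else character(0)
  met <- lapply(names(.metabolic_categories), function(cat) {
    sprintf("MET_%s_%03d", toupper(cat), seq_len(.pool_per_category))
  })
  names(met) <- names(.metabolic_categories)
  n_fixed <- length(reg) + length(risk) + length(prot) +
    length(.metabolic_categories) * .pool_per_category
  if (cfg$n_genes < n_fixed + 20) {
    stop2("n_genes = %d too small to host regulator/signature/metabolic blocks (need >= %d)",
          cfg$n_genes, n_fixed + 20)
  }
  noise <- sprintf("GENE%05d", seq_len(cfg$n_genes - n_fixed))
  list(panel = panel, regulators = reg, risk = risk, protective = prot,
       metabolic = met, noise = noise)
}

#' Simulate the gene-set collection matching a synthetic cohort
#'
#' Emits one `MRNA_METHYLATION` set (the 23 regulators plus 10 decoy genes)
#' and 50 metabolic sets partitioned into four categories (carbohydrate 12,
#' lipid 13, amino acid 13, other 12) over the metabolic gene block, with
#' controlled within-category overlap, plus the category annotation. The
#' collection is a deterministic function of the config (shared seed), so a
#' standalone call reproduces exactly the sets embedded in
#' [simulate_cohort()].
#'
#' @param config a [sim_config()].
#' @return list with `sets` (named list, GMT-style) and `categories` (named
#'   character vector over the 50 metabolic sets).
#' @export
simulate_gene_sets <- function(config) {
  validate_sim_config(config)
  lay <- gene_layout(config)
  with_seed(config$seed + 7919L, {
    sets <- list()
    categories <- character(0)
    for (cat in names(.metabolic_categories)) {
      pool <- sample(lay$metabolic[[cat]])
      n_sets <- .metabolic_categories[[cat]]
      sizes <- sample(config$set_size_min:config$set_size_max, n_sets,
                      replace = TRUE)
      borrowed_n <- floor(sizes * config$set_overlap / 2)
      core_n <- sizes - borrowed_n
      if (sum(core_n) > length(pool)) {
        stop2("metabolic gene pool for category '%s' too small for %d disjoint cores",
              cat, n_sets)
      }
      offsets <- cumsum(c(0L, core_n[-n_sets]))
      cores <- lapply(seq_len(n_sets), function(i) {
        pool[(offsets[i] + 1L):(offsets[i] + core_n[i])]
      })
      for (i in seq_len(n_sets)) {
        members <- cores[[i]]
        if (borrowed_n[i] > 0) {
          donor <- setdiff(unlist(cores[-i]), members)
          members <- c(members, sample(donor, min(borrowed_n[i], length(donor))))
        }
        nm <- sprintf("%s_SET_%02d", toupper(cat), i)
        sets[[nm]] <- sort(members)
        categories[[nm]] <- cat
      }
    }
    decoys <- head(lay$noise, 10L)
    sets <- c(list(MRNA_METHYLATION = c(lay$regulators, decoys)), sets)
    attr(sets, "descriptions") <- setNames(rep("synthetic", length(sets)),
                                           names(sets))
    list(sets = sets, categories = categories)
  })
}

#' Simulate a synthetic HCC-like cohort with known latent structure
#'
#' Generates a gene-by-sample log2 expression matrix, a clinical table
#' (survival, age, TNM and T stage, treatment response), the matching gene-set
#' collection and the ground truth (per-sample latent pattern, per-gene role).
#' See [sim_config()] for what the defaults encode. The same seed yields a
#' bit-identical cohort.
#'
#' @param config a [sim_config()].
#' @return list of class `m6a_cohort` with elements `expression`, `clinical`,
#'   `gene_sets`, `categories`, `truth` (list with `cluster`, `gene_roles`)
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  lay <- gene_layout(config)
  gs <- simulate_gene_sets(config)
  k <- config$n_clusters
  n <- config$n_samples
  with_seed(config$seed, {
    z <- sample.int(k, n, replace = TRUE, prob = config$cluster_props)
    sample_ids <- sprintf("S%04d", seq_len(n))

    genes <- c(lay$regulators, lay$risk, lay$protective,
               unlist(lay$metabolic, use.names = FALSE), lay$noise)
    expr <- matrix(rnorm(length(genes) * n, sd = config$noise_sd),
                   nrow = length(genes), ncol = n,
                   dimnames = list(genes, sample_ids))

    ## regulator block: every regulator spans (k-1)*regulator_shift log2
    ## units from the lowest to the highest pattern; the role decides where
    ## the transition happens (readers switch at pattern 1 -> 2, writers at
    ## the top pattern, erasers grade linearly), so C1 vs C2 differ mostly in
    ## readers and C1 vs C3 mostly in writers while overall expression stays
    ## monotone in the pattern index
    sft <- config$regulator_shift
    span <- sft * (k - 1)
    role <- setNames(lay$panel$role, lay$panel$gene)
    reg_base <- runif(length(lay$regulators), 4, 8)
    names(reg_base) <- lay$regulators
    for (g in lay$regulators) {
      delta <- switch(role[[g]],
        reader = span * (z >= 2),
        writer = span * (z == k),
        eraser = sft * (z - 1))
      expr[g, ] <- expr[g, ] + reg_base[[g]] + delta
    }

    ## prognostic signature blocks: coupled to the pattern index with slope
    ## +/- regulator_shift per step
    for (g in lay$risk) {
      expr[g, ] <- expr[g, ] + runif(1, 4, 8) + sft * (z - 1)
    }
    for (g in lay$protective) {
      expr[g, ] <- expr[g, ] + runif(1, 4, 8) - sft * (z - 1)
    }

    ## metabolic block: one latent activity axis per category. Each axis is a
    ## monotone non-increasing function of the pattern index, scaled so its
    ## correlation with the index equals metabolic_coupling, but the *shape*
    ## differs by category (carbohydrate drops at pattern 1 -> 2, amino acid
    ## at the top pattern, lipid drops progressively with its largest gap at
    ## the top, other linearly). The category-specific transition points keep
    ## the strata separable in pathway-score space rather than collapsing
    ## onto a single graded axis, while lipid activity stays strictly ordered
    ## so the top pattern has the lowest lipid enrichment.
    rho <- abs(config$metabolic_coupling)
    met_profile <- list(
      carbohydrate = -(z >= 2),
      lipid        = -((z - 1) / max(k - 1, 1))^2,
      amino_acid   = -(z == k),
      other        = -(z - 1) / max(k - 1, 1))
    for (cat in names(lay$metabolic)) {
      g_raw <- met_profile[[cat]]
      if (sd(g_raw) > 0) {
        g_std <- (g_raw - mean(g_raw)) / sd(g_raw)
        a <- min(1, rho / abs(cor(z, g_raw)))
        m_lat <- a * g_std + sqrt(1 - a^2) * rnorm(n)
      } else {
        m_lat <- rnorm(n)
      }
      lambda <- .category_scale[[cat]]
      for (g in lay$metabolic[[cat]]) {
        expr[g, ] <- expr[g, ] + runif(1, 4, 8) + lambda * m_lat
      }
    }
    expr[lay$noise, ] <- expr[lay$noise, ] +
      matrix(rep(runif(length(lay$noise), 2, 10), n), ncol = n)

    ## survival: exponential, log-hazard set by the latent pattern
    rate <- config$baseline_hazard * exp(config$cluster_log_hazard[z])
    t_event <- rexp(n, rate = rate)
    t_cens <- runif(n, 0, config$censor_time_max)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    w <- (z - 1) / max(k - 1, 1)
    stage_lo <- c(0.45, 0.30, 0.20, 0.05)
    stage_hi <- c(0.15, 0.25, 0.35, 0.25)
    draw_stage <- function() {
      vapply(seq_len(n), function(i) {
        p <- (1 - w[i]) * stage_lo + w[i] * stage_hi
        sample.int(4L, 1L, prob = p)
      }, integer(1))
    }
    stage_tnm <- c("i", "ii", "iii", "iv")[draw_stage()]
    stage_t <- paste0("t", draw_stage())
    age <- round(rnorm(n, mean = 62 - 2 * (z - 1), sd = 10))
    response <- ifelse(rbinom(n, 1L, config$response_probs[z]) == 1L,
                       "PR/SD", "PD")

    clinical <- data.frame(sample_id = sample_ids, os_time = os_time,
                           os_event = os_event, age = age,
                           stage_tnm = stage_tnm, stage_t = stage_t,
                           response = response, stringsAsFactors = FALSE)

    gene_roles <- data.frame(
      gene = genes,
      role = rep(c("regulator", "risk_signature", "protective_signature",
                   "metabolic", "noise"),
                 c(length(lay$regulators), length(lay$risk),
                   length(lay$protective),
                   length(unlist(lay$metabolic)), length(lay$noise))),
      category = c(rep(NA_character_, length(lay$regulators) +
                         length(lay$risk) + length(lay$protective)),
                   rep(names(lay$metabolic),
                       vapply(lay$metabolic, length, integer(1))),
                   rep(NA_character_, length(lay$noise))),
      stringsAsFactors = FALSE)

    structure(list(expression = expr, clinical = clinical,
                   gene_sets = gs$sets, categories = gs$categories,
                   truth = list(cluster = setNames(z, sample_ids),
                                gene_roles = gene_roles),
                   config = config),
              class = "m6a_cohort")
  })
}

#' @export
print.m6a_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples, %d latent patterns (seed %d)\n",
              nrow(x$expression), ncol(x$expression),
              x$config$n_clusters, x$config$seed))
  cat(sprintf("gene sets: %d (%d metabolic, 4 categories)\n",
              length(x$gene_sets), length(x$categories)))
  invisible(x)
}

#' Write a synthetic cohort to a fixture directory
#'
#' Writes `expression.tsv`, `clinical.tsv`, `gene_sets.gmt`,
#' `categories.tsv`, `truth_samples.tsv`, `truth_genes.tsv` and a
#' `manifest.json` recording the config (including the seed). The files round
#' trip losslessly through the package readers (up to float formatting).
#'
#' @param cohort an `m6a_cohort` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    categories = file.path(dir, "categories.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_expression(cohort$expression, paths[["expression"]])
  write.table(cohort$clinical, paths[["clinical"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  write_categories(cohort$categories, paths[["categories"]])
  write.table(data.frame(sample_id = names(cohort$truth$cluster),
                         cluster = unname(cohort$truth$cluster)),
              paths[["truth_samples"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth$gene_roles, paths[["truth_genes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(package = "m6Apattern",
                   created = format(Sys.time(), tz = "UTC"),
                   config = unclass(cohort$config),
                   files = as.list(basename(paths[names(paths) != "manifest"])))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths[["manifest"]])
  invisible(paths)
}
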