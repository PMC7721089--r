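## Readers and writers for the plain-text formats the pipeline touches:
## expression matrices (TSV/CSV, genes x samples), clinical tables, GMT gene
## sets and the metabolic category annotation. All readers validate rather
## than silently coerce.

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a gene-by-sample expression matrix
#'
#' Expects TSV (or CSV, by file extension) with the first column holding gene
#' symbols and the header row holding sample IDs. Values are assumed to be on
#' log2 scale (e.g. log2 FPKM). Duplicate gene rows are collapsed by keeping
#' the row with the highest mean expression (`dup_policy = "max-mean"`), the
#' usual convention for probe/transcript collapse. Genes containing any
#' missing value are dropped with a reported count, since downstream
#' clustering and testing assume complete rows.
#'
#' @param path file path.
#' @param dup_policy how to collapse duplicated gene symbols; only
#'   `"max-mean"` (keep the duplicate with the largest row mean) or
#'   `"error"` are supported.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, dup_policy = c("max-mean", "error")) {
  dup_policy <- match.arg(dup_policy)
  d <- .read_table_auto(path)
  assert_that(ncol(d) >= 2, "expression file needs a gene column plus samples")
  genes <- as.character(d[[1]])
  sample_ids <- colnames(d)[-1]
  if (anyDuplicated(sample_ids)) {
    stop2("duplicated sample IDs in header: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- d[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop2("non-numeric value at row %d, column '%s'", bad, sample_ids[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m <- collapse_duplicate_genes(m, dup_policy)
  m <- drop_incomplete_genes(m)
  validate_expression(m)
  m
}

collapse_duplicate_genes <- function(m, dup_policy = "max-mean") {
  if (!anyDuplicated(rownames(m))) return(m)
  if (dup_policy == "error") stop2("duplicated gene symbols in expression matrix")
  means <- rowMeans(m, na.rm = TRUE)
  ord <- order(rownames(m), -means)
  m <- m[ord, , drop = FALSE]
  keep <- !duplicated(rownames(m))
  n_dropped <- sum(!keep)
  log_info("collapsed %d duplicated gene row(s) by max-mean", n_dropped)
  m[keep, , drop = FALSE]
}

#' Drop genes with missing values
#'
#' @param m gene-by-sample matrix.
#' @return `m` restricted to complete rows; the number of dropped genes is
#'   reported.
#' @export
drop_incomplete_genes <- function(m) {
  bad <- !complete.cases(m) | apply(m, 1L, function(x) any(!is.finite(x)))
  if (any(bad)) {
    log_info("dropped %d gene(s) with missing/non-finite values", sum(bad))
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' @rdname read_expression
#' @param m gene-by-sample numeric matrix.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  d <- data.frame(gene = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene symbols. Duplicated members within a set are removed with
#' a warning. An empty file yields an empty collection with a warning.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn2("empty GMT file: %s", path)
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop2("GMT line %d has fewer than 3 fields", i)
    nm <- f[[1]]
    if (nm %in% names(sets)) stop2("duplicated gene-set name '%s' (line %d)", nm, i)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn2("set '%s': %d duplicated member(s) removed", nm,
            sum(duplicated(members)))
      members <- unique(members)
    }
    if (!length(members)) stop2("gene set '%s' (line %d) is empty", nm, i)
    sets[[nm]] <- members
    descs[[nm]] <- f[[2]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute is written to the second GMT field.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Requires columns `sample_id`, `os_time` (overall survival time, non
#' negative) and `os_event` (0/1). Optional columns `age`, `stage_tnm`
#' (i/ii/iii/iv, case-insensitive, "stage iii"-style prefixes accepted),
#' `stage_t`, `response` (`PD` or `PR/SD`) and any extra label columns are
#' kept. Samples lacking survival information are excluded with a reported
#' count.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return data frame with one row per retained sample.
#' @export
read_clinical <- function(path) {
  d <- .read_table_auto(path)
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop2("clinical table missing column(s): %s",
                          paste(miss, collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  assert_that(!anyDuplicated(d$sample_id), "duplicated sample_id in clinical table")
  drop <- is.na(d$os_time) | is.na(d$os_event)
  if (any(drop)) {
    log_info("excluded %d sample(s) without survival information", sum(drop))
    d <- d[!drop, , drop = FALSE]
  }
  assert_that(is.numeric(d$os_time) && all(d$os_time >= 0),
              "os_time must be non-negative numeric")
  if (!all(d$os_event %in% c(0, 1))) stop2("os_event must be 0/1")
  d$os_event <- as.integer(d$os_event)
  if ("stage_tnm" %in% names(d)) d$stage_tnm <- normalize_stage(d$stage_tnm)
  if ("response" %in% names(d)) {
    ok <- is.na(d$response) | d$response %in% c("PD", "PR/SD")
    if (!all(ok)) stop2("response values must be 'PD' or 'PR/SD'")
  }
  rownames(d) <- NULL
  d
}

normalize_stage <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^stage[ _]*", "", x)
  map <- c(i = "i", ii = "ii", iii = "iii", iv = "iv",
           "1" = "i", "2" = "ii", "3" = "iii", "4" = "iv")
  out <- unname(map[x])
  out[is.na(x) | x == ""] <- NA_character_
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop2("unrecognized stage value(s): %s",
                      paste(unique(x[bad]), collapse = ", "))
  out
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Restricts both inputs to the intersection of sample IDs, in the same order
#' (clinical order), and reports how many samples were dropped on each side.
#'
#' @param expr gene-by-sample matrix.
#' @param clinical clinical data frame with `sample_id`.
#' @return list with `expression` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  validate_expression(expr)
  shared <- intersect(clinical$sample_id, colnames(expr))
  if (!length(shared)) stop2("no sample IDs shared between expression and clinical")
  d_expr <- ncol(expr) - length(shared)
  d_clin <- nrow(clinical) - length(shared)
  if (d_expr > 0) log_info("dropped %d expression sample(s) without clinical data", d_expr)
  if (d_clin > 0) log_info("dropped %d clinical sample(s) without expression", d_clin)
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expression = expr[, shared, drop = FALSE], clinical = clinical)
}

#' Concatenate expression cohorts by column
#'
#' Plain column concatenation over the shared genes. No batch correction is
#' applied: merged cohorts from different platforms will carry batch effects,
#' and a warning says so.
#'
#' @param ... two or more gene-by-sample matrices.
#' @return merged matrix over the intersection of gene symbols.
#' @export
merge_cohorts <- function(...) {
  mats <- list(...)
  assert_that(length(mats) >= 2, "merge_cohorts needs at least two matrices")
  for (m in mats) validate_expression(m)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) stop2("no genes shared across cohorts")
  ids <- unlist(lapply(mats, colnames))
  assert_that(!anyDuplicated(ids), "sample IDs collide across cohorts")
  warn2("cohorts concatenated without batch correction; cross-platform batch effects are not removed")
  do.call(cbind, lapply(mats, function(m) m[genes, , drop = FALSE]))
}

#' Read / write a gene-set category annotation
#'
#' Two-column TSV (`set`, `category`) mapping gene-set names to a metabolic
#' category (`carbohydrate`, `lipid`, `amino_acid`, `other`).
#'
#' @param path file path.
#' @return `read_categories` returns a named character vector (set -> category).
#' @export
read_categories <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("set", "category") %in% names(d)),
              "category file must have columns 'set' and 'category'")
  setNames(as.character(d$category), as.character(d$set))
}

#' @rdname read_categories
#' @param categories named character vector (set name -> category).
#' @export
write_categories <- function(categories, path) {
  write.table(data.frame(set = names(categories), category = unname(categories)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
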