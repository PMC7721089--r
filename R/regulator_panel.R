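## The curated m6A regulator panel.
##
## m6A (N6-methyladenosine) is deposited by "writer" methyltransferase-complex
## proteins, removed by "eraser" demethylases, and bound by "reader" proteins.
## The default panel is the curated 23-gene set used throughout the package:
## 8 writers, 2 erasers, 13 readers.

.m6a_writers <- c("METTL3", "METTL14", "RBM15", "RBM15B", "WTAP",
                  "KIAA1429", "CBLL1", "ZC3H13")
.m6a_erasers <- c("ALKBH5", "FTO")
.m6a_readers <- c("YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2", "YTHDF3",
                  "IGF2BP1", "IGF2BP2", "IGF2BP3", "HNRNPA2B1", "HNRNPC",
                  "FMR1", "LRPPRC", "ELAVL1")

new_panel <- function(gene, role) {
  gene <- toupper(as.character(gene))
  role <- as.character(role)
  assert_that(all(nzchar(gene)), "panel gene symbols must be non-empty")
  assert_that(!anyDuplicated(gene), "panel gene symbols must be unique")
  assert_that(all(role %in% c("writer", "eraser", "reader")),
              "panel roles must be writer/eraser/reader")
  structure(data.frame(gene = gene, role = role, stringsAsFactors = FALSE),
            class = c("m6a_panel", "data.frame"))
}

#' The default 23-gene m6A regulator panel
#'
#' Returns the curated panel of 23 m6A regulators: 8 writers (METTL3, METTL14,
#' RBM15, RBM15B, WTAP, KIAA1429, CBLL1, ZC3H13), 2 erasers (ALKBH5, FTO) and
#' 13 readers (YTHDC1, YTHDC2, YTHDF1, YTHDF2, YTHDF3, IGF2BP1-3, HNRNPA2B1,
#' HNRNPC, FMR1, LRPPRC, ELAVL1). Symbols are matched exactly (upper case); no
#' alias resolution (e.g. KIAA1429/VIRMA) is attempted — rename genes upstream
#' if your annotation uses a different symbol.
#'
#' @return A data frame of class `m6a_panel` with columns `gene` and `role`.
#' @examples
#' p <- m6a_regulators()
#' table(p$role)
#' @export
m6a_regulators <- function() {
  new_panel(c(.m6a_writers, .m6a_erasers, .m6a_readers),
            rep(c("writer", "eraser", "reader"),
                c(length(.m6a_writers), length(.m6a_erasers), length(.m6a_readers))))
}

#' Reduce a regulator panel to the clustering panel
#'
#' Drops the IGF2BP family (IGF2BP1/2/3) from a panel, yielding the 20-gene
#' panel used for pattern clustering (the IGF2BPs are excluded for data
#' availability reasons in the reference cohorts). Order of the remaining
#' entries is preserved. If the panel already lacks the IGF2BPs the panel is
#' returned unchanged with a warning.
#'
#' @param panel an `m6a_panel` data frame (default: [m6a_regulators()]).
#' @return The reduced `m6a_panel`.
#' @export
clustering_panel <- function(panel = m6a_regulators()) {
  drop <- c("IGF2BP1", "IGF2BP2", "IGF2BP3")
  if (!any(drop %in% panel$gene)) {
    warn2("panel contains no IGF2BP genes; returning it unchanged")
    return(panel)
  }
  keep <- panel[!panel$gene %in% drop, , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("m6a_panel", "data.frame")
  keep
}

#' Restrict a panel to the genes present in an expression matrix
#'
#' @param panel an `m6a_panel`.
#' @param expr gene-by-sample numeric matrix with gene rownames.
#' @return A list with `panel` (the sub-panel present in `expr`) and `missing`
#'   (character vector of absent symbols; each absence is reported).
#' @export
restrict_panel <- function(panel, expr) {
  validate_expression(expr)
  present <- panel$gene %in% rownames(expr)
  missing <- panel$gene[!present]
  if (length(missing)) {
    for (g in missing) log_info("panel gene %s absent from expression matrix", g)
  }
  if (!any(present)) {
    stop2("no panel gene is present in the expression matrix")
  }
  sub <- panel[present, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("m6a_panel", "data.frame")
  list(panel = sub, missing = missing)
}

#' @export
print.m6a_panel <- function(x, ...) {
  cnt <- table(factor(x$role, levels = c("writer", "eraser", "reader")))
  cat(sprintf("m6A regulator panel: %d genes (%d writers, %d erasers, %d readers)\n",
              nrow(x), cnt[["writer"]], cnt[["eraser"]], cnt[["reader"]]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write a regulator panel as two-column TSV
#'
#' The file format is tab-separated with header `gene`, `role`.
#'
#' @param path file path.
#' @return `read_panel` returns an `m6a_panel`; `write_panel` returns `path`
#'   invisibly.
#' @export
read_panel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "role") %in% names(d)),
              "panel file must have columns 'gene' and 'role'")
  new_panel(d$gene, d$role)
}

#' @rdname read_panel
#' @param panel an `m6a_panel`.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
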