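write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("read_expression parses a toy matrix", {
  path <- write_lines_tmp(c("gene\tS1\tS2",
                            "A\t1\t2", "B\t3\t4", "C\t5\t6"))
  m <- read_expression(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), c("A", "B", "C"))
  expect_equal(colnames(m), c("S1", "S2"))
  expect_equal(m["B", "S2"], 4)
})

test_that("read_expression reads CSV by extension", {
  path <- write_lines_tmp(c("gene,S1,S2", "A,1,2", "B,3,4"), ext = ".csv")
  m <- read_expression(path)
  expect_equal(m["A", "S2"], 2)
})

test_that("duplicate gene rows collapse to the max-mean row", {
  path <- write_lines_tmp(c("gene\tS1\tS2",
                            "A\t1\t2",    # mean 1.5
                            "A\t10\t20",  # mean 15, kept
                            "B\t0\t0"))
  m <- suppressMessages(read_expression(path))
  expect_equal(nrow(m), 2L)
  expect_equal(unname(m["A", ]), c(10, 20))
  expect_error(read_expression(path, dup_policy = "error"), "duplicated gene")
})

test_that("read_expression rejects malformed input with coordinates", {
  dup <- write_lines_tmp(c("gene\tS1\tS1", "A\t1\t2"))
  expect_error(read_expression(dup), "duplicated sample IDs.*S1")
  bad <- write_lines_tmp(c("gene\tS1\tS2", "A\t1\tx", "B\t2\t3"))
  expect_error(read_expression(bad), "row 1, column 'S2'")
})

test_that("genes with missing values are dropped with a report", {
  path <- write_lines_tmp(c("gene\tS1\tS2", "A\t1\tNA", "B\t2\t3"))
  expect_message(m <- read_expression(path), "dropped 1 gene")
  expect_equal(rownames(m), "B")
})

test_that("expression write/read round-trips on random fixtures", {
  set.seed(5)
  for (i in 1:3) {
    ng <- sample(3:40, 1)
    ns <- sample(2:10, 1)
    m <- matrix(round(rnorm(ng * ns), 6), nrow = ng,
                dimnames = list(sprintf("G%03d", seq_len(ng)),
                                sprintf("S%03d", seq_len(ns))))
    path <- tempfile(fileext = ".tsv")
    write_expression(m, path)
    expect_equal(read_expression(path), m)
    unlink(path)
  }
})

test_that("read_gmt parses, deduplicates and validates", {
  path <- write_lines_tmp(c("SET1\tdesc1\tA\tB\tC",
                            "SET2\tdesc2\tB\tD\tE\tF"), ext = ".gmt")
  sets <- read_gmt(path)
  expect_length(sets, 2L)
  expect_equal(sets$SET1, c("A", "B", "C"))
  expect_equal(attr(sets, "descriptions")[["SET2"]], "desc2")

  short <- write_lines_tmp(c("SET1\tdesc\tA", "SET2\tonlydesc"), ext = ".gmt")
  expect_error(read_gmt(short), "line 2")

  dup <- write_lines_tmp("SET1\tdesc\tA\tA\tB", ext = ".gmt")
  expect_warning(sets <- read_gmt(dup), "duplicated member")
  expect_equal(sets$SET1, c("A", "B"))

  empty <- write_lines_tmp(character(0), ext = ".gmt")
  expect_warning(sets <- read_gmt(empty), "empty GMT")
  expect_length(sets, 0L)
})

test_that("gmt write/read round-trips", {
  sets <- list(ALPHA = c("A", "B"), BETA = c("C", "D", "E"))
  attr(sets, "descriptions") <- c(ALPHA = "first", BETA = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$ALPHA, sets$ALPHA)
  expect_equal(back$BETA, sets$BETA)
  expect_equal(attr(back, "descriptions"), attr(sets, "descriptions"))
  unlink(path)
})

test_that("read_clinical applies the survival exclusion rule and typing", {
  path <- write_lines_tmp(c("sample_id\tos_time\tos_event\tstage_tnm",
                            "S1\t1.5\t1\tStage III",
                            "S2\t\t0\tii",
                            "S3\t2\t0\t3",
                            "S4\t0.2\t1\tiv",
                            "S5\t3\t1\ti"))
  expect_message(d <- read_clinical(path), "excluded 1 sample")
  expect_equal(nrow(d), 4L)
  expect_equal(d$stage_tnm, c("iii", "iii", "iv", "i"))

  bad_event <- write_lines_tmp(c("sample_id\tos_time\tos_event",
                                 "S1\t1\t2"))
  expect_error(read_clinical(bad_event), "os_event")

  missing_col <- write_lines_tmp(c("sample_id\tos_time", "S1\t1"))
  expect_error(read_clinical(missing_col), "os_event")

  bad_stage <- write_lines_tmp(c("sample_id\tos_time\tos_event\tstage_tnm",
                                 "S1\t1\t1\tvx"))
  expect_error(read_clinical(bad_stage), "stage")
})

test_that("align_cohort intersects and orders samples", {
  m <- matrix(1:6, nrow = 2,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  clin <- data.frame(sample_id = c("S3", "S1"), os_time = c(1, 2),
                     os_event = c(1L, 0L))
  al <- suppressMessages(align_cohort(m, clin))
  expect_equal(colnames(al$expression), c("S3", "S1"))
  expect_equal(al$clinical$sample_id, c("S3", "S1"))

  expect_message(align_cohort(m, clin), "dropped 1 expression sample")

  disjoint <- data.frame(sample_id = "X1", os_time = 1, os_event = 1L)
  expect_error(align_cohort(m, disjoint), "no sample IDs shared")
})

test_that("merge_cohorts concatenates with a batch-effect warning", {
  a <- matrix(1:4, nrow = 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  b <- matrix(5:8, nrow = 2, dimnames = list(c("B", "A"), c("S3", "S4")))
  expect_warning(m <- merge_cohorts(a, b), "batch")
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(m["A", "S3"], b["A", "S3"])
  dup <- matrix(1:4, nrow = 2, dimnames = list(c("A", "B"), c("S1", "S5")))
  expect_error(suppressWarnings(merge_cohorts(a, dup)), "collide")
})

test_that("categories round-trip through TSV", {
  cats <- c(SET1 = "lipid", SET2 = "other")
  path <- tempfile(fileext = ".tsv")
  write_categories(cats, path)
  expect_equal(read_categories(path), cats)
  unlink(path)
})
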