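rand_groups <- function(ng, na, nb, seed, shift = 0) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(ng))
  list(a = matrix(rnorm(ng * na) + shift, nrow = ng,
                  dimnames = list(genes, NULL)),
       b = matrix(rnorm(ng * nb), nrow = ng, dimnames = list(genes, NULL)))
}

test_that("identical groups give zero fold change and p = 1", {
  g <- rand_groups(50, 4, 4, seed = 1)
  res <- moderated_test(g$a, g$a)
  expect_equal(res$log2_fc, rep(0, 50))
  expect_equal(res$p, rep(1, 50))
})

test_that("prior_df = 0 reproduces the ordinary pooled t-test", {
  g <- rand_groups(200, 5, 7, seed = 2)
  res <- moderated_test(g$a, g$b, prior_df = 0)
  ## independent oracle: textbook pooled two-sample t, gene by gene
  for (i in c(1, 50, 117, 200)) {
    tt <- t.test(g$a[i, ], g$b[i, ], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated statistics match the limma oracle", {
  g <- rand_groups(500, 4, 4, seed = 3)
  res <- moderated_test(g$a, g$b)
  design <- cbind(intercept = 1, groupA = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(cbind(g$a, g$b), design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, "groupA"]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, "groupA"]), tolerance = 1e-8)
})

test_that("finite prior df matches the limma oracle on heterogeneous variances", {
  set.seed(30)
  ng <- 400
  genes <- sprintf("g%04d", seq_len(ng))
  ## true gene variances drawn from a scaled inverse chi-square -> finite d0
  sds <- sqrt(4 / rchisq(ng, df = 4))
  a <- matrix(rnorm(ng * 4, sd = sds), nrow = ng, dimnames = list(genes, NULL))
  b <- matrix(rnorm(ng * 4, sd = sds), nrow = ng, dimnames = list(genes, NULL))
  res <- moderated_test(a, b)
  expect_true(is.finite(attr(res, "d0")))
  design <- cbind(intercept = 1, groupA = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(cbind(a, b), design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, "groupA"]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, "groupA"]), tolerance = 1e-8)
})

test_that("swapping groups negates the effect and keeps p", {
  g <- rand_groups(100, 4, 6, seed = 4)
  ab <- moderated_test(g$a, g$b)
  ba <- moderated_test(g$b, g$a)
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p, ba$p)
})

test_that("moderation shrinks the null t-statistic spread at small n", {
  g <- rand_groups(500, 3, 3, seed = 5)
  mod <- moderated_test(g$a, g$b)
  plain <- moderated_test(g$a, g$b, prior_df = 0)
  expect_lt(var(mod$t_mod), var(plain$t_mod))
})

test_that("a strong single-gene effect is detected across seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    a <- matrix(rnorm(20, mean = 2, sd = 0.5), nrow = 1,
                dimnames = list("g1", NULL))
    b <- matrix(rnorm(20, mean = 0, sd = 0.5), nrow = 1,
                dimnames = list("g1", NULL))
    moderated_test(a, b)$p < 1e-6
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("group size and input validation", {
  g <- rand_groups(10, 4, 4, seed = 6)
  expect_error(moderated_test(g$a[, 1, drop = FALSE], g$b), "at least 2")
  expect_error(moderated_test(g$a[1:5, ], g$b), "aligned")
})

test_that("bh_adjust follows the step-up rule", {
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("cluster_degs recovers planted signature genes on the reference cohort", {
  fit <- default_fit()
  planted <- c(sprintf("SIGR%03d", 1:40), sprintf("SIGP%03d", 1:40))
  expect_gt(mean(planted %in% fit$degs$genes), 0.9)
})

test_that("cluster_degs is near-silent under the null", {
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    expr <- matrix(rnorm(300 * 24), nrow = 300,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("S%02d", 1:24)))
    labels <- setNames(rep(1:3, each = 8), colnames(expr))
    d <- cluster_degs(expr, labels)
    length(d$genes) / 300
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 2 * sd(frac) / sqrt(20))
})

test_that("cluster_degs validates labels and skips tiny clusters", {
  set.seed(8)
  expr <- matrix(rnorm(20 * 9), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("S%02d", 1:9)))
  expect_error(cluster_degs(expr, rep(1L, 9)), "at least 2 clusters")

  labels <- c(rep(1L, 4), rep(2L, 4), 3L)
  ## the singleton cluster 3 appears in two pairwise contrasts: two warnings
  w <- capture_warnings(d <- cluster_degs(expr, labels))
  expect_length(w, 2)
  expect_true(all(grepl("fewer than 2 samples", w)))
  expect_setequal(unique(d$table$contrast), "C1_vs_C2")

  expect_error(cluster_degs(expr, rep(1:2, length.out = 5)),
               "one label per sample")
})

test_that("one_vs_rest mode emits one contrast per cluster", {
  set.seed(9)
  expr <- matrix(rnorm(30 * 12), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("S%02d", 1:12)))
  labels <- setNames(rep(1:3, each = 4), colnames(expr))
  d <- cluster_degs(expr, labels, mode = "one_vs_rest")
  expect_setequal(unique(d$table$contrast),
                  c("C1_vs_rest", "C2_vs_rest", "C3_vs_rest"))
})
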