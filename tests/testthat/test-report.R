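test_that("crosstab matches the hand-computed chi-square", {
  a <- rep(c("x", "y"), each = 10)
  b <- rep(c("p", "q"), each = 10)
  ct <- crosstab(a, b)
  ## perfect association in a balanced 2x2 table: chi2 = n = 20
  expect_equal(ct$chi2, 20)
  expect_equal(ct$df, 1)
  expect_equal(ct$p, pchisq(20, 1, lower.tail = FALSE))
  expect_false(ct$low_expected)

  ## hand-computed 2x3 oracle: sum (O - E)^2 / E
  a2 <- c(rep("g1", 30), rep("g2", 30))
  b2 <- c(rep(c("u", "v", "w"), c(20, 5, 5)), rep(c("u", "v", "w"), c(10, 10, 10)))
  obs <- table(a2, b2)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2_hand <- sum((obs - exp_)^2 / exp_)
  ct2 <- crosstab(a2, b2)
  expect_equal(ct2$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(ct2$df, 2)
})

test_that("crosstab applies Yates correction only when asked", {
  a <- c(rep("x", 6), rep("y", 6))
  b <- c(rep("p", 4), rep("q", 2), rep("p", 2), rep("q", 4))
  plain <- crosstab(a, b)
  yates <- crosstab(a, b, correct = TRUE)
  expect_gt(plain$chi2, yates$chi2)
  expect_true(plain$low_expected)
})

test_that("crosstab rejects degenerate margins and drops missing labels", {
  expect_error(crosstab(rep("x", 10), rep(c("p", "q"), 5)), "2 non-empty")
  expect_error(crosstab(c("x", "y"), c("p")), "align")
  a <- c("x", "x", "y", "y", NA)
  b <- c("p", "q", "p", "q", "p")
  ct <- crosstab(a, b)
  expect_equal(sum(ct$observed), 4)
})

test_that("crosstab type-I error is near nominal under permutation", {
  set.seed(51)
  p_vals <- vapply(1:2000, function(i) {
    a <- sample(rep(c("x", "y"), each = 20))
    b <- sample(rep(c("p", "q"), each = 20))
    crosstab(a, b)$p
  }, numeric(1))
  rate <- mean(p_vals < 0.05)
  ## the uncorrected chi-square on a discrete 2x2 table is valid but
  ## conservative: the rejection rate must not exceed the nominal level
  ## (plus Monte Carlo error) and must not collapse to zero
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(rate, 0.005)
})

test_that("score_pathway_correlation handles exact and degenerate cases", {
  scores <- data.frame(sample_id = sprintf("S%02d", 1:10),
                       m6ascore = 1:10)
  enr <- rbind(UP = 1:10, DOWN = 10:1, FLAT = rep(0.3, 10))
  colnames(enr) <- scores$sample_id
  expect_warning(res <- score_pathway_correlation(scores, enr),
                 "zero-variance")
  expect_equal(res$set, c("DOWN", "UP"))  # sorted by increasing r
  expect_equal(res$r, c(-1, 1), tolerance = 1e-12)

  ## permuting sample columns does not change the result
  perm <- sample(colnames(enr))
  expect_warning(res2 <- score_pathway_correlation(scores, enr[, perm]))
  expect_equal(res2, res)

  expect_error(suppressWarnings(
    score_pathway_correlation(scores, enr["FLAT", , drop = FALSE])),
    "usable variance")
  expect_error(score_pathway_correlation(scores[1:2, ], enr[, 1:2]),
               "3 aligned")
})

test_that("lipid pathways correlate negatively with the m6Ascore on the reference fit", {
  fit <- default_fit()
  cors <- fit$report$correlations
  co <- default_cohort()
  lipid_sets <- names(co$categories)[co$categories == "lipid"]
  r_lipid <- cors$r[cors$set %in% lipid_sets]
  expect_equal(length(r_lipid), sum(co$categories == "lipid"))
  expect_lt(mean(r_lipid), 0)
})

test_that("response_contrast computes rates and a 2x2 test", {
  grp <- rep(c("low", "high"), each = 20)
  rsp <- c(rep(c("PR/SD", "PD"), c(5, 15)), rep(c("PR/SD", "PD"), c(15, 5)))
  out <- suppressMessages(response_contrast(grp, rsp))
  expect_equal(out$rates$rate[out$rates$group == "low"], 0.25)
  expect_equal(out$rates$rate[out$rates$group == "high"], 0.75)
  expect_s3_class(out$test, "m6a_crosstab")
  expect_lt(out$test$p, 0.05)

  ## missing responses are excluded from rates
  rsp_na <- rsp; rsp_na[1:10] <- NA
  out2 <- suppressMessages(response_contrast(grp, rsp_na))
  expect_equal(sum(out2$rates$n), 30)

  ## degenerate: all responses identical -> rates kept, test skipped
  expect_warning(out3 <- suppressMessages(
    response_contrast(grp, rep("PD", 40))), "degenerate")
  expect_null(out3$test)
  expect_true(all(out3$rates$rate == 0))

  expect_error(response_contrast(grp, rsp[1:10]), "align")
})

test_that("high-score group has the higher response rate on the reference fit", {
  fit <- default_fit()
  rates <- fit$report$response$rates
  expect_gt(rates$rate[rates$group == "high"],
            rates$rate[rates$group == "low"])
})

test_that("alluvial_table counts every path and sums to n", {
  df <- data.frame(a = c("x", "x", "y", "y", "y"),
                   b = c("p", "p", "q", "q", "p"))
  tab <- alluvial_table(df)
  expect_equal(sum(tab$n), 5)
  expect_equal(tab$n[tab$a == "x" & tab$b == "p"], 2)
  expect_equal(tab$n[tab$a == "y" & tab$b == "q"], 2)

  ## identical columns give a diagonal flow
  df2 <- data.frame(a = rep(c("1", "2"), 5), b = rep(c("1", "2"), 5))
  tab2 <- alluvial_table(df2)
  expect_equal(nrow(tab2), 2)
  expect_true(all(tab2$a == tab2$b))

  ## missing labels become an explicit level
  df3 <- data.frame(a = c("x", NA), b = c("p", "p"))
  tab3 <- alluvial_table(df3)
  expect_true("missing" %in% tab3$a)
  expect_equal(sum(tab3$n), 2)

  expect_error(alluvial_table(df["a"]), "2 label columns")
})

test_that("the reference alluvial table is coherent with the stratifications", {
  fit <- default_fit()
  tab <- fit$report$alluvial
  expect_equal(sum(tab$n), fit$n_samples)
  expect_true(all(c("m6Acluster", "score_group", "metabolic") %in% names(tab)))
  ## dominant path (marginal over any other columns) links the high-risk
  ## cluster C3, high scores, and the lipid-low subtype
  agg <- aggregate(n ~ m6Acluster + score_group + metabolic, data = tab, sum)
  top <- agg[which.max(agg$n), ]
  expect_equal(top$m6Acluster, "C3")
  expect_equal(top$score_group, "high")
  expect_equal(top$metabolic, "LML")
})
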