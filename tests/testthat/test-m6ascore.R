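sim_surv_gene <- function(n, beta, seed, base = 0.2, cmax = 10) {
  set.seed(seed)
  x <- rnorm(n)
  tt <- rexp(n, rate = base * exp(beta * x))
  cc <- runif(n, 0, cmax)
  list(expr = matrix(x, nrow = 1,
                     dimnames = list("g1", sprintf("S%04d", seq_len(n)))),
       clinical = data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                             os_time = pmin(tt, cc),
                             os_event = as.integer(tt <= cc)))
}

test_that("cox_screen is unbiased enough on null genes", {
  inside <- vapply(1:50, function(s) {
    d <- sim_surv_gene(500, beta = 0, seed = s)
    row <- cox_screen(d$expr, d$clinical)
    abs(row$log_hr) < 2 * row$se
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("cox_screen recovers a moderate effect", {
  betas <- vapply(1:10, function(s) {
    d <- sim_surv_gene(1000, beta = 0.5, seed = 100 + s)
    cox_screen(d$expr, d$clinical)$log_hr
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.5), 0.1)
})

test_that("cox_screen flags degenerate genes and warns on few events", {
  d <- sim_surv_gene(50, beta = 0, seed = 1)
  expr <- rbind(d$expr, g2 = rep(3, 50))
  rownames(expr) <- c("g1", "g2")
  res <- suppressMessages(cox_screen(expr, d$clinical))
  expect_equal(res$gene, "g1")
  expect_equal(attr(res, "flagged")$gene, "g2")
  expect_equal(attr(res, "flagged")$reason, "zero variance")

  few <- d$clinical
  few$os_event <- c(rep(1L, 5), rep(0L, 45))
  expect_warning(suppressMessages(cox_screen(d$expr, few)), "unstable")
})

test_that("signature_partition applies the HR = 1 / p < alpha rule", {
  screen <- data.frame(gene = c("A", "B", "C"),
                       hr = c(2.0, 0.5, 1.5),
                       log_hr = log(c(2.0, 0.5, 1.5)),
                       se = 0.1, p = c(0.01, 0.01, 0.5), n_used = 100)
  sig <- signature_partition(screen)
  expect_equal(sig$risk$gene, "A")
  expect_equal(sig$protective$gene, "B")

  all_ns <- transform(screen, p = 0.5)
  expect_error(signature_partition(all_ns), "no gene passed")

  unit <- data.frame(gene = c("A", "B"), hr = c(1, 2), log_hr = c(0, log(2)),
                     se = 0.1, p = c(0.01, 0.01), n_used = 100)
  expect_warning(sig2 <- signature_partition(unit), "HR exactly 1")
  expect_equal(sig2$risk$gene, "B")
  expect_equal(nrow(sig2$protective), 0L)
})

test_that("signature screen recovers planted prognostic genes", {
  fit <- default_fit()
  planted_risk <- sprintf("SIGR%03d", 1:40)
  planted_prot <- sprintf("SIGP%03d", 1:40)
  sens <- (sum(planted_risk %in% fit$signature$risk$gene) +
             sum(planted_prot %in% fit$signature$protective$gene)) / 80
  expect_gte(sens, 0.8)
})

test_that("minmax_scale maps to [-1, 1] with a frozen-bounds option", {
  m <- matrix(c(0, 5, 10), nrow = 1, dimnames = list("A", paste0("S", 1:3)))
  sc <- minmax_scale(m)
  expect_equal(unname(sc[1, ]), c(-1, 0, 1))

  cm <- matrix(4, nrow = 1, ncol = 3, dimnames = list("A", paste0("S", 1:3)))
  expect_warning(sc0 <- minmax_scale(cm), "constant")
  expect_equal(unname(sc0[1, ]), c(0, 0, 0))

  ## idempotence against the recorded bounds
  again <- minmax_scale(unclass(sc),
                        bounds = data.frame(gene = "A", min = -1, max = 1))
  expect_equal(unname(again[1, ]), unname(sc[1, ]))

  ## frozen bounds reproduce the training scale on new samples
  new <- matrix(c(2.5, 12), nrow = 1, dimnames = list("A", c("N1", "N2")))
  sc_new <- minmax_scale(new, bounds = attr(sc, "bounds"))
  expect_equal(unname(sc_new[1, ]), c(-0.5, 1.4))
})

test_that("m6Ascore ignores genes outside the partition", {
  sig <- structure(list(
    risk = data.frame(gene = "R1", hr = 2, log_hr = log(2), p = 0.01),
    protective = data.frame(gene = "P1", hr = 0.5, log_hr = log(0.5), p = 0.01),
    alpha = 0.05, bounds = NULL), class = "m6a_signature")
  set.seed(10)
  base <- matrix(rnorm(9), nrow = 3,
                 dimnames = list(c("R1", "P1", "X1"), paste0("S", 1:3)))
  with_noise <- base
  with_noise["X1", ] <- base["X1", ] + 100
  expect_equal(compute_m6ascore(base, sig)$m6ascore,
               compute_m6ascore(with_noise, sig)$m6ascore)
  expect_error(compute_m6ascore(base[3, , drop = FALSE], sig),
               "no signature gene")
})

test_that("score_groups splits at the median with ties to low", {
  sc <- data.frame(sample_id = paste0("S", 1:4), m6ascore = c(1, 2, 3, 4))
  g <- score_groups(sc)
  expect_equal(as.character(g$score_group), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutoff"), 2.5)

  tied <- data.frame(sample_id = paste0("S", 1:3), m6ascore = c(5, 5, 5))
  expect_warning(gt <- score_groups(tied), "all scores")
  expect_true(all(gt$score_group == "low"))

  set.seed(11)
  many <- data.frame(sample_id = paste0("S", 1:101), m6ascore = rnorm(101))
  gm <- score_groups(many)
  expect_lte(abs(sum(gm$score_group == "high") - sum(gm$score_group == "low")), 1)

  gn <- score_groups(sc, cutoff = 3.5)
  expect_equal(as.character(gn$score_group), c("low", "low", "low", "high"))
})

test_that("a frozen signature round-trips through its TSV and scores new data", {
  set.seed(12)
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(c("R1", "R2", "P1", "P2"), paste0("S", 1:10)))
  sig <- structure(list(
    risk = data.frame(gene = c("R1", "R2"), hr = c(2, 3), log_hr = log(c(2, 3)),
                      p = c(0.01, 0.02)),
    protective = data.frame(gene = c("P1", "P2"), hr = c(0.5, 0.4),
                            log_hr = log(c(0.5, 0.4)), p = c(0.03, 0.04)),
    alpha = 0.05, bounds = NULL), class = "m6a_signature")
  frozen <- freeze_signature(sig, expr)
  expect_error(write_signature(sig, tempfile()), "freeze")

  path <- tempfile(fileext = ".tsv")
  write_signature(frozen, path)
  back <- read_signature(path)
  set.seed(13)
  new <- matrix(rnorm(20), nrow = 4, dimnames = list(rownames(expr),
                                                     paste0("N", 1:5)))
  expect_equal(compute_m6ascore(new, back)$m6ascore,
               compute_m6ascore(new, frozen)$m6ascore, tolerance = 1e-9)
  unlink(path)
})
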