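# one-hot pair matrix over a signature's own pairs
onehot_matrix <- function(sig, hot = integer(0)) {
  ids <- paste(sig$gene_a, sig$gene_b, sep = "|")
  vals <- matrix(0L, nrow(sig), 1, dimnames = list(ids, "patient"))
  vals[hot, 1] <- 1L
  pair_matrix(vals, data.frame(gene_a = sig$gene_a, gene_b = sig$gene_b,
                               stringsAsFactors = FALSE))
}

test_that("the packaged renal-cancer signature scores one-hot patients by
           its printed coefficients", {
  sig <- kirc_signature()
  expect_identical(nrow(sig), 11L)
  expect_equal(unname(risk_score(onehot_matrix(sig), sig)), 0)
  for (k in seq_len(nrow(sig)))
    expect_equal(unname(risk_score(onehot_matrix(sig, k), sig)),
                 sig$coefficient[k])
  # all-ones patient: independently hand-summed coefficient total
  expect_equal(unname(risk_score(onehot_matrix(sig, 1:11), sig)),
               0.28703670273521753, tolerance = 1e-12)
})

test_that("risk score is linear over disjoint indicator supports", {
  sig <- kirc_signature()
  s_a <- risk_score(onehot_matrix(sig, c(1, 3, 5)), sig)
  s_b <- risk_score(onehot_matrix(sig, c(2, 8)), sig)
  s_ab <- risk_score(onehot_matrix(sig, c(1, 2, 3, 5, 8)), sig)
  expect_equal(unname(s_ab), unname(s_a + s_b))
})

test_that("scoring respects the signature's stored pair orientation", {
  sig <- irgp_signature("ZZZ", "AAA", 2.5, provenance = "toy")
  co <- expression_cohort(matrix(c(1, 9), 2, 1,
                                 dimnames = list(c("AAA", "ZZZ"), "S1")),
                          "toy", TRUE)
  # canonical matrix stores AAA|ZZZ = (1 > 9) = 0; signature wants ZZZ>AAA
  m <- build_pairs(co, c("AAA", "ZZZ"))
  expect_equal(unname(risk_score(m, sig)), 2.5)
  # direct evaluation in signature orientation agrees
  expect_equal(unname(risk_score(signature_pairs(co, sig), sig)), 2.5)
  # missing genes are named
  bad <- irgp_signature("AAA", "MISSING", 1)
  expect_error(risk_score(m, bad), "AAA\\|MISSING")
})

test_that("univariate screen controls type-I error on null pairs", {
  dat <- make_pair_survival(n = 300, n_true = 0, n_null = 400, seed = 21,
                            cens_max = 20)
  sc <- univariate_cox_screen(dat$pairs, dat$clinical, alpha = 0.001)
  expect_lte(length(sc$retained), 4L) # ~0.1% expected of 400
  expect_identical(nrow(sc$table), 400L)
})

test_that("univariate screen recovers a strong pair and reports Wald stats", {
  dat <- make_pair_survival(n = 400, n_true = 1, n_null = 10, log_hr = 0.7,
                            seed = 31, cens_max = 25)
  sc <- univariate_cox_screen(dat$pairs, dat$clinical, alpha = 0.001)
  expect_true(dat$true_ids %in% sc$retained)
  row <- sc$table[sc$table$pair == dat$true_ids, ]
  expect_equal(row$hr, exp(row$coef))
  expect_lt(row$lower95, row$hr)
  expect_gt(row$upper95, row$hr)
})

test_that("univariate log-HR covers the generating value at nominal rate", {
  hits <- 0
  for (s in 1:20) {
    dat <- make_pair_survival(n = 300, n_true = 1, n_null = 0, log_hr = 0.7,
                              seed = 100 + s, cens_max = 25)
    tab <- univariate_cox_screen(dat$pairs, dat$clinical, alpha = 1)$table
    hits <- hits + (log(tab$lower95) <= 0.7 && 0.7 <= log(tab$upper95))
  }
  expect_gte(hits, 18) # 95% CI coverage over 20 seeds
})

test_that("constant pairs are skipped with a warning, not fitted", {
  dat <- make_pair_survival(n = 50, n_true = 0, n_null = 3, seed = 5)
  dat$pairs$values[1, ] <- 1L
  expect_warning(sc <- univariate_cox_screen(dat$pairs, dat$clinical),
                 "constant pair")
  expect_identical(nrow(sc$table), 2L)
})

test_that("single screened pair yields a one-pair signature of correct sign", {
  dat <- make_pair_survival(n = 300, n_true = 1, n_null = 0, log_hr = 0.8,
                            seed = 41, cens_max = 25)
  sig <- lasso_cox_select(dat$pairs, dat$clinical, seed = 1)
  expect_identical(nrow(sig), 1L)
  expect_gt(sig$coefficient, 0)
})

test_that("LASSO selection is deterministic under a fixed seed", {
  dat <- make_pair_survival(n = 250, n_true = 3, n_null = 30, seed = 51,
                            cens_max = 20)
  a <- lasso_cox_select(dat$pairs, dat$clinical, seed = 9)
  b <- lasso_cox_select(dat$pairs, dat$clinical, seed = 9)
  expect_identical(a, b)
})

test_that("median stratification uses a strict cutoff with ties to low", {
  p <- median_stratify(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(attr(p, "cutoff"), 2.5)
  expect_identical(p$group, c("low", "low", "high", "high"))
  p2 <- median_stratify(c(5, 5, 5))
  expect_identical(unique(p2$group), "low")
  p3 <- median_stratify(c(1, 2, 3))
  expect_identical(p3$group[2], "low") # score == median -> low
})
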