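test_that("spearman matches the worked example and the Fisher-z interval", {
  res <- spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(corEstimate(res), 1 - 6 * 4 / (5 * 24))  # = 0.8 via sum d^2
  ci <- corCI(res)
  expect_equal(ci[1], tanh(atanh(0.8) - qnorm(0.975) / sqrt(2)),
               tolerance = 1e-10)
  expect_equal(ci[2], tanh(atanh(0.8) + qnorm(0.975) / sqrt(2)),
               tolerance = 1e-10)
  expect_equal(round(ci, 2), c(-0.28, 0.99))
  # two-tailed t approximation with n - 2 df
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(corPValue(res), 2 * pt(-tstat, 3))
})

test_that("perfect monotone and anti-monotone series give +/- 1", {
  expect_equal(corEstimate(spearmanCorrelation(1:3, 1:3)), 1)
  expect_equal(corEstimate(spearmanCorrelation(1:3, 3:1)), -1)
})

test_that("spearman equals the brute-force rank-Pearson oracle on all n = 5 permutations", {
  y <- 1:5
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  expect_equal(nrow(perms), 120L)
  for (i in seq_len(nrow(perms))) {
    x <- perms[i, ]
    expect_equal(corEstimate(spearmanCorrelation(x, y)),
                 rankPearsonOracle(x, y), tolerance = 1e-12)
  }
  # and with ties, against the same oracle
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    yy <- sample(1:5, 8, replace = TRUE)
    if (var(x) == 0 || var(yy) == 0) next
    expect_equal(corEstimate(spearmanCorrelation(x, yy)),
                 rankPearsonOracle(x, yy), tolerance = 1e-12)
  }
})

test_that("spearman is symmetric and invariant under monotone transforms", {
  set.seed(4)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(corEstimate(spearmanCorrelation(x, y)),
               corEstimate(spearmanCorrelation(y, x)))
  expect_equal(corEstimate(spearmanCorrelation(exp(3 * x), y)),
               corEstimate(spearmanCorrelation(x, y)))
  expect_equal(corEstimate(spearmanCorrelation(x, qlogis(plogis(y)))),
               corEstimate(spearmanCorrelation(x, y)))
})

test_that("spearman rejects degenerate input and supports exact small-sample p", {
  expect_error(spearmanCorrelation(1:2, 2:1), "3 complete")
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
  resT <- spearmanCorrelation(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  resE <- spearmanCorrelation(1:8, c(2, 1, 4, 3, 6, 5, 8, 7),
                              pMethod = "exact")
  expect_equal(corEstimate(resE), corEstimate(resT))
  ref <- cor.test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7), method = "spearman",
                  exact = TRUE)$p.value
  expect_equal(corPValue(resE), ref)
  expect_error(spearmanCorrelation(1:12, rnorm(12), pMethod = "exact"),
               "n <= 10")
})

test_that("the moderate-correlation cutoff is 0.5 in absolute value", {
  expect_true(moderateCorrelationFlag(0.5))
  expect_true(moderateCorrelationFlag(-0.6))
  expect_false(moderateCorrelationFlag(0.49))
  expect_true(moderateCorrelationFlag(spearmanCorrelation(1:4, c(1, 2, 4, 3))))
})

makeMerged <- function(n = 24, seed = 6) {
  set.seed(seed)
  acute <- runif(n)
  data.frame(
    study_id = sprintf("s%02d", 1:n),
    cns_disease = sample(c("yes", "no", "unclear"), n, replace = TRUE,
                         prob = c(0.25, 0.6, 0.15)),
    acute_composite = acute * 100 + rnorm(n, 0, 8),
    nf70_pct_area = runif(n, 5, 25),
    fiber_density = runif(n, 1000, 5000),
    serum_nfl_pg_ml = exp(log(10) + 1.5 * acute + rnorm(n, 0, 0.4)),
    tissue_nfl_pg_ml = exp(log(500) + 1.5 * acute + rnorm(n, 0, 0.4)),
    serum_csf_ratio = runif(n, 0.01, 0.1),
    serum_z = rnorm(n)
  )
}

test_that("the analysis panel crosses all variables over both subgroups", {
  merged <- makeMerged()
  panel <- runPanel(merged)
  expect_equal(nrow(panel), 4 * 3 * 2)
  all_n <- panel$n[panel$subgroup == "all"]
  expect_true(all(all_n == nrow(merged)))
  # subgroup restriction never increases n
  for (i in seq_len(nrow(panel)))
    if (panel$subgroup[i] == "no_cns") {
      twin <- panel$n[panel$subgroup == "all" &
                        panel$x_var == panel$x_var[i] &
                        panel$y_var == panel$y_var[i]]
      expect_lte(panel$n[i], twin)
    }
  # the subgroup n matches the configured CNS rule exactly
  expect_equal(unique(panel$n[panel$subgroup == "no_cns"]),
               sum(merged$cns_disease != "yes"))
  strict <- runPanel(merged, "exclude_yes_and_unclear")
  expect_equal(unique(strict$n[strict$subgroup == "no_cns"]),
               sum(merged$cns_disease == "no"))
  expect_error(runPanel(merged[, -2]), "cns_disease")
})

test_that("reports format correlations deterministically", {
  merged <- makeMerged()
  panel <- runPanel(merged)
  rep1 <- renderReport(panel)
  rep2 <- renderReport(panel)
  expect_identical(rep1, rep2)
  expect_match(rep1[1], "Spearman")

  empty <- panel[0, ]
  expect_equal(renderReport(empty), "== Spearman rank correlations ==")

  one <- data.frame(x_var = "serum_nfl", y_var = "acute_composite",
                    subgroup = "all", r = 0.8, ci_low = -0.28,
                    ci_high = 0.99, p = 0.104, n = 5L, moderate = TRUE)
  line <- renderReport(one)[2]
  expect_match(line, "r = 0.80 \\[-0.28 to 0.99\\]", fixed = FALSE)
  expect_match(line, "n = 5")
})
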