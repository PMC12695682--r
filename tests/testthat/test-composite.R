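toyComponents <- function() {
  data.frame(study_id = c("a", "b", "c"),
             degen_density = c(40, 80, 20),
             ovoid_fraction = c(0.1, 0.4, NA),
             cd68_total_pctmax = c(30, 100, 60))
}

test_that("the acute composite averages the available %max components", {
  # hand-computed: degen %max = (50, 100, 25); ovoid %max = (25, 100, NA)
  res <- acuteComposite(toyComponents())
  expect_equal(res$acute_composite,
               c(mean(c(50, 25, 30)), mean(c(100, 100, 100)),
                 mean(c(25, 60))))
  expect_equal(res$n_components, c(3L, 3L, 2L))

  # worked examples on explicit %max values
  flat <- data.frame(study_id = c("p", "q"),
                     degen_density = c(50, 100),
                     ovoid_fraction = c(1, 1),
                     cd68_total_pctmax = c(30, 100))
  r <- acuteComposite(flat)
  expect_equal(r$acute_composite[1], mean(c(50, 100, 30)))
  # the patient holding every dataset maximum scores exactly 100
  expect_equal(r$acute_composite[2], 100)
})

test_that("a missing ovoid component averages the remaining two", {
  comp <- data.frame(study_id = c("a", "b"),
                     degen_density = c(50, 100),
                     ovoid_fraction = c(NA_real_, NA_real_),
                     cd68_total_pctmax = c(100, 40))
  res <- acuteComposite(comp)
  expect_equal(res$acute_composite, c(mean(c(50, 100)), mean(c(100, 40))))
  expect_true(all(res$n_components == 2L))
})

test_that("the composite is invariant to rescaling the raw densities", {
  base <- acuteComposite(toyComponents())
  for (c0 in c(0.5, 3, 117)) {
    scaled <- toyComponents()
    scaled$degen_density <- scaled$degen_density * c0
    expect_equal(acuteComposite(scaled)$acute_composite,
                 base$acute_composite)
  }
})

test_that("the composite is bounded by its component extremes and maxima map to 100", {
  set.seed(31)
  comp <- data.frame(study_id = sprintf("s%d", 1:20),
                     degen_density = runif(20, 0, 300),
                     ovoid_fraction = runif(20),
                     cd68_total_pctmax = runif(20, 0, 100))
  res <- acuteComposite(comp)
  mat <- cbind(res$degen_pctmax, res$ovoid_pctmax, res$cd68_pctmax)
  expect_true(all(res$acute_composite >= apply(mat, 1, min) - 1e-9))
  expect_true(all(res$acute_composite <= apply(mat, 1, max) + 1e-9))
  expect_equal(sum(res$degen_pctmax == 100), 1L)
  expect_equal(sum(res$ovoid_pctmax == 100), 1L)
})

test_that("patients with fewer than two components get no score, with warning", {
  comp <- data.frame(study_id = c("a", "b"),
                     degen_density = c(10, NA),
                     ovoid_fraction = c(0.5, NA),
                     cd68_total_pctmax = c(50, 20))
  expect_warning(res <- acuteComposite(comp), "< 2 available")
  expect_true(is.na(res$acute_composite[2]))
  expect_false(is.na(res$acute_composite[1]))
})

test_that("component cross-correlation reports each pair on complete pairs", {
  set.seed(5)
  n <- 20
  acute <- runif(n)
  comp <- data.frame(study_id = sprintf("s%d", 1:n),
                     degen_density = acute * 100 + rnorm(n, 0, 5),
                     ovoid_fraction = acute + rnorm(n, 0, 0.05),
                     cd68_total_pctmax = acute * 80 + rnorm(n, 0, 4))
  cc <- componentCrossCorrelation(comp)
  expect_equal(nrow(cc), 3L)
  expect_true(all(cc$r > 0))
  # a duplicated component correlates perfectly with itself
  dup <- comp; dup$ovoid_fraction <- dup$degen_density
  cc2 <- componentCrossCorrelation(dup)
  expect_equal(cc2$r[cc2$var1 == "degen_density" &
                       cc2$var2 == "ovoid_fraction"], 1)
  # an anti-monotone pair gives -1
  anti <- comp; anti$ovoid_fraction <- -dup$degen_density
  cc3 <- componentCrossCorrelation(anti)
  expect_equal(cc3$r[cc3$var1 == "degen_density" &
                       cc3$var2 == "ovoid_fraction"], -1)
  # insufficient overlap yields an annotated NA cell
  sparse <- comp
  sparse$ovoid_fraction[3:n] <- NA
  cc4 <- componentCrossCorrelation(sparse)
  row <- cc4[cc4$var1 == "degen_density" & cc4$var2 == "ovoid_fraction", ]
  expect_true(is.na(row$r))
  expect_equal(row$n, 2)
})

test_that("chronic parameters stay two separate labelled series", {
  out <- chronicParameters(c("a", "b"), c(12.3, NA), c(5200, 4100))
  expect_equal(sort(unique(out$parameter)),
               c("fiber_density", "nf70_pct_area"))
  expect_equal(out$value[out$parameter == "nf70_pct_area"], 12.3)
  expect_equal(nrow(out), 3L)   # the missing NF70 value is dropped
  expect_lte(nrow(out), 2 * 2)
})
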