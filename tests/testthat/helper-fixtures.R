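# Shared test helpers: an independent rank-Pearson oracle and small
# geometric fixtures built in code.

# brute-force Spearman oracle: average ranks computed explicitly, Pearson
# correlation written out as sums (independent of stats::cor)
rankPearsonOracle <- function(x, y) {
  avgRank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  dx <- rx - sum(rx) / length(rx)
  dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# axis-aligned rectangle ROI, 0-based pixel corners
rectRoi <- function(x0, y0, x1, y1, label = "R", usable = TRUE) {
  FascicleROI(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
              label = label, usable = usable)
}

# cohort fixture path
table1Path <- function() {
  system.file("extdata", "cohort_table1.csv", package = "nflaxon")
}
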