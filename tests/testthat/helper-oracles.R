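## Independent naive oracles and shared fixtures for the test-suite.

## Printed reference cells of the worked example's accuracy table
## (position-sorted order rs00005, rs00002, rs00007, rs00006).
worked_example_expected <- data.frame(
  SNP_no = c("5", "2", "7", "6"),
  SNP = c("rs00005", "rs00002", "rs00007", "rs00006"),
  position = c(221, 402, 518, 955),
  N = c(5L, 5L, 5L, 5L),
  maf = c("26.0", "49.5", "40.3", "26.1"),
  iam_chance = c("0.546", "0.97", "0.344", "0.446"),
  iam_hwe = c("0.448", "0.968", "0.289", "0.326"),
  hiq = c("0.739", "0.929", "0.72", "0.963"),
  accuracy = c("HOT", "TEPID", "HOT", "HOT"),
  info = c("0.099", "0.98", "-0.057", "-0.056"),
  r2_mach = c("0.319", "0.0", "0.631", "0.488"),
  r2_beagle = c("0.113", "-97", "0.294", "0.179"),
  stringsAsFactors = FALSE)

## Naive two-pass MACH r2: explicit mean then explicit sum of squares,
## written without reusing any package helper.
oracle_mach_r2 <- function(triplets) {
  m <- triplets[stats::complete.cases(triplets), , drop = FALSE]
  w <- m[, 2] + 2 * m[, 3]
  n <- length(w)
  theta <- sum(w) / (2 * n)
  if (theta <= 0 || theta >= 1 || n < 2) return(NA_real_)
  mu <- sum(w) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (w[i] - mu)^2
  (ss / n) / (2 * theta * (1 - theta))
}

## Naive two-pass Beagle allelic r2 with the pooled "true dose" variance
## term computed explicitly from the second moments.
oracle_beagle_r2 <- function(triplets) {
  m <- triplets[stats::complete.cases(triplets), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  w <- m[, 2] + 2 * m[, 3]
  v <- m[, 2] + 4 * m[, 3]
  z <- numeric(n)
  for (i in seq_len(n)) z[i] <- which.max(m[i, ]) - 1  # first max
  mz <- sum(z) / n; mw <- sum(w) / n
  cz <- 0; vz <- 0
  for (i in seq_len(n)) {
    cz <- cz + (z[i] - mz) * (w[i] - mw)
    vz <- vz + (z[i] - mz)^2
  }
  cz <- cz / n; vz <- vz / n
  vt <- sum(v) / n - mw^2
  if (vz <= 0 || vt <= 0) return(NA_real_)
  cz^2 / (vz * vt)
}

## Random posterior matrix on the simplex (Dirichlet-ish via normalization).
random_triplets <- function(n) {
  x <- matrix(stats::rexp(3 * n), n, 3)
  x / rowSums(x)
}

## Parse an accuracy table written by the package back into a
## character matrix (header stripped).
read_accuracy_file <- function(path) {
  ln <- readLines(path)
  do.call(rbind, strsplit(ln[-1], "\t", fixed = TRUE))
}
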