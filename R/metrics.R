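#' Per-marker dosage moments
#'
#' Computes the shared building blocks for all accuracy indices from one
#' marker's a-posteriori genotype probabilities: the expected allele dosage
#' `w = p1 + 2*p2`, its second moment `v = p1 + 4*p2`, the best-guess
#' genotype `z` (argmax of the triplet, ties resolved toward the smaller
#' genotype), the counted-allele frequency estimate
#' `theta_hat = sum(w) / (2 * n)` and the folded minor-allele frequency in
#' percent.
#'
#' @param triplets Numeric matrix with one row per sample and three columns
#'   holding the probabilities of genotypes 0, 1 and 2.  Rows with any `NA`
#'   are treated as missing imputations and dropped from all moments.
#' @return A list of class `"marker_stats"` with elements `n_used`, `w`,
#'   `v`, `z`, `theta_hat` and `maf_pct`.  When no sample is usable,
#'   `n_used` is 0 and the remaining elements are empty/`NA`.
#' @examples
#' m <- rbind(c(0.47, 0.18, 0.35), c(0.89, 0.02, 0.09))
#' s <- marker_stats(m)
#' s$w  # expected dosages 0.88 and 0.20
#' @export
marker_stats <- function(triplets) {
  triplets <- as.matrix(triplets)
  if (ncol(triplets) != 3L)
    stop("'triplets' must have exactly 3 columns (genotypes 0, 1, 2)")
  keep <- stats::complete.cases(triplets)
  m <- triplets[keep, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L) {
    return(structure(list(n_used = 0L, w = numeric(0), v = numeric(0),
                          z = integer(0), theta_hat = NA_real_,
                          maf_pct = NA_real_, triplets = m),
                     class = "marker_stats"))
  }
  w <- m[, 2L] + 2 * m[, 3L]
  v <- m[, 2L] + 4 * m[, 3L]
  ## ties.method = "first" resolves argmax ties toward genotype 0 < 1 < 2
  z <- max.col(m, ties.method = "first") - 1L
  theta <- sum(w) / (2 * n)
  structure(list(n_used = n, w = w, v = v, z = z, theta_hat = theta,
                 maf_pct = 100 * min(theta, 1 - theta), triplets = m),
            class = "marker_stats")
}

#' IMPUTE2-style info score
#'
#' Fraction of the statistical information about the allele frequency that
#' survives imputation:
#' `info = 1 - sum(v - w^2) / (2 * n * theta * (1 - theta))`.
#' Perfectly certain genotype probabilities give 1; values near or below 0
#' mean the dosages carry essentially no frequency information.
#'
#' @param stats A `"marker_stats"` object from [marker_stats()].
#' @return A single number (never above 1, may be negative), or `NA` for a
#'   monomorphic marker (`theta_hat` 0 or 1) or when no samples are usable.
#' @export
impute_info <- function(stats) {
  if (stats$n_used < 1L || is.na(stats$theta_hat)) return(NA_real_)
  th <- stats$theta_hat
  denom <- 2 * stats$n_used * th * (1 - th)
  if (denom <= 0) return(NA_real_)
  1 - sum(stats$v - stats$w^2) / denom
}

#' MACH r-squared
#'
#' Ratio of the population variance (1/n denominator) of the expected
#' dosages to the binomial variance implied by the estimated allele
#' frequency: `Var(w) / (2 * theta * (1 - theta))`.  Its square root scales
#' the effective power of an allelic association test.
#'
#' @inheritParams impute_info
#' @return A non-negative number, or `NA` for a monomorphic marker or
#'   `n_used < 2`.
#' @export
mach_r2 <- function(stats) {
  if (stats$n_used < 2L || is.na(stats$theta_hat)) return(NA_real_)
  th <- stats$theta_hat
  denom <- 2 * th * (1 - th)
  if (denom <= 0) return(NA_real_)
  pop_var(stats$w) / denom
}

#' Beagle allelic r-squared
#'
#' Squared correlation between the best-guess genotype `z` and the true
#' (unobserved) genotype, estimated as
#' `Cov(z, w)^2 / (Var(z) * (mean(v) - mean(w)^2))` with population (1/n)
#' moments; the second factor of the denominator is the variance of a
#' genotype drawn from the pooled posterior ("true-dose" variance).
#'
#' @inheritParams impute_info
#' @return A number in `[0, 1]`, or `NA` when the best-guess genotypes are
#'   constant or the true-dose variance is zero.
#' @export
beagle_r2 <- function(stats) {
  if (stats$n_used < 2L) return(NA_real_)
  z <- as.numeric(stats$z)
  w <- stats$w
  vz <- pop_var(z)
  vt <- mean(stats$v) - mean(w)^2
  if (vz <= 0 || vt <= 0) return(NA_real_)
  cz <- mean((z - mean(z)) * (w - mean(w)))
  cz^2 / (vz * vt)
}

## population (1/n) variance
pop_var <- function(x) mean((x - mean(x))^2)

#' Anchor distributions for the Iam indices
#'
#' The Iam pair measures how concentrated the posterior triplets are
#' relative to an "anchor" genotype distribution: either pure chance
#' (1/3, 1/3, 1/3) or Hardy-Weinberg proportions at the marker's estimated
#' allele frequency.
#'
#' @param theta Counted-allele frequency in `[0, 1]`.
#' @return Numeric vector of length 3 (probabilities of genotypes 0, 1, 2).
#' @export
hwe_anchor <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1)
  c((1 - theta)^2, 2 * theta * (1 - theta), theta^2)
}

#' @rdname hwe_anchor
#' @export
chance_anchor <- function() rep(1 / 3, 3)

## Shared Iam construction: one minus the ratio of the mean Gini-Simpson
## diversity of the individual posteriors to the diversity of the anchor.
## For q = anchor probabilities, sum(q*(1-q)) = 1 - sum(q^2); identically
## for each posterior triplet.  Equals the normalized mean squared
## Euclidean distance to the uniform anchor when the anchor is (1/3)^3.
iam_index <- function(triplets, anchor) {
  m <- triplets[stats::complete.cases(triplets), , drop = FALSE]
  if (nrow(m) == 0L) return(NA_real_)
  anchor_div <- 1 - sum(anchor^2)
  if (anchor_div <= 0) return(NA_real_)
  mean_div <- mean(1 - rowSums(m^2))
  1 - mean_div / anchor_div
}

#' Iam accuracy indices
#'
#' `iam_chance()` and `iam_hwe()` quantify the share of the anchor
#' distribution's genotype uncertainty that imputation has resolved into
#' individual-specific information:
#' `Iam = 1 - mean_i(1 - sum_g p_gi^2) / (1 - sum_g a_g^2)`,
#' where `a` is the anchor.  With the uniform chance anchor this reduces to
#' the mean squared Euclidean distance of the triplets from (1/3, 1/3, 1/3)
#' divided by 2/3, so it is 0 for uniformly uninformative posteriors and 1
#' for fully certain ones.  The HWE anchor instead credits only information
#' beyond what the population allele frequency already provides.
#' The recommended filtering threshold for both is 0.47.
#'
#' @param triplets Numeric matrix of posterior triplets (rows = samples).
#' @param theta Counted-allele frequency used to build the HWE anchor;
#'   defaults to the estimate from the triplets themselves.
#' @return A number in `[0, 1]`, or `NA` when no samples are usable
#'   (`iam_hwe` additionally when `theta` is 0 or 1, which degenerates the
#'   anchor).
#' @export
iam_chance <- function(triplets) {
  iam_index(as.matrix(triplets), chance_anchor())
}

#' @rdname iam_chance
#' @export
iam_hwe <- function(triplets, theta = NULL) {
  m <- as.matrix(triplets)
  if (is.null(theta)) theta <- marker_stats(m)$theta_hat
  if (is.na(theta) || theta <= 0 || theta >= 1) return(NA_real_)
  iam_index(m, hwe_anchor(theta))
}

#' hiQ dosage-heterogeneity index
#'
#' Complements the Iam pair by asking whether the dosages are heterogeneous
#' enough across samples to support statistical inference.  hiQ is the
#' between-individual share of the total variance of a genotype drawn from
#' the pooled posteriors:
#' `hiQ = Var(w) / (mean(v) - mean(w)^2)` with population (1/n) moments --
#' an intraclass correlation of the dosage signal.  It is 1 when every
#' posterior is certain and the dosages vary (all variation is real
#' between-individual signal), and 0 when all dosages are equal (any
#' remaining variation is within-individual imputation noise).  Values
#' below the recommended threshold 0.97 flag dosages too similar, relative
#' to their uncertainty, for association testing.
#'
#' @inheritParams iam_chance
#' @return A number in `[0, 1]`, or `NA` when fewer than 2 samples are
#'   usable or the pooled-draw variance is zero (fully degenerate
#'   monomorphic marker).
#' @export
hiq <- function(triplets, theta = NULL) {
  m <- as.matrix(triplets)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) return(NA_real_)
  w <- m[, 2L] + 2 * m[, 3L]
  v <- m[, 2L] + 4 * m[, 3L]
  tot <- mean(v) - mean(w)^2
  if (tot <= 0) return(NA_real_)
  pop_var(w) / tot
}
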