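we_triplets <- list(
  rs00005 = rbind(c(0.47, 0.18, 0.35), c(0.89, 0.02, 0.09),
                  c(0.03, 0.96, 0.01), c(0.94, 0.00, 0.06),
                  c(0.62, 0.34, 0.04)),
  rs00002 = matrix(rep(c(0.01, 0.99, 0), 5), 5, 3, byrow = TRUE))

test_that("marker moments: dosage, second moment, best guess, MAF", {
  s <- marker_stats(rbind(c(0.47, 0.18, 0.35)))
  expect_equal(s$w, 0.88)
  expect_equal(s$v, 1.58)
  expect_equal(s$z, 0L)                     # argmax
  s5 <- marker_stats(we_triplets$rs00005)
  expect_equal(s5$theta_hat, 0.26)
  expect_equal(s5$maf_pct, 26.0)
  ## ties break toward the smaller genotype
  expect_equal(marker_stats(rbind(c(0.4, 0.4, 0.2)))$z, 0L)
  expect_equal(marker_stats(rbind(c(0.2, 0.4, 0.4)))$z, 1L)
  ## monomorphic marker
  sm <- marker_stats(matrix(rep(c(1, 0, 0), 3), 3, 3, byrow = TRUE))
  expect_equal(sm$theta_hat, 0)
  expect_equal(sm$maf_pct, 0)
  ## no usable samples
  s0 <- marker_stats(matrix(NA_real_, 2, 3))
  expect_equal(s0$n_used, 0L)
  expect_true(is.na(s0$theta_hat))
})

test_that("info is 1 for degenerate posteriors and 0 at the HWE anchor", {
  ## degenerate at true genotypes, polymorphic
  m <- diag(3)[c(1, 1, 2, 3, 2), ]
  expect_equal(impute_info(marker_stats(m)), 1)
  ## every posterior equal to HWE(theta): info exactly 0
  for (theta in c(0.1, 0.3, 0.48)) {
    a <- hwe_anchor(theta)
    m <- matrix(a, 50, 3, byrow = TRUE)
    expect_equal(impute_info(marker_stats(m)), 0, tolerance = 1e-12)
  }
  ## monomorphic -> undefined
  mono <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  expect_true(is.na(impute_info(marker_stats(mono))))
})

test_that("MACH r2 is 0 for constant dosages and undefined when monomorphic", {
  s2 <- marker_stats(we_triplets$rs00002)
  expect_equal(mach_r2(s2), 0)
  mono <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  expect_true(is.na(mach_r2(marker_stats(mono))))
  ## HWE-anchor posteriors: all w identical -> 0
  a <- matrix(hwe_anchor(0.3), 20, 3, byrow = TRUE)
  expect_equal(mach_r2(marker_stats(a)), 0)
})

test_that("Beagle r2 is 1 for perfect imputation and sentinel when degenerate", {
  m <- diag(3)[c(1, 2, 1, 3, 2, 1), ]
  expect_equal(beagle_r2(marker_stats(m)), 1)
  expect_true(is.na(beagle_r2(marker_stats(we_triplets$rs00002))))  # constant z
  a <- matrix(hwe_anchor(0.3), 20, 3, byrow = TRUE)
  expect_true(is.na(beagle_r2(marker_stats(a))))
})

test_that("MACH and Beagle r2 match naive two-pass oracles on random markers", {
  set.seed(42)
  for (k in seq_len(1000)) {
    m <- random_triplets(sample(3:20, 1))
    s <- marker_stats(m)
    expect_equal(mach_r2(s), oracle_mach_r2(m), tolerance = 1e-10)
    b1 <- beagle_r2(s); b2 <- oracle_beagle_r2(m)
    if (is.na(b2)) expect_true(is.na(b1))
    else expect_equal(b1, b2, tolerance = 1e-10)
  }
})

test_that("Iam endpoints: uniform posteriors give 0, degenerate give 1", {
  u <- matrix(1 / 3, 10, 3)
  expect_equal(iam_chance(u), 0)
  d <- diag(3)[c(1, 2, 3, 1, 2), ]
  expect_equal(iam_chance(d), 1)
  ## all posteriors at the HWE anchor: Iam_HWE exactly 0
  for (theta in c(0.2, 0.26, 0.45)) {
    a <- matrix(hwe_anchor(theta), 15, 3, byrow = TRUE)
    expect_equal(iam_hwe(a, theta), 0, tolerance = 1e-12)
  }
  ## degenerate anchor -> undefined
  expect_true(is.na(iam_hwe(d, 0)))
})

test_that("chance-anchor blur gives iam_chance = lambda^2 exactly", {
  for (lam in c(0, 0.25, 0.5, 1)) {
    spec <- sim_spec(n_samples = 40, theta = 0.3, lam = lam,
                     anchor = "chance", n_markers = 3, seed = 9)
    for (rec in simulate_markers(spec))
      expect_equal(iam_chance(rec$triplets), lam^2, tolerance = 1e-9)
  }
})

test_that("hiQ is the between-individual share of dosage-draw variance", {
  ## degenerate posteriors with variable genotypes: all signal
  d <- diag(3)[c(1, 2, 1, 3), ]
  expect_equal(hiq(d), 1)
  ## identical dosages: no between-individual signal
  expect_equal(hiq(we_triplets$rs00002), 0)
  ## anchor-blur at lam = 0: dosages constant at the anchor mean
  a <- matrix(hwe_anchor(0.3), 25, 3, byrow = TRUE)
  expect_equal(hiq(a), 0)
  ## fully certain monomorphic marker: zero total variance -> undefined
  mono <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  expect_true(is.na(hiq(mono)))
  ## bounded in [0, 1]
  set.seed(7)
  for (k in 1:200) {
    q <- hiq(random_triplets(sample(2:15, 1)))
    if (!is.na(q)) expect_true(q >= 0 && q <= 1)
  }
})

test_that("allele-orientation flip leaves the shared indices unchanged", {
  set.seed(13)
  for (k in seq_len(200)) {
    m <- random_triplets(sample(3:15, 1))
    f <- m[, 3:1]
    s <- marker_stats(m); sf <- marker_stats(f)
    expect_equal(sf$maf_pct, s$maf_pct, tolerance = 1e-9)
    expect_equal(impute_info(sf), impute_info(s), tolerance = 1e-9)
    expect_equal(mach_r2(sf), mach_r2(s), tolerance = 1e-9)
    expect_equal(iam_chance(f), iam_chance(m), tolerance = 1e-9)
    bf <- beagle_r2(sf); b <- beagle_r2(s)
    if (is.na(b)) expect_true(is.na(bf))
    else expect_equal(bf, b, tolerance = 1e-12)
  }
})

test_that("all indices are invariant under sample permutation", {
  set.seed(14)
  for (k in seq_len(50)) {
    m <- random_triplets(10)
    p <- m[sample(10), ]
    expect_equal(iam_chance(p), iam_chance(m), tolerance = 1e-12)
    expect_equal(iam_hwe(p), iam_hwe(m), tolerance = 1e-12)
    expect_equal(hiq(p), hiq(m), tolerance = 1e-12)
    s <- marker_stats(m); sp <- marker_stats(p)
    expect_equal(impute_info(sp), impute_info(s), tolerance = 1e-12)
    expect_equal(mach_r2(sp), mach_r2(s), tolerance = 1e-12)
    expect_equal(beagle_r2(sp), beagle_r2(s), tolerance = 1e-12)
  }
})

test_that("moment bounds hold on random posteriors", {
  set.seed(15)
  for (k in seq_len(100)) {
    m <- random_triplets(sample(2:20, 1))
    s <- marker_stats(m)
    expect_true(all(s$w >= 0 & s$w <= 2))
    expect_true(all(s$v >= s$w^2 - 1e-12))          # Jensen
    expect_true(all(s$v <= 2 * s$w + 1e-12))        # support {0,1,2}
    expect_true(s$maf_pct >= 0 && s$maf_pct <= 50)
    expect_true(impute_info(s) <= 1 + 1e-12)
    b <- beagle_r2(s)
    if (!is.na(b)) expect_true(b >= 0 && b <= 1 + 1e-12)
    ic <- iam_chance(m)
    expect_true(ic >= 0 && ic <= 1 + 1e-12)
  }
})

test_that("mean info, MACH r2 and iam_chance increase with blur fidelity", {
  lams <- c(0.2, 0.5, 0.8)
  means <- sapply(lams, function(lam) {
    spec <- sim_spec(n_samples = 100, theta = 0.3, lam = lam,
                     anchor = "hwe", n_markers = 200, seed = 2024)
    vals <- sapply(simulate_markers(spec), function(r) {
      s <- marker_stats(r$triplets)
      c(info = impute_info(s), mach = mach_r2(s), iamc = iam_chance(r$triplets))
    })
    rowMeans(vals, na.rm = TRUE)
  })
  for (row in rownames(means))
    expect_true(!is.unsorted(means[row, ]),
                label = paste("mean", row, "nondecreasing in lambda"))
})
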