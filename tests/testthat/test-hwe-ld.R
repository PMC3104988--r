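test_that("het_stats matches plug-in formulas", {
  d <- make_pop(list(L1 = rep("001/002", 10)))
  hs <- het_stats(d)
  expect_equal(hs$per_locus$Ho, 1)
  expect_equal(hs$per_locus$He, (20 / 19) * 0.5)
  dm <- make_pop(list(L1 = rep("001/001", 10)))
  hsm <- het_stats(dm)
  expect_equal(hsm$per_locus$Ho, 0)
  expect_equal(hsm$per_locus$He, 0)
  # large HWE sample: Ho close to He, Fis near 0
  sim <- simulate_cyclic(population_spec("cyclic", n = 500, n_loci = 4,
                                         seed = 8))
  hh <- het_stats(sim$dataset)
  expect_lt(abs(hh$overall[["Ho"]] - hh$overall[["He"]]), 0.05)
  expect_lt(abs(fis_wc(sim$dataset)$multilocus), 0.05)
})

test_that("fis_wc hits the fixed-heterozygote and HW-exact anchors", {
  d <- make_fixed_het_pop(n = 12, n_loci = 3)
  f <- fis_wc(d)
  expect_equal(f$multilocus, -1)
  expect_equal(f$per_locus$fis, rep(-1, 3))
  # genotype counts exactly at HW proportions: the Weir-Cockerham
  # single-sample estimator equals 1/(2n-1), i.e. 0 up to O(1/n)
  n <- 100
  d2 <- make_pop(list(L1 = c(rep("001/001", 25), rep("001/002", 50),
                             rep("002/002", 25))))
  expect_equal(fis_wc(d2)$multilocus, 1 / (2 * n - 1), tolerance = 1e-12)
  # monomorphic loci are skipped and flagged
  d3 <- make_pop(list(L1 = rep("001/002", 6), L2 = rep("001/001", 6)))
  f3 <- fis_wc(d3)
  expect_true(f3$per_locus$monomorphic[2])
  expect_equal(f3$multilocus, -1)
})

test_that("fis_wc recovers a true inbreeding coefficient", {
  sim <- simulate_cyclic(population_spec("cyclic", n = 200, n_loci = 8,
                                         F = 0.2, seed = 31))
  expect_lt(abs(fis_wc(sim$dataset)$multilocus - 0.2), 0.07)
})

test_that("fis permutation test: maximal excess and null-under-null", {
  d <- make_fixed_het_pop(n = 15, n_loci = 4)
  tr <- fis_permutation_test(d, n_perm = 500, seed = 3)
  expect_equal(tr$statistic, -1)
  expect_equal(tr$p_value, 1 / 501)
  # all loci monomorphic -> NA
  dm <- make_pop(list(L1 = rep("001/001", 5)))
  expect_true(is.na(fis_permutation_test(dm, n_perm = 100)$p_value))
  # same seed is bit-reproducible
  sim <- simulate_cyclic(population_spec("cyclic", n = 25, seed = 17))
  t1 <- fis_permutation_test(sim$dataset, n_perm = 200, seed = 5)
  t2 <- fis_permutation_test(sim$dataset, n_perm = 200, seed = 5)
  expect_identical(t1$p_value, t2$p_value)
})

test_that("hwe_score_test agrees with complete enumeration (all-AB table)", {
  a1 <- rep("A", 5); a2 <- rep("B", 5)
  # the conditional distribution over the 3 attainable tables puts mass
  # P(H = 5) = (32/120) / (32/120 + 8/6 + 1/2) = 0.126984... on the
  # observed (maximally heterozygous) table; with ties counted half the
  # excess mid-p is 0.126984/2 and the deficiency mid-p its complement
  pe <- oracle_hwe_exact_p(a1, a2, "excess")
  expect_equal(pe, 0.126984126984127 / 2, tolerance = 1e-12)
  tr <- hwe_score_test(a1, a2, "excess", dememorization = 2000,
                       batches = 50, iters_per_batch = 2000, seed = 4)
  expect_lt(abs(tr$p_value - pe), 3 * tr$se)
  trd <- hwe_score_test(a1, a2, "deficiency", dememorization = 2000,
                        batches = 50, iters_per_batch = 2000, seed = 4)
  expect_equal(trd$p_value + tr$p_value, 1.0, tolerance = 1e-12)
  expect_lt(abs(trd$p_value - oracle_hwe_exact_p(a1, a2, "deficiency")),
            3 * trd$se)
  expect_true(is.na(hwe_score_test(rep("A", 4), rep("A", 4))$p_value))
  expect_error(hwe_score_test(a1, a2, batches = 2), "minimum")
})

test_that("hwe_score_test matches enumeration on random small tables", {
  set.seed(99)
  for (case in 1:5) {
    n <- sample(4:10, 1)
    k <- sample(2:3, 1)
    repeat {
      g1 <- sample(LETTERS[1:k], n, TRUE)
      g2 <- sample(LETTERS[1:k], n, TRUE)
      if (length(unique(c(g1, g2))) >= 2) break
    }
    for (tail in c("excess", "deficiency")) {
      pe <- oracle_hwe_exact_p(g1, g2, tail)
      tr <- hwe_score_test(g1, g2, tail, dememorization = 2000,
                           batches = 40, iters_per_batch = 2000,
                           seed = case)
      expect_lt(abs(tr$p_value - pe), 3 * tr$se + 1e-9)
    }
  }
})

test_that("multilocus_hwe combines per-locus p-values by Fisher's method", {
  sim <- simulate_cyclic(population_spec("cyclic", n = 25, n_loci = 4,
                                         seed = 12))
  res <- multilocus_hwe(sim$dataset, dememorization = 1000, batches = 20,
                        iters_per_batch = 500, seed = 2)
  for (tl in c("excess", "deficiency")) {
    per <- res$per_locus[res$per_locus$tail == tl, ]
    ps <- pmax(per$p[!is.na(per$p)], 1 / (20 * 500 + 1))
    expect_equal(
      res$combined$p_fisher[res$combined$tail == tl],
      pchisq(-2 * sum(log(ps)), df = 2 * length(ps), lower.tail = FALSE),
      tolerance = 1e-12)
  }
  # Bonferroni family = populations x 2 tails
  expect_equal(res$combined$p_bonferroni,
               pmin(1, res$combined$p_fisher * 2))
  # fixed-het clones: excess overwhelmingly significant
  d <- make_fixed_het_pop(n = 20, n_loci = 4)
  r2 <- multilocus_hwe(d, dememorization = 1000, batches = 20,
                       iters_per_batch = 500, seed = 3)
  expect_lt(r2$combined$p_bonferroni[r2$combined$tail == "excess"], 0.001)
})

test_that("rbar_d: perfect association, relabeling invariance, bounds", {
  sim <- simulate_cyclic(population_spec("cyclic", n = 20, n_loci = 1,
                                         alleles_range = c(4, 4),
                                         seed = 14))
  d <- sim$dataset
  # duplicate the locus -> perfect linkage, statistic exactly 1
  dd <- genotype_dataset(d$individuals, unname(d$populations),
                         c("L1", "L2"), cbind(d$a1, d$a1),
                         cbind(d$a2, d$a2))
  tr <- rbar_d(dd, n_perm = 100, seed = 1)
  expect_equal(tr$statistic, 1, tolerance = 1e-12)
  # relabeling alleles leaves the statistic unchanged
  relab <- function(x) chartr("123456789", "987654321", x)
  dr <- genotype_dataset(dd$individuals, unname(dd$populations), dd$loci,
                         relab(dd$a1), relab(dd$a2))
  expect_equal(rbar_d(dr, n_perm = 50, seed = 1)$statistic, tr$statistic,
               tolerance = 1e-12)
  # monomorphic locus excluded with warning; < 2 usable loci -> NA
  dm <- genotype_dataset(d$individuals, unname(d$populations),
                         c("L1", "L2"), cbind(d$a1, "001"),
                         cbind(d$a2, "001"))
  expect_warning(trm <- rbar_d(dm, n_perm = 50, seed = 1),
                 "zero distance variance")
  expect_true(is.na(trm$p_value))
})

test_that("clone correction removes the clonal linkage signal", {
  set.seed(6)
  mixed <- simulate_mixed(population_spec("mixed", n = 32,
                                          asexual_fraction = 0.65,
                                          n_clones = 1, seed = 23))
  d <- mixed$dataset
  raw <- rbar_d(d, n_perm = 400, seed = 2)
  cc <- rbar_d(d, n_perm = 400, seed = 2, clone_correct = TRUE)
  expect_lt(raw$p_value, 0.01)
  expect_gt(cc$p_value, 0.05)
  expect_lt(cc$n_used, raw$n_used)
})

test_that("resampling tests are bit-reproducible given a seed", {
  sim <- simulate_cyclic(population_spec("cyclic", n = 18, seed = 44))
  a <- rbar_d(sim$dataset, n_perm = 100, seed = 9)
  b <- rbar_d(sim$dataset, n_perm = 100, seed = 9)
  expect_identical(a$p_value, b$p_value)
  h1 <- hwe_score_test(sim$dataset$a1[, 1], sim$dataset$a2[, 1],
                       batches = 20, iters_per_batch = 500,
                       dememorization = 500, seed = 10)
  h2 <- hwe_score_test(sim$dataset$a1[, 1], sim$dataset$a2[, 1],
                       batches = 20, iters_per_batch = 500,
                       dememorization = 500, seed = 10)
  expect_identical(h1$p_value, h2$p_value)
})
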