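test_that("partition_mlmg groups strictly identical genotypes", {
  # all identical
  d <- make_fixed_het_pop(n = 8)
  p <- partition_mlmg(d)
  expect_identical(as.integer(p$G), 1L)
  # all distinct
  d2 <- make_pop(list(L1 = sprintf("%03d/%03d", 1:6, 1:6)))
  p2 <- partition_mlmg(d2)
  expect_identical(as.integer(p2$G), 6L)
  expect_equal(unname(genotypic_richness(p2)), 1)
  # unordered pairs: AB == BA
  d3 <- genotype_dataset(c("x", "y"), c("p", "p"), "L1",
                         a1 = matrix(c("02", "01")),
                         a2 = matrix(c("01", "02")))
  expect_identical(as.integer(partition_mlmg(d3)$G), 1L)
  expect_error(partition_mlmg(make_pop(list(L1 = "NA/NA"))), "missing")
})

test_that("partition recovers constructed clone copy numbers", {
  copies <- c(10, 8, 5, 4, 3)
  calls <- list(
    L1 = rep(sprintf("%03d/%03d", 1:5, 6:10), copies),
    L2 = rep(sprintf("%03d/%03d", 11:15, 11:15), copies))
  d <- make_pop(calls)
  p <- partition_mlmg(d)
  expect_identical(as.integer(p$G), 5L)
  expect_setequal(p$table$n_copies, copies)
  # and from the generator's own ground truth
  sim <- simulate_obligate(population_spec("obligate", n = 30,
                                           n_clones = 5, seed = 11))
  p2 <- partition_mlmg(sim$dataset)
  expect_identical(as.integer(p2$G), 5L)
  expect_setequal(p2$table$n_copies, sim$truth$copy_numbers)
})

test_that("genotypic richness follows (G-1)/(N-1)", {
  mk <- function(G, N) {
    calls <- list(L1 = sprintf("%03d/%03d", c(seq_len(G), rep(1, N - G)),
                               c(seq_len(G), rep(1, N - G))))
    partition_mlmg(make_pop(calls))
  }
  expect_equal(unname(genotypic_richness(mk(15, 29))), 0.5)
  expect_equal(unname(genotypic_richness(mk(1, 10))), 0)
  d1 <- make_pop(list(L1 = "001/001"))
  expect_true(is.na(genotypic_richness(partition_mlmg(d1))))
})

test_that("pid_locus matches closed forms and brute-force enumeration", {
  expect_equal(unname(pid_locus(1)), c(1, 1))
  expect_equal(unname(pid_locus(c(0.5, 0.5))), c(0.375, 0.59375))
  p4 <- rep(0.25, 4)
  expect_equal(pid_locus(p4)[["p_id"]], oracle_pid(p4), tolerance = 1e-12)
  expect_equal(pid_locus(p4)[["p_id_sib"]], oracle_pid_sib(p4),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    got <- pid_locus(p)
    expect_equal(got[["p_id"]], oracle_pid(p), tolerance = 1e-12)
    expect_equal(got[["p_id_sib"]], oracle_pid_sib(p), tolerance = 1e-12)
  }
  expect_error(pid_locus(c(0.5, 0.6)), "sum to 1")
})

test_that("loci_needed returns the smallest sufficient panel", {
  # 8 loci, each with 4 equifrequent alleles: P_IDsib = 0.40527...,
  # 0.40527^5 > 0.01 > 0.40527^6, so m = 6
  geno <- c("001/002", "003/004", "001/003", "002/004",
            "001/004", "002/003", "001/002", "003/004")
  calls <- rep(list(geno), 8)
  names(calls) <- paste0("L", 1:8)
  d <- make_pop(calls)
  res <- loci_needed(d, threshold = 0.01)
  psib <- pid_locus(rep(0.25, 4))[["p_id_sib"]]
  expect_equal(res$m, 6L)
  expect_false(res$insufficient)
  expect_equal(res$curve$cum_p_id_sib, cumprod(rep(psib, 8)),
               tolerance = 1e-12)
  # one locus, generous threshold
  d1 <- make_pop(list(L1 = c("001/001", "002/002")))
  expect_identical(loci_needed(d1, threshold = 0.9)$m, 1L)
  # insufficient flag when even all loci fail
  expect_true(loci_needed(d1, threshold = 1e-6)$insufficient)
})

test_that("round-robin frequencies subsample clones once per locus", {
  # 3-locus toy: one clone x4 plus 2 singletons
  clone <- c("001/002", "003/003", "005/006")
  s1 <- c("001/001", "003/004", "005/005")
  s2 <- c("002/002", "004/004", "006/006")
  calls <- list(L1 = c(rep(clone[1], 4), s1[1], s2[1]),
                L2 = c(rep(clone[2], 4), s1[2], s2[2]),
                L3 = c(rep(clone[3], 4), s1[3], s2[3]))
  d <- make_pop(calls)
  rr <- round_robin_freqs(d, by = "dataset")
  # at L1 the off-L1 classes are {clone, s1, s2}: alleles 001,002 | 001,001
  # | 002,002 -> 001: 3/6, 002: 3/6
  expect_equal(rr$freqs$L1, c(`001` = 0.5, `002` = 0.5))
  # every locus sums to 1
  expect_true(all(abs(vapply(rr$freqs, sum, numeric(1)) - 1) < 1e-12))
  # invariant to duplicating clone copies
  idx <- c(seq_len(6), 1, 1, 1)
  d2 <- genotype_dataset(paste0("j", 1:9), rep("p1", 9), d$loci,
                         d$a1[idx, ], d$a2[idx, ])
  rr2 <- round_robin_freqs(d2, by = "dataset")
  expect_equal(rr$freqs, rr2$freqs)
})

test_that("round-robin equals plain frequencies when all MLMGs distinct on any subset", {
  sim <- simulate_cyclic(population_spec("cyclic", n = 15, n_loci = 8,
                                         seed = 21))
  d <- sim$dataset
  # with 8 highly polymorphic loci, every 7-locus profile is unique here
  rr <- round_robin_freqs(d, by = "dataset")
  pl <- allele_freqs(d, by = "dataset")
  expect_equal(rr$freqs, pl$freqs)
  d1 <- subset_individuals(d, 1:6)
  d1 <- genotype_dataset(d1$individuals, unname(d1$populations), "loc01",
                         d1$a1[, 1, drop = FALSE], d1$a2[, 1, drop = FALSE])
  expect_warning(round_robin_freqs(d1, by = "dataset"), "single locus")
})

test_that("p_gen follows the inbreeding-adjusted product rule", {
  ft <- structure(list(freqs = list(L1 = c(A = 0.5, B = 0.5)),
                       mode = "plain", basis = "individuals"),
                  class = "allele_freq_table")
  expect_equal(p_gen("A", "B", ft, fis = 0), 0.5)
  expect_equal(p_gen("A", "B", ft, fis = 1), 0)
  expect_equal(p_gen("A", "A", ft, fis = 1), 0.5)   # p^2 + p(1-p)
  ft2 <- structure(list(freqs = list(L1 = c(A = 0.5, B = 0.5),
                                     L2 = c(C = 0.5, D = 0.5))),
                   class = "allele_freq_table")
  expect_equal(p_gen(c("A", "C"), c("B", "D"), ft2, fis = 0), 0.25)
  expect_error(p_gen("A", "Z", ft, fis = 0), "frequency basis mismatch")
  # clamping under extreme negative fis
  ftr <- structure(list(freqs = list(L1 = c(A = 0.9, B = 0.1))),
                   class = "allele_freq_table")
  expect_gte(p_gen("B", "B", ftr, fis = -1), 0)
})

test_that("p_sex equals the exact binomial upper tail", {
  expect_equal(p_sex(2, 2, 0.5), 0.25)
  expect_equal(p_sex(3, 10, 0), 0)
  expect_equal(p_sex(5, 5, 1), 1)
  expect_true(is.na(p_sex(1, 10, 0.5)))
  expect_error(p_sex(5, 3, 0.5), "exceed")
  for (N in c(5, 17, 33)) for (n in c(2, 3, N)) for (p in c(0.01, 0.3, 0.9))
    expect_equal(p_sex(n, N, p), oracle_binom_upper(n, N, p),
                 tolerance = 1e-12)
})

test_that("gd_ratio: exact path matches enumeration oracle, MC within 3 SE", {
  # monoclonal at one biallelic locus, N = 30
  d <- make_pop(list(L1 = rep("001/002", 30)))
  ex <- gd_ratio(d, method = "exact")
  expect_equal(ex$E_G, oracle_expected_G(list(c(0.5, 0.5)), 30),
               tolerance = 1e-12)
  expect_equal(ex$ratio, 1 / ex$E_G)
  expect_lt(abs(ex$ratio - 1 / 3), 0.01)
  # MC vs exact on a case where the replicate counts actually vary
  d10 <- make_pop(list(L1 = rep("001/002", 10)))
  ex10 <- gd_ratio(d10, method = "exact")
  expect_equal(ex10$E_G, oracle_expected_G(list(c(0.5, 0.5)), 10),
               tolerance = 1e-12)
  mc <- gd_ratio(d10, B = 400, seed = 7, method = "mc")
  expect_lt(abs(mc$E_G - ex10$E_G), 3 * mc$se_E_G + 1e-9)
  # hugely polymorphic, all distinct -> ratio ~ 1
  sim <- simulate_cyclic(population_spec("cyclic", n = 20, n_loci = 8,
                                         alleles_range = c(15, 22),
                                         seed = 3))
  r <- gd_ratio(sim$dataset, B = 300, seed = 2, method = "mc")
  expect_gt(r$ratio, 0.95)
  expect_lt(r$ratio, 1.1)
  # monomorphic everywhere: E[G] = 1, ratio = G_obs
  dm <- make_pop(list(L1 = rep("001/001", 10)))
  rm_ <- gd_ratio(dm, method = "exact")
  expect_equal(rm_$E_G, 1)
  expect_equal(rm_$ratio, 1)
})

test_that("clonal_stats assembles per-population tables", {
  ob <- simulate_obligate(population_spec("obligate", n = 30, n_clones = 2,
                                          seed = 2))
  cy <- simulate_cyclic(population_spec("cyclic", n = 20, seed = 4,
                                        pop_name = "pop_c"))
  d <- genotype_dataset(
    c(ob$dataset$individuals, cy$dataset$individuals),
    c(unname(ob$dataset$populations), unname(cy$dataset$populations)),
    ob$dataset$loci, rbind(ob$dataset$a1, cy$dataset$a1),
    rbind(ob$dataset$a2, cy$dataset$a2))
  cs <- clonal_stats(d, B = 200, seed = 1)
  expect_setequal(cs$summary$population, c("pop_1", "pop_c"))
  ob_row <- cs$summary[cs$summary$population == "pop_1", ]
  expect_identical(ob_row$G, 2L)
  expect_lt(ob_row$gd_ratio, 0.75)
  # repeated clones must look clonal
  ps <- cs$psex[cs$psex$population == "pop_1", ]
  expect_true(all(ps$p_sex < 0.01, na.rm = TRUE))
  expect_true(all(ps$n_copies >= 2))
})
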