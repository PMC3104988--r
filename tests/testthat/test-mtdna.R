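test_that("haplotype collapsing is deterministic and order-invariant", {
  seqs <- c("AAAA", "AATA", "AAAA", "CCCC", "AATA", "AAAA")
  hs <- collapse_haplotypes(seqs)
  expect_identical(length(hs$haplotypes), 3L)
  expect_identical(unname(hs$counts), c(3L, 2L, 1L))
  expect_identical(unname(hs$haplotypes[hs$hap_id[1]]), "AAAA")
  # all identical
  expect_identical(length(collapse_haplotypes(rep("ACGT", 5))$haplotypes),
                   1L)
  # diversity is invariant to input order
  set.seed(2)
  perm <- sample(length(seqs))
  h1 <- haplotype_diversity(collapse_haplotypes(seqs))
  h2 <- haplotype_diversity(collapse_haplotypes(seqs[perm]))
  expect_equal(h1[["h"]], h2[["h"]])
  expect_error(haplotype_set(c("AC", "ACG")), "equal length")
  expect_error(haplotype_set("ACGX"), "invalid characters")
})

test_that("generator templates are recovered by collapsing", {
  hs <- simulate_haplotypes(97, 23, length = 591, divergence = 0.05,
                            seed = 13)
  expect_identical(length(hs$haplotypes), 23L)
  expect_identical(length(hs$sequences), 97L)
  expect_identical(sum(hs$counts), 97L)
})

test_that("haplotype diversity matches the unbiased estimator", {
  # six pairwise-distinct sequences: h = 1 exactly
  hs <- simulate_haplotypes(6, 6, length = 200, divergence = 0.05,
                            seed = 3)
  hd <- haplotype_diversity(hs)
  expect_equal(hd[["h"]], 1)
  # all identical -> 0
  expect_equal(haplotype_diversity(collapse_haplotypes(
    rep("ACGTACGT", 4)))[["h"]], 0)
  # 3/3 split in n = 6 -> (6/5)(1 - 0.5) = 0.6
  hs3 <- collapse_haplotypes(rep(c("AAAA", "TTTT"), each = 3))
  expect_equal(haplotype_diversity(hs3)[["h"]], 0.6)
  expect_true(is.na(haplotype_diversity(collapse_haplotypes("AAAA"))[["h"]]))
  # brute-force oracle on random haplotype sets
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pool <- c("AAAA", "AATA", "AACA", "TTTT", "GGGG")
    seqs <- sample(pool, n, replace = TRUE)
    expect_equal(haplotype_diversity(collapse_haplotypes(seqs))[["h"]],
                 oracle_hap_diversity(seqs), tolerance = 1e-12)
  }
})

test_that("nucleotide diversity and segregating sites match brute force", {
  s2 <- c("AAAAAAAAAA", "AAAAAAAAAT")
  nd <- nucleotide_diversity(collapse_haplotypes(s2))
  expect_equal(nd[["pi"]], 0.1)
  expect_identical(as.integer(nd[["S"]]), 1L)
  same <- nucleotide_diversity(collapse_haplotypes(rep(s2[1], 4)))
  expect_equal(same[["pi"]], 0)
  expect_identical(as.integer(same[["S"]]), 0L)
  # 3 sequences, pairwise diffs 1, 2, 3 over L = 100 -> pi = 0.02
  base <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  x <- base; x[1] <- "T"
  y <- base; y[2] <- "T"; y[3] <- "T"; y[1] <- "T"
  # diffs: base vs x = 1; base vs y = 3; x vs y = 2
  seqs3 <- c(paste(base, collapse = ""), paste(x, collapse = ""),
             paste(y, collapse = ""))
  expect_equal(nucleotide_diversity(collapse_haplotypes(seqs3))[["pi"]],
               0.02)
  # random sets vs brute-force oracle, including repeated haplotypes
  set.seed(7)
  for (i in 1:15) {
    hs <- simulate_haplotypes(sample(4:10, 1), 3, length = 60,
                              divergence = 0.1, seed = i)
    expect_equal(nucleotide_diversity(hs)[["pi"]],
                 oracle_pi(hs$sequences), tolerance = 1e-12)
  }
  # sites with N are excluded pairwise
  sn <- c("AANA", "AATA", "AATA")
  expect_equal(nucleotide_diversity(collapse_haplotypes(sn))[["pi"]], 0)
})

test_that("regional diversity summary has the Table-2 layout", {
  hs <- simulate_haplotypes(30, 8, length = 300, divergence = 0.04,
                            region_labels = rep(c("R1", "R2", "R3"), 10),
                            seed = 5)
  ds <- diversity_summary(hs)
  expect_identical(ds$region, c("R1", "R2", "R3", "Total"))
  expect_identical(sum(ds$n[1:3]), 30L)
  expect_true(all(ds$k <= ds$n))
  expect_true(all(ds$h >= 0 & ds$h <= 1, na.rm = TRUE))
})

test_that("region distances: within, between and net", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("T", 10), rep("A", 90)), collapse = "")
  hs <- haplotype_set(c(a, a, b, b), regions = c("X", "X", "Y", "Y"))
  rd <- region_distance_summary(hs)
  expect_equal(unname(rd$within), c(0, 0))
  expect_equal(rd$between["X", "Y"], 0.1)
  expect_equal(rd$net["X", "Y"], 0.1)
  # identical (monomorphic) regions -> net exactly 0; identically
  # composed polymorphic regions -> net is between - mean(within), which
  # only vanishes asymptotically
  hs2 <- haplotype_set(c(a, a, a, a), regions = c("X", "X", "Y", "Y"))
  rd2 <- region_distance_summary(hs2)
  expect_equal(rd2$net["X", "Y"], 0)
  hs2b <- haplotype_set(c(rep(a, 10), rep(b, 10), rep(a, 10), rep(b, 10)),
                        regions = rep(c("X", "Y"), each = 20))
  rd2b <- region_distance_summary(hs2b)
  expect_equal(rd2b$net["X", "Y"],
               rd2b$between["X", "Y"] - mean(rd2b$within), tolerance = 1e-12)
  expect_lt(abs(rd2b$net["X", "Y"]), 0.01)
  # brute force on a 3-region simulated set
  hs3 <- simulate_haplotypes(12, 6, length = 80, divergence = 0.08,
                             region_labels = rep(c("P", "Q", "R"), 4),
                             seed = 9)
  rd3 <- region_distance_summary(hs3)
  idx <- split(seq_along(hs3$sequences), hs3$regions)
  pd <- function(i, j) {
    x <- strsplit(hs3$sequences[i], "")[[1]]
    y <- strsplit(hs3$sequences[j], "")[[1]]
    mean(x != y)
  }
  manual_between <- mean(outer(idx$P, idx$Q, Vectorize(pd)))
  expect_equal(rd3$between["P", "Q"], manual_between, tolerance = 1e-12)
})

test_that("ApoI digestion finds R^AATTY sites and calls species groups", {
  dg <- apoi_digest("GGAAATTCGG")
  expect_identical(dg$cuts, 3L)
  expect_identical(dg$fragments, c(3L, 7L))
  # no site: single fragment, tenebrosa-group (window covered)
  seq_free <- paste(rep("ACGG", 200), collapse = "")
  dg2 <- apoi_digest(seq_free)
  expect_identical(dg2$fragments, 800L)
  expect_identical(dg2$group, "tenebrosa-group")
  # 711-bp amplicon with the diagnostic site at position 344
  hs <- simulate_haplotypes(4, 2, length = 711, divergence = 0.03,
                            seed = 21, plant_apoi_at = 344)
  for (s in hs$sequences) {
    d3 <- apoi_digest(s)
    expect_identical(d3$fragments, c(344L, 367L))
    expect_identical(d3$group, "pulicaria-group")
  }
  # scrubbed sequences digest to a single fragment
  hs0 <- simulate_haplotypes(3, 2, length = 711, divergence = 0.03,
                             seed = 22, scrub_apoi = TRUE)
  expect_true(all(digest_haplotypes(hs0)$group == "tenebrosa-group"))
  # ambiguous bases never match; empty sequence errors
  expect_identical(apoi_digest("GAATTN")$n_sites, 0L)
  expect_error(apoi_digest(""), "empty")
})

test_that("fragment lengths always sum to sequence length", {
  set.seed(12)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    dg <- apoi_digest(s)
    expect_identical(sum(dg$fragments), 150L)
    expect_identical(dg$cuts, sort(dg$cuts))
  }
})

test_that("FASTA round trip preserves sequences and labels", {
  hs <- simulate_haplotypes(8, 4, length = 120, divergence = 0.05,
                            seed = 6)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_haplotypes(hs, f)
  rt <- read_fasta_haplotypes(f)
  expect_identical(rt$sequences, hs$sequences)
  expect_identical(rt$labels, hs$labels)
})
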