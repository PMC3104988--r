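# Small fixture builders, all programmatic.

# build a one-population dataset from a list of genotype strings like
# c("01/02", "01/01") per locus: calls[[locus]][i] = "a/b"
make_pop <- function(calls, pop = "p1", ids = NULL) {
  n <- length(calls[[1]])
  loci <- names(calls)
  if (is.null(loci)) loci <- paste0("L", seq_along(calls))
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  a1 <- matrix(NA_character_, n, length(calls))
  a2 <- matrix(NA_character_, n, length(calls))
  for (j in seq_along(calls)) {
    parts <- strsplit(calls[[j]], "/", fixed = TRUE)
    a1[, j] <- vapply(parts, function(x) if (x[1] == "NA") NA_character_
                      else x[1], character(1))
    a2[, j] <- vapply(parts, function(x) if (x[1] == "NA") NA_character_
                      else x[2], character(1))
  }
  genotype_dataset(ids, rep(pop, n), loci, a1, a2)
}

# n copies of the same fixed-heterozygote genotype at each locus
make_fixed_het_pop <- function(n = 10, n_loci = 3, pop = "p1") {
  calls <- lapply(seq_len(n_loci), function(j)
    rep(sprintf("%03d/%03d", 2 * j - 1, 2 * j), n))
  names(calls) <- paste0("L", seq_len(n_loci))
  make_pop(calls, pop = pop)
}

# random small dataset for round-trip fuzzing (numeric labels <= 999)
random_dataset <- function(seed) {
  set.seed(seed)
  n_pop <- sample(1:3, 1)
  n_loci <- sample(1:4, 1)
  loci <- paste0("loc", seq_len(n_loci))
  ids <- character(); pops <- character()
  a1 <- NULL; a2 <- NULL
  for (p in seq_len(n_pop)) {
    n <- sample(1:6, 1)
    ids <- c(ids, sprintf("p%d_i%d", p, seq_len(n)))
    pops <- c(pops, rep(paste0("pop_", p), n))
    m1 <- matrix(sprintf("%03d", sample(1:20, n * n_loci, TRUE)), n)
    m2 <- matrix(sprintf("%03d", sample(1:20, n * n_loci, TRUE)), n)
    miss <- matrix(runif(n * n_loci) < 0.1, n)
    m1[miss] <- NA; m2[miss] <- NA
    a1 <- rbind(a1, m1); a2 <- rbind(a2, m2)
  }
  genotype_dataset(ids, pops, loci, a1, a2)
}

expect_same_dataset <- function(d1, d2) {
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(unname(d1$populations), unname(d2$populations))
  expect_identical(d1$loci, d2$loci)
  expect_identical(unname(d1$a1), unname(d2$a1))
  expect_identical(unname(d1$a2), unname(d2$a2))
}
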