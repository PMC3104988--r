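# Independent oracles used by the tests.  These deliberately avoid the
# package's own computational paths: probabilities are obtained by explicit
# enumeration or summation so that agreement is evidence, not tautology.

# genotype space of a frequency vector: list of (i, j, prob) under HW
.enum_genotypes <- function(p) {
  k <- length(p)
  out <- list()
  for (i in seq_len(k)) for (j in i:k) {
    pr <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    out[[length(out) + 1L]] <- list(i = i, j = j, pr = pr)
  }
  out
}

# P(two random HW individuals share a genotype): sum over genotypes of P_g^2
oracle_pid <- function(p) {
  sum(vapply(.enum_genotypes(p), function(g) g$pr^2, numeric(1)))
}

# P(two full sibs share a genotype): enumerate ordered parental genotype
# pairs; given parents, each sib independently receives one uniformly
# chosen allele from each parent.
oracle_pid_sib <- function(p) {
  gts <- .enum_genotypes(p)
  total <- 0
  for (g1 in gts) for (g2 in gts) {
    # offspring genotype distribution given parents g1 x g2
    off <- new.env()
    for (a in c(g1$i, g1$j)) for (b in c(g2$i, g2$j)) {
      key <- paste(sort(c(a, b)), collapse = "/")
      off[[key]] <- (if (is.null(off[[key]])) 0 else off[[key]]) + 0.25
    }
    share <- sum(vapply(ls(off), function(k) off[[k]]^2, numeric(1)))
    total <- total + g1$pr * g2$pr * share
  }
  total
}

# exact upper binomial tail by explicit summation (no pbinom)
oracle_binom_upper <- function(n, N, p) {
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- n:N
  sum(exp(lchoose(N, i) + i * log(p) + (N - i) * log1p(-p)))
}

# All genotype tables with the allele counts of (a1, a2) (integer codes),
# with their Levene conditional probabilities and heterozygote counts.
# Supports up to 3 alleles.  Returns data.frame(H, prob).
oracle_hwe_tables <- function(a1, a2) {
  counts <- table(factor(c(a1, a2)))
  k <- length(counts)
  stopifnot(k <= 3)
  n <- length(a1)
  cnt <- as.integer(counts)
  rows <- list()
  add <- function(nii, nij) {  # nii: homozygote counts, nij: het counts
    H <- sum(nij)
    logw <- H * log(2) - sum(lfactorial(c(nii, nij)))
    rows[[length(rows) + 1L]] <<- data.frame(H = H, logw = logw)
  }
  if (k == 1) {
    add(n, integer(0))
  } else if (k == 2) {
    for (n12 in 0:min(cnt)) {
      r1 <- cnt[1] - n12; r2 <- cnt[2] - n12
      if (r1 %% 2 || r2 %% 2) next
      add(c(r1 / 2, r2 / 2), n12)
    }
  } else {
    for (n12 in 0:min(cnt[1], cnt[2]))
      for (n13 in 0:min(cnt[1] - n12, cnt[3]))
        for (n23 in 0:min(cnt[2] - n12, cnt[3] - n13)) {
          r1 <- cnt[1] - n12 - n13
          r2 <- cnt[2] - n12 - n23
          r3 <- cnt[3] - n13 - n23
          if (r1 %% 2 || r2 %% 2 || r3 %% 2) next
          add(c(r1, r2, r3) / 2, c(n12, n13, n23))
        }
  }
  df <- do.call(rbind, rows)
  w <- exp(df$logw - max(df$logw))
  df$prob <- w / sum(w)
  df
}

# exact one-sided score-test mid-p: full mass of strictly more extreme
# tables plus half the mass of tables tying the observed heterozygote
# count (the tie-counted-half convention of the implementation)
oracle_hwe_exact_p <- function(a1, a2, tail = c("excess", "deficiency")) {
  tail <- match.arg(tail)
  tab <- oracle_hwe_tables(a1, a2)
  Hobs <- sum(a1 != a2)
  if (tail == "excess")
    sum(tab$prob[tab$H > Hobs]) + 0.5 * sum(tab$prob[tab$H == Hobs])
  else
    sum(tab$prob[tab$H < Hobs]) + 0.5 * sum(tab$prob[tab$H == Hobs])
}

# analytic expected number of distinct multilocus genotypes among N HW
# draws, by explicit enumeration over the full genotype space
oracle_expected_G <- function(freq_list, N) {
  spaces <- lapply(freq_list, function(p)
    vapply(.enum_genotypes(p), function(g) g$pr, numeric(1)))
  Pg <- Reduce(function(x, y) as.numeric(outer(x, y)), spaces)
  stopifnot(abs(sum(Pg) - 1) < 1e-9)
  sum(1 - (1 - Pg)^N)
}

# brute-force unbiased haplotype diversity: the probability that two
# sequences drawn without replacement differ, i.e. the fraction of
# unequal unordered pairs (algebraically equal to n(1 - sum f^2)/(n-1))
oracle_hap_diversity <- function(seqs) {
  n <- length(seqs)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff <- diff + (seqs[i] != seqs[j])
  diff / (n * (n - 1) / 2)
}

# brute-force nucleotide diversity over all sequence pairs, pairwise
# deletion of non-ACGT sites
oracle_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    x <- strsplit(seqs[i], "")[[1]]
    y <- strsplit(seqs[j], "")[[1]]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    tot <- tot + sum(x[ok] != y[ok]) / sum(ok)
  }
  tot / (n * (n - 1) / 2)
}
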