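#' Test result container
#'
#' Light S3 record for resampling-based tests: the observed statistic, the
#' p-value, the tail tested, the method, resampling parameters and the
#' seed, plus (for chain-based tests) a Monte Carlo standard error.
#'
#' @param statistic observed statistic.
#' @param p_value p-value in `[0, 1]` (or `NA`).
#' @param tail `"excess"`, `"deficiency"` or `"two-sided"`.
#' @param method character description.
#' @param se Monte Carlo standard error of the p estimate, if available.
#' @param params list of resampling parameters.
#' @param seed RNG seed used, if any.
#' @return an object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, tail, method, se = NA_real_,
                        params = list(), seed = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must be in [0, 1]")
  structure(list(statistic = statistic, p_value = p_value, tail = tail,
                 method = method, se = se, params = params, seed = seed),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.6g, p = %.6g%s\n", x$method, x$tail,
              x$statistic, x$p_value,
              if (is.finite(x$se)) sprintf(" (MC SE %.2g)", x$se) else ""))
  invisible(x)
}

#' Observed and expected heterozygosity
#'
#' Per locus: Ho is the observed heterozygote proportion and He the
#' unbiased expected heterozygosity `(2n/(2n-1)) (1 - sum p^2)` (Nei);
#' overall values are means across loci.
#'
#' @param dataset a complete single-population [genotype_dataset()] (use
#'   [split_populations()] for multi-population data).
#' @return list with `per_locus` (data.frame locus, n, Ho, He) and
#'   `overall` (`c(Ho=, He=)`).
#' @export
het_stats <- function(dataset) {
  .assert_complete(dataset)
  n <- length(dataset$individuals)
  if (n == 0L) return(list(per_locus = NULL, overall = c(Ho = NA, He = NA)))
  per <- lapply(seq_along(dataset$loci), function(j) {
    ho <- mean(dataset$a1[, j] != dataset$a2[, j])
    p <- table(c(dataset$a1[, j], dataset$a2[, j]))
    p <- as.numeric(p) / sum(p)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = dataset$loci[j], n = n, Ho = ho, He = he)
  })
  per <- do.call(rbind, per)
  list(per_locus = per,
       overall = c(Ho = mean(per$Ho), He = mean(per$He)))
}

# Per-locus Weir-Cockerham variance components for a single sample.
# Returns c(sum_b, sum_c) summed over alleles; both 0 for a monomorphic
# locus.  f = 1 - c/(b + c).
.wc_components <- function(x1, x2) {
  n <- length(x1)
  alleles <- unique(c(x1, x2))
  if (length(alleles) < 2L) return(c(b = 0, c = 0))
  het <- x1 != x2
  sb <- 0; sc <- 0
  for (a in alleles) {
    p <- (sum(x1 == a) + sum(x2 == a)) / (2 * n)
    hbar <- sum(het & (x1 == a | x2 == a)) / n
    sb <- sb + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    sc <- sc + hbar / 2
  }
  c(b = sb, c = sc)
}

#' Weir-Cockerham inbreeding coefficient (Fis)
#'
#' Single-sample Weir & Cockerham (1984) estimator: per allele,
#' `b = n/(n-1) [p(1-p) - (2n-1) hbar / (4n)]` and `c = hbar/2` with
#' `hbar` the observed frequency of heterozygotes carrying the allele;
#' `f = 1 - sum(c) / sum(b + c)`.  The multilocus value combines loci by
#' summing the components (numerators and denominators) across loci.
#' Fixed heterozygosity at a locus gives exactly -1.  Monomorphic loci
#' have undefined Fis and are skipped (flagged in the output).
#'
#' @param dataset a complete single-population [genotype_dataset()] with
#'   at least 2 individuals.
#' @return list with `per_locus` (data.frame locus, fis, monomorphic) and
#'   `multilocus` (numeric, NA if no polymorphic locus).
#' @export
fis_wc <- function(dataset) {
  .assert_complete(dataset)
  n <- length(dataset$individuals)
  if (n < 2L) stop("need at least 2 individuals")
  comp <- t(vapply(seq_along(dataset$loci), function(j)
    .wc_components(dataset$a1[, j], dataset$a2[, j]), numeric(2L)))
  mono <- comp[, 1L] == 0 & comp[, 2L] == 0
  fis <- ifelse(mono, NA_real_,
                1 - comp[, 2L] / (comp[, 1L] + comp[, 2L]))
  multi <- if (all(mono)) NA_real_ else
    1 - sum(comp[!mono, 2L]) / sum(comp[!mono, 1L] + comp[!mono, 2L])
  list(per_locus = data.frame(locus = dataset$loci, fis = fis,
                              monomorphic = mono),
       multilocus = multi)
}

# multilocus WC f from per-locus heterozygote counts, given fixed allele
# counts: only the per-locus H matters (see vignette), which makes the
# permutation null cheap.
.fis_from_H <- function(H, n, one_minus_sump2) {
  b <- n / (n - 1) * (one_minus_sump2 - (2 * n - 1) / (2 * n^2) * H)
  cc <- H / n
  1 - sum(cc) / sum(b + cc)
}

#' Permutation test of the multilocus Fis
#'
#' The null distribution is built by shuffling the 2N allele copies among
#' individuals, independently per locus, and recomputing the multilocus
#' Weir-Cockerham Fis; the two-sided p-value is the smoothed proportion of
#' permuted |Fis| at least as large as observed,
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param dataset a complete single-population [genotype_dataset()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a [test_result()].
#' @export
fis_permutation_test <- function(dataset, n_perm = 10000L, seed = 1L) {
  .assert_complete(dataset)
  n <- length(dataset$individuals)
  if (n < 2L) stop("need at least 2 individuals")
  codes <- lapply(seq_along(dataset$loci), function(j) {
    lv <- unique(c(dataset$a1[, j], dataset$a2[, j]))
    rbind(match(dataset$a1[, j], lv), match(dataset$a2[, j], lv))
  })
  poly <- vapply(codes, function(x) length(unique(c(x))) > 1L, logical(1L))
  if (!any(poly))
    return(test_result(NA_real_, NA_real_, "two-sided",
                       "Fis permutation test (all loci monomorphic)"))
  codes <- codes[poly]
  omsp <- vapply(codes, function(x) {
    p <- tabulate(c(x)) / (2 * n); 1 - sum(p^2)
  }, numeric(1L))
  Hobs <- vapply(codes, function(x) sum(x[1L, ] != x[2L, ]), numeric(1L))
  obs <- .fis_from_H(Hobs, n, omsp)
  set.seed(seed)
  L <- length(codes)
  null <- numeric(n_perm)
  odd <- seq(1L, 2L * n, by = 2L); even <- odd + 1L
  flat <- lapply(codes, function(x) c(x))   # copy vector per locus
  for (r in seq_len(n_perm)) {
    H <- numeric(L)
    for (l in seq_len(L)) {
      x <- flat[[l]][sample.int(2L * n)]
      H[l] <- sum(x[odd] != x[even])
    }
    null[r] <- .fis_from_H(H, n, omsp)
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  test_result(obs, p, "two-sided", "Fis permutation test",
              params = list(n_perm = n_perm), seed = seed)
}

#' Exact score test of Hardy-Weinberg equilibrium (Markov chain)
#'
#' One-sided score (U) test of heterozygote excess or deficiency at a
#' single locus.  The test statistic is the Weir-Cockerham Fis; the null
#' is the conditional (Levene) distribution of genotype tables given the
#' observed allele counts, explored with a switch-type Markov chain over
#' allele-copy arrangements.  The p-value is a mid-p: the fraction of
#' chain time spent in tables strictly more extreme than the observed
#' one plus half the time spent in tables tying it (ties counted half
#' toward the tail), with a standard error estimated from batch means.
#' The half-tie convention keeps the discrete test calibrated; the
#' conservative full-tie p is `p + 0.5 * P(tie)` and can be recovered
#' from the two tails since `p_excess + p_deficiency = 1`.
#'
#' With fixed allele counts Fis is strictly decreasing in the heterozygote
#' count, so extremeness reduces to comparisons of `H` with `H_obs`.
#'
#' Chain defaults follow common practice for exact HWE testing (1000
#' batches of 20000 iterations after 20000 dememorization steps); they can
#' be reduced for bulk runs.
#'
#' @param a1,a2 character (or integer) vectors: the two alleles of each
#'   individual at the locus.
#' @param tail `"excess"` or `"deficiency"`.
#' @param dememorization,batches,iters_per_batch chain parameters
#'   (minimums: 10 batches of 100 iterations).
#' @param seed RNG seed.
#' @return a [test_result()]; statistic `NA` and p `NA` for a monomorphic
#'   locus.
#' @export
hwe_score_test <- function(a1, a2, tail = c("excess", "deficiency"),
                           dememorization = 20000L, batches = 1000L,
                           iters_per_batch = 20000L, seed = 1L) {
  tail <- match.arg(tail)
  if (batches < 10L || iters_per_batch < 100L || dememorization < 0L)
    stop("chain parameters below minimum (>=10 batches of >=100 iterations)")
  keep <- !(is.na(a1) | is.na(a2))
  a1 <- as.character(a1)[keep]; a2 <- as.character(a2)[keep]
  lv <- unique(c(a1, a2))
  if (length(lv) < 2L)
    return(test_result(NA_real_, NA_real_, tail,
                       "HWE score test (monomorphic locus)"))
  comp <- .wc_components(a1, a2)
  fis <- 1 - comp[["c"]] / (comp[["b"]] + comp[["c"]])
  alleles <- as.integer(rbind(match(a1, lv), match(a2, lv)))
  set.seed(seed)
  bm <- hwe_chain_cpp(alleles, as.integer(dememorization),
                      as.integer(batches), as.integer(iters_per_batch),
                      tail == "excess")
  p <- mean(bm)
  se <- stats::sd(bm) / sqrt(length(bm))
  test_result(fis, p, tail, "HWE exact score test (Markov chain)",
              se = se,
              params = list(dememorization = dememorization,
                            batches = batches,
                            iters_per_batch = iters_per_batch),
              seed = seed)
}

#' Population-level Hardy-Weinberg testing across loci
#'
#' Runs the Markov-chain score test at every polymorphic locus of every
#' population, for both tails, and combines the per-locus one-sided
#' p-values of each population by Fisher's method (`-2 sum log p` against
#' a chi-squared with 2m df).  Per-locus p-values are clamped below at
#' `1/(batches * iters_per_batch + 1)` so the combination is defined when
#' the chain never leaves the extreme set.  Combined p-values additionally
#' receive a Bonferroni adjustment with family size `populations x 2
#' tails`.
#'
#' @param dataset a complete [genotype_dataset()].
#' @param dememorization,batches,iters_per_batch chain parameters (see
#'   [hwe_score_test()]).
#' @param seed base RNG seed; each population x locus x tail gets a
#'   distinct derived seed.
#' @param alpha significance level for the Bonferroni flags.
#' @return list with `per_locus` (data.frame population, locus, tail, fis,
#'   p, se) and `combined` (data.frame population, tail, n_loci, p_fisher,
#'   p_bonferroni, significant).
#' @export
multilocus_hwe <- function(dataset, dememorization = 20000L,
                           batches = 1000L, iters_per_batch = 20000L,
                           seed = 1L, alpha = 0.05) {
  .assert_complete(dataset)
  pops <- split_populations(dataset)
  eps <- 1 / (as.numeric(batches) * iters_per_batch + 1)
  per <- list(); comb <- list()
  k <- 0L
  for (p in names(pops)) {
    d <- pops[[p]]
    for (tail in c("excess", "deficiency")) {
      ps <- c()
      for (j in seq_along(d$loci)) {
        k <- k + 1L
        tr <- hwe_score_test(d$a1[, j], d$a2[, j], tail = tail,
                             dememorization = dememorization,
                             batches = batches,
                             iters_per_batch = iters_per_batch,
                             seed = seed + k)
        per[[length(per) + 1L]] <-
          data.frame(population = p, locus = d$loci[j], tail = tail,
                     fis = tr$statistic, p = tr$p_value, se = tr$se)
        if (!is.na(tr$p_value)) ps <- c(ps, max(tr$p_value, eps))
      }
      pf <- if (length(ps)) {
        stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                      lower.tail = FALSE)
      } else NA_real_
      comb[[length(comb) + 1L]] <-
        data.frame(population = p, tail = tail, n_loci = length(ps),
                   p_fisher = pf)
    }
  }
  combined <- do.call(rbind, comb)
  fam <- length(pops) * 2L
  combined$p_bonferroni <- pmin(1, combined$p_fisher * fam)
  combined$significant <- !is.na(combined$p_bonferroni) &
    combined$p_bonferroni < alpha
  list(per_locus = do.call(rbind, per), combined = combined)
}
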