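#' Standardized index of association (r_bar_d)
#'
#' Multilocus linkage disequilibrium based on the index of association:
#' for every pair of individuals, the per-locus genotype distance is
#' `(2 - shared alleles)/2` (shared alleles counted with multiplicity, so
#' AB vs AA scores 0.5) and `D` is the sum over loci.  Then
#' `r_bar_d = (Var(D) - sum_l Var(d_l)) / (2 sum_{j<k} sqrt(Var(d_j)
#' Var(d_k)))`, which is 0 in expectation under free recombination and 1
#' for perfectly associated loci.
#'
#' The null distribution is obtained by shuffling the 2N allele copies
#' among individuals independently for each locus; the p-value is the
#' smoothed upper-tail proportion `(1 + #{perm >= obs}) / (n_perm + 1)`.
#' With `clone_correct = TRUE` only the first individual of each
#' multilocus genotype is kept before testing (the clone-corrected
#' variant); this is the test that distinguishes disequilibrium caused by
#' clonal copies from disequilibrium among distinct genotypes.
#'
#' Loci with zero distance variance (e.g. monomorphic) are excluded with a
#' warning; fewer than two usable loci gives `NA`.
#'
#' @param dataset a complete single-population [genotype_dataset()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param clone_correct keep one individual per MLMG first.
#' @return a [test_result()] with the extra fields `n_used` (individuals
#'   entering the test) and `n_loci_used`.
#' @export
rbar_d <- function(dataset, n_perm = 1000L, seed = 1L,
                   clone_correct = FALSE) {
  .assert_complete(dataset)
  d <- dataset
  if (clone_correct) {
    gs <- .genotype_strings(d)
    d <- subset_individuals(d, !duplicated(gs))
  }
  n <- length(d$individuals)
  L <- length(d$loci)
  if (L < 2L) stop("need at least 2 loci")
  if (n < 3L) stop("need at least 3 individuals",
                   if (clone_correct) " after clone correction" else "")
  m1 <- matrix(0L, n, L); m2 <- matrix(0L, n, L)
  nv <- 0L
  for (j in seq_len(L)) {
    lv <- unique(c(d$a1[, j], d$a2[, j]))
    m1[, j] <- match(d$a1[, j], lv)
    m2[, j] <- match(d$a2[, j], lv)
    if (length(lv) < 2L) nv <- nv + 1L
  }
  if (nv > 0L)
    warning(nv, " locus/loci with zero distance variance excluded from r_bar_d")
  set.seed(seed)
  res <- rbard_perm_cpp(m1, m2, as.integer(n_perm))
  obs <- res$observed
  if (is.na(obs)) {
    return(test_result(NA_real_, NA_real_, "excess",
                       "r_bar_d permutation test (insufficient usable loci)",
                       params = list(n_perm = n_perm,
                                     clone_correct = clone_correct)))
  }
  perms <- res$perms[!is.na(res$perms)]
  p <- (1 + sum(perms >= obs)) / (length(perms) + 1)
  out <- test_result(obs, p, "excess", "r_bar_d permutation test",
                     params = list(n_perm = n_perm,
                                   clone_correct = clone_correct),
                     seed = seed)
  out$n_used <- n
  out$n_loci_used <- L - nv
  out
}
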