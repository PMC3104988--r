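#' Partition individuals into multilocus genotypes (MLMGs)
#'
#' Two individuals belong to the same multilocus genotype class iff their
#' order-normalized allele pairs are equal at every locus (strict identity;
#' no mutation-tolerant lineage aggregation).  MLMG identifiers are
#' deterministic: classes are numbered in lexicographic order of their
#' genotype string.
#'
#' @param dataset a complete [genotype_dataset()] (no missing calls).
#' @return an object of class `clonal_partition`: list with `mlmg` (named
#'   character vector, individual -> MLMG id), `populations` (individual ->
#'   population), and `table` (data.frame population, mlmg, n_copies), plus
#'   `G`/`N` per population.
#' @export
partition_mlmg <- function(dataset) {
  .assert_complete(dataset)
  gs <- .genotype_strings(dataset)
  uniq <- sort(unique(gs))
  ids <- stats::setNames(
    sprintf("MLMG_%0*d", max(3L, nchar(length(uniq))), seq_along(uniq)),
    uniq)
  mlmg <- stats::setNames(unname(ids[gs]), dataset$individuals)
  pops <- unname(dataset$populations)
  tab <- as.data.frame(table(population = pops, mlmg = unname(mlmg)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  names(tab)[3L] <- "n_copies"
  tab <- tab[order(tab$population, tab$mlmg), ]
  rownames(tab) <- NULL
  G <- tapply(tab$n_copies, tab$population, length)
  N <- tapply(tab$n_copies, tab$population, sum)
  structure(list(mlmg = mlmg, populations = dataset$populations,
                 table = tab,
                 G = G[unique(pops)], N = N[unique(pops)]),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat("clonal_partition:\n")
  print(data.frame(population = names(x$G), G = as.integer(x$G),
                   N = as.integer(x$N), row.names = NULL))
  invisible(x)
}

#' Genotypic richness R = (G - 1) / (N - 1)
#'
#' Zero for a monoclonal population, one when every individual carries a
#' distinct multilocus genotype.  Undefined (`NA`) for populations of a
#' single individual.
#'
#' @param partition a [partition_mlmg()] result.
#' @return named numeric vector, one R per population.
#' @export
genotypic_richness <- function(partition) {
  G <- as.numeric(partition$G); N <- as.numeric(partition$N)
  r <- ifelse(N >= 2, (G - 1) / (N - 1), NA_real_)
  stats::setNames(r, names(partition$G))
}

#' Single-locus probability of identity
#'
#' For a vector of allele frequencies p, the probability that two unrelated
#' individuals drawn from a Hardy-Weinberg population share a genotype is
#' `P_ID = 2 (sum p^2)^2 - sum p^4`; among full siblings it is
#' `P_IDsib = 0.25 + 0.5 sum p^2 + 0.5 (sum p^2)^2 - 0.25 sum p^4`
#' (the conservative upper bound used to judge marker-panel resolution).
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return named numeric vector `c(p_id =, p_id_sib =)`.
#' @export
pid_locus <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  c(p_id = 2 * s2^2 - s4,
    p_id_sib = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4)
}

#' How many loci are needed to resolve individuals?
#'
#' Ranks loci by increasing sibling probability of identity and returns the
#' smallest panel size m whose cumulative product of the m smallest
#' `P_IDsib` values falls below `threshold` (0.01 gives the usual "99%
#' certainty" reading).  The full cumulative curve is returned so the
#' marginal value of each additional locus can be inspected.
#'
#' @param dataset a [genotype_dataset()]; frequencies are estimated over
#'   the whole dataset (per-individual plain counts, complete calls only).
#' @param threshold cumulative `P_IDsib` cutoff.
#' @return list with `m` (integer or NA), `insufficient` (logical),
#'   `curve` (data.frame locus, p_id, p_id_sib, cum_p_id_sib).
#' @export
loci_needed <- function(dataset, threshold = 0.01) {
  if (!length(dataset$loci)) stop("dataset has no loci")
  ft <- allele_freqs(dataset, by = "dataset")
  per <- t(vapply(ft$freqs, pid_locus, numeric(2L)))
  ord <- order(per[, "p_id_sib"])
  cum <- cumprod(per[ord, "p_id_sib"])
  m <- which(cum < threshold)[1L]
  list(m = if (is.na(m)) NA_integer_ else as.integer(m),
       insufficient = is.na(m),
       curve = data.frame(locus = dataset$loci[ord],
                          p_id = per[ord, "p_id"],
                          p_id_sib = per[ord, "p_id_sib"],
                          cum_p_id_sib = cum,
                          row.names = NULL))
}

#' Plain allele frequencies
#'
#' Relative allele frequencies per locus, counted over individuals (two
#' gene copies each), over one representative per unique MLMG
#' (`basis = "mlmg"`), per population or for the whole dataset.
#'
#' @param dataset a complete [genotype_dataset()].
#' @param by `"population"` (a table per population) or `"dataset"`.
#' @param basis count every individual, or one individual per MLMG.
#' @return For `by = "dataset"`, an object of class `allele_freq_table`:
#'   list with `freqs` (per locus, named numeric vector summing to 1),
#'   `mode = "plain"`, `basis`.  For `by = "population"`, a named list of
#'   such tables.
#' @export
allele_freqs <- function(dataset, by = c("population", "dataset"),
                         basis = c("individuals", "mlmg")) {
  by <- match.arg(by); basis <- match.arg(basis)
  .assert_complete(dataset)
  if (by == "population") {
    return(lapply(split_populations(dataset), allele_freqs,
                  by = "dataset", basis = basis))
  }
  d <- dataset
  if (basis == "mlmg") {
    gs <- .genotype_strings(dataset)
    d <- subset_individuals(dataset, !duplicated(gs))
  }
  freqs <- lapply(seq_along(d$loci), function(j) {
    x <- c(d$a1[, j], d$a2[, j])
    tab <- table(x)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  structure(list(freqs = stats::setNames(freqs, d$loci),
                 mode = "plain", basis = basis),
            class = "allele_freq_table")
}

#' Round-robin allele frequencies
#'
#' The clone-aware frequency estimator used for P_sex: for each locus `l`,
#' individuals are partitioned into multilocus genotypes defined on *all
#' loci except* `l`; one representative (the first occurrence) is kept per
#' class and allele frequencies at `l` are counted from those
#' representatives only.  A clone of 50 copies therefore contributes a
#' single genotype per locus, which removes the upward bias that clonal
#' replication exerts on common-allele frequencies.
#'
#' With a single locus no round robin is possible; the function falls back
#' to unique-MLMG plain frequencies with a warning.
#'
#' @param dataset a complete [genotype_dataset()], usually one population.
#' @param by `"population"` or `"dataset"` (compute on the dataset as one
#'   pool).
#' @return an `allele_freq_table` (or named list of them), `mode =
#'   "round_robin"`.
#' @export
round_robin_freqs <- function(dataset, by = c("population", "dataset")) {
  by <- match.arg(by)
  .assert_complete(dataset)
  if (by == "population") {
    return(lapply(split_populations(dataset), round_robin_freqs,
                  by = "dataset"))
  }
  L <- length(dataset$loci)
  if (L < 2L) {
    warning("single locus: falling back to unique-MLMG plain frequencies")
    out <- allele_freqs(dataset, by = "dataset", basis = "mlmg")
    out$mode <- "round_robin_fallback"
    return(out)
  }
  pairs <- matrix(paste(dataset$a1, dataset$a2, sep = "/"),
                  nrow = length(dataset$individuals))
  freqs <- lapply(seq_len(L), function(j) {
    key <- apply(pairs[, -j, drop = FALSE], 1L, paste, collapse = "|")
    rep_idx <- which(!duplicated(key))
    x <- c(dataset$a1[rep_idx, j], dataset$a2[rep_idx, j])
    tab <- table(x)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  structure(list(freqs = stats::setNames(freqs, dataset$loci),
                 mode = "round_robin", basis = "mlmg"),
            class = "allele_freq_table")
}

#' Probability of a multilocus genotype under (possibly inbred) random
#' mating
#'
#' Per locus, a homozygote for allele i has probability
#' `p_i^2 + p_i (1 - p_i) f` and a heterozygote i/j has probability
#' `2 p_i p_j (1 - f)`; the multilocus probability is the product over
#' loci (independent loci).  Negative per-locus probabilities arising under
#' extreme negative `f` are clamped to 0 (no renormalization).
#'
#' @param a1,a2 character vectors: the two (order-normalized) alleles of
#'   the focal genotype at each locus, in `freq_table` locus order.
#' @param freq_table an `allele_freq_table` covering the same loci.
#' @param fis inbreeding coefficient in `[-1, 1]` (0 = Hardy-Weinberg).
#' @return probability in `[0, 1]`.
#' @export
p_gen <- function(a1, a2, freq_table, fis = 0) {
  if (fis < -1 || fis > 1) stop("fis must be in [-1, 1]")
  loci <- names(freq_table$freqs)
  if (length(a1) != length(loci) || length(a2) != length(loci))
    stop("genotype must supply one allele pair per locus of the table")
  pr <- 1
  for (j in seq_along(loci)) {
    f <- freq_table$freqs[[j]]
    if (!(a1[j] %in% names(f)) || !(a2[j] %in% names(f)))
      stop(sprintf(
        "allele '%s' absent from frequency table at locus %s (frequency basis mismatch)",
        if (a1[j] %in% names(f)) a2[j] else a1[j], loci[j]))
    p <- f[[a1[j]]]
    if (a1[j] == a2[j]) {
      g <- p^2 + p * (1 - p) * fis
    } else {
      g <- 2 * p * f[[a2[j]]] * (1 - fis)
    }
    pr <- pr * max(0, g)
  }
  min(1, pr)
}

#' P_sex: probability that repeated MLMG copies arose from independent
#' sexual events
#'
#' Given that an MLMG with per-draw probability `p_gen_value` was observed
#' `n_copies` times among `N` sampled individuals, returns the upper-tail
#' binomial probability `P(X >= n_copies)` with `X ~ Binomial(N,
#' p_gen_value)` (all N samples counted, including the focal copies).
#' Small values mean that so many identical genotypes are implausible under
#' sexual reproduction, i.e. the copies are clonemates.
#'
#' @param n_copies observed number of copies (>= 2; `NA` returned below 2).
#' @param N sample size of the population.
#' @param p_gen_value per-draw genotype probability from [p_gen()].
#' @return probability in `[0, 1]`, or `NA` when `n_copies < 2`.
#' @export
p_sex <- function(n_copies, N, p_gen_value) {
  if (p_gen_value < 0 || p_gen_value > 1) stop("p_gen_value must be in [0, 1]")
  if (n_copies > N) stop("n_copies cannot exceed N")
  if (n_copies < 2) return(NA_real_)
  stats::pbinom(n_copies - 1, size = N, prob = p_gen_value,
                lower.tail = FALSE)
}

#' Genotypic diversity ratio: observed vs expected genotype counts
#'
#' Ratio of the observed number of distinct multilocus genotypes to the
#' number expected under Hardy-Weinberg proportions and independent
#' segregation of loci, at the observed sample size N.  Values well below
#' 1 indicate clonal amplification of a few genotypes; the classical
#' decision threshold is 0.75.
#'
#' The expectation `E(G)` is computed analytically as
#' `sum_g (1 - (1 - P_g)^N)` over the full multilocus genotype space when
#' that space has at most `exact_limit` states, and otherwise by seeded
#' Monte Carlo (B replicate samples of N multilocus genotypes drawn from
#' the plain sample allele frequencies).  `method` can force either route.
#'
#' @param dataset a complete single-population [genotype_dataset()].
#' @param B number of Monte Carlo replicates (>= 100).
#' @param seed RNG seed (required for the Monte Carlo route).
#' @param method `"auto"`, `"exact"` or `"mc"`.
#' @param exact_limit largest genotype-space size for the analytic route.
#' @return list with `ratio`, `G_obs`, `E_G`, `se_E_G` (MC standard error
#'   of `E(G)`; 0 for the exact route), `se_ratio`, `method`, `B`, `seed`.
#' @export
gd_ratio <- function(dataset, B = 1000L, seed = NULL,
                     method = c("auto", "exact", "mc"),
                     exact_limit = 1e4) {
  method <- match.arg(method)
  .assert_complete(dataset)
  if (B < 100L) stop("B must be >= 100")
  N <- length(dataset$individuals)
  G_obs <- length(unique(.genotype_strings(dataset)))
  ft <- allele_freqs(dataset, by = "dataset")$freqs
  n_geno <- vapply(ft, function(f) {
    k <- length(f); k * (k + 1) / 2
  }, numeric(1L))
  space <- prod(n_geno)
  if (method == "auto") method <- if (space <= exact_limit) "exact" else "mc"

  if (method == "exact") {
    # per-locus genotype probability vectors under HW
    per_locus <- lapply(ft, function(f) {
      k <- length(f)
      idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
      p <- f[idx[, 1L]] * f[idx[, 2L]]
      p <- ifelse(idx[, 1L] == idx[, 2L], p, 2 * p)
      unname(p)
    })
    Pg <- Reduce(function(x, y) as.numeric(outer(x, y)), per_locus)
    E_G <- sum(1 - (1 - Pg)^N)
    se <- 0
  } else {
    if (is.null(seed)) stop("seed is required for the Monte Carlo route")
    set.seed(seed)
    counts <- numeric(B)
    L <- length(ft)
    for (b in seq_len(B)) {
      cols <- vector("list", L)
      for (j in seq_len(L)) {
        f <- ft[[j]]
        x1 <- sample.int(length(f), N, replace = TRUE, prob = f)
        x2 <- sample.int(length(f), N, replace = TRUE, prob = f)
        cols[[j]] <- paste(pmin(x1, x2), pmax(x1, x2))
      }
      counts[b] <- length(unique(do.call(paste, cols)))
    }
    E_G <- mean(counts)
    se <- stats::sd(counts) / sqrt(B)
  }
  ratio <- G_obs / E_G
  list(ratio = ratio, G_obs = G_obs, E_G = E_G, se_E_G = se,
       se_ratio = ratio * se / E_G, method = method, B = B, seed = seed)
}

#' Per-population clonality statistics
#'
#' Convenience wrapper producing, for every population: G, N, genotypic
#' richness R, the genotypic diversity ratio, and for every repeated MLMG
#' (n >= 2) its P_sex and P_sex(Fis) based on round-robin allele
#' frequencies.  `fis` supplies the per-population multilocus inbreeding
#' coefficient used by P_sex(Fis) (defaults to the Weir-Cockerham estimate
#' from [fis_wc()]).
#'
#' An MLMG whose allele is absent from the round-robin pool at some locus
#' cannot be scored against those frequencies (basis mismatch); its P_sex
#' is reported as `NA` with a note rather than an error.
#'
#' @param dataset a complete [genotype_dataset()].
#' @param B,seed passed to [gd_ratio()].
#' @param fis optional named numeric (population -> Fis) for P_sex(Fis).
#' @return list with `summary` (data.frame population, G, N, R, gd_ratio)
#'   and `psex` (data.frame population, mlmg, n_copies, p_sex, p_sex_fis,
#'   note).
#' @export
clonal_stats <- function(dataset, B = 1000L, seed = 1L, fis = NULL) {
  .assert_complete(dataset)
  part <- partition_mlmg(dataset)
  R <- genotypic_richness(part)
  pops <- split_populations(dataset)
  if (is.null(fis)) {
    fis <- vapply(pops, function(d) fis_wc(d)$multilocus, numeric(1L))
  }
  gd <- vapply(seq_along(pops), function(i)
    gd_ratio(pops[[i]], B = B, seed = seed + i)$ratio, numeric(1L))
  summary <- data.frame(population = names(pops),
                        G = as.integer(part$G[names(pops)]),
                        N = as.integer(part$N[names(pops)]),
                        R = unname(R[names(pops)]),
                        gd_ratio = gd, row.names = NULL)
  rows <- list()
  for (p in names(pops)) {
    d <- pops[[p]]
    rr <- round_robin_freqs(d, by = "dataset")
    tab <- part$table[part$table$population == p &
                        part$table$n_copies >= 2L, , drop = FALSE]
    if (!nrow(tab)) next
    N <- length(d$individuals)
    mlmg_of <- part$mlmg[d$individuals]
    for (k in seq_len(nrow(tab))) {
      ind <- d$individuals[which(mlmg_of == tab$mlmg[k])[1L]]
      i <- match(ind, d$individuals)
      pg <- try(p_gen(d$a1[i, ], d$a2[i, ], rr, fis = 0), silent = TRUE)
      note <- ""
      if (inherits(pg, "try-error")) {
        ps <- NA_real_; psf <- NA_real_
        note <- "allele absent from round-robin pool"
      } else {
        ps <- p_sex(tab$n_copies[k], N, pg)
        f <- max(-1, min(1, fis[[p]]))
        pgf <- p_gen(d$a1[i, ], d$a2[i, ], rr, fis = f)
        psf <- p_sex(tab$n_copies[k], N, pgf)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(population = p, mlmg = tab$mlmg[k],
                   n_copies = tab$n_copies[k], p_sex = ps,
                   p_sex_fis = psf, note = note)
    }
  }
  psex <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), mlmg = character(),
               n_copies = integer(), p_sex = numeric(),
               p_sex_fis = numeric(), note = character())
  list(summary = summary, psex = psex, partition = part)
}
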