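#' Specification of a synthetic population
#'
#' Captures the generative "world" the microsatellite pipeline assumes:
#' panmictic cyclic parthenogens (Hardy-Weinberg draws with an optional
#' inbreeding coefficient F), obligate clones descended from a handful of
#' founder genotypes (optionally F1 hybrids between two divergent allele
#' pools, which fixes heterozygosity), or a mixture of both.  Defaults
#' reflect the motivating study system: 8 microsatellite loci with 5-22
#' alleles per locus, populations of a few dozen individuals, strongly
#' skewed (geometric) clone copy numbers.
#'
#' @param mode `"cyclic"`, `"obligate"` or `"mixed"`.
#' @param n number of individuals.
#' @param n_loci number of loci.
#' @param alleles_range integer length-2: min/max alleles per locus.
#' @param dirichlet Dirichlet concentration for allele frequencies (1 =
#'   uniform over the simplex).
#' @param F inbreeding coefficient for the cyclic component.
#' @param n_clones number of founder clones for the obligate component.
#' @param copy_law `"geometric"` (skewed clone sizes) or `"uniform"`.
#' @param hybrid draw founder alleles one from each of two disjoint pools
#'   (fixed heterozygosity at every locus)?
#' @param asexual_fraction fraction of clonal individuals in mixed mode.
#' @param missing_rate per-call missingness probability.
#' @param mutation_rate per allele copy probability of a +/-1 stepwise
#'   mutation in clone copies.
#' @param pop_name population label.
#' @param seed RNG seed.
#' @return object of class `population_spec` (a validated list).
#' @export
population_spec <- function(mode = c("cyclic", "obligate", "mixed"),
                            n = 30L, n_loci = 8L,
                            alleles_range = c(5L, 22L), dirichlet = 1,
                            F = 0, n_clones = 5L,
                            copy_law = c("geometric", "uniform"),
                            hybrid = TRUE, asexual_fraction = 0.5,
                            missing_rate = 0, mutation_rate = 0,
                            pop_name = "pop_1", seed = 1L) {
  mode <- match.arg(mode)
  copy_law <- match.arg(copy_law)
  stopifnot(n >= 1L, n_loci >= 1L, length(alleles_range) == 2L,
            alleles_range[1L] >= 2L, alleles_range[2L] >= alleles_range[1L],
            dirichlet > 0, missing_rate >= 0, missing_rate < 1,
            mutation_rate >= 0, mutation_rate < 1)
  if (F < -1 || F > 1) stop("F must be in [-1, 1]")
  if (n_clones > n) stop("clone count cannot exceed n")
  if (mode == "mixed" && (asexual_fraction <= 0 || asexual_fraction >= 1))
    stop("asexual_fraction must be in (0, 1) for mixed mode")
  structure(list(mode = mode, n = as.integer(n), n_loci = as.integer(n_loci),
                 alleles_range = as.integer(alleles_range),
                 dirichlet = dirichlet, F = F,
                 n_clones = as.integer(n_clones), copy_law = copy_law,
                 hybrid = hybrid, asexual_fraction = asexual_fraction,
                 missing_rate = missing_rate, mutation_rate = mutation_rate,
                 pop_name = pop_name, seed = as.integer(seed)),
            class = "population_spec")
}

# Dirichlet(concentration) frequencies for k alleles labelled by `labels`
.rdirichlet_freqs <- function(k, conc, labels) {
  x <- stats::rgamma(k, shape = conc)
  while (sum(x) == 0) x <- stats::rgamma(k, shape = conc)
  stats::setNames(x / sum(x), labels)
}

# draw allele pools: per locus a named frequency vector; pool B (for
# hybrid founders) uses an offset label range so the two pools are
# disjoint
.draw_pools <- function(spec, offset_b = 500L) {
  kvals <- seq(spec$alleles_range[1L], spec$alleles_range[2L])
  k <- kvals[sample.int(length(kvals), spec$n_loci, replace = TRUE)]
  poolA <- lapply(k, function(kk)
    .rdirichlet_freqs(kk, spec$dirichlet, sprintf("%03d", seq_len(kk))))
  poolB <- lapply(k, function(kk)
    .rdirichlet_freqs(kk, spec$dirichlet,
                      sprintf("%03d", offset_b + seq_len(kk))))
  loci <- sprintf("loc%02d", seq_len(spec$n_loci))
  list(A = stats::setNames(poolA, loci), B = stats::setNames(poolB, loci),
       loci = loci)
}

# sample n genotypes at one locus under HW with inbreeding F; returns
# 2 x n character matrix.  F < 0 is handled through explicit genotype
# probabilities (hom: p^2 + p(1-p)F, het: 2pq(1-F)) with clamping; an F
# below the feasibility bound -p_min/(1 - p_min) is an error.
.sample_locus <- function(freqs, n, F) {
  k <- length(freqs)
  if (F < 0) {
    pmin_ <- min(freqs)
    if (F < -pmin_ / (1 - pmin_) - 1e-12)
      stop(sprintf("F = %.3f below feasibility bound %.3f for these frequencies",
                   F, -pmin_ / (1 - pmin_)))
  }
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pr <- freqs[idx[, 1L]] * freqs[idx[, 2L]]
  pr <- ifelse(idx[, 1L] == idx[, 2L],
               pr + freqs[idx[, 1L]] * (1 - freqs[idx[, 1L]]) * F,
               2 * pr * (1 - F))
  pr <- pmax(0, pr)
  g <- sample.int(nrow(idx), n, replace = TRUE, prob = pr)
  lab <- names(freqs)
  rbind(lab[idx[g, 1L]], lab[idx[g, 2L]])
}

.inject_missing <- function(a1, a2, rate) {
  if (rate <= 0) return(list(a1 = a1, a2 = a2))
  drop <- matrix(stats::runif(length(a1)) < rate, nrow = nrow(a1))
  a1[drop] <- NA_character_; a2[drop] <- NA_character_
  list(a1 = a1, a2 = a2)
}

# internal: cyclic genotypes from given pools (no seeding, no missing)
.cyclic_draw <- function(pools, n, F, prefix, pop_name) {
  L <- length(pools$loci)
  a1 <- matrix(NA_character_, n, L); a2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    g <- .sample_locus(pools$A[[j]], n, F)
    a1[, j] <- g[1L, ]; a2[, j] <- g[2L, ]
  }
  genotype_dataset(sprintf("%s_%s%03d", pop_name, prefix, seq_len(n)),
                   rep(pop_name, n), pools$loci, a1, a2)
}

#' Simulate a panmictic (cyclic parthenogen) population
#'
#' Allele frequencies are Dirichlet draws per locus; genotypes are
#' independent across loci and follow inbreeding-adjusted Hardy-Weinberg
#' proportions (homozygote `p^2 + p(1-p)F`, heterozygote `2pq(1-F)`).
#' Returns the dataset together with a machine-readable truth record.
#'
#' @param spec a [population_spec()] with `mode = "cyclic"`.
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (frequencies, F, seed, per-individual origin).
#' @export
simulate_cyclic <- function(spec) {
  if (spec$mode != "cyclic") stop("spec mode must be 'cyclic'")
  set.seed(spec$seed)
  pools <- .draw_pools(spec)
  ds <- .cyclic_draw(pools, spec$n, spec$F, "cyc", spec$pop_name)
  m <- .inject_missing(ds$a1, ds$a2, spec$missing_rate)
  ds <- genotype_dataset(ds$individuals, unname(ds$populations), ds$loci,
                         m$a1, m$a2)
  list(dataset = ds,
       truth = list(mode = "cyclic", freqs = pools$A, F = spec$F,
                    seed = spec$seed,
                    origin = stats::setNames(rep("sexual", spec$n),
                                             ds$individuals)))
}

# stepwise mutation: with prob rate per allele copy move one step on the
# integer allele ladder (reflect at 1 so labels stay positive)
.mutate_copies <- function(a, rate) {
  hit <- stats::runif(length(a)) < rate
  if (!any(hit)) return(a)
  v <- as.integer(a[hit])
  step <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
  v <- pmax(1L, v + step)
  a[hit] <- sprintf("%03d", v)
  a
}

# skewed copy numbers for n_clones clones summing to n, each >= 1
.copy_numbers <- function(n, n_clones, law) {
  if (n_clones == 1L) return(n)
  w <- switch(law,
              geometric = 0.5^(seq_len(n_clones) - 1L),
              uniform = rep(1, n_clones))
  extra <- stats::rmultinom(1L, n - n_clones, prob = w)[, 1L]
  as.integer(extra + 1L)
}

#' Simulate an obligately parthenogenetic (clonal) population
#'
#' Draws `n_clones` founder genotypes and copies them with skewed copy
#' numbers.  With `hybrid = TRUE` each founder receives one allele from
#' pool A and one from pool B per locus; the pools have disjoint allele
#' labels, so founders are heterozygous at every locus (the fixed
#' heterozygosity / strongly negative Fis signature of F1-hybrid clones).
#' Optional stepwise mutation perturbs copies on the integer allele
#' ladder.
#'
#' @param spec a [population_spec()] with `mode = "obligate"`.
#' @return list with `dataset` and `truth` (founder genotypes, copy
#'   numbers, per-individual founder of origin).
#' @export
simulate_obligate <- function(spec) {
  if (spec$mode != "obligate") stop("spec mode must be 'obligate'")
  set.seed(spec$seed)
  pools <- .draw_pools(spec)
  L <- spec$n_loci
  founders_a1 <- matrix(NA_character_, spec$n_clones, L)
  founders_a2 <- matrix(NA_character_, spec$n_clones, L)
  for (j in seq_len(L)) {
    fa <- pools$A[[j]]
    fb <- if (spec$hybrid) pools$B[[j]] else pools$A[[j]]
    x <- names(fa)[sample.int(length(fa), spec$n_clones, replace = TRUE,
                              prob = fa)]
    y <- names(fb)[sample.int(length(fb), spec$n_clones, replace = TRUE,
                              prob = fb)]
    founders_a1[, j] <- pmin(x, y); founders_a2[, j] <- pmax(x, y)
  }
  copies <- .copy_numbers(spec$n, spec$n_clones, spec$copy_law)
  origin <- rep(seq_len(spec$n_clones), copies)
  a1 <- founders_a1[origin, , drop = FALSE]
  a2 <- founders_a2[origin, , drop = FALSE]
  if (spec$mutation_rate > 0) {
    a1 <- matrix(.mutate_copies(a1, spec$mutation_rate), nrow = spec$n)
    a2 <- matrix(.mutate_copies(a2, spec$mutation_rate), nrow = spec$n)
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  m <- .inject_missing(a1, a2, spec$missing_rate)
  ids <- sprintf("%s_clo%03d", spec$pop_name, seq_len(spec$n))
  ds <- genotype_dataset(ids, rep(spec$pop_name, spec$n), pools$loci,
                         m$a1, m$a2)
  list(dataset = ds,
       truth = list(mode = "obligate",
                    founders = list(a1 = founders_a1, a2 = founders_a2),
                    copy_numbers = copies,
                    origin = stats::setNames(paste0("founder_", origin),
                                             ids),
                    hybrid = spec$hybrid, seed = spec$seed,
                    pools = pools[c("A", "B")]))
}

#' Simulate a population with a mixed breeding system
#'
#' Concatenates a cyclic (sexual) draw and an obligate (clonal) draw that
#' share the same allele pools; the truth record labels each individual's
#' origin.  `asexual_fraction` controls the clonal share.
#'
#' @param spec a [population_spec()] with `mode = "mixed"`.
#' @return list with `dataset` and `truth`.
#' @export
simulate_mixed <- function(spec) {
  if (spec$mode != "mixed") stop("spec mode must be 'mixed'")
  set.seed(spec$seed)
  pools <- .draw_pools(spec)
  n_asex <- max(1L, round(spec$n * spec$asexual_fraction))
  n_sex <- spec$n - n_asex
  L <- spec$n_loci
  # sexual component from pool A
  sex <- .cyclic_draw(pools, n_sex, spec$F, "sex", spec$pop_name)
  # clonal component: founders from the same pools
  n_clones <- min(spec$n_clones, n_asex)
  fa1 <- matrix(NA_character_, n_clones, L)
  fa2 <- matrix(NA_character_, n_clones, L)
  for (j in seq_len(L)) {
    fa <- pools$A[[j]]
    fb <- if (spec$hybrid) pools$B[[j]] else pools$A[[j]]
    x <- names(fa)[sample.int(length(fa), n_clones, replace = TRUE,
                              prob = fa)]
    y <- names(fb)[sample.int(length(fb), n_clones, replace = TRUE,
                              prob = fb)]
    fa1[, j] <- pmin(x, y); fa2[, j] <- pmax(x, y)
  }
  copies <- .copy_numbers(n_asex, n_clones, spec$copy_law)
  origin_c <- rep(seq_len(n_clones), copies)
  a1 <- rbind(sex$a1, fa1[origin_c, , drop = FALSE])
  a2 <- rbind(sex$a2, fa2[origin_c, , drop = FALSE])
  ids <- c(sex$individuals, sprintf("%s_clo%03d", spec$pop_name, seq_len(n_asex)))
  m <- .inject_missing(a1, a2, spec$missing_rate)
  ds <- genotype_dataset(ids, rep(spec$pop_name, spec$n), pools$loci,
                         m$a1, m$a2)
  origin <- stats::setNames(c(rep("sexual", n_sex),
                              paste0("founder_", origin_c)), ids)
  list(dataset = ds,
       truth = list(mode = "mixed", origin = origin,
                    asexual_fraction = spec$asexual_fraction,
                    copy_numbers = copies, seed = spec$seed))
}

#' Simulate a population according to its spec mode
#' @param spec a [population_spec()].
#' @return list with `dataset` and `truth`.
#' @export
simulate_population <- function(spec) {
  switch(spec$mode,
         cyclic = simulate_cyclic(spec),
         obligate = simulate_obligate(spec),
         mixed = simulate_mixed(spec))
}

#' Simulate two divergent parental populations and their F1 hybrids
#'
#' Draws two allele pools with disjoint labels, simulates a panmictic
#' population from each (populations `parA`, `parB`) and builds an F1
#' hybrid population (`hyb`) whose individuals carry one allele from each
#' pool per locus.  This is the constructed scenario behind the
#' "hybrid group sits between its parents in ordination space" check.
#'
#' @param n_per_group individuals per group.
#' @param n_loci number of loci.
#' @param alleles_range min/max alleles per locus.
#' @param dirichlet Dirichlet concentration.
#' @param seed RNG seed.
#' @return list with `dataset` (three populations) and `truth`.
#' @export
simulate_hybrid_panel <- function(n_per_group = 15L, n_loci = 8L,
                                  alleles_range = c(5L, 22L),
                                  dirichlet = 1, seed = 1L) {
  spec <- population_spec("cyclic", n = n_per_group, n_loci = n_loci,
                          alleles_range = alleles_range,
                          dirichlet = dirichlet, seed = seed)
  set.seed(seed)
  pools <- .draw_pools(spec)
  n <- n_per_group; L <- n_loci
  draw_from <- function(pool, prefix, pop) {
    a1 <- matrix(NA_character_, n, L); a2 <- matrix(NA_character_, n, L)
    for (j in seq_len(L)) {
      g <- .sample_locus(pool[[j]], n, 0)
      a1[, j] <- g[1L, ]; a2[, j] <- g[2L, ]
    }
    genotype_dataset(sprintf("%s%03d", prefix, seq_len(n)),
                     rep(pop, n), pools$loci, a1, a2)
  }
  pa <- draw_from(pools$A, "A", "parA")
  pb <- draw_from(pools$B, "B", "parB")
  h1 <- matrix(NA_character_, n, L); h2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    x <- names(pools$A[[j]])[sample.int(length(pools$A[[j]]), n, TRUE,
                                        prob = pools$A[[j]])]
    y <- names(pools$B[[j]])[sample.int(length(pools$B[[j]]), n, TRUE,
                                        prob = pools$B[[j]])]
    h1[, j] <- pmin(x, y); h2[, j] <- pmax(x, y)
  }
  hy <- genotype_dataset(sprintf("H%03d", seq_len(n)), rep("hyb", n),
                         pools$loci, h1, h2)
  ds <- genotype_dataset(
    c(pa$individuals, pb$individuals, hy$individuals),
    c(unname(pa$populations), unname(pb$populations),
      unname(hy$populations)),
    pools$loci, rbind(pa$a1, pb$a1, hy$a1), rbind(pa$a2, pb$a2, hy$a2))
  list(dataset = ds,
       truth = list(pools = pools[c("A", "B")], seed = seed,
                    groups = stats::setNames(unname(ds$populations),
                                             ds$individuals)))
}

#' Simulate aligned mtDNA haplotype sets
#'
#' Template haplotypes are generated by mutating a random ancestral
#' sequence at `ceil(divergence * length)` random sites each (re-drawn
#' until pairwise distinct); the `n_sequences` sequences are assigned to
#' templates by a geometric (skewed) or uniform frequency law with every
#' template represented at least once.  Optionally an ApoI recognition
#' site (`GAATTC`) is planted at a fixed position in all templates, with
#' all accidental sites elsewhere scrubbed so the planted site is the
#' only cut; `scrub_apoi = TRUE` without planting yields site-free
#' sequences.
#'
#' @param n_sequences number of sequences.
#' @param n_haplotypes number of distinct templates (<= n_sequences).
#' @param length alignment length.
#' @param divergence per-template fraction of mutated sites in (0, 1).
#' @param region_labels optional region label vector (length
#'   `n_sequences`, or one label recycled).
#' @param seed RNG seed.
#' @param frequency_law `"geometric"` or `"uniform"`.
#' @param plant_apoi_at optional 1-based position at which to plant an
#'   ApoI site (the cut then falls after this position).
#' @param scrub_apoi remove all (other) ApoI sites.
#' @return a [haplotype_set()] with attribute `truth` (templates,
#'   assignment, seed).
#' @export
simulate_haplotypes <- function(n_sequences, n_haplotypes, length = 591L,
                                divergence = 0.03, region_labels = NULL,
                                seed = 1L,
                                frequency_law = c("geometric", "uniform"),
                                plant_apoi_at = NULL, scrub_apoi = FALSE) {
  frequency_law <- match.arg(frequency_law)
  if (n_haplotypes > n_sequences)
    stop("n_haplotypes cannot exceed n_sequences")
  if (divergence <= 0 || divergence >= 1)
    stop("divergence must be in (0, 1)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  n_mut <- max(1L, ceiling(divergence * length))
  make_template <- function() {
    s <- anc
    pos <- sample.int(length, n_mut)
    s[pos] <- vapply(s[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1L))
    s
  }
  templates <- character(n_haplotypes)
  for (i in seq_len(n_haplotypes)) {
    for (try in 1:100) {
      cand <- paste(make_template(), collapse = "")
      if (!cand %in% templates[seq_len(i - 1L)]) break
    }
    if (cand %in% templates[seq_len(i - 1L)])
      stop("could not generate distinct templates; increase divergence")
    templates[i] <- cand
  }
  scrub <- function(s, keep_at = NULL) {
    x <- strsplit(s, "")[[1L]]
    repeat {
      hits <- apoi_digest(paste(x, collapse = ""))$cuts
      hits <- setdiff(hits, keep_at)
      if (!length(hits)) break
      x[hits[1L]] <- "C"    # C is not R: destroys the site
    }
    paste(x, collapse = "")
  }
  if (!is.null(plant_apoi_at)) {
    p <- as.integer(plant_apoi_at)
    if (p < 1L || p + 5L > length)
      stop("planted site does not fit in the sequence")
    templates <- vapply(templates, function(s) {
      substr(s, p, p + 5L) <- "GAATTC"
      scrub(s, keep_at = p)
    }, character(1L), USE.NAMES = FALSE)
  } else if (scrub_apoi) {
    templates <- vapply(templates, scrub, character(1L), USE.NAMES = FALSE)
  }
  w <- switch(frequency_law,
              geometric = 0.5^(seq_len(n_haplotypes) - 1L),
              uniform = rep(1, n_haplotypes))
  extra <- stats::rmultinom(1L, n_sequences - n_haplotypes, prob = w)[, 1L]
  counts <- extra + 1L
  assignment <- rep(seq_len(n_haplotypes), counts)
  seqs <- templates[assignment]
  if (!is.null(region_labels) && length(region_labels) == 1L)
    region_labels <- rep(region_labels, n_sequences)
  hs <- haplotype_set(seqs, labels = sprintf("sim%03d",
                                             seq_len(n_sequences)),
                      regions = region_labels)
  attr(hs, "truth") <- list(templates = templates, assignment = assignment,
                            counts = counts, seed = seed)
  hs
}

#' Write a simulation truth record as JSON
#'
#' @param truth the `truth` element of a simulation result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
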