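#' Diploid multilocus genotype dataset
#'
#' The central container of the package: a set of diploid individuals typed
#' at a common panel of codominant loci (microsatellites in the motivating
#' application), each individual assigned to a population and, optionally,
#' populations grouped into regions.
#'
#' Allele calls are stored as two character matrices `a1`, `a2`
#' (individuals x loci) that are *order-normalized*: `a1[i, l] <= a2[i, l]`
#' so that the unordered genotype AB is identical to BA.  A missing call is
#' `NA` in both matrices; half-missing calls are not representable (they are
#' coerced to fully missing by the readers, since every downstream statistic
#' assumes two observed alleles).
#'
#' Allele labels are opaque strings: all statistics depend on allele
#' identity only, never on fragment size.
#'
#' @param individuals character vector of unique individual identifiers.
#' @param populations character vector, one population label per individual.
#' @param loci character vector of unique locus names.
#' @param a1,a2 character matrices (`length(individuals)` x `length(loci)`)
#'   of allele labels; pairs need not be pre-sorted.
#' @param regions optional named character vector mapping population label
#'   to region label.
#'
#' @return An object of class `genotype_dataset` with elements
#'   `individuals`, `populations`, `regions`, `loci`, `a1`, `a2`,
#'   `ploidy` (always 2).
#' @export
genotype_dataset <- function(individuals, populations, loci, a1, a2,
                             regions = NULL) {
  individuals <- as.character(individuals)
  populations <- as.character(populations)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  mode(a1) <- "character"; mode(a2) <- "character"
  n <- length(individuals)
  if (anyDuplicated(individuals))
    stop("duplicate individual IDs: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (length(populations) != n)
    stop("'populations' must have one label per individual")
  if (any(!nzchar(populations)) || anyNA(populations))
    stop("population labels must be non-empty")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (!all(dim(a1) == c(n, length(loci))) ||
      !all(dim(a2) == c(n, length(loci))))
    stop("allele matrices must be individuals x loci")
  # order-normalize so AB == BA; a half-missing pair is invalid
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls are not representable; coerce to missing first")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(individuals = individuals,
         populations = stats::setNames(populations, individuals),
         regions = regions,
         loci = loci, a1 = a1, a2 = a2, ploidy = 2L),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d population(s)\n",
              length(x$individuals), length(x$loci),
              length(unique(x$populations))))
  nm <- sum(is.na(x$a1))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm,
              100 * nm / length(x$a1)))
  invisible(x)
}

#' Number of individuals
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(dataset) length(dataset$individuals)

#' Subset a genotype dataset by individuals
#'
#' Keeps individuals in their original order regardless of the order of
#' `keep`.
#'
#' @param dataset a `genotype_dataset`.
#' @param keep character vector of individual IDs or logical/integer index.
#' @return a `genotype_dataset`.
#' @export
subset_individuals <- function(dataset, keep) {
  if (is.character(keep)) keep <- dataset$individuals %in% keep
  idx <- seq_along(dataset$individuals)[keep]
  idx <- sort(idx)
  genotype_dataset(dataset$individuals[idx],
                   unname(dataset$populations[idx]),
                   dataset$loci,
                   dataset$a1[idx, , drop = FALSE],
                   dataset$a2[idx, , drop = FALSE],
                   regions = dataset$regions)
}

#' Split a dataset into one dataset per population
#' @param dataset a `genotype_dataset`.
#' @return named list of `genotype_dataset`, in order of first appearance.
#' @export
split_populations <- function(dataset) {
  pops <- unique(unname(dataset$populations))
  out <- lapply(pops, function(p)
    subset_individuals(dataset, unname(dataset$populations) == p))
  stats::setNames(out, pops)
}

#' Keep only individuals with a complete multilocus genotype
#'
#' Drops every individual with at least one missing call, reporting how
#' many individuals were removed per population.  Idempotent; may return an
#' empty dataset (with a warning) if no individual is complete.
#'
#' @param dataset a `genotype_dataset`.
#' @param quiet suppress the per-population removal message.
#' @return a `genotype_dataset` containing only complete individuals.
#' @export
complete_cases_genotypes <- function(dataset, quiet = FALSE) {
  ok <- rowSums(is.na(dataset$a1)) == 0L
  if (!all(ok) && !quiet) {
    rem <- table(unname(dataset$populations)[!ok])
    message("complete_cases_genotypes: removed ",
            sum(!ok), " individual(s): ",
            paste(sprintf("%s=%d", names(rem), rem), collapse = ", "))
  }
  if (!any(ok)) warning("no individual has a complete genotype")
  subset_individuals(dataset, ok)
}

# genotype string per individual, e.g. "012/015|003/003"; assumes complete
.genotype_strings <- function(dataset) {
  apply(matrix(paste(dataset$a1, dataset$a2, sep = "/"),
               nrow = length(dataset$individuals)),
        1L, paste, collapse = "|")
}

.assert_complete <- function(dataset) {
  if (anyNA(dataset$a1))
    stop("dataset contains missing calls; run complete_cases_genotypes() first")
}
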