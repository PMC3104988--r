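#' Haplotype set: aligned sequences collapsed to unique haplotypes
#'
#' Stores equal-length nucleotide sequences (alphabet `A C G T N -`),
#' their labels and optional region assignment, together with the
#' collapsed haplotypes: unique sequences in order of first occurrence,
#' with counts.  Haplotype identifiers are deterministic (`H01`, `H02`,
#' ... by first occurrence).
#'
#' @param sequences character vector of equal-length sequences.
#' @param labels optional sequence labels (default `seq_1`, ...).
#' @param regions optional character vector of region labels, one per
#'   sequence.
#' @return object of class `haplotype_set`: list with `sequences`,
#'   `labels`, `regions`, `hap_id` (per sequence), `haplotypes` (named
#'   character), `counts` (named integer), `length`.
#' @export
haplotype_set <- function(sequences, labels = NULL, regions = NULL) {
  sequences <- toupper(as.character(sequences))
  if (!length(sequences)) stop("no sequences")
  L <- nchar(sequences)
  if (any(L != L[1L])) stop("sequences must have equal length")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) stop("invalid characters in sequence(s) ",
                     paste(which(bad), collapse = ", "))
  if (is.null(labels)) labels <- paste0("seq_", seq_along(sequences))
  if (!is.null(regions) && length(regions) != length(sequences))
    stop("'regions' must have one label per sequence")
  first <- !duplicated(sequences)
  haps <- sequences[first]
  ids <- sprintf("H%0*d", max(2L, nchar(length(haps))), seq_along(haps))
  hap_id <- ids[match(sequences, haps)]
  counts <- stats::setNames(as.integer(table(factor(hap_id, levels = ids))),
                            ids)
  structure(list(sequences = sequences, labels = labels, regions = regions,
                 hap_id = hap_id,
                 haplotypes = stats::setNames(haps, ids),
                 counts = counts, length = L[1L]),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d sequences of length %d, %d haplotypes\n",
              length(x$sequences), x$length, length(x$haplotypes)))
  invisible(x)
}

#' Collapse aligned sequences to haplotypes
#'
#' @param x a character vector of aligned sequences or an existing
#'   [haplotype_set()].
#' @param ... passed to [haplotype_set()].
#' @return a [haplotype_set()].
#' @export
collapse_haplotypes <- function(x, ...) {
  if (inherits(x, "haplotype_set")) return(x)
  haplotype_set(x, ...)
}

#' Read aligned FASTA sequences into a haplotype set
#'
#' @param path FASTA file.
#' @param regions optional region labels (recycled named vector keyed by
#'   sequence label, or one per sequence).
#' @return a [haplotype_set()].
#' @export
read_fasta_haplotypes <- function(path, regions = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s)
    paste(toupper(s), collapse = ""), character(1L))
  if (!is.null(names(regions)))
    regions <- unname(regions[names(dna)])
  haplotype_set(unname(seqs), labels = names(dna), regions = regions)
}

#' Write haplotype-set sequences to FASTA
#'
#' @param hapset a [haplotype_set()].
#' @param path output path.
#' @param unique_only write one record per haplotype instead of all
#'   sequences.
#' @return `path`, invisibly.
#' @export
write_fasta_haplotypes <- function(hapset, path, unique_only = FALSE) {
  if (unique_only) {
    seqs <- hapset$haplotypes; labs <- names(hapset$haplotypes)
  } else {
    seqs <- hapset$sequences; labs <- hapset$labels
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", labs), seqs)), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Unbiased haplotype diversity
#'
#' `h = n (1 - sum f_i^2) / (n - 1)` with `f_i` the haplotype relative
#' frequencies; its sampling standard deviation follows Nei's (1987)
#' variance formula.  `NA` for fewer than 2 sequences.
#'
#' @param hapset a [haplotype_set()].
#' @return named numeric `c(h =, sd =, n =, k =)`.
#' @export
haplotype_diversity <- function(hapset) {
  n <- length(hapset$sequences)
  if (n < 2L) return(c(h = NA_real_, sd = NA_real_, n = n,
                       k = length(hapset$haplotypes)))
  f <- hapset$counts / n
  s2 <- sum(f^2); s3 <- sum(f^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(0, v)), n = n, k = length(hapset$haplotypes))
}

# pairwise difference count and comparable-site count between two
# sequences; sites with N or '-' in either sequence are excluded when
# deletion = "pairwise" (they have already been removed globally under
# complete deletion).
.seq_diff <- function(s1, s2) {
  x <- strsplit(s1, "")[[1L]]; y <- strsplit(s2, "")[[1L]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  c(diff = sum(x[ok] != y[ok]), comparable = sum(ok))
}

.valid_site_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

#' Nucleotide diversity and segregating sites
#'
#' `pi` is the mean per-site pairwise difference across all sequence
#' pairs; `S` the number of variable sites.  Sites with `N` or gaps are
#' excluded pairwise (each pair compared over its own comparable sites) or
#' globally (`deletion = "complete"`).  The standard deviation uses Nei's
#' (1987) total variance for pi.
#'
#' @param hapset a [haplotype_set()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return named numeric `c(pi =, sd =, S =, n =, L =)`.
#' @export
nucleotide_diversity <- function(hapset, deletion = c("pairwise",
                                                      "complete")) {
  deletion <- match.arg(deletion)
  n <- length(hapset$sequences)
  haps <- hapset$haplotypes
  cnt <- hapset$counts
  mat <- .valid_site_matrix(unname(haps))
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(mat)
    if (!any(keep)) return(c(pi = NA_real_, sd = NA_real_, S = 0L,
                             n = n, L = 0L))
    mat <- mat[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  # segregating sites: >=2 distinct valid bases at a site, over all seqs
  S <- sum(apply(mat, 2L, function(col) {
    b <- unique(col[col %in% c("A", "C", "G", "T")])
    length(b) >= 2L
  }))
  if (n < 2L) return(c(pi = NA_real_, sd = NA_real_, S = S, n = n,
                       L = ncol(mat)))
  k <- length(cnt)
  num <- 0; tot_pairs <- n * (n - 1) / 2
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      ok <- valid[i, ] & valid[j, ]
      cs <- sum(ok)
      if (cs == 0L) next
      dd <- sum(mat[i, ok] != mat[j, ok])
      num <- num + cnt[i] * cnt[j] * dd / cs
    }
  }
  pi <- unname(num / tot_pairs)
  L <- ncol(mat)
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  c(pi = pi, sd = sqrt(max(0, v)), S = S, n = n, L = L)
}

#' Per-region diversity summary
#'
#' Computes n, k, S, h and pi for every region of a haplotype set (the
#' layout of a regional mtDNA polymorphism table), plus a `Total` row.
#'
#' @param hapset a [haplotype_set()] with `regions`.
#' @return data.frame with columns region, n, k, S, h, h_sd, pi, pi_sd.
#' @export
diversity_summary <- function(hapset) {
  if (is.null(hapset$regions)) stop("haplotype set has no region labels")
  regions <- unique(hapset$regions)
  one <- function(idx, name) {
    hs <- haplotype_set(hapset$sequences[idx], hapset$labels[idx])
    hd <- haplotype_diversity(hs)
    nd <- nucleotide_diversity(hs)
    data.frame(region = name, n = as.integer(hd[["n"]]),
               k = as.integer(hd[["k"]]), S = as.integer(nd[["S"]]),
               h = hd[["h"]], h_sd = hd[["sd"]],
               pi = nd[["pi"]], pi_sd = nd[["sd"]])
  }
  rows <- lapply(regions, function(r) one(hapset$regions == r, r))
  rows[[length(rows) + 1L]] <- one(rep(TRUE, length(hapset$sequences)),
                                   "Total")
  do.call(rbind, rows)
}

#' Within-, between- and net p-distances among regions
#'
#' `within` is the mean pairwise per-site distance inside a region
#' (`NA` with fewer than 2 sequences), `between(A, B)` the mean over all
#' cross-region pairs, and `net(A, B) = between - (within_A +
#' within_B)/2`.
#'
#' @param hapset a [haplotype_set()] with `regions`.
#' @param deletion passed to the pairwise comparison (see
#'   [nucleotide_diversity()]).
#' @return list with `within` (named vector), `between` and `net`
#'   (matrices).
#' @export
region_distance_summary <- function(hapset, deletion = c("pairwise",
                                                         "complete")) {
  deletion <- match.arg(deletion)
  if (is.null(hapset$regions)) stop("haplotype set has no region labels")
  regions <- unique(hapset$regions)
  if (length(regions) < 2L) stop("need at least 2 regions")
  seqs <- hapset$sequences
  mat <- .valid_site_matrix(seqs)
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(mat)
    mat <- mat[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- length(seqs)
  pd <- matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    ok <- valid[i, ] & valid[j, ]
    pd[i, j] <- pd[j, i] <-
      if (any(ok)) sum(mat[i, ok] != mat[j, ok]) / sum(ok) else NA_real_
  }
  within <- vapply(regions, function(r) {
    idx <- which(hapset$regions == r)
    if (length(idx) < 2L) return(NA_real_)
    mean(pd[idx, idx][upper.tri(diag(length(idx)))])
  }, numeric(1L))
  between <- matrix(NA_real_, length(regions), length(regions),
                    dimnames = list(regions, regions))
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i == j) next
    ia <- which(hapset$regions == regions[i])
    ib <- which(hapset$regions == regions[j])
    between[i, j] <- mean(pd[ia, ib, drop = FALSE])
  }
  net <- between - (outer(within, within, "+")) / 2
  list(within = within, between = between, net = net)
}

#' In-silico ApoI restriction digestion
#'
#' Scans the linear sequence for the ApoI recognition site `R^AATTY`
#' (R = A/G, Y = C/T; cleavage after the R) and returns all cut positions
#' (1-based index of the last base of the 5' fragment) and the resulting
#' fragment lengths.  Ambiguous bases never match.
#'
#' The species-group call mirrors the diagnostic use of this enzyme on the
#' ND5 amplicon of the *Daphnia pulex* complex: lineages of the
#' *pulicaria* group carry a cleavage site near position 344 of the 711-bp
#' amplicon that members of the *tenebrosa* group lack.  A sequence with
#' at least one cut inside the `diagnostic_window` is called
#' `pulicaria-group`; a sequence covering the window but without a cut
#' there is called `tenebrosa-group`; a sequence too short to contain the
#' window is `ambiguous`.
#'
#' @param sequence a single nucleotide string.
#' @param diagnostic_window integer length-2 vector of 1-based positions
#'   within which a cut is diagnostic.
#' @return object of class `digest_result`: list with `cuts`, `fragments`,
#'   `group`, `n_sites`, `length`.
#' @export
apoi_digest <- function(sequence, diagnostic_window = c(300L, 400L)) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  L <- nchar(sequence)
  cuts <- integer()
  if (L >= 6L) {
    x <- strsplit(sequence, "")[[1L]]
    for (i in seq_len(L - 5L)) {
      if ((x[i] == "A" || x[i] == "G") &&
          x[i + 1L] == "A" && x[i + 2L] == "A" &&
          x[i + 3L] == "T" && x[i + 4L] == "T" &&
          (x[i + 5L] == "C" || x[i + 5L] == "T"))
        cuts <- c(cuts, i)
    }
  }
  fragments <- diff(c(0L, cuts, L))
  in_window <- any(cuts >= diagnostic_window[1L] &
                     cuts <= diagnostic_window[2L])
  group <- if (in_window) "pulicaria-group"
           else if (L < diagnostic_window[1L]) "ambiguous"
           else "tenebrosa-group"
  structure(list(cuts = cuts, fragments = fragments, group = group,
                 n_sites = length(cuts), length = L),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("ApoI digest: %d site(s), fragments [%s] -> %s\n",
              x$n_sites, paste(x$fragments, collapse = ", "), x$group))
  invisible(x)
}

#' Digest every sequence of a haplotype set
#'
#' @param hapset a [haplotype_set()].
#' @param ... passed to [apoi_digest()].
#' @return data.frame with label, n_sites, cuts, fragments, group.
#' @export
digest_haplotypes <- function(hapset, ...) {
  rows <- lapply(seq_along(hapset$sequences), function(i) {
    dg <- apoi_digest(hapset$sequences[i], ...)
    data.frame(label = hapset$labels[i], n_sites = dg$n_sites,
               cuts = paste(dg$cuts, collapse = ","),
               fragments = paste(dg$fragments, collapse = ","),
               group = dg$group)
  })
  do.call(rbind, rows)
}
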