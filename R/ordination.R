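#' Binary allele presence/absence matrix
#'
#' One column per (locus, allele) combination observed anywhere in the
#' dataset; entry 1 iff the individual carries at least one copy.  This is
#' the coding used upstream of the Nei/Dice distance, which deliberately
#' ignores shared absences.
#'
#' @param dataset a complete [genotype_dataset()].
#' @return integer 0/1 matrix, rows = individuals, columns named
#'   `locus.allele`.
#' @export
binary_allele_matrix <- function(dataset) {
  .assert_complete(dataset)
  cols <- list()
  for (j in seq_along(dataset$loci)) {
    alleles <- sort(unique(c(dataset$a1[, j], dataset$a2[, j])))
    for (a in alleles) {
      cols[[paste(dataset$loci[j], a, sep = ".")]] <-
        as.integer(dataset$a1[, j] == a | dataset$a2[, j] == a)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- dataset$individuals
  m
}

#' Nei/Dice distance on a binary allele matrix
#'
#' Similarity `S = 2a / (2a + b + c)` where `a` counts shared presences
#' and `b`, `c` the presences unique to each row; distance is `1 - S`.
#' Shared absences do not contribute, which is the reason this index is
#' preferred for presence/absence allele codings.
#'
#' @param m 0/1 matrix (rows = individuals); all-zero rows are an error.
#' @return object of class `dist_matrix`: list with `labels`, `d`
#'   (symmetric matrix) and `metric`.
#' @export
nei_binary_distance <- function(m) {
  m <- as.matrix(m)
  if (any(rowSums(m) == 0)) stop("all-zero row: no alleles recorded")
  a <- m %*% t(m)                       # shared presences
  tot <- rowSums(m)
  denom <- outer(tot, tot, "+")         # 2a + b + c
  d <- 1 - 2 * a / denom
  diag(d) <- 0
  structure(list(labels = rownames(m), d = d, metric = "nei_binary"),
            class = "dist_matrix")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues; axes with negative eigenvalues are dropped and
#' reported (no Cailliez/Lingoes correction).  Percent variation is
#' computed over the positive eigenvalues only.
#'
#' @param dm a `dist_matrix` (from e.g. [nei_binary_distance()]), a `dist`
#'   object or a symmetric matrix.
#' @param tol relative tolerance below which an eigenvalue counts as zero.
#' @return object of class `pcoa_ordination`: list with `coords` (n x
#'   n_axes), `eigenvalues` (positive ones), `percent`,
#'   `negative_eigenvalues`, `labels`.
#' @export
pcoa <- function(dm, tol = 1e-9) {
  if (inherits(dm, "dist_matrix")) {
    D <- dm$d; labels <- dm$labels
  } else if (inherits(dm, "dist")) {
    D <- as.matrix(dm); labels <- attr(dm, "Labels")
  } else {
    D <- as.matrix(dm); labels <- rownames(D)
  }
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  thr <- tol * max(abs(e$values))
  pos <- e$values > thr
  neg <- e$values < -thr
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- labels
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coords = coords,
                 eigenvalues = e$values[pos],
                 percent = 100 * e$values[pos] / sum(e$values[pos]),
                 negative_eigenvalues = e$values[neg],
                 labels = labels),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("pcoa_ordination: %d points, %d positive axes", nrow(x$coords),
              ncol(x$coords)))
  if (ncol(x$coords) >= 2L)
    cat(sprintf(" (axis 1: %.1f%%, axis 2: %.1f%%)", x$percent[1L],
                x$percent[2L]))
  cat("\n")
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalue(s), largest magnitude %.3g\n",
                length(x$negative_eigenvalues),
                max(abs(x$negative_eigenvalues))))
  invisible(x)
}

#' Cascaded K-means with the Calinski-Harabasz criterion
#'
#' Runs K-means (Hartigan-Wong, best of `n_starts` restarts) on all
#' retained ordination axes for each K in `k_min:k_max` and selects the K
#' maximizing the Calinski-Harabasz criterion
#' `CH(K) = [B/(K-1)] / [W/(n-K)]`.  Deterministic given `seed`.  K values
#' exceeding the number of distinct points are skipped with a warning.  A
#' `low_confidence` flag is raised when the criterion is maximal at
#' `k_min` and decreases monotonically (no real cluster structure).
#'
#' @param ordination a [pcoa()] result (or any matrix of coordinates).
#' @param k_min,k_max range of cluster numbers to try.
#' @param n_starts random restarts per K.
#' @param seed RNG seed.
#' @return list with `best_k`, `labels` (named cluster vector for
#'   `best_k`), `criterion` (data.frame k, calinski), `low_confidence`.
#' @export
cascade_kmeans <- function(ordination, k_min = 2L, k_max = 10L,
                           n_starts = 25L, seed = 1L) {
  X <- if (inherits(ordination, "pcoa_ordination")) ordination$coords
       else as.matrix(ordination)
  n <- nrow(X)
  if (n < k_max + 1L)
    stop("need at least k_max + 1 points (have ", n, ")")
  ndistinct <- nrow(unique(X))
  set.seed(seed)
  ks <- k_min:k_max
  ch <- rep(NA_real_, length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    if (ndistinct < K) {
      warning("K = ", K, " skipped: only ", ndistinct, " distinct points")
      next
    }
    fit <- suppressWarnings(
      stats::kmeans(X, centers = K, nstart = n_starts, iter.max = 100L))
    ch[i] <- (fit$betweenss / (K - 1)) / (fit$tot.withinss / (n - K))
    fits[[i]] <- fit
  }
  if (all(is.na(ch))) stop("no K value could be fitted")
  best <- which.max(ch)
  labels <- stats::setNames(fits[[best]]$cluster, rownames(X))
  usable <- which(!is.na(ch))
  low_conf <- ks[best] == k_min &&
    length(usable) > 1L && all(diff(ch[usable]) < 0)
  list(best_k = ks[best], labels = labels,
       criterion = data.frame(k = ks, calinski = ch),
       low_confidence = low_conf)
}

#' Intermediacy of a putatively hybrid group in ordination space
#'
#' Projects the centroid of the test group onto the segment joining the
#' two parental centroids, in the full retained-axis space.  The returned
#' relative position `t` is 0 at parent A, 1 at parent B; the test group
#' is geometrically intermediate iff `0 < t < 1`.  The off-axis distance
#' (distance from the test centroid to the A-B line) is also returned.
#'
#' @param ordination a [pcoa()] result.
#' @param groups character vector of group labels, one per individual (in
#'   ordination row order), or named by individual.
#' @param parent_a,parent_b,test the three group labels.
#' @return list with `t`, `off_axis`, `intermediate`, `centroids`.
#' @export
hybrid_intermediacy <- function(ordination, groups, parent_a, parent_b,
                                test) {
  X <- ordination$coords
  if (!is.null(names(groups))) groups <- groups[rownames(X)]
  groups <- as.character(groups)
  if (length(groups) != nrow(X))
    stop("'groups' must label every ordinated individual")
  cent <- function(g) {
    idx <- which(groups == g)
    if (!length(idx)) stop("group '", g, "' has no members")
    colMeans(X[idx, , drop = FALSE])
  }
  ca <- cent(parent_a); cb <- cent(parent_b); ct <- cent(test)
  ab <- cb - ca
  denom <- sum(ab^2)
  if (denom == 0) stop("parental centroids coincide")
  t <- sum((ct - ca) * ab) / denom
  resid <- (ct - ca) - t * ab
  list(t = t, off_axis = sqrt(sum(resid^2)),
       intermediate = t > 0 && t < 1,
       centroids = rbind(parent_a = ca, parent_b = cb, test = ct))
}

#' Cavalli-Sforza and Edwards chord distance between two populations
#'
#' GENDIST-style normalization:
#' `D^2 = 4 sum_l (1 - sum_a sqrt(x_la y_la)) / sum_l (m_l - 1)` where
#' `m_l` is the number of distinct alleles at locus `l` (union of the two
#' populations); `D = sqrt(D^2)`.  The alternative per-locus
#' `2 sqrt(2) / pi` scaling can be selected with
#' `normalization = "angular"`.
#'
#' @param freqs_a,freqs_b `allele_freq_table`s (or plain named lists of
#'   per-locus frequency vectors) over the same loci.
#' @param normalization `"gendist"` (default) or `"angular"`.
#' @return numeric distance.
#' @export
chord_distance <- function(freqs_a, freqs_b,
                           normalization = c("gendist", "angular")) {
  normalization <- match.arg(normalization)
  fa <- if (inherits(freqs_a, "allele_freq_table")) freqs_a$freqs else freqs_a
  fb <- if (inherits(freqs_b, "allele_freq_table")) freqs_b$freqs else freqs_b
  if (!setequal(names(fa), names(fb)))
    stop("populations must share the same loci")
  loci <- names(fa)
  terms <- numeric(length(loci)); m <- integer(length(loci))
  for (i in seq_along(loci)) {
    alleles <- union(names(fa[[loci[i]]]), names(fb[[loci[i]]]))
    x <- fa[[loci[i]]][alleles]; x[is.na(x)] <- 0
    y <- fb[[loci[i]]][alleles]; y[is.na(y)] <- 0
    terms[i] <- 1 - sum(sqrt(x * y))
    m[i] <- length(alleles)
  }
  if (normalization == "gendist") {
    denom <- sum(m - 1L)
    if (denom == 0L) return(0)
    sqrt(4 * sum(terms) / denom)
  } else {
    mean(2 * sqrt(2) / pi * sqrt(2 * terms))
  }
}

#' Pairwise chord distances between all populations of a dataset
#'
#' @param dataset a complete [genotype_dataset()].
#' @param ... passed to [chord_distance()].
#' @return a symmetric matrix of chord distances.
#' @export
chord_distance_matrix <- function(dataset, ...) {
  ft <- allele_freqs(dataset, by = "population")
  pops <- names(ft)
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) > 1L) {
    for (i in seq_along(pops)[-length(pops)])
      for (j in seq((i + 1L), length(pops))) {
        D[i, j] <- D[j, i] <- chord_distance(ft[[i]], ft[[j]], ...)
      }
  }
  D
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies:
#' `AR = sum_a [1 - C(N - N_a, g) / C(N, g)]` with `N` the gene copies
#' sampled in the population and `N_a` the copies of allele `a`.  With
#' `g = "auto"` the rarefaction size is the smallest population's gene
#' count `2n`, so values are comparable across populations.  `AR` equals
#' the raw allele count when `g = N` and 1 at a monomorphic locus.
#'
#' @param dataset a complete [genotype_dataset()].
#' @param g rarefaction size in gene copies, or `"auto"`.
#' @return list with `per_locus` (matrix populations x loci), `mean`
#'   (named vector per population) and `g`.
#' @export
allelic_richness <- function(dataset, g = "auto") {
  .assert_complete(dataset)
  pops <- split_populations(dataset)
  sizes <- vapply(pops, function(d) 2L * length(d$individuals), integer(1L))
  if (identical(g, "auto")) g <- min(sizes)
  g <- as.integer(g)
  if (g < 1L) stop("g must be >= 1")
  if (g > min(sizes))
    stop("g exceeds the smallest population's gene count (", min(sizes), ")")
  ar <- matrix(NA_real_, length(pops), length(dataset$loci),
               dimnames = list(names(pops), dataset$loci))
  for (p in names(pops)) {
    d <- pops[[p]]
    N <- 2L * length(d$individuals)
    for (j in seq_along(d$loci)) {
      cnt <- table(c(d$a1[, j], d$a2[, j]))
      ar[p, j] <- sum(1 - exp(lchoose(N - as.numeric(cnt), g) -
                                lchoose(N, g)))
    }
  }
  list(per_locus = ar, mean = rowMeans(ar), g = g)
}
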