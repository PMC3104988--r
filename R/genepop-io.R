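#' Read a GenePop genotype file
#'
#' Parses the classic GenePop 4 dialect: a title line, one locus name per
#' line (or a single comma-separated line), `POP` separators, and one row
#' per individual of the form `id , 0102 0304 ...` with 2- or 3-digit
#' allele codes per allele.  The codes `00`/`000` denote a missing allele;
#' a call with both alleles missing is stored as missing.  A half-missing
#' call (one allele coded `000`) is coerced to fully missing with a
#' warning, because all downstream statistics assume two observed alleles.
#'
#' Populations are unnamed in the format; they receive labels `pop_1`,
#' `pop_2`, ... in file order (override with `pop_names`).  Individuals are
#' never reordered within a population.
#'
#' @param path file path.
#' @param pop_names optional character vector of population labels, one per
#'   `POP` block.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a GenePop file: fewer than 3 lines")
  body <- lines[-1L]                      # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a GenePop file: no POP separator found")
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("not a GenePop file: no locus names before POP")

  ids <- character(); pops <- character()
  a1 <- list(); a2 <- list()
  pop_i <- 0L; half_missing <- 0L
  for (k in seq(first_pop, length(body))) {
    ln <- body[k]
    if (toupper(trimws(ln)) == "POP") { pop_i <- pop_i + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop(sprintf("line %d: expected 'id , genotypes' row", k + 1L))
    id <- trimws(parts[1L])
    fields <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                       "[[:space:]]+")[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != length(loci))
      stop(sprintf("line %d: %d genotype fields but %d loci",
                   k + 1L, length(fields), length(loci)))
    w <- nchar(fields)
    if (any(w != w[1L]) || !w[1L] %in% c(4L, 6L))
      stop(sprintf("line %d: allele fields must all be 4 or 6 digits wide",
                   k + 1L))
    half <- w[1L] %/% 2L
    x1 <- substr(fields, 1L, half)
    x2 <- substr(fields, half + 1L, w[1L])
    miss_code <- strrep("0", half)
    m1 <- x1 == miss_code; m2 <- x2 == miss_code
    hm <- xor(m1, m2)
    half_missing <- half_missing + sum(hm)
    miss <- m1 | m2
    x1[miss] <- NA_character_; x2[miss] <- NA_character_
    ids <- c(ids, id)
    pops <- c(pops, as.character(pop_i))
    a1[[length(a1) + 1L]] <- x1
    a2[[length(a2) + 1L]] <- x2
  }
  if (half_missing > 0L)
    warning(half_missing,
            " half-missing call(s) coerced to fully missing")
  if (is.null(pop_names)) pop_names <- paste0("pop_", seq_len(pop_i))
  if (length(pop_names) != pop_i)
    stop("pop_names must have one label per POP block (found ", pop_i, ")")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  genotype_dataset(ids, pop_names[as.integer(pops)], loci,
                   do.call(rbind, a1), do.call(rbind, a2))
}

#' Write a GenePop genotype file
#'
#' Writes 3-digit allele codes (the preferred width on output; 2-digit
#' files are accepted on input).  Allele labels must therefore be integer
#' strings in 1..999; datasets with non-numeric labels or more than 999
#' distinct alleles at a locus are not representable and raise an error.
#' Missing calls become `000000`.  Population labels are not representable
#' in the format (blocks are separated by bare `POP` lines); a round trip
#' through [read_genepop()] restores them as `pop_1`, `pop_2`, ...
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "breedmode export") {
  lab <- c(dataset$a1, dataset$a2)
  lab <- lab[!is.na(lab)]
  if (length(lab)) {
    num <- suppressWarnings(as.integer(lab))
    if (anyNA(num) || any(num < 1L) || any(num > 999L))
      stop("allele labels must be integer strings in 1..999 for GenePop output")
  }
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", as.integer(x)))
  rows <- matrix(paste0(fmt(dataset$a1), fmt(dataset$a2)),
                 nrow = length(dataset$individuals))
  con <- file(path, open = "wb")   # binary mode forces LF endings
  on.exit(close(con))
  out <- c(title, dataset$loci)
  pops <- unname(dataset$populations)
  for (p in unique(pops)) {
    out <- c(out, "POP")
    idx <- which(pops == p)
    out <- c(out, paste(dataset$individuals[idx], ",",
                        apply(rows[idx, , drop = FALSE], 1L, paste,
                              collapse = " ")))
  }
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a genotype CSV file
#'
#' Expected header: `individual,population,<locus>_a,<locus>_b,...` with
#' one row per individual and two columns per locus.  An empty cell is a
#' missing allele; a half-missing call is coerced to fully missing with a
#' warning.
#'
#' @param path file path.
#' @return a [genotype_dataset()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = "")
  need <- c("individual", "population")
  if (!all(need %in% names(df)))
    stop("CSV must have 'individual' and 'population' columns")
  if (anyDuplicated(df$individual))
    stop("duplicate individual IDs: ",
         paste(unique(df$individual[duplicated(df$individual)]),
               collapse = ", "))
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  bcols <- paste0(loci, "_b")
  if (!all(bcols %in% names(df)))
    stop("each locus needs both <locus>_a and <locus>_b columns")
  a1 <- as.matrix(df[, acols, drop = FALSE])
  a2 <- as.matrix(df[, bcols, drop = FALSE])
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing call(s) coerced to fully missing")
    a1[half] <- NA_character_; a2[half] <- NA_character_
  }
  genotype_dataset(df$individual, df$population, loci, a1, a2)
}

#' Write a genotype CSV file
#'
#' Inverse of [read_genotype_csv()]; missing calls become empty cells.
#' UTF-8, LF line endings.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(dataset, path) {
  df <- data.frame(individual = dataset$individuals,
                   population = unname(dataset$populations),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(dataset$loci)) {
    df[[paste0(dataset$loci[j], "_a")]] <- dataset$a1[, j]
    df[[paste0(dataset$loci[j], "_b")]] <- dataset$a2[, j]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "", eol = "\n",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
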