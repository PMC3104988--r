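#' Classify a population's breeding system
#'
#' Implements the classical decision rules on the genotypic diversity
#' (GD) ratio and Hardy-Weinberg status:
#'
#' * rule 1 — GD ratio `< gd_threshold` AND out of Hardy-Weinberg
#'   equilibrium (Bonferroni-adjusted combined score-test p below
#'   `alpha`, either tail) -> `"obligate"`;
#' * rule 2 — GD ratio `> gd_threshold` AND in Hardy-Weinberg
#'   equilibrium -> `"cyclic"`;
#' * otherwise (including GD exactly at the threshold) ->
#'   `"mixed-or-uncertain"`.
#'
#' P_sex values, r_bar_d results and the Fis sign are advisory evidence
#' recorded in the rule trace, not part of the binary rule.
#'
#' @param stats list with required elements `gd_ratio`,
#'   `hwe_excess_p_adj`, `hwe_deficiency_p_adj` and optional `psex`
#'   (numeric vector), `psex_fis`, `rd1_p`, `rd2_p`, `fis`.
#' @param alpha significance level.
#' @param gd_threshold GD-ratio decision threshold.
#' @param psex_threshold threshold below which a repeated MLMG is deemed
#'   clonal (trace only).
#' @return list with `verdict` and `trace` (character vector).
#' @export
classify_population <- function(stats, alpha = 0.05, gd_threshold = 0.75,
                                psex_threshold = 0.01) {
  need <- c("gd_ratio", "hwe_excess_p_adj", "hwe_deficiency_p_adj")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("missing required statistic(s): ", paste(miss, collapse = ", "))
  for (nm in need) if (is.null(stats[[nm]]) || is.na(stats[[nm]]))
    stop("missing required statistic(s): ", nm)
  gd <- stats$gd_ratio
  pex <- stats$hwe_excess_p_adj
  pdef <- stats$hwe_deficiency_p_adj
  hwe_rejected <- min(pex, pdef) < alpha
  hwe_dir <- if (!hwe_rejected) "none"
             else if (pex <= pdef) "excess" else "deficiency"
  verdict <- if (gd < gd_threshold && hwe_rejected) "obligate"
             else if (gd > gd_threshold && !hwe_rejected) "cyclic"
             else "mixed-or-uncertain"
  trace <- c(
    sprintf("GD ratio = %.3f (threshold %.2f): %s", gd, gd_threshold,
            if (gd < gd_threshold) "below" else if (gd > gd_threshold)
              "above" else "at threshold"),
    sprintf("HWE %s (adjusted p: excess %.3g, deficiency %.3g, alpha %.2f%s)",
            if (hwe_rejected) paste0("rejected, heterozygote ", hwe_dir)
            else "not rejected", pex, pdef, alpha,
            if (hwe_dir == "excess") "; excess direction recorded" else ""),
    sprintf("rule fired: %s",
            if (verdict == "obligate") "1 (GD below threshold & HWE rejected)"
            else if (verdict == "cyclic")
              "2 (GD above threshold & HWE not rejected)"
            else "neither 1 nor 2 -> mixed-or-uncertain"))
  if (!is.null(stats$psex) && length(stats$psex)) {
    ps <- stats$psex[!is.na(stats$psex)]
    trace <- c(trace, sprintf(
      "advisory: %d/%d repeated MLMGs with P_sex < %.2g",
      sum(ps < psex_threshold), length(ps), psex_threshold))
  }
  if (!is.null(stats$fis) && !is.na(stats$fis))
    trace <- c(trace, sprintf("advisory: multilocus Fis = %.3f (%s)",
                              stats$fis,
                              if (stats$fis < 0) "negative" else
                                "non-negative"))
  if (!is.null(stats$rd1_p) && !is.na(stats$rd1_p)) {
    rd2 <- if (!is.null(stats$rd2_p) && !is.na(stats$rd2_p))
      sprintf("%.3g", stats$rd2_p) else "NA"
    trace <- c(trace, sprintf(
      "advisory: r_bar_d p = %.3g raw, %s clone-corrected", stats$rd1_p,
      rd2))
  }
  list(verdict = verdict, trace = trace)
}

#' Run the full breeding-mode pipeline on a genotype dataset
#'
#' Orchestrates the whole analysis: complete-case filtering, MLMG
#' partitioning, clonality statistics (R, GD ratio, round-robin P_sex and
#' P_sex(Fis)), heterozygosity and Weir-Cockerham Fis with permutation
#' significance (raw and clone-corrected), Markov-chain Hardy-Weinberg
#' score tests per locus with Fisher-combined and Bonferroni-adjusted
#' population values, r_bar_d with and without clone correction, an
#' optional PCoA, and finally the breeding-mode classification with its
#' rule trace for every population.
#'
#' The run is fully reproducible from `(dataset, seed, parameters)`;
#' every resampling stage derives its own sub-seed from `seed`.
#'
#' @param dataset a [genotype_dataset()] (may contain missing calls; they
#'   are removed first).
#' @param seed master seed.
#' @param gd_B Monte Carlo replicates for the GD-ratio expectation.
#' @param hwe_chain list with `dememorization`, `batches`,
#'   `iters_per_batch` (reduced defaults keep bulk runs fast; raise for
#'   publication-grade p-values).
#' @param rd_perm permutations for r_bar_d.
#' @param fis_perm permutations for the Fis test.
#' @param alpha,gd_threshold,psex_threshold classification parameters.
#' @param ordinate run PCoA + cascade K-means on the pooled dataset.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return object of class `breeding_mode_report`: list with `summary`
#'   (per-population data.frame incl. verdict), `traces`, `psex`,
#'   `hwe`, `rd`, `het`, `ordination`, `parameters`.
#' @export
run_pipeline <- function(dataset, seed = 1L, gd_B = 1000L,
                         hwe_chain = list(dememorization = 2000L,
                                          batches = 100L,
                                          iters_per_batch = 2000L),
                         rd_perm = 1000L, fis_perm = 1000L,
                         alpha = 0.05, gd_threshold = 0.75,
                         psex_threshold = 0.01, ordinate = TRUE,
                         out_dir = NULL) {
  ds <- complete_cases_genotypes(dataset, quiet = TRUE)
  if (!length(ds$individuals)) stop("no complete genotypes to analyse")
  pops <- split_populations(ds)
  npop <- length(pops)

  fis1 <- vapply(pops, function(d) fis_wc(d)$multilocus, numeric(1L))
  cs <- clonal_stats(ds, B = gd_B, seed = seed, fis = fis1)
  hwe <- multilocus_hwe(ds, dememorization = hwe_chain$dememorization,
                        batches = hwe_chain$batches,
                        iters_per_batch = hwe_chain$iters_per_batch,
                        seed = seed + 1000L, alpha = alpha)

  het <- list(); rd <- list()
  fis2 <- rep(NA_real_, npop); names(fis2) <- names(pops)
  fis1_p <- fis2
  rd1 <- vector("list", npop); rd2 <- vector("list", npop)
  names(rd1) <- names(rd2) <- names(pops)
  for (i in seq_along(pops)) {
    p <- names(pops)[i]
    d <- pops[[i]]
    het[[p]] <- het_stats(d)
    if (length(d$individuals) >= 2L) {
      fis1_p[p] <- fis_permutation_test(d, n_perm = fis_perm,
                                        seed = seed + 2000L + i)$p_value
      gs <- .genotype_strings(d)
      dcc <- subset_individuals(d, !duplicated(gs))
      if (length(dcc$individuals) >= 2L)
        fis2[p] <- fis_wc(dcc)$multilocus
    }
    rd1[[p]] <- tryCatch(
      rbar_d(d, n_perm = rd_perm, seed = seed + 3000L + i),
      error = function(e) NULL, warning = function(w)
        suppressWarnings(rbar_d(d, n_perm = rd_perm,
                                seed = seed + 3000L + i)))
    rd2[[p]] <- tryCatch(
      rbar_d(d, n_perm = rd_perm, seed = seed + 4000L + i,
             clone_correct = TRUE),
      error = function(e) NULL, warning = function(w)
        suppressWarnings(rbar_d(d, n_perm = rd_perm,
                                seed = seed + 4000L + i,
                                clone_correct = TRUE)))
  }
  getp <- function(x) if (is.null(x)) NA_real_ else x$p_value
  gets <- function(x) if (is.null(x)) NA_real_ else x$statistic

  comb <- hwe$combined
  verdicts <- character(npop); traces <- vector("list", npop)
  names(traces) <- names(pops)
  summ <- cs$summary
  summ <- summ[match(names(pops), summ$population), ]
  for (i in seq_along(pops)) {
    p <- names(pops)[i]
    pex <- comb$p_bonferroni[comb$population == p & comb$tail == "excess"]
    pdef <- comb$p_bonferroni[comb$population == p &
                                comb$tail == "deficiency"]
    st <- list(gd_ratio = summ$gd_ratio[i],
               hwe_excess_p_adj = pex, hwe_deficiency_p_adj = pdef,
               psex = cs$psex$p_sex[cs$psex$population == p],
               fis = fis1[[p]],
               rd1_p = getp(rd1[[p]]), rd2_p = getp(rd2[[p]]))
    cl <- classify_population(st, alpha = alpha,
                              gd_threshold = gd_threshold,
                              psex_threshold = psex_threshold)
    verdicts[i] <- cl$verdict; traces[[p]] <- cl$trace
  }
  summary <- data.frame(
    summ,
    fis1 = unname(fis1[names(pops)]), fis1_p = unname(fis1_p),
    fis2 = unname(fis2),
    hwe_excess_p = comb$p_fisher[comb$tail == "excess"][
      match(names(pops), comb$population[comb$tail == "excess"])],
    hwe_excess_p_adj = comb$p_bonferroni[comb$tail == "excess"][
      match(names(pops), comb$population[comb$tail == "excess"])],
    hwe_deficiency_p = comb$p_fisher[comb$tail == "deficiency"][
      match(names(pops), comb$population[comb$tail == "deficiency"])],
    hwe_deficiency_p_adj = comb$p_bonferroni[comb$tail == "deficiency"][
      match(names(pops), comb$population[comb$tail == "deficiency"])],
    rd1 = vapply(rd1, gets, numeric(1L))[names(pops)],
    rd1_p = vapply(rd1, getp, numeric(1L))[names(pops)],
    rd2 = vapply(rd2, gets, numeric(1L))[names(pops)],
    rd2_p = vapply(rd2, getp, numeric(1L))[names(pops)],
    verdict = verdicts, row.names = NULL)

  ordination <- NULL
  if (ordinate && length(ds$individuals) >= 3L) {
    bm <- binary_allele_matrix(ds)
    ordination <- pcoa(nei_binary_distance(bm))
  }

  report <- structure(
    list(summary = summary, traces = traces, psex = cs$psex,
         hwe = hwe, het = het,
         rd = list(raw = rd1, clone_corrected = rd2),
         ordination = ordination,
         parameters = list(seed = seed, gd_B = gd_B,
                           hwe_chain = hwe_chain, rd_perm = rd_perm,
                           fis_perm = fis_perm, alpha = alpha,
                           gd_threshold = gd_threshold,
                           psex_threshold = psex_threshold)),
    class = "breeding_mode_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.breeding_mode_report <- function(x, ...) {
  cat("breeding_mode_report\n")
  print(x$summary[, c("population", "G", "N", "R", "gd_ratio", "fis1",
                      "verdict")])
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `summary.tsv` (per-population statistics + verdict),
#' `psex.tsv` (per repeated MLMG), `hwe_per_locus.tsv`, and
#' `report.json` with the verdicts, traces and run parameters.  All
#' files are UTF-8 with LF endings.
#'
#' @param report a `breeding_mode_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    con <- file(file.path(out_dir, name), open = "wb")
    on.exit(close(con), add = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n",
                       fileEncoding = "UTF-8")
  }
  tsv(report$summary, "summary.tsv")
  tsv(report$psex, "psex.tsv")
  tsv(report$hwe$per_locus, "hwe_per_locus.tsv")
  jsonlite::write_json(
    list(verdicts = as.list(stats::setNames(report$summary$verdict,
                                            report$summary$population)),
         traces = report$traces, parameters = report$parameters),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
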