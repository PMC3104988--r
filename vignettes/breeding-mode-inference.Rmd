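---
title: "Inferring reproductive mode from multilocus genotypes"
author: "breedmode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reproductive mode from multilocus genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedmode)
```

# The inference problem

Many cladocerans (and other facultatively sexual organisms) alternate
between clonal (apomictic) propagation and episodic sex; some lineages
abandon sex entirely. Given a sample of diploid individuals typed at a
panel of codominant microsatellite loci, `breedmode` asks: does this
population reproduce by **cyclic parthenogenesis** (effectively panmictic
at the genotype level), by **obligate parthenogenesis** (a handful of
clonal lineages copied many times), or by something in between?

The signatures of clonality the package quantifies are:

* **Repeated multilocus genotypes (MLMGs).** Under sexual reproduction,
  multilocus genotypes are essentially unique once enough polymorphic
  loci are scored; exact repeats indicate clonemates. `partition_mlmg()`
  groups individuals by strict genotype identity, `genotypic_richness()`
  reports `R = (G-1)/(N-1)`, and `p_sex()` gives the probability that the
  `n` observed copies of an MLMG arose from independent sexual events:
  the upper binomial tail `P(X >= n)`, `X ~ Bin(N, p_gen)`, where
  `p_gen` is the genotype's Hardy–Weinberg probability (`p_gen()`), with
  an inbreeding-adjusted variant `P_sex(Fis)` for populations away from
  HWE.
* **Heterozygote excess.** Clones of hybrid origin carry fixed
  heterozygosity, giving strongly negative Weir–Cockerham `Fis`
  (`fis_wc()`; exactly −1 when a single heterozygous genotype is fixed),
  tested by allele-copy permutation (`fis_permutation_test()`) and by the
  exact one-sided score tests of HWE (`hwe_score_test()`).
* **Multilocus linkage disequilibrium.** Clonal copying creates
  associations across loci; `rbar_d()` implements the standardized index
  of association with a per-locus allele permutation null, with optional
  clone correction (one individual per MLMG) to separate copy-driven from
  lineage-driven disequilibrium.
* **Genotypic diversity ratio.** `gd_ratio()` compares the observed
  number of distinct MLMGs with the number expected under HWE and
  independent loci at the same sample size; the classical decision
  threshold is 0.75.

`classify_population()` combines the GD ratio and HWE status into the
classical rule: GD below 0.75 **and** HWE rejected → obligate; GD above
0.75 **and** HWE not rejected → cyclic; everything else (including GD
exactly at the threshold, whose textbook statement is self-contradictory)
→ mixed-or-uncertain. `P_sex`, `r̄_d` and the `Fis` sign are recorded as
advisory evidence in the rule trace, mirroring how these statistics are
used in practice: as corroboration, not as part of the binary rule.

A complementary mtDNA toolkit (`haplotype_set()`, `haplotype_diversity()`,
`nucleotide_diversity()`, `region_distance_summary()`, `apoi_digest()`)
summarizes haplotype variation and performs in-silico ApoI RFLP species
group assignment on the ND5 amplicon (recognition site `R^AATTY`; a cut
in the diagnostic window around position 344 of the 711-bp amplicon marks
the *pulicaria* species group, its absence the *tenebrosa* group).

# Statistical choices and conventions

**Probability of identity.** `pid_locus()` uses the standard unrelated and
sibling formulas, `P_ID = 2(Σp²)² − Σp⁴` and
`P_IDsib = 0.25 + 0.5Σp² + 0.5(Σp²)² − 0.25Σp⁴`. The sibling variant is
the conservative bound used by `loci_needed()` to decide how many loci
resolve individuals at a given certainty (default 99%, i.e. cumulative
`P_IDsib < 0.01` over the most informative loci).

**Round-robin allele frequencies.** `P_sex` is computed from
clone-corrected frequencies: for each locus, individuals are grouped into
MLMGs defined on *all other* loci, one representative per group is kept,
and frequencies at the focal locus are counted from representatives only
(`round_robin_freqs()`). This is the one-representative-per-MLMG reading
of the round-robin/sub-sampling estimator; a clone of 50 copies
contributes once per locus. If a scored MLMG carries an allele absent
from the representative pool (possible but rare), its `P_sex` is reported
as `NA` with a note rather than silently switching frequency bases.

**Weir–Cockerham Fis.** The single-sample variance-components estimator:
per allele `b = n/(n−1)[p(1−p) − (2n−1)h̄/(4n)]`, `c = h̄/2`, and
`f = 1 − Σc/Σ(b+c)`, components summed over alleles and loci for the
multilocus value. Note the finite-sample property that exactly
HW-proportioned genotype counts give `f = 1/(2n−1)`, not 0; tests account
for this. Because allele counts are fixed under both the permutation null
and the exact-test null, the multilocus `f` depends on the data only
through the per-locus heterozygote counts — this is what makes the
permutation and chain nulls cheap.

**Exact HWE score tests.** The null is the Levene conditional
distribution of genotype tables given allele counts. The sampler is a
switch-type Markov chain over arrangements of the 2n allele copies
(uniformly random transpositions; the uniform stationary law over
arrangements induces the Levene law on tables), implemented in C++ and
driven by R's RNG for bit-reproducibility. The statistic is the
Weir–Cockerham `Fis`, strictly decreasing in the heterozygote count `H`
at fixed allele counts, so extremeness reduces to comparing `H` with
`H_obs`. Ties are counted half toward the tail (a mid-p): for the
all-heterozygote table with n = 5 and allele counts 5/5, complete
enumeration puts mass 0.12698 on the observed (maximal-H) table, so the
excess mid-p is 0.06349 and the deficiency mid-p its complement — the
two tails always sum to exactly 1. The mid-p convention was chosen over
counting the observed table fully because the full-tie p is
systematically conservative on discrete tables: in the type-I
calibration over 500 panmictic populations the full-tie test rejects at
~0.024 instead of the nominal 0.05, falling outside the accepted
[0.03, 0.07] band, while the mid-p test is calibrated. Default chain
settings are 1000 batches of 20 000
iterations after 20 000 dememorization steps; the pipeline uses reduced
settings for bulk runs, and the batch-mean standard error is always
reported so chain noise is visible. Per-population, per-tail p-values
are combined across loci by Fisher's method with the per-locus p clamped
below at `1/(batches × iters + 1)`, and Bonferroni-adjusted with family
size = populations × 2 tails.

**r̄_d.** Per-locus pair distance `(2 − shared alleles)/2` with
multiplicity (AB vs AA → 0.5), `r̄_d = (Var D − ΣVar d_l) /
(2Σ_{j<k}√(Var d_j Var d_k))`; loci with zero distance variance are
excluded. The null permutes the 2N allele copies among individuals within
each locus independently; p-values use `(1 + hits)/(B + 1)` smoothing.

**PCoA and clustering.** `binary_allele_matrix()` codes allele presence
per (locus, allele); `nei_binary_distance()` is the Dice/Nei–Li
similarity complement, chosen because shared *absence* of an allele
carries no information (appending all-zero columns provably changes
nothing). `pcoa()` is Gower double-centering with negative eigenvalues
dropped and reported (no Cailliez/Lingoes correction — the simplest
behaviour consistent with classic `pco` usage); K-means
(`cascade_kmeans()`) runs on **all** positive axes, best of 25 restarts
per K, with the Calinski–Harabasz criterion selecting K.
`hybrid_intermediacy()` projects a test group's centroid onto the segment
joining two parental centroids; `t ∈ (0, 1)` means geometrically
intermediate, the ordination signature of hybrid origin.

**Chord distance.** `chord_distance()` uses the GENDIST normalization
`D² = 4Σ_l(1 − Σ_a√(x y)) / Σ_l(m_l − 1)`; the angular per-locus
`2√2/π` form is available behind a flag.

**mtDNA statistics.** Unbiased haplotype diversity
`h = n(1 − Σf²)/(n − 1)` with Nei's (1987) sampling variance; nucleotide
diversity is the mean per-site pairwise difference with pairwise deletion
of sites containing `N`/gaps (complete deletion behind a flag — the
original analyses do not state their setting). Net between-region
distance is `between − mean(within)`; note this vanishes only
asymptotically for identically composed polymorphic regions.

# The synthetic world

The raw genotypes that motivated this machinery were never deposited, so
the package ships seeded generators whose defaults *are* the stated
study conditions: 8 microsatellite loci, 5–22 alleles per locus
(Dirichlet(1) frequencies), populations of a few dozen individuals
(2–60 in the study; default n = 30), geometric clone copy-number law
(matching the heavily skewed observed clone sizes, e.g. one clone of 60
copies), call-level uniform missingness (the study went from 606 sampled
to 561 complete genotypes), and an optional ±1 stepwise mutation on an
integer allele ladder for clone copies.

* `simulate_cyclic()` draws HW genotypes with optional inbreeding `F`
  (negative `F` handled by explicit genotype probabilities with a
  feasibility bound).
* `simulate_obligate()` copies a few founder genotypes; with
  `hybrid = TRUE` founders take one allele from each of two
  disjoint-label pools, fixing heterozygosity — the F1-hybrid clone
  signature (Fis → −1).
* `simulate_mixed()` concatenates both components over shared pools.
* `simulate_hybrid_panel()` builds two divergent parental populations
  plus an F1 group for the ordination checks.
* `simulate_haplotypes()` mutates an ancestral sequence into template
  haplotypes, assigns copies by a skewed law, and can plant (or scrub)
  ApoI sites at chosen positions.

Every generator is bit-reproducible from `(spec, seed)` and returns a
truth record consumed by the tests. What the generators deliberately do
**not** model: coalescent ancestry, migration, linkage, allele-size
homoplasy, scoring error, resting-egg bank demography. A green test
therefore establishes that the statistics recover the *stated* generative
structure, not that they are robust to every failure mode of real
microsatellite data.

# Numerical and validation notes

* All resampling (chain, permutations, Monte Carlo) runs off R's RNG and
  a caller-supplied seed; identical seeds give identical results to the
  bit.
* The GD-ratio expectation switches to the exact
  `Σ_g(1 − (1 − P_g)^N)` enumeration when the multilocus genotype space
  has ≤ 10⁴ states; the Monte Carlo route reports a standard error.
  Beware that on tiny genotype spaces with large N the MC replicates are
  almost surely constant (SE = 0), which is why MC-vs-oracle agreement is
  validated at sample sizes where the SE is positive.
* The acceptance suite (tests/testthat/test-acceptance.R) validates each
  operation against an independent oracle: brute-force genotype-pair
  enumeration for P(ID), explicit binomial summation for P_sex, complete
  enumeration of genotype tables under the Levene law for the score test
  (20 random tables, agreement within 3 reported chain SEs), analytic
  E[G] for the GD ratio, type-I calibration of the HWE and r̄_d tests on
  500 panmictic populations (rejection rate in [0.03, 0.07] at α = 0.05),
  parameter recovery for Fis (F = 0.2, bias < 0.05), ≥95%/≥90%
  obligate/cyclic classifier recovery on 100 + 100 seeded populations,
  ≥95% hybrid intermediacy, and the diagnostic digest fragments
  (344, 367) of a planted-site 711-bp amplicon.
* Known limitations: no mutation-tolerant clone lineage aggregation
  (strict MLMG identity only), no model-corrected sequence distances or
  likelihood phylogenetics, no fragment-size binning, diploids only.
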