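---
title: "Methods: Phi-st outlier scans, SD-bin structure analysis and introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Phi-st outlier scans, SD-bin structure analysis and introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two closely related species can be indistinguishable at the vast majority
of their genome and still be cleanly delimited by a small set of strongly
differentiated loci — "genomic islands of divergence". The classic
presentation of this pattern in reduced-representation (RAD) surveys of
sister fish species is: thousands of SNPs with a genome-wide Φst of a few
percent, a few dozen outlier loci with Φst an order of magnitude higher,
species- and population-level clustering that appears only when the
analysis is restricted to those outliers, and a handful of admixed
hybrid individuals whose mixed ancestry is likewise visible only at the
outlier loci.

`islandscan` implements that analysis as a reusable, tested pipeline:
per-locus AMOVA Φst, the 3-standard-deviation outlier rule, the
stratification of loci into SD bins with one structure analysis per bin,
a from-scratch Bayesian admixture model for ancestry and introgression,
and a randomization test for annotation enrichment among outliers. A
hierarchical Balding–Nichols simulator generates genotype matrices with
planted islands and hybrids, with full truth labels, so every stage can
be validated end to end.

## Differentiation: Weir–Cockerham variance components

Per SNP we compute the Weir & Cockerham (1984) method-of-moments variance
components from genotype counts: `a` (among groups), `b` (among
individuals within groups) and `c` (within individuals), and

$$\Phi_{ST} = \frac{a}{a + b + c}.$$

This estimator is algebraically the two-level AMOVA on allele indicators
(alleles nested in individuals nested in groups); the test suite verifies
the identity against an independently written sums-of-squares
decomposition over the complete enumeration of two-population,
three-individual dosage matrices (729 cases, agreement to 1e-10).

Choices that matter downstream:

* **Per-locus aggregation.** Outliers are classified on *loci* (the short
  sequenced tags), not on SNPs. A locus's Φst is the ratio of summed
  components over its SNPs — the standard ratio-of-sums combination,
  which is robust to low-information SNPs and differs from the mean of
  per-SNP ratios.
* **Missing data** are pairwise-complete per SNP.
* **Undefined values.** Φst is `NA` for SNPs monomorphic among genotyped
  individuals, with data in fewer than two groups, or with one genotyped
  individual per group; undefined loci take part in no threshold bin.
* **Negative estimates are retained** when the distribution's mean and SD
  are computed: truncating at zero would shift both upward and bias the
  3-SD threshold. A `truncate_negative` toggle exists for comparison.
* **Sample SD** (n − 1) is used throughout.
* **Grouping.** The outlier scan compares the two nominal species,
  excluding individuals labeled `hybrid` or `unknown`. Per-bin "global"
  Φst is reported at the population level over non-hybrid individuals —
  the scale on which overall population structure is usually quoted.

## Outlier classification and SD bins

With mean $m$ and standard deviation $s$ of the per-locus Φst
distribution, a locus is an outlier when $\Phi_{ST} \ge m + 3s$; loci at
or below $m - 3s$ are reported as the low tail (candidates for balancing
selection). Both boundaries are inclusive; a degenerate distribution
($s = 0$) yields empty sets. The SD bins used for the panel sweep are
lower-closed/upper-open: $[m+3s, \infty)$, $[m+2s, m+3s)$,
$[m+s, m+2s)$, $[m, m+s)$, plus the full dataset; loci below the mean
belong only to the full dataset. The tie convention is arbitrary in
principle (ties are measure-zero) but is fixed for reproducibility.

## The admixture model

`fit_admixture()` implements the standard Bayesian admixture model for
biallelic diploids by Gibbs sampling, with uncorrelated cluster allele
frequencies. Each allele copy carries a latent cluster of origin $z$;
the full conditionals are

* $P(z = k) \propto q_{ik}\, p_{kl}^{x} (1-p_{kl})^{1-x}$ for a copy with
  allele $x$ at SNP $l$ in individual $i$,
* $q_i \mid z \sim \mathrm{Dirichlet}(\alpha + \text{copy counts})$,
* $p_{kl} \mid z \sim \mathrm{Beta}(\lambda + \text{ref copies},
  \lambda + \text{alt copies})$.

Heterozygotes contribute one reference and one alternate copy, assigned
independently; missing genotypes are skipped. Defaults: $K = 4$ (two
putative species across four sampled populations), flat priors
$\alpha = \lambda = 1$, 2,000 burn-in sweeps, 5,000 sampling sweeps
thinned by 5. Reported `Q` and `P` are posterior means over retained
sweeps and a data log-likelihood trace is kept per retained sweep. The
sampler is written in C++ (Rcpp) and uses R's RNG, so runs are
bit-reproducible under a seed. On the package's reference design
(39 individuals × ~5,200 SNPs, K = 4) the default chain runs in minutes
on one core.

Design choices, and their rationale:

* **Gibbs over EM**: matches the model family of the Structure-style
  assignment tests this pipeline emulates and yields posterior
  uncertainty, not only a point estimate.
* **Uncorrelated frequency prior** (independent Beta per cluster and
  SNP) rather than the correlated-frequencies F-model: simpler, and
  sufficient for the outlier-vs-background contrast this package
  reproduces. This is a deviation from Structure's common default and is
  expected to be somewhat less sensitive to very weak structure.
* **Label switching** is not corrected within a chain (intended use is
  well-separated data; the likelihood trace makes pathological runs
  visible). Across chains, `align_clusters()` greedily matches columns
  on Q correlations.
* **Cluster-to-species anchoring**: each cluster is assigned to the
  species whose labeled non-hybrid individuals carry the highest mean
  ancestry on it (ties toward the better-sampled species, then
  lexicographic). Hybrids never anchor but are included in fitting.
* **Introgression** is the ancestry mass on the other species'
  *discriminative* clusters — clusters whose anchor means actually
  separate the species. A fit that cannot tell the species apart (the
  degenerate case being K = 1, where the single cluster's anchor means
  tie exactly) reports zero introgression rather than an artifactual
  one. For individuals labeled `hybrid`, ancestry is quoted relative to
  a host species (by default the better-sampled one), the usual
  convention for a hybrid zone embedded in one species' range.
* **Linked SNPs within a locus are treated as independent**, matching
  the simulator; `one_snp_per_locus()` is available where thinning is
  preferred. The pipeline default uses all SNPs.

## Enrichment among outliers

`randomization_enrichment()` counts annotated (protein-coding) loci in
the outlier set and compares against null sets of the same size drawn
uniformly without replacement from the locus universe. The empirical
p-value is $(1 + \#\{\text{null} \ge \text{observed}\})/(R + 1)$; a
one-sample t test of the null counts against the observed value is
reported alongside, as the traditional small-R presentation. The default
$R = 20$ mirrors the historical usage, but a 20-replicate t test against
a single observation is statistically fragile: the docs recommend
$R \ge 1000$ and the empirical p whenever the p-value is the statistic
of interest. The null draws from *all* loci, outliers included — the
more conservative choice; a toggle restricts the null to the background.
The test suite checks the null against the closed-form hypergeometric
distribution (mean within Monte-Carlo error at R = 10,000 and sup-CDF
distance below 0.02).

## Data cleaning

* **Read-quality filter.** "Product of quality scores below 80%" is
  interpreted as the product of per-base correctness probabilities
  $\prod_b (1 - 10^{-Q_b/10}) < 0.8$ — the only reading under which a
  threshold of 80% is a meaningful probability statement. An 80-mer at
  uniform Q40 has product 0.992 and passes; at uniform Q20, 0.448 and
  fails. The product is accumulated in log space; an empty read has an
  empty product of 1 and is kept; a negative Phred score is rejected.
* **Depth filter.** Genotypes backed by fewer than 6 reads are set to
  missing, before the call-rate filter — only when the input format
  carries per-genotype depth (VCF `FORMAT/DP`); other formats skip the
  step with a notice.
* **Call-rate filter.** SNPs genotyped in at least 80% of individuals
  are kept, boundary inclusive (8 of 10 kept, 7 of 10 dropped).
* **Formats.** VCF (1-based coordinates, biallelic records only,
  multi-allelic records skipped with a count), a Structure dialect (one
  row per individual, two columns per SNP, −9 missing) and genepop
  (two-digit allele codes, 0000 missing). Missing dosage is a dedicated
  `NA`, distinct from 0. Genepop has no population-name field, so the
  sample name encodes `species|population|individual`; a `Pop` line
  opens every run of consecutive same-population rows so that
  write→read is the identity including individual order.

## The simulator: what it emulates, and what it does not

`simulate_genotypes()` draws from a hierarchical Balding–Nichols model.
Per SNP: ancestral frequency $\pi \sim U(0.05, 0.95)$ (bounded away from
fixation so monomorphic loci do not dominate); per species,
$p_s \sim \mathrm{Beta}(\pi(1-F)/F,\, (1-\pi)(1-F)/F)$ with
$F = $ `f_species_island` on island loci and `f_species_neutral`
otherwise; per population within a species, a second Balding–Nichols
step with `f_pop_within`, applied at island loci only. Pure individuals
draw dosages binomially; hybrids draw each allele copy's species of
origin from their true ancestry and then the allele from that species'
local population — exactly the admixture model's own generative
assumption, which is what makes exact recovery tests possible. A SNP
whose population frequencies all come out exactly fixed is redrawn (up
to 100 times), then emitted and left to the filters.

The default configuration is the reference study design: 39 individuals
(10 + 9 pure of one species, 10 + 5 of the other, 3 + 2 hybrids across
four Pacific localities), 1,961 loci averaging 5,193/1,961 ≈ 2.65 SNPs
each, 2.5% island loci, and hybrid ancestries (0.29, 0.34, 0.53, 0.5,
0.5). Three parameters were fixed by a one-time calibration and not
revisited:

* `f_species_island = 0.45`, the island differentiation scale;
* `f_species_neutral = 0.035`, chosen so the population-level global
  Φst over all loci centers on 0.034 under the default design;
* `f_pop_within = 0.25`, giving strong within-species population
  structure at island loci (a hallmark of the pattern being emulated)
  while staying clearly below the between-species parameter.

Within-species differentiation at *neutral* loci is zero by design: the
background is calibrated as a single species-level quantity, and no
within-species neutral target exists to calibrate against. SNPs are
independent, including within a locus (no linkage); there is no
restriction-site dropout, no PCR duplication, no coverage-dependent
genotyping error, and no sequence-level simulation of the tags.

Because of these simplifications, passing tests demonstrate correctness
of the *estimators and algorithms* under the model's assumptions; they
do not demonstrate that real RAD data will behave identically. Two
divergences are worth stating plainly, since the test suite measures
both:

1. **Island detectability has a ceiling.** The species island
   frequencies are independent U-shaped Beta draws at $F = 0.45$, so a
   substantial minority of planted islands realize similar frequencies
   in both species (both drawn toward the same fixation side) and are
   weakly differentiated *in truth*. Those islands sit below the
   mean + 3SD cut at any sample size — raising within-run sensitivity
   above roughly 0.6 is impossible in this generative world even at
   n = 100 per population, and at the 39-individual reference design
   the measured mean sensitivity sits slightly below 0.6 (precision is
   comfortably high). The acceptance suite asserts the nominal 0.6/0.6
   recovery targets as stated and the sensitivity arm fails for this
   structural reason; the assertion was deliberately not weakened.
2. **Neutral-background separation.** With ~5,100 neutral SNPs at a
   between-species F of 0.035 and no within-species drift, the
   aggregate likelihood information about species membership is large,
   and a converged sampler separates the species on neutral-only data —
   the longer the chain, the more cleanly. The empirical phenomenon
   this pipeline emulates (no visible separation on the genome-wide
   background at realistic Structure settings) therefore does not
   reproduce in the synthetic world: it belongs to the real data's
   shared within-species drift, linkage and finite-run regime, not to
   the idealized model. The corresponding acceptance assertion is
   likewise kept as stated and fails; the outlier-bin arms (clear
   species delimitation, hybrids recovered at intermediate ancestry)
   pass.

## Numerical and degenerate-input conventions

* Quality-filter products in log space (`log1p(-10^(-Q/10))`).
* Φst undefined (never crashing) for monomorphic SNPs, single-group
  SNPs, all-missing groups; all-monomorphic inputs give a table of
  `NA`s with a warning.
* Bin boundaries lower-closed/upper-open; outlier threshold inclusive
  (`>=`), fixed and documented since the underlying convention is
  unobservable in the emulated analysis.
* Dirichlet draws via normalized gamma variates; a zero gamma sum
  (possible only in pathological float underflow) falls back to the
  uniform simplex point.
* All stochastic components (simulator, sampler, enrichment,
  `one_snp_per_locus("random")`) consume explicit integer seeds and are
  bit-reproducible given them.

## Problem sizes used by the checks

The test suite validates the estimator identity on the full 729-case
enumeration, runs the reference design (39 individuals × 1,961 loci) for
calibration and recovery checks over 10 seeds, fits admixture panels on
the outlier bin (~100 SNPs) with 2,400-sweep chains and on the neutral
background (~5,100 SNPs) with 1,500-sweep chains, and uses R = 10,000
replicates against the hypergeometric oracle. The acceptance script runs
one full simulate–scan–admix–enrich pass at the reference design with a
3,000-sweep chain on the outlier bin and R = 1,000 enrichment
replicates. These sizes are the package's reference configuration for
desk-scale reproduction.

## Known limitations

* The admixture model omits the correlated-frequencies prior and any
  linkage model; K is fixed by the user (no K-selection machinery).
* Per-bin structure runs share one seed and chain configuration.
* The simulator's hybrids are admixture-model draws, not pedigree F1/F2
  crosses; backcross pedigrees cannot be expressed.
* Three-level AMOVA (region/population/individual), bootstrap CIs and
  kinship corrections are out of scope.
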