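---
title: "Comparing molecular signatures of selection and knockout fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing molecular signatures of selection and knockout fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsignal)
```

## The problem

Molecular population genetics offers many per-gene statistics that are
routinely read as evidence of past selection, but they measure different
things on different timescales: interspecific substitution ratios (dN/dS),
contrasts of polymorphism and divergence (the McDonald–Kreitman neutrality
index NI and the direction of selection DOS), and summaries of the site
frequency spectrum within a species (Tajima's D, Fu & Li's D\*, Fay & Wu's
H, Zeng's E). `selsignal` computes all seven per gene from standard inputs,
classifies genes as selection candidates per statistic, tests whether a
focal gene set (e.g. essential genes) is shifted within each distribution,
and asks whether any signature predicts the fitness consequence of knocking
the gene out, as measured by knockout-line fruit production relative to the
wild type. A synthetic-data module generates every input with known ground
truth, so the whole pipeline can be exercised and calibrated at desk scale
without genome-database downloads.

## The statistics

**Pairwise dN/dS.** Ortholog CDS pairs are aligned end-to-end
(Needleman–Wunsch with affine gaps; defaults mirror EMBOSS needle: match
+5, mismatch −4, gap open 10, gap extend 0.5, end gaps penalised). dN and
dS are then estimated by Nei–Gojobori (1986) counting: per-codon
synonymous/nonsynonymous site fractions (excluding mutational paths through
stop codons from the denominator), pathway-averaged difference counts, and
the Jukes–Cantor correction d = −(3/4)·log(1 − (4/3)p). We deliberately use
the counting estimator rather than a maximum-likelihood codon model: it is
transparent, fast, dependency-free, and the downstream use of dN/dS here is
purely threshold- and rank-based, where the two families of estimators
agree. Proportions p ≥ 3/4 are outside the correction's domain and are
flagged `saturated` with the estimate undefined. Ortholog pairs are
retained when reciprocal identity ≥ 75% (defined as the *minimum* of the
two per-sequence identities — the conservative reading of "reciprocal"),
0.02 < dS < 2 and dN < 2, all bounds strict.

**MK statistics.** Per gene, polymorphisms are classified synonymous or
nonsynonymous by substituting the (strand-adjusted) alternative allele into
its codon; when a gene's transcripts read a SNP in conflicting frames the
SNP is *ambiguous* and excluded — a per-gene statistic needs one consistent
classification. With Dn, Ds nonsilent/silent substitutions and Pn, Ps
nonsilent/silent polymorphisms:

$$\mathrm{NI} = \log\frac{(2D_s+1)(2P_n+1)}{(2D_n+1)(2P_s+1)}, \qquad
\mathrm{DOS} = \frac{D_n}{D_n+D_s} - \frac{P_n}{P_n+P_s}.$$

The doubled-count-plus-one correction keeps NI finite for every table. The
log base is natural (the log-odds convention); base 10 is available and
recorded in output. Substitution counts come from the fractional NG86
pathway sums rounded half-away-from-zero, because MK counts are
contingency-table entries; polymorphisms are counted once per segregating
site, not per carrying accession. DOS is undefined when either margin is
zero.

**SFS statistics.** Per-gene multi-accession haplotype alignments with an
outgroup row yield the unfolded spectrum: sites with a gap or N in any used
row are excluded, multiallelic ingroup sites are excluded, and a biallelic
site is polarized when the outgroup allele matches one ingroup allele
(otherwise it stays in the folded tally but not the unfolded one). With
derived-count classes $S_i$:

$$\theta_W = S/a_1,\quad
\theta_\pi = \sum_i \frac{2i(n-i)S_i}{n(n-1)},\quad
\theta_H = \sum_i \frac{2i^2 S_i}{n(n-1)},\quad
\theta_L = \frac{1}{n-1}\sum_i i S_i,$$

with $a_1 = \sum_{i<n} 1/i$. Tajima's D and Fu & Li's D\* need no
polarization and use all biallelic ingroup segregating sites (D\* defines
singletons by the rarer allele occurring once); H and E use polarized sites
only, and both site counts are reported. D uses the Tajima (1989) variance
constants; D\* the Fu & Li (1993) constants as corrected by Simonsen et
al. (1995); the normalized H and E variances follow Zeng et al. (2006),
plugging $\theta_W$ for θ and the unbiased $S(S-1)/(a_1^2+a_2)$ for θ².
These constants were verified against a simulation oracle: under the
package's own neutral coalescent the empirical variance of each estimator
difference matches the closed form at the true θ, and the normalized
statistics have mean ≈ 0 and variance ≈ 1 (the calibration is asserted in
the test suite at n = 25, θ = 10, 1000 replicates).

Fay & Wu's H defaults to the *unnormalized* $\theta_\pi - \theta_H$, whose
magnitude grows with diversity — the scale on which genome-wide medians of
several units arise in real data; the variance-normalized form is available
by option (`variant = "normalized"`). The exact identity
$\theta_\pi - \theta_H = 2(\theta_\pi - \theta_L)$ holds by construction
and is asserted to 1e−12. A degenerate corner: at n = 3 Tajima's variance
coefficients vanish identically, so D is reported as 0 when the numerator
is also 0 and undefined otherwise.

Estimates from alignments with fewer than 50 biallelic ingroup segregating
sites are unreliable and the profile is flagged invalid with no statistic
values; the threshold is the count before polarization, since D and D\*
are defined on it.

## Selection candidates, intersection, and the randomisation test

Threshold mode applies the conventional strict inequalities dN/dS > 1,
DOS > 0, NI < 0, D < 0, D\* < 0, H < 0, E < 0; outlier mode flags the top
5% of each distribution in its selection-indicating direction (empirical
quantile with linear interpolation, ties at the cutoff included). A gene is
in the method intersection only when all seven statistics are defined and
flagged.

The randomisation test draws s random gene subsets of the focal size
(default s = 10,000) without replacement from all genes with a defined
value. For a focal set hypothesised to sit *low* in the distribution, q
counts random subsets whose median is strictly greater than the focal
median; with r = s − q the p-value is (r + 1)/(s + 1), floored at
1/(s + 1) ≈ 1.00 × 10⁻⁴ at the default s. Ties count toward r — the
conservative choice. Tail directions for the essential-gene analysis are
lower for dN/dS, DOS and H, higher for NI, D, D\* and E, matching each
statistic's interpretation under purifying selection. Subsets are drawn
separately from each statistic's defined-value domain (the domains differ
because of the segregating-site filter).

## Fitness association

Relative fitness of a knockout observation is its fruit count divided by
the wild-type fruit count of the same experimental replicate (undefined and
dropped when the wild type produced none); a gene's fitness w is the mean
over its replicates, and genes need more than three observations (≥ 4).
Lines whose reported `area_ratio` exceeds 1.5 likely carry multiple T-DNA
insertions and can be filtered; missing ratios are retained and flagged.
An optional chamber-wise Z-standardisation (population SD) removes
growth-chamber offsets before averaging. Association is tested two ways:
a two-group Kruskal–Wallis test of w between candidate and non-candidate
genes per statistic, and complete-case Spearman correlations of w with
each statistic (raw and Benjamini–Hochberg-adjusted p-values reported).
When several wild-type plants share a replicate, the divisor is their mean
fruit count.

## The synthetic-data generator

The generator emulates, with known ground truth, each input the pipeline
consumes:

* **Haplotype alignments** come from a neutral n-coalescent with
  infinite-sites mutation (rate θ/2 per lineage per unit coalescent time;
  every mutation hits a fresh site), so E[S] = θ·a₁ and E[θπ] = θ — both
  asserted in the suite. The outgroup row is the true ancestor plus
  independent Poisson divergence (default 0.1 substitutions/site, the
  divergence scale of a close congener), which realistically produces
  third-allele and mispolarized sites.
* **Spectrum skew** re-draws a site's derived count towards the singleton
  or the n−1 class with a given probability, emulating sweep-like and
  inbreeding/expansion-like spectra without modelling their causes. This is
  the regime in which H and E become strongly rank-anticorrelated, as they
  are in real data; under purely neutral spectra the correlation is much
  weaker (about −0.6), which the estimator-correlation test documents by
  using skewed spectra.
* **Ortholog pairs** evolve a stop-free random CDS along a branch with
  target Poisson(branch × 3L) substitutions, accepting candidate changes
  with relative rate 1 (synonymous) versus ω (nonsynonymous) and rejecting
  stops — an acceptance-ratio scheme rather than a full codon rate matrix,
  sufficient because only estimator recovery and ordering are asserted
  downstream. The defaults (L = 200 codons, branch 0.1, per-gene true ω
  lognormal with median 0.25) reflect a typical CDS and congener
  divergence.
* **MK tables** are independent Poisson draws per cell.
* **Fitness tables** draw wild-type fruit counts Poisson around a
  chamber-specific mean (baseline 60 fruits), knockout counts Poisson
  around that mean × (1 + effect) × mean-one lognormal gene noise
  (log-SD 0.2), with a configurable fraction of lines having
  `area_ratio` > 1.5 or missing.

Study-scale defaults are fixed in `sim_config()`: 50 genes, 20 haplotypes,
θ = 20 per locus (so most genes clear the 50-segregating-site filter),
essential fraction 0.1 with true-ω decrement 0.1. What the generator does
*not* emulate: recombination, migration and demography, realistic selfing
genealogies (inbreeding appears only as spectrum skew), alignment gaps
(gap handling is tested on constructed fixtures), and linked selection.
Passing calibration on this generator therefore shows the estimators and
tests are implemented correctly, not that they are robust to the
demographic confounding that affects real *Arabidopsis* data — indeed the
sensitivity of D, D\*, H and E to demography is part of the scientific
story.

## Problem sizes and numerical choices

The test suite runs the calibrations at: 2000 coalescent replicates
(n = 10, θ = 5) for E[S]; 1000 replicates (n = 25, θ = 10) for the
statistic means and variances; 200 replicates per ω ∈ {0.2, 1, 5} at
L = 300 codons for NG86 recovery (the ω = 1 mean must land in
[0.85, 1.15] — the counting estimator has a small upward Jensen bias from
the dS denominator, visible but within this band at these settings); 2000
Poisson MK tables for NI/DOS unbiasedness; 200 simulated fitness datasets
of 379 genes for the null (type-I) and power checks; and 100 runs of
2000-gene essential-set randomisation (200 essential genes, true-ω shift
0.1, s = 2000) for end-to-end power. These sizes make every property
decidable in minutes on one core while keeping Monte-Carlo error well
inside the asserted bands.

Further deliberate choices, in one place:

* Heterozygous VCF genotypes take the ALT allele (the species is highly
  selfing, so heterozygous calls are rare and often artefactual); they are
  counted in the reader's log. Internally coordinates are 0-based
  half-open only inside offset arithmetic; all stored objects use the
  1-based inclusive GFF3/VCF convention.
* Minus-strand genes store the CDS 5'→3' in mRNA sense and complement
  alleles at substitution time.
* Accession-sequence identity is matching columns over alignment length;
  identity exactly 75% is kept (the rule drops strictly below threshold).
* Transcripts whose CDS length is not a positive multiple of 3 are
  excluded with a log entry; a gene with no in-frame transcript is
  dropped. Longest-CDS ties break to the lexicographically smallest
  transcript id.
* Alignment traceback ties are irrelevant downstream (only matched-column
  counts and codon pairings are consumed); the optimal score is unique and
  is checked against an exhaustive-search oracle for short sequences.
* All generators are pure functions of (parameters, seed); the pipeline
  takes one mandatory top-level seed, and two runs with the same seed are
  byte-identical.

## Limitations

NG86 dN/dS is not numerically equivalent to maximum-likelihood codon-model
estimates (no transition/transversion or codon-frequency correction); the
retention bounds are applied to the NG86 values as printed. Lineage-specific
(branch-model) dN/dS with a third genome is out of scope, as are GO-term
enrichment, variant calling, and whole-genome alignment — the pipeline
assumes pre-aligned per-gene inputs. The polymorphism classifier inside the
pipeline uses the first haplotype's codon context per site; simultaneous
same-codon variants are classified marginally.

## A short session

```{r example}
cfg <- sim_config(seed = 42, n_genes = 12, n_haplotypes = 12, theta = 25,
                  L = 80)
ds <- file.path(tempdir(), "demo_ds")
generate_full_dataset(cfg, ds, overwrite = TRUE)
res <- run_all(ds, file.path(tempdir(), "demo_out"),
               pipeline_config(seed = 7, s = 1000), overwrite = TRUE)
head(res$stats)
res$randomisation[, c("statistic", "direction", "observed_median", "p")]
```
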