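---
title: "Runs of homozygosity and genomic inbreeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity and genomic inbreeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`homburden` implements a complete case-control homozygosity analysis for
SNP-array genotypes: SNP-wise tests of homozygosity against disease
status, detection of runs of homozygosity (ROH), pooling of overlapping
ROHs into recurrent consensus regions, per-individual ROH burden and
odds-ratio analyses, genomic inbreeding coefficients, and
covariate-adjusted logistic association with a permutation safeguard.
This vignette explains the statistical machinery, the parameters that
matter, and the design decisions taken where more than one reasonable
choice existed.

## The scientific setting

Recessive disease alleles express themselves when both copies descend
from a common ancestor (autozygosity). Two genomic footprints of
autozygosity are examined in a case-control cohort:

* **Runs of homozygosity** - long contiguous stretches of homozygous
  genotypes. If a recessive risk locus exists, cases should carry ROHs
  over it more often than controls; if cases descend from more related
  parents overall, their ROH burden should be higher genome-wide.
* **SNP-wise inbreeding coefficients** - per-individual excess
  homozygosity relative to Hardy-Weinberg expectations, aggregated over
  all markers rather than over long runs.

Both views are computed from the same `genotype_matrix`: samples by
markers, calls coded 0/1/2 as copies of the counted ("b") allele, `NA`
for missing, autosomes 1-22 only, 1-based inclusive bp coordinates.

## Minimum run length: how long must a "run" be?

Short homozygous stretches arise by chance. With mean per-SNP
heterozygosity $\bar h$, $m$ markers and $n$ individuals, the expected
number of chance runs of $L$ consecutive homozygous calls is
approximately $(1-\bar h)^L \, m \, n$. `min_roh_snps()` returns the
smallest $L$ bringing this expectation below a tolerance (default 0.05);
at $\bar h = 0.35$, $m = 410{,}973$, $n = 2{,}123$ this gives $L = 55$
with about 0.04 expected chance runs.

Linkage disequilibrium makes adjacent genotypes non-independent, so 55
*independent* calls correspond to more *observed* SNPs.
`ld_tag_groups()` counts separable LD tag groups by a greedy left-to-right
scan (a SNP joins the nearest previous tag within 250 kb whose genotype
correlation satisfies $r^2 > 0.8$, else founds a new group), and
`adjust_min_snps()` inflates $L$ by the markers-per-tag-group ratio:
$\lceil 55 \cdot 410{,}973 / 310{,}000 \rceil = 73$. The pipeline default
`min_snps = 75` is the slightly more conservative adopted value; both
numbers are reported so the choice is auditable.

## The windowed ROH caller

`call_rohs()` scans each individual and chromosome with windows of
`window_snps = 50` consecutive SNPs. A window is *homozygous* iff it
contains at most `window_het_max = 0` heterozygotes and
`window_miss_max = 5` missing calls. A SNP is *eligible* if the fraction
of homozygous windows among the windows containing it reaches
`snp_window_frac = 0.05`, **or** if it lies in at least one fully
homozygous window. The second clause is deliberate: a boundary SNP of a
true run is covered by exactly one fully homozygous window, a hit
fraction of 1/50 = 0.02, so the bare fraction threshold would shave the
outermost SNPs off every run. With the clause, on clean data
(zero-heterozygote allowance, no missingness) the caller provably equals
the brute-force "maximal homozygous run" oracle for any run of at least
`window_snps` SNPs - the property the test suite checks against an
independent oracle implementation.

Maximal stretches of eligible SNPs become segments, split wherever
adjacent SNPs are more than `max_gap_kb = 1000` apart, and filtered by

* `min_snps = 75` genotyped SNPs (missing calls do not break a run and
  count toward the window allowance, but not toward `n_snps`);
* `min_kb = 1000` - segment length is `(end_bp - start_bp)/1000` with
  ends at the first/last SNP of the run, the segment-reporting
  convention of the standard tool;
* density: at most `min_density_kb_per_snp = 50` kb per SNP.

## Recurrent consensus regions

`pool_rohs()` clusters same-chromosome segments by single-linkage
interval overlap, takes the *intersection* of member spans as the
consensus, and keeps clusters with more than five distinct carriers, a
consensus of at least 500 kb, and at least 75 genotyped markers inside
it. "Nearly identical start and end locations" has no printed tolerance
in the source material, so the deterministic
overlap-cluster-plus-intersection construction is used; carriers are
persons, not segments (an individual with two overlapping segments
counts once). Each region gets

* `carrier_chi2()`: an uncorrected df = 1 Pearson chi-square on the
  carrier/non-carrier by case/control table, with an optional
  label-permutation p (hypergeometric resampling of the table);
* `homozygosity_proportion_test()`: per-SNP homozygote proportions in
  cases and controls across the consensus, compared with a one-tailed
  Welch t-test whose direction follows the carrier excess. Welch is
  used because only a "t-test" is named by the method's source; the
  pooled-variance alternative differs negligibly here.

No continuity correction is applied anywhere: the published table
statistics (6.59, 4.55, 3.73 for carrier counts 7/1, 7/2, 0/5 at group
sizes 906/1,217) reproduce exactly under the uncorrected formula when
*truncated* (not rounded) to two decimals, which is the printing
convention `trunc_digits()` encodes.

## Burden and binned odds ratios

`summarize_burden()` gives per-person segment count, total kb and mean
segment kb; `group_burden_test()` compares any of these between groups
by Welch t-test (pooled-variance optional) plus a two-sided
label-permutation test on the absolute mean difference, with subgroup
support (a case subset against all controls). `median_split()` divides
the cohort at the median of a statistic (strictly below versus at or
above, the cut value reported). `binned_or()` forms classes at
control-side quantiles (ties fall into the lower class, so realised
counts can be unequal - as in published tables), uses the lowest class
as reference, and reports the crude OR $(a d_{ref})/(b c_{ref})$ with
the Woolf interval $\exp(\ln \mathrm{OR} \pm z_{0.975}\sqrt{\sum 1/n_{cell}})$,
the uncorrected chi-square p, and a logistic-regression p side by side
(the published tables do not state which model produced their p-values;
both are emitted). Published ORs reproduce from the printed counts at
two-decimal truncation; the published intervals do not all match
unadjusted Woolf intervals (e.g. one row prints 0.32-0.89 where Woolf
gives 0.330-0.896), so the package reports the Woolf form and documents
the discrepancy rather than guessing the unstated recipe.

## Inbreeding coefficients

With dosage $x$, sample allele frequency $p$ and $h = 2p(1-p)$,
`fhat_estimators()` computes per SNP

$$F_1 = \frac{(x-2p)^2}{h} - 1, \qquad
  F_2 = 1 - \frac{x(2-x)}{h}, \qquad
  F_3 = \frac{x^2 - (1+2p)x + 2p^2}{h},$$

averaged over the individual's non-missing markers with $0 < p < 1$
(mean of ratios, the per-SNP normalisation of the classical estimators;
a ratio-of-sums variant is exposed). $F_1$ estimates inbreeding through
the variance of additive values, $F_2$ through excess homozygosity,
$F_3$ through the correlation of uniting gametes; all three may be
negative on finite data. Frequencies come from the pooled analysis
sample - cases and controls together - as no group-specific reference
is stated for the source analysis. All three estimators are invariant
to which allele is counted.

`f_roh()` is the segment-based alternative:
$F_{ROH} = \sum L_{ROH} / L_{AUTO}$, the summed bp length of segments at
or above the 1,000 kb criterion over the SNP-mappable autosomal genome
length, $L_{AUTO} = 2{,}676{,}172{,}944$ bp by default (a configurable
constant; the exact centromere exclusions behind it are not published).
`per_chromosome_f()` restricts $F_1$ to each chromosome; the SNP-weighted
mean of the columns reproduces the genome-wide value to numerical
precision, and the per-chromosome SD across samples rises as chromosome
marker counts fall (shorter chromosomes average fewer terms), giving the
negative SD-versus-length correlation seen in real data.

## Covariate-adjusted association and permutation

`logistic_glm()` fits status (case = 1) on an inbreeding measure plus
covariates - sex, the top 10 ancestry PCs from `genotype_pca()`
(standardised $(x-2p)/\sqrt{2p(1-p)}$, missing as 0, LD-pruned by
default, deterministic sign convention), and per-sample missingness -
reporting the Wald z-test for the measure. Perfect separation is
flagged rather than reported as a p-value; collinear covariates raise an
error naming the columns.

`perm_regressor_residuals()` implements the permutation-of-regressor-
residuals safeguard: the measure is regressed linearly on the
covariates, its residuals replace it in the GLM (observed statistic =
Wald p), and each permutation shuffles the residuals and refits,
leaving the covariate-outcome structure intact. The add-one estimator
$(1 + \#\{p^{*} \le p_{obs}\})/(B+1)$ avoids zero p-values, so
$p_{perm} \ge 1/(B+1)$; fixed seeds give identical results. Two-sided
alternatives are the default (the source analysis does not state
sidedness; a switch is provided).

## The synthetic cohort generator

Real deposited cohort data are not redistributable, so every stage is
validated on `simulate_cohort()`. The generator is a *test instrument*,
not an estimate of any real data set:

* marker positions uniform per chromosome over lengths proportional to
  hg18 autosomes, rescaled so the total equals $L_{AUTO}$ - keeping
  $F_{ROH}$ magnitudes on a realistic scale;
* allele frequencies Uniform on `maf_range` (default 0.05-0.5,
  mirroring the MAF > 0.05 analysis filter);
* genotypes from the inbreeding-inflated Hardy-Weinberg trinomial
  $P(2) = p^2 + Fp(1-p)$, $P(1) = 2p(1-p)(1-F)$,
  $P(0) = (1-p)^2 + Fp(1-p)$, with per-individual $F$ drawn normal per
  group and clamped to $[0,1]$ (the trinomial needs valid
  probabilities; estimators may still return negative values). The
  default group means/SDs (cases 0.002/0.008, controls 0/0.006) mirror
  the group summaries reported for a real outbred cohort;
* planted autozygous tracts: homozygous stretches of configurable kb
  length, placed uniformly away from chromosome ends, overlaps within
  an individual merged so the truth stays unambiguous; the tract allele
  at each SNP is drawn once with probability $p$;
* missingness applied last, uniformly at random;
* disease models: `label_driven` (labels independent of genotypes - the
  null), `logistic_on_F`, or `recessive_locus` with per-genotype
  penetrances.

What the generator does *not* emulate: linkage disequilibrium and
haplotype structure, recombination maps, and population stratification
(PC covariates are exercised with noise covariates in tests). A green
test therefore establishes correctness of the *algorithms and their
statistical calibration under the stated model*, not robustness to
LD-driven artefacts in real arrays.

## Numerical conventions and edge cases

* Coordinates 1-based inclusive; segment length `end - start` bp (kb =
  bp/1000); BED export converts to 0-based half-open.
* Report statistics truncate to two decimals (`trunc_digits()`); full
  precision is kept internally.
* Markers with undefined or boundary frequencies are skipped per
  estimator with a logged count; all-missing markers are flagged
  `NA`.
* A PED/MAP pair stores no allele order, so a marker whose first
  observed genotype is homozygous for the counted allele flips coding
  through a text round trip (content preserved); the binary fileset
  stores both alleles and round-trips bit-exactly.
* Degenerate tests (zero margins, zero variance, empty groups) are
  flagged explicitly rather than silently dropped; identical groups
  give t = 0, p = 1 (two-sided) or p = 0.5 (one-tailed).
* Uniformity of discrete per-SNP p-values is checked by tail
  calibration and a permuted-label two-sample comparison, because a
  one-sample Kolmogorov-Smirnov test is invalid for discrete
  statistics at high resolution.

## Known limitations

* No LOD-based or IBD/haplotype-based ROH inference; the windowed scan
  is genotype-only.
* Natural-selection metrics (iHS, $F_{st}$, Fay and Wu's H) are treated
  as external annotation; only their conventional thresholds are kept
  as metadata. No gene or pathway annotation.
* No VCF input, sex chromosomes, imputation, or mixed models.
* Allele frequencies are computed on the final analysis set; whether
  the original analysis computed them before or after sample QC is not
  recoverable, and the difference is negligible at cohort scale.
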