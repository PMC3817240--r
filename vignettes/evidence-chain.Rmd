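---
title: "An integrated evidence chain for candidate-pathway studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated evidence chain for candidate-pathway studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsel)
```

# The problem

Candidate-pathway studies of complex disease — the motivating case is the
RTK/ERK signalling pathway in prostate-cancer risk — combine several layers
of evidence about the same set of SNPs and genes:

1. **Per-SNP association**: an additive logistic regression of case/control
   status on genotype dosage, adjusted for age; odds ratios, 95% CIs and
   two-sided Wald P values.
2. **Gene- and pathway-level association**: the adaptive rank truncated
   product (ARTP) permutation test, which combines per-SNP P values within a
   gene, and gene-level evidence across the pathway, without assuming how
   many SNPs carry signal.
3. **Recent positive selection**: extended haplotype homozygosity (EHH) and
   the integrated haplotype score (iHS) from phased haplotypes, plus an
   empirical gene-window caller for candidate targets of selection.
4. **Regulatory function**: additive linear-model eQTL tests against probe
   expression, with permutation significance and the 1 Mb cis/trans rule.
5. **Intersection**: SNPs that are simultaneously associated (P < 0.05),
   under suggestive selection (|iHS| > 1.65), and supported by eQTL evidence
   are the final candidates.

The cohort and consortium data behind such studies (case/control genotypes,
reference-panel haplotypes, expression panels) are access-controlled, so the
package ships a ground-truth simulator that emulates their statistical
structure. Every stage is therefore testable end to end offline, and small
packaged fixtures of published summary tables support worked examples whose
arithmetic *is* reproducible.

# Models and procedures

## Association

`fit_snp_logistic()` fits `status ~ dosage + age` by iteratively reweighted
least squares (relative deviance change < 1e-8, at most 50 iterations),
reporting `OR = exp(beta)`, the 95% CI `exp(beta ± 1.959964·se)` and the
two-sided Wald P. Additive dosage coding is used throughout — the
conventional default when no genetic model is asserted. Missing genotypes
are dropped pairwise (per SNP); no imputation is attempted. Monomorphic SNPs
and SNPs leaving fewer than 10 cases or controls are skipped with a reason;
separation (|beta| > 10) or non-convergence yields a flagged record with a
missing P, rather than a misleading number.

`wald_p_from_or_ci()` inverts the printed columns of a published table
(`se = (ln U95 − ln L95)/(2·1.959964)`), which lets the tests verify
published rows to within the rounding of the printed inputs (all four
checked rows agree within 0.2% relative).

## ARTP

For a gene with SNP P values `p_1..p_L`, the rank truncated product
statistic at truncation point k is the product of the k smallest P values
(computed as a sum of logs). One phenotype-permutation ensemble (covariates
stay attached to their samples; only labels are permuted) yields the null
reference: each replicate's W(k) is ranked within the ensemble, the minimum
over the truncation grid of those rank-based significances is the adaptive
statistic, and the gene P is the single-layer adjustment
`(1 + #[replicates with MinP ≤ observed MinP])/(B+1)`. The pathway layer
applies the identical construction over genes, feeding on the same
ensemble's per-gene MinP statistics — no nested resampling, so B
permutations price both layers.

Inside the ensemble the per-SNP statistic is the covariate-adjusted score
test evaluated at the covariate-only null fit. This is vectorised across
SNPs with two matrix products per replicate, which is what makes
10,000-permutation runs affordable; a full per-SNP logistic refit is
available (`method = "wald"`) and agrees with the score test on toys to two
decimals. The truncation grid defaults to {1, 2, 3, 4, 5, 10, 15, 20}
capped at the SNP count — the conventional default family — and is echoed
in the result for transparency. Ties in W count as "≤" (conservative), and
every reported P respects the floor `1/(B+1)`.

An optional `prefilter_alpha` reproduces the workflow in which only SNPs
with observed association P below a threshold enter the gene test. Because
the filter is chosen on the observed data but applied to the permutation
replicates' fixed SNP set, it is a selection-biased variant; it is OFF by
default and flagged in printed output when used.

## EHH / iHS

Among the haplotypes carrying a given allele at a core SNP, EHH at distance
x is the probability that two random carriers are identical over the entire
segment from the core to x: `sum_e C(n_e,2)/C(n_c,2)` over distinct extended
haplotypes. It is computed by incremental partition refinement (a compiled
loop; tested against an explicit all-pairs oracle). iHH integrates the EHH
curve over *genetic* distance by the trapezoid rule, each direction
truncated after the first point below the EHH floor of 0.05 (the
conventional cut-off); a curve that reaches the panel edge above the floor
is flagged truncated and its SNP excluded from the scan. The unstandardised
score is `uiHS = ln(iHH_A / iHH_D)` (A = ancestral-allele carriers, D =
derived), so strongly negative values mean unusually long derived-allele
haplotypes. Scores are standardised within derived-allele-frequency bins of
width 0.05 (bins under 10 SNPs merge with their nearest neighbour), making
the genome-wide distribution mean 0, sd 1 per bin; under neutrality about 5%
of SNPs exceed |iHS| = 1.959, which the calibration tests check. Core SNPs
require minor allele frequency strictly above 5%. Both tails count as
interesting; thresholds 1.65 (suggestive) and 2 (strong) are the defaults.

`ihs_scan(standardize = <reference scan>)` applies a previous scan's bin
means/sds instead of estimating them from the focal panel. This mirrors how
candidate regions are scored in practice — standardisation parameters come
from the genome-wide background — and matters at simulation scale, where a
planted sweep can occupy a visible fraction of the panel and would otherwise
contaminate its own frequency bins.

The gene-window caller takes, for each gene, the scored SNP nearest the gene
midpoint as index SNP ("nearest the midpoint" resolves an ambiguity in the
verbal rule; the choice is configurable in spirit by passing gene start/end
as a degenerate interval), forms a window of 50 scored SNPs centred there
(clipped at chromosome ends and flagged if short), counts SNPs with
|iHS| > 2, and compares that count with every sliding 50-SNP window
genome-wide: a gene is a candidate if its count reaches the upper 10% of
that empirical distribution, and the reported `fraction` is the proportion
of windows at least as extreme. With no significant SNP anywhere, no gene
is called (the quantile rule alone would otherwise flag everything at
count 0).

## eQTL

`eqtl_test()` is ordinary least squares of expression on dosage with a
two-sided t test (closed form; checked against `summary.lm`). It requires 3
distinct dosage values, or 2 with at least 10 samples. Permutation
significance shuffles the expression vector (the standard per-pair scheme)
and reports `(1 + #[|t_perm| ≥ |t_obs|])/(B+1)`. A pair is cis iff on the
same chromosome within 1 Mb inclusive — the boundary is not stated in the
verbal rule and is resolved as ≤ — otherwise trans. Replication across
expression panels is modelled as independent scans; no meta-analysis is
performed.

## Pipeline

`run_pipeline()` chains association → ARTP → iHS scan → candidate join
(P < 0.05 and |iHS| > 1.65) → gene-window scan → eQTL on surviving loci →
evidence table, persisting every stage as TSV plus a JSON manifest echoing
the configuration. Stage seeds derive from the configured seed by fixed
offsets, so a re-run is byte-identical. The final table mirrors the
published layout: genotype counts (effect = minor allele), SNP iHS, gene
window fraction, association P, gene ARTP P and best cis/trans permutation
P. Multiple-testing stance mirrors the study conventions exactly (raw 0.05
/ 1.65 / 2 / upper-10%); no genomic control or population-structure
adjustment is applied.

# The simulator: what it emulates, and what it does not

`simulate_neutral_panel()` draws founder haplotypes at per-SNP derived
frequencies uniform on (0.05, 0.95) and builds descendants by block-wise
mosaic copying (25 founders, 25-SNP blocks, 0.005 per-site copy flips).
This produces tunable block LD at trivial cost — the analyses downstream
need LD structure, not demographic realism. A coalescent or forward
simulator would add realism (recombination-rate heterogeneity, allele ages,
frequency spectra) that none of the tested statistics requires.

`simulate_sweep()` imposes a hard sweep by replication with recombination
escape: one derived-carrying haplotype becomes the sweep lineage; every
derived carrier and enough random ancestral carriers to reach the target
frequency are overwritten by a copy of it between two breakpoints drawn at
exponential genetic distances from the core (mean 0.25 cM at frequency 0.5,
scaled quadratically with the implied logistic growth rate so that sweeps
observed at higher frequency carry longer haplotypes, the qualitative
pattern seen in real scans), plus fresh point flips at 5e-4 per copied
site — an order of magnitude below the standing-variation scale because the
sweep is recent. With escape and flips both zero the construction
degenerates to a whole-chromosome hard sweep with EHH ≡ 1 in the derived
class. At desk scale the 0.6 → 0.8 step of the detectability-vs-frequency
curve is a statistical tie: the neutral reference's uiHS spread grows at
extreme derived frequencies and offsets the longer raw haplotypes; the raw
derived-class iHH still grows per seed, which the property test checks
separately.

`simulate_phenotype()` draws ages from N(65, 8) and status from a logistic
model `intercept + Σ log-odds·dosage + 0.03·(age − 65)`, with the intercept
solved by `uniroot` so the marginal prevalence hits the target within 0.01.
The default 50% case fraction approximates a balanced case/control design
(the emulated cohort is ~58% cases); the small fixed age coefficient makes
the covariate non-trivial without confounding the genotype effects.

`simulate_expression()` gives designated SNP-probe pairs
`E = beta·dosage + N(0, noise_sd)`, placing those probes within 1 Mb of
their SNP; all other probes are standard-normal noise placed beyond 1 Mb of
every SNP, so the designated pairs and only they are labelled cis.

What passing tests on these data do **not** show: robustness to population
stratification, genotyping error, imputation uncertainty, non-additive
genetic models, expression normalisation artefacts, or realistic allele
ages — none of which the simulator generates.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; BED input is converted on
  read. Gene flanks (default 100 kb) are boundary-inclusive.
* Ancestral allele comes from the `AA` INFO tag; absent that, the sample
  major allele is used and the variant flagged `ancestral_inferred`, the
  standard fallback without outgroup data.
* Genetic-map interpolation is linear between map points, extrapolating at
  the nearest interval's rate; a single-point map falls back to 1 cM/Mb
  with a warning.
* Permutation P values always include the observed replicate in the
  denominator (`1/(B+1)` floor; never zero). B < 20 triggers a coarseness
  warning.
* The significance filter uses strict inequality at 0.05; the selection
  thresholds use strict |iHS| > 1.65 / 2. On the packaged evidence fixture
  this reproduces a subtlety of the published table: 26 of its 27 rows pass
  |iHS| > 1.65 strictly (one row sits at 1.647), matching the published
  count of 26 selected SNPs.
* The windows' empirical quantile uses R's default (type 7) definition.
* Score-test variances that are non-positive (degenerate columns) map to
  P = 1 rather than NaN.

# Problem sizes in the test-suite

The suite's simulations are sized for a single CPU: null calibrations use
hundreds of replicates at n of a few hundred to a few thousand samples;
iHS calibration and sweep positive controls use 2,000 haplotypes × 2,000
SNPs; the exhaustive oracles run at n = 8 (70 case assignments) and n = 6
(720 orderings); end-to-end runs use ~500-1,000 samples, 1,500-1,600 SNPs
and a few hundred permutations. These are the package's chosen study
conditions for verifying calibration and power; production runs simply
scale the same functions up.

# Known limitations

* The per-SNP score test inside permutations is a one-step approximation;
  it agrees closely with full refits at moderate effect sizes but can
  diverge under near-separation (where the full-refit option exists).
* The gene-window empirical distribution is computed over the panel
  provided; with few chromosomes it has few effective degrees of freedom,
  and the upper-10% rule is correspondingly coarse.
* The published pathway-level P values cannot be reproduced without the
  original cohort genotypes; the package reproduces the published tables'
  *arithmetic* (Wald-from-CI, percentage denominators, extreme-value
  identification) and validates the methods on synthetic ground truth
  instead.
* iHS is one of several selection statistics; cross-population statistics
  (XP-EHH, Fst) are out of scope.
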