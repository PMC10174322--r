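---
title: "Methods: ceRNA network inference in cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference in cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

# Scope and model

`cernet` infers competing-endogenous-RNA (ceRNA) networks from three
count matrices (lncRNA, miRNA, mRNA) measured on the same two-group
sample set, plus transcript and mature-miRNA sequences. The underlying
biological model is the sponge hypothesis: a lncRNA and an mRNA sharing
miRNA response elements (MREs) compete for the same miRNA pool, so the
miRNA should be anti-correlated with both partners while the partners
are positively correlated with each other, and both partners should
carry predicted binding sites for the shared miRNA. A triplet enters the
network only when all four pieces of evidence hold simultaneously.

The pipeline starts from transcript records and count matrices, not
reads: alignment, assembly and quantification are upstream of this
package.

# Differential expression

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$.

* **Normalization.** Median-of-ratios size factors: the median over
  genes of the ratio of a sample's count to the gene's geometric mean
  across samples; genes with any zero count carry no ratio. We rescale
  size factors to geometric mean 1 by default; this fixes the arbitrary
  overall scale and changes nothing that depends on ratios.
* **Dispersion.** Per-gene method-of-moments estimates on normalized
  counts pooled within groups, with the shot-noise correction
  $\hat\alpha = \max(0, (v - \xi\mu)/\mu^2)$, $\xi = \mathrm{mean}(1/s_j)$.
  A parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted by least
  squares over genes with positive estimates (coefficients floored at
  0), and the working dispersion is the **maximum** of the gene-wise
  value and the trend. With 3–4 replicates per group the gene-wise
  estimator is very noisy; taking the maximum is deliberately
  conservative, and the measured type-I error of the full screen on null
  simulations sits at the lower edge of the nominal band (see the
  acceptance suite) rather than above it.
* **Exact test.** Conditional on a gene's total count $K$, all splits
  $(a, K-a)$ are enumerated with group masses given by NB distributions
  whose means are the pooled rate times the group's summed size factors
  and whose variances include the $\alpha$ term with $\sum_j s_j^2$;
  the two-sided p-value sums the probabilities of splits no more likely
  than the observed one. At $\alpha = 0$ this reduces exactly to a
  conditional binomial enumeration, which the test suite checks to
  1e-12 for all $K \le 50$. Ties between split probabilities are
  detected with a relative tolerance of 1e-7 so that mathematically
  equal tails are not split by floating-point rounding.
* **Screen.** `Up` iff $\log_2\mathrm{FC} > 1$ and $p \le 0.05$; `Down`
  symmetric; fold changes are oriented case/reference (second group
  level over first), so FC > 1 means up in the case group. BH q-values
  are reported but the screen gates on p: that is the convention the
  report format follows, and both columns are printed so users can gate
  on q instead. Genes with zero counts in all samples have no defined
  fold change and are dropped with a recorded count.

# MRE prediction

Transcripts are handled 5'→3' in the RNA alphabet (FASTA readers accept
T and convert). A site candidate is a transcript position matching the
reverse complement of miRNA positions 2–8. Candidates are classified
with the canonical taxonomy (8mer, 7mer-m8, 7mer-A1, 6mer, strongest
first, using the A-anchor opposite position 1), then extended by a
Smith–Waterman alignment of the full reverse-complemented miRNA over a
window of width `len(miRNA) + 10` around the seed, with affine gaps
(−9 open, −4 extend), +5 match, +1 G:U wobble, −3 mismatch, and all
substitution scores multiplied by 4 when the miRNA position lies in the
seed (2–8). A hit is emitted at score ≥ 140 — the score of a bare
perfect seed (7 × 5 × 4), so any emitted hit has at least a perfect
seed's worth of weighted pairing. Overlapping hits of one miRNA on one
transcript are merged keeping the best score (ties: leftmost).

Two deliberate conventions:

* **Strict seed (no wobble) by default.** `max_wobble_in_seed = 0`.
  Chance candidates occur at the $4^{-7}$ 7-mer rate (~0.06 expected
  per 1000-nt random transcript); tolerating one G:U roughly doubles
  the candidate surface and pushes the decoy false-positive pair rate
  on random transcripts above 5%. Strict Watson–Crick seed pairing is
  also the established "strict" convention of the weighted-alignment
  predictors this module mirrors. The parameter is exposed for users
  who want wobble seeds.
* **No free-energy term.** Thermodynamic filtering is omitted; the
  score is purely alignment-based. This is a simplification, kept
  because the score threshold already anchors hits to a perfect seed.

Coordinates are 0-based half-open internally and 1-based closed in
written reports.

# Coexpression screens and MuTaME scoring

Correlations are Pearson's r on $\log_2(\text{count}/s_j + 1)$ (pseudo
count fixed at 1), with p-values from the t-transform with $n-2$
degrees of freedom. Defaults $|r| \ge 0.7$, $p \le 0.05$ are the common
vendor-pipeline convention; both are configurable. Zero-variance
features are skipped with a recorded count.

For a candidate pair (A = lncRNA, B = mRNA) with shared miRNA set $M$:

* $S_1 = |M|^2 / (|M_A||M_B|)$ — how much of each transcript's miRNA
  repertoire is shared;
* $S_2$ — mean site density $n/(p_n - p_1 + 7)$ per shared miRNA and
  transcript ($1/\mathrm{len}$ for single sites);
* $S_3$ — mean spread ratio $\min(\text{gaps})/\text{mean(gaps)}$ (1
  when fewer than two sites);
* $S_4$ — shared-miRNA hits over all hits on the pair.

The raw score is $\sum_i \ln S_i$ (components floored at $10^{-12}$)
and the reported score min–max normalizes raw values to 0–100 across
the evaluated pairs of the run.

**The score gates nothing by default** (`score_min = 0`). This is a
considered design choice: because the 0–100 scale is normalized within
each run, its meaning depends entirely on the composition of the
evaluated pair set — in a run where most candidate pairs are genuine,
an absolute cutoff at 50 would discard about half of the true pairs
purely by construction. The score is therefore treated as a ranking
key (it drives `top_axes`) rather than an evidence threshold; the
evidence thresholds are the sign-constrained correlations and the
shared-MRE requirement. Users who want a score gate, or the optional
hypergeometric co-targeting test (`require_hyper`), can enable them in
`screen_thresholds()`.

Triplet assembly takes the strictest consistent reading of the
intersection: a triplet needs the negative miRNA–lncRNA edge, the
negative miRNA–mRNA edge, the positive lncRNA–mRNA edge, *and* the
miRNA among the pair's shared predicted MREs. Ranking of the top axes
uses (score desc, |r(L,G)| desc, lexicographic ids) — the tie-break is
an explicit convention so output is reproducible under permutation of
the input.

# Enrichment, qPCR and ROC

Over-representation uses the upper-tail hypergeometric p (via
`phyper`), one test per gene set with non-zero overlap, BH FDR across
tested sets, ranked by p (ties: larger overlap, then term id). The
universe defaults to the genes tested for differential expression, the
conventional background; sets are intersected with the universe before
testing. Depletion and topology-aware GO methods are out of scope.

`ddct` averages technical replicates on the Ct scale, then
$2^{-\Delta\Delta Ct}$ against the calibrator-group mean. `roc_auc` is
the midrank Mann–Whitney statistic (exactly the pair-counting
probability with half-credit for ties); `auc_ci` uses DeLong's
structural-components variance — the standard for single-marker AUCs —
with a stratified bootstrap as the alternative and as the automatic
fallback when the DeLong variance degenerates at AUC 0 or 1. CIs are
truncated to [0, 1].

# The synthetic-data generator

The generator emulates the qualitative structure of a small two-group
tissue study: by default 4 samples per group (the layer sizes and
numbers of planted effects are configurable), log-normal baseline
means (median 100 counts), log-uniform size factors in [0.5, 2],
NB dispersion following $\alpha(\mu) = 0.05 + 3/\mu$, ~10% of features
with planted $|\log_2\mathrm{FC}|$ drawn half-normal around 2, and a
configurable number of planted ceRNA triplets. Each triplet shares a
per-sample latent factor $z_j \sim N(0,1)$ — a stand-in for sponge
activity — that multiplies the lncRNA and mRNA means by
$2^{c \cdot 2.5 \cdot z_j}$ and the miRNA mean by the reciprocal,
where $c$ is `coupling`. The amplitude 2.5 log2 units at full coupling
makes the shared signal dominate NB noise for typically expressed
features, which is what gives the planted sign structure its high
penetrance at `coupling` ≥ 0.8. Sequences are uniform-random RNA
(300–1000 nt), miRNAs 22 nt with a 5' U (the dominant convention for
mature miRNAs, and what makes planted sites canonical 8mers);
`site_per_pair` exact seed complements are written at recorded,
non-overlapping positions into both partner transcripts of each
triplet.

All randomness derives from one seed with fixed per-stage offsets, so
adding a later stage never reshuffles an earlier one and outputs are
byte-identical across runs.

What the generator does **not** emulate: read-level noise and mapping
artefacts, GC and length biases, correlated library composition
effects, miRNA isoforms, non-canonical or 3'-compensatory binding
sites, overlapping triplet membership (each feature joins at most one
planted triplet), and any real secondary structure in the transcripts.
Passing the planted-truth benchmarks therefore demonstrates internal
consistency of the inference chain under its own assumptions, not
performance on real tissue data.

# Problem sizes and reproducibility

The test and acceptance suites run the recovery benchmarks on a
reference configuration of 20 samples per group, 60/55/120 features
per layer, 50 planted triplets at coupling 0.8 — large enough that
correlation screens at $|r| \ge 0.7$ are well inside their power
regime, small enough that the whole suite completes in a couple of
minutes on one core. Null calibration uses 2000 genes at 4 vs 4;
oracle comparisons enumerate all exact-test totals to $K = 50$ and all
hypergeometric configurations to $N = 15$; DeLong coverage uses 1000
replicates at 20 + 20. `scripts/acceptance.R` recomputes all of these
from a single `--seed`.

# Known limitations

* The exact test follows the classical fixed-dispersion conditional
  enumeration; GLM designs, covariates and shrunken fold changes are
  out of scope.
* MuTaME component weights are equal (unweighted sum of logs); all
  four components are reported per pair so alternative weightings can
  be audited downstream.
* The correlation screens are marginal (no partial correlations); with
  strong group effects, differentially expressed features correlate
  through the group factor, which the shared-MRE requirement — not the
  correlation screen — is what keeps out of the network.
* Orientation classification of lncRNAs uses genomic span overlap with
  a documented tie-break (largest overlap, then antisense, then lowest
  id); exon-level overlap is not considered.
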