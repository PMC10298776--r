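---
title: "Models and methods in caqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in caqtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices behind
`caqtlkit`. It states no empirical result that the test suite does not
itself compute.

## The joint cis-effect model

For one peak and one candidate variant, donor $j$ contributes a total
fragment count $y_j$ and, when heterozygous, an allele-informative depth
$d_j$ with $a_j$ alternate-allele reads. Both observations are driven by
one cis effect, the allelic ratio $\pi \in (0,1)$ ($\pi = 0.5$: no
effect; allelic fold change $\pi/(1-\pi)$):

$$
y_j \sim \mathrm{NB}\!\left(s_j\,\lambda\,e^{x_j'\gamma}\,
  [(2-g_j)(1-\pi)+g_j\pi],\ \phi\right), \qquad
a_j \sim \mathrm{BB}(d_j,\ p',\ \theta),
$$

with $p = \pi(1-\psi)/(\pi(1-\psi)+(1-\pi)\psi)$ and
$p' = p(1-2\partial)+\partial$. Here $s_j$ is the donor's library-size
factor, $\lambda$ baseline accessibility, $\gamma$ optional covariate
coefficients, $\phi$ the negative-binomial overdispersion, $\psi$ the
reference-mapping bias (0.5 = unbiased), $\partial$ the probability a
read's allele assignment is flipped, and $\theta$ the beta-binomial
overdispersion (binomial as $\theta \to 0$). The LRT compares the
profile maximum over $\pi \in [0.001, 0.999]$ against $\pi = 0.5$ on a
$\chi^2_1$ scale.

**Identifiability and the $\psi$/$\partial$ priors.** With a single
variant per test (the tested variant is also the allele-informative
site), the beta-binomial mean confounds $\pi$ and $\psi$: a free $\psi$
under the null can absorb any allelic imbalance, and the allelic
component would contribute nothing to the test. Tools that fit this
model on real data resolve this with multiple feature SNPs and phasing;
at this package's scale we instead place weak shrinkage priors
$\psi \sim \mathrm{Beta}(10, 10)$ (sd $\approx 0.11$ around 0.5) and
$\partial \sim \mathrm{Beta}(1, 19)$ (favoring small error) on the
allelic component, and both nested fits maximize the same penalized
objective. Genuinely extreme mapping bias still pulls $\hat\psi$ out of
the QC band $[0.2, 0.8]$ because the likelihood dominates the prior at
realistic depths; the priors only anchor the otherwise flat direction.

**Optimization.** A bounded Brent profile over $\pi$ with inner
coordinate ascent (Brent per coordinate) over $(\log\lambda, \gamma,
\log\phi)$ and $(\mathrm{logit}\,\psi, \partial, \log\theta)$, which are
conditionally independent given $\pi$. Convergence tolerance $10^{-6}$
on the objective; fixed start $\pi = 0.5$, $\psi = 0.5$,
$\partial = 0.01$, $\phi = \theta = 0.1$. After the profile search the
optimizer re-checks a small set of restart points ($\pi \in \{0.1, 0.25,
0.5, 0.75, 0.9\}$) because the profile can be bimodal at low depth. A
fit whose alternative objective falls below the null is flagged
non-converged and reported with $p = 1$, `qc_pass = FALSE`.

## Multiplicity and the permutation FDR

Within a peak, the lead variant minimizes the Bonferroni-adjusted
p-value $\min(1, p \cdot m)$ ($m$ = variants tested in the peak; ties
break by raw p, then genomic position). Across peaks, lead q-values are
Benjamini–Hochberg. Genome-wide control then compares observed lead
q-values with those from `n_perm = 2` reruns in which donor labels of
the whole dosage matrix are shuffled (preserving LD):

$$
\widehat{\mathrm{FDR}}(t) = \frac{\mathrm{mean}_k\,|\{q \in P_k : q \le t\}|}
     {\max(1, |\{q \in R : q \le t\}|)},
$$

with the threshold the largest observed $q$ at which
$\widehat{\mathrm{FDR}} \le \alpha$ (default 0.10; 0.20 for the
promoter-propagation stage).

**Permuted q-values are placed on the observed BH scale.** BH q-values
computed *inside* a pure-null permuted set concentrate near 1 (uniform
p-values yield $q_{(i)} \approx 1$), while null q-values inside a
signal-carrying observed set are deflated by the true signals' ranks;
comparing the two directly is sharply anti-conservative (realized FDR
$\approx 0.3$ at nominal 0.10 on the package's own mixed simulation).
Each permuted lead p-value therefore receives the q-value it would have
obtained among the observed results (the observed BH step function,
`bh_map`), which makes the ratio above the standard calibrated
permutation FDR expressed on the q scale. The counting formula itself is
unchanged.

## Heterogeneity across cell types

Counts from all cell types are normalized by median-of-ratios size
factors followed by $\log_2(\mathrm{count}/s + 1)$ — a lighter-weight
stand-in for a variance-stabilizing transform; the inferential contract
(nested linear models) does not depend on the exact curve. For each
peak–lead pair significant in at least one cell type, the full model
`value ~ genotype * celltype + covariates` is compared with the
no-interaction reduced model by an F test, with BH correction at FDR
0.10. Default covariates when supplied: age, sex, 4 genotype PCs, 4
accessibility PCs (the source protocol is ambiguous between 3 and 4
genotype PCs; 4 is the default and it is configurable).

Pairwise effect sharing uses Spearman correlation of $\hat\pi$ over
pairs significant in at least one member of each cell-type pair, and
$\pi_1 = 1 - \pi_0$ with Storey's bootstrap $\pi_0$: the
$\pi_0(\lambda)$ grid is $0.05, 0.10, \dots, 0.95$ and $\lambda$ is
chosen by bootstrap MSE against the grid minimum (100 resamples).

## Single-cell co-accessibility

Cells are aggregated into bins of $k = 30$ nearest neighbors in the
embedding; a candidate seed is rejected if its neighborhood shares more
than 80% of members with an accepted bin. Within overlapping 1 Mb
windows (stride 500 kb — the stride and the mean-across-windows
reconciliation are this package's choices), peak counts are standardized
and an L1-penalized inverse covariance is estimated with element-wise
penalty $\rho_{ij} = \mathrm{penalty} \cdot d_{ij}/10^6$ by an
in-package graphical lasso (blockwise coordinate descent; penalty
matrices are required for the distance scaling, which excludes canned
single-penalty implementations). Precision is converted to partial
correlations; a pair's score is its mean over covering windows.

Two numerical safeguards matter:

* **Robust depth normalization.** Bins are divided by median-of-ratios
  size factors before scoring. Without any correction, the shared
  per-bin depth factor (loadings proportional to peak rates) produces
  spurious positive links between high-baseline neighbors. Two simpler
  alternatives fail: dividing by bin totals is compositional (module
  activity leaks into all other peaks with the opposite sign), and
  conditioning on the bin total as an extra variable removes genuine
  signal whenever planted modules dominate the total (synchronized
  modules make the total a readout of their shared state). The median
  ratio is insensitive to the minority of co-accessible peaks and tracks
  only depth.
* **Penalty calibration.** With $k = 30$, the information in $n$ cells
  supports at most $\sim n/k$ independent bins, so null partial
  correlations fluctuate with sd $\approx \sqrt{k/n}$ ($\approx 0.05$ at
  10,000 cells) — comparable to the 0.05 score gate. The default base
  penalty 2.5 soft-thresholds those fluctuations away from zero distance
  upward while leaving module-scale signal (partial correlation
  $\rho/(1+\rho) \approx 0.45$ for a 3-peak module with marginal
  correlation 0.85) intact out to
  $d \approx (0.45 - 0.05)/2.5 \times 10^6 \approx 160$ kb. Links must
  additionally exceed score 0.05, span > 10 kb (midpoint to midpoint —
  unambiguous for variable-width peaks), and replicate at score > 0.05
  in ≥ 4 of the per-donor reruns.

Promoter peaks intersect a TSS ± 2 kb. Significant caQTLs are
classified promoter-direct, distal-linked, promoter–promoter-linked, or
unlinked; for linked promoters the lead variant is re-tested against the
promoter peak's totals in population-only mode (the lead is generally
outside the promoter peak, so no allelic reads exist there) at a relaxed
empirical FDR of 0.20, and effect coupling is summarized by the Pearson
correlation of $\hat\pi$ between the caQTL peak and its best-associated
promoter, overall and in distance bins (10–50, 50–100, 100–200,
200–350, 350–1000 kb).

## Fine-mapping and trait enrichment

Per GWAS signal: dosage-correlation $r^2$ with the index variant within
± 2.5 Mb from the reference panel, a strict $r^2 > 0.1$ pre-filter,
Wakefield approximate Bayes factors
$\mathrm{aBF} = \sqrt{V/(V+W)}\,\exp(W z^2 / (2(V+W)))$ with $W = 0.04$,
PPA by per-signal normalization **after** the LD filter (the
normalization is defined over "variants included in the signal"), and
the 99% credible set as the smallest descending-PPA prefix reaching
0.99, boundary ties broken toward the smaller genomic position (the
source is silent on ties). One causal variant per signal is assumed
throughout; conditional/multi-signal fine-mapping is out of scope.

Trait enrichment per cell type: the observed statistic is the summed PPA
of credible-set variants inside the cell type's significant caQTL peaks;
the null redraws `|caQTL peaks|` peaks without replacement from the
tested-but-not-significant background 1,000 times. The empirical p-value
uses the add-one formula $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) /
(n+1)$, avoiding $p = 0$. `log_or` is defined as
$\log(\mathrm{obs}/\mathrm{mean(null)})$ — a stand-in, since the printed
quantity it echoes has no published formula; it must not be compared
against published values.

## Motif disruption

PFMs are converted to log-odds PWMs (bits) with pseudocount 0.8 against
a configurable background (uniform by default). Tail p-values
$P(S \ge s)$ under independent background bases are computed exactly by
dynamic-programming convolution of per-position score distributions
discretized at $10^{-3}$ bits; enumeration for motif length ≤ 8 is the
test oracle. A variant's two alleles are scored over all windows
covering it on both strands; an allele is "bound" at exact
$p < 5\times10^{-4}$. Effects: **strong** when exactly one allele is
bound and the range-scaled score change is ≥ 0.15; **weak** when both
are bound and the change is ≥ 0.05; both cutoffs are configurable
approximations of the cited classifier, whose internal thresholds are
not published. Per-motif caQTL enrichment is a one-tailed binomial test
of the caQTL disruption count against the all-tested-variants rate, BH
across motifs; a global any-motif Fisher test is also reported. The
bundled five PFMs (ETS/IRF/SPI1/RUNX/CEBP-like) are synthetic stand-ins
for a motif database, as their filename states.

## The synthetic cohort: what it emulates, and what a green test shows

`simulate_cohort` mirrors the data layout of a 10-donor PBMC snATAC
study: 4 cell types with abundances (T 0.45, Mono 0.30, B 0.15, NK
0.10) scaling depth; peaks of 300–800 bp spaced 8–25 kb over 5
chromosomes; LD blocks of 6 variants copied from 4 weighted founder
haplotypes (high within-block $r^2$, independence across blocks); 20% of
peaks carry a caQTL with $\pi \in [0.6, 0.85]$ (random direction),
$\psi \in [0.45, 0.55]$, $\partial \in [0, 0.05]$, shared across all
cell types with probability 0.6, else specific to one; library factors
$s_j \sim$ lognormal(0, 0.25); allele-informative depth is
binomial(total, 0.2) — the informative fraction is a free choice, the
source does not state it. The count model is the exact generative
counterpart of the fitted likelihood ($\phi = 0.1$, $\theta = 0.02$).

Choices worth knowing when reading test results:

* **MAF targets are snapped** to the nearest achievable founder-pool
  frequency in [0.05, 0.95] and the snapped value is recorded as the
  variant's `maf`; exact arbitrary MAFs are not achievable under founder
  copying with shared founder weights.
* **Planted causal variants are testable by construction** (heterozygous
  in ≥ 2 donors): an effect planted on an untestable variant could never
  be recovered by any mapping rule.
* **GWAS marginal noise is drawn jointly** with correlation equal to the
  dosage correlation: marginal estimates of variants in LD come from the
  same phenotype data, so perfect-LD proxies receive near-identical
  statistics. One signal per chromosome keeps the single-causal
  assumption valid inside the ± 2.5 Mb window.
* **Module activity lives in the embedding**: each cell carries a 2-D
  latent regulatory state appended to its cluster coordinates, and a
  module is "on" on one side of a module-specific hyperplane
  (orthogonal directions for same-chromosome modules). kNN bins are then
  state-coherent — the premise that makes aggregation-based
  co-accessibility work; i.i.d. per-cell activity would average away
  under binning and no method could recover it. Module peaks get a
  fixed representative accessibility (0.2 fragments/cell) and module
  members lie within ± 100 kb of a promoter anchor, the typical
  enhancer–promoter range. The default of 2,500 cells per donor is
  conservative for PBMC snATAC and, at k = 30, supports enough
  independent bins for the 0.05 score gate to separate signal from
  aggregation noise.

What the generator does **not** emulate: nucleosome-scale structure, TSS
enrichment profiles, fragment-level data, doublets, imputation error,
trans effects, multi-causal GWAS signals, and realistic motif sequence
context (pipeline motif scans use random flanking sequence). A green
suite therefore establishes internal statistical correctness and
calibration under the stated model, not concordance with any particular
real cohort.

## Degenerate inputs and edge rules

Empty testable-pair sets return empty tables, not errors. Monomorphic
variants are excluded from LD (undefined $r^2$) and from GWAS summary
output. All-zero count matrices refuse normalization. Zero requested
cells yield an empty matrix. A promoter peak overlapping several TSS
windows carries all gene ids. Odds ratios from degenerate Fisher tables
are Haldane-corrected (+0.5 per cell). `empirical_fdr` with no
permutations is an error; an all-`NA` threshold means nothing passes.
Coordinates are 0-based half-open internally (BED convention); VCF
positions are 1-based and converted at the boundary, and round-trip
through `write_vcf`/`read_vcf` exactly.
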