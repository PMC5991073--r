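---
title: "Window-based miRNA association testing: model, simulation null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based miRNA association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwin)
```

## The problem

Genome-wide association studies of lithium response in bipolar disorder produce
per-SNP p-values, but microRNA genes are short (hairpin records span roughly
60–150 bp) and rarely contain a genotyped SNP at all. The unit of interest is
therefore not a SNP but a *window*: the miRNA transcript plus 20 kb of flanking
sequence on each side, which captures the majority of proximal regulatory
variation. `mirwin` tests each such window for association using only summary
statistics (SNP id, chromosome, position, p-value), an external reference
genotype panel for linkage disequilibrium (LD), and miRBase-style coordinates.

Two phenotype definitions run through the same machinery. Both derive from the
Alda scale: an A score in 0–10 rating symptom improvement under lithium, and
five B criteria (each 0, 1 or 2) penalising confounding. The total score is
`max(0, A − ΣB)`; subjects with total ≥ 7 are *good responders* (dichotomous
phenotype), and the continuous phenotype is the raw A score with subjects
excluded when ΣB > 4. A useful consequence, verified exhaustively over all
11 × 3⁵ input combinations in the test suite: a good responder always has
ΣB ≤ 3, so no good responder is ever excluded from the continuous analysis.

## The set statistic

For a window containing $m$ SNPs with p-values $p_1, \dots, p_m$, each p-value
is transformed to its upper-tail $\chi^2_1$ quantile
$q_i = F^{-1}_{\chi^2_1}(1 - p_i)$, so that small p-values become large
statistics. The top-fraction statistic with fraction $f$ (default $f = 0.1$,
the "top-0.1" test) sums the $k$ largest transformed values,

$$T = \sum_{(i) \le k} q_{(i)}, \qquad k = \max(1, \lceil f\,m \rceil).$$

Summing raw p-values would invert the evidence ordering — a highly significant
SNP would *decrease* the statistic — so the quantile transform is the only
reading of a "sum over the most significant SNPs" consistent with the test's
purpose. The ceiling with a floor of one guarantees that windows with fewer
than ten SNPs are still testable; `k_rounding = "floor"` is available for
sensitivity analysis.

## The simulated null and the selection correction

Under the null, the vector of association z-scores of the $m$ SNPs is
approximately multivariate normal with mean zero and correlation equal to the
LD correlation $R$ of the SNPs, estimated here as the Pearson correlation of
genotype dosages in the reference panel. Each null replicate draws
$z \sim \mathcal{N}(0, R)$, squares componentwise (giving correlated
$\chi^2_1$ values), and — crucially — **re-selects the top $k$ values within
that replicate** before summing. The observed statistic selects its $k$ SNPs
by looking at the data, so the null statistic must be allowed to do the same;
freezing the selection at the observed top SNPs' indices produces a null that
is stochastically too small and an anti-conservative test. The package keeps
that fixed-index variant behind `selection = "fixed_index"` purely as a
regression contrast: at $m = 20$, $\rho = 0.9$ the fixed-index variant rejects
a true null about 30% of the time at $\alpha = 0.05$ while the corrected test
sits at 5% (this contrast is asserted in the acceptance suite).

The empirical p-value uses the add-one estimator

$$\hat p = \frac{1 + \#\{T^{sim} \ge T^{obs}\}}{1 + n_{sim}},$$

which never returns zero and counts ties against the observed statistic
(conservative). Simulation counts escalate through stages
(10³, 10⁴, 10⁵, 10⁶ by default): a window leaves the ladder as soon as
$\hat p \ge 10 / n_{sim}$, so cheap windows stop at 10³ replicates while the
smallest p-values get a floor of 10⁻⁶ — ample resolution for window-level
p-values in the 10⁻⁴ range and far below any Benjamini–Hochberg threshold a
scan of a few thousand miRNAs could clear.

Each window draws from its own RNG stream seeded by a hash of
`(master seed, window name)`, so results are bit-identical regardless of the
order in which windows are processed.

## LD estimation and repair

LD is computed on genotype dosages (0/1/2 counts of the alternate allele,
missing calls mean-imputed per SNP) rather than phased haplotypes: it works
with any VCF and matches the standard $r$ measure. SNPs that are monomorphic
or below a panel minor-allele frequency of 0.01 (configurable `maf_min`) are
dropped — their correlations are undefined or wildly unstable — and SNPs
present in the summary statistics but absent from the panel are likewise
excluded from the test *and* from the reported SNP count, so the simulated
null covers exactly the tested SNPs.

Estimated correlation matrices can fail positive semidefiniteness by
numerical noise. `ensure_psd()` clips eigenvalues at 10⁻⁸, reassembles, and
rescales to unit diagonal; an already-PSD matrix is returned untouched. A
repair that would move any entry by more than 0.1 aborts instead — at that
point the panel is too small or inconsistent for the window and a quietly
"repaired" matrix would misrepresent the LD. Eigenvalue clipping was chosen
over nearest-correlation iteration because it is deterministic, cheap, and
accurate enough at the panel sizes involved.

## Multiple testing and enrichment

Per-miRNA empirical p-values are corrected with the Benjamini–Hochberg
step-up procedure, applied separately within each scan (each phenotype's
genome-wide table, and separately for a candidate scan), since each reported
table constitutes its own correction context.

Two one-sided Fisher exact tests summarise SNP-level enrichment: membership
in any miRNA window versus nominal significance (p < 0.05), and membership in
an externally supplied cis-miR-eQTL SNP list versus nominal significance.
Both ask whether significant SNPs are *more* frequent in the category than
expected, hence the one-sided (greater) alternative. A SNP inside several
overlapping windows is counted once — the table's unit is the SNP, and double
counting would break the marginal totals. Degenerate tables (an empty row or
column) return p = 1 with a warning, except an eQTL list with *no* overlap
with the summary statistics, which raises an error because it almost always
indicates an id-space mismatch rather than a biological null.

## The synthetic-data generators

No consortium GWAS, miRBase dump, 1000 Genomes panel or eQTL catalogue is
redistributable here, so the `gen_*` family generates inputs with exactly the
statistical structure the test assumes:

* **Reference panel** — haplotypes in independent LD blocks; within a block,
  allele $j$ copies allele $j-1$ with probability $\rho$ and is otherwise
  redrawn at the block allele frequency. This first-order copying chain gives
  pairwise allele correlation exactly $\rho^{|i-j|}$, positive semidefinite by
  construction and controllable by a single parameter. All SNPs of a block
  share one allele frequency (drawn from `maf_range`, default 0.05–0.5) so the
  autoregressive target holds exactly on the allele scale; frequencies vary
  across blocks. Blocks are regenerated until every empirical MAF lies inside
  the requested range.
* **Summary statistics** — z-scores drawn directly from
  $\mathcal{N}(\mu, R_{block})$ with $R_{block}$ the panel's *empirical*
  dosage correlation and $\mu$ nonzero only at injected causal SNPs. Drawing
  from the MVN the test itself assumes (rather than regressing simulated
  phenotypes) makes type-I-error calibration a sharp check of the test, not of
  an intermediate GWAS model. P-values are two-sided normal tails, clamped at
  10⁻³⁰⁰ so the $\chi^2$ transform stays finite.
* **Annotations, phenotypes, eQTL lists** — hairpin-length transcripts placed
  at panel SNP positions (with a configurable fraction on chromosome X to
  exercise the autosome filter); Alda tables with configurable marginals; and
  SNP-id subsets optionally biased into miRNA windows to create true
  enrichment for power tests.

What the generators deliberately do **not** emulate: coalescent/demographic
realism, imputation uncertainty, genotype missingness patterns, between-block
LD leakage, and the meta-analytic machinery behind real summary statistics.
Passing tests therefore demonstrate that the statistic, its null simulation
and the pipeline plumbing are correct under the stated model — not that the
model captures every feature of consortium data.

## Numerical and design choices

| choice | value | why |
|---|---|---|
| flank (`flank_bp`) | 20,000 bp | symmetric window capturing proximal regulation; strand ignored (no asymmetry to justify) |
| top fraction `f` | 0.1 | highest sensitivity at low false-positive rate among window-level summaries |
| `k` rounding | `max(1, ceiling(f·m))` | small windows stay testable; "top 10%" read as at-least |
| p-value floor | 1/(1+n_sim), n_sim ≤ 10⁶ | add-one Monte-Carlo estimator |
| zero p-values | clamped to 1e-300 | keeps qchisq finite |
| panel MAF filter | 0.01 | near-monomorphic SNPs destabilise $R$ |
| PSD repair | eigenvalue clip at 1e-8, max entry shift 0.1 | deterministic, refuses to paper over bad panels |
| tie-breaks | top SNP by p, then position, then id | reproducible tables |
| Fisher alternative | one-sided greater | the question is an excess, not any deviation |
| BH context | within each scan/table | each reported `p_corr` column is self-contained |
| enrichment α | 0.05 | nominal significance, exposed as `alpha` |

Overlapping miRNA windows are tested independently, never merged: results are
reported per miRNA even for clustered loci, and a SNP may legitimately
contribute to several windows.

## Problem sizes used in the shipped tests

The test-suite simulations were sized to give sharp statistical verdicts at
interactive runtimes: 10,000 null windows (window sizes 5–150 SNPs, block LD
ρ ∈ {0, 0.5, 0.9}, 10³ replicates each) for type-I calibration against the
exact binomial 99% band around 0.05; 1,000 windows at ρ = 0.9 for the
selection-bias contrast; 10⁵-replicate runs against the single-SNP and
$\chi^2_m$ closed forms; 10⁶ package replicates against a 10⁷-draw
`MASS::mvrnorm` oracle for windows of up to three SNPs; and 400 replicates per
noncentrality (4, 5, 6) for the power curve at m = 20, ρ = 0.5, 10⁴
simulations per window (power ≈ 0.75, 0.95, 0.995). The end-to-end synthetic
demonstrations use panels of a few hundred subjects and a few dozen windows.

## Known limitations

* The null model assumes the summary statistics' LD matches the reference
  panel's; ancestry mismatch between GWAS and panel biases the null in either
  direction, and no diagnostic for that mismatch is provided.
* Analytic tail approximations (moment matching of quadratic forms) are not
  implemented; very small p-values pay for 10⁶ simulations.
* Phenotype derivation is provided for completeness of synthetic end-to-end
  runs; the pipeline consumes association p-values from summary statistics
  and never re-runs the per-SNP GWAS.
* Whether "the preprocessed transcript" means hairpin or primary-transcript
  coordinates is resolved pragmatically: printed spans of 60–150 bp indicate
  hairpin records, so the annotation reader defaults to accepting
  hairpin-scale feature types (`miRNA_primary_transcript`, `miRNA`), with the
  filter configurable.
* Trans-eQTL enrichment and lncRNA loci are out of scope.
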