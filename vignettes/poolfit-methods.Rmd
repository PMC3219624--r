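---
title: "Methods: pooled tag-array fitness analysis in poolfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled tag-array fitness analysis in poolfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by **poolfit**,
the assumptions behind it, the parameters a user may want to move, the
numerical decisions taken where the method description left room, and what
the synthetic-data generator does and does not emulate.

## The assay and its analysis model

A pooled fitness experiment grows thousands of tagged transposon mutants
competitively. Each mutant strain carries a TagModule with two unique
20-bp barcodes; the uptag reads the strain out in the upPool, the downtag
in the dnPool, so a strain archived in both pools yields two independent
measurements per condition. Tag abundance is measured on arrays carrying
five replicate probes per tag, before growth ("start") and after growth in
a condition.

The strain-level pipeline is deliberately simple and robust:

1. **Probe averaging.** Tag level = arithmetic mean of the five replicate
   probes' log2 intensities, per hybridization. Missing hybridizations
   yield absent values, never zeros.
2. **Detection.** Background is the median linear-scale level of the
   pool's *unused* tags (tag modules on the array not assigned to any
   strain). A read-out is detected iff its linear start level is ≥ 5×
   background. The threshold is inclusive and compared in log space with a
   1e-9 epsilon so the exact boundary counts as detected.
3. **Low-start filter.** Within each pool, the `floor(0.02 N)` detected
   read-outs with the lowest average start level are dropped: ratios
   against a weak start signal are unstable. Ties are broken by strain_id,
   then tag_id, lexicographically, so the filter is deterministic. The
   filter is applied per pool because each pool has its own start arrays;
   this was a genuinely open choice and is recorded here as the package's
   decision.
4. **Log ratios.** Fitness = condition tag level − start reference. When
   the experiment table's `group` column names a paired start
   hybridization (the assay's primary design: every experiment hybridizes
   its own start sample), that array is the reference; otherwise the
   average of the pool's start arrays is substituted. The paired design
   matters statistically: a start reference shared across many conditions
   injects a common per-strain error into every ratio, correlating a
   gene's Z scores across experiments and inflating the chi-squared
   phenotype test. With paired references the correlation is zero by
   construction.
5. **Normalization.** Per hybridization, the median fitness within every
   (pool × replicon) group is subtracted, then within every 96-well plate
   group. The two passes interact slightly (plates straddle replicons), so
   the pair of passes is iterated, median-polish style, until every group
   median is < 1e-10 (typically 2–4 iterations; capped at 100). The first
   iteration is exactly the stated order; the iteration makes the
   operation idempotent and the "all group medians are zero" invariant
   exact. The megaplasmid is centered separately from the main chromosome
   because replicon copy number and recovery can shift all of its strains
   coherently.

### Gene scores

Gene fitness in a condition is the mean over the gene's measured strain
read-outs in both pools of that condition; if any *good* insertion
(gene_fraction in [0.05, 0.80], boundaries inclusive, measured along the
transcribed strand) is present, only good insertions are used — edge
insertions often leave partial function or truncate the neighboring
transcript. Insertions with no gene are never scored.

The reliability statistic is

\[ T = \frac{\mu\sqrt{n}}{\Psi + s}, \qquad s = 0 \text{ when } n = 1, \]

with Ψ the median sample SD over all (gene, experiment) cells with n ≥ 2.
Two decisions deserve a note:

* **Form of T.** The method description names the ingredients (x, μ, n,
  Ψ) but the display equation itself is not machine-readable in our
  source. The implemented form uses exactly those ingredients, is
  "t-like", shrinks the denominator toward Ψ for small n, and handles
  singletons (T = x/Ψ). Because the downstream Z transform is a full
  empirical-quantile calibration, any monotone variant of T (e.g.
  μ/(Ψ/√n + s/√n)) yields the same Z scores up to the stratification; the
  choice is immaterial to calibrated inference, which is why we did not
  pursue alternatives further.
* **Aggregation of Ψ.** "Median across all genes with more than one
  measurement" does not say how a gene's per-experiment SDs collapse to
  one number. We take the median over all (gene, experiment) cells with
  n ≥ 2 — one Ψ per experiment set, computed from the same matrix being
  scored — which uses every observation and is robust to a handful of
  high-variance genes.

### Empirical null calibration

Control experiments are independent recoveries of the pools with no
treatment; under the no-signal hypothesis a condition experiment's T
should look like a control T. The calibration collects control T values
separately for genes with 1, 2, 3 and ≥4 measurements (the distribution
of T depends on n) and maps a statistic to

\[ Z = \Phi^{-1}\left(\frac{\mathrm{rank} - 0.5}{N}\right) \]

by linear interpolation of the mid-rank ECDF. Outside the observed control
range, Z continues linearly from the boundary value with slope 1/scale,
where scale is the scaled MAD of the stratum's control values: a finite
control sample cannot resolve extreme tails, and the linear continuation
keeps Z finite, monotone and continuous. A stratum with fewer than 50
control values is merged upward into the next stratum (the top stratum
merges downward) with a warning.

The phenotype test is X² = Σ Z² over all *condition* experiments (the
calibration controls are excluded from the combination), with df equal to
the number of non-missing Z per gene, so missingness is handled per gene.
Strong patterns are the union of the top third of X² among all tested
genes (boundary ties included; "among all genes" rather than "among
significant genes" was an open reading — we test all, which is the more
inclusive and simpler rule) and genes whose minimum Z crosses the
Bonferroni threshold Φ⁻¹(α/m).

### Compendium analytics

Correlations are Pearson over pairwise-complete observations, with a
minimum-overlap guard (default 10 experiments) because the fitness matrix
has missing cells; correlation P-values use the t transform with n − 2 df,
with P = 0 at |r| = 1 by convention and undefined below n = 3. Operon QC
and polarity use *adjacent* co-operonic pairs, ordered along the direction
of transcription; polarity events are counted per (pair, experiment) —
the event scale, not the pair scale — and compared with a two-sided
binomial test (sidedness was unstated; two-sided is conservative).

### Subrole prediction

Features are the gene × experiment fitness (and/or expression) matrix,
mean-centered per experiment with missing values then set to zero (an
unmeasured gene sits at the experiment average). Labels lacking a subrole
or containing "unknown"/"other" are removed; when a gene retains several
assignments we keep one label per gene (the first specific record) — a
known divergence risk if multi-label genes matter. Cross-validation is
operon-wise: operons, never genes, are partitioned into 10 folds (random
order, each operon to the currently smallest fold, bounding imbalance by
the largest operon), because co-operonic genes share function and would
otherwise leak label information between training and test. The classifier
is a standard random forest (500 trees, package defaults otherwise; the
original analysis also used an R randomForest with default settings) and
the reported confidence is the fraction of trees voting for the winning
class. Unlabeled genes are predicted by a final forest trained on all
labeled genes. The regulon null shuffles target assignments across pairs
uniformly, re-excluding autoregulatory draws; the original shuffle was not
described, so ours is documented here and seed-controlled.

## The synthetic-data generator

`simulateDataset()` emulates the statistical structure of a two-pool
compendium: a two-replicon genome (~3.5% of genes on a megaplasmid) with
geometric operon sizes; uniform insertion positions within genes;
strain-to-pool assignment with ~43% of strains in both pools; unique tags
per pool with unused tags left for background estimation; 96-well plate
groups; truly-undetectable read-outs (default 2%); start levels N(10, 1)
in log2 with a 3% low tail placed just *above* the detection threshold so
the low-start filter — not detection — removes them; paired start arrays
per experiment plus shared start arrays; per-(plate, array) batch effects;
a per-array megaplasmid shift; and sparse, mostly deleterious true effects
copied to operon mates with probability `operonShare`. The seeding rate is
deflated by the genome's expected operon amplification so the realized
nonzero fraction equals `sparsity`. Optionally each functional subrole
imprints a shared signature on its members so subrole is learnable from
fitness.

Defaults (the package's standing study conditions): 400 genes, 900
insertions, 40 conditions, 14 control conditions (each assayed in both
pools, mirroring real conditions so the null strata have the right
measurement-count structure), probe SD 0.3 log2, plate SD 0.15 log2,
sparsity 0.05, effect scale 3 log2, operon share 0.8, edge attenuation
0.5. The intensity noise model and start-level distribution are not
published for the original assay; these values are stand-ins chosen to
reproduce the assay's qualitative behavior (QC correlations, detection
rates) and are configurable.

**What the generator does not emulate:** sequence-dependent insertion
hot-spots, hybridization chemistry and probe cross-hybridization, spatial
array artifacts, dye effects, megaplasmid copy-number dynamics, and
condition-correlated biological noise. Passing tests therefore demonstrate
correctness of the *analysis* under the stated noise model, not robustness
to every artifact of real arrays.

## Numerical choices and degenerate inputs

* Even-count medians are midpoints (R's default), including in Ψ.
* The 2% filter removes `floor(f N)` strains — exact, not rounded.
* Detection at exactly 5× background is detected (inclusive, with a 1e-9
  log-space epsilon against floating-point representation).
* Good-window boundaries 0.05 and 0.80 are inclusive.
* A constant gene vector has undefined cofitness; the pair is omitted.
* Genes with no Z at all are excluded from the phenotype test; genes with
  no measured strain are absent from the gene matrix.
* Empty normalization groups are skipped; group medians of all-NA groups
  do not poison other entries.
* All stage seeds derive deterministically from one global seed
  (`seed * 1009 + 97k mod 2^31`), so identical configurations produce
  byte-identical output files.

## Problem sizes used by the test and acceptance suites

The suites validate calibration at 1,000 genes × 14 controls
(leave-one-control-out normality), type-I error at 2,000 pure-null genes
× 10 conditions, parameter recovery at 400 genes with −4 log2 effects at
probe SD 0.5, fold integrity over 100 random genomes, and end-to-end
determinism on the 400-gene default pipeline. These sizes were chosen as
the smallest at which the binomial/normality checks have useful power.
Truth-recovery RMSE is computed over genes with at least one good
insertion: genes measured only by edge insertions estimate an attenuated
effect *by design* (edge attenuation is part of the ground truth), so
including them would conflate the estimand with estimator error.

## Known limitations

* The empirical null assumes control recoveries share the noise structure
  of condition experiments; growth-dependent overdispersion in real
  conditions would make |Z| anticonservative there.
* Chi-squared combination assumes Z independent across experiments for a
  gene; residual shared-reference noise (when paired starts are absent and
  few start arrays are averaged) violates this mildly.
* One label per gene in subrole prediction; multi-label genes lose
  information.
* Cofitness P-values are nominal Pearson P-values, not
  compendium-wide-FDR-adjusted; the package deliberately mirrors the
  fixed-threshold analysis style (P < 0.001, Bonferroni) of the assay.
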