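# poolfit

Analysis of pooled, DNA-tagged transposon mutant fitness assays — the
experimental design in which thousands of barcoded ("TagModule") transposon
mutants of a bacterium are grown together competitively, and each strain's
abundance before ("start") and after growth in a condition is read out from
tag microarray intensities. The package turns probe-level tag intensities
into calibrated, genome-wide gene-phenotype maps and supports the
annotation analyses built on top of them. It is aimed at microbial
functional genomicists working with two-pool (uptag/downtag) mutant
collections on multi-replicon genomes.

## The model

**Strain fitness.** For each strain read-out, fitness is the normalized log
ratio

    f = log2(condition intensity) − log2(start intensity)

after (1) averaging the 5 replicate probes per tag, (2) discarding strains
not detected at ≥5× over array background (background = median level of
unused tags) and the lowest 2% of start levels, and (3) median-centering
each hybridization within every (pool × replicon) group and every 96-well
plate group, so that the median mutant is neutral and plate batch effects
are removed.

**Gene fitness.** A gene's fitness in a condition is the mean over its
strains in both pools, restricted to "good" insertions (central 5–80% of
the gene, where polar truncation artifacts are least likely) whenever any
exist.

**Significance.** Reliability is scored with a moderated t-like statistic

    T = μ √n / (Ψ + s)

where μ, s, n are the mean, SD and count of the gene's measurements and
Ψ = median over multi-measurement genes of s — a variance floor that keeps
small-n genes honest. T is mapped to a Z score by an *empirical null*: the
quantiles of T observed in control experiments (independent pool
recoveries), calibrated separately for genes with 1, 2, 3 or ≥4
measurements, so that Z ~ N(0, 1) in the absence of signal. Per gene, the
phenotype test combines Z scores across all conditions with X² = ΣZ²
(chi-squared, df = number of observations); genes with a defect in a single
condition are caught by a Bonferroni rule (Z < Φ⁻¹(α/m), i.e. −3.88 at
α = 0.01 over 195 experiments).

**Annotation analytics.** Cofitness (Pearson correlation of gene fitness
vectors across the compendium), per-experiment QC — r(Same), the
correlation of identical strains across the two pools, and r(Operon), the
correlation of adjacent co-operonic genes — operon polarity counts
(upstream-only vs downstream-only sick, binomial test), auxotroph
concordance in minimal vs rich media, fitness-vs-expression comparisons,
random-forest prediction of functional subroles with operon-wise 10-fold
cross-validation and vote-fraction confidences, and regulon (TF→target)
correlation against shuffled nulls.

Because the original hybridization data is not bundled, the package ships
a first-class synthetic-data generator (`simulateDataset()` and friends)
that emulates the assay's statistical structure — two pools with shared
strains, unused background tags, paired start arrays, plate batch effects,
a megaplasmid replicon, control recoveries, and sparse operon-correlated
true effects — with known ground truth, so every stage is testable end to
end.

## Worked example

```r
library(poolfit)

sim <- simulateDataset(nGenes = 200, nInsertions = 450, nConditions = 15,
                       nControls = 14, seed = 7)
sf <- computeStrainFitness(sim$intensities, sim$experiments,
                           poolStrains(sim$pools), sim$genome)
sf
#> StrainFitness: 648 (strain, pool) read-outs x 58 hybridizations
#>   detected 638, retained after low-start filter 626

gs <- scoreAndCalibrate(sf)
gs
#> GeneScores: 184 genes x 29 experiments (15 condition, 14 control); Psi = 0.155; Z calibrated

tests <- phenotypeTest(gs, alpha = 0.001)
table(tests$significant)
#> FALSE  TRUE
#>   115    69

zstar <- bonferroniZThreshold(0.01, 15)   # -3.21 for 15 conditions
strong <- strongPatternGenes(tests, gs, zstar)
length(strong)
#> [1] 67
```

Reading: of 200 simulated genes, 184 received measurable insertions; 626 of
648 read-outs survive detection and the low-start filter. With 5% of
gene-condition cells carrying true defects, 69 genes show a fitness pattern
significantly different from random at P < 0.001, and 67 qualify as strong
patterns (top third of X² or a single-condition defect beyond the
Bonferroni threshold).

The whole pipeline, including cofitness, QC, polarity, subrole prediction
and regulon analysis, runs as one call and writes TSV outputs stamped with
the config hash and seed:

```r
runPipeline(defaultPipelineConfig(), outDir = "out", seed = 7)
```

or from a shell via the thin driver
`Rscript inst/scripts/poolfit.R run --out out --seed 7`.

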