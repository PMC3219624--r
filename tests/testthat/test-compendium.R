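test_that("cofitness correlations and P-values behave as Pearson statistics", {
  set.seed(1)
  m <- matrix(rnorm(4 * 20), 4, 20,
              dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  m["g2", ] <- -m["g1", ]
  cof <- cofitness(m)
  expect_equal(diag(cof$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cof$r["g1", "g2"], -1)
  expect_equal(cof$r, t(cof$r))

  # constant vector: pair undefined
  m2 <- m; m2["g3", ] <- 2
  expect_true(all(is.na(cofitness(m2)$r["g3", c("g1", "g2", "g4")])))
  # insufficient overlap omitted
  m3 <- m; m3["g4", 1:15] <- NA
  expect_true(is.na(cofitness(m3, minExperiments = 10)$r["g4", "g1"]))
  expect_error(cofitness(m[, 1:5], minExperiments = 10),
               class = "poolfit_validation_error")

  expect_equal(cofitnessPvalue(0, 50), 1)
  expect_equal(cofitnessPvalue(1, 50), 0)
  expect_equal(cofitnessPvalue(0.5, 10), 0.1411, tolerance = 1e-3)
  expect_lt(cofitnessPvalue(0.4, 195), 1e-8)
  expect_true(is.na(cofitnessPvalue(0.5, 2)))
  # P monotone decreasing in |r| at fixed n
  ps <- cofitnessPvalue(seq(0.1, 0.9, 0.1), rep(30, 9))
  expect_true(all(diff(ps) < 0))
})

test_that("polarity counts match a brute-force double loop", {
  fit <- matrix(c(-3, 0, -4, -0.5, 0, 0,
                  0, -3, -1.5, -3, 0, 0,
                  -2.5, -0.2, 1, 0, -9, 0), nrow = 6,
                dimnames = list(sprintf("g%d", 1:6), c("e1", "e2", "e3")))
  pairs <- data.frame(up = c("g1", "g3", "g5"), down = c("g2", "g4", "g6"))
  pc <- polarityCounts(fit, pairs)
  bf <- brutePolarity(fit, pairs)
  expect_equal(pc$up_only, bf$up_only)
  expect_equal(pc$down_only, bf$down_only)

  expect_equal(polarityTest(10, 10), 1)
  expect_lt(polarityTest(3333, 2233), 1e-15)
  expect_equal(polarityTest(0, 0), 1)
})

test_that("polarity on the simulated compendium matches brute force", {
  sim <- standardSim()
  fit <- fitnessMatrix(sim$gs)[, poolfit:::conditionColumns(sim$gs)]
  pairs <- operonAdjacentPairs(sim$genome)
  pc <- polarityCounts(fit, pairs)
  bf <- brutePolarity(fit, pairs)
  expect_identical(pc$up_only, bf$up_only)
  expect_identical(pc$down_only, bf$down_only)
})

test_that("experiment QC recovers same-strain and operon correlations", {
  sim <- standardSim()
  qc <- experimentQC(sim$sf, sim$gs, sim$genome)
  expect_true(all(qc$r_same >= -1 & qc$r_same <= 1, na.rm = TRUE))
  expect_true(all(qc$r_operon >= -1 & qc$r_operon <= 1, na.rm = TRUE))
  expect_equal(nrow(qc), ncol(sim$gs))
})

test_that("strong signal drives r_same up; pure noise leaves r_operon near 0", {
  # dense strong effects: same strain in both pools must agree
  g <- simulateGenome(nGenes = 100, seed = 61)
  lib <- simulateInsertionLibrary(g, 240, seed = 61)
  ps <- assemblePools(lib, nTagModules = 230, poolOverlap = 0.6, seed = 61)
  tr <- simulateTruth(g, nConditions = 6, nControls = 2, sparsity = 0.3,
                      effectScale = 3, operonShare = 1, seed = 61)
  sim <- simulateIntensities(ps, tr, g, probeSd = 0.2, seed = 61)
  sf <- computeStrainFitness(sim$intensities, sim$experiments,
                             poolStrains(ps), g)
  gs <- scoreGenes(sf)
  qc <- experimentQC(sf, gs, g)
  expect_gt(median(qc$r_same[qc$class == "condition"]), 0.9)

  # operon mates with fully shared effects are strongly cofit
  nbr <- operonNeighborCorrelation(fitnessMatrix(gs), g, minExperiments = 5)
  expect_gt(median(nbr, na.rm = TRUE), 0.7)

  # pure-noise dataset: operon correlation centered at zero
  tr0 <- simulateTruth(g, nConditions = 6, nControls = 2, sparsity = 0,
                       seed = 62)
  sim0 <- simulateIntensities(ps, tr0, g, probeSd = 0.2, seed = 62)
  sf0 <- computeStrainFitness(sim0$intensities, sim0$experiments,
                              poolStrains(ps), g)
  qc0 <- experimentQC(sf0, scoreGenes(sf0), g)
  expect_lt(abs(median(qc0$r_operon, na.rm = TRUE)), 0.15)
})

test_that("auxotroph concordance separates minimal from rich media", {
  fit <- matrix(c(-3, -3, -3, 0, 0.2, -0.1), 3, 2,
                dimnames = list(c("a", "b", "c"), c("minimal", "rich")))
  ac <- auxotrophConcordance(fit, c("a", "b", "c"), "minimal", "rich")
  expect_equal(ac$fraction_minimal, 1)
  expect_equal(ac$fraction_rich, 0)
  expect_error(auxotrophConcordance(fit, character(0), "minimal", "rich"),
               class = "poolfit_parameter_error")
  ac2 <- auxotrophConcordance(fit, c("a", "zz"), "minimal", "rich")
  expect_equal(ac2$excluded, "zz")

  # simulated auxotroph block: -4 in minimal only
  g <- simulateGenome(nGenes = 100, seed = 71)
  lib <- simulateInsertionLibrary(g, 240, seed = 71)
  ps <- assemblePools(lib, nTagModules = 230, seed = 71)
  aux <- sample(g$gene_id, 12)
  eff <- matrix(0, 100, 4, dimnames = list(
    g$gene_id, c("minimal", "rich", "ctrl01", "ctrl02")))
  eff[aux, "minimal"] <- -4
  tr <- new("TrueFitness", effects = eff,
            conditionClass = c("condition", "condition", "control", "control"),
            edgeAttenuation = 1, operonShare = 0)
  sim <- simulateIntensities(ps, tr, g, probeSd = 0.3, seed = 71)
  sf <- computeStrainFitness(sim$intensities, sim$experiments,
                             poolStrains(ps), g)
  fitG <- fitnessMatrix(scoreGenes(sf))
  measured <- intersect(aux, rownames(fitG))
  ac3 <- auxotrophConcordance(fitG, measured, "minimal", "rich")
  expect_gte(ac3$fraction_minimal, 0.9)
  expect_lte(ac3$fraction_rich, 0.1)
})

test_that("operon cofitness rises with phenotype significance bins", {
  tests <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      chisq = seq(1, 100), df = 10, pvalue = 0.5,
                      significant = FALSE)
  # flat correlations give flat medians
  nbrFlat <- setNames(rep(0.3, 100), tests$gene_id)
  bins <- operonCofitnessBySignificance(tests, nbrFlat, nBins = 10)
  expect_equal(bins$median_r, rep(0.3, 10))
  expect_error(operonCofitnessBySignificance(tests, nbrFlat, nBins = 200),
               class = "poolfit_parameter_error")

  # informative pattern: correlation grows with chi-squared
  nbrUp <- setNames(0.01 * seq(1, 100) + rnorm(100, 0, 0.05), tests$gene_id)
  binsUp <- operonCofitnessBySignificance(tests, nbrUp, nBins = 10)
  expect_gt(cor(binsUp$bin, binsUp$median_r, method = "spearman"), 0)
})

test_that("relative fitness vs expression comparison obeys the sign rules", {
  set.seed(5)
  fit <- matrix(rnorm(60), 30, 2,
                dimnames = list(sprintf("g%02d", 1:30), c("A", "B")))
  rel <- fit[, "A"] - fit[, "B"]
  ex <- -rel
  names(ex) <- rownames(fit)
  cmp <- fitnessExpressionComparison(fit, "A", "B", ex)
  expect_equal(cmp$correlation, -1)
  expect_equal(unname(cmp$relative_fitness), unname(rel))

  exInd <- setNames(rnorm(30), rownames(fit))
  cmp2 <- fitnessExpressionComparison(fit, "A", "B", exInd)
  expect_lt(abs(cmp2$correlation), 0.5)

  # a gene up-regulated in A and sicker in A lands in up/more-important
  fit3 <- fit; fit3["g01", ] <- c(-3, 0)
  ex3 <- exInd; ex3["g01"] <- 2
  cmp3 <- fitnessExpressionComparison(fit3, "A", "B", ex3)
  expect_true("g01" %in% cmp3$quadrants$up_more_important)
  expect_error(fitnessExpressionComparison(fit[1:3, ], "A", "B", ex[1:3]),
               class = "poolfit_validation_error")
})
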