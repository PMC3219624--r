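test_that("simulated genomes respect their structural invariants", {
  for (s in 1:3) {
    g <- simulateGenome(nGenes = 120, meanOperonSize = 2, seed = s)
    expect_equal(nrow(g), 120)
    expect_false(anyDuplicated(g$gene_id) > 0)
    expect_true(all(g$start <= g$end))
    # operons: contiguous blocks, one replicon, one strand
    for (op in split(g, g$operon_id)) {
      expect_equal(length(unique(op$replicon)), 1)
      expect_equal(length(unique(op$strand)), 1)
      idx <- which(g$operon_id == op$operon_id[1])
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("genome generator honors degenerate and stated parameters", {
  g <- simulateGenome(nGenes = 100, megaplasmidFraction = 0, seed = 1)
  expect_true(all(g$replicon == "chromosome"))

  g1 <- simulateGenome(nGenes = 100, meanOperonSize = 1, seed = 2)
  expect_true(all(table(g1$operon_id) == 1))

  g5 <- simulateGenome(nGenes = 500, meanOperonSize = 2.5, seed = 1)
  expect_lt(abs(mean(table(g5$operon_id)) - 2.5), 0.3)

  expect_error(simulateGenome(nGenes = 5), class = "poolfit_parameter_error")
  expect_error(simulateGenome(100, meanOperonSize = 0.5),
               class = "poolfit_parameter_error")
})

test_that("insertion positions are strand-aware and uniform within genes", {
  g <- simulateGenome(nGenes = 60, seed = 3)
  lib <- simulateInsertionLibrary(g, 5000, intergenicFraction = 0, seed = 2)
  expect_true(all(!is.na(lib$gene_id)))
  expect_true(all(lib$gene_fraction >= 0 & lib$gene_fraction <= 1))

  # boundary: an insertion at the start bp of a + strand gene has fraction 0
  gi <- match(lib$gene_id, g$gene_id)
  atStart <- which(lib$insertion_pos == g$start[gi] & g$strand[gi] == "+")
  if (length(atStart)) expect_equal(lib$gene_fraction[atStart], rep(0, length(atStart)))
  # and fraction 1 for a - strand gene (transcribed-strand orientation)
  atStartMinus <- which(lib$insertion_pos == g$start[gi] & g$strand[gi] == "-")
  if (length(atStartMinus))
    expect_equal(lib$gene_fraction[atStartMinus], rep(1, length(atStartMinus)))

  ks <- suppressWarnings(ks.test(lib$gene_fraction, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pool assembly tracks overlap, plates, capacity and failures", {
  g <- simulateGenome(nGenes = 60, seed = 1)
  lib <- simulateInsertionLibrary(g, 200, seed = 1)
  ps <- assemblePools(lib, nTagModules = 250, detectFailureRate = 0, seed = 1)
  expect_length(ps@undetectableTags, 0)
  st <- poolStrains(ps)
  plates <- table(unique(st[, c("strain_id", "plate")])$plate)
  expect_equal(sort(as.integer(plates), decreasing = TRUE), c(96, 96, 8))

  lib2 <- simulateInsertionLibrary(g, 1000, seed = 2)
  ps2 <- assemblePools(lib2, nTagModules = 1000, poolOverlap = 0.5, seed = 2)
  nBoth <- sum(table(poolStrains(ps2)$strain_id) == 2)
  expect_lt(abs(nBoth - 500), 3 * sqrt(1000 * 0.25) + 1)

  expect_error(assemblePools(lib2, nTagModules = 100, seed = 1),
               class = "poolfit_capacity_error")
})

test_that("true fitness effects are sparse, operon-shared and zero in controls", {
  g <- simulateGenome(nGenes = 400, seed = 5)

  t0 <- simulateTruth(g, nConditions = 5, sparsity = 0, seed = 1)
  expect_true(all(trueEffects(t0) == 0))

  t1 <- simulateTruth(g, nConditions = 10, sparsity = 0.05, operonShare = 1,
                      seed = 2)
  eff <- trueEffects(t1)
  ctrl <- t1@conditionClass == "control"
  expect_true(all(eff[, ctrl] == 0))
  # full sharing: within any operon touched by an effect, all members agree
  for (op in split(g$gene_id, g$operon_id)) {
    sub <- eff[op, !ctrl, drop = FALSE]
    hit <- colSums(sub != 0) > 0
    if (any(hit))
      expect_true(all(apply(sub[, hit, drop = FALSE], 2,
                            function(v) length(unique(v)) == 1)))
  }

  t2 <- simulateTruth(g, nConditions = 40, sparsity = 0.05, seed = 3)
  nz <- sum(trueEffects(t2)[, t2@conditionClass == "condition"] != 0)
  expect_lt(abs(nz - 0.05 * 400 * 40), 0.2 * 0.05 * 400 * 40)
})

test_that("intensity tables have the stated probe structure and recover effects", {
  g <- simulateGenome(nGenes = 40, seed = 7)
  lib <- simulateInsertionLibrary(g, 100, intergenicFraction = 0, seed = 7)
  ps <- assemblePools(lib, nTagModules = 130, detectFailureRate = 0, seed = 7)
  tr <- simulateTruth(g, nConditions = 3, nControls = 2, sparsity = 0, seed = 7)
  sim <- simulateIntensities(ps, tr, g, probeSd = 1e-4, plateSd = 0,
                             repliconShift = 0, nProbes = 5, seed = 7)

  # each array carries its own pool's tags, every one with exactly 5 probes
  cnt <- table(sim$intensities$experiment_id, sim$intensities$tag_id)
  expect_true(all(cnt %in% c(0, 5)))
  upRows <- sim$intensities$experiment_id == "start01_up"
  expect_equal(sum(upRows), 130 * 5)  # full tag capacity of the pool

  # with zero truth and negligible noise, condition/start ratios vanish
  lv <- summarizeTags(sim$intensities)
  ratios <- strainLogRatios(lv, sim$experiments)
  st <- poolStrains(ps)
  expect_lt(max(abs(ratios[st$tag_id, ]), na.rm = TRUE), 0.01)

  # a -3 effect is recovered from the raw emitted rows
  eff <- trueEffects(tr)
  eff["g0001", 1] <- -3
  tr2 <- new("TrueFitness", effects = eff, conditionClass = tr@conditionClass,
             edgeAttenuation = 1, operonShare = 0)
  sim2 <- simulateIntensities(ps, tr2, g, probeSd = 0.2, plateSd = 0,
                              repliconShift = 0, seed = 8)
  lv2 <- summarizeTags(sim2$intensities)
  ratios2 <- strainLogRatios(lv2, sim2$experiments)
  tags <- st$tag_id[!is.na(st$gene_id) & st$gene_id == "g0001"]
  condCol <- grep("^C01_", colnames(ratios2), value = TRUE)
  vals <- na.omit(as.vector(ratios2[tags, condCol]))
  se <- 0.2 / sqrt(5) / sqrt(length(vals)) * sqrt(2)  # probe noise, both arrays
  expect_lt(abs(mean(vals) + 3), 3 * se + 0.05)
})

test_that("expression simulation couples TF-target pairs as requested", {
  g <- simulateGenome(nGenes = 80, seed = 9)
  reg <- simulateRegulons(g, nTFs = 8, targetsPerTF = 3, autoregFraction = 0,
                          seed = 9)
  ex <- simulateExpression(g, reg, nExperiments = 100, coupling = 0.9, seed = 4)
  rs <- mapply(function(a, b) cor(ex[a, ], ex[b, ]), reg$tf, reg$target)
  expect_lt(abs(median(rs) - 0.9), 0.1)

  ex0 <- simulateExpression(g, reg, nExperiments = 100, coupling = 0, seed = 5)
  rs0 <- mapply(function(a, b) cor(ex0[a, ], ex0[b, ]), reg$tf, reg$target)
  expect_lt(abs(median(rs0)), 0.15)

  expect_error(simulateExpression(g, reg, nExperiments = 1),
               class = "poolfit_parameter_error")
  badReg <- data.frame(tf = "nope", target = g$gene_id[1])
  expect_error(simulateExpression(g, badReg, nExperiments = 10),
               class = "poolfit_validation_error")
})

test_that("identical seeds give identical emitted tables", {
  a <- simulateDataset(nGenes = 50, nInsertions = 120, nConditions = 3,
                       nControls = 2, seed = 11)
  b <- simulateDataset(nGenes = 50, nInsertions = 120, nConditions = 3,
                       nControls = 2, seed = 11)
  expect_identical(a$genome, b$genome)
  expect_identical(a$intensities, b$intensities)
  expect_identical(trueEffects(a$truth), trueEffects(b$truth))
})
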