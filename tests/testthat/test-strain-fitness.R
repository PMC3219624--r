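test_that("probe averaging is a plain per-tag arithmetic mean", {
  df <- data.frame(
    experiment_id = rep(c("e1", "e2"), c(5, 1)),
    tag_id = c(rep("t1", 5), "t2"),
    probe_index = c(1:5, 1),
    log2_intensity = c(7, 8, 9, 10, 11, 6.5))
  lv <- summarizeTags(df)
  expect_equal(lv["t1", "e1"], 9.0)
  expect_equal(lv["t2", "e2"], 6.5)
  expect_true(is.na(lv["t1", "e2"]))  # absent, not zero
  df2 <- df; df2$log2_intensity <- c(rep(8, 5), 6.5)
  expect_equal(summarizeTags(df2)["t1", "e1"], 8.0)
})

test_that("detection threshold is 5x background, inclusive", {
  # two strains + three unused tags fixing background at log2 = 5
  exps <- data.frame(experiment_id = "start_up", pool = "up", class = "start",
                     condition_name = NA, group = NA)
  strains <- data.frame(strain_id = c("s1", "s2"), pool = "up",
                        tag_id = c("up_t1", "up_t2"))
  mkLevels <- function(lv1, lv2) {
    m <- matrix(c(lv1, lv2, 5, 5, 5), ncol = 1,
                dimnames = list(c("up_t1", "up_t2", "u1", "u2", "u3"),
                                "start_up"))
    m
  }
  det <- detectStrains(mkLevels(5 + log2(5), 5), exps, strains)
  expect_true(det[["up_t1"]])    # exactly 5x: detected (inclusive)
  expect_false(det[["up_t2"]])   # at background: not detected
  # no unused tags -> background cannot be estimated
  strains3 <- data.frame(strain_id = c("s1", "s2", "u1", "u2", "u3"),
                         pool = "up",
                         tag_id = c("up_t1", "up_t2", "u1", "u2", "u3"))
  expect_error(detectStrains(mkLevels(10, 10), exps, strains3),
               class = "poolfit_validation_error")
})

test_that("low-start filter removes an exact count with deterministic ties", {
  exps <- data.frame(experiment_id = "start_up", pool = "up", class = "start",
                     condition_name = NA, group = NA)
  n <- 100
  tags <- sprintf("up_t%03d", 1:n)
  strains <- data.frame(strain_id = sprintf("s%03d", 1:n), pool = "up",
                        tag_id = tags)
  lv <- matrix(c(stats::rnorm(n, 10, 1), 5), ncol = 1,
               dimnames = list(c(tags, "unused"), "start_up"))
  det <- rep(TRUE, n); names(det) <- tags
  kept <- filterLowStart(lv, exps, strains, det, fraction = 0.02)
  expect_equal(sum(!kept), 2)
  expect_setequal(which(!kept), order(lv[tags, 1])[1:2])

  expect_equal(filterLowStart(lv, exps, strains, det, fraction = 0), det,
               ignore_attr = TRUE)

  lvEq <- lv; lvEq[tags, 1] <- 9
  keptEq <- filterLowStart(lvEq, exps, strains, det, fraction = 0.02)
  expect_equal(strains$strain_id[!keptEq], c("s001", "s002"))

  expect_error(filterLowStart(lv, exps, strains, det, fraction = 1),
               class = "poolfit_parameter_error")
})

test_that("raw fitness is the condition minus (averaged) start level", {
  exps <- data.frame(
    experiment_id = c("start_a", "start_b", "cond1"), pool = "up",
    class = c("start", "start", "condition"),
    condition_name = c(NA, NA, "C1"), group = NA)
  lv <- matrix(c(9.0, 9.2, 8.0), nrow = 1,
               dimnames = list("t1", exps$experiment_id))
  r <- strainLogRatios(lv, exps)
  expect_equal(r["t1", "cond1"], -1.1)

  lv2 <- matrix(c(9, 7), nrow = 1, dimnames = list("t1", c("start_a", "cond1")))
  r2 <- strainLogRatios(lv2, exps[c(1, 3), ])
  expect_equal(r2["t1", "cond1"], -2.0)
  expect_equal(strainLogRatios(
    matrix(c(9, 9), 1, dimnames = list("t1", c("start_a", "cond1"))),
    exps[c(1, 3), ])["t1", "cond1"], 0.0)
})

test_that("normalization zeroes every pool/replicon and plate group median", {
  prov <- data.frame(pool = "up", replicon = "chromosome", plate = "p1")
  m <- matrix(c(-1, 0, 3), ncol = 1)
  out <- normalizeStrainFitness(m, prov[rep(1, 3), ])
  expect_equal(as.vector(out), c(-1, 0, 3))  # median already 0

  mC <- matrix(rep(2.5, 4), ncol = 1)
  expect_equal(as.vector(normalizeStrainFitness(mC, prov[rep(1, 4), ])),
               rep(0, 4))

  # two replicons with medians +1 and -1 are centered independently
  prov2 <- data.frame(pool = "up",
                      replicon = rep(c("chromosome", "megaplasmid"), each = 3),
                      plate = "p1")
  m2 <- matrix(c(0, 1, 2, -2, -1, 0), ncol = 1)
  out2 <- normalizeStrainFitness(m2, prov2)
  expect_equal(median(out2[1:3, 1]), 0)
  expect_equal(median(out2[4:6, 1]), 0)
})

test_that("normalization invariants hold on simulated data and it is idempotent", {
  sim <- standardSim()
  sf <- sim$sf
  fit <- fitnessMatrix(sf)
  rd <- strainInfo(sf)
  for (j in sample(ncol(fit), 6)) {
    v <- fit[, j]
    for (g in split(seq_along(v), interaction(rd$pool, rd$replicon, drop = TRUE))) {
      if (any(!is.na(v[g]))) expect_lt(abs(median(v[g], na.rm = TRUE)), 1e-9)
    }
    for (g in split(seq_along(v), interaction(rd$pool, rd$plate, drop = TRUE))) {
      if (any(!is.na(v[g]))) expect_lt(abs(median(v[g], na.rm = TRUE)), 1e-9)
    }
  }
  again <- normalizeStrainFitness(fit, rd)
  expect_equal(again, fit, tolerance = 1e-8)
})

test_that("plate normalization reduces error against truth when plates drift", {
  g <- simulateGenome(nGenes = 120, seed = 21)
  lib <- simulateInsertionLibrary(g, 280, seed = 21)
  ps <- assemblePools(lib, nTagModules = 300, seed = 21)
  tr <- simulateTruth(g, nConditions = 6, nControls = 2, sparsity = 0.05,
                      seed = 21)
  sim <- simulateIntensities(ps, tr, g, probeSd = 0.2, plateSd = 0.5, seed = 21)
  st <- poolStrains(ps)
  rmse <- function(platePass) {
    sf <- computeStrainFitness(sim$intensities, sim$experiments, st, g,
                               platePass = platePass)
    gs <- scoreGenes(sf)
    fit <- fitnessMatrix(gs)
    eff <- trueEffects(tr)
    condCols <- intersect(colnames(fit), colnames(eff))
    rd <- strainInfo(sf)
    goodGenes <- intersect(rownames(fit),
                           unique(rd$gene_id[rd$good & rd$retained]))
    d <- fit[goodGenes, condCols] - eff[goodGenes, condCols]
    sqrt(mean(d^2, na.rm = TRUE))
  }
  expect_lt(rmse(TRUE), rmse(FALSE))
})

test_that("detection failure rate propagates to the undetected fraction", {
  sim <- standardSim()
  rd <- strainInfo(sim$sf)
  fracUndetected <- mean(!rd$detected)
  # 2% truly undetectable read-outs were simulated
  expect_lt(abs(fracUndetected - 0.02), 0.015)
  # undetected and filtered read-outs carry no fitness values
  expect_true(all(is.na(fitnessMatrix(sim$sf)[!rd$retained, ])))
})
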