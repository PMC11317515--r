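# The synthetic-data generator: determinism, ground-truth bookkeeping,
# missingness structure and planted-effect recovery.

test_that("identical configs give bit-identical experiments", {
  cfg <- simConfig(nProteins = 300, seed = 99)
  a <- simulateProximityExperiment(cfg)
  b <- simulateProximityExperiment(cfg)
  expect_identical(intensities(a), intensities(b))
  expect_identical(as.data.frame(rowData(a)), as.data.frame(rowData(b)))
  s1 <- simulateStressExperiment(cfg)
  s2 <- simulateStressExperiment(cfg)
  expect_identical(intensities(s1), intensities(s2))
  # different seeds diverge
  expect_false(identical(
    intensities(simulateProximityExperiment(simConfig(nProteins = 300,
                                                      seed = 100))),
    intensities(a)))
})

test_that("every protein gets exactly one class and classes are conserved", {
  cfg <- simConfig(nProteins = 1000, seed = 4)
  pe <- simulateProximityExperiment(cfg)
  tc <- truthClass(pe)
  expect_length(tc, 1000)
  expect_identical(sum(table(tc)), 1000L)
  expect_setequal(unique(tc),
                  c("PROXIMITY_TRUE", "MUSCLE_CYTO", "ENDOGENOUS_BACKGROUND",
                    "STRESS_SHIFT_IN", "STRESS_SHIFT_OUT", "NULL"))
  # stress experiment shares identifiers and ground truth
  se <- simulateStressExperiment(cfg)
  expect_identical(rownames(se), rownames(pe))
  expect_identical(truthClass(se), tc)
  # null proteins have zero true effects
  rd <- rowData(pe)
  expect_true(all(rd$trueLog2fcIvsIII[tc == "NULL"] == 0))
  expect_true(all(rowData(se)$trueLog2fcIVvsV[tc == "NULL"] == 0))
})

test_that("zero-effect configs produce group means that differ only by noise", {
  cfg <- simConfig(nProteins = 800, effectProximity = 0, effectMuscle = 0,
                   effectStress = 0, dropoutSlope = 0, seed = 21)
  pe <- simulateProximityExperiment(cfg)
  rd <- rowData(pe)
  expect_true(all(rd$trueLog2fcIvsIII == 0))
  v <- intensities(pe)
  dI <- rowMeans(v[, sampleRoles(pe) == "i"]) -
    rowMeans(v[, sampleRoles(pe) == "iii"])
  expect_lt(abs(mean(dI)), 3 * sd(dI) / sqrt(length(dI)))
  se <- simulateStressExperiment(cfg)
  vs <- intensities(se)
  dS <- rowMeans(vs[, sampleRoles(se) == "iv"]) -
    rowMeans(vs[, sampleRoles(se) == "v"])
  expect_lt(abs(mean(dS)), 3 * sd(dS) / sqrt(length(dS)))
})

test_that("dropoutSlope = 0 disables missingness; otherwise MNAR is monotone", {
  cfg0 <- simConfig(nProteins = 400, dropoutSlope = 0, seed = 8)
  expect_false(any(missingMask(simulateProximityExperiment(cfg0))))

  cfg <- simConfig(nProteins = 3000, dropoutSlope = 1, seed = 8)
  pe <- simulateProximityExperiment(cfg)
  v <- intensities(pe)
  missRate <- rowMeans(is.na(v))
  level <- rowMeans(v, na.rm = TRUE)
  dec <- cut(level, quantile(level, 0:10 / 10, na.rm = TRUE),
             include.lowest = TRUE, labels = FALSE)
  lowRate <- mean(missRate[dec == 1], na.rm = TRUE)
  highRate <- mean(missRate[dec == 10], na.rm = TRUE)
  expect_gt(lowRate, highRate)
})

test_that("planted proximity effects are recovered within 3 SEM", {
  cfg <- simConfig(nProteins = 2000, fracProximityTrue = 0.02,
                   effectProximity = 3, dropoutSlope = 0, seed = 7)
  pe <- simulateProximityExperiment(cfg)
  v <- intensities(pe)
  prox <- truthClass(pe) == "PROXIMITY_TRUE"
  d <- rowMeans(v[prox, sampleRoles(pe) == "i"]) -
    rowMeans(v[prox, sampleRoles(pe) == "iii"])
  expect_lt(abs(mean(d) - 3), 3 * sd(d) / sqrt(length(d)))
  # MUSCLE_CYTO: up in i and ii over iii, no i-vs-ii effect
  mus <- truthClass(pe) == "MUSCLE_CYTO"
  dII <- rowMeans(v[mus, sampleRoles(pe) == "ii"]) -
    rowMeans(v[mus, sampleRoles(pe) == "iii"])
  expect_lt(abs(mean(dII) - cfg@effectMuscle),
            3 * sd(dII) / sqrt(length(dII)))
  # ENDOGENOUS_BACKGROUND: flat across roles
  bg <- truthClass(pe) == "ENDOGENOUS_BACKGROUND"
  dBG <- rowMeans(v[bg, sampleRoles(pe) == "i"]) -
    rowMeans(v[bg, sampleRoles(pe) == "iii"])
  expect_lt(abs(mean(dBG)), 3 * sd(dBG) / sqrt(length(dBG)))
})

test_that("planted stress shifts are recovered within 3 SEM, symmetrically", {
  cfg <- simConfig(nProteins = 2000, fracStressShiftIn = 0.01,
                   fracStressShiftOut = 0.01, effectStress = 2,
                   dropoutSlope = 0, seed = 11)
  se <- simulateStressExperiment(cfg)
  v <- intensities(se)
  ratio <- rowMeans(v[, sampleRoles(se) == "iv"]) -
    rowMeans(v[, sampleRoles(se) == "v"])
  din <- ratio[truthClass(se) == "STRESS_SHIFT_IN"]
  dout <- ratio[truthClass(se) == "STRESS_SHIFT_OUT"]
  expect_lt(abs(mean(din) - 2), 3 * sd(din) / sqrt(length(din)))
  expect_lt(abs(mean(dout) + 2), 3 * sd(dout) / sqrt(length(dout)))
})

test_that("paired-omics truth reproduces the planted quadrant fractions", {
  po <- simulatePairedOmics(nFeatures = 2000,
                            quadrantFracs = c(both_up = 0.25,
                                              both_down = 0.25,
                                              tx_up_prot_down = 0.25,
                                              tx_down_prot_up = 0.25),
                            effectTx = 2, effectProt = 2, seed = 3)
  counts <- table(po$truth$quadrant)
  expect_true(all(counts[c("both_up", "both_down", "tx_up_prot_down",
                           "tx_down_prot_up")] == 500))
  up <- po$truth$quadrant == "both_up"
  expect_true(all(po$truth$trueTxLog2fc[up] > 0))
  expect_true(all(po$truth$trueProtLog2fc[up] > 0))
  disc <- po$truth$quadrant == "tx_up_prot_down"
  expect_true(all(po$truth$trueProtLog2fc[disc] < 0))

  # all-null config: no feature has a nonzero true effect
  po0 <- simulatePairedOmics(nFeatures = 100,
                             quadrantFracs = c(both_up = 0, both_down = 0,
                                               tx_up_prot_down = 0,
                                               tx_down_prot_up = 0),
                             seed = 1)
  expect_true(all(po0$truth$trueTxLog2fc == 0))
  expect_true(all(po0$truth$quadrant == "null"))
})

test_that("simulated gene sets are reproducible and decoys are uniform", {
  universe <- sprintf("U%04d", 1:2000)
  classMembers <- universe[1:40]
  gs <- simulateGeneSets(universe, nSets = 10, planted = classMembers,
                         decoySize = 20, seed = 5)
  expect_identical(names(gs)[1], "planted_set")
  expect_identical(length(gs), 10L)
  jacc <- length(intersect(gs[["planted_set"]], classMembers)) /
    length(union(gs[["planted_set"]], classMembers))
  expect_identical(jacc, 1)

  f1 <- tempfile(); f2 <- tempfile()
  writeGmt(simulateGeneSets(universe, 10, classMembers, seed = 5), f1)
  writeGmt(simulateGeneSets(universe, 10, classMembers, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))

  # expected decoy overlap with a 40-member class: n*K/N = 20*40/2000 = 0.4
  big <- simulateGeneSets(universe, nSets = 1000, decoySize = 20, seed = 6)
  ov <- vapply(geneSets(big), function(s)
    length(intersect(s, classMembers)), numeric(1))
  se3 <- 3 * sqrt(20 * 0.02 * 0.98 * (1980 / 1999) / 1000)
  expect_lt(abs(mean(ov) - 0.4), se3)

  expect_error(simulateGeneSets(universe, 5, decoySize = 3000),
               "exceeds universe")
  expect_error(simulateGeneSets(character(0), 5), "nonempty")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(fracProximityTrue = 0.9, fracMuscleBackground = 0.3),
               "sum to <= 1")
  expect_error(simConfig(nReplicates = 1), "nReplicates")
  expect_error(simConfig(noiseSd = 0), "noiseSd")
  expect_error(simConfig(dropoutSlope = -1), "dropoutSlope")
})
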