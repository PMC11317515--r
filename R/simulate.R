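# Synthetic proximity-proteomics generator. All randomness is drawn in a
# fixed, documented order from one stream per call:
#   1. per-protein baselines (seed), shared by both experiments;
#   2. replicate noise (seed + offset per experiment);
#   3. dropout Bernoulli draws.
# Class labels are a deterministic function of the config (no RNG), so the
# proximity and stress experiments generated from the same config share both
# the identifier space and the ground truth.

.classCounts <- function(cfg) {
  n <- cfg@nProteins
  counts <- c(
    PROXIMITY_TRUE = round(cfg@fracProximityTrue * n),
    MUSCLE_CYTO = round(cfg@fracMuscleBackground * n),
    ENDOGENOUS_BACKGROUND = round(cfg@fracEndogenousBackground * n),
    STRESS_SHIFT_IN = round(cfg@fracStressShiftIn * n),
    STRESS_SHIFT_OUT = round(cfg@fracStressShiftOut * n))
  if (sum(counts) > n)
    stop("class fractions exceed 1 after rounding")
  c(counts, "NULL" = n - sum(counts))
}

.assignClasses <- function(cfg) {
  counts <- .classCounts(cfg)
  rep(names(counts), counts)
}

.proteinIds <- function(n) sprintf("PROT%05d", seq_len(n))

.baselines <- function(cfg) {
  withSeed(cfg@seed, stats::rnorm(cfg@nProteins, cfg@baseMean, cfg@baseSd))
}

.applyDropout <- function(values, cfg) {
  if (cfg@dropoutSlope == 0)
    return(values)
  pMiss <- stats::plogis(cfg@dropoutSlope * (cfg@dropoutMidpoint - values))
  drop <- stats::runif(length(values)) < pMiss
  values[drop] <- NA_real_
  values
}

.buildExperiment <- function(cfg, roles, batch, meanOffset, noiseSeedOffset,
                             truth, trueEffects) {
  n <- cfg@nProteins
  nrep <- cfg@nReplicates
  samples <- as.vector(t(outer(roles, seq_len(nrep),
                               function(r, k) sprintf("%s_%s_rep%d", batch, r, k))))
  roleVec <- rep(roles, each = nrep)
  base <- .baselines(cfg)
  values <- withSeed(cfg@seed + noiseSeedOffset, {
    mu <- base + meanOffset   # n x (roles*nrep) matrix of means
    v <- mu + stats::rnorm(length(mu), 0, cfg@noiseSd)
    .applyDropout(v, cfg)
  })
  dimnames(values) <- list(.proteinIds(n), samples)
  ProximityExperiment(values, role = roleVec, batch = batch,
                      replicate = rep(seq_len(nrep), times = length(roles)),
                      rowData = cbind(DataFrame(truthClass = truth),
                                      DataFrame(trueEffects)))
}

#' Simulate the non-stress three-control proximity experiment
#'
#' Generates log2 LFQ intensities for the ratiometric design: fusion-ligase
#' proximity samples (role i), free-ligase cytosol samples (role ii) and the
#' no-ligase negative control (role iii), `nReplicates` each. Planted
#' structure: `PROXIMITY_TRUE` proteins (and the stress-shift classes, which
#' are bait-proximal proteins by construction) are elevated by
#' `effectProximity` in role i only; `MUSCLE_CYTO` proteins are elevated by
#' `effectMuscle` in roles i and ii (abundant in muscle cytosol, hence
#' labeled by both ligases); `ENDOGENOUS_BACKGROUND` and `NULL` proteins
#' have equal means in all roles. Intensity-dependent dropout follows the
#' logistic rule in [simConfig()]. Ground truth (class and true
#' per-comparison effects) is stored in `rowData()`.
#'
#' @param config a [SimConfig-class].
#' @return A [ProximityExperiment-class] with batch `"nonstress_expt"`.
#' @examples
#' pe <- simulateProximityExperiment(simConfig(nProteins = 100, seed = 3))
#' table(truthClass(pe))
#' @export
simulateProximityExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  truth <- .assignClasses(config)
  nrep <- config@nReplicates
  roles <- c("i", "ii", "iii")
  # per-protein mean offset by role
  offI <- ifelse(truth %in% c("PROXIMITY_TRUE", "STRESS_SHIFT_IN",
                              "STRESS_SHIFT_OUT"), config@effectProximity,
                 ifelse(truth == "MUSCLE_CYTO", config@effectMuscle, 0))
  offII <- ifelse(truth == "MUSCLE_CYTO", config@effectMuscle, 0)
  offIII <- rep(0, config@nProteins)
  meanOffset <- cbind(matrix(offI, config@nProteins, nrep),
                      matrix(offII, config@nProteins, nrep),
                      matrix(offIII, config@nProteins, nrep))
  effects <- list(trueLog2fcIvsIII = offI - offIII,
                  trueLog2fcIvsII = offI - offII,
                  trueLog2fcIIvsIII = offII - offIII)
  .buildExperiment(config, roles, "nonstress_expt", meanOffset,
                   noiseSeedOffset = 1L, truth = truth,
                   trueEffects = effects)
}

#' Simulate the mechanical-stress proximity experiment
#'
#' Generates the stress arm of the combined design: proximity samples from
#' optogenetically contracted worms with ATR (role iv) versus the same
#' illumination without ATR (role v). `STRESS_SHIFT_IN` proteins move toward
#' the bait (+`effectStress` log2 in iv vs v), `STRESS_SHIFT_OUT` move away
#' symmetrically; all other classes are unchanged. `batchShift` is added to
#' every intensity relative to the non-stress experiment. The identifier
#' space, baselines and ground-truth classes are shared with
#' [simulateProximityExperiment()] for the same config, so intersecting the
#' two experiments is meaningful.
#'
#' @param config a [SimConfig-class].
#' @return A [ProximityExperiment-class] with batch `"stress_expt"`.
#' @examples
#' se <- simulateStressExperiment(simConfig(nProteins = 100, seed = 3))
#' table(sampleRoles(se))
#' @export
simulateStressExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  truth <- .assignClasses(config)
  nrep <- config@nReplicates
  offIV <- ifelse(truth == "STRESS_SHIFT_IN", config@effectStress,
                  ifelse(truth == "STRESS_SHIFT_OUT", -config@effectStress, 0))
  meanOffset <- config@batchShift +
    cbind(matrix(offIV, config@nProteins, nrep),
          matrix(0, config@nProteins, nrep))
  .buildExperiment(config, c("iv", "v"), "stress_expt", meanOffset,
                   noiseSeedOffset = 2L, truth = truth,
                   trueEffects = list(trueLog2fcIVvsV = offIV))
}

#' Simulate paired transcript and protein measurements
#'
#' Emulates parallel transcriptome/proteome profiling of stressed versus
#' unstressed animals: for each feature, replicate-level log-scale
#' measurements in two conditions for both assays, with a planted
#' concordance quadrant (`both_up`, `both_down`, `tx_up_prot_down`,
#' `tx_down_prot_up`) or no effect. Differential statistics are computed by
#' the package's own two-sample t-test on the replicates — a documented
#' stand-in for the count-based DE model a real transcriptome would use —
#' and returned as ready-to-pair tables.
#'
#' @param nFeatures number of features.
#' @param quadrantFracs named fractions for `both_up`, `both_down`,
#'   `tx_up_prot_down`, `tx_down_prot_up`; the remainder is null. Must sum
#'   to <= 1.
#' @param effectTx,effectProt absolute log2 effect sizes of planted changes.
#' @param nReplicates replicates per condition and assay.
#' @param noiseSd replicate noise SD (log2).
#' @param baseMean baseline log2 abundance for both assays.
#' @param seed integer seed.
#' @return list with `transcripts` and `proteins` (`DFrame`s: `id`,
#'   `log2fc`, `pvalue`), the replicate matrices (`txMatrix`, `protMatrix`,
#'   conditions in `txCondition`/`protCondition`), and `truth` (`DFrame`:
#'   `id`, `quadrant`, `trueTxLog2fc`, `trueProtLog2fc`).
#' @examples
#' po <- simulatePairedOmics(nFeatures = 200, seed = 3)
#' table(po$truth$quadrant)
#' @export
simulatePairedOmics <- function(nFeatures = 2000,
                                quadrantFracs = c(both_up = 0.05,
                                                  both_down = 0.05,
                                                  tx_up_prot_down = 0.025,
                                                  tx_down_prot_up = 0.025),
                                effectTx = 2, effectProt = 2,
                                nReplicates = 4, noiseSd = 0.5,
                                baseMean = 10, seed = 1L) {
  need <- c("both_up", "both_down", "tx_up_prot_down", "tx_down_prot_up")
  quadrantFracs <- quadrantFracs[need]
  quadrantFracs[is.na(quadrantFracs)] <- 0
  names(quadrantFracs) <- need
  if (any(quadrantFracs < 0) || sum(quadrantFracs) > 1 + 1e-12)
    stop("quadrant fractions must be nonnegative and sum to <= 1")
  counts <- round(quadrantFracs * nFeatures)
  if (sum(counts) > nFeatures)
    stop("quadrant fractions exceed 1 after rounding")
  quadrant <- rep(c(need, "null"), c(counts, nFeatures - sum(counts)))
  sgn <- cbind(tx = c(1, -1, 1, -1, 0)[match(quadrant, c(need, "null"))],
               prot = c(1, -1, -1, 1, 0)[match(quadrant, c(need, "null"))])
  trueTx <- sgn[, "tx"] * effectTx
  trueProt <- sgn[, "prot"] * effectProt
  ids <- sprintf("FEAT%05d", seq_len(nFeatures))

  withSeed(seed, {
    gen <- function(trueFc) {
      ctrl <- matrix(stats::rnorm(nFeatures * nReplicates, baseMean, noiseSd),
                     nFeatures, nReplicates)
      stress <- matrix(stats::rnorm(nFeatures * nReplicates,
                                    baseMean + trueFc, noiseSd),
                       nFeatures, nReplicates)
      cbind(stress, ctrl)
    }
    txMat <- gen(trueTx)
    protMat <- gen(trueProt)
  })
  cond <- rep(c("stress", "control"), each = nReplicates)
  dimnames(txMat) <- list(ids, paste0("tx_", cond, "_", seq_len(nReplicates)))
  dimnames(protMat) <- list(ids, paste0("prot_", cond, "_",
                                        seq_len(nReplicates)))

  deTable <- function(m) {
    tt <- rowTTest(m[, cond == "stress", drop = FALSE],
                   m[, cond == "control", drop = FALSE])
    DataFrame(id = ids, log2fc = tt$estimate, pvalue = tt$p)
  }
  list(transcripts = deTable(txMat), proteins = deTable(protMat),
       txMatrix = txMat, protMatrix = protMat,
       txCondition = cond, protCondition = cond,
       truth = DataFrame(id = ids, quadrant = quadrant,
                         trueTxLog2fc = trueTx, trueProtLog2fc = trueProt))
}

#' Simulate a gene-set collection with one planted set
#'
#' Builds a GMT-writable collection for exercising ORA and GSEA: one
#' designated set (`planted_set`) made of the supplied member identifiers
#' (e.g. the proteins of a ground-truth class), plus decoy sets drawn
#' uniformly at random from the universe.
#'
#' @param universe character vector of all identifiers.
#' @param nSets total number of sets including the planted one.
#' @param planted identifiers the planted set should contain; empty for an
#'   all-decoy collection.
#' @param decoySize members per decoy set.
#' @param seed integer seed.
#' @return A [GeneSetCollection-class].
#' @examples
#' gs <- simulateGeneSets(paste0("P", 1:100), nSets = 5,
#'                        planted = paste0("P", 1:10), seed = 1)
#' names(gs)
#' @export
simulateGeneSets <- function(universe, nSets = 50, planted = character(0),
                             decoySize = 20, seed = 1L) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0)
    stop("universe must be nonempty")
  if (decoySize > length(universe))
    stop("set size exceeds universe size")
  nDecoy <- nSets - (length(planted) > 0)
  sets <- withSeed(seed, {
    decoys <- lapply(seq_len(nDecoy), function(i)
      sort(sample(universe, decoySize)))
    names(decoys) <- sprintf("decoy_%03d", seq_len(nDecoy))
    if (length(planted))
      c(list(planted_set = sort(unique(as.character(planted)))), decoys)
    else decoys
  })
  GeneSetCollection(sets)
}
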