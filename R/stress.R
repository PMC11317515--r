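#' Combine the non-stress and stress experiments
#'
#' Intersects the proteins detected in the two proximity experiments
#' (detection = present in the matrix, i.e. surviving that experiment's
#' valid-value filtering), binds their samples into one matrix with batch
#' labels retained, and reports the overlap summary. The overlap percentage
#' is `100 * nShared / nStress` — shared detections as a fraction of the
#' stress-experiment detections. PCA QC can be run on the combined object
#' after imputation.
#'
#' @param nonstress,stress [ProximityExperiment-class] objects sharing a
#'   protein identifier namespace.
#' @return A [ProximityExperiment-class] restricted to shared proteins;
#'   `metadata()$overlap` holds `nNonstress`, `nStress`, `nShared`,
#'   `overlapPct`.
#' @examples
#' cfg <- simConfig(nProteins = 300, seed = 5)
#' comb <- combineExperiments(simulateProximityExperiment(cfg),
#'                            simulateStressExperiment(cfg))
#' metadata(comb)$overlap
#' @export
combineExperiments <- function(nonstress, stress) {
  shared <- intersect(rownames(nonstress), rownames(stress))
  if (length(shared) == 0)
    stop("empty intersection: the experiments share no proteins")
  values <- cbind(intensities(nonstress)[shared, , drop = FALSE],
                  intensities(stress)[shared, , drop = FALSE])
  imp <- cbind(isImputed(nonstress)[shared, , drop = FALSE],
               isImputed(stress)[shared, , drop = FALSE])
  rd <- rowData(nonstress)[shared, , drop = FALSE]
  out <- ProximityExperiment(
    values,
    role = c(sampleRoles(nonstress), sampleRoles(stress)),
    batch = c(sampleBatches(nonstress), sampleBatches(stress)),
    replicate = c(sampleReplicates(nonstress), sampleReplicates(stress)),
    imputed = imp, rowData = rd)
  metadata(out)$overlap <- list(
    nNonstress = nrow(nonstress), nStress = nrow(stress),
    nShared = length(shared),
    overlapPct = 100 * length(shared) / nrow(stress))
  out
}

#' Gate to muscle-expressed, bait-proximal proteins
#'
#' Selects the proteins eligible for the stress-shift test: those at least
#' `2^foldThresholdLog2`-fold positively enriched (by group-mean difference
#' only, no significance test) in the non-stress arm, in bait proximity
#' (i vs iii) or among muscle cytosol proteins (ii vs iii). `mode = "either"`
#' (default) requires one of the two; `"both"` requires both.
#'
#' @param combined a combined [ProximityExperiment-class] (see
#'   [combineExperiments()]) whose non-stress arm has roles i, ii, iii.
#' @param foldThresholdLog2 gate threshold in log2 units (1 = 2-fold).
#' @param mode `"either"` or `"both"`.
#' @return A `DFrame` with `proteinId`, the two gate fold changes and
#'   `passesGate`; `metadata()$summary$nGated` counts the gated set.
#' @export
gateMuscleExpressed <- function(combined, foldThresholdLog2 = 1,
                                mode = c("either", "both")) {
  mode <- match.arg(mode)
  requireRoles(combined, c("i", "ii", "iii"), batch = "nonstress_expt",
               minPerRole = 1)
  values <- intensities(combined)
  gmean <- function(r) rowMeans(
    values[, roleColumns(combined, r, "nonstress_expt"), drop = FALSE],
    na.rm = TRUE)
  fcI <- gmean("i") - gmean("iii")
  fcII <- gmean("ii") - gmean("iii")
  passes <- if (mode == "either")
    (fcI >= foldThresholdLog2) | (fcII >= foldThresholdLog2)
  else
    (fcI >= foldThresholdLog2) & (fcII >= foldThresholdLog2)
  passes[is.na(passes)] <- FALSE
  out <- DataFrame(proteinId = rownames(values),
                   gateLog2fcIvsIII = fcI, gateLog2fcIIvsIII = fcII,
                   passesGate = unname(passes),
                   row.names = rownames(values))
  metadata(out)$summary <- list(nGated = sum(passes), mode = mode,
                                foldThresholdLog2 = foldThresholdLog2)
  out
}

#' Stress-shift volcano analysis
#'
#' For every gated protein, scores its movement toward or away from the bait
#' under mechanical stress: `log2Ratio = mean(iv) - mean(v)` (stress
#' proximity with versus without ATR), two-tailed Student's t-test p, and a
#' Benjamini-Hochberg q computed over the gated set only. `significant`
#' means `q <= alpha`; significant proteins are split into `"toward"`
#' (positive ratio) and `"away"` (negative ratio), all others `"none"`.
#'
#' @param combined a combined [ProximityExperiment-class] with roles iv and
#'   v (>= 2 samples each).
#' @param gate output of [gateMuscleExpressed()], or a character vector of
#'   gated protein ids.
#' @param alpha FDR threshold.
#' @param equalVar Student (default) or Welch t-test.
#' @return A [StressShiftTable-class] with one row per gated protein and
#'   `metadata()$summary` counts.
#' @export
stressVolcano <- function(combined, gate, alpha = 0.05, equalVar = TRUE) {
  requireRoles(combined, c("iv", "v"))
  if (is(gate, "DFrame"))
    gatedIds <- gate$proteinId[gate$passesGate]
  else
    gatedIds <- as.character(gate)
  if (length(gatedIds) == 0)
    stop("gated set is empty")
  gatedIds <- intersect(gatedIds, rownames(combined))
  values <- intensities(combined)[gatedIds, , drop = FALSE]
  vIV <- values[, roleColumns(combined, "iv"), drop = FALSE]
  vV <- values[, roleColumns(combined, "v"), drop = FALSE]
  tt <- rowTTest(vIV, vV, equalVar = equalVar)
  tested <- is.na(tt$reason)
  q <- rep(NA_real_, length(gatedIds))
  q[tested] <- bhAdjust(tt$p[tested])
  significant <- tested & !is.na(q) & q <= alpha
  direction <- ifelse(significant & tt$estimate > 0, "toward",
               ifelse(significant & tt$estimate < 0, "away", "none"))
  gateCols <- if (is(gate, "DFrame"))
    gate[gatedIds, c("gateLog2fcIvsIII", "gateLog2fcIIvsIII")]
  else
    DataFrame(gateLog2fcIvsIII = NA_real_, gateLog2fcIIvsIII = NA_real_)
  out <- new("StressShiftTable", DataFrame(
    proteinId = gatedIds,
    detectedInNonstress = TRUE, detectedInStress = TRUE,
    gateCols,
    passesGate = TRUE,
    log2RatioIVvsV = tt$estimate, pIVvsV = tt$p, qIVvsV = q,
    significant = unname(significant), direction = unname(direction),
    exclusionReason = tt$reason,
    row.names = gatedIds))
  metadata(out)$summary <- list(nGated = length(gatedIds),
                                nSignificant = sum(significant),
                                nToward = sum(direction == "toward"),
                                nAway = sum(direction == "away"),
                                alpha = alpha)
  out
}
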