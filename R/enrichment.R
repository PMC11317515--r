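#' Ratiometric enrichment against dual controls
#'
#' The non-stress analysis: for every testable protein, compares the
#' fusion-ligase proximity samples (role i) against the negative control
#' (role iii) and against the free-ligase muscle cytosol (role ii) with the
#' two-tailed Student's t-test, adjusts each comparison separately by
#' Benjamini-Hochberg over the tested proteins, and flags
#' `enrichedVsNeg` / `enrichedVsMuscle` when `q <= alpha` with a positive
#' log2 fold change ("enriched in proximity" is directional, while the
#' p-value stays two-sided). `enrichedBoth` is the conjunction — the
#' ratiometric interactor call. Proteins that cannot be tested in either
#' comparison (fewer than two values in a group, or zero variance) carry an
#' `exclusionReason` and no flags.
#'
#' @param pe a preprocessed [ProximityExperiment-class] with roles i, ii,
#'   iii (normalized, and imputed or valid-value-filtered).
#' @param alpha FDR threshold on the BH q-value.
#' @param equalVar use Student's pooled-variance t (default) or Welch.
#' @return An [EnrichmentTable-class] with one row per protein and
#'   `metadata()$summary` holding `nTested`, `nVsNeg`, `nVsMuscle`, `nBoth`.
#' @examples
#' pe <- simulateProximityExperiment(simConfig(nProteins = 300, seed = 2))
#' pe <- imputeDownshift(medianNormalize(pe), seed = 2)
#' et <- ratiometricEnrichment(pe)
#' metadata(et)$summary
#' @export
ratiometricEnrichment <- function(pe, alpha = 0.05, equalVar = TRUE) {
  requireRoles(pe, c("i", "ii", "iii"))
  values <- intensities(pe)
  vI <- values[, roleColumns(pe, "i"), drop = FALSE]
  vII <- values[, roleColumns(pe, "ii"), drop = FALSE]
  vIII <- values[, roleColumns(pe, "iii"), drop = FALSE]
  vsNeg <- rowTTest(vI, vIII, equalVar = equalVar)
  vsMus <- rowTTest(vI, vII, equalVar = equalVar)
  tested <- is.na(vsNeg$reason) & is.na(vsMus$reason)
  if (sum(tested) < 2)
    warning("fewer than 2 tested proteins; q-values equal p-values")
  qNeg <- qMus <- rep(NA_real_, nrow(values))
  qNeg[tested] <- bhAdjust(vsNeg$p[tested])
  qMus[tested] <- bhAdjust(vsMus$p[tested])
  flagNeg <- tested & !is.na(qNeg) & qNeg <= alpha & vsNeg$estimate > 0
  flagMus <- tested & !is.na(qMus) & qMus <= alpha & vsMus$estimate > 0
  reason <- ifelse(tested, NA_character_,
                   ifelse(!is.na(vsNeg$reason), vsNeg$reason, vsMus$reason))
  out <- new("EnrichmentTable", DataFrame(
    proteinId = rownames(values),
    log2fcIvsIII = vsNeg$estimate, pIvsIII = vsNeg$p, qIvsIII = qNeg,
    log2fcIvsII = vsMus$estimate, pIvsII = vsMus$p, qIvsII = qMus,
    enrichedVsNeg = unname(flagNeg), enrichedVsMuscle = unname(flagMus),
    enrichedBoth = unname(flagNeg & flagMus),
    exclusionReason = reason,
    row.names = rownames(values)))
  metadata(out)$summary <- list(nTested = sum(tested),
                                nVsNeg = sum(flagNeg),
                                nVsMuscle = sum(flagMus),
                                nBoth = sum(flagNeg & flagMus),
                                alpha = alpha)
  out
}

#' Export rows for the dual-comparison scatter plot
#'
#' Flattens an [EnrichmentTable-class] into plot-ready rows: x is the
#' proximity-vs-cytosol log2 fold change, y the proximity-vs-negative one,
#' with a category per protein (`enriched_both` dominating the two
#' single-comparison categories, else `not_enriched`). Untested proteins are
#' omitted.
#'
#' @param table an [EnrichmentTable-class].
#' @param annotations optional named character vector mapping protein ids to
#'   an extra annotation column.
#' @return data.frame with `proteinId`, `x`, `y`, `category` and optional
#'   `annotation`.
#' @export
scatterTable <- function(table, annotations = NULL) {
  stopifnot(is(table, "EnrichmentTable"))
  tested <- is.na(table$exclusionReason)
  t2 <- table[tested, ]
  category <- ifelse(t2$enrichedBoth, "enriched_both",
              ifelse(t2$enrichedVsNeg, "enriched_vs_neg",
              ifelse(t2$enrichedVsMuscle, "enriched_vs_muscle",
                     "not_enriched")))
  out <- data.frame(proteinId = t2$proteinId,
                    x = t2$log2fcIvsII, y = t2$log2fcIvsIII,
                    qVsNeg = t2$qIvsIII, qVsMuscle = t2$qIvsII,
                    category = category, stringsAsFactors = FALSE)
  if (!is.null(annotations))
    out$annotation <- unname(annotations[out$proteinId])
  out
}
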