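# Orchestration: the co-IP interactor GSEA workflow and the end-to-end
# synthetic pipeline with a machine-readable summary.

#' GSEA over a ranked co-immunoprecipitation interactor table
#'
#' Ranks an interactor differential table and runs [prerankedGsea()], then
#' filters and orders the results by normalized enrichment score. The
#' default ranking metric is the signed log2 fold change;
#' `rankBy = "signedLogP"` uses `sign(log2fc) * -log10(p)` instead. With
#' `direction = "positive"` (default) rows with `NES >= nesCutoff` are
#' reported; `direction = "both"` applies the cutoff symmetrically to
#' `|NES|`, reporting depletion as well.
#'
#' @param interactors data.frame-like with columns `id`, `log2fc`, `p`
#'   (or `pvalue`).
#' @param sets a [GeneSetCollection-class].
#' @param nesCutoff NES reporting threshold.
#' @param direction `"positive"` or `"both"`.
#' @param rankBy `"log2fc"` or `"signedLogP"`.
#' @param pWeight,nPerm,minSize,seed passed to [prerankedGsea()].
#' @return `DFrame` of GSEA rows passing the cutoff, ranked by decreasing
#'   NES.
#' @export
runCoipGsea <- function(interactors, sets, nesCutoff = 0.5,
                        direction = c("positive", "both"),
                        rankBy = c("log2fc", "signedLogP"),
                        pWeight = 1, nPerm = 1000, minSize = 5,
                        seed = NULL) {
  direction <- match.arg(direction)
  rankBy <- match.arg(rankBy)
  df <- as.data.frame(interactors)
  if (!"p" %in% colnames(df) && "pvalue" %in% colnames(df))
    df$p <- df$pvalue
  if (!all(c("id", "log2fc") %in% colnames(df)))
    stop("interactor table needs columns id and log2fc")
  metric <- switch(rankBy,
    log2fc = df$log2fc,
    signedLogP = sign(df$log2fc) * -log10(pmax(df$p, .Machine$double.xmin)))
  if (!all(is.finite(metric)))
    stop("ranking metric must be finite for every id")
  res <- prerankedGsea(df$id, metric, sets, pWeight = pWeight,
                       nPerm = nPerm, minSize = minSize, seed = seed)
  if (nrow(res) == 0)
    stop("no gene set overlaps the ranked identifiers")
  keep <- if (direction == "positive") !is.na(res$nes) & res$nes >= nesCutoff
          else !is.na(res$nes) & abs(res$nes) >= nesCutoff
  res <- res[keep, ]
  res[order(res$nes, decreasing = TRUE), ]
}

#' Default end-to-end run configuration
#'
#' The parameter set consumed by [runPipeline()]: simulation settings (a
#' [simConfig()] argument list), preprocessing, enrichment, stress-shift,
#' integration and GSEA parameters. Any subset can be overridden by the
#' `config` argument of [runPipeline()]; unknown keys are rejected.
#'
#' @return nested named list of parameters.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    sim = list(nProteins = 1709L, nReplicates = 4L,
               fracProximityTrue = 0.02, fracMuscleBackground = 0.05,
               fracEndogenousBackground = 0.10,
               fracStressShiftIn = 0.005, fracStressShiftOut = 0.005,
               effectProximity = 3, effectMuscle = 2, effectStress = 2,
               baseMean = 26, baseSd = 2, dropoutSlope = 1,
               batchShift = 1, noiseSd = 0.5),
    omics = list(nFeatures = 2000L, effectTx = 2, effectProt = 2,
                 quadrantFracs = c(both_up = 0.05, both_down = 0.05,
                                   tx_up_prot_down = 0.025,
                                   tx_down_prot_up = 0.025)),
    preprocess = list(minValid = 3L, scope = "each_group",
                      imputeWidth = 0.3, imputeDownshift = 1.8),
    enrich = list(alpha = 0.05),
    stress = list(foldThresholdLog2 = 1.0, gateMode = "either",
                  alpha = 0.05),
    integrate = list(filterMode = "transcript_significant", alpha = 0.05),
    gsea = list(nPerm = 200L, nesCutoff = 0.5, nSets = 25L,
                decoySize = 20L))
}

.mergeConfig <- function(defaults, override, path = "") {
  if (is.null(override))
    return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under '", path, "'") else "",
                 paste(unknown, collapse = ", ")))
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .mergeConfig(defaults[[k]], override[[k]], k)
    else
      defaults[[k]] <- override[[k]]
  }
  defaults
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on simulated data: generate the
#' non-stress and stress proximity experiments, preprocess both
#' (median-normalize, valid-value filter, impute), run the ratiometric
#' enrichment, combine the experiments with PCA QC, gate and run the
#' stress-shift volcano, simulate and integrate the paired omics tables,
#' and run per-quadrant ORA plus the planted-set GSEA. Writes per-stage
#' TSVs, a deterministic `summary.json` with the counts at every filter,
#' and a plain-text `run.log` echoing every parameter and the package
#' version. Rerunning with the same config and seed reproduces
#' `summary.json` byte for byte.
#'
#' @param config nested list overriding [defaultRunConfig()], or a path to
#'   a YAML file with the same structure; unknown keys abort.
#' @param outDir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("proxirun")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultRunConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logLine <- function(fmt, ...) {
    writeLines(sprintf(fmt, ...), logCon)
  }
  logLine("ProxiStress pipeline, package version %s",
          as.character(utils::packageVersion("ProxiStress")))
  logLine("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logLine("parameters:")
  flat <- unlist(cfg)
  for (k in names(flat)) logLine("  %s = %s", k, flat[k])

  stage <- "simulate"
  summary <- list(parameters = cfg)
  tryCatch({
    simCfg <- do.call(simConfig, c(cfg$sim, list(seed = cfg$seed)))
    nonstress <- simulateProximityExperiment(simCfg)
    stress <- simulateStressExperiment(simCfg)
    logLine("simulate: %d proteins, %d replicates, seed %d",
            simCfg@nProteins, simCfg@nReplicates, cfg$seed)

    stage <- "preprocess"
    prep <- function(pe, seedOffset) {
      pe <- medianNormalize(pe)
      pe <- filterValidValues(pe, minValid = cfg$preprocess$minValid,
                              scope = cfg$preprocess$scope)
      imputeDownshift(pe, width = cfg$preprocess$imputeWidth,
                      downshift = cfg$preprocess$imputeDownshift,
                      seed = cfg$seed + seedOffset)
    }
    nonstress <- prep(nonstress, 101L)
    stress <- prep(stress, 102L)
    summary$nDetectedNonstress <- nrow(nonstress)
    summary$nDetectedStress <- nrow(stress)

    stage <- "enrich"
    et <- ratiometricEnrichment(nonstress, alpha = cfg$enrich$alpha)
    summary$enrichment <- metadata(et)$summary
    writeTsv(et, file.path(outDir, "enrichment.tsv"))
    writeTsv(scatterTable(et), file.path(outDir, "scatter.tsv"))

    stage <- "combine"
    comb <- combineExperiments(nonstress, stress)
    summary$overlap <- metadata(comb)$overlap
    pca <- pcaScores(comb, 2)
    summary$pcaExplainedVariance <- unname(pca$explainedVariance)
    writeTsv(data.frame(sample = rownames(pca$scores), pca$scores,
                        role = sampleRoles(comb), batch = sampleBatches(comb)),
             file.path(outDir, "pca_scores.tsv"))

    stage <- "stress_shift"
    gate <- gateMuscleExpressed(comb,
                                foldThresholdLog2 = cfg$stress$foldThresholdLog2,
                                mode = cfg$stress$gateMode)
    st <- stressVolcano(comb, gate, alpha = cfg$stress$alpha)
    summary$stressShift <- metadata(st)$summary
    writeTsv(st, file.path(outDir, "stress_shift.tsv"))

    stage <- "integrate"
    po <- do.call(simulatePairedOmics,
                  c(cfg$omics, list(seed = cfg$seed + 103L)))
    fp <- pairFeatures(po$transcripts, po$proteins)
    fp <- assignQuadrants(fp, filterMode = cfg$integrate$filterMode,
                          alpha = cfg$integrate$alpha)
    summary$quadrants <- metadata(fp)$summary
    writeTsv(fp, file.path(outDir, "quadrants.tsv"))

    stage <- "ora"
    bothUp <- fp$id[fp$includedInProportions & fp$quadrant == "both_up"]
    gsOmics <- simulateGeneSets(fp$id, nSets = cfg$gsea$nSets,
                                planted = bothUp,
                                decoySize = cfg$gsea$decoySize,
                                seed = cfg$seed + 104L)
    oraRes <- quadrantOra(fp, "both_up", gsOmics)
    summary$oraBothUp <- list(nReported = nrow(oraRes),
                              topSet = if (nrow(oraRes)) oraRes$setName[1]
                                       else NA_character_)
    writeTsv(oraRes, file.path(outDir, "ora_both_up.tsv"))

    stage <- "gsea"
    interactors <- data.frame(id = et$proteinId, log2fc = et$log2fcIvsIII,
                              p = et$pIvsIII)
    interactors <- interactors[is.finite(interactors$log2fc), ]
    gsProx <- simulateGeneSets(interactors$id, nSets = cfg$gsea$nSets,
                               planted = rownames(nonstress)[
                                 truthClass(nonstress) == "PROXIMITY_TRUE"],
                               decoySize = cfg$gsea$decoySize,
                               seed = cfg$seed + 105L)
    gsea <- runCoipGsea(interactors, gsProx,
                        nesCutoff = cfg$gsea$nesCutoff,
                        nPerm = cfg$gsea$nPerm, seed = cfg$seed + 106L)
    summary$gsea <- list(nReported = nrow(gsea),
                         topSet = if (nrow(gsea)) gsea$setName[1]
                                  else NA_character_)
    writeTsv(gsea, file.path(outDir, "gsea.tsv"))
  }, error = function(e) {
    logLine("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logLine("completed; summary written to summary.json")
  invisible(summary)
}
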