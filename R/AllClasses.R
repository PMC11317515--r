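#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<- assays<- colData<- rowData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.ROLES <- c("i", "ii", "iii", "iv", "v")
.BATCHES <- c("nonstress_expt", "stress_expt")
.TRUTH_CLASSES <- c("PROXIMITY_TRUE", "MUSCLE_CYTO", "ENDOGENOUS_BACKGROUND",
                    "STRESS_SHIFT_IN", "STRESS_SHIFT_OUT", "NULL")

#' Container for log2 LFQ intensities with sample roles
#'
#' `ProximityExperiment` extends [SummarizedExperiment] and holds the
#' protein-by-sample log2 label-free quantification matrix of a
#' proximity-labeling experiment. Missing values are encoded as `NA` in the
#' `"log2intensity"` assay; cells filled in by [imputeDownshift()] are marked
#' in the logical `"imputed"` assay so observed and imputed values stay
#' distinguishable. `colData()` carries the sample design: `role` (one of
#' `"i"` fusion-ligase proximity, `"ii"` free-ligase cytosol, `"iii"`
#' no-ligase negative control, `"iv"` stress proximity with ATR, `"v"`
#' stress proximity without ATR), `batch`
#' (`"nonstress_expt"`/`"stress_expt"`), and `replicate`.
#'
#' Simulated objects additionally carry ground truth in `rowData()`: a
#' `truthClass` column and the true log2 effects per comparison.
#'
#' @seealso [ProximityExperiment()] for construction,
#'   [simulateProximityExperiment()] and [simulateStressExperiment()] for
#'   synthetic data.
#' @export
setClass("ProximityExperiment", contains = "SummarizedExperiment")

setValidity("ProximityExperiment", function(object) {
  msg <- character(0)
  if (!"log2intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'log2intensity' is required")
  cd <- colData(object)
  for (col in c("role", "batch", "replicate"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("role" %in% colnames(cd) && !all(cd$role %in% .ROLES))
    msg <- c(msg, sprintf("roles must be in {%s}", paste(.ROLES, collapse = ", ")))
  if ("batch" %in% colnames(cd) && !all(cd$batch %in% .BATCHES))
    msg <- c(msg, sprintf("batches must be in {%s}", paste(.BATCHES, collapse = ", ")))
  if ("imputed" %in% assayNames(object)) {
    imp <- assay(object, "imputed")
    if (!is.logical(imp))
      msg <- c(msg, "assay 'imputed' must be logical")
    else if (any(imp & is.na(assay(object, "log2intensity"))))
      msg <- c(msg, "imputed cells must hold finite log2 intensities")
  }
  if (is.null(rownames(object)) && nrow(object) > 0)
    msg <- c(msg, "protein identifiers (rownames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ProximityExperiment
#'
#' @param values numeric matrix of log2 intensities, proteins x samples, with
#'   `NA` for missing cells; rownames are protein identifiers.
#' @param role character vector, one of `"i".."v"` per sample.
#' @param batch experiment batch per sample (`"nonstress_expt"` or
#'   `"stress_expt"`); recycled if length 1.
#' @param replicate integer replicate index per sample; defaults to a running
#'   index within each (role, batch) group.
#' @param geneNames optional per-protein gene symbols.
#' @param imputed optional logical matrix marking imputed cells.
#' @param rowData optional extra per-protein annotation (e.g. ground truth).
#' @return A [ProximityExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 26), 2, 6,
#'             dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
#' pe <- ProximityExperiment(m, role = rep(c("i", "ii", "iii"), each = 2))
#' sampleRoles(pe)
#' @export
ProximityExperiment <- function(values, role, batch = "nonstress_expt",
                                replicate = NULL, geneNames = NULL,
                                imputed = NULL, rowData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  role <- as.character(role)
  if (length(role) != ncol(values))
    stop("'role' must give one role per sample")
  batch <- rep_len(as.character(batch), ncol(values))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(role), paste(role, batch),
                            FUN = seq_along)
  }
  cd <- DataFrame(role = role, batch = batch,
                  replicate = as.integer(replicate),
                  row.names = colnames(values))
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(geneNames)) rd$geneName <- as.character(geneNames)
  if (!is.null(rowData)) rd <- cbind(rd, DataFrame(rowData))
  alist <- SimpleList(log2intensity = values)
  if (!is.null(imputed)) {
    imputed <- as.matrix(imputed)
    dimnames(imputed) <- dimnames(values)
    alist$imputed <- imputed
  }
  new("ProximityExperiment",
      SummarizedExperiment(assays = alist, colData = cd, rowData = rd))
}

#' @describeIn ProximityExperiment-class compact display with role/batch counts
#' @param object a `ProximityExperiment`
#' @export
setMethod("show", "ProximityExperiment", function(object) {
  callNextMethod()
  tab <- table(role = colData(object)$role, batch = colData(object)$batch)
  cat("sample design:",
      paste(sprintf("%s/%s:%d", rownames(tab)[row(tab)],
                    colnames(tab)[col(tab)], tab)[tab > 0],
            collapse = " "), "\n")
  nmiss <- sum(is.na(assay(object, "log2intensity")))
  cat(sprintf("missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / max(1, length(assay(object, "log2intensity")))))
})

#' Named collection of gene sets with GMT semantics
#'
#' A light container for flat gene-set collections: a named list of unique
#' member identifiers plus one description per set, round-trippable through
#' the GMT format via [readGmt()] / [writeGmt()].
#'
#' @slot sets named list of character vectors (set members).
#' @slot descriptions character vector, one description per set.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  if (is.null(names(object@sets)) && length(object@sets) > 0)
    msg <- c(msg, "sets must be named")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be unique")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "one description per set is required")
  if (!all(vapply(object@sets, is.character, logical(1))) &&
      length(object@sets) > 0)
    msg <- c(msg, "set members must be character vectors")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (default `"na"` each, as GMT
#'   writers conventionally emit).
#' @return A [GeneSetCollection-class].
#' @examples
#' gs <- GeneSetCollection(list(setA = c("P1", "P2"), setB = c("P3")))
#' lengths(geneSets(gs))
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection-class number of sets
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class display a summary
#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d sets", length(object)))
  if (length(object)) {
    sz <- lengths(object@sets)
    cat(sprintf(" (sizes %d..%d)", min(sz), max(sz)))
  }
  cat("\n")
  if (length(object))
    cat("  ", paste(utils::head(names(object), 5), collapse = ", "),
        if (length(object) > 5) ", ..." else "", "\n", sep = "")
})

#' Simulation configuration for the synthetic proximity-proteomics generator
#'
#' Collects the generative parameters shared by
#' [simulateProximityExperiment()] and [simulateStressExperiment()]:
#' protein and replicate counts, the fractions of proteins in each
#' ground-truth class, log2 effect sizes, the log2-intensity location/scale,
#' the logistic missing-not-at-random dropout curve, the additive batch
#' offset between the two experiments, replicate noise, and the seed.
#'
#' Fractions must be nonnegative and sum to at most 1; the remainder is the
#' null class. `dropoutSlope = 0` disables missingness entirely.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig", representation(
  nProteins = "integer", nReplicates = "integer",
  fracProximityTrue = "numeric", fracMuscleBackground = "numeric",
  fracEndogenousBackground = "numeric", fracStressShiftIn = "numeric",
  fracStressShiftOut = "numeric",
  effectProximity = "numeric", effectMuscle = "numeric",
  effectStress = "numeric",
  baseMean = "numeric", baseSd = "numeric",
  dropoutMidpoint = "numeric", dropoutSlope = "numeric",
  batchShift = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  fr <- c(object@fracProximityTrue, object@fracMuscleBackground,
          object@fracEndogenousBackground, object@fracStressShiftIn,
          object@fracStressShiftOut)
  if (any(fr < 0)) msg <- c(msg, "class fractions must be nonnegative")
  if (sum(fr) > 1 + 1e-12) msg <- c(msg, "class fractions must sum to <= 1")
  if (object@nProteins < 1) msg <- c(msg, "nProteins must be >= 1")
  if (object@nReplicates < 2) msg <- c(msg, "nReplicates must be >= 2")
  if (object@baseSd <= 0 || object@noiseSd <= 0)
    msg <- c(msg, "baseSd and noiseSd must be > 0")
  if (object@dropoutSlope < 0)
    msg <- c(msg, "dropoutSlope must be >= 0 (0 disables dropout)")
  if (any(c(object@effectProximity, object@effectMuscle,
            object@effectStress) < 0))
    msg <- c(msg, "effect sizes are log2 units and must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults emulate the scale of a whole-worm miniTurbo pulldown: 1709
#' protein groups, four biological replicates per condition, log2 LFQ
#' intensities centered at 26 with SD 2, replicate noise SD 0.5, logistic
#' dropout centered two baseline SDs below the mean, a +1 log2 batch offset
#' for the stress experiment, a 3 log2 proximity effect and 2 log2 muscle and
#' stress effects.
#'
#' @param nProteins number of simulated protein groups.
#' @param nReplicates replicates per condition (>= 2).
#' @param fracProximityTrue,fracMuscleBackground,fracEndogenousBackground,fracStressShiftIn,fracStressShiftOut
#'   class fractions; the remainder of proteins is null.
#' @param effectProximity,effectMuscle,effectStress log2 effect sizes (> 0
#'   for planted signal).
#' @param baseMean,baseSd per-protein baseline log2 intensity location/scale.
#' @param dropoutMidpoint,dropoutSlope logistic missingness:
#'   `P(missing) = plogis(dropoutSlope * (dropoutMidpoint - intensity))`;
#'   slope 0 disables dropout.
#' @param batchShift additive log2 offset applied to the stress experiment.
#' @param noiseSd replicate noise SD (log2).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nProteins = 200, seed = 1)
#' cfg
#' @export
simConfig <- function(nProteins = 1709L, nReplicates = 4L,
                      fracProximityTrue = 0.02,
                      fracMuscleBackground = 0.05,
                      fracEndogenousBackground = 0.10,
                      fracStressShiftIn = 0.005,
                      fracStressShiftOut = 0.005,
                      effectProximity = 3, effectMuscle = 2,
                      effectStress = 2,
                      baseMean = 26, baseSd = 2,
                      dropoutMidpoint = baseMean - 2 * baseSd,
                      dropoutSlope = 1,
                      batchShift = 1, noiseSd = 0.5, seed = 1L) {
  new("SimConfig",
      nProteins = as.integer(nProteins),
      nReplicates = as.integer(nReplicates),
      fracProximityTrue = fracProximityTrue,
      fracMuscleBackground = fracMuscleBackground,
      fracEndogenousBackground = fracEndogenousBackground,
      fracStressShiftIn = fracStressShiftIn,
      fracStressShiftOut = fracStressShiftOut,
      effectProximity = effectProximity, effectMuscle = effectMuscle,
      effectStress = effectStress,
      baseMean = baseMean, baseSd = baseSd,
      dropoutMidpoint = dropoutMidpoint, dropoutSlope = dropoutSlope,
      batchShift = batchShift, noiseSd = noiseSd, seed = as.integer(seed))
}

#' @describeIn SimConfig-class display the configuration
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  for (sl in slotNames(object))
    cat(sprintf("  %-24s %s\n", sl, paste(slot(object, sl), collapse = " ")))
})

# Result tables: DFrame subclasses so they print, subset and export like any
# Bioconductor results object, with run summaries kept in metadata().

#' Per-protein ratiometric enrichment results
#'
#' A `DFrame` subclass returned by [ratiometricEnrichment()]: per protein,
#' the log2 fold change, p and Benjamini-Hochberg q of the bait-vs-negative
#' (i vs iii) and bait-vs-cytosol (i vs ii) comparisons, the three enrichment
#' flags, and an `exclusionReason` for untested proteins. `metadata()$summary`
#' holds the headline counts.
#' @export
setClass("EnrichmentTable", contains = "DFrame")

#' Per-protein stress-shift results
#'
#' A `DFrame` subclass returned by [stressVolcano()]: gate fold changes, the
#' stress/non-stress (iv vs v) log2 ratio, p and q, the significance flag and
#' the toward/away direction, for every protein passing the muscle-expression
#' gate. `metadata()$summary` holds counts.
#' @export
setClass("StressShiftTable", contains = "DFrame")

#' Paired transcript/protein features with quadrant labels
#'
#' A `DFrame` subclass returned by [pairFeatures()] and annotated by
#' [assignQuadrants()]: per feature, both assays' log2 fold change and p,
#' the concordance quadrant, and the inclusion filter it passed.
#' `metadata()` carries the unmatched-feature summary and, after
#' [assignQuadrants()], the quadrant proportions.
#' @export
setClass("FeaturePairTable", contains = "DFrame")

.showResultTable <- function(object, what) {
  cat(sprintf("%s with %d rows\n", what, nrow(object)))
  s <- metadata(object)$summary
  if (!is.null(s)) {
    flat <- unlist(s)
    cat("summary:", paste(names(flat), flat, sep = "=", collapse = " "), "\n")
  }
  show(S4Vectors::DataFrame(utils::head(as.data.frame(object), 6)))
  invisible(NULL)
}

#' @describeIn EnrichmentTable-class display with summary counts
#' @param object the table
#' @export
setMethod("show", "EnrichmentTable", function(object)
  .showResultTable(object, "EnrichmentTable"))

#' @describeIn StressShiftTable-class display with summary counts
#' @param object the table
#' @export
setMethod("show", "StressShiftTable", function(object)
  .showResultTable(object, "StressShiftTable"))

#' @describeIn FeaturePairTable-class display with summary counts
#' @param object the table
#' @export
setMethod("show", "FeaturePairTable", function(object)
  .showResultTable(object, "FeaturePairTable"))
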