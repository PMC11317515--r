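#' Intensity values, missingness and imputation masks
#'
#' `intensities()` returns the proteins x samples log2 intensity matrix
#' (`NA` where missing). `missingMask()` is `TRUE` where no value was ever
#' observed or imputed; `isImputed()` is `TRUE` where a value was filled in
#' by [imputeDownshift()].
#'
#' @param x a [ProximityExperiment-class]
#' @param ... unused
#' @return a numeric or logical proteins x samples matrix
#' @name intensities
#' @aliases missingMask isImputed
#' @examples
#' pe <- simulateProximityExperiment(simConfig(nProteins = 50, seed = 1))
#' dim(intensities(pe))
#' mean(missingMask(pe))
NULL

#' @rdname intensities
#' @export
setMethod("intensities", "ProximityExperiment", function(x, ...)
  assay(x, "log2intensity"))

#' @rdname intensities
#' @export
setMethod("missingMask", "ProximityExperiment", function(x)
  is.na(assay(x, "log2intensity")) | isImputed(x))

#' @rdname intensities
#' @export
setMethod("isImputed", "ProximityExperiment", function(x) {
  if ("imputed" %in% assayNames(x)) assay(x, "imputed")
  else matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
})

#' Sample design accessors
#'
#' Role (`"i".."v"`), experiment batch and replicate index per sample,
#' as stored in `colData()`.
#'
#' @param x a [ProximityExperiment-class]
#' @return a character or integer vector, one entry per sample
#' @name sampleRoles
#' @aliases sampleBatches sampleReplicates
NULL

#' @rdname sampleRoles
#' @export
setMethod("sampleRoles", "ProximityExperiment", function(x)
  colData(x)$role)

#' @rdname sampleRoles
#' @export
setMethod("sampleBatches", "ProximityExperiment", function(x)
  colData(x)$batch)

#' @rdname sampleRoles
#' @export
setMethod("sampleReplicates", "ProximityExperiment", function(x)
  colData(x)$replicate)

#' Ground-truth class of simulated proteins
#'
#' For simulated experiments, the planted class of every protein
#' (`PROXIMITY_TRUE`, `MUSCLE_CYTO`, `ENDOGENOUS_BACKGROUND`,
#' `STRESS_SHIFT_IN`, `STRESS_SHIFT_OUT` or `NULL`); `NULL`-class proteins
#' have all true effects equal to zero. Returns `NULL` for objects without
#' ground truth (e.g. read from a file).
#'
#' @param x a [ProximityExperiment-class]
#' @return character vector or `NULL`
#' @name truthClass
#' @export
setMethod("truthClass", "ProximityExperiment", function(x)
  rowData(x)$truthClass)

#' Gene set membership and descriptions
#'
#' @param x a [GeneSetCollection-class]
#' @return `geneSets()`: the named list of member vectors;
#'   `setDescriptions()`: the per-set description strings.
#' @name geneSets
#' @aliases setDescriptions
NULL

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname geneSets
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @describeIn GeneSetCollection-class extract one set's members by name or index
#' @param i set name or index
#' @param j,... unused
#' @export
setMethod("[[", "GeneSetCollection", function(x, i, j, ...) x@sets[[i]])

#' @describeIn GeneSetCollection-class subset to a collection of fewer sets
#' @param drop unused
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = TRUE)
  GeneSetCollection(x@sets[i], x@descriptions[i]))
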