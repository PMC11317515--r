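#' @rdname intensities
#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname intensities
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname sampleRoles
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname sampleRoles
#' @export
setGeneric("sampleBatches", function(x) standardGeneric("sampleBatches"))

#' @rdname sampleRoles
#' @export
setGeneric("sampleReplicates", function(x) standardGeneric("sampleReplicates"))

#' @rdname truthClass
#' @export
setGeneric("truthClass", function(x) standardGeneric("truthClass"))

#' @rdname geneSets
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname medianNormalize
#' @export
setGeneric("medianNormalize", function(x, ...) standardGeneric("medianNormalize"))

#' @rdname filterValidValues
#' @export
setGeneric("filterValidValues",
           function(x, ...) standardGeneric("filterValidValues"))

#' @rdname imputeDownshift
#' @export
setGeneric("imputeDownshift", function(x, ...) standardGeneric("imputeDownshift"))

#' @rdname pcaScores
#' @export
setGeneric("pcaScores", function(x, ...) standardGeneric("pcaScores"))
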