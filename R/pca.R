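#' Principal component scores for sample-level QC
#'
#' PCA of the samples of a complete (imputed) intensity matrix, used to check
#' that negative-control samples separate from ligase samples and to expose
#' batch structure when two experiments are combined. Each protein is
#' mean-centered across samples and the sample-space scores are taken from
#' the singular value decomposition; explained-variance fractions are
#' `d_i^2 / sum(d^2)`, non-increasing and summing to at most 1 over the
#' returned components.
#'
#' @param x numeric proteins x samples matrix without missing values, or a
#'   [ProximityExperiment-class] after imputation.
#' @param nComponents number of components to return.
#' @param ... passed through from the generic.
#' @return list with `scores` (samples x `nComponents`) and
#'   `explainedVariance` (length `nComponents`).
#' @examples
#' m <- matrix(rnorm(200, 25), 20, 10,
#'             dimnames = list(paste0("P", 1:20), paste0("s", 1:10)))
#' pcaScores(m, 2)$explainedVariance
#' @name pcaScores
NULL

#' @rdname pcaScores
#' @export
setMethod("pcaScores", "matrix", function(x, nComponents = 2, ...) {
  if (anyNA(x))
    stop("missing values present; impute before PCA")
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds matrix rank bound")
  centered <- x - rowMeans(x)
  sv <- svd(t(centered), nu = nComponents, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(nComponents))
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, explainedVariance = ev[seq_len(nComponents)])
})

#' @rdname pcaScores
#' @export
setMethod("pcaScores", "ProximityExperiment",
          function(x, nComponents = 2, ...)
            pcaScores(intensities(x), nComponents = nComponents))
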