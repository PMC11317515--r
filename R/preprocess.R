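# Perseus-style preprocessing: median normalization, valid-value filtering,
# downshifted-normal imputation.

#' Median-center each sample
#'
#' Subtracts the per-sample median of observed (non-missing) log2
#' intensities, so every sample's observed median becomes 0. Missingness is
#' unchanged; the operation is idempotent.
#'
#' @param x a [ProximityExperiment-class] or numeric matrix with `NA`s.
#' @param ... passed through from the generic.
#' @return same class as `x`.
#' @name medianNormalize
NULL

#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "matrix", function(x, ...) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (anyNA(med))
    stop("a sample has no observed values")
  sweep(x, 2, med)
})

#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "ProximityExperiment", function(x, ...) {
  assay(x, "log2intensity") <- medianNormalize(intensities(x))
  x
})

#' Filter proteins by valid-value counts
#'
#' Keeps proteins quantified often enough to test: at least `minValid`
#' observed values in at least one (role, batch) group (`scope =
#' "any_group"`) or in every group (`scope = "each_group"`). Dropped
#' proteins are recorded in `metadata()$exclusions` with a reason
#' (`"no_valid_values"` when nothing was observed at all, otherwise
#' `"insufficient_valid_values"`).
#'
#' @param x a [ProximityExperiment-class].
#' @param minValid minimum observed values per group; the default 3
#'   guarantees a defined t statistic even if one replicate of four is
#'   missing.
#' @param scope `"any_group"` or `"each_group"`.
#' @param ... passed through from the generic.
#' @return the filtered [ProximityExperiment-class].
#' @name filterValidValues
NULL

#' @rdname filterValidValues
#' @export
setMethod("filterValidValues", "ProximityExperiment",
          function(x, minValid = 3, scope = c("any_group", "each_group"),
                   ...) {
  scope <- match.arg(scope)
  groups <- paste(sampleRoles(x), sampleBatches(x), sep = ".")
  ug <- unique(groups)
  if (any(table(groups) < minValid))
    stop("minValid exceeds the size of a design group")
  obs <- !is.na(intensities(x))
  counts <- vapply(ug, function(g)
    rowSums(obs[, groups == g, drop = FALSE]), numeric(nrow(x)))
  counts <- matrix(counts, nrow = nrow(x))
  keep <- if (scope == "any_group")
    rowSums(counts >= minValid) >= 1
  else
    rowSums(counts >= minValid) == length(ug)
  reason <- unname(ifelse(rowSums(obs) == 0, "no_valid_values",
                          "insufficient_valid_values"))
  excl <- DataFrame(proteinId = rownames(x)[!keep],
                    reason = reason[!keep])
  out <- x[keep, ]
  metadata(out)$exclusions <- excl
  out
})

#' Impute missing values from a downshifted normal distribution
#'
#' Standard left-censored (missing-not-at-random) imputation for label-free
#' proteomics: missing cells are drawn from
#' `Normal(m - downshift * s, (width * s)^2)` where `m` and `s` are the mean
#' and SD of the observed values of the imputation unit — each sample when
#' `perSample = TRUE` (default), otherwise the whole matrix. The canonical
#' parameters `width = 0.3`, `downshift = 1.8` place imputed values in the
#' low-abundance tail. Observed cells are never altered; imputed cells are
#' flagged in the `"imputed"` assay so [missingMask()] still identifies them
#' as never-observed.
#'
#' @param x a [ProximityExperiment-class].
#' @param width SD of the imputation distribution, as a fraction of the
#'   observed SD.
#' @param downshift center offset below the observed mean, in observed SDs.
#' @param perSample impute per sample (default) or from the global moments.
#' @param seed integer seed; identical seed gives identical imputations.
#' @param ... passed through from the generic.
#' @return the completed [ProximityExperiment-class].
#' @name imputeDownshift
NULL

#' @rdname imputeDownshift
#' @export
setMethod("imputeDownshift", "ProximityExperiment",
          function(x, width = 0.3, downshift = 1.8, perSample = TRUE,
                   seed = NULL, ...) {
  values <- intensities(x)
  miss <- is.na(values)
  if (!any(miss)) {
    if (!"imputed" %in% assayNames(x))
      assays(x, withDimnames = FALSE)$imputed <-
        matrix(FALSE, nrow(x), ncol(x))
    return(x)
  }
  filled <- values
  withSeed(seed, {
    if (perSample) {
      for (j in seq_len(ncol(values))) {
        obs <- values[, j][!miss[, j]]
        nmiss <- sum(miss[, j])
        if (nmiss == 0) next
        if (length(obs) < 2)
          stop(sprintf("sample '%s' has < 2 observed values",
                       colnames(values)[j]))
        filled[miss[, j], j] <- stats::rnorm(nmiss,
                                             mean(obs) - downshift * stats::sd(obs),
                                             width * stats::sd(obs))
      }
    } else {
      obs <- values[!miss]
      if (length(obs) < 2)
        stop("matrix has < 2 observed values")
      filled[miss] <- stats::rnorm(sum(miss),
                                   mean(obs) - downshift * stats::sd(obs),
                                   width * stats::sd(obs))
    }
  })
  assay(x, "log2intensity") <- filled
  imp <- isImputed(x) | miss
  assays(x, withDimnames = FALSE)$imputed <- imp
  x
})
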