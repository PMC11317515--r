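#' Over-representation analysis by the hypergeometric test
#'
#' Tests each gene set for over-representation in a selection, conditioned on
#' a detection universe: every set is intersected with the universe before
#' testing, `k = |selection ∩ set|`, and the one-sided p-value is
#' [hypergeometricTail()]`(k, K, n, N)` with `K` the in-universe set size,
#' `n` the selection size and `N` the universe size. Benjamini-Hochberg q's
#' are computed across the tested sets. Sets with no member in the universe
#' are skipped and listed in `metadata()$skipped`.
#'
#' @param selection character vector of selected identifiers (must be a
#'   subset of `universe`).
#' @param universe character vector: all identifiers eligible for selection
#'   (typically everything detected in the experiment).
#' @param sets a [GeneSetCollection-class] or named list of member vectors.
#' @return A `DFrame` with one row per tested set: `setName`, `k`, `K`, `n`,
#'   `N`, `enrichmentRatio = (k/n)/(K/N)`, `pHyper`, `qBh`, ordered as in
#'   `sets`.
#' @examples
#' sets <- GeneSetCollection(list(A = paste0("P", 1:10),
#'                                B = paste0("P", 11:30)))
#' ora(paste0("P", 1:8), paste0("P", 1:200), sets)
#' @export
ora <- function(selection, universe, sets) {
  universe <- unique(as.character(universe))
  selection <- unique(as.character(selection))
  if (length(universe) == 0)
    stop("empty universe")
  if (length(selection) == 0)
    stop("empty selection")
  if (!all(selection %in% universe))
    stop("selection must be a subset of the universe")
  if (is(sets, "GeneSetCollection"))
    sets <- geneSets(sets)
  members <- lapply(sets, intersect, universe)
  K <- lengths(members)
  keep <- K > 0
  skipped <- names(sets)[!keep]
  n <- length(selection)
  N <- length(universe)
  k <- vapply(members[keep], function(m) length(intersect(selection, m)),
              integer(1))
  p <- mapply(function(k1, K1) hypergeometricTail(k1, K1, n, N),
              k, K[keep])
  out <- DataFrame(setName = names(sets)[keep], k = as.integer(k),
                   K = as.integer(K[keep]), n = n, N = N,
                   enrichmentRatio = (k / n) / (K[keep] / N),
                   pHyper = as.numeric(p), qBh = bhAdjust(as.numeric(p)))
  metadata(out)$skipped <- skipped
  if (length(skipped))
    message(sprintf("%d set(s) skipped (no overlap with universe): %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  out
}
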