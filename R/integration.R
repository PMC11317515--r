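#' Pair transcript and protein differential tables
#'
#' Inner-joins per-feature differential statistics from the transcriptomic
#' and proteomic assays on feature identifier, optionally through an
#' explicit protein-to-transcript identifier map. Ambiguous (many-to-many)
#' mappings are rejected with a listing; unmatched features are counted in
#' `metadata()$unmatched`.
#'
#' @param transcripts,proteins data.frame-like tables with columns `id`,
#'   `log2fc`, `pvalue` and unique ids.
#' @param idMap optional data.frame with columns `proteinId`,
#'   `transcriptId`; by default identifiers are matched as-is.
#' @return A [FeaturePairTable-class] keyed by the transcript identifier,
#'   with `quadrant` and `includedBy` initialized to `"unassigned"` /
#'   `"neither"` until [assignQuadrants()] is run.
#' @export
pairFeatures <- function(transcripts, proteins, idMap = NULL) {
  tx <- as.data.frame(transcripts)
  pr <- as.data.frame(proteins)
  need <- c("id", "log2fc", "pvalue")
  if (!all(need %in% colnames(tx)) || !all(need %in% colnames(pr)))
    stop("tables need columns id, log2fc, pvalue")
  if (anyDuplicated(tx$id) || anyDuplicated(pr$id))
    stop("feature ids must be unique within each table")
  if (!is.null(idMap)) {
    idMap <- as.data.frame(idMap)
    dupP <- idMap$proteinId[duplicated(idMap$proteinId)]
    dupT <- idMap$transcriptId[duplicated(idMap$transcriptId)]
    if (length(dupP) || length(dupT))
      stop(sprintf("ambiguous many-to-many id mappings: %s",
                   paste(utils::head(unique(c(dupP, dupT)), 10),
                         collapse = ", ")))
    pr$id <- idMap$transcriptId[match(pr$id, idMap$proteinId)]
    pr <- pr[!is.na(pr$id), , drop = FALSE]
  }
  shared <- intersect(tx$id, pr$id)
  it <- match(shared, tx$id)
  ip <- match(shared, pr$id)
  out <- new("FeaturePairTable", DataFrame(
    id = shared,
    transcriptLog2fc = tx$log2fc[it], transcriptP = tx$pvalue[it],
    proteinLog2fc = pr$log2fc[ip], proteinP = pr$pvalue[ip],
    quadrant = "unassigned", includedBy = "neither",
    row.names = shared))
  metadata(out)$unmatched <- list(
    nTranscriptOnly = sum(!tx$id %in% shared),
    nProteinOnly = sum(!pr$id %in% shared),
    transcriptOnly = utils::head(setdiff(tx$id, shared), 20),
    proteinOnly = utils::head(setdiff(pr$id, shared), 20))
  out
}

#' Assign concordance quadrants and compute change-type proportions
#'
#' Classifies each paired feature by the signs of its transcript and
#' protein log2 fold changes into `both_up`, `both_down`,
#' `tx_up_prot_down` or `tx_down_prot_up`; a fold change of exactly zero in
#' either assay leaves the feature `unassigned`. Features are included in
#' the proportion summary when the filtering assay's p-value passes `alpha`
#' — the transcript p under `filterMode = "transcript_significant"`, the
#' protein p under `"protein_significant"` — regardless of the other
#' assay's significance. `includedBy` records which of the two filters each
#' feature would pass. Proportions are `100 * quadrant count / included
#' assigned count` and sum to 100.
#'
#' @param pairs a [FeaturePairTable-class] from [pairFeatures()].
#' @param filterMode `"transcript_significant"` or `"protein_significant"`.
#' @param alpha inclusion p-value threshold, in (0, 1].
#' @return the annotated [FeaturePairTable-class];
#'   `metadata()$summary$proportions` holds the four percentages.
#' @examples
#' po <- simulatePairedOmics(nFeatures = 400, seed = 7)
#' fp <- pairFeatures(po$transcripts, po$proteins)
#' fp <- assignQuadrants(fp, "transcript_significant")
#' metadata(fp)$summary$proportions
#' @export
assignQuadrants <- function(pairs,
                            filterMode = c("transcript_significant",
                                           "protein_significant"),
                            alpha = 0.05) {
  stopifnot(is(pairs, "FeaturePairTable"))
  filterMode <- match.arg(filterMode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  sTx <- !is.na(pairs$transcriptP) & pairs$transcriptP <= alpha
  sPr <- !is.na(pairs$proteinP) & pairs$proteinP <= alpha
  pairs$includedBy <- ifelse(sTx & sPr, "both",
                      ifelse(sTx, "transcript_filter",
                      ifelse(sPr, "protein_filter", "neither")))
  st <- sign(pairs$transcriptLog2fc)
  sp <- sign(pairs$proteinLog2fc)
  quadrant <- rep("unassigned", nrow(pairs))
  quadrant[st > 0 & sp > 0] <- "both_up"
  quadrant[st < 0 & sp < 0] <- "both_down"
  quadrant[st > 0 & sp < 0] <- "tx_up_prot_down"
  quadrant[st < 0 & sp > 0] <- "tx_down_prot_up"
  pairs$quadrant <- quadrant
  included <- if (filterMode == "transcript_significant") sTx else sPr
  assigned <- included & quadrant != "unassigned"
  qlev <- c("both_up", "both_down", "tx_up_prot_down", "tx_down_prot_up")
  counts <- vapply(qlev, function(q) sum(quadrant[assigned] == q),
                   integer(1))
  props <- if (sum(assigned) > 0) 100 * counts / sum(assigned)
           else stats::setNames(rep(NA_real_, 4), qlev)
  pairs$includedInProportions <- unname(assigned)
  metadata(pairs)$summary <- list(filterMode = filterMode, alpha = alpha,
                                  nIncluded = sum(included),
                                  nAssigned = sum(assigned),
                                  proportions = props)
  pairs
}

#' Per-quadrant over-representation analysis
#'
#' Runs [ora()] on the included features of one concordance quadrant
#' against a gene-set collection, then applies the filter-mode-dependent
#' q-value cutoff to the reported rows: 0.01 for transcript-filtered runs,
#' 0.05 for protein-filtered runs (overridable via `qCutoff`).
#'
#' @param pairs a [FeaturePairTable-class] after [assignQuadrants()].
#' @param quadrant one of `"both_up"`, `"both_down"`, `"tx_up_prot_down"`,
#'   `"tx_down_prot_up"`.
#' @param sets a [GeneSetCollection-class].
#' @param universeMode `"all_pairs"` (default: every paired feature) or
#'   `"filtered_pairs"` (features passing the inclusion filter).
#' @param qCutoff q-value filter on the reported rows; default depends on
#'   the filter mode recorded in `pairs`.
#' @return `DFrame` of [ora()] rows with `qBh <= qCutoff`, sorted by q;
#'   empty (with a warning) when the quadrant has no included features.
#' @export
quadrantOra <- function(pairs, quadrant, sets,
                        universeMode = c("all_pairs", "filtered_pairs"),
                        qCutoff = NULL) {
  stopifnot(is(pairs, "FeaturePairTable"))
  universeMode <- match.arg(universeMode)
  s <- metadata(pairs)$summary
  if (is.null(s))
    stop("run assignQuadrants() before quadrantOra()")
  if (is.null(qCutoff))
    qCutoff <- if (s$filterMode == "transcript_significant") 0.01 else 0.05
  selection <- pairs$id[pairs$includedInProportions &
                          pairs$quadrant == quadrant]
  if (length(selection) == 0) {
    warning(sprintf("quadrant '%s' has no included features", quadrant))
    return(DataFrame(setName = character(0), k = integer(0), K = integer(0),
                     n = integer(0), N = integer(0),
                     enrichmentRatio = numeric(0), pHyper = numeric(0),
                     qBh = numeric(0)))
  }
  universe <- if (universeMode == "all_pairs") pairs$id
              else pairs$id[pairs$includedBy != "neither" &
                              (if (s$filterMode == "transcript_significant")
                                 pairs$includedBy %in% c("transcript_filter", "both")
                               else pairs$includedBy %in% c("protein_filter", "both"))]
  res <- ora(selection, universe, sets)
  res <- res[!is.na(res$qBh) & res$qBh <= qCutoff, ]
  res[order(res$qBh, res$pHyper), ]
}
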