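# Preranked GSEA: weighted Kolmogorov-Smirnov-style running sum with a
# gene-permutation null, signed normalization and permutation FDR.

# Enrichment score for hit positions `pos` (sorted, 1-based ranks in a list
# of length N) with weights `w = |metric|^p` at those positions. Hits step
# the running sum up by w/sum(w); each miss steps it down by 1/(N - NH).
# The ES is the extreme deviation from zero; the peak index is kept for the
# leading edge.
.esScore <- function(pos, w, N) {
  NH <- length(pos)
  NR <- sum(w)
  if (NR == 0) { # all-zero metric inside the set: fall back to equal steps
    w <- rep(1, NH)
    NR <- NH
  }
  penalty <- 1 / (N - NH)
  idx <- seq_len(NH)
  afterHit <- cumsum(w) / NR - (pos - idx) * penalty
  beforeHit <- c(0, cumsum(w)[-NH] / NR) - (pos - 1 - (idx - 1)) * penalty
  top <- max(afterHit)
  bottom <- min(beforeHit)
  # ties between the positive and negative extreme (|top| == |bottom| up to
  # rounding) resolve to the positive deviation
  if (top + bottom >= -1e-12)
    list(es = top, peak = which.max(afterHit), positive = TRUE)
  else
    list(es = bottom, peak = which.min(beforeHit), positive = FALSE)
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted running-sum enrichment score of each gene set over
#' a ranked list: walking the list from top to bottom, members increment the
#' sum by `|metric|^pWeight / sum over members`, non-members decrement by
#' `1/(N - N_H)`; the enrichment score (ES) is the maximum signed deviation.
#' The null distribution is built by gene permutation (random member sets of
#' the same size drawn from the ranked list), the only null available in
#' preranked mode. The normalized enrichment score divides each ES by the
#' mean magnitude of same-sign null scores; permutation p-values and FDR
#' q-values are computed within the signed null and observed pools, as in
#' the reference GSEA procedure. Ties in the metric are broken by stable
#' input order.
#'
#' @param ids character vector of unique identifiers.
#' @param metric finite ranking metric, same length as `ids`; the list is
#'   ranked by decreasing metric.
#' @param sets a [GeneSetCollection-class] or named list.
#' @param pWeight weighting exponent on `|metric|` (1 = classic weighted
#'   GSEA; 0 = unweighted Kolmogorov-Smirnov statistic).
#' @param nPerm number of permutations per set (>= 10).
#' @param minSize sets with fewer in-list members are skipped.
#' @param seed integer seed for the permutation null; the caller's RNG
#'   stream is left untouched.
#' @return A `DFrame` with one row per tested set: `setName`, `size`, `es`,
#'   `nes`, `pPerm`, `fdrQ`, `leadingEdge` (comma-joined identifiers).
#'   Skipped sets are listed in `metadata()$skipped`.
#' @examples
#' ids <- paste0("G", 1:50)
#' metric <- seq(5, -5, length.out = 50)
#' sets <- list(top = ids[1:8], spread = ids[seq(2, 50, by = 6)])
#' prerankedGsea(ids, metric, sets, nPerm = 100, seed = 1)
#' @export
prerankedGsea <- function(ids, metric, sets, pWeight = 1, nPerm = 1000,
                          minSize = 5, seed = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("ranked identifiers must be unique")
  if (!all(is.finite(metric)))
    stop("ranking metric must be finite")
  if (length(metric) != length(ids))
    stop("ids and metric lengths differ")
  if (nPerm < 10)
    stop("nPerm must be >= 10")
  if (is(sets, "GeneSetCollection"))
    sets <- geneSets(sets)

  ord <- order(metric, decreasing = TRUE)   # stable: ties keep input order
  rankedIds <- ids[ord]
  rankedMetric <- metric[ord]
  N <- length(rankedIds)
  w0 <- abs(rankedMetric)^pWeight
  rankOf <- seq_len(N)
  names(rankOf) <- rankedIds

  inList <- lapply(sets, function(s) unname(rankOf[intersect(s, rankedIds)]))
  sizes <- lengths(inList)
  if (any(sizes >= N))
    stop("a set covers the whole ranked list; ES is undefined")
  keep <- sizes >= minSize
  skipped <- names(sets)[!keep]

  withSeed(seed, {
    obs <- lapply(inList[keep], function(pos) {
      pos <- sort(pos)
      .esScore(pos, w0[pos], N)
    })
    es <- vapply(obs, `[[`, numeric(1), "es")

    # one shared null pool per distinct set size
    nullBySize <- lapply(unique(sizes[keep]), function(s) {
      vapply(seq_len(nPerm), function(b) {
        pos <- sort(sample.int(N, s))
        .esScore(pos, w0[pos], N)$es
      }, numeric(1))
    })
    names(nullBySize) <- as.character(unique(sizes[keep]))
  })

  nes <- pPerm <- rep(NA_real_, sum(keep))
  nullNesPool <- numeric(0)
  for (i in seq_along(es)) {
    nul <- nullBySize[[as.character(sizes[keep][i])]]
    pos <- nul[nul >= 0]
    neg <- nul[nul < 0]
    if (es[i] >= 0 && length(pos)) {
      nes[i] <- es[i] / mean(pos)
      pPerm[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
    } else if (es[i] < 0 && length(neg)) {
      nes[i] <- es[i] / mean(abs(neg))
      pPerm[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
    }
    if (length(pos)) nullNesPool <- c(nullNesPool, pos / mean(pos))
    if (length(neg)) nullNesPool <- c(nullNesPool, neg / mean(abs(neg)))
  }

  # permutation FDR over the signed NES pools
  fdrQ <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[i]))
      return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(nullNesPool[nullNesPool >= 0] >= nes[i])
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      num <- mean(nullNesPool[nullNesPool < 0] <= nes[i])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    if (!is.finite(den) || den == 0)
      return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  leading <- vapply(seq_along(obs), function(i) {
    pos <- sort(inList[keep][[i]])
    pk <- obs[[i]]$peak
    le <- if (obs[[i]]$positive) pos[seq_len(pk)] else pos[pk:length(pos)]
    paste(rankedIds[le], collapse = ",")
  }, character(1))

  out <- DataFrame(setName = names(sets)[keep],
                   size = as.integer(sizes[keep]),
                   es = unname(es), nes = nes, pPerm = pPerm, fdrQ = fdrQ,
                   leadingEdge = leading)
  metadata(out)$skipped <- skipped
  metadata(out)$params <- list(pWeight = pWeight, nPerm = nPerm,
                               minSize = minSize, seed = seed)
  out
}
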