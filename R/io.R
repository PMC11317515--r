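# Readers/writers for the plain-text formats of the field: MaxQuant-style
# proteinGroups TSV, GMT gene sets, RNK ranked lists.

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification table with
#' `LFQ intensity <sample>` columns, removes decoy and artifact rows
#' (`Reverse`, `Potential contaminant`, `Only identified by site` marked
#' `"+"`), log2-transforms the intensities and encodes absences as missing:
#' MaxQuant writes `0` for an LFQ intensity it could not compute, so zeros,
#' empty cells and `NaN` all become `NA`.
#'
#' @param path TSV file.
#' @param design optional data.frame with columns `sample`, `role`, `batch`,
#'   `replicate` describing the LFQ columns; without it all samples get role
#'   `"i"` in the non-stress batch.
#' @param lfqPrefix column-name prefix identifying quantification columns.
#' @param filterDecoys drop flagged rows (default `TRUE`).
#' @return A [ProximityExperiment-class] on the log2 scale.
#' @seealso [writeProteinGroups()]
#' @export
readProteinGroups <- function(path, design = NULL,
                              lfqPrefix = "LFQ intensity ",
                              filterDecoys = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  lfqCols <- grep(lfqPrefix, colnames(df), fixed = TRUE, value = TRUE)
  if (length(lfqCols) == 0)
    stop(sprintf("no columns matching LFQ prefix '%s'", lfqPrefix))
  if (!"Protein IDs" %in% colnames(df))
    stop("column 'Protein IDs' is required")
  if (filterDecoys) {
    for (flag in c("Reverse", "Potential contaminant",
                   "Only identified by site")) {
      if (flag %in% colnames(df))
        df <- df[is.na(df[[flag]]) | df[[flag]] != "+", , drop = FALSE]
    }
  }
  ids <- df[["Protein IDs"]]
  if (anyDuplicated(ids))
    stop("duplicate protein ids in input")
  raw <- as.matrix(df[, lfqCols, drop = FALSE])
  suppressWarnings(storage.mode(raw) <- "double")
  raw[!is.finite(raw) | raw <= 0] <- NA_real_
  values <- log2(raw)
  sampleNames <- sub(lfqPrefix, "", lfqCols, fixed = TRUE)
  dimnames(values) <- list(ids, sampleNames)
  if (is.null(design)) {
    role <- rep("i", ncol(values))
    batch <- "nonstress_expt"
    replicate <- seq_len(ncol(values))
  } else {
    design <- as.data.frame(design)
    m <- match(sampleNames, design$sample)
    if (anyNA(m))
      stop(sprintf("design is missing samples: %s",
                   paste(sampleNames[is.na(m)], collapse = ", ")))
    role <- design$role[m]
    batch <- design$batch[m]
    replicate <- design$replicate[m]
  }
  geneNames <- if ("Gene names" %in% colnames(df)) df[["Gene names"]] else NULL
  ProximityExperiment(values, role = role, batch = batch,
                      replicate = replicate, geneNames = geneNames)
}

#' Write a ProximityExperiment as a proteinGroups-style TSV
#'
#' Inverse of [readProteinGroups()]: intensities are written on the raw
#' scale (`2^log2`) with 10 significant digits, missing cells as `0`, and
#' empty decoy-flag columns so the file round-trips through the reader.
#'
#' @param pe a [ProximityExperiment-class].
#' @param path output file.
#' @param lfqPrefix prefix for the quantification columns.
#' @return `path`, invisibly.
#' @export
writeProteinGroups <- function(pe, path, lfqPrefix = "LFQ intensity ") {
  values <- intensities(pe)
  raw <- 2^values
  raw[is.na(raw)] <- 0
  out <- data.frame(`Protein IDs` = rownames(pe), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[["Gene names"]] <- rowData(pe)$geneName %||% rownames(pe)
  out[["Reverse"]] <- ""
  out[["Potential contaminant"]] <- ""
  out[["Only identified by site"]] <- ""
  for (j in seq_len(ncol(values)))
    out[[paste0(lfqPrefix, colnames(values)[j])]] <-
      sprintf("%.10g", raw[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return `readGmt()`: a [GeneSetCollection-class]; `writeGmt()`: `path`,
#'   invisibly.
#' @name gmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop(sprintf("malformed GMT line(s): %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  GeneSetCollection(sets, vapply(parts, `[[`, character(1), 2))
}

#' @rdname gmt
#' @param x a [GeneSetCollection-class].
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(seq_along(x@sets), function(i)
    paste(c(names(x@sets)[i], x@descriptions[i], x@sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write RNK ranked-list files
#'
#' RNK is the two-column tab-separated preranked-GSEA input: identifier and
#' ranking score.
#'
#' @param path file path.
#' @return `readRnk()`: data.frame with `id` and `score`; `writeRnk()`:
#'   `path`, invisibly.
#' @name rnk
#' @export
readRnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "score"))
  df$score <- as.numeric(df$score)
  df
}

#' @rdname rnk
#' @param ids identifiers.
#' @param scores ranking metric, same length.
#' @export
writeRnk <- function(ids, scores, path) {
  stopifnot(length(ids) == length(scores))
  writeLines(paste(ids, sprintf("%.10g", scores), sep = "\t"), path)
  invisible(path)
}

#' Read a sample-design table
#'
#' TSV with header columns `sample`, `role`, `batch`, `replicate`, mapping
#' each quantification column to its role in the five-role design.
#'
#' @param path file path.
#' @return data.frame usable as the `design` argument of
#'   [readProteinGroups()].
#' @export
readSampleDesign <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "role", "batch", "replicate")
  if (!all(need %in% colnames(df)))
    stop(sprintf("design needs columns: %s", paste(need, collapse = ", ")))
  df
}
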