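# File I/O: FASTA in, TSV/BED out, and the run configuration record.

#' Read protein sequences from FASTA
#'
#' Wraps `Biostrings::readAAStringSet`. Record ids are the header up to the
#' first whitespace. Under the strict policy (default) any record with a
#' non-standard residue aborts with the record id; with
#' `skipNonstandard = TRUE` such records are dropped with a message, which
#' is the batch-run behavior.
#'
#' @param path FASTA file
#' @param skipNonstandard drop offending records instead of stopping
#' @return named character vector of validated sequences
#' @export
readFasta <- function(path, skipNonstandard = FALSE) {
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) stop("no sequences in ", path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    warning("duplicate record ids in ", path)
  ok <- !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), seqs)
  if (all(ok)) return(seqs)
  if (!skipNonstandard)
    stop("non-standard residues in record(s): ",
         paste(names(seqs)[!ok], collapse = ", "),
         " (use skipNonstandard = TRUE to drop them)")
  message("dropping ", sum(!ok), " record(s) with non-standard residues")
  seqs[ok]
}

#' Write sequences to FASTA
#' @param sequences named character vector
#' @param path output path
#' @export
writeFasta <- function(sequences, path) {
  aas <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Per-residue classification table
#'
#' One row per residue: id, position, residue, label, and the phi / alpha /
#' v_model / classifier distance of the window centered there (terminal
#' residues inherit the first/last window, as in the labeling rule).
#'
#' @param object a [ParSeClassification-class]
#' @param id sequence identifier for the first column
#' @return data.frame
#' @export
residueTable <- function(object, id = "seq") {
  n <- nchar(object@sequence)
  w <- object@constants$windowLength
  half <- (w - 1L) %/% 2L
  widx <- pmin(pmax(seq_len(n) - half, 1L), nrow(object@windows))
  win <- object@windows
  data.frame(id = id, position = seq_len(n),
             residue = strsplit(object@sequence, "")[[1]],
             label = object@residueLabels,
             phi = win$phi[widx], alpha = win$alpha[widx],
             vModel = win$vModel[widx], distance = win$distance[widx])
}

#' @rdname residueTable
#' @param path output TSV path
#' @export
writeResidueTable <- function(object, path, id = "seq") {
  utils::write.table(residueTable(object, id), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Regions as genomic-style ranges
#'
#' Converts called regions to a `GRanges` on the protein coordinate system
#' (seqname = protein id, 1-based inclusive), with `label` as the name and
#' the mean classifier distance as the score. Export to BED converts to
#' 0-based half-open at the boundary only.
#'
#' @inheritParams residueTable
#' @return a [GenomicRanges::GRanges]
#' @export
regionsAsGRanges <- function(object, id = "seq") {
  r <- regions(object)
  if (!length(r))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(seqnames = id,
                         ranges = IRanges(IRanges::start(r), IRanges::end(r)),
                         name = mcols(r)$label,
                         score = mcols(r)$score)
}

#' Write regions to BED
#'
#' BED (0-based half-open) via `rtracklayer`; the name field carries the
#' region label and the score field the mean classifier distance.
#'
#' @param gr a `GRanges` from [regionsAsGRanges()] (or a concatenation over
#'   proteins)
#' @param path output .bed path
#' @export
writeRegionsBED <- function(gr, path) {
  if (length(gr)) {
    # BED scores are clamped to [0, 1000] by convention
    gr$score <- pmin(pmax(gr$score, 0), 1000)
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read regions back from BED
#' @param path .bed path
#' @return `GRanges` (1-based inclusive coordinates)
#' @export
readRegionsBED <- function(path) rtracklayer::import(path, format = "BED")

#' Write the per-protein scan summary
#' @param summary output of [scanSequences()]
#' @param path output TSV path
#' @export
writeProteinSummary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of a run --- classifier constants, region-calling
#' parameters, potential coefficients, condensed-phase concentrations per
#' protein family, fitting grids, seed, and the nonstandard-residue policy
#' --- with defaults equal to the published values. `format()`/`cat()` of
#' the returned list is written to the log by the command-line driver so
#' every run records its full configuration.
#'
#' @param ... overrides of the defaults
#' @return named list
#' @export
runConfig <- function(...) {
  cfg <- list(
    constants = classifierConstants(),
    minRegionLength = 20L,
    purity = 0.9,
    potentials = c(a = 0, b = 0, c = 0),
    cDense = c(`A1-LCD` = 0.03, Ddx4 = 0.01, `LAF-1 RGG` = 0.01,
               other = 0.03),
    aGrid = c(0, 1, 0.01),
    bcGrid = c(-50, 50, 0.2),
    seed = 1L,
    skipNonstandard = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}
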