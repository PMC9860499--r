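# Sequence validation -------------------------------------------------------

#' Validate and normalize an amino-acid sequence
#'
#' Uppercases the input and rejects any character outside the 20-letter
#' standard alphabet, reporting the first offending position. Ambiguity and
#' gap codes (`B`, `Z`, `X`, `U`, `*`, `-`) are rejected: the property scales
#' are defined only for the standard residues.
#'
#' @param sequence character scalar (or an object coercible via
#'   `as.character`, e.g. a `Biostrings::AAString`)
#' @return the validated uppercase sequence (invisibly usable as input to
#'   every other function)
#' @export
checkSequence <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop("sequence must be a single non-empty string")
  bad <- regexpr(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), s)
  if (bad > 0L)
    stop(sprintf("non-standard residue '%s' at position %d",
                 substr(s, bad, bad), bad))
  s
}

.seqChars <- function(sequence) strsplit(checkSequence(sequence), "")[[1]]

# Per-residue lookup of a value vector indexed by one-letter code.
.residueValues <- function(values, sequence) unname(values[.seqChars(sequence)])

# Scale means ---------------------------------------------------------------

#' Mean scale value of a sequence
#'
#' The composition-only average `sum(scale_i) / N` over all residues; it is
#' invariant under any permutation of the sequence.
#'
#' @param scale a [PropertyScale-class] (or a bare named numeric of length 20)
#' @param sequence amino-acid string
#' @return numeric scalar
#' @export
sequenceMean <- function(scale, sequence) {
  v <- if (is(scale, "PropertyScale")) scale@values else scale[AA_STANDARD]
  mean(.residueValues(v, sequence))
}

#' Sliding-window scale profile
#'
#' Window `k` (1-based) covers residues `k .. k + windowLength - 1`; the
#' profile has `N - windowLength + 1` values, each the [sequenceMean()] of
#' its window.
#'
#' @inheritParams sequenceMean
#' @param windowLength window size in residues (default 25)
#' @return numeric vector of window means
#' @export
windowProfile <- function(scale, sequence, windowLength = 25L) {
  v <- if (is(scale, "PropertyScale")) scale@values else scale[AA_STANDARD]
  x <- .residueValues(v, sequence)
  n <- length(x)
  if (n < windowLength)
    stop(sprintf("sequence length %d is below the minimum window length %d",
                 n, windowLength))
  .runningMean(x, windowLength)
}

# Running mean over fixed-width windows via cumulative sums.
.runningMean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(length(x) + 1L)] - cs[1L:(length(x) - w + 1L)]) / w
}

# Registry ------------------------------------------------------------------

#' The builtin scale registry
#'
#' Returns a [ScaleRegistry-class] preloaded with the four scales the
#' classifier depends on:
#' \describe{
#'   \item{beta_turn}{normalized reverse-turn frequencies (Levitt 1978;
#'     AAindex LEVM780103)}
#'   \item{helix}{right-handed helical state occurrence (Rackovsky &
#'     Scheraga 1982; AAindex RACS820102), the helix propensity of the P/D
#'     discriminant}
#'   \item{hydrophobicity}{the structure-based interactivity scale of
#'     Bastolla et al. 2005 (AAindex BASU050102), the phi of the F cutoff}
#'   \item{ppii}{experimental polyproline-II propensities in unfolded
#'     peptides (Shi et al. 2005, with Gly/Pro conventions of Tomasso et
#'     al. 2016), used by the hydrodynamic-radius model}
#' }
#' @return a `ScaleRegistry`
#' @export
builtinScales <- function() {
  scales <- list(
    propertyScale("beta_turn", .BETA_TURN_VALUES, "turn",
                  "Levitt 1978, Biochemistry 17:4277 (AAindex LEVM780103)"),
    propertyScale("helix", .HELIX_VALUES, "helix",
                  "Rackovsky & Scheraga 1982, Macromolecules 15:1340 (AAindex RACS820102)"),
    propertyScale("hydrophobicity", .PHI_VALUES, "hydrophobicity_structural",
                  "Bastolla et al. 2005, Proteins 58:22 (AAindex BASU050102)"),
    propertyScale("ppii", .PPII_VALUES, "other",
                  "Shi et al. 2005, PNAS 102:17964; Gly/Pro per Tomasso et al. 2016"))
  names(scales) <- vapply(scales, function(s) s@name, character(1))
  new("ScaleRegistry", scales = scales)
}

#' Retrieve a scale from a registry by name
#' @param registry a [ScaleRegistry-class]
#' @param name scale name
#' @return a [PropertyScale-class]
#' @export
getScale <- function(registry, name) {
  if (!name %in% names(registry@scales))
    stop(sprintf("no scale named '%s' in registry", name))
  registry@scales[[name]]
}

#' Add scales to a registry
#' @param registry a [ScaleRegistry-class]
#' @param scales a `PropertyScale` or list of them
#' @return the enlarged registry
#' @export
addScale <- function(registry, scales) {
  if (is(scales, "PropertyScale")) scales <- list(scales)
  for (s in scales) {
    if (s@name %in% names(registry@scales))
      stop(sprintf("scale '%s' already registered", s@name))
    registry@scales[[s@name]] <- s
  }
  validObject(registry)
  registry
}

#' @rdname getScale
#' @export
scaleNames <- function(registry) names(registry@scales)

# AAindex1 ------------------------------------------------------------------

#' Read amino-acid scales from an AAindex1 flat file
#'
#' Parses the standard AAindex1 format (records delimited by `//`; `H`
#' accession, `D` description, `I` line followed by two rows of ten values in
#' the A/R/N/D... layout). Entries containing `NA` values are skipped and
#' counted; malformed records are skipped with a warning naming the
#' accession.
#'
#' @param path file path (or connection) to an AAindex1-format file
#' @return list of [PropertyScale-class] objects; attribute `skipped` gives
#'   the number of entries dropped for missing values
#' @export
readAAindex <- function(path) {
  lines <- readLines(path)
  recEnds <- grep("^//", lines)
  recStarts <- c(1L, head(recEnds, -1L) + 1L)
  scales <- list()
  skipped <- 0L
  for (r in seq_along(recEnds)) {
    rec <- lines[recStarts[r]:recEnds[r]]
    acc <- sub("^H\\s+", "", grep("^H ", rec, value = TRUE)[1])
    if (is.na(acc)) next                      # blank trailing record
    dIdx <- grep("^D ", rec)
    desc <- if (length(dIdx)) {
      dEnd <- dIdx
      while (dEnd + 1L <= length(rec) && grepl("^\\s", rec[dEnd + 1L]))
        dEnd <- dEnd + 1L
      paste(trimws(sub("^D ", "", rec[dIdx:dEnd])), collapse = " ")
    } else ""
    iIdx <- grep("^I ", rec)
    if (length(iIdx) != 1L || iIdx + 2L > length(rec)) {
      warning(sprintf("AAindex entry %s: malformed I block, skipped", acc))
      next
    }
    vals <- suppressWarnings(
      as.numeric(unlist(strsplit(trimws(rec[c(iIdx + 1L, iIdx + 2L)]), "\\s+"))))
    if (length(vals) != 20L) {
      warning(sprintf("AAindex entry %s: expected 20 values, got %d, skipped",
                      acc, length(vals)))
      next
    }
    if (any(is.na(vals))) { skipped <- skipped + 1L; next }
    names(vals) <- AA_STANDARD                # I-line layout is A R N D ... V
    scales[[acc]] <- propertyScale(acc, vals, categorizeScale(desc), desc)
  }
  attr(scales, "skipped") <- skipped
  scales
}

#' Write scales in AAindex1 layout
#'
#' Writes a minimal, re-readable AAindex1 record per scale (H/D/I blocks).
#' Round-trips losslessly through [readAAindex()].
#'
#' @param scales list of [PropertyScale-class] (or a [ScaleRegistry-class])
#' @param path output path
#' @export
writeAAindex <- function(scales, path) {
  if (is(scales, "ScaleRegistry")) scales <- scales@scales
  con <- file(path, "w")
  on.exit(close(con))
  for (s in scales) {
    v <- s@values[AA_STANDARD]
    writeLines(c(
      paste("H", s@name),
      paste("D", s@source),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(formatC(v[1:10], format = "g", digits = 15), collapse = " ")),
      paste0("  ", paste(formatC(v[11:20], format = "g", digits = 15), collapse = " ")),
      "//"), con)
  }
  invisible(path)
}

# Categorization ------------------------------------------------------------

.CATEGORY_KEYWORDS <- list(
  turn = c("beta-turn", "tight turn", "reverse turn", "turn", "chain reversal",
           "bend"),
  sheet = c("beta-sheet", "sheet", "strand", "extended structure",
            "beta structure", "beta-structure"),
  helix = c("alpha-helix", "helix", "helical"),
  coil = c("coil", "loop"),
  aperiodic = c("aperiodic"),
  flexibility = c("flexib", "mobility", "b-factor", "temperature factor"),
  charge = c("charge", "isoelectric", "electric", "pk"),
  composition = c("composition", "frequency in", "relative mutability",
                  "occurrence"),
  size = c("size", "volume", "weight", "bulkiness", "length of side chain",
           "width", "steric", "surface area"),
  hydrophobicity_structural = c("buried", "burial", "accessib", "contact",
                                "interactivity", "interior", "exposure"),
  hydrophobicity_solution = c("transfer free energy", "transfer energy",
                              "partition", "solvation", "solubility",
                              "hydration"))

.HYDRO_KEYWORDS <- c("hydrophob", "hydropath", "lipophil")

#' Assign a scale-type category from descriptive text
#'
#' Keyword-driven mapping into the categories used for scale screening.
#' Hydrophobicity-like titles are split into structure-based
#' (`hydrophobicity_structural`: burial, contact, accessibility metrics from
#' structure surveys) and solution-based (`hydrophobicity_solution`:
#' transfer/partition experiments); anything unmatched is `other`. The
#' keyword lists are package constants, documented here because the grouping
#' itself is a modeling choice.
#'
#' @param description title or description text (empty allowed)
#' @return a category string
#' @export
categorizeScale <- function(description) {
  d <- tolower(paste(description, collapse = " "))
  if (!nzchar(trimws(d))) return("other")
  hydro <- any(vapply(.HYDRO_KEYWORDS, grepl, logical(1), x = d, fixed = TRUE))
  for (cat in names(.CATEGORY_KEYWORDS)) {
    hit <- any(vapply(.CATEGORY_KEYWORDS[[cat]], grepl, logical(1),
                      x = d, fixed = TRUE))
    if (hit) {
      if (hydro && !startsWith(cat, "hydrophobicity")) next
      return(cat)
    }
  }
  if (hydro) return("hydrophobicity_solution")   # default for bare "hydrophobicity"
  "other"
}

#' Export a registry as TSV
#'
#' One row per scale: name, category, source, then the 20 values in
#' alphabetical one-letter order (A, C, D, ... Y).
#'
#' @param registry a [ScaleRegistry-class]
#' @param path output path
#' @export
exportRegistry <- function(registry, path) {
  aaAlpha <- sort(AA_STANDARD)
  rows <- lapply(registry@scales, function(s)
    data.frame(name = s@name, category = s@category, source = s@source,
               t(s@values[aaAlpha]), check.names = FALSE))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
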