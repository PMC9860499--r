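#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom utils head tail
#' @importFrom stats setNames
NULL

#' The 20 standard amino acids, one-letter codes
#'
#' Ordering follows the conventional A/R/N/D... (alphabetical by three-letter
#' code) layout used by AAindex.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.SCALE_CATEGORIES <- c("helix", "sheet", "turn", "coil", "aperiodic",
                       "flexibility", "size", "composition", "charge",
                       "hydrophobicity_structural", "hydrophobicity_solution",
                       "other")

#' PropertyScale: a per-residue physicochemical or conformational index
#'
#' A named numeric vector assigning one finite value to each of the 20
#' standard amino acids, together with a category (mirroring the groups used
#' when screening scale types: helix, sheet, turn, coil, aperiodic,
#' flexibility, size, composition, charge, structure- or solution-based
#' hydrophobicity, other) and a free-text source citation.
#'
#' @slot name short identifier
#' @slot category one of the scale-type categories (see
#'   [categorizeScale()])
#' @slot values named numeric of length 20, names = one-letter codes
#' @slot source free-text provenance
#' @export
setClass("PropertyScale",
         representation(name = "character", category = "character",
                        values = "numeric", source = "character"))

setValidity("PropertyScale", function(object) {
  v <- object@values
  if (length(v) != 20L || !setequal(names(v), AA_STANDARD))
    return("values must have exactly 20 entries named by the standard amino acids")
  if (any(!is.finite(v)))
    return("all scale values must be finite")
  if (length(object@category) != 1L || !object@category %in% .SCALE_CATEGORIES)
    return(paste("category must be one of:", paste(.SCALE_CATEGORIES, collapse = ", ")))
  TRUE
})

#' Construct a PropertyScale
#'
#' @param name short identifier
#' @param values named numeric, one value per standard amino acid (any order)
#' @param category scale-type category; if missing, derived from `name` via
#'   [categorizeScale()]
#' @param source free-text citation
#' @return a [PropertyScale-class] object
#' @export
propertyScale <- function(name, values, category = NULL, source = "") {
  if (is.null(category)) category <- categorizeScale(name)
  new("PropertyScale", name = name, category = category,
      values = values[AA_STANDARD], source = source)
}

#' ScaleRegistry: a named collection of property scales
#'
#' Always resolves the four builtin scales the classifier depends on
#' (`beta_turn`, `helix`, `hydrophobicity`, `ppii`); additional scales (for
#' example parsed from an AAindex1 file) can be added with [addScale()].
#'
#' @slot scales named list of [PropertyScale-class]
#' @export
setClass("ScaleRegistry", representation(scales = "list"))

setValidity("ScaleRegistry", function(object) {
  nm <- vapply(object@scales, function(s) s@name, character(1))
  if (anyDuplicated(nm)) return("duplicate scale names in registry")
  if (!identical(names(object@scales), unname(nm)))
    return("registry list names must equal the scale names")
  TRUE
})

#' ParSeClassification: windowed classification of one protein sequence
#'
#' Produced by [classifyWindows()]. Holds the per-window hydrophobicity
#' (phi), helix propensity (alpha), v_model, F/P/D label and classifier
#' distance; the per-residue label string; and the classifier constants used.
#'
#' @slot sequence the input amino-acid sequence (uppercase)
#' @slot windows a [S4Vectors::DataFrame] with one row per 25-residue window
#'   (columns: window, center, phi, alpha, vModel, label, distance)
#' @slot residueLabels character vector of per-residue labels, length N
#' @slot constants the [classifierConstants()] list used
#' @export
setClass("ParSeClassification",
         representation(sequence = "character", windows = "DataFrame",
                        residueLabels = "character", constants = "list"))

setValidity("ParSeClassification", function(object) {
  n <- nchar(object@sequence)
  w <- object@windows
  if (nrow(w) != n - object@constants$windowLength + 1L)
    return("window count must be N - windowLength + 1")
  if (length(object@residueLabels) != n)
    return("residueLabels must have one label per residue")
  if (!all(w$label %in% c("F", "P", "D")))
    return("window labels must be F, P or D")
  if (any(w$distance < 0))
    return("classifier distances must be nonnegative")
  TRUE
})

#' @describeIn ParSeClassification-class compact display
#' @param object a `ParSeClassification`
#' @export
setMethod("show", "ParSeClassification", function(object) {
  n <- nchar(object@sequence)
  tab <- table(factor(object@windows$label, levels = c("F", "P", "D")))
  cat("ParSeClassification | N =", n, "|", nrow(object@windows), "windows\n")
  cat("  window labels: F =", tab[["F"]], " P =", tab[["P"]],
      " D =", tab[["D"]], "\n")
  cat("  summed P classifier distance:",
      format(summedPDistance(object), digits = 4), "\n")
  reg <- regions(object)
  cat("  regions (>=", object@constants$minRegionLength, "aa, >=",
      object@constants$purity * 100, "% pure):", length(reg), "\n")
})

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale", sQuote(object@name), "[", object@category, "]\n")
  print(round(object@values, 4))
})

setMethod("show", "ScaleRegistry", function(object) {
  cat("ScaleRegistry with", length(object@scales), "scales:",
      paste(names(object@scales), collapse = ", "), "\n")
})
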