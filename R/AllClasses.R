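#' @useDynLib mirStem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rlnorm rmultinom runif rbinom pnbinom dnbinom p.adjust
#' @importFrom utils write.table read.table head
NULL

#' UniqueTagSet: collapsed small RNA tags with two-library counts
#'
#' A distinct (unique) small RNA sequence together with its read counts
#' in the two sequenced libraries. This is the unit that flows through
#' every filtering and annotation stage: reads are collapsed to unique
#' tags after adapter trimming, and all downstream matching operates on
#' tags while expression uses the per-library counts.
#'
#' @slot sequences character vector of tag sequences (DNA alphabet,
#'   thymine form; uracil is converted on input).
#' @slot countBR integer read count of each tag in the first
#'   (browning-resistant, "BR") library.
#' @slot countBS integer read count of each tag in the second
#'   (browning-sensitive, "BS") library.
#' @export
setClass("UniqueTagSet",
  representation(
    sequences = "character",
    countBR = "integer",
    countBS = "integer"
  ),
  validity = function(object) {
    n <- length(object@sequences)
    if (length(object@countBR) != n || length(object@countBS) != n)
      return("sequences and counts must have equal length")
    if (any(object@countBR < 0) || any(object@countBS < 0))
      return("counts must be non-negative")
    if (n > 0 && any(object@countBR + object@countBS == 0))
      return("a tag must have at least one read in some library")
    if (n > 0 && anyDuplicated(object@sequences))
      return("tag sequences must be unique")
    TRUE
  }
)

#' Construct a UniqueTagSet
#'
#' @param sequences character vector of tag sequences (A/C/G/T; U is
#'   mapped to T).
#' @param countBR,countBS per-tag read counts in the two libraries.
#' @return A [UniqueTagSet-class] object.
#' @examples
#' uniqueTagSet(c("TGGATTGAAGGGAGCTCTACA", "TTTGGATTGAAGGGAGCTCTA"),
#'              countBR = c(10L, 3L), countBS = c(2L, 5L))
#' @export
uniqueTagSet <- function(sequences = character(),
                         countBR = integer(length(sequences)),
                         countBS = integer(length(sequences))) {
  sequences <- toupper(as.character(sequences))
  sequences <- chartr("U", "T", sequences)
  new("UniqueTagSet", sequences = sequences,
      countBR = as.integer(countBR), countBS = as.integer(countBS))
}

#' @describeIn UniqueTagSet-class number of unique tags
#' @param x a `UniqueTagSet`
#' @export
setMethod("length", "UniqueTagSet", function(x) length(x@sequences))

#' Tag sequences of a UniqueTagSet
#' @param x a [UniqueTagSet-class]
#' @return character vector of tag sequences.
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname tagSequences
#' @export
setMethod("tagSequences", "UniqueTagSet", function(x) x@sequences)

#' Per-library read counts of a UniqueTagSet
#' @param x a [UniqueTagSet-class]
#' @return integer matrix with columns `BR` and `BS`.
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname tagCounts
#' @export
setMethod("tagCounts", "UniqueTagSet", function(x) {
  cbind(BR = x@countBR, BS = x@countBS)
})

#' @export
setMethod("[", "UniqueTagSet", function(x, i, j, ..., drop = TRUE) {
  new("UniqueTagSet", sequences = x@sequences[i],
      countBR = x@countBR[i], countBS = x@countBS[i])
})

setMethod("show", "UniqueTagSet", function(object) {
  cat("UniqueTagSet with", length(object), "tags\n")
  if (length(object) > 0) {
    cat("  total reads BR:", sum(object@countBR),
        " BS:", sum(object@countBS), "\n")
    cat("  length range:", paste(range(nchar(object@sequences)),
                                 collapse = "-"), "nt\n")
  }
})

#' FoldResult: an RNA secondary structure with its free energy
#'
#' The minimum-energy nested secondary structure of a sequence under the
#' built-in stacking-energy model (see [foldRNA]), stored as a pair
#' table (for each position, its partner or 0), the equivalent
#' dot-bracket string, and the structure's free energy in kcal/mol.
#'
#' @slot sequence the folded sequence (as given).
#' @slot pairTable integer vector; `pairTable[i]` is the 1-based partner
#'   of position i, or 0 if unpaired.
#' @slot dotBracket Vienna dot-bracket string.
#' @slot energy free energy of the structure, kcal/mol (<= 0).
#' @export
setClass("FoldResult",
  representation(
    sequence = "character",
    pairTable = "integer",
    dotBracket = "character",
    energy = "numeric"
  ),
  validity = function(object) {
    n <- nchar(object@sequence)
    pt <- object@pairTable
    if (length(pt) != n) return("pairTable length must match sequence")
    paired <- which(pt > 0)
    if (any(pt[pt > 0] < 1 | pt[pt > 0] > n)) return("partner out of range")
    if (!all(pt[pt[paired]] == paired)) return("pairTable is not an involution")
    if (any(pt[paired] == paired)) return("a base cannot pair with itself")
    if (object@energy > 0) return("energy must be <= 0")
    # hairpin loop >= 3: |i - j| > 3 for every pair
    if (any(abs(pt[paired] - paired) <= 3))
      return("hairpin loop smaller than 3 nt")
    # nestedness: no crossing pairs
    op <- paired[pt[paired] > paired]
    if (length(op) > 1) {
      cl <- pt[op]
      for (a in seq_along(op)) {
        cross <- op > op[a] & op < cl[a] & cl > cl[a]
        if (any(cross)) return("crossing base pairs (pseudoknot)")
      }
    }
    TRUE
  }
)

#' Free energy of a fold
#' @param x a [FoldResult-class]
#' @return numeric, kcal/mol.
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))

#' @rdname mfe
#' @export
setMethod("mfe", "FoldResult", function(x) x@energy)

#' Dot-bracket string of a fold
#' @param x a [FoldResult-class]
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname dotBracket
#' @export
setMethod("dotBracket", "FoldResult", function(x) x@dotBracket)

#' Pair table of a fold
#' @param x a [FoldResult-class]
#' @return integer vector of 1-based partners (0 = unpaired).
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairTable
#' @export
setMethod("pairTable", "FoldResult", function(x) x@pairTable)

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult (", nchar(object@sequence), " nt, MFE ",
      object@energy, " kcal/mol)\n", sep = "")
  cat(" ", object@sequence, "\n ", object@dotBracket, "\n")
})
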