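#' Fold an RNA sequence under the built-in stacking-energy model
#'
#' Computes the minimum-free-energy nested secondary structure of a
#' sequence by dynamic programming. The energy model is deliberately
#' simple and fully specified: a base pair contributes a stacking term
#' only when stacked directly on an adjacent inner pair (GC/CG -3.0,
#' AU/UA -2.0, GU/UG -1.0 kcal/mol per stacked pair), unpaired bases
#' cost nothing, and hairpin loops must contain at least `minLoop`
#' unpaired bases. The all-unpaired structure therefore has energy 0,
#' and MFE is always <= 0. Co-optimal structures are resolved
#' deterministically by maximizing the pair count, then preferring
#' 5'-most pairings.
#'
#' The model is used as a stability threshold for hairpin candidates,
#' not as a replacement for full nearest-neighbour thermodynamics; an
#' external thermodynamic folder can be plugged in wherever a
#' `folder` argument is accepted (see [mirnaCriteria]): any function
#' taking a sequence and returning a list with elements `dotBracket`
#' and `energy` is accepted, and its energies are used verbatim.
#'
#' @param seq a single sequence, length 1..1000, over A/C/G/U (T is
#'   accepted and treated as U).
#' @param minLoop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return A [FoldResult-class].
#' @examples
#' fr <- foldRNA("GGGAAAACCC")
#' dotBracket(fr)
#' mfe(fr)
#' @export
foldRNA <- function(seq, minLoop = 3L) {
  seq <- validateSeq(seq, what = "fold input")
  n <- nchar(seq)
  if (n < 1 || n > 1000)
    stop("sequence length must be in [1, 1000], got ", n)
  code <- encodeSeq(seq)
  res <- .foldCpp(code, as.integer(minLoop))
  pt <- res$pairTable
  new("FoldResult", sequence = seq, pairTable = pt,
      dotBracket = pairTableToDotBracket(pt), energy = res$energy)
}

# A=0, C=1, G=2, U/T=3
encodeSeq <- function(seq) {
  code <- match(strsplit(chartr("T", "U", seq), "")[[1]],
                c("A", "C", "G", "U")) - 1L
  code
}

validateSeq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !is.character(seq))
    stop(what, " must be a single character string")
  seq <- toupper(seq)
  if (grepl("[^ACGTU]", seq))
    stop(what, " contains invalid characters (allowed: A, C, G, T, U)")
  seq
}

pairTableToDotBracket <- function(pt) {
  db <- rep(".", length(pt))
  db[pt > seq_along(pt)] <- "("
  db[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(db, collapse = "")
}

#' Duplex statistics for a mature miRNA within a folded precursor
#'
#' Given a folded precursor and the position of a putative mature miRNA
#' on it, measures the miRNA/miRNA* duplex: how many mature positions
#' are base-paired (`overlap_bp`), how many bulges interrupt the duplex,
#' and where the star (miRNA*) sequence lies. The star interval is the
#' minimal interval covering the partners of all paired mature
#' positions, extended at its 3' end by `overhang3` nucleotides (the
#' canonical Dicer 2-nt 3' overhang), clipped to the precursor.
#'
#' A "bulge" is a maximal run of unpaired positions strictly inside the
#' duplex on either strand (mature-side runs between the first and last
#' paired mature positions, and star-side runs between the outermost
#' partners); a symmetric internal loop therefore counts once per
#' strand.
#'
#' If the mature interval has no paired position, or its partners fall
#' back inside the mature interval itself (the mature spans the terminal
#' loop), the result is flagged rather than raising an error.
#'
#' @param fr a [FoldResult-class] for the precursor.
#' @param matureStart 1-based start of the mature sequence on the
#'   precursor.
#' @param matureLen mature length in nt.
#' @param overhang3 3' overhang applied to the star interval (default 2).
#' @return A list with elements `overlap_bp`, `n_bulges`, `star_start`,
#'   `star_end`, `overhang3`, `arm` ("5p" or "3p"), `monotone` (TRUE
#'   when the partners decrease monotonically along the mature, i.e.
#'   the duplex is a single antiparallel helix), `loop_gap` (unpaired
#'   span between the mature and the star interval, nt), and `flagged`
#'   (TRUE when the mature is unpaired or overlaps the loop).
#' @export
duplexStats <- function(fr, matureStart, matureLen, overhang3 = 2L) {
  stopifnot(is(fr, "FoldResult"))
  n <- nchar(fr@sequence)
  matureStart <- as.integer(matureStart)
  matureLen <- as.integer(matureLen)
  if (matureStart < 1 || matureStart + matureLen - 1 > n)
    stop("mature interval outside the precursor")
  idx <- matureStart:(matureStart + matureLen - 1L)
  pt <- fr@pairTable
  partners <- pt[idx]
  paired <- partners > 0
  overlap <- sum(paired)
  if (overlap == 0) {
    return(list(overlap_bp = 0L, n_bulges = NA_integer_,
                star_start = NA_integer_, star_end = NA_integer_,
                overhang3 = as.integer(overhang3), arm = NA_character_,
                monotone = NA, loop_gap = NA_integer_, flagged = TRUE))
  }
  pp <- partners[paired]
  starLo <- min(pp)
  starHi <- max(pp)
  # mature spanning the loop: partners land inside the mature itself
  flagged <- any(pp >= min(idx) & pp <= max(idx))
  arm <- if (starLo > max(idx)) "5p" else if (starHi < min(idx)) "3p"
         else NA_character_
  if (is.na(arm)) flagged <- TRUE
  # a true miRNA/miRNA* duplex is a single antiparallel helix (with
  # bulges): partners must decrease monotonically along the mature
  monotone <- !is.unsorted(rev(pp), strictly = TRUE)
  # loop gap: unpaired span between the mature and the star interval
  loopGap <- if (is.na(arm)) NA_integer_
             else if (arm == "5p") starLo - max(idx[paired]) - 1L
             else min(idx[paired]) - starHi - 1L
  # both arms read 5'->3' left to right, so the star 3' end is its
  # right (max-coordinate) end when the star is downstream of the
  # mature, and also its right end when upstream -- on the sequence the
  # 3' direction is always increasing position for the + strand
  starEnd <- min(n, starHi + as.integer(overhang3))
  starStart <- starLo
  # bulges: maximal unpaired runs strictly inside the duplex
  matureIn <- idx[which(paired)[1]:which(paired)[sum(paired)]]
  bulges <- countUnpairedRuns(pt, matureIn) +
    countUnpairedRuns(pt, starLo:starHi)
  list(overlap_bp = as.integer(overlap), n_bulges = as.integer(bulges),
       star_start = as.integer(starStart), star_end = as.integer(starEnd),
       overhang3 = as.integer(overhang3), arm = arm,
       monotone = monotone, loop_gap = as.integer(loopGap),
       flagged = flagged)
}

countUnpairedRuns <- function(pt, idx) {
  if (length(idx) < 3) return(0L)
  inner <- idx[-c(1, length(idx))]
  unp <- pt[inner] == 0
  sum(unp & !c(FALSE, unp[-length(unp)]))
}
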