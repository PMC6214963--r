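#' Acceptance criteria for novel miRNA candidates
#'
#' Bundles the hairpin-based thresholds: mature length gate 18-25 nt, a
#' minimum of 16 bp pairing between mature and star, no more than four
#' duplex bulges, precursor minimum free energy at or below -18
#' kcal/mol (free energies are negative; the bound is on stability),
#' and miRNA* support. Star support is recorded on every accepted
#' record but only required when `requireStar = TRUE`, since genuine
#' miRNAs frequently lack sequenced star reads (the passenger strand is
#' degraded). A minimum read-depth filter (`minReads`, total reads
#' across both libraries) screens out single-copy background tags, the
#' usual practice for hairpin-based discovery.
#'
#' @param matureLenRange inclusive mature length gate in nt.
#' @param minOverlap minimum paired mature positions in the duplex.
#' @param maxBulges maximum duplex bulges.
#' @param maxAsymmetry maximum excess of the star span (minus the
#'   overhang) over the mature length, in nt: bounds the miRNA/miRNA*
#'   asymmetry.
#' @param maxStarDistance maximum unpaired span between the mature and
#'   the star (the terminal-loop side gap), nt; hairpin loops are
#'   short, so a distant "star" marks a spurious duplex.
#' @param maxEnergy precursor MFE threshold, kcal/mol (candidate must
#'   fold at or below it).
#' @param requireStar if TRUE, candidates without a detected star read
#'   are rejected.
#' @param minReads minimum total read count of the mature tag.
#' @param overhang3 star 3' overhang in nt.
#' @param starShift tolerance (nt) when matching tags to the star
#'   interval.
#' @param folder optional external folding function (sequence ->
#'   `list(dotBracket=, energy=)`); its energies are used verbatim.
#' @return a list of class `mirnaCriteria`.
#' @export
mirnaCriteria <- function(matureLenRange = c(18L, 25L),
                          minOverlap = 16L,
                          maxBulges = 4L,
                          maxAsymmetry = 4L,
                          maxStarDistance = 35L,
                          maxEnergy = -18,
                          requireStar = FALSE,
                          minReads = 5L,
                          overhang3 = 2L,
                          starShift = 2L,
                          folder = NULL) {
  structure(list(matureLenRange = as.integer(matureLenRange),
                 minOverlap = as.integer(minOverlap),
                 maxBulges = as.integer(maxBulges),
                 maxAsymmetry = as.integer(maxAsymmetry),
                 maxStarDistance = as.integer(maxStarDistance),
                 maxEnergy = maxEnergy,
                 requireStar = requireStar,
                 minReads = as.integer(minReads),
                 overhang3 = as.integer(overhang3),
                 starShift = as.integer(starShift),
                 folder = folder),
            class = "mirnaCriteria")
}

#' Excise candidate precursor windows around a mapped tag
#'
#' For each perfect-match position of a tag on the reference, two
#' windows are excised, one per arm hypothesis: treating the tag as the
#' 5p arm, `[start - 10, end + flank3]`; as the 3p arm,
#' `[start - flank5, end + 10]`. Windows are clipped to the reference;
#' a window that clips below 50 nt is discarded (with its reason
#' recorded in the `discarded` attribute).
#'
#' @param tagSeq the tag sequence.
#' @param hits data.frame of mapping positions with columns `ref`
#'   (reference name), `start` (1-based), `strand` (`+`/`-`); on the
#'   minus strand `start` refers to the position of the tag's reverse
#'   complement on the plus strand.
#' @param refs named character vector of reference sequences.
#' @param flank5,flank3 flank sizes in nt (defaults 160).
#' @return list of candidate lists (`ref`, `start`, `end` 1-based
#'   inclusive window on the plus strand, `strand`, `sequence` oriented
#'   5'->3' on the candidate strand, `matureStart`, `matureLen`, `armHyp`).
#' @export
exciseCandidates <- function(tagSeq, hits, refs, flank5 = 160L,
                             flank3 = 160L) {
  out <- list()
  discarded <- character(0)
  L <- nchar(tagSeq)
  for (h in seq_len(nrow(hits))) {
    refName <- hits$ref[h]
    refSeq <- refs[[refName]]
    n <- nchar(refSeq)
    s <- hits$start[h]
    e <- s + L - 1L
    strand <- hits$strand[h]
    for (hyp in c("5p", "3p")) {
      if (strand == "+") {
        lo <- if (hyp == "5p") s - 10L else s - flank5
        hi <- if (hyp == "5p") e + flank3 else e + 10L
      } else {
        # on the minus strand the tag's 5' side is at higher plus
        # coordinates
        lo <- if (hyp == "5p") s - flank3 else s - 10L
        hi <- if (hyp == "5p") e + 10L else e + flank5
      }
      lo <- max(1L, lo)
      hi <- min(n, hi)
      if (hi - lo + 1L < 50L) {
        discarded <- c(discarded,
                       sprintf("%s:%d:%s:%s window < 50 nt after clipping",
                               refName, s, strand, hyp))
        next
      }
      seq <- substr(refSeq, lo, hi)
      if (strand == "-") seq <- revcompDNA(seq)
      matureStart <- if (strand == "+") s - lo + 1L else hi - e + 1L
      out[[length(out) + 1L]] <- list(
        ref = refName, start = lo, end = hi, strand = strand,
        sequence = seq, matureStart = matureStart, matureLen = L,
        armHyp = hyp)
    }
  }
  attr(out, "discarded") <- discarded
  out
}

#' Evaluate a precursor candidate against the hairpin criteria
#'
#' Folds the candidate window (built-in folder, or the plug-in folder
#' from the criteria), measures the miRNA/miRNA* duplex, and accepts
#' the candidate iff all criteria hold: mature length inside the gate,
#' mature on a stem arm (not spanning the loop), duplex overlap >=
#' `minOverlap`, at most `maxBulges` bulges, MFE at or below
#' `maxEnergy`, and - only when `requireStar` - a detected star read.
#' Star detection looks for any tag whose sequence occurs in the
#' star interval extended by `starShift` nt on both sides.
#'
#' @param cand one candidate from [exciseCandidates] (the `fold`
#'   element is computed here if absent).
#' @param allTags a [UniqueTagSet-class] used for star detection and
#'   read counts (pass the unannotated tags).
#' @param criteria a [mirnaCriteria] list.
#' @return list with `accepted` (logical); when accepted, `annotation`
#'   (one-row data.frame with arm, mature, Length, LP, MFE, reads,
#'   star_detected, location and precursor coordinates), otherwise
#'   `reason`, a machine-readable rejection code (`mature_length`,
#'   `min_reads`, `mature_in_loop`, `duplex_incoherent`,
#'   `min_overlap`, `max_bulges`, `asymmetry`, `star_distance`,
#'   `mfe`, `star_required`).
#' @export
evaluateCandidate <- function(cand, allTags, criteria = mirnaCriteria()) {
  reject <- function(reason) list(accepted = FALSE, reason = reason)
  L <- cand$matureLen
  if (L < criteria$matureLenRange[1] || L > criteria$matureLenRange[2])
    return(reject("mature_length"))
  mature <- substr(cand$sequence, cand$matureStart,
                   cand$matureStart + L - 1L)
  seqs <- tagSequences(allTags)
  cnt <- tagCounts(allTags)
  tagIdx <- match(mature, seqs)
  readsBR <- if (is.na(tagIdx)) 0L else cnt[tagIdx, "BR"]
  readsBS <- if (is.na(tagIdx)) 0L else cnt[tagIdx, "BS"]
  if (readsBR + readsBS < criteria$minReads)
    return(reject("min_reads"))

  doFold <- function(s) {
    if (is.null(criteria$folder)) return(foldRNA(s))
    ext <- criteria$folder(s)
    new("FoldResult", sequence = s,
        pairTable = dotBracketToPairTable(ext$dotBracket),
        dotBracket = ext$dotBracket, energy = ext$energy)
  }
  # the first fold locates the duplex inside the excision window; the
  # candidate is then trimmed to the hairpin extent (duplex plus a
  # short pad) and re-folded, iterating in case the structure shifts
  # on the trimmed sequence, so LP and MFE describe the precursor,
  # not the arbitrary window
  pad <- 5L
  offset <- 0L # precursor start minus one, in window coordinates
  precSeq <- cand$sequence
  matureStart <- cand$matureStart
  fr <- if (is.null(cand$fold)) doFold(precSeq) else cand$fold
  ds <- NULL
  for (iter in 1:4) {
    ds <- duplexStats(fr, matureStart, L, overhang3 = criteria$overhang3)
    if (ds$flagged || is.na(ds$arm)) return(reject("mature_in_loop"))
    if (!isTRUE(ds$monotone)) return(reject("duplex_incoherent"))
    tlo <- max(1L, min(matureStart, ds$star_start) - pad)
    thi <- min(nchar(precSeq),
               max(matureStart + L - 1L, ds$star_end) + pad)
    if (tlo == 1L && thi == nchar(precSeq)) break # extent is stable
    precSeq <- substr(precSeq, tlo, thi)
    offset <- offset + tlo - 1L
    matureStart <- matureStart - tlo + 1L
    fr <- doFold(precSeq)
  }
  lo <- offset + 1L
  hi <- offset + nchar(precSeq)
  if (ds$overlap_bp < criteria$minOverlap) return(reject("min_overlap"))
  if (ds$n_bulges > criteria$maxBulges) return(reject("max_bulges"))
  starSpan <- ds$star_end - ds$star_start + 1L - ds$overhang3
  if (starSpan - L > criteria$maxAsymmetry) return(reject("asymmetry"))
  if (!is.na(ds$loop_gap) && ds$loop_gap > criteria$maxStarDistance)
    return(reject("star_distance"))
  if (mfe(fr) > criteria$maxEnergy) return(reject("mfe"))
  # precursor interval in plus-strand reference coordinates
  if (cand$strand == "+") {
    precStart <- cand$start + lo - 1L
    precEnd <- cand$start + hi - 1L
  } else {
    precStart <- cand$end - hi + 1L
    precEnd <- cand$end - lo + 1L
  }

  # star support: any tag occurring in the star interval +/- starShift
  sh <- criteria$starShift
  starRegion <- substr(precSeq, max(1L, ds$star_start - sh),
                       min(nchar(precSeq), ds$star_end + sh))
  starLen <- ds$star_end - ds$star_start + 1L
  candTags <- seqs[abs(nchar(seqs) - starLen) <= 2L + sh]
  starDetected <- any(vapply(candTags, function(t)
    grepl(t, starRegion, fixed = TRUE), logical(1)))
  if (criteria$requireStar && !starDetected)
    return(reject("star_required"))

  ann <- data.frame(
    arm = ds$arm,
    mature = mature,
    length = L,
    LP = nchar(precSeq),
    MFE = mfe(fr),
    reads_BR = readsBR,
    reads_BS = readsBS,
    star_detected = starDetected,
    location = cand$ref,
    precursor_start = precStart,
    precursor_end = precEnd,
    strand = cand$strand,
    stringsAsFactors = FALSE)
  list(accepted = TRUE, annotation = ann,
       dotBracket = dotBracket(fr))
}

#' Build a validated miRNA annotation record
#'
#' Constructs one annotation row from its fields, deriving the mature
#' length from the sequence and enforcing the record invariants: the
#' length gate (18-25 nt by default), MFE at or below the energy
#' bound, and LP at least the mature length.
#'
#' @param name record name.
#' @param mature mature sequence 5'->3'.
#' @param arm "5p" or "3p".
#' @param LP precursor length (nt).
#' @param MFE precursor minimum free energy (kcal/mol).
#' @param readsBR,readsBS per-library read counts.
#' @param starDetected logical, miRNA* support.
#' @param location reference/precursor location label.
#' @param criteria a [mirnaCriteria] list supplying the gates.
#' @return one-row data.frame with the annotation columns.
#' @export
mirnaAnnotation <- function(name, mature, arm, LP, MFE,
                            readsBR = 0L, readsBS = 0L,
                            starDetected = FALSE, location = NA_character_,
                            criteria = mirnaCriteria()) {
  mature <- chartr("U", "T", validateSeq(mature, "mature"))
  len <- nchar(mature)
  if (len < criteria$matureLenRange[1] || len > criteria$matureLenRange[2])
    stop("mature length ", len, " outside the gate [",
         criteria$matureLenRange[1], ", ", criteria$matureLenRange[2], "]")
  if (!arm %in% c("5p", "3p")) stop("arm must be 5p or 3p")
  if (MFE > criteria$maxEnergy)
    stop("MFE ", MFE, " above the energy bound ", criteria$maxEnergy)
  if (LP < len) stop("precursor shorter than the mature sequence")
  data.frame(name = name, arm = arm, mature = mature, length = len,
             LP = as.integer(LP), MFE = MFE,
             reads_BR = as.integer(readsBR),
             reads_BS = as.integer(readsBS),
             star_detected = starDetected, location = location,
             stringsAsFactors = FALSE)
}

dotBracketToPairTable <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  pt
}

#' Map tags to references by perfect match
#'
#' Exact occurrences of each tag on either strand of the references.
#' Minus-strand hits report the plus-strand start of the tag's reverse
#' complement.
#'
#' @param tags a [UniqueTagSet-class].
#' @param refs named character vector of reference sequences.
#' @return data.frame with columns `tag_id`, `ref`, `start`, `strand`.
#' @export
mapTagsToRefs <- function(tags, refs) {
  seqs <- tagSequences(tags)
  subj <- Biostrings::DNAStringSet(refs)
  rows <- list()
  scan <- function(patterns, strand) {
    widths <- nchar(patterns)
    for (w in unique(widths)) {
      ii <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[ii]))
      for (r in seq_along(subj)) {
        m <- Biostrings::matchPDict(pd, subj[[r]])
        starts <- Biostrings::startIndex(m)
        hit <- which(lengths(starts) > 0)
        for (k in hit) {
          rows[[length(rows) + 1L]] <<- data.frame(
            tag_id = ii[k], ref = names(refs)[r],
            start = starts[[k]], strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  scan(seqs, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)), use.names = FALSE)
  scan(rc, "-")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tag_id = integer(), ref = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  out[order(out$tag_id, out$ref, out$start), , drop = FALSE]
}

#' Discover novel miRNAs among unannotated tags
#'
#' Runs the full candidate pipeline: map unannotated tags to the
#' references, excise precursor windows for both arm hypotheses, fold
#' and evaluate each window under the criteria, and deduplicate
#' windows of the same tag by best (lowest) MFE. Accepted records
#' mirror the novel-miRNA report columns (name, arm, mature sequence,
#' Length, LP, MFE, per-library reads, star support, location).
#'
#' @param tags a [UniqueTagSet-class] of unannotated tags (after ncRNA
#'   filtering and known-miRNA assignment).
#' @param refs named character vector of reference sequences.
#' @param criteria a [mirnaCriteria] list.
#' @param flank5,flank3 excision flanks (nt).
#' @return list with `annotations` (data.frame, one row per accepted
#'   mature), and `rejections` (data.frame of candidate-level reason
#'   codes).
#' @export
findNovelMirnas <- function(tags, refs, criteria = mirnaCriteria(),
                            flank5 = 160L, flank3 = 160L) {
  cnt <- tagCounts(tags)
  total <- rowSums(cnt)
  eligible <- which(total >= criteria$minReads)
  hits <- mapTagsToRefs(tags[eligible], refs)
  annRows <- list()
  rejRows <- list()
  seqsEl <- tagSequences(tags[eligible])
  for (t in unique(hits$tag_id)) {
    th <- hits[hits$tag_id == t, , drop = FALSE]
    cands <- exciseCandidates(seqsEl[t], th, refs,
                              flank5 = flank5, flank3 = flank3)
    best <- NULL
    for (cand in cands) {
      res <- evaluateCandidate(cand, tags, criteria)
      if (res$accepted) {
        if (is.null(best) || res$annotation$MFE < best$annotation$MFE)
          best <- res
      } else {
        rejRows[[length(rejRows) + 1L]] <- data.frame(
          sequence = seqsEl[t], ref = cand$ref, start = cand$start,
          armHyp = cand$armHyp, reason = res$reason,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) annRows[[length(annRows) + 1L]] <- best$annotation
  }
  ann <- do.call(rbind, annRows)
  if (is.null(ann)) {
    ann <- data.frame(name = character(), arm = character(),
                      mature = character(), length = integer(),
                      LP = integer(), MFE = numeric(),
                      reads_BR = integer(), reads_BS = integer(),
                      star_detected = logical(), location = character(),
                      precursor_start = integer(),
                      precursor_end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  } else {
    ann <- ann[order(ann$location, ann$precursor_start, ann$arm), ,
               drop = FALSE]
    # records whose precursor intervals overlap on the same reference
    # are arms of the same hairpin and share a locus number
    locus <- integer(nrow(ann))
    nLoci <- 0L
    lastLoc <- ""
    lastEnd <- -1L
    for (r in seq_len(nrow(ann))) {
      if (ann$location[r] != lastLoc || ann$precursor_start[r] > lastEnd) {
        nLoci <- nLoci + 1L
        lastLoc <- ann$location[r]
        lastEnd <- ann$precursor_end[r]
      } else {
        lastEnd <- max(lastEnd, ann$precursor_end[r])
      }
      locus[r] <- nLoci
    }
    ann <- cbind(name = sprintf("novel-%d-%s", locus, ann$arm),
                 ann, stringsAsFactors = FALSE)
    rownames(ann) <- NULL
  }
  rej <- do.call(rbind, rejRows)
  if (is.null(rej))
    rej <- data.frame(sequence = character(), ref = character(),
                      start = integer(), armHyp = character(),
                      reason = character(), stringsAsFactors = FALSE)
  list(annotations = ann, rejections = rej)
}
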