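#' Match a tag against known mature miRNAs
#'
#' Compares the tag to every database entry of equal length by ungapped
#' Hamming distance and reports the entries within `maxMismatch`
#' mismatches (default 2, the standard mismatch tolerance for known
#' miRNA identification). Length variants and indels are deliberately
#' not matched.
#'
#' @param tag a single tag sequence (A/C/G/T/U).
#' @param matureDb data.frame from [readMatureDb] (columns `id`,
#'   `family`, `conserved`, `sequence`).
#' @param maxMismatch maximum Hamming distance (default 2).
#' @return data.frame with one row per match: `db_id`, `family`,
#'   `conserved`, `mismatches`, `best` (TRUE for the minimum-distance
#'   matches). Zero rows if nothing matches.
#' @export
matchKnown <- function(tag, matureDb, maxMismatch = 2L) {
  tag <- validateSeq(tag, what = "tag")
  tag <- chartr("U", "T", tag)
  cand <- which(nchar(matureDb$sequence) == nchar(tag))
  if (length(cand) == 0) return(emptyKnownMatch())
  tv <- utf8ToInt(tag)
  d <- vapply(cand, function(i)
    sum(utf8ToInt(matureDb$sequence[i]) != tv), integer(1))
  keep <- d <= maxMismatch
  cand <- cand[keep]
  d <- d[keep]
  if (length(cand) == 0) return(emptyKnownMatch())
  data.frame(db_id = matureDb$id[cand], family = matureDb$family[cand],
             conserved = matureDb$conserved[cand], mismatches = d,
             best = d == min(d), stringsAsFactors = FALSE,
             row.names = NULL)
}

emptyKnownMatch <- function() {
  data.frame(db_id = character(), family = character(),
             conserved = logical(), mismatches = integer(),
             best = logical(), stringsAsFactors = FALSE)
}

#' Assign every tag of a set to its best known miRNA
#'
#' Vectorised wrapper around [matchKnown]: each tag is assigned to its
#' minimum-mismatch database entry, with ties broken lexicographically
#' by family name and then by entry id, so the assignment is
#' deterministic.
#'
#' @param tags a [UniqueTagSet-class].
#' @param matureDb data.frame from [readMatureDb].
#' @param maxMismatch maximum Hamming distance (default 2).
#' @return data.frame with one row per matched tag: `tag_id` (index
#'   into `tags`), `sequence`, `db_id`, `family`, `conserved`,
#'   `mismatches`.
#' @export
assignKnown <- function(tags, matureDb, maxMismatch = 2L) {
  seqs <- tagSequences(tags)
  empty <- data.frame(tag_id = integer(), sequence = character(),
                      db_id = character(), family = character(),
                      conserved = logical(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0 || nrow(matureDb) == 0) return(empty)
  # deterministic tie-break order: family, then id
  dbOrd <- order(matureDb$family, matureDb$id)
  db <- matureDb[dbOrd, , drop = FALSE]
  tagLen <- nchar(seqs)
  dbLen <- nchar(db$sequence)
  rows <- vector("list", length(unique(tagLen)))
  li <- 0L
  for (L in sort(unique(tagLen))) {
    dIdx <- which(dbLen == L)
    if (length(dIdx) == 0) next
    tIdx <- which(tagLen == L)
    tagMat <- matrix(utf8ToInt(paste(seqs[tIdx], collapse = "")),
                     nrow = length(tIdx), ncol = L, byrow = TRUE)
    bestMm <- rep(maxMismatch + 1L, length(tIdx))
    bestDb <- rep(NA_integer_, length(tIdx))
    for (d in dIdx) {
      e <- utf8ToInt(db$sequence[d])
      mm <- as.integer(rowSums(tagMat != matrix(e, nrow = length(tIdx),
                                                ncol = L, byrow = TRUE)))
      # strict improvement keeps the first (lexicographically smallest)
      # entry among ties
      upd <- mm < bestMm
      bestMm[upd] <- mm[upd]
      bestDb[upd] <- d
    }
    hit <- !is.na(bestDb) & bestMm <= maxMismatch
    if (!any(hit)) next
    li <- li + 1L
    rows[[li]] <- data.frame(
      tag_id = tIdx[hit], sequence = seqs[tIdx[hit]],
      db_id = db$id[bestDb[hit]], family = db$family[bestDb[hit]],
      conserved = db$conserved[bestDb[hit]],
      mismatches = bestMm[hit], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(li)])
  if (is.null(out)) return(empty)
  out <- out[order(out$tag_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the known miRNA family expression table
#'
#' Aggregates assigned tags into one row per family with the member
#' count, per-library read sums, their total, and the BS/BR expression
#' ratio rounded half-away-from-zero to 2 decimals. Each tag
#' contributes once, under its best match. Ratio conventions: when
#' `reads_BR` is 0 the ratio is undefined and reported as `NA`
#' (rendered as an em dash in the TSV); when `reads_BS` is 0 the ratio
#' is 0.00.
#'
#' @param matches data.frame from [assignKnown] (a best match per tag).
#' @param tags the [UniqueTagSet-class] the matches refer to.
#' @return data.frame with columns `family`, `conserved`, `members`,
#'   `reads_BR`, `reads_BS`, `total`, `ratio`, sorted with conserved
#'   families first, then by family name.
#' @export
buildFamilyTable <- function(matches, tags) {
  if (nrow(matches) > 0 &&
      (any(matches$tag_id < 1) || any(matches$tag_id > length(tags))))
    stop("match refers to a tag outside the tag set")
  cnt <- tagCounts(tags)
  fams <- sort(unique(matches$family))
  rows <- lapply(fams, function(f) {
    m <- matches[matches$family == f, , drop = FALSE]
    br <- sum(cnt[m$tag_id, "BR"])
    bs <- sum(cnt[m$tag_id, "BS"])
    data.frame(family = f, conserved = m$conserved[1],
               members = length(unique(m$db_id)),
               reads_BR = br, reads_BS = bs, total = br + bs,
               ratio = familyRatio(br, bs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(family = character(), conserved = logical(),
                      members = integer(), reads_BR = integer(),
                      reads_BS = integer(), total = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  out <- out[order(!out$conserved, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# BS/BR expression ratio, 2 decimals, half away from zero;
# NA when BR = 0 (undefined), 0 when BS = 0.
familyRatio <- function(readsBR, readsBS) {
  if (readsBR == 0) return(NA_real_)
  roundHalfAway(readsBS / readsBR, 2L)
}

roundHalfAway <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Render the family table in its printable form
#'
#' Replaces the undefined ratio (`NA`, reads_BR = 0) with an em dash
#' and formats ratios with two decimals.
#'
#' @param familyTable data.frame from [buildFamilyTable].
#' @return data.frame with `ratio` as character.
#' @export
formatFamilyTable <- function(familyTable) {
  out <- familyTable
  out$ratio <- ifelse(is.na(out$ratio), "—",
                      sprintf("%.2f", out$ratio))
  out
}
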