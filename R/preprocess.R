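#' Classify raw reads, trim adapters, and collapse to unique tags
#'
#' Assigns every high-quality read of one library to exactly one of the
#' standard small RNA removal categories, trims the 3' adapter off the
#' clean reads, and collapses them to unique tags with counts.
#'
#' Classification, in precedence order:
#' \enumerate{
#'   \item reads whose mean Phred quality is below `qualityFloor` are
#'     dropped before categorisation (`raw` minus `high_quality`);
#'   \item `adapter5_contaminant`: the 5' adapter is found at the read
#'     start (ligation artifact);
#'   \item `insert_null`: the 3' adapter starts at position 1, i.e. the
#'     insert is empty (adapter dimer);
#'   \item `adapter3_null`: no 3' adapter is found and the read is too
#'     long (`> maxLen`) to be a complete untrimmed insert, or the
#'     adapter is only found beyond `maxLen`;
#'   \item `polyA`: the trimmed insert is >= 80\% adenine;
#'   \item `smaller_than_min`: the trimmed insert is shorter than
#'     `minLen`;
#'   \item `clean`: everything else, i.e. trimmed inserts with length in
#'     `[minLen, maxLen]`.
#' }
#' A read without any 3' adapter occurrence whose full length already
#' lies within the clean window is treated as an untrimmed insert and
#' classified from step 5 on; this makes trimming idempotent (re-running
#' on already-clean tags reports them all clean and unchanged).
#'
#' Adapter detection is seed-and-extend: the adapter's first 8 nt must
#' occur exactly, and the remaining overlapping adapter bases may
#' mismatch at most once.
#'
#' The category counts always satisfy the conservation identity
#' `clean + adapter3_null + insert_null + adapter5_contaminant +
#' smaller_than_min + polyA = high_quality`.
#'
#' @param reads character vector of read sequences, or a path to a
#'   FASTQ/FASTA file (see [readSrnaReads]).
#' @param adapter3,adapter5 adapter sequences (non-empty).
#' @param minLen,maxLen clean length window in nt (defaults 18 and 30).
#' @param qualityFloor minimum mean Phred score (default 20); only
#'   applied when qualities are available.
#' @param qualities optional character vector of Phred-33 quality
#'   strings parallel to `reads`.
#' @return A list with `tags`, a data.frame of unique clean tags
#'   (`sequence`, `count`), and `stats`, a named list of category
#'   counts plus `percent`, each category as percent of `high_quality`.
#' @examples
#' out <- classifyAndTrim(c("TGGATTGAAGGGAGCTCTACAAGATCGGAAGAGC"),
#'                        adapter3 = "AGATCGGAAGAGCACACGTC",
#'                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
#' out$tags
#' @export
classifyAndTrim <- function(reads, adapter3, adapter5,
                            minLen = 18L, maxLen = 30L,
                            qualityFloor = 20, qualities = NULL) {
  if (length(reads) == 1L && grepl("[^ACGTUNacgtun]", reads) &&
      file.exists(reads)) {
    parsed <- readSrnaReads(reads)
    reads <- parsed$sequences
    qualities <- parsed$qualities
  }
  if (nchar(adapter3) == 0 || nchar(adapter5) == 0)
    stop("adapters must be non-empty")
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  if (minLen >= maxLen) stop("minLen must be < maxLen")
  reads <- toupper(chartr("U", "T", as.character(reads)))

  nraw <- length(reads)
  if (nraw == 0) {
    stats <- emptyStats()
    return(list(tags = data.frame(sequence = character(),
                                  count = integer()), stats = stats))
  }

  keep <- rep(TRUE, nraw)
  if (!is.null(qualities)) {
    meanQ <- vapply(qualities,
                    function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                    USE.NAMES = FALSE)
    keep <- meanQ >= qualityFloor
  }
  hq <- reads[keep]
  nhq <- length(hq)

  category <- rep(NA_character_, nhq)
  insert <- rep(NA_character_, nhq)

  # 5' adapter at read start (seed-and-extend on the adapter5 prefix)
  a5pos <- adapterHit(hq, adapter5)
  is5 <- !is.na(a5pos) & a5pos == 1L
  category[is5] <- "adapter5_contaminant"

  todo <- which(is.na(category))
  a3pos <- adapterHit(hq[todo], adapter3)
  len <- nchar(hq[todo])

  hit <- !is.na(a3pos)
  insNull <- hit & a3pos == 1L
  category[todo[insNull]] <- "insert_null"
  # adapter absent and read too long to be a bare insert, or the
  # adapter only found beyond the clean window
  noAd <- !hit & len > maxLen
  lateAd <- hit & !insNull & (a3pos - 1L) > maxLen
  category[todo[noAd | lateAd]] <- "adapter3_null"

  rest <- is.na(category[todo])
  insert[todo[rest]] <- ifelse(hit[rest],
                               substr(hq[todo[rest]], 1L, a3pos[rest] - 1L),
                               hq[todo[rest]])

  todo2 <- which(is.na(category))
  ins <- insert[todo2]
  nA <- nchar(ins) - nchar(gsub("A", "", ins, fixed = TRUE))
  isPolyA <- nchar(ins) > 0 & nA >= 0.8 * nchar(ins)
  category[todo2[isPolyA]] <- "polyA"
  short <- !isPolyA & nchar(ins) < minLen
  category[todo2[short]] <- "smaller_than_min"
  category[todo2[!isPolyA & !short]] <- "clean"

  cleanSeq <- insert[category == "clean"]
  tab <- table(cleanSeq)
  tags <- data.frame(sequence = names(tab),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE, row.names = NULL)
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  cats <- c("clean", "adapter3_null", "insert_null",
            "adapter5_contaminant", "smaller_than_min", "polyA")
  counts <- vapply(cats, function(k) sum(category == k), integer(1))
  stats <- c(list(raw = nraw, high_quality = nhq), as.list(counts))
  stats$percent <- if (nhq > 0) round(100 * counts / nhq, 2) else counts * 0
  list(tags = tags, stats = stats)
}

emptyStats <- function() {
  cats <- c("clean", "adapter3_null", "insert_null",
            "adapter5_contaminant", "smaller_than_min", "polyA")
  s <- c(list(raw = 0L, high_quality = 0L),
         stats::setNames(as.list(integer(length(cats))), cats))
  s$percent <- stats::setNames(numeric(length(cats)), cats)
  s
}

# Leftmost seed-and-extend adapter hit: position of the adapter start in
# each read, or NA. Seed = first 8 nt (or the whole adapter if shorter)
# exact; extension allows <= 1 mismatch over the remaining overlap.
adapterHit <- function(reads, adapter) {
  seedLen <- min(8L, nchar(adapter))
  seed <- substr(adapter, 1L, seedLen)
  adTail <- substr(adapter, seedLen + 1L, nchar(adapter))
  extendOK <- function(read, pos) {
    if (nchar(adTail) == 0) return(TRUE)
    from <- pos + seedLen
    if (from > nchar(read)) return(TRUE)
    rt <- substr(read, from, min(nchar(read), from + nchar(adTail) - 1L))
    at <- substr(adTail, 1L, nchar(rt))
    sum(utf8ToInt(rt) != utf8ToInt(at)) <= 1L
  }
  p <- as.integer(regexpr(seed, reads, fixed = TRUE))
  out <- rep(NA_integer_, length(reads))
  for (i in which(p > 0)) {
    pos <- p[i]
    read <- reads[i]
    repeat {
      if (extendOK(read, pos)) {
        out[i] <- pos
        break
      }
      nxt <- regexpr(seed, substr(read, pos + 1L, nchar(read)),
                     fixed = TRUE)
      if (nxt < 0) break
      pos <- pos + as.integer(nxt)
    }
  }
  out
}

#' Read length distribution of unique tags
#'
#' Tabulates read counts (not unique-tag counts) by tag length and the
#' fraction of reads at each length. Fractions sum to 1.
#'
#' @param tags a [UniqueTagSet-class], or a data.frame with columns
#'   `sequence` and `count` as returned by [classifyAndTrim].
#' @return data.frame with columns `length`, `reads`, `fraction`,
#'   sorted by length; only observed lengths appear.
#' @export
lengthDistribution <- function(tags) {
  if (is(tags, "UniqueTagSet")) {
    if (length(tags) == 0) stop("empty tag set")
    len <- nchar(tagSequences(tags))
    cnt <- rowSums(tagCounts(tags))
  } else {
    if (nrow(tags) == 0) stop("empty tag set")
    len <- nchar(tags$sequence)
    cnt <- tags$count
  }
  agg <- tapply(cnt, len, sum)
  out <- data.frame(length = as.integer(names(agg)),
                    reads = as.numeric(agg), row.names = NULL)
  out$fraction <- out$reads / sum(out$reads)
  out[order(out$length), , drop = FALSE]
}

#' Combine per-library tag tables into a UniqueTagSet
#'
#' @param tagsBR,tagsBS data.frames with `sequence` and `count` columns
#'   from [classifyAndTrim] run on each library.
#' @return a [UniqueTagSet-class] over the union of sequences.
#' @export
combineLibraries <- function(tagsBR, tagsBS) {
  seqs <- sort(union(tagsBR$sequence, tagsBS$sequence))
  br <- tagsBR$count[match(seqs, tagsBR$sequence)]
  bs <- tagsBS$count[match(seqs, tagsBS$sequence)]
  br[is.na(br)] <- 0L
  bs[is.na(bs)] <- 0L
  uniqueTagSet(seqs, countBR = br, countBS = bs)
}
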