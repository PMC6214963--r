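#' Filter tags matching non-coding RNA classes
#'
#' Removes tags that are perfect substrings of a classed non-coding RNA
#' reference record (rRNA, tRNA, snRNA, snoRNA) on either strand,
#' before miRNA identification. Exact (0-mismatch) matching is the
#' deliberate, reproducible default; `maxMismatch` loosens it.
#'
#' A tag hitting records of several classes is annotated with the
#' highest-precedence class: rRNA > tRNA > snRNA > snoRNA.
#'
#' @param tags a [UniqueTagSet-class].
#' @param ncdb data.frame from [readNcDb] (columns `id`, `class`,
#'   `sequence`), or a path to such a FASTA.
#' @param maxMismatch allowed mismatches in the substring match
#'   (default 0, exact).
#' @return list with `removed`, a data.frame of annotations (`tag_id`,
#'   `sequence`, `class`, `db_id`, `strand`), and `kept`, the
#'   [UniqueTagSet-class] of surviving tags. `removed` and `kept`
#'   partition the input.
#' @export
filterNcRNA <- function(tags, ncdb, maxMismatch = 0L) {
  if (is.character(ncdb) && length(ncdb) == 1L) ncdb <- readNcDb(ncdb)
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  bad <- setdiff(unique(ncdb$class), classes)
  if (length(bad) > 0)
    stop("unknown ncRNA class label: ", paste(bad, collapse = ", "))
  n <- length(tags)
  emptyRemoved <- data.frame(tag_id = integer(), sequence = character(),
                             class = character(), db_id = character(),
                             strand = character(), stringsAsFactors = FALSE)
  if (n == 0 || nrow(ncdb) == 0)
    return(list(removed = emptyRemoved, kept = tags))

  seqs <- tagSequences(tags)
  subjects <- Biostrings::DNAStringSet(ncdb$sequence)

  # hits[t, r]: does tag t occur in record r (either strand)?
  countHits <- function(patterns) {
    # returns n_patterns x n_records logical matrix of substring hits
    out <- matrix(FALSE, length(patterns), nrow(ncdb))
    widths <- nchar(patterns)
    for (w in unique(widths)) {
      ii <- which(widths == w)
      if (maxMismatch == 0) {
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[ii]))
        cnt <- Biostrings::vcountPDict(pd, subjects)
        out[ii, ] <- cnt > 0
      } else {
        for (k in ii) {
          out[k, ] <- Biostrings::vcountPattern(
            patterns[k], subjects, max.mismatch = maxMismatch) > 0
        }
      }
    }
    out
  }
  fwd <- countHits(seqs)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)), use.names = FALSE)
  rev_ <- countHits(rc) # tag matches record minus strand

  any_ <- fwd | rev_
  hit <- rowSums(any_) > 0
  removedIdx <- which(hit)
  if (length(removedIdx) == 0)
    return(list(removed = emptyRemoved, kept = tags))

  prec <- match(ncdb$class, classes) # 1 = highest precedence
  ann <- t(vapply(removedIdx, function(t) {
    recs <- which(any_[t, ])
    best <- recs[order(prec[recs], recs)][1]
    c(class = ncdb$class[best], db_id = ncdb$id[best],
      strand = if (fwd[t, best]) "+" else "-")
  }, c(class = "", db_id = "", strand = "")))

  removed <- data.frame(tag_id = removedIdx, sequence = seqs[removedIdx],
                        class = ann[, "class"], db_id = ann[, "db_id"],
                        strand = ann[, "strand"], stringsAsFactors = FALSE,
                        row.names = NULL)
  keptIdx <- setdiff(seq_len(n), removedIdx)
  list(removed = removed, kept = tags[keptIdx])
}
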