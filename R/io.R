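#' Read small RNA reads from FASTQ or FASTA
#'
#' FASTQ files are structurally validated first (complete 4-line
#' records, matching sequence/quality lengths); a malformed record
#' raises an error naming the record index. Parsing itself is done with
#' Biostrings.
#'
#' @param path file path; format is taken from the extension
#'   (`.fastq`/`.fq` vs `.fasta`/`.fa`).
#' @return list with `sequences` (character) and `qualities` (character
#'   Phred-33 strings for FASTQ, otherwise `NULL`).
#' @export
readSrnaReads <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("fastq", "fq")) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
      stop("malformed FASTQ: truncated record ",
           floor(length(lines) / 4) + 1)
    idx <- seq(1, length(lines), by = 4)
    bad <- which(!startsWith(lines[idx], "@") |
                   !startsWith(lines[idx + 2], "+") |
                   nchar(lines[idx + 1]) != nchar(lines[idx + 3]))
    if (length(bad) > 0)
      stop("malformed FASTQ record ", bad[1], " in ", path)
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(sequences = as.character(x, use.names = FALSE),
         qualities = as.character(S4Vectors::mcols(x)$qualities,
                                  use.names = FALSE))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    list(sequences = as.character(x, use.names = FALSE), qualities = NULL)
  }
}

#' Read a mature miRNA database FASTA
#'
#' Headers follow the convention `id|family|conserved-flag`, e.g.
#' `lcy-miR159a|miR159|1`. The conserved flag (1/0) is optional and
#' defaults to conserved.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `family`, `conserved`,
#'   `sequence`.
#' @export
readMatureDb <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, "", 1),
    family = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], ""),
    conserved = vapply(parts, function(p)
      if (length(p) > 2) p[3] == "1" else TRUE, logical(1)),
    sequence = chartr("U", "T", toupper(as.character(x, use.names = FALSE))),
    stringsAsFactors = FALSE
  )
}

#' Read a non-coding RNA contaminant database FASTA
#'
#' Headers carry the ncRNA class after a `|` separator, e.g.
#' `RF00001_frag1|rRNA`. Allowed classes: rRNA, tRNA, snRNA, snoRNA.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `class`, `sequence`.
#' @export
readNcDb <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  cls <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  db <- data.frame(
    id = vapply(parts, `[`, "", 1),
    class = cls,
    sequence = chartr("U", "T", toupper(as.character(x, use.names = FALSE))),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(db$class), c("rRNA", "tRNA", "snRNA", "snoRNA"))
  if (length(bad) > 0 || anyNA(db$class))
    stop("ncRNA database has records with unknown class label: ",
         paste(bad, collapse = ", "))
  db
}

#' Write collapsed tags as FASTA
#'
#' One record per unique tag, header `tag<N>|<countBR>|<countBS>`.
#'
#' @param tags a [UniqueTagSet-class].
#' @param path output path.
#' @export
writeTagFasta <- function(tags, path) {
  seqs <- Biostrings::DNAStringSet(tagSequences(tags))
  cnt <- tagCounts(tags)
  names(seqs) <- sprintf("tag%d|%d|%d", seq_len(length(tags)),
                         cnt[, "BR"], cnt[, "BS"])
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read collapsed tags written by [writeTagFasta]
#' @param path FASTA path.
#' @return a [UniqueTagSet-class].
#' @export
readTagFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  uniqueTagSet(as.character(x, use.names = FALSE),
               countBR = as.integer(vapply(parts, `[`, "", 2)),
               countBS = as.integer(vapply(parts, `[`, "", 3)))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
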