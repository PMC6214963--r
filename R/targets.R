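#' Score a miRNA/target-site duplex with the expectation penalty
#'
#' Computes the plant-miRNA complementarity expectation E of an
#' explicit alignment between a miRNA and a candidate site: each
#' aligned miRNA position contributes 0 for a Watson-Crick pair, 0.5
#' for a G:U wobble, 1.0 for a mismatch; gaps (an unpaired miRNA base,
#' or a bulged site base) cost 2.0. All penalties are doubled in the
#' core region, miRNA positions 2-13 counted from the miRNA 5' end.
#' Lower E means a better target; 0 is perfect complementarity.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site target site on the transcript, 5'->3'.
#' @param alignment data.frame with integer columns `mirnaPos` and
#'   `sitePos` (NA marks a gap on that side), one row per duplex
#'   column. Every miRNA position must be covered; a miRNA position i
#'   pairs the site base at the aligned `sitePos`. Omitting
#'   `alignment` uses the ungapped antiparallel alignment, which
#'   requires equal lengths.
#' @param seedRange core positions with doubled penalties (default
#'   `c(2, 13)`).
#' @return the expectation score E (numeric >= 0).
#' @examples
#' # a site that is the exact reverse complement scores 0
#' scoreDuplex("TGGCATACGTTCAAGGAGAGC",
#'             site = revcompDNA("TGGCATACGTTCAAGGAGAGC"))
#' @export
scoreDuplex <- function(mirna, site, alignment = NULL,
                        seedRange = c(2L, 13L)) {
  mirna <- chartr("U", "T", validateSeq(mirna, "miRNA"))
  site <- chartr("U", "T", validateSeq(site, "site"))
  M <- nchar(mirna)
  S <- nchar(site)
  if (is.null(alignment)) {
    if (M != S)
      stop("without an explicit alignment, miRNA and site must have ",
           "equal length")
    # antiparallel: miRNA position i against site position S - i + 1
    alignment <- data.frame(mirnaPos = seq_len(M),
                            sitePos = S - seq_len(M) + 1L)
  }
  mp <- alignment$mirnaPos
  spos <- alignment$sitePos
  if (!setequal(stats::na.omit(mp), seq_len(M)))
    stop("alignment must cover every miRNA position exactly once")
  if (anyDuplicated(stats::na.omit(spos)) > 0)
    stop("alignment reuses a site position")
  w <- function(p) ifelse(p >= seedRange[1] & p <= seedRange[2], 2, 1)
  mb <- strsplit(mirna, "")[[1]]
  sb <- strsplit(site, "")[[1]]
  E <- 0
  for (r in seq_len(nrow(alignment))) {
    i <- mp[r]
    j <- spos[r]
    if (is.na(i)) {
      # bulged site base: attributed to the adjacent miRNA position on
      # its 5' side
      prv <- mp[seq_len(r - 1L)]
      prv <- prv[!is.na(prv)]
      p <- if (length(prv) > 0) max(prv) else 1L
      E <- E + 2 * w(p)
    } else if (is.na(j)) {
      E <- E + 2 * w(i)
    } else {
      pen <- duplexPenalty(mb[i], sb[j])
      E <- E + pen * w(i)
    }
  }
  E
}

# penalty of pairing a miRNA base with a site (mRNA) base:
# Watson-Crick 0, G:U wobble 0.5 (miRNA G against site T, or miRNA T
# against site G), otherwise mismatch 1
duplexPenalty <- function(m, s) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (wc[[m]] == s) return(0)
  if ((m == "G" && s == "T") || (m == "T" && s == "G")) return(0.5)
  1
}

#' Scan transcripts for miRNA target sites
#'
#' Slides the miRNA along every transcript and reports each site whose
#' best antiparallel alignment (dynamic programming, at most `maxGap`
#' gaps) has expectation E at or below `cutoff`. A transcript may
#' contribute several sites; overlapping hits of the same miRNA are
#' reduced to the best-scoring one. The inhibition mode is
#' `translation` when a mismatch or gap touches the central positions
#' 9-11 of the miRNA (the cleavage site), `cleavage` otherwise.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcripts named character vector of transcript sequences,
#'   or a `DNAStringSet`.
#' @param cutoff maximum E (default 3).
#' @param maxGap maximum gaps per site (default 1).
#' @param seedRange doubled-penalty core (default `c(2, 13)`).
#' @return data.frame with columns `mirna`, `transcript`, `start`,
#'   `end` (1-based inclusive), `E`, `inhibition`, `duplex` (a
#'   three-line rendering separated by `/`).
#' @export
scanTranscripts <- function(mirna, transcripts, cutoff = 3,
                            maxGap = 1L, seedRange = c(2L, 13L)) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  mirna <- chartr("U", "T", validateSeq(mirna, "miRNA"))
  if (is(transcripts, "DNAStringSet")) {
    tx <- as.character(transcripts)
  } else {
    tx <- transcripts
  }
  if (length(tx) == 0)
    return(emptyTargetFrame())
  if (is.null(names(tx)))
    names(tx) <- sprintf("tx%d", seq_along(tx))
  mcode <- encodeSeq(mirna)
  M <- length(mcode)
  rows <- list()
  for (t in seq_along(tx)) {
    seqT <- toupper(chartr("U", "T", tx[[t]]))
    if (grepl("[^ACGT]", seqT)) next
    hits <- .scanCpp(mcode, encodeSeq(seqT), cutoff, as.integer(maxGap),
                     as.integer(seedRange[1]), as.integer(seedRange[2]),
                     1.0, 0.5, 2.0)
    if (nrow(hits) == 0) next
    # collapse overlapping windows to the best site
    hits <- hits[order(hits$E, hits$start), , drop = FALSE]
    keep <- logical(nrow(hits))
    taken <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(nrow(hits))) {
      ov <- nrow(taken) > 0 &&
        any(hits$start[k] <= taken[, 2] & hits$end[k] >= taken[, 1])
      if (!ov) {
        keep[k] <- TRUE
        taken <- rbind(taken, c(hits$start[k], hits$end[k]))
      }
    }
    hits <- hits[keep, , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      site <- substr(seqT, hits$start[k], hits$end[k])
      dec <- decorateAlignment(mirna, site, hits$ops[k])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mirna, transcript = names(tx)[t],
        start = hits$start[k], end = hits$end[k], E = hits$E[k],
        inhibition = if (dec$centralDisrupted) "translation" else "cleavage",
        duplex = dec$duplex, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(emptyTargetFrame())
  rownames(out) <- NULL
  out
}

emptyTargetFrame <- function() {
  data.frame(mirna = character(), transcript = character(),
             start = integer(), end = integer(), E = numeric(),
             inhibition = character(), duplex = character(),
             stringsAsFactors = FALSE)
}

# ops come from the scanner 5'->3' along the miRNA (the traceback
# emits the miRNA 5'-end column first); rebuild the duplex rendering
# (miRNA 5'->3' on top, site 3'->5' below) and flag central (9-11)
# mismatches/gaps
decorateAlignment <- function(mirna, site, ops) {
  opv <- strsplit(ops, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]]) # site 3'->5'
  i <- 1L
  j <- 1L
  top <- character(0)
  mid <- character(0)
  bot <- character(0)
  central <- FALSE
  M <- length(mb)
  for (op in opv) {
    if (op %in% c("M", "W", "X")) {
      top <- c(top, mb[i])
      bot <- c(bot, sb[j])
      mid <- c(mid, c(M = "|", W = "o", X = " ")[[op]])
      if (op == "X" && i >= 9 && i <= 11) central <- TRUE
      i <- i + 1L
      j <- j + 1L
    } else if (op == "D") {
      top <- c(top, mb[i])
      bot <- c(bot, "-")
      mid <- c(mid, " ")
      if (i >= 9 && i <= 11) central <- TRUE
      i <- i + 1L
    } else { # I: site base bulged
      top <- c(top, "-")
      bot <- c(bot, sb[j])
      mid <- c(mid, " ")
      if (i >= 9 && i <= 11) central <- TRUE
      j <- j + 1L
    }
  }
  list(duplex = paste(paste(top, collapse = ""),
                      paste(mid, collapse = ""),
                      paste(bot, collapse = ""), sep = "/"),
       centralDisrupted = central)
}
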