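# Independent oracles used to freeze expected values. These share no
# code with the package implementation paths they check.

# ---- exhaustive folding oracle ------------------------------------
# enumerate every nested structure (min hairpin loop `minLoop`) and
# score it directly under the stacking model; returns the optimum
# energy and the maximum pair count among energy-optimal structures
bruteFold <- function(seq, minLoop = 3L) {
  seq <- chartr("T", "U", toupper(seq))
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  canPair <- function(x, y) {
    p <- paste0(b[x], b[y])
    p %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  pairE <- function(x, y) {
    p <- paste0(b[x], b[y])
    if (p %in% c("GC", "CG")) -3 else if (p %in% c("AU", "UA")) -2
    else if (p %in% c("GU", "UG")) -1 else 0
  }
  # all structures of region i..j as lists of pair matrices
  structs <- function(i, j) {
    if (j - i + 1 < 2) return(list(matrix(integer(0), ncol = 2)))
    out <- structs(i + 1, j) # i unpaired
    ks <- if (j >= i + minLoop + 1) (i + minLoop + 1):j else integer(0)
    for (k in ks) {
      if (!canPair(i, k)) next
      left <- structs(i + 1, k - 1)
      right <- structs(k + 1, j)
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- rbind(L, R, c(i, k))
    }
    out
  }
  energyOf <- function(pairs) {
    if (nrow(pairs) == 0) return(0)
    pt <- integer(n)
    pt[pairs[, 1]] <- pairs[, 2]
    pt[pairs[, 2]] <- pairs[, 1]
    e <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (j - i >= 2 && pt[i + 1] == j - 1) e <- e + pairE(i, j)
    }
    e
  }
  ss <- structs(1L, n)
  es <- vapply(ss, energyOf, numeric(1))
  emin <- min(es, 0)
  maxPairs <- if (length(ss)) max(vapply(ss[es == emin], nrow, integer(1)))
              else 0L
  list(energy = emin, maxPairs = maxPairs)
}

# ---- Audic-Claverie summation oracle ------------------------------
# direct log-space summation of the conditional distribution of y'
bruteAcPvalue <- function(x, y, N1, N2, sided = 2L) {
  r <- N2 / N1
  upper <- max(200L, 20L * (x + y + 10L))
  yy <- 0:upper
  lf <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
    lgamma(yy + 1) - (x + yy + 1) * log1p(r)
  f <- exp(lf)
  lo <- sum(f[yy <= y])
  hi <- sum(f[yy >= y])
  tail <- min(lo, hi)
  if (sided == 2L) min(1, 2 * tail) else min(1, tail)
}

# ---- exhaustive target-alignment oracle ---------------------------
# best expectation E over all alignments of the miRNA against every
# window of the transcript with at most maxGap gaps (gap = one
# unpaired miRNA base, or one bulged transcript base), scored with
# scoreDuplex (the small explicit-alignment scorer)
bruteTargetBest <- function(mirna, transcript, maxGap = 1L) {
  M <- nchar(mirna)
  Tn <- nchar(transcript)
  best <- Inf
  bestPerStart <- rep(Inf, Tn)
  for (s in seq_len(Tn)) {
    for (len in (M - maxGap):(M + maxGap)) {
      if (len < 1 || s + len - 1 > Tn) next
      site <- substr(transcript, s, s + len - 1)
      es <- c()
      if (len == M) {
        es <- c(es, scoreDuplex(mirna, site))
      }
      if (maxGap >= 1 && len == M - 1) {
        # one miRNA base unpaired at position g
        for (g in seq_len(M)) {
          al <- data.frame(
            mirnaPos = seq_len(M),
            sitePos = ifelse(seq_len(M) < g, len - seq_len(M) + 1,
                      ifelse(seq_len(M) == g, NA, len - seq_len(M) + 2)))
          es <- c(es, scoreDuplex(mirna, site, al))
        }
      }
      if (maxGap >= 1 && len == M + 1) {
        # one transcript base bulged between miRNA positions g and g+1
        for (g in 0:M) {
          mp <- c(seq_len(g), NA, if (g < M) (g + 1):M)
          sp <- integer(0)
          used <- len
          for (i in seq_along(mp)) {
            sp <- c(sp, used)
            used <- used - 1L
          }
          al <- data.frame(mirnaPos = mp, sitePos = sp)
          es <- c(es, scoreDuplex(mirna, site, al))
        }
      }
      if (length(es)) {
        bestPerStart[s] <- min(bestPerStart[s], min(es))
        best <- min(best, min(es))
      }
    }
  }
  list(best = best, perStart = bestPerStart)
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
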