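#' Configuration for the two-library small RNA simulation
#'
#' Holds every knob of the synthetic-data generator. The defaults are
#' the package's reference study conditions: two libraries of 1e5
#' reads, 30 planted known miRNA families of 2 members, 10 planted
#' novel hairpins (3 with a detectable miRNA*), read-length classes
#' dominated by 24-nt (unmapped siRNA-like background) and 21-nt
#' (miRNA) tags, Illumina small RNA adapters, and contaminant
#' proportions of roughly one percent adapter artifacts, a few percent
#' short fragments, and five percent ncRNA fragments.
#'
#' @slot rngSeed integer seed; identical seeds give byte-identical
#'   output files.
#' @slot nBackgroundRefs,refLength number and length (nt) of reference
#'   sequences; hairpins are embedded into these.
#' @slot nKnownFamilies,membersPerFamily planted known miRNA families.
#' @slot nNovelHairpins,nStarDetectable planted novel hairpins and how
#'   many of them also yield star (miRNA*) reads.
#' @slot libraryDepth reads per library.
#' @slot plantedFcPlan named numeric vector, miRNA id to true log2 fold
#'   change (BR over BS). Empty means: build the default plan (four
#'   known members and four novel miRNAs at fold changes +1, -1, +2,
#'   -2; everything else 0).
#' @slot contaminantFractions named numeric: proportions (of
#'   high-quality reads) for `adapter3_null`, `insert_null`,
#'   `adapter5_contaminant`, `smaller_than_min`, `polyA`, `ncRNA`.
#' @slot backgroundFractions named numeric, proportions of the clean
#'   pool: `unmapped` (siRNA-like 24-nt tags from loci outside the
#'   reference set - the dominant background, since a small EST/GSS
#'   reference captures few siRNA loci) and `mapped` (tags drawn from
#'   windows of the references themselves; 0 by default, available to
#'   stress the novel-miRNA specificity).
#' @slot adapter3,adapter5 adapter sequences.
#' @slot lowQualityFraction fraction of reads emitted with uniformly
#'   low base qualities.
#' @export
setClass("SimulationConfig",
  representation(
    rngSeed = "integer",
    nBackgroundRefs = "integer",
    refLength = "integer",
    nKnownFamilies = "integer",
    membersPerFamily = "integer",
    nNovelHairpins = "integer",
    nStarDetectable = "integer",
    libraryDepth = "integer",
    plantedFcPlan = "numeric",
    contaminantFractions = "numeric",
    backgroundFractions = "numeric",
    adapter3 = "character",
    adapter5 = "character",
    lowQualityFraction = "numeric"
  ),
  validity = function(object) {
    cf <- object@contaminantFractions
    if (any(cf < 0) || any(cf > 1) || sum(cf) >= 1)
      return("contaminant fractions must lie in [0,1] and sum to < 1")
    if (object@libraryDepth <= 0) return("libraryDepth must be > 0")
    if (object@nStarDetectable > object@nNovelHairpins)
      return("nStarDetectable cannot exceed nNovelHairpins")
    if (sum(object@backgroundFractions) >= 1)
      return("background fractions must sum to < 1")
    TRUE
  }
)

#' @rdname SimulationConfig-class
#' @param rngSeed,nBackgroundRefs,refLength,nKnownFamilies see slots.
#' @param membersPerFamily,nNovelHairpins,nStarDetectable see slots.
#' @param libraryDepth,plantedFcPlan,contaminantFractions see slots.
#' @param backgroundFractions,adapter3,adapter5,lowQualityFraction see
#'   slots.
#' @export
simulationConfig <- function(rngSeed = 1L,
                             nBackgroundRefs = 20L,
                             refLength = 2000L,
                             nKnownFamilies = 30L,
                             membersPerFamily = 2L,
                             nNovelHairpins = 10L,
                             nStarDetectable = 3L,
                             libraryDepth = 100000L,
                             plantedFcPlan = numeric(),
                             contaminantFractions = c(
                               adapter3_null = 0.010,
                               insert_null = 0.002,
                               adapter5_contaminant = 0.0005,
                               smaller_than_min = 0.027,
                               polyA = 0.0005,
                               ncRNA = 0.05),
                             backgroundFractions = c(unmapped = 0.52,
                                                     mapped = 0),
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             lowQualityFraction = 0.005) {
  new("SimulationConfig",
      rngSeed = as.integer(rngSeed),
      nBackgroundRefs = as.integer(nBackgroundRefs),
      refLength = as.integer(refLength),
      nKnownFamilies = as.integer(nKnownFamilies),
      membersPerFamily = as.integer(membersPerFamily),
      nNovelHairpins = as.integer(nNovelHairpins),
      nStarDetectable = as.integer(nStarDetectable),
      libraryDepth = as.integer(libraryDepth),
      plantedFcPlan = plantedFcPlan,
      contaminantFractions = contaminantFractions,
      backgroundFractions = backgroundFractions,
      adapter3 = adapter3, adapter5 = adapter5,
      lowQualityFraction = lowQualityFraction)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: depth", object@libraryDepth, "per library,",
      object@nKnownFamilies, "known families,",
      object@nNovelHairpins, "novel hairpins, seed",
      object@rngSeed, "\n")
})

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a single DNA sequence string
#' @param x a DNA sequence (character scalar).
#' @return the reverse complement, character scalar.
#' @export
revcompDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct a hairpin precursor around a mature miRNA
#'
#' Builds a stem-loop precursor that contains the mature sequence on
#' one arm and a star sequence (the reverse complement with `nBulges`
#' single-base insertions, giving star-side bulge loops) on the other,
#' joined by a non-pairing A/C loop, with a 2-nt 3' overhang. The
#' construction is verified by folding with the built-in folder: the
#' returned precursor's minimum-energy structure pairs every mature
#' position outside the planted bulges and reproduces exactly
#' `nBulges` duplex bulges. Bulge positions and the loop are drawn from
#' the current RNG state, so results are reproducible under
#' [set.seed]; construction is retried a bounded number of times and
#' an error is raised if no satisfying precursor is found.
#'
#' @param mature mature miRNA sequence, 18-25 nt, unambiguous
#'   A/C/G/T/U.
#' @param nBulges number of star-side bulges to plant (0-4).
#' @param loopLen loop length in nt (>= 3).
#' @param arm which arm carries the mature sequence ("5p" or "3p").
#' @param maxAttempts bound on construction retries.
#' @return list with `precursor`, `matureStart`, `matureLen`, `arm`,
#'   `star` (the star strand sequence), `starStart`, `starEnd`
#'   (its interval on the precursor), and `fold` (the verified
#'   [FoldResult-class]).
#' @examples
#' set.seed(42)
#' hp <- plantHairpin("TCGGACCAGGCTTCATTCCCC", nBulges = 1, loopLen = 8)
#' hp$fold
#' @export
plantHairpin <- function(mature, nBulges = 0L, loopLen = 6L,
                         arm = c("5p", "3p"), maxAttempts = 60L) {
  arm <- match.arg(arm)
  mature <- validateSeq(mature, what = "mature")
  mature <- chartr("U", "T", mature)
  L <- nchar(mature)
  if (L < 18 || L > 25) stop("mature must be 18-25 nt, got ", L)
  nBulges <- as.integer(nBulges)
  if (nBulges < 0 || nBulges > 4) stop("nBulges must be in 0..4")
  if (loopLen < 3) stop("loopLen must be >= 3")
  star0 <- revcompDNA(mature)
  for (attempt in seq_len(maxAttempts)) {
    loop <- randSeq(loopLen, c("A", "C"))
    over <- randSeq(2L, c("A", "C"))
    star <- star0
    if (nBulges > 0) {
      # insertion gaps strictly inside the star, pairwise non-adjacent
      ok <- FALSE
      for (k in seq_len(20)) {
        gaps <- sort(sample(4:(L - 4), nBulges))
        if (nBulges == 1 || min(diff(gaps)) >= 3) { ok <- TRUE; break }
      }
      if (!ok) next
      chars <- strsplit(star0, "")[[1]]
      out <- character(0)
      prev <- 0L
      for (g in gaps) {
        ins <- pickNonPairing(chars[g], chars[g + 1])
        out <- c(out, chars[(prev + 1):g], ins)
        prev <- g
      }
      star <- paste(c(out, chars[(prev + 1):L]), collapse = "")
    }
    if (arm == "5p") {
      precursor <- paste0(mature, loop, star, over)
      matureStart <- 1L
    } else {
      precursor <- paste0(star, loop, mature, over)
      matureStart <- nchar(star) + loopLen + 1L
    }
    fr <- foldRNA(precursor)
    ds <- duplexStats(fr, matureStart, L)
    if (!ds$flagged && ds$overlap_bp >= min(16L, L) &&
        identical(ds$n_bulges, nBulges) && mfe(fr) <= -18) {
      return(list(precursor = precursor, matureStart = matureStart,
                  matureLen = L, arm = arm, star = star,
                  starStart = ds$star_start, starEnd = ds$star_end,
                  fold = fr))
    }
  }
  stop("could not construct a verifiable hairpin for this mature ",
       "sequence within ", maxAttempts, " attempts")
}

# a base that pairs (Watson-Crick or wobble) with neither neighbour,
# if one exists; otherwise the least-pairing fallback
pickNonPairing <- function(n1, n2) {
  partners <- c(A = "T", C = "G", G = "CT", T = "AG")
  forbidden <- unlist(strsplit(c(partners[[n1]], partners[[n2]]), ""))
  free <- setdiff(c("A", "C"), forbidden)
  if (length(free) > 0) return(free[1])
  free <- setdiff(c("G", "T"), forbidden)
  if (length(free) > 0) return(free[1])
  "A"
}

#' Simulate the two small RNA libraries with known ground truth
#'
#' Generates reference sequences with embedded hairpin precursors, a
#' known mature miRNA database, an ncRNA contaminant database, and two
#' read libraries ("BR" and "BS") whose per-category proportions follow
#' the configured contaminant fractions and whose per-miRNA counts have
#' expectation ratio `2^fc` between the libraries for every planted
#' fold change. Counts are multinomial at the configured depth over a
#' species table whose miRNA abundances are log-normal, reproducing
#' heavy-tailed family expression without claiming a particular real
#' distribution.
#'
#' @param config a [SimulationConfig-class].
#' @return An object of class `SrnaSimulation`: a list with `refs`
#'   (named character), `matureDb`, `ncDb` (data.frames),
#'   `readsBR`/`readsBS` and `qualBR`/`qualBS` (character vectors),
#'   `truth` (the truth table data.frame), `hairpins` (construction
#'   details per planted hairpin), and `config`.
#' @export
simulateLibraries <- function(config) {
  validObject(config)
  if (config@nBackgroundRefs < 1) stop("need at least one reference")
  set.seed(config@rngSeed)
  cfg <- config

  refs <- vapply(seq_len(cfg@nBackgroundRefs),
                 function(i) randSeq(cfg@refLength), "")
  names(refs) <- sprintf("ref%02d", seq_along(refs))

  ## known mature database
  matureLens <- sample(c(20L, 21L, 22L, 24L), cfg@nKnownFamilies,
                       replace = TRUE, prob = c(0.15, 0.55, 0.15, 0.15))
  knownIds <- character(0)
  knownRows <- list()
  for (f in seq_len(cfg@nKnownFamilies)) {
    fam <- sprintf("miRsim%02d", f)
    for (m in seq_len(cfg@membersPerFamily)) {
      id <- sprintf("%s%s", fam, letters[m])
      knownRows[[length(knownRows) + 1L]] <- data.frame(
        id = id, family = fam, conserved = f <= ceiling(cfg@nKnownFamilies * 0.8),
        sequence = randSeq(matureLens[f]), stringsAsFactors = FALSE)
      knownIds <- c(knownIds, id)
    }
  }
  matureDb <- do.call(rbind, knownRows)

  ## novel hairpins embedded in the references
  hairpins <- list()
  usedIv <- replicate(length(refs), cbind(start = integer(0),
                                          end = integer(0)),
                      simplify = FALSE)
  novelIds <- character(0)
  if (cfg@nNovelHairpins > 0) {
    for (i in seq_len(cfg@nNovelHairpins)) {
      id <- sprintf("nov%02d", i)
      novelIds <- c(novelIds, id)
      refIdx <- ((i - 1L) %% length(refs)) + 1L
      planted <- FALSE
      for (attempt in seq_len(40L)) {
        matLen <- sample(20:23, 1, prob = c(0.15, 0.55, 0.15, 0.15))
        mat <- randSeq(matLen)
        # keep novels clearly away from the known database
        if (nrow(assignKnown(uniqueTagSet(mat, 1L, 0L), matureDb)) > 0)
          next
        hp <- tryCatch(
          plantHairpin(mat, nBulges = sample(0:3, 1),
                       loopLen = sample(6:14, 1),
                       arm = sample(c("5p", "3p"), 1)),
          error = function(e) NULL)
        if (is.null(hp)) next
        pos <- placeInterval(nchar(refs[refIdx]), nchar(hp$precursor),
                             usedIv[[refIdx]])
        candidateRef <- paste0(substr(refs[refIdx], 1, pos - 1),
                               hp$precursor,
                               substr(refs[refIdx],
                                      pos + nchar(hp$precursor),
                                      nchar(refs[refIdx])))
        # self-consistency: the hairpin must still be accepted when
        # folded in its genomic context (flanking sequence can perturb
        # the minimum-energy structure)
        probe <- uniqueTagSet(mat, 10L, 10L)
        found <- findNovelMirnas(probe,
                                 stats::setNames(candidateRef,
                                                 names(refs)[refIdx]))
        if (nrow(found$annotations) == 0) next
        refs[refIdx] <- candidateRef
        usedIv[[refIdx]] <- rbind(usedIv[[refIdx]],
                                  cbind(start = pos,
                                        end = pos + nchar(hp$precursor) - 1L))
        hp$id <- id
        hp$ref <- names(refs)[refIdx]
        hp$refStart <- pos
        hp$starDetectable <- i <= cfg@nStarDetectable
        hairpins[[i]] <- hp
        planted <- TRUE
        break
      }
      if (!planted)
        stop("could not plant a context-verified hairpin for ", id)
    }
  }

  ## plant two perfect target sites for the first two known members
  if (nrow(matureDb) >= 2) {
    for (k in 1:2) {
      site <- revcompDNA(matureDb$sequence[k])
      refIdx <- length(refs) - k + 1L
      pos <- placeInterval(nchar(refs[refIdx]), nchar(site),
                           usedIv[[refIdx]])
      usedIv[[refIdx]] <- rbind(usedIv[[refIdx]],
                                cbind(start = pos,
                                      end = pos + nchar(site) - 1L))
      refs[refIdx] <- paste0(substr(refs[refIdx], 1, pos - 1), site,
                             substr(refs[refIdx], pos + nchar(site),
                                    nchar(refs[refIdx])))
    }
  }

  ## ncRNA contaminant database
  ncRows <- list()
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    for (j in 1:3) {
      ncRows[[length(ncRows) + 1L]] <- data.frame(
        id = sprintf("%s_rec%d", cl, j), class = cl,
        sequence = randSeq(120L), stringsAsFactors = FALSE)
    }
  }
  ncDb <- do.call(rbind, ncRows)

  ## fold-change plan
  plan <- cfg@plantedFcPlan
  if (length(plan) == 0) {
    plan <- defaultFcPlan(knownIds, novelIds)
  }
  allMirIds <- c(knownIds, novelIds)
  fc <- stats::setNames(rep(0, length(allMirIds)), allMirIds)
  fc[names(plan)[names(plan) %in% allMirIds]] <-
    plan[names(plan) %in% allMirIds]

  ## species table: every distinct read sequence with per-library
  ## expected proportions
  species <- buildSpeciesTable(cfg, matureDb, hairpins, refs, ncDb, fc)

  ## draw the libraries
  pBR <- species$wBR / sum(species$wBR)
  pBS <- species$wBS / sum(species$wBS)
  cntBR <- as.integer(rmultinom(1, cfg@libraryDepth, pBR))
  cntBS <- as.integer(rmultinom(1, cfg@libraryDepth, pBS))
  mkLib <- function(cnt) {
    idx <- rep.int(seq_len(nrow(species)), cnt)
    idx <- sample(idx) # seeded shuffle
    reads <- species$read[idx]
    qual <- ifelse(species$lowq[idx],
                   strrep("#", nchar(reads)), strrep("I", nchar(reads)))
    list(reads = reads, qual = qual)
  }
  libBR <- mkLib(cntBR)
  libBS <- mkLib(cntBS)

  ## truth table
  mir <- species[species$type == "mirna" & !species$variant, , drop = FALSE]
  truth <- data.frame(
    id = mir$id,
    sequence = mir$insert,
    kind = mir$kind,
    family = mir$family,
    arm = mir$arm,
    ref = mir$ref,
    precursor_start = mir$precStart,
    precursor_end = mir$precEnd,
    expected_BR = cfg@libraryDepth * species$wBR[species$type == "mirna" &
                                                   !species$variant] /
      sum(species$wBR),
    expected_BS = cfg@libraryDepth * species$wBS[species$type == "mirna" &
                                                   !species$variant] /
      sum(species$wBS),
    true_fc = fc[mir$id],
    star_planted = mir$starPlanted,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(refs = refs, matureDb = matureDb, ncDb = ncDb,
                 readsBR = libBR$reads, qualBR = libBR$qual,
                 readsBS = libBS$reads, qualBS = libBS$qual,
                 truth = truth, hairpins = hairpins, config = cfg),
            class = "SrnaSimulation")
}

defaultFcPlan <- function(knownIds, novelIds) {
  plan <- numeric(0)
  fcs <- c(1, -1, 2, -2)
  if (length(knownIds) >= 4)
    plan <- c(plan, stats::setNames(fcs, knownIds[seq_len(4)]))
  if (length(novelIds) >= 4)
    plan <- c(plan, stats::setNames(fcs, novelIds[seq_len(4)]))
  plan
}

placeInterval <- function(refLen, width, used, margin = 40L) {
  for (k in seq_len(200)) {
    pos <- sample(margin:(refLen - width - margin), 1)
    if (nrow(used) == 0 ||
        all(pos + width - 1L < used[, "start"] - margin |
              pos > used[, "end"] + margin))
      return(pos)
  }
  stop("could not place an interval of width ", width,
       " in a reference of length ", refLen)
}

# one row per distinct read sequence; wBR/wBS are unnormalised
# sampling weights per library
buildSpeciesTable <- function(cfg, matureDb, hairpins, refs, ncDb, fc) {
  rows <- list()
  add <- function(read, insert, type, id = NA_character_,
                  kind = NA_character_, family = NA_character_,
                  arm = NA_character_, ref = NA_character_,
                  precStart = NA_integer_, precEnd = NA_integer_,
                  starPlanted = FALSE, variant = FALSE,
                  wBR = 0, wBS = 0, lowq = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      read = read, insert = insert, type = type, id = id, kind = kind,
      family = family, arm = arm, ref = ref, precStart = precStart,
      precEnd = precEnd, starPlanted = starPlanted, variant = variant,
      wBR = wBR, wBS = wBS, lowq = lowq, stringsAsFactors = FALSE)
  }
  a3 <- cfg@adapter3
  cf <- cfg@contaminantFractions
  bg <- cfg@backgroundFractions
  cleanFrac <- 1 - sum(cf)
  mirFrac <- cleanFrac * (1 - sum(bg))

  ## miRNA pool: known members (+ a 1-mismatch variant each), novel
  ## matures, star reads
  mirPool <- list()
  baseAbund <- function() rlnorm(1, meanlog = log(100), sdlog = 1)
  for (i in seq_len(nrow(matureDb))) {
    id <- matureDb$id[i]
    w <- if (fc[id] != 0) 600 else baseAbund()
    mirPool[[length(mirPool) + 1L]] <- list(
      id = id, seq = matureDb$sequence[i], kind = "known",
      family = matureDb$family[i], arm = NA, ref = NA,
      precStart = NA, precEnd = NA, star = FALSE, w = w)
  }
  for (hp in hairpins) {
    w <- if (fc[hp$id] != 0) 600 else baseAbund()
    mirPool[[length(mirPool) + 1L]] <- list(
      id = hp$id, seq = substr(hp$precursor, hp$matureStart,
                               hp$matureStart + hp$matureLen - 1L),
      kind = "novel", family = NA, arm = hp$arm, ref = hp$ref,
      precStart = hp$refStart,
      precEnd = hp$refStart + nchar(hp$precursor) - 1L,
      star = isTRUE(hp$starDetectable), w = w)
  }
  for (sp in mirPool) {
    f <- fc[sp$id]
    wBR <- sp$w * 2^(f / 2)
    wBS <- sp$w * 2^(-f / 2)
    add(paste0(sp$seq, a3), sp$seq, "mirna", id = sp$id, kind = sp$kind,
        family = sp$family, arm = sp$arm, ref = sp$ref,
        precStart = sp$precStart, precEnd = sp$precEnd,
        starPlanted = sp$star, wBR = wBR, wBS = wBS)
    # sequencing-noise variant at Hamming distance 1 (still within the
    # known-matching tolerance); deterministic position
    v <- mutateOne(sp$seq)
    add(paste0(v, a3), v, "mirna_variant", id = sp$id, kind = sp$kind,
        family = sp$family, variant = TRUE,
        wBR = 0.08 * wBR, wBS = 0.08 * wBS)
  }
  for (hp in hairpins) {
    if (!isTRUE(hp$starDetectable)) next
    f <- fc[hp$id]
    add(paste0(hp$star, a3), hp$star, "star", id = paste0(hp$id, "*"),
        kind = "star", ref = hp$ref,
        wBR = 40 * 2^(f / 2), wBS = 40 * 2^(-f / 2))
  }

  ## background: unmapped siRNA-like tags (24-nt dominant) and mapped
  ## reference windows
  nUn <- 3000L
  unLens <- sample(c(23L, 24L, 25L), nUn, replace = TRUE,
                   prob = c(0.12, 0.76, 0.12))
  unW <- rlnorm(nUn, 0, 1)
  unW <- unW / sum(unW) * cleanFrac * bg[["unmapped"]]
  for (i in seq_len(nUn)) {
    s <- randSeq(unLens[i])
    add(paste0(s, a3), s, "background", wBR = unW[i], wBS = unW[i])
  }
  if (bg[["mapped"]] > 0) {
    nMap <- 50L
    mapW <- rlnorm(nMap, 0, 1)
    mapW <- mapW / sum(mapW) * cleanFrac * bg[["mapped"]]
    refLens <- nchar(refs)
    for (i in seq_len(nMap)) {
      r <- sample(length(refs), 1)
      wdt <- sample(c(21L, 24L), 1, prob = c(0.35, 0.65))
      st <- sample(refLens[r] - wdt, 1)
      s <- substr(refs[r], st, st + wdt - 1L)
      add(paste0(s, a3), s, "background_mapped", ref = names(refs)[r],
          wBR = mapW[i], wBS = mapW[i])
    }
  }

  ## ncRNA fragments
  nNc <- 300L
  ncW <- rlnorm(nNc, 0, 1)
  ncW <- ncW / sum(ncW) * cf[["ncRNA"]]
  for (i in seq_len(nNc)) {
    r <- sample(nrow(ncDb), 1)
    wdt <- sample(18:28, 1)
    st <- sample(nchar(ncDb$sequence[r]) - wdt, 1)
    s <- substr(ncDb$sequence[r], st, st + wdt - 1L)
    add(paste0(s, a3), s, "ncrna", id = ncDb$id[r],
        wBR = ncW[i], wBS = ncW[i])
  }

  ## removal-category reads
  if (cf[["adapter3_null"]] > 0) {
    for (i in 1:20) add(randSeqNoAdapter(34L, a3), NA_character_,
                        "adapter3_null",
                        wBR = cf[["adapter3_null"]] / 20,
                        wBS = cf[["adapter3_null"]] / 20)
  }
  if (cf[["insert_null"]] > 0)
    add(a3, "", "insert_null", wBR = cf[["insert_null"]],
        wBS = cf[["insert_null"]])
  if (cf[["adapter5_contaminant"]] > 0) {
    for (i in 1:5) add(paste0(cfg@adapter5, randSeq(21L), a3),
                       NA_character_, "adapter5",
                       wBR = cf[["adapter5_contaminant"]] / 5,
                       wBS = cf[["adapter5_contaminant"]] / 5)
  }
  if (cf[["smaller_than_min"]] > 0) {
    for (i in 1:20) {
      s <- randSeq(sample(10:17, 1))
      add(paste0(s, a3), s, "short", wBR = cf[["smaller_than_min"]] / 20,
          wBS = cf[["smaller_than_min"]] / 20)
    }
  }
  if (cf[["polyA"]] > 0)
    add(paste0(strrep("A", 24L), a3), strrep("A", 24L), "polyA",
        wBR = cf[["polyA"]], wBS = cf[["polyA"]])

  ## low-quality reads (removed before categorisation)
  if (cfg@lowQualityFraction > 0) {
    for (i in 1:5) add(paste0(randSeq(21L), a3), NA_character_, "lowq",
                       wBR = cfg@lowQualityFraction / 5,
                       wBS = cfg@lowQualityFraction / 5, lowq = TRUE)
  }

  out <- do.call(rbind, rows)
  # normalise the miRNA pool (matures + variants + stars) to exactly
  # its share of the clean pool, per library; with a balanced
  # fold-change plan the two libraries' pool sums are equal and every
  # per-miRNA expectation ratio is exactly 2^fc
  pool <- out$type %in% c("mirna", "mirna_variant", "star")
  out$wBR[pool] <- out$wBR[pool] * mirFrac / sum(out$wBR[pool])
  out$wBS[pool] <- out$wBS[pool] * mirFrac / sum(out$wBS[pool])
  # low-quality reads sit on top of the unit budget: rescale the rest
  if (cfg@lowQualityFraction > 0) {
    lq <- cfg@lowQualityFraction
    out$wBR[!out$lowq] <- out$wBR[!out$lowq] * (1 - lq)
    out$wBS[!out$lowq] <- out$wBS[!out$lowq] * (1 - lq)
  }
  out
}

mutateOne <- function(seq) {
  pos <- (nchar(seq) %/% 2L)
  base <- substr(seq, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), base)[1]
  paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
}

randSeqNoAdapter <- function(n, adapter) {
  seed <- substr(adapter, 1, 8)
  repeat {
    s <- randSeq(n)
    if (!grepl(seed, s, fixed = TRUE)) return(s)
  }
}

#' Write a simulation bundle to disk
#'
#' Produces `reads_BR.fastq`, `reads_BS.fastq`, `refs.fasta`,
#' `mature_db.fasta`, `ncdb.fasta`, `truth.tsv` and `config.yaml` in
#' `dir`. Identical configurations (including the seed) give
#' byte-identical files.
#'
#' @param sim result of [simulateLibraries].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastq <- function(reads, qual, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("read%d", seq_along(x))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  writeFastq(sim$readsBR, sim$qualBR, file.path(dir, "reads_BR.fastq"))
  writeFastq(sim$readsBS, sim$qualBS, file.path(dir, "reads_BS.fastq"))
  refs <- Biostrings::DNAStringSet(sim$refs)
  Biostrings::writeXStringSet(refs, file.path(dir, "refs.fasta"))
  mat <- Biostrings::DNAStringSet(sim$matureDb$sequence)
  names(mat) <- sprintf("%s|%s|%d", sim$matureDb$id, sim$matureDb$family,
                        as.integer(sim$matureDb$conserved))
  Biostrings::writeXStringSet(mat, file.path(dir, "mature_db.fasta"))
  nc <- Biostrings::DNAStringSet(sim$ncDb$sequence)
  names(nc) <- sprintf("%s|%s", sim$ncDb$id, sim$ncDb$class)
  Biostrings::writeXStringSet(nc, file.path(dir, "ncdb.fasta"))
  writeTsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  yaml::write_yaml(list(
    rng_seed = cfg@rngSeed, n_background_refs = cfg@nBackgroundRefs,
    ref_length = cfg@refLength, n_known_families = cfg@nKnownFamilies,
    members_per_family = cfg@membersPerFamily,
    n_novel_hairpins = cfg@nNovelHairpins,
    n_star_detectable = cfg@nStarDetectable,
    library_depth = cfg@libraryDepth,
    planted_fc_plan = as.list(cfg@plantedFcPlan),
    contaminant_fractions = as.list(cfg@contaminantFractions),
    background_fractions = as.list(cfg@backgroundFractions),
    adapter3 = cfg@adapter3, adapter5 = cfg@adapter5,
    low_quality_fraction = cfg@lowQualityFraction),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
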