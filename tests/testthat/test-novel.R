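test_that("excision windows follow the two arm hypotheses", {
  set.seed(90)
  refs <- c(refA = randomSeq(1000))
  tagSeq <- substr(refs[["refA"]], 100, 120) # 21-mer at position 100
  hits <- data.frame(ref = "refA", start = 100L, strand = "+",
                     stringsAsFactors = FALSE)
  cands <- exciseCandidates(tagSeq, hits, refs)
  expect_length(cands, 2L)
  hyp5 <- cands[[which(vapply(cands, `[[`, "", "armHyp") == "5p")]]
  hyp3 <- cands[[which(vapply(cands, `[[`, "", "armHyp") == "3p")]]
  expect_equal(c(hyp5$start, hyp5$end), c(90L, 280L))
  expect_equal(c(hyp3$start, hyp3$end), c(1L, 130L)) # clipped at 1
  expect_equal(substr(hyp5$sequence, hyp5$matureStart,
                      hyp5$matureStart + 20L), tagSeq)
  expect_equal(substr(hyp3$sequence, hyp3$matureStart,
                      hyp3$matureStart + 20L), tagSeq)

  # no mapping positions: no candidates
  none <- exciseCandidates(tagSeq, hits[0, ], refs)
  expect_length(none, 0L)

  # a window that clips below 50 nt is discarded with a reason
  shortRef <- c(s = randomSeq(40))
  h2 <- data.frame(ref = "s", start = 10L, strand = "+",
                   stringsAsFactors = FALSE)
  c2 <- exciseCandidates(substr(shortRef[["s"]], 10, 30), h2, shortRef)
  expect_length(c2, 0L)
  expect_length(attr(c2, "discarded"), 2L)
})

test_that("mapTagsToRefs finds plus and minus strand hits", {
  set.seed(91)
  refs <- c(r1 = randomSeq(500))
  fwd <- substr(refs[["r1"]], 50, 70)
  rev_ <- revcompDNA(substr(refs[["r1"]], 200, 221))
  tags <- uniqueTagSet(c(fwd, rev_), c(5L, 5L), c(5L, 5L))
  hits <- mapTagsToRefs(tags, refs)
  expect_true(any(hits$tag_id == 1 & hits$start == 50 & hits$strand == "+"))
  expect_true(any(hits$tag_id == 2 & hits$start == 200 & hits$strand == "-"))
})

test_that("rejection reasons are specific and machine-readable", {
  set.seed(92)
  mat <- randomSeq(21)
  hp <- plantHairpin(mat, nBulges = 0, loopLen = 8)
  tags <- uniqueTagSet(mat, 20L, 20L)
  base <- list(ref = "r", start = 1L, end = nchar(hp$precursor),
               strand = "+", sequence = hp$precursor,
               matureStart = hp$matureStart, matureLen = 21L,
               fold = hp$fold)

  # 26-nt mature: outside the published 18-25 gate
  long <- base
  long$matureLen <- 26L
  expect_equal(evaluateCandidate(long, tags)$reason, "mature_length")

  # truncated duplex: loosen nothing else, just shorten the overlap
  crit <- mirnaCriteria(minOverlap = 22L) # impossible for a 21-mer
  expect_equal(evaluateCandidate(base, tags, crit)$reason, "min_overlap")

  # insufficient read support
  lowTags <- uniqueTagSet(mat, 1L, 1L)
  expect_equal(evaluateCandidate(base, lowTags)$reason, "min_reads")

  # energy bound: demand an unattainably stable precursor
  critE <- mirnaCriteria(maxEnergy = -500)
  expect_equal(evaluateCandidate(base, tags, critE)$reason, "mfe")
})

test_that("star detection reflects planted star reads", {
  set.seed(93)
  mat <- randomSeq(21)
  hp <- plantHairpin(mat, nBulges = 1, loopLen = 9)
  cand <- list(ref = "r", start = 1L, end = nchar(hp$precursor),
               strand = "+", sequence = hp$precursor,
               matureStart = hp$matureStart, matureLen = 21L,
               fold = hp$fold)
  noStar <- uniqueTagSet(mat, 30L, 30L)
  withStar <- uniqueTagSet(c(mat, hp$star), c(30L, 4L), c(30L, 3L))
  expect_false(evaluateCandidate(cand, noStar)$annotation$star_detected)
  expect_true(evaluateCandidate(cand, withStar)$annotation$star_detected)
  # the star requirement gate
  crit <- mirnaCriteria(requireStar = TRUE)
  expect_equal(evaluateCandidate(cand, noStar, crit)$reason,
               "star_required")
  expect_true(evaluateCandidate(cand, withStar, crit)$accepted)
})

test_that("acceptance is monotone when thresholds are loosened", {
  set.seed(94)
  refs <- c(rr = randomSeq(3000))
  tags <- character(0)
  for (i in 1:40) {
    s <- sample(2950, 1)
    tags <- c(tags, substr(refs[["rr"]], s, s + sample(20:23, 1)))
  }
  tags <- unique(tags)
  ts <- uniqueTagSet(tags, rep(6L, length(tags)), rep(6L, length(tags)))
  strict <- findNovelMirnas(ts, refs, mirnaCriteria())
  loose <- findNovelMirnas(ts, refs,
                           mirnaCriteria(minOverlap = 12L,
                                         maxBulges = 6L,
                                         maxEnergy = -10))
  strictKeys <- paste(strict$annotations$mature,
                      strict$annotations$location)
  looseKeys <- paste(loose$annotations$mature,
                     loose$annotations$location)
  expect_true(all(strictKeys %in% looseKeys))
})

test_that("accepted records satisfy the annotation invariants", {
  pipe <- acceptancePipeline()
  ann <- pipe$novel$annotations
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$length == nchar(ann$mature)))
  expect_true(all(ann$length >= 18 & ann$length <= 25))
  expect_true(all(ann$MFE <= -18))
  expect_true(all(ann$LP >= ann$length))
  expect_true(all(ann$arm %in% c("5p", "3p")))
  expect_true(all(ann$reads_BR + ann$reads_BS >= 5))
})

test_that("background specificity: few random mapped tags pass the gates", {
  # the hairpin criteria under the built-in folder accept a small
  # fraction of arbitrary genomic tags; this pins the rate down
  set.seed(95)
  refs <- stats::setNames(
    vapply(1:10, function(i) randomSeq(2000), ""),
    sprintf("bg%02d", 1:10))
  tags <- character(0)
  for (i in 1:250) {
    r <- sample(10, 1)
    w <- sample(c(21L, 24L), 1)
    s <- sample(2000 - w, 1)
    tags <- c(tags, substr(refs[[r]], s, s + w - 1L))
  }
  tags <- unique(tags)
  ts <- uniqueTagSet(tags, rep(5L, length(tags)), rep(5L, length(tags)))
  nv <- findNovelMirnas(ts, refs)
  expect_lt(nrow(nv$annotations) / length(tags), 0.05)
})

test_that("ingesting published records reproduces their lengths", {
  rows <- novelMirnaRows()
  for (r in seq_len(nrow(rows))) {
    ann <- mirnaAnnotation(rows$name[r], rows$mature[r], rows$arm[r],
                           LP = rows$LP[r], MFE = rows$MFE[r])
    expect_equal(ann$length, rows$length[r], info = rows$name[r])
  }
  expect_error(mirnaAnnotation("x", randomSeq(26), "5p", 100, -30),
               "outside the gate")
})
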