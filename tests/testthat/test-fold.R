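test_that("simple hairpins fold to the known optimum", {
  fr <- foldRNA("AAAAAAAAAA")
  expect_equal(mfe(fr), 0)
  expect_true(all(pairTable(fr) == 0))
  expect_equal(dotBracket(fr), "..........")

  fr <- foldRNA("GGGAAAACCC")
  oracle <- bruteFold("GGGAAAACCC")
  expect_equal(mfe(fr), oracle$energy)
  expect_equal(dotBracket(fr), "(((....)))")
})

test_that("fold energy equals the exhaustive-enumeration optimum", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(5:14, 1)
    s <- randomSeq(n)
    fr <- foldRNA(s)
    oracle <- bruteFold(s)
    expect_equal(mfe(fr), oracle$energy, info = s)
    # co-optimal tie-break: the returned structure has the maximal
    # pair count among energy-optimal structures
    expect_equal(sum(pairTable(fr) > 0) / 2, oracle$maxPairs, info = s)
  }
})

test_that("fold results satisfy the structural invariants", {
  set.seed(55)
  for (i in 1:25) {
    s <- randomSeq(sample(10:60, 1))
    fr <- foldRNA(s)
    expect_true(validObject(fr)) # involution, nesting, loop >= 3
    expect_lte(mfe(fr), 0)
    # dot-bracket consistent with the pair table
    db <- strsplit(dotBracket(fr), "")[[1]]
    pt <- pairTable(fr)
    expect_equal(db == "(", pt > seq_along(pt))
    expect_equal(db == ".", pt == 0)
  }
})

test_that("extending a sequence with a closing stem never worsens MFE", {
  set.seed(77)
  for (i in 1:10) {
    s <- randomSeq(sample(15:30, 1))
    closed <- paste0("GGGGG", s, "CCCCC")
    expect_lte(mfe(foldRNA(closed)), mfe(foldRNA(s)))
  }
})

test_that("energy is reverse-complement symmetric for GC-only sequences", {
  set.seed(88)
  for (i in 1:10) {
    s <- randomSeq(sample(12:30, 1), alphabet = c("G", "C"))
    expect_equal(mfe(foldRNA(s)), mfe(foldRNA(revcompDNA(s))))
  }
})

test_that("invalid fold input raises a validation error", {
  expect_error(foldRNA("ACGTN"), "invalid characters")
  expect_error(foldRNA(""), "length")
  expect_error(foldRNA(strrep("A", 1001)), "length")
})

test_that("duplexStats measures a perfect duplex and flags loop matures", {
  mature <- "GCGCGCGCAGCAGCAGCAGGG"
  hp <- paste0(mature, "AACAAC", revcompDNA(mature), "AC")
  fr <- foldRNA(hp)
  ds <- duplexStats(fr, 1, nchar(mature))
  expect_equal(ds$overlap_bp, 21L)
  expect_equal(ds$n_bulges, 0L)
  expect_equal(ds$arm, "5p")
  expect_false(ds$flagged)
  expect_true(ds$monotone)

  # mature placed inside the terminal loop: no partners, flagged
  loopStart <- nchar(mature) + 1L
  dsLoop <- duplexStats(fr, loopStart, 5L)
  expect_equal(dsLoop$overlap_bp, 0L)
  expect_true(dsLoop$flagged)
})

test_that("duplexStats bulge count agrees with the construction", {
  set.seed(31)
  for (b in 0:4) {
    hp <- plantHairpin(randomSeq(21), nBulges = b, loopLen = 8)
    ds <- duplexStats(hp$fold, hp$matureStart, hp$matureLen)
    expect_equal(ds$n_bulges, b)
    expect_equal(ds$overlap_bp, 21L)
  }
})

test_that("an external folder adapter is used verbatim", {
  # plug-in contract: sequence in, dot-bracket + energy out
  fakeFolder <- function(s) {
    n <- nchar(s)
    list(dotBracket = paste(rep(".", n), collapse = ""), energy = -99)
  }
  crit <- mirnaCriteria(folder = fakeFolder)
  cand <- list(ref = "r", start = 1L, end = 40L, strand = "+",
               sequence = randomSeq(40), matureStart = 2L,
               matureLen = 21L)
  tags <- uniqueTagSet(substr(cand$sequence, 2, 22), 10L, 10L)
  res <- evaluateCandidate(cand, tags, crit)
  # the all-unpaired external structure leaves the mature unpaired
  expect_false(res$accepted)
  expect_equal(res$reason, "mature_in_loop")
})
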