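smallConfig <- function(seed = 7L, ...) {
  simulationConfig(rngSeed = seed, libraryDepth = 15000L,
                   nKnownFamilies = 6L, nNovelHairpins = 3L,
                   nStarDetectable = 1L, ...)
}

test_that("config invariants are enforced", {
  expect_error(simulationConfig(libraryDepth = 0L), "libraryDepth")
  expect_error(simulationConfig(nStarDetectable = 5L,
                                nNovelHairpins = 2L), "exceed")
  expect_error(simulationConfig(contaminantFractions = c(
    adapter3_null = 0.6, insert_null = 0.5, adapter5_contaminant = 0,
    smaller_than_min = 0, polyA = 0, ncRNA = 0)), "sum")
})

test_that("perfect-complement hairpins pair every mature base", {
  set.seed(81)
  mat <- randomSeq(21)
  hp <- plantHairpin(mat, nBulges = 0, loopLen = 6)
  ds <- duplexStats(hp$fold, hp$matureStart, 21)
  expect_equal(ds$overlap_bp, 21L)
  expect_equal(ds$n_bulges, 0L)
  expect_true(grepl(mat, hp$precursor, fixed = TRUE))
  expect_error(plantHairpin("ACGTNACGTACGTACGTACGT"), "invalid")
})

test_that("a published mature builds a precursor the evaluator accepts", {
  set.seed(82)
  mat <- "TCGGACCAGGCTTCATTCCCC" # Lc-miRn1-3p mature
  hp <- plantHairpin(mat, nBulges = 1, loopLen = 8)
  cand <- list(ref = "r", start = 1L, end = nchar(hp$precursor),
               strand = "+", sequence = hp$precursor,
               matureStart = hp$matureStart, matureLen = hp$matureLen,
               fold = hp$fold)
  tags <- uniqueTagSet(mat, 50L, 40L)
  res <- evaluateCandidate(cand, tags, mirnaCriteria())
  expect_true(res$accepted)
  expect_equal(res$annotation$mature, mat)
  expect_equal(res$annotation$length, 21L)
})

test_that("identical seeds give identical libraries and truth tables", {
  cfg <- smallConfig()
  s1 <- simulateLibraries(cfg)
  s2 <- simulateLibraries(cfg)
  expect_identical(s1$readsBR, s2$readsBR)
  expect_identical(s1$readsBS, s2$readsBS)
  expect_identical(s1$truth, s2$truth)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  writeSimulation(s1, d1)
  writeSimulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  s3 <- simulateLibraries(smallConfig(seed = 8L))
  expect_false(identical(s1$readsBR, s3$readsBR))
})

test_that("contaminant-free simulation yields zero removal categories", {
  cfg <- smallConfig(
    contaminantFractions = c(adapter3_null = 0, insert_null = 0,
                             adapter5_contaminant = 0,
                             smaller_than_min = 0, polyA = 0,
                             ncRNA = 0),
    lowQualityFraction = 0)
  sim <- simulateLibraries(cfg)
  out <- classifyAndTrim(sim$readsBR, cfg@adapter3, cfg@adapter5,
                         qualities = sim$qualBR)
  s <- out$stats
  expect_equal(s$adapter3_null, 0L)
  expect_equal(s$insert_null, 0L)
  expect_equal(s$adapter5_contaminant, 0L)
  expect_equal(s$smaller_than_min, 0L)
  expect_equal(s$polyA, 0L)
  expect_equal(s$clean, s$high_quality)
})

test_that("an all-zero fold-change plan gives balanced counts", {
  # every planted miRNA with expected count >= 200 stays within
  # half a log2 unit of zero (binomial sampling error at this depth)
  cfg <- smallConfig(seed = 9L, plantedFcPlan = c(none = 0))
  sim <- simulateLibraries(cfg)
  truth <- sim$truth
  expect_true(all(truth$true_fc == 0))
  ct <- classifyAndTrim(sim$readsBR, cfg@adapter3, cfg@adapter5)
  cs <- classifyAndTrim(sim$readsBS, cfg@adapter3, cfg@adapter5)
  tags <- combineLibraries(ct$tags, cs$tags)
  idx <- match(truth$sequence, tagSequences(tags))
  cnt <- tagCounts(tags)
  for (r in which(truth$expected_BR >= 200 & !is.na(idx))) {
    fcHat <- log2(cnt[idx[r], "BR"] / cnt[idx[r], "BS"])
    expect_lt(abs(fcHat), 0.5)
  }
})

test_that("planted mature sequences occur in their precursors", {
  sim <- simulateLibraries(smallConfig(seed = 10L))
  truth <- sim$truth
  novel <- truth[truth$kind == "novel", ]
  for (r in seq_len(nrow(novel))) {
    prec <- substr(sim$refs[[novel$ref[r]]], novel$precursor_start[r],
                   novel$precursor_end[r])
    expect_true(grepl(novel$sequence[r], prec, fixed = TRUE))
  }
  # star coordinates carry the 2-nt 3' overhang by construction
  for (hp in sim$hairpins) {
    ds <- duplexStats(hp$fold, hp$matureStart, hp$matureLen)
    expect_equal(ds$overhang3, 2L)
    expect_equal(hp$starEnd, ds$star_end)
  }
})

test_that("read category proportions match the configured fractions", {
  sim <- acceptanceSim() # depth 1e5 (the study-scale run)
  cfg <- sim$config
  out <- classifyAndTrim(sim$readsBR, cfg@adapter3, cfg@adapter5,
                         qualities = sim$qualBR)
  s <- out$stats
  cf <- cfg@contaminantFractions
  observed <- c(s$adapter3_null, s$insert_null,
                s$adapter5_contaminant, s$smaller_than_min, s$polyA,
                s$high_quality - s$adapter3_null - s$insert_null -
                  s$adapter5_contaminant - s$smaller_than_min - s$polyA)
  expected <- c(cf[["adapter3_null"]], cf[["insert_null"]],
                cf[["adapter5_contaminant"]], cf[["smaller_than_min"]],
                cf[["polyA"]])
  expected <- c(expected, 1 - sum(expected))
  gof <- suppressWarnings(stats::chisq.test(observed, p = expected))
  expect_gt(gof$p.value, 0.01)
})
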