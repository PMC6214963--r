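AD3 <- "TGGAATTCTCGGGTGCCAAGG"
AD5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

# the ten-read hand fixture: 2 adapter-only, 1 no-adapter
# (machine-length), 1 with a 5' adapter prefix, 1 trimming to 16 nt,
# 1 poly(A), 4 clean
handReads <- function() {
  set.seed(2024)
  clean <- replicate(4, paste0(randomSeq(21), AD3))
  c(AD3,                                  # insert_null
    AD3,                                  # insert_null
    "ACGGATTCGTAAGCTGGCCTTAGACCAGTAAGCT", # adapter3_null (34 nt, no adapter)
    paste0(AD5, randomSeq(21), AD3),      # adapter5_contaminant
    paste0(randomSeq(16), AD3),           # smaller_than_min
    paste0(strrep("A", 24), AD3),         # polyA
    clean)
}

test_that("the hand fixture lands in the expected categories", {
  out <- classifyAndTrim(handReads(), AD3, AD5)
  s <- out$stats
  expect_equal(s$raw, 10L)
  expect_equal(s$high_quality, 10L)
  expect_equal(s$insert_null, 2L)
  expect_equal(s$adapter3_null, 1L)
  expect_equal(s$adapter5_contaminant, 1L)
  expect_equal(s$smaller_than_min, 1L)
  expect_equal(s$polyA, 1L)
  expect_equal(s$clean, 4L)
  expect_equal(sum(out$tags$count), 4L)
  expect_true(all(nchar(out$tags$sequence) == 21))
})

test_that("category counts always sum to the high-quality total", {
  set.seed(12)
  for (rep in 1:5) {
    reads <- character(0)
    for (i in 1:60) {
      kind <- sample(6, 1)
      reads <- c(reads, switch(kind,
        paste0(randomSeq(sample(18:30, 1)), AD3),
        AD3,
        randomSeq(sample(31:40, 1)),
        paste0(AD5, randomSeq(20), AD3),
        paste0(randomSeq(sample(1:17, 1)), AD3),
        paste0(strrep("A", sample(18:25, 1)), AD3)))
    }
    s <- classifyAndTrim(reads, AD3, AD5)$stats
    expect_equal(s$clean + s$adapter3_null + s$insert_null +
                   s$adapter5_contaminant + s$smaller_than_min + s$polyA,
                 s$high_quality)
  }
})

test_that("trimming is idempotent on already-clean tags", {
  set.seed(3)
  reads <- replicate(20, paste0(randomSeq(sample(19:28, 1)), AD3))
  first <- classifyAndTrim(reads, AD3, AD5)
  second <- classifyAndTrim(rep(first$tags$sequence, first$tags$count),
                            AD3, AD5)
  expect_equal(second$stats$clean, second$stats$high_quality)
  expect_equal(sort(second$tags$sequence), sort(first$tags$sequence))
  expect_equal(second$tags$count[order(second$tags$sequence)],
               first$tags$count[order(first$tags$sequence)])
})

test_that("quality filtering removes low-quality reads before categorisation", {
  reads <- c(paste0(randomSeq(21), AD3), paste0(randomSeq(21), AD3))
  quals <- c(strrep("I", nchar(reads[1])), strrep("#", nchar(reads[2])))
  s <- classifyAndTrim(reads, AD3, AD5, qualities = quals)$stats
  expect_equal(s$raw, 2L)
  expect_equal(s$high_quality, 1L)
  expect_equal(s$clean, 1L)
})

test_that("empty input gives all-zero stats, not an error", {
  out <- classifyAndTrim(character(0), AD3, AD5)
  expect_equal(out$stats$raw, 0L)
  expect_equal(out$stats$high_quality, 0L)
  expect_equal(nrow(out$tags), 0L)
})

test_that("malformed FASTQ raises an error naming the record", {
  fp <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), fp) # quality too short
  expect_error(readSrnaReads(fp), "record 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fp)
  expect_error(readSrnaReads(fp), "truncated")
})

test_that("length distribution fractions are exact", {
  tags <- data.frame(sequence = strrep("A", 24), count = 10L)
  ld <- lengthDistribution(tags)
  expect_equal(ld$length, 24L)
  expect_equal(ld$reads, 10)
  expect_equal(ld$fraction, 1.0)

  tags2 <- data.frame(sequence = c(randomSeq(21), randomSeq(24)),
                      count = c(30L, 70L))
  ld2 <- lengthDistribution(tags2)
  expect_equal(ld2$fraction[ld2$length == 21], 0.3)
  expect_equal(ld2$fraction[ld2$length == 24], 0.7)
  expect_equal(sum(ld2$fraction), 1, tolerance = 1e-9)
  expect_error(lengthDistribution(data.frame(sequence = character(),
                                             count = integer())),
               "empty")
})

test_that("collapsed tag totals conserve clean reads across libraries", {
  set.seed(9)
  readsBR <- replicate(50, paste0(randomSeq(sample(18:26, 1)), AD3))
  readsBS <- replicate(40, paste0(randomSeq(sample(18:26, 1)), AD3))
  br <- classifyAndTrim(readsBR, AD3, AD5)
  bs <- classifyAndTrim(readsBS, AD3, AD5)
  tags <- combineLibraries(br$tags, bs$tags)
  expect_equal(sum(tagCounts(tags)), br$stats$clean + bs$stats$clean)
})
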