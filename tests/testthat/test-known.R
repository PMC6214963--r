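knownFixtureDb <- function() {
  set.seed(61)
  data.frame(
    id = c("famA-1", "famA-2", "famB-1", "famC-1"),
    family = c("famA", "famA", "famB", "famC"),
    conserved = c(TRUE, TRUE, TRUE, FALSE),
    sequence = c(randomSeq(21), randomSeq(21), randomSeq(21),
                 randomSeq(24)),
    stringsAsFactors = FALSE)
}

mutateAt <- function(seq, pos, to = NULL) {
  b <- substr(seq, pos, pos)
  repl <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), b)[1] else to
  paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
}

test_that("matchKnown applies the Hamming tolerance exactly", {
  db <- knownFixtureDb()
  # identical tag: one best match with 0 mismatches
  m0 <- matchKnown(db$sequence[1], db, maxMismatch = 2)
  expect_equal(m0$mismatches[m0$db_id == "famA-1"], 0L)
  expect_true(m0$best[m0$db_id == "famA-1"])

  # distance 2: matched (the published mismatch ceiling)
  t2 <- mutateAt(mutateAt(db$sequence[1], 3), 10)
  m2 <- matchKnown(t2, db, maxMismatch = 2)
  expect_true("famA-1" %in% m2$db_id)
  expect_equal(m2$mismatches[m2$db_id == "famA-1"], 2L)

  # distance 3 from everything: empty (brute-force checked)
  t3 <- mutateAt(mutateAt(mutateAt(db$sequence[1], 3), 10), 15)
  bruteMin <- min(vapply(db$sequence[nchar(db$sequence) == 21],
                         function(s) sum(strsplit(s, "")[[1]] !=
                                           strsplit(t3, "")[[1]]),
                         numeric(1)))
  expect_gte(bruteMin, 3)
  expect_equal(nrow(matchKnown(t3, db, maxMismatch = 2)), 0L)

  expect_error(matchKnown("ACGTNACGTNACGTNACGTNA", db), "invalid")
})

test_that("assignKnown picks the minimum-mismatch family deterministically", {
  db <- knownFixtureDb()
  tagExact <- db$sequence[3]
  tagNear <- mutateAt(db$sequence[2], 5)
  set.seed(62)
  tagNone <- randomSeq(21)
  tags <- uniqueTagSet(c(tagExact, tagNear, tagNone),
                       c(10L, 4L, 1L), c(2L, 6L, 1L))
  asg <- assignKnown(tags, db)
  expect_equal(nrow(asg), 2L)
  expect_equal(asg$family[asg$sequence == tagExact], "famB")
  expect_equal(asg$family[asg$sequence == tagNear], "famA")
  expect_equal(asg$mismatches[asg$sequence == tagNear], 1L)
})

test_that("family table reproduces printed totals and ratios", {
  rows <- familyTableRows()
  # build one synthetic tag per family carrying the printed counts
  # (zero-count libraries get a placeholder read to keep tags valid)
  set.seed(63)
  seqs <- vapply(seq_len(nrow(rows)), function(i) randomSeq(21), "")
  db <- data.frame(id = paste0(rows$family, "-1"), family = rows$family,
                   conserved = rows$conserved, sequence = seqs,
                   stringsAsFactors = FALSE)
  tags <- uniqueTagSet(seqs, rows$reads_BR, rows$reads_BS)
  asg <- assignKnown(tags, db)
  tab <- buildFamilyTable(asg, tags)
  for (i in seq_len(nrow(rows))) {
    r <- tab[tab$family == rows$family[i], ]
    expect_equal(r$total, rows$total[i], info = rows$family[i])
    expect_equal(r$ratio, rows$ratio[i], info = rows$family[i])
  }
  # undefined ratios render as an em dash
  shown <- formatFamilyTable(tab)
  expect_true(all(shown$ratio[is.na(tab$ratio)] == "—"))
})

test_that("swapping libraries inverts the ratio up to rounding", {
  set.seed(64)
  for (i in 1:20) {
    br <- sample(1:5000, 1)
    bs <- sample(1:5000, 1)
    seqs <- randomSeq(21)
    db <- data.frame(id = "f-1", family = "f", conserved = TRUE,
                     sequence = seqs, stringsAsFactors = FALSE)
    t1 <- buildFamilyTable(assignKnown(uniqueTagSet(seqs, br, bs), db),
                           uniqueTagSet(seqs, br, bs))
    t2 <- buildFamilyTable(assignKnown(uniqueTagSet(seqs, bs, br), db),
                           uniqueTagSet(seqs, bs, br))
    expect_equal(t1$ratio, round(bs / br, 2), tolerance = 0.005 + 1e-9)
    expect_equal(t2$ratio, round(br / bs, 2), tolerance = 0.005 + 1e-9)
  }
})

test_that("no tag is double-counted across families", {
  db <- knownFixtureDb()
  set.seed(65)
  seqs <- c(db$sequence[1:3], vapply(1:5, function(i) randomSeq(21), ""))
  tags <- uniqueTagSet(seqs, rep(3L, 8), rep(2L, 8))
  tab <- buildFamilyTable(assignKnown(tags, db), tags)
  expect_lte(sum(tab$reads_BR), sum(tagCounts(tags)[, "BR"]))
  expect_lte(sum(tab$reads_BS), sum(tagCounts(tags)[, "BS"]))
})
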