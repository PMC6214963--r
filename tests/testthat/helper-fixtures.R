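# Published worked-example fixtures and the shared acceptance-scale
# simulation (built once per test run).

# Known miRNA family expression rows: family, members, reads in the
# browning-resistant (BR) and browning-sensitive (BS) libraries, their
# total, and the printed BS/BR ratio (2 decimals; NA = undefined,
# printed as an em dash when BR is 0).
familyTableRows <- function() {
  rows <- rbind(
    c("miR156/157", 14,   40,   40,   80, "1.00", 1),
    c("miR159",     12, 2305, 1840, 4145, "0.80", 1),
    c("miR160",      4,   29,   17,   46, "0.59", 1),
    c("miR162",      4,  424,  358,  782, "0.84", 1),
    c("miR164",      7,   88,   66,  154, "0.75", 1),
    c("miR165/166", 14, 2818, 2359, 5177, "0.84", 1),
    c("miR167",      8,  321,  309,  630, "0.96", 1),
    c("miR168",      3,   31,   19,   50, "0.61", 1),
    c("miR169",      8,  553,  256,  809, "0.46", 1),
    c("miR171",      8,   46,   33,   79, "0.72", 1),
    c("miR172",      8,   55,   33,   88, "0.60", 1),
    c("miR173",      1,    0,    1,    1, NA,     1),
    c("miR319",     10, 1883, 1364, 3247, "0.72", 1),
    c("miR390",      5,  104,   83,  187, "0.80", 1),
    c("miR393",      2,    0,    2,    2, NA,     1),
    c("miR394",      3,    3,    1,    4, "0.33", 1),
    c("miR395",      8,   17,   16,   33, "0.94", 1),
    c("miR396",     11, 8218, 9997, 18215, "1.22", 1),
    c("miR397",      1,    2,    2,    4, "1.00", 1),
    c("miR398",      3,  105,   76,  181, "0.72", 1),
    c("miR399",      6, 1984,  883, 2867, "0.45", 1),
    c("miR408",      2,    4,    0,    4, "0.00", 1),
    c("miR482",      4,    4,    2,    6, "0.50", 1),
    c("miR535",      1,    1,    0,    1, "0.00", 1),
    c("miR403",      1,    0,    1,    1, NA,     0),
    c("miR414",      1,    2,    0,    2, "0.00", 0),
    c("miR477",      6,   92,   50,  142, "0.54", 0),
    c("miR529",      1,    0,    2,    2, NA,     0),
    c("miR827",      1,  138,   84,  222, "0.61", 0),
    c("miR845",      5,   69,   67,  136, "0.97", 0),
    c("miR854",      1,    1,    0,    1, "0.00", 0),
    c("miR858",      1,  156,   18,  174, "0.12", 0),
    c("miR894",      1,  226,  184,  410, "0.81", 0),
    c("miR1511",     2,   80,   61,  141, "0.76", 0),
    c("miR1863",     2,   39,   36,   75, "0.92", 0),
    c("miR2111",     6,   59,   71,  130, "1.20", 0),
    c("miR2118",     1,    1,    0,    1, "0.00", 0),
    c("miR3630",     1,    1,    1,    2, "1.00", 0),
    c("miR502",      1,    3,    5,    8, "1.67", 0),
    c("miR5293",     1,    1,    0,    1, "0.00", 0),
    c("miR5298",     1,    0,    1,    1, NA,     0),
    c("miR5654",     1,    1,    0,    1, "0.00", 0))
  data.frame(family = rows[, 1],
             members = as.integer(rows[, 2]),
             reads_BR = as.integer(rows[, 3]),
             reads_BS = as.integer(rows[, 4]),
             total = as.integer(rows[, 5]),
             ratio = suppressWarnings(as.numeric(rows[, 6])),
             conserved = rows[, 7] == "1",
             stringsAsFactors = FALSE)
}

# Published novel-miRNA records (name, mature 5'->3', printed length,
# precursor length LP, MFE, arm). Only rows whose printed sequence
# length equals the printed Length column are included.
novelMirnaRows <- function() {
  rows <- rbind(
    c("Lc-miRn1-5p",  "GGAATGTTGTCTGGTGCGAGA",   21,  87, -52.9, "5p"),
    c("Lc-miRn1-3p",  "TCGGACCAGGCTTCATTCCCC",   21,  87, -52.9, "3p"),
    c("Lc-miRn5-5p",  "GGAATGTTGTCTGGCTCGAGG",   21, 154, -47.0, "5p"),
    c("Lc-miRn5-3p",  "TCGGACCAGGCTTCATTCCCC",   21, 154, -47.0, "3p"),
    c("Lc-miRn8-5p",  "AATGCGGTCTGGTTCGAGAGC",   21, 107, -46.6, "5p"),
    c("Lc-miRn8-3p",  "TCTCGGACCAGGCTTCATTCT",   21, 107, -46.6, "3p"),
    c("Lc-miRn10-5p", "TGGAGAAGCAGGGCACGTGCTG",  22, 202, -56.6, "5p"),
    c("Lc-miRn10-3p", "TCATGTGCCCCTCTTCGCCATC",  22, 202, -56.6, "3p"),
    c("Lc-miRn13-5p", "CCACAGCTTTCTTGAACTGCA",   21, 143, -63.7, "5p"),
    c("Lc-miRn13-3p", "GTTCAATAAAGCTGTGGGAAG",   21, 143, -63.7, "3p"),
    c("Lc-miRn15-5p", "TGGCATAGGCTACTTGGAAAC",   21, 133, -36.8, "5p"),
    c("Lc-miRn15-3p", "TTCCAAGTCCACCCATGCCCGC",  22, 133, -36.8, "3p"),
    c("Lc-miRn25b-5p", "TTCCACAGCTTTCTTGAACTT",  21, 166, -61.4, "5p"),
    c("Lc-miRn25b-3p", "GTTCAAGAAAGCTGTGGGAGA",  21, 166, -61.4, "3p"),
    c("Lc-miRn37a-5p", "TTCCACAGCTTTCTTGAACTT",  21, 143, -56.3, "5p"),
    c("Lc-miRn37a-3p", "CTCAAGAAAGCTGTGGGACATC", 22, 143, -56.3, "3p"),
    c("Lc-miRn38-5p", "GGAATGTTGGCTGGCTCGAGG",   21, 146, -44.5, "5p"),
    c("Lc-miRn38-3p", "TCGGACCAGGCTTCATTCCCC",   21, 146, -44.5, "3p"),
    c("Lc-miRn39-5p", "TTTTTCCACAGCTTTCTTGAACT", 23, 132, -32.7, "5p"),
    c("Lc-miRn39-3p", "CTCAAGAAAGCTGTGGGAAATTA", 23, 132, -32.7, "3p"),
    c("Lc-miRn43-5p", "CAGAGCTCCTTGAAGTCCAATA",  22, 236, -86.5, "5p"),
    c("Lc-miRn54-5p", "TGGAGAAGCAGGGCACGTGCAT",  22, 135, -66.6, "5p"),
    c("Lc-miRn54-3p", "TCATGTGCCCCTCTTCTCCATC",  22, 135, -66.6, "3p"),
    c("Lc-miRn66-5p", "TGGAGAAGCAGGGCACGTGCA",   21,  96, -40.2, "5p"),
    c("Lc-miRn66-3p", "CACGTGCTCCCCTTCTCCAAC",   21,  96, -40.2, "3p"))
  data.frame(name = rows[, 1], mature = rows[, 2],
             length = as.integer(rows[, 3]), LP = as.integer(rows[, 4]),
             MFE = as.numeric(rows[, 5]), arm = rows[, 6],
             stringsAsFactors = FALSE)
}

# ---- shared acceptance-scale simulation ---------------------------
# the reference study conditions: depth 1e5 per library, 30 known
# families, 10 novel hairpins, planted fold changes {0, +/-1, +/-2};
# built once and reused by the acceptance tests
.simCache <- new.env(parent = emptyenv())

acceptanceSim <- function() {
  if (is.null(.simCache$sim)) {
    cfg <- simulationConfig(rngSeed = 20260901L)
    .simCache$cfg <- cfg
    .simCache$sim <- simulateLibraries(cfg)
  }
  .simCache$sim
}

acceptancePipeline <- function() {
  if (is.null(.simCache$pipe)) {
    sim <- acceptanceSim()
    dir <- file.path(tempdir(), "mirstem-acceptance-sim")
    writeSimulation(sim, dir)
    .simCache$pipe <- suppressMessages(runPipeline(list(
      reads_br = file.path(dir, "reads_BR.fastq"),
      reads_bs = file.path(dir, "reads_BS.fastq"),
      refs = file.path(dir, "refs.fasta"),
      mature_db = file.path(dir, "mature_db.fasta"),
      ncdb = file.path(dir, "ncdb.fasta"),
      outdir = file.path(dir, "out"))))
  }
  .simCache$pipe
}
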