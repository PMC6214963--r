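#' Run the full small RNA analysis pipeline
#'
#' Orchestrates every stage over a pair of libraries: preprocessing
#' (adapter classification and trimming of both FASTQ files), ncRNA
#' filtering, known miRNA family assignment, novel miRNA discovery,
#' two-library differential expression, and target scanning of the
#' differentially expressed miRNAs. Writes six TSV reports plus a run
#' manifest into the output directory:
#' \itemize{
#'   \item `preprocess_stats.tsv` - per-library removal-category counts
#'     and percentages;
#'   \item `length_distribution.tsv` - read counts and fractions by tag
#'     length;
#'   \item `family_table.tsv` - known miRNA families: members,
#'     per-library reads, total, BS/BR ratio;
#'   \item `novel_mirnas.tsv` - accepted novel miRNAs with arm, mature
#'     sequence, Length, LP, MFE, per-library reads, star support,
#'     location;
#'   \item `diff_expression.tsv` - normalized expressions, log2 fold
#'     change, Audic-Claverie p-value and regulation call per miRNA;
#'   \item `target_sites.tsv` - predicted target sites of the
#'     differentially expressed miRNAs.
#' }
#' `manifest.yaml` records every effective parameter, input path and
#' stage record counts, so a run is reproducible from the manifest
#' alone. Identical configurations give byte-identical outputs (no
#' stage uses random numbers).
#'
#' @param config either a path to a YAML configuration file or a list
#'   with the same structure; see [pipelineConfig] for the recognised
#'   fields and defaults.
#' @return invisibly, a list with every stage result (`stats`,
#'   `lengthDist`, `tags`, `ncRemoved`, `familyTable`, `novel`, `de`,
#'   `targets`, `outputs`).
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logStage <- function(...) message("[mirStem] ", ...)

  for (f in c("reads_br", "reads_bs", "refs", "mature_db", "ncdb")) {
    if (!file.exists(cfg[[f]]))
      stop("config error: input file for '", f, "' not found: ", cfg[[f]])
  }

  logStage("preprocess: ", cfg$reads_br, " + ", cfg$reads_bs)
  br <- classifyAndTrim(cfg$reads_br, cfg$adapter3, cfg$adapter5,
                        minLen = cfg$min_len, maxLen = cfg$max_len,
                        qualityFloor = cfg$quality_floor)
  bs <- classifyAndTrim(cfg$reads_bs, cfg$adapter3, cfg$adapter5,
                        minLen = cfg$min_len, maxLen = cfg$max_len,
                        qualityFloor = cfg$quality_floor)
  tags <- combineLibraries(br$tags, bs$tags)
  cleanBR <- br$stats$clean
  cleanBS <- bs$stats$clean
  logStage("clean reads BR=", cleanBR, " BS=", cleanBS,
           "; unique tags=", length(tags))

  statsTab <- data.frame(
    category = c("raw", "high_quality", "clean", "adapter3_null",
                 "insert_null", "adapter5_contaminant",
                 "smaller_than_min", "polyA"),
    BR = unlist(br$stats[c("raw", "high_quality", "clean",
                           "adapter3_null", "insert_null",
                           "adapter5_contaminant", "smaller_than_min",
                           "polyA")]),
    BS = unlist(bs$stats[c("raw", "high_quality", "clean",
                           "adapter3_null", "insert_null",
                           "adapter5_contaminant", "smaller_than_min",
                           "polyA")]),
    stringsAsFactors = FALSE, row.names = NULL)
  lenDist <- lengthDistribution(tags)

  ncdb <- readNcDb(cfg$ncdb)
  nc <- filterNcRNA(tags, ncdb, maxMismatch = cfg$nc_max_mismatch)
  logStage("ncRNA filter removed ", nrow(nc$removed), " tags, kept ",
           length(nc$kept))

  matureDb <- readMatureDb(cfg$mature_db)
  known <- assignKnown(nc$kept, matureDb, maxMismatch = cfg$max_mismatch)
  famTable <- buildFamilyTable(known, nc$kept)
  logStage("known assignment: ", nrow(known), " tags in ",
           nrow(famTable), " families")

  refs <- as.character(Biostrings::readDNAStringSet(cfg$refs))
  unann <- nc$kept[setdiff(seq_len(length(nc$kept)), known$tag_id)]
  criteria <- mirnaCriteria(minOverlap = cfg$min_overlap,
                            maxBulges = cfg$max_bulges,
                            maxEnergy = cfg$max_energy,
                            requireStar = cfg$require_star,
                            minReads = cfg$min_reads)
  novel <- findNovelMirnas(unann, refs, criteria,
                           flank5 = cfg$flank5, flank3 = cfg$flank3)
  logStage("novel discovery: ", nrow(novel$annotations),
           " accepted records")

  ## differential expression over known members + novel matures
  deIn <- deCountTable(known, nc$kept, novel$annotations)
  de <- callDifferential(deIn, N1 = cleanBR, N2 = cleanBS,
                         fcCut = cfg$fc_cut, pCut = cfg$p_cut,
                         sided = cfg$sided)
  logStage("differential expression: ",
           sum(de$call %in% c("up", "down")), " DE miRNAs of ",
           nrow(de))

  deMirs <- de[de$call %in% c("up", "down"), , drop = FALSE]
  deSeqs <- deIn$sequence[match(deMirs$id, deIn$id)]
  targetRows <- list()
  for (i in seq_along(deSeqs)) {
    ts <- scanTranscripts(deSeqs[i], refs, cutoff = cfg$target_cutoff,
                          maxGap = cfg$target_max_gap)
    if (nrow(ts) > 0) {
      ts$mirna <- deMirs$id[i]
      targetRows[[length(targetRows) + 1L]] <- ts
    }
  }
  targets <- do.call(rbind, targetRows)
  if (is.null(targets)) targets <- emptyTargetFrame()
  logStage("target scan: ", nrow(targets), " sites for ",
           length(deSeqs), " DE miRNAs")

  outputs <- c(
    preprocess_stats = file.path(cfg$outdir, "preprocess_stats.tsv"),
    length_distribution = file.path(cfg$outdir, "length_distribution.tsv"),
    family_table = file.path(cfg$outdir, "family_table.tsv"),
    novel_mirnas = file.path(cfg$outdir, "novel_mirnas.tsv"),
    diff_expression = file.path(cfg$outdir, "diff_expression.tsv"),
    target_sites = file.path(cfg$outdir, "target_sites.tsv"))
  writeTsv(statsTab, outputs[["preprocess_stats"]])
  writeTsv(lenDist, outputs[["length_distribution"]])
  writeTsv(formatFamilyTable(famTable), outputs[["family_table"]])
  writeTsv(novel$annotations, outputs[["novel_mirnas"]])
  writeTsv(de, outputs[["diff_expression"]])
  writeTsv(targets, outputs[["target_sites"]])

  manifest <- c(cfg, list(
    n_raw_BR = br$stats$raw, n_raw_BS = bs$stats$raw,
    n_clean_BR = cleanBR, n_clean_BS = cleanBS,
    n_unique_tags = length(tags),
    n_nc_removed = nrow(nc$removed),
    n_known_tags = nrow(known),
    n_families = nrow(famTable),
    n_novel_records = nrow(novel$annotations),
    n_de = sum(de$call %in% c("up", "down")),
    n_target_sites = nrow(targets)))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

  invisible(list(stats = statsTab, lengthDist = lenDist, tags = tags,
                 ncRemoved = nc$removed, familyTable = famTable,
                 novel = novel, de = de, targets = targets,
                 outputs = outputs))
}

# per-miRNA two-library counts feeding the differential test: known
# database members get the summed counts of their best-matching tags;
# novel miRNAs get their mature tag counts
deCountTable <- function(known, tags, novelAnn) {
  cnt <- tagCounts(tags)
  rows <- list()
  if (nrow(known) > 0) {
    for (id in unique(known$db_id)) {
      m <- known[known$db_id == id, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, sequence = m$sequence[which.min(m$mismatches)],
        x = sum(cnt[m$tag_id, "BR"]), y = sum(cnt[m$tag_id, "BS"]),
        kind = "known", stringsAsFactors = FALSE)
    }
  }
  if (nrow(novelAnn) > 0) {
    for (r in seq_len(nrow(novelAnn))) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = novelAnn$name[r], sequence = novelAnn$mature[r],
        x = novelAnn$reads_BR[r], y = novelAnn$reads_BS[r],
        kind = "novel", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), sequence = character(),
                      x = integer(), y = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Pipeline configuration with defaults
#'
#' Reads a YAML file (or accepts an equivalent list) and fills in the
#' default for every missing parameter. Required fields: `reads_br`,
#' `reads_bs`, `refs`, `mature_db`, `ncdb`, `outdir`.
#'
#' @param config path to a YAML file, or a list.
#' @return a complete named list of parameters.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config error: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: expected a list or a path")
  defaults <- list(
    adapter3 = "TGGAATTCTCGGGTGCCAAGG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    min_len = 18L, max_len = 30L, quality_floor = 20,
    nc_max_mismatch = 0L, max_mismatch = 2L,
    min_overlap = 16L, max_bulges = 4L, max_energy = -18,
    require_star = FALSE, min_reads = 5L,
    flank5 = 160L, flank3 = 160L,
    fc_cut = 1.0, p_cut = 0.05, sided = 2L,
    target_cutoff = 3, target_max_gap = 1L,
    rng_seed = 1L)
  required <- c("reads_br", "reads_bs", "refs", "mature_db", "ncdb",
                "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("config error: missing required fields: ",
         paste(missing, collapse = ", "))
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  unknown <- setdiff(names(config), c(required, names(defaults)))
  if (length(unknown) > 0)
    stop("config error: unknown fields: ", paste(unknown, collapse = ", "))
  config
}
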