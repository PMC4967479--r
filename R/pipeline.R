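#' Pipeline configuration
#'
#' A flat named list of every tunable threshold, with the defaults used
#' throughout the package. A YAML file may override any subset; explicit
#' function arguments override the file. Round-trips unchanged through
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param ... Overrides of the defaults.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(...) {
  def <- list(
    evalue_max = 1e-10, conservation_min = 0.5,
    min_support = 10, ambiguity_margin = 0.1,
    min_tail = 8, max_tail_mismatch = 0,
    stop_window = 60, positional_window = 300,
    proximal = c(-90, -42), distal = c(-300, -240),
    depletion_alpha = 0.01,
    len_min = 25, len_max = 32, max_mismatch = 1,
    flank = 30, term_threshold = 0.5,
    min_downstream = 13, coverage_min = 20,
    seed = 1, log_level = "info"
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, ov)
  stopifnot(cfg$evalue_max > 0, cfg$conservation_min >= 0,
            cfg$conservation_min <= 1, cfg$min_support >= 1,
            cfg$ambiguity_margin >= 0, cfg$ambiguity_margin < 1,
            cfg$min_tail >= 5, cfg$len_min <= cfg$len_max,
            cfg$min_downstream > 0, cfg$coverage_min >= 0)
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @rdname pipelineConfig
#' @param config A configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(...)
}

#' Simulate a full synthetic study bundle
#'
#' Writes transcripts (FASTA + annotation TSV), the profile-alignment
#' record stream (TSV), footprints (SAM), the genetic code (JSON) and the
#' ground truth (JSON) into `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param sim_cfg A [simConfig()]; its seed governs all randomness.
#' @param config A [pipelineConfig()] (logging only here).
#' @return Invisible named list of output paths plus the in-memory `sim`.
#' @export
runSimulate <- function(out_dir, sim_cfg = simConfig(),
                        config = pipelineConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log(config, "simulating ", sim_cfg$n_transcripts, " transcripts (code ",
       codeName(sim_cfg$code), ", seed ", sim_cfg$seed, ")")
  sim <- simulateTranscriptome(sim_cfg)
  rec <- simulateAlignmentRecords(sim)
  paths <- list(
    fasta = file.path(out_dir, "transcripts.fasta"),
    annotation = file.path(out_dir, "transcripts.annotation.tsv"),
    records = file.path(out_dir, "alignment_records.tsv"),
    sam = file.path(out_dir, "rpfs.sam"),
    code = file.path(out_dir, "genetic_code.json"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  writeTranscripts(sim$transcripts, paths$fasta, paths$annotation)
  writeAlignmentRecords(rec, paths$records)
  simulateRPFs(sim, sam = paths$sam)
  writeGeneticCode(sim_cfg$code, paths$code)
  writeGroundTruth(sim, paths$truth)
  invisible(c(paths, list(sim = sim)))
}

#' Genetic-code inference workflow
#'
#' Filters a profile-alignment record stream, accumulates and normalises
#' the codon/amino-acid matrix, calls the code, and writes the prediction
#' report (TSV + JSON), the per-amino-acid logo matrix (TSV) and a rejects
#' summary (JSON). An empty record stream yields an all-UNASSIGNED report
#' with a warning.
#'
#' @param records Record data.frame or TSV path.
#' @param out_dir Output directory.
#' @param config A [pipelineConfig()].
#' @return Invisible list: `prediction` ([GeneticCodePrediction-class]),
#'   `matrix` (per-codon-normalised [CodonAminoMatrix-class]), paths.
#' @export
runInferCode <- function(records, out_dir, config = pipelineConfig()) {
  if (is.character(records)) {
    if (!file.exists(records))
      stop("record stream not found: ", records, call. = FALSE)
    records <- readAlignmentRecords(records)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- filterRecords(records, config$evalue_max, config$conservation_min)
  if (nrow(kept) == 0L)
    warning("no records pass the filters; all codons will be UNASSIGNED")
  m <- accumulateMatrix(kept)
  m_codon <- normalizeMatrix(m, "per_codon")
  m_aa <- normalizeMatrix(m, "per_amino_acid")
  pred <- predictCode(m_codon, config$min_support, config$ambiguity_margin)
  paths <- list(report_tsv = file.path(out_dir, "code_prediction.tsv"),
                report_json = file.path(out_dir, "code_prediction.json"),
                logo = file.path(out_dir, "logo_matrix.tsv"),
                rejects = file.path(out_dir, "filter_rejects.json"))
  writePredictionReport(pred, paths$report_tsv, paths$report_json)
  exportLogoMatrix(m_aa, paths$logo)
  jsonlite::write_json(
    list(input_records = nrow(records), retained = nrow(kept),
         rejects = as.list(attr(kept, "rejects")),
         evalue_max = config$evalue_max,
         conservation_min = config$conservation_min),
    paths$rejects, auto_unbox = TRUE, pretty = TRUE)
  .log(config, "inferred code: ",
       sum(codeCalls(pred)$call != "UNASSIGNED"), "/64 codons called")
  invisible(list(prediction = pred, matrix = m_codon, logo_matrix = m_aa,
                 paths = paths))
}

#' Poly(A)-anchored transcript-end workflow
#'
#' Detects poly(A) tails, calls primary stops in the terminal window,
#' summarises 3' UTR lengths, accumulates positional codon counts (full
#' and coding-restricted), tests stop-set codons for proximal depletion
#' and profiles base composition. Writes per-transcript calls, histogram
#' and positional-count TSVs plus summary/depletion JSONs.
#'
#' @param transcripts Annotated `DNAStringSet`, or FASTA path.
#' @param out_dir Output directory.
#' @param code [GeneticCodeTable-class] or path to its JSON (defines the
#'   stop set).
#' @param annotation Annotation TSV path (when `transcripts` is a path).
#' @param config A [pipelineConfig()].
#' @return Invisible list of results and paths.
#' @export
runEnds <- function(transcripts, out_dir, code = standardGeneticCode(),
                    annotation = NULL, config = pipelineConfig()) {
  if (is.character(transcripts))
    transcripts <- readTranscripts(transcripts, annotation)
  if (is.character(code)) code <- readGeneticCode(code)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  polya <- detectPolyA(transcripts, config$min_tail,
                       config$max_tail_mismatch)
  tailed <- polya[!is.na(polya$polya_site), , drop = FALSE]
  if (nrow(tailed) == 0L)
    warning("no poly(A) tails detected; transcript-end calls are empty")
  ss <- stopSet(code)
  stops <- findPrimaryStop(transcripts, tailed, ss, config$stop_window)
  paths <- list(
    calls = file.path(out_dir, "primary_stops.tsv"),
    utr_hist = file.path(out_dir, "utr_histogram.tsv"),
    utr_summary = file.path(out_dir, "utr_summary.json"),
    positional = file.path(out_dir, "positional_counts.tsv"),
    positional_coding = file.path(out_dir, "positional_counts_coding.tsv"),
    depletion = file.path(out_dir, "depletion.json"),
    base_freq = file.path(out_dir, "base_frequencies.tsv")
  )
  utils::write.table(stops, paths$calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res <- list(polya = polya, stops = stops, paths = paths)
  if (nrow(stops)) {
    utr <- utrLengthDistribution(stops)
    utils::write.table(utr$histogram, paths$utr_hist, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(utr[c("n", "median", "q1", "q3", "fraction_zero")],
                         paths$utr_summary, auto_unbox = TRUE, digits = NA)
    pc_all <- positionalCodonCounts(transcripts, tailed,
                                    config$positional_window)
    pc_cod <- positionalCodonCounts(transcripts, tailed,
                                    config$positional_window,
                                    region = "coding", stops = stops)
    writePositionalCounts(pc_all, paths$positional)
    writePositionalCounts(pc_cod, paths$positional_coding)
    dep <- stopDepletionTest(pc_cod, ss, config$proximal, config$distal,
                             config$depletion_alpha)
    jsonlite::write_json(dep, paths$depletion, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    bf <- baseFrequencyProfile(transcripts, tailed,
                               config$positional_window, config$proximal)
    utils::write.table(format(bf, digits = 8), paths$base_freq, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res <- c(res, list(utr = utr, positional = pc_all,
                       positional_coding = pc_cod, depletion = dep,
                       base_freq = bf))
    .log(config, nrow(stops), " primary stops; 3'UTR median ",
         utr$median, " nt")
  }
  invisible(res)
}

#' Ribosome-profiling termination/readthrough workflow
#'
#' Filters footprints, computes per-length frame distributions, builds the
#' stop-anchored 3'-end metaprofile, classifies the termination signature
#' and estimates per-transcript readthrough with cohort summaries.
#'
#' @param rpfs Footprint `GRanges`, or SAM/BAM path.
#' @param transcripts Annotated `DNAStringSet`, or FASTA path.
#' @param stops [findPrimaryStop()] output (or its TSV path).
#' @param out_dir Output directory.
#' @param annotation Annotation TSV path (when `transcripts` is a path).
#' @param config A [pipelineConfig()].
#' @return Invisible list of results and paths.
#' @export
runRiboseq <- function(rpfs, transcripts, stops, out_dir,
                       annotation = NULL, config = pipelineConfig()) {
  if (is.character(transcripts))
    transcripts <- readTranscripts(transcripts, annotation)
  if (is.character(rpfs)) rpfs <- readRPFs(rpfs, transcripts)
  if (is.character(stops))
    stops <- utils::read.delim(stops, stringsAsFactors = FALSE)
  if (length(rpfs) == 0L)
    stop("no mapped footprints supplied", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- filterRPFs(rpfs, config$len_min, config$len_max,
                     config$max_mismatch)
  fd <- frameDistribution(kept, transcripts)
  anchors <- data.frame(transcript_id = stops$transcript_id,
                        anchor_start = stops$stop_start,
                        class = "stop", stringsAsFactors = FALSE)
  prof <- endMetaprofile(kept, anchors, transcripts, config$flank,
                         anchor_class = "stop")
  term <- classifyTermination(prof, config$term_threshold)
  rt <- estimateReadthrough(kept, stops, config$min_downstream,
                            config$coverage_min)
  paths <- list(
    frames = file.path(out_dir, "frame_distribution.tsv"),
    metaprofile = file.path(out_dir, "stop_metaprofile.tsv"),
    termination = file.path(out_dir, "termination.json"),
    readthrough = file.path(out_dir, "readthrough.tsv"),
    summary = file.path(out_dir, "readthrough_summary.json")
  )
  utils::write.table(format(fd, digits = 8), paths$frames, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mp <- data.frame(offset = prof@offsets, count = rowSums(prof@counts),
                   class = prof@anchorClass)
  utils::write.table(mp, paths$metaprofile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(term, paths$termination, auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(rt$per_transcript, paths$readthrough, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(rt$summary,
                         list(min_downstream = config$min_downstream,
                              coverage_min = config$coverage_min,
                              denominator = "stop_anchored")),
                       paths$summary, auto_unbox = TRUE, digits = NA)
  .log(config, "readthrough: mean ",
       signif(100 * rt$summary$mean_rate, 3), "%, median ",
       signif(100 * rt$summary$median_rate, 3), "% over ",
       rt$summary$n_covered, " covered transcripts")
  invisible(list(filtered = kept, frames = fd, metaprofile = prof,
                 termination = term, readthrough = rt, paths = paths))
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a cohort, then runs the code-inference, transcript-end and
#' ribo-seq workflows on the simulated files.
#'
#' @param out_dir Output directory (subdirectories per stage).
#' @param sim_cfg A [simConfig()].
#' @param config A [pipelineConfig()].
#' @return Invisible list with each stage's results.
#' @export
runAll <- function(out_dir, sim_cfg = simConfig(),
                   config = pipelineConfig()) {
  simp <- runSimulate(file.path(out_dir, "simulate"), sim_cfg, config)
  infer <- runInferCode(simp$records, file.path(out_dir, "infer_code"),
                        config)
  ends <- runEnds(simp$fasta, file.path(out_dir, "ends"), simp$code,
                  annotation = simp$annotation, config = config)
  ribo <- runRiboseq(simp$sam, simp$fasta, ends$stops,
                     file.path(out_dir, "riboseq"),
                     annotation = simp$annotation, config = config)
  invisible(list(simulate = simp, infer = infer, ends = ends,
                 riboseq = ribo))
}
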