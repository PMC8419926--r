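#' Build a validated run configuration
#'
#' A run configuration collects the stage parameters of the whole pipeline
#' with the package defaults; unknown keys are rejected. It can be read
#' from / written to YAML.
#'
#' @param ... overrides for the defaults below.
#' @return list of class `fatac_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    out_dir = "fatac_out",
    seed = 1L,
    # simulation (used when no alignment input is given)
    n_chrom = 2L, chrom_length = 150000L, n_genes = 100L,
    motifs = NULL, condition = "WT",
    sim = list(),
    # insertions
    shift_plus = 5L, shift_minus = -5L, mapq_floor = 30L,
    # inputs (optional; when set, simulation is skipped)
    fragments_path = NULL, genome_fasta = NULL, annotation_gff3 = NULL,
    # qc
    tss_flank = 1000L, tss_bin = 10L, corr_bin = 1000L,
    # peaks
    peak_window = 200L, peak_step = 50L, peak_min_q = 0.05, peak_merge_gap = 100L,
    # footprints
    fp_sizes = seq(11L, 31L, 2L), fp_shoulder = 35L, fp_threshold = -10,
    # asymmetry
    asym_flank = 100L, asym_n_perm = 1000L,
    # motifs
    promoter_bp = 1000L,
    verbosity = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "fatac_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()].
#' @return a `fatac_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

pipeline_log <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1L) > 0) message("[fatac] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or fixture loading), insertion-track construction,
#' QC, peak calling, footprint detection, strand-asymmetry testing and known
#' motif scanning, writing each stage's outputs plus a JSON provenance
#' record (parameters, seed, stage counts) under `config$out_dir`. Re-running
#' with the same configuration reproduces the outputs.
#'
#' @param config a `fatac_config` from [run_config()] or [read_config()].
#' @return invisible list with the main in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "fatac_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts_log <- list()

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$fragments_path)) {
    genome_seq <- read_fasta(cfg$genome_fasta)
    chrom_lengths <- setNames(nchar(genome_seq), names(genome_seq))
    genes <- read_gff3(cfg$annotation_gff3)
    genome <- structure(
      list(seq = genome_seq, chrom_lengths = chrom_lengths, genes = genes,
           motif_instances = tibble()),
      class = "fatac_genome"
    )
    fragments <- fragments_from_alignments(cfg$fragments_path, cfg$mapq_floor)
    truth <- NULL
    pipeline_log(cfg, "loaded ", nrow(fragments), " fragments from ", cfg$fragments_path)
  } else {
    motifs <- cfg$motifs %||% tibble(motif = "PrtT", consensus = "CCGHCGG",
                                     n_instances = 30L)
    genome <- make_genome(cfg$n_chrom, cfg$chrom_length, cfg$n_genes,
                          seed = derive_seed(cfg$seed, "genome"), motifs = motifs)
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = derive_seed(cfg$seed, "sim")),
                                         cfg$sim))
    sim <- simulate_condition(genome, sim_cfg, cfg$condition)
    fragments <- sim$fragments
    truth <- sim$truth
    write_fixtures(genome, fragments, truth, file.path(cfg$out_dir, "fixtures"))
    pipeline_log(cfg, "simulated ", nrow(fragments), " fragments (",
                 cfg$condition, ")")
  }
  counts_log$fragments_in <- nrow(fragments)

  # --- insertions -----------------------------------------------------
  fragments <- deduplicate(fragments)
  counts_log$fragments_dedup <- nrow(fragments)
  events <- insertion_events(fragments, cfg$shift_plus, cfg$shift_minus,
                             genome$chrom_lengths)
  counts_log$events <- nrow(events)
  counts_log$events_dropped <- attr(events, "n_dropped")
  track <- build_track(events, genome)
  write_bedgraph_pair(track, file.path(cfg$out_dir, "insertions"))

  # --- qc -------------------------------------------------------------
  hist <- length_histogram(fragments)
  readr::write_tsv(hist, file.path(cfg$out_dir, "fragment_lengths.tsv"))
  period <- estimate_period(hist)
  qc_tss <- NULL
  if (nrow(genome$genes) > 0) {
    qc_tss <- tss_matrix(fragments, genome$genes, genome$chrom_lengths,
                         flank = cfg$tss_flank, bin = cfg$tss_bin)
    readr::write_tsv(qc_tss$profile, file.path(cfg$out_dir, "tss_profile.tsv"))
  }
  pipeline_log(cfg, "period estimate: ", period$period, " bp")

  # --- peaks ----------------------------------------------------------
  peaks <- call_peaks(track, cfg$peak_window, cfg$peak_step, cfg$peak_min_q,
                      cfg$peak_merge_gap)
  counts_log$peaks <- nrow(peaks)
  write_narrowpeak(peaks, file.path(cfg$out_dir, "peaks.narrowPeak"))
  annot <- annotate_peaks(peaks, genome$genes, cfg$promoter_bp)
  readr::write_tsv(annot, file.path(cfg$out_dir, "peak_annotation.tsv"))
  pipeline_log(cfg, counts_log$peaks, " peaks")

  # --- footprints -----------------------------------------------------
  fp <- detect_footprints(track, peaks,
                          footprint_params(cfg$fp_sizes, cfg$fp_shoulder,
                                           cfg$fp_threshold))
  counts_log$footprints <- nrow(fp)
  if (nrow(fp) > 0) {
    write_bed(tibble(chrom = fp$chrom, start = fp$start, end = fp$end,
                     name = fp$peak_id,
                     score = pmin(1000, round(-10 * fp$score)),
                     strand = "."),
              file.path(cfg$out_dir, "footprints.bed"))
  }
  pipeline_log(cfg, counts_log$footprints, " footprints")

  # --- asymmetry + motifs --------------------------------------------
  asym <- NULL
  motif_hits <- NULL
  if (nrow(genome$motif_instances) > 0) {
    inst <- genome$motif_instances
    asym <- permutation_test(track, inst, cfg$asym_flank, cfg$asym_n_perm,
                             seed = derive_seed(cfg$seed, "asym"))
    readr::write_tsv(asym$profile, file.path(cfg$out_dir, "strand_profile.tsv"))
    jsonlite::write_json(tidy(asym), file.path(cfg$out_dir, "asymmetry.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (nrow(fp) > 0) {
    fp_ext <- extend_footprints(fp, 10L, genome$chrom_lengths)
    motif_hits <- bind_rows(lapply(known_motifs()$motif, function(m) {
      scan_motif(genome, m, intervals = fp_ext)
    }))
    if (nrow(motif_hits) > 0) {
      write_bed(tibble(chrom = motif_hits$chrom, start = motif_hits$start,
                       end = motif_hits$end, name = motif_hits$motif,
                       score = 0, strand = motif_hits$strand),
                file.path(cfg$out_dir, "motif_instances.bed"))
    }
  }

  provenance <- list(
    package = "fatac",
    version = as.character(utils::packageVersion("fatac")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("motifs", "sim"))],
    counts = counts_log
  )
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(
    genome = genome, fragments = fragments, track = track, truth = truth,
    histogram = hist, period = period, tss = qc_tss, peaks = peaks,
    annotation = annot, footprints = fp, asymmetry = asym,
    motif_hits = motif_hits, out_dir = cfg$out_dir
  ))
}
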