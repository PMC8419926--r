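# Readers and writers for the standard formats the pipeline touches.
# Convention: all in-memory coordinates are 0-based half-open; GFF3 is the
# only 1-based inclusive boundary and is converted on read/write.

#' Write genome sequences to FASTA
#'
#' @param genome a `fatac_genome` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "fatac_genome")) genome$seq else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene annotation to GFF3
#'
#' Emits `gene` and `exon` features, converting the package's 0-based
#' half-open intervals to GFF3's 1-based inclusive coordinates.
#'
#' @param genes gene annotation tibble (as in `fatac_genome$genes`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tfatac\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    ex <- g$exons[[1]]
    if (!is.null(ex) && nrow(ex) > 0) {
      for (k in seq_len(nrow(ex))) {
        writeLines(sprintf("%s\tfatac\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                           g$chrom, ex$start[k] + 1L, ex$end[k], g$strand,
                           g$gene_id, k, g$gene_id), con)
      }
    }
  }
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Parses gene and exon features, converting 1-based inclusive coordinates
#' to 0-based half-open. The TSS is the gene start on the + strand and
#' `end - 1` on the - strand.
#'
#' @param path GFF3 file.
#' @return gene annotation tibble (gene_id, chrom, start, end, strand, tss,
#'   tts, exons).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), tss = integer(),
                  tts = integer(), exons = list()))
  }
  out <- tibble(
    gene_id = as.character(genes$ID),
    chrom = as.character(genes$seqnames),
    start = as.integer(genes$start - 1L),
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  out <- mutate(out,
    tss = as.integer(ifelse(.data$strand == "+", .data$start, .data$end - 1L)),
    tts = as.integer(ifelse(.data$strand == "+", .data$end - 1L, .data$start))
  )
  parents <- if (nrow(exons) > 0) {
    vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  } else {
    character(0)
  }
  out$exons <- lapply(out$gene_id, function(g) {
    ex <- exons[parents == g, , drop = FALSE]
    if (nrow(ex) == 0) {
      tibble(start = integer(), end = integer())
    } else {
      arrange(tibble(start = as.integer(ex$start - 1L), end = as.integer(ex$end)),
              .data$start)
    }
  })
  arrange(out, .data$chrom, .data$start)
}

sort_records <- function(x) arrange(x, .data$chrom, .data$start, .data$end)

#' Read/write BED6 interval records
#'
#' @param path file path.
#' @param records tibble with chrom, start, end, name, score, strand.
#' @return `read_bed()` returns the records tibble; writers return the path.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicdc")
  as_tibble(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  col_or <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else default
  }
  out <- tibble(
    chrom = records$chrom,
    start = as.integer(records$start),
    end = as.integer(records$end),
    name = col_or("name", "."),
    score = col_or("score", 0),
    strand = col_or("strand", ".")
  )
  if (any(out$start >= out$end)) abort("BED records require start < end")
  readr::write_tsv(sort_records(out), path, col_names = FALSE)
  invisible(path)
}

#' Read/write BEDPE paired-end fragment records
#'
#' @param path file path.
#' @param fragments fragment tibble (chrom, start, end); each fragment is
#'   written as a read pair covering its two ends.
#' @param read_length nominal read length used for the two blocks.
#' @return `read_bedpe()` returns the raw 10-column tibble;
#'   `write_bedpe()` returns the path.
#' @export
read_bedpe <- function(path) {
  readr::read_tsv(path, col_names = c("chrom1", "start1", "end1", "chrom2",
                                      "start2", "end2", "name", "score",
                                      "strand1", "strand2"),
                  col_types = "ciiciicccc")
}

#' @rdname read_bedpe
#' @export
write_bedpe <- function(fragments, path, read_length = 50L) {
  fr <- sort_records(fragments)
  rl <- pmin(as.integer(read_length), fr$end - fr$start)
  out <- tibble(
    chrom1 = fr$chrom, start1 = as.integer(fr$start),
    end1 = as.integer(fr$start + rl),
    chrom2 = fr$chrom, start2 = as.integer(fr$end - rl),
    end2 = as.integer(fr$end),
    name = sprintf("frag%07d", seq_len(nrow(fr))),
    score = ".", strand1 = "+", strand2 = "-"
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read/write ENCODE narrowPeak records
#'
#' 10-column BED6+4; column 10 is the summit offset from the interval start,
#' with -1 meaning "no summit".
#'
#' @param path file path.
#' @param peaks a `fatac_peaks` tibble.
#' @return `read_narrowpeak()` returns a peaks tibble; the writer returns
#'   the path.
#' @export
read_narrowpeak <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand", "signalValue",
                                           "pValue", "qValue", "peak"),
                       col_types = "ciicdcdddi")
  tibble(
    peak_id = x$name, chrom = x$chrom, start = x$start, end = x$end,
    summit = ifelse(x$peak < 0, NA_integer_, x$start + x$peak),
    count = NA_integer_,
    enrichment = x$signalValue,
    p = 10^(-x$pValue), q = 10^(-x$qValue)
  )
}

#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(peaks, path) {
  pk <- sort_records(peaks)
  out <- tibble(
    chrom = pk$chrom, start = as.integer(pk$start), end = as.integer(pk$end),
    name = pk$peak_id,
    score = as.integer(pmin(1000, round(-10 * log10(pmax(pk$q, 1e-100))))),
    strand = ".",
    signalValue = round(pk$enrichment, 5),
    pValue = round(-log10(pmax(pk$p, 1e-300)), 5),
    qValue = round(-log10(pmax(pk$q, 1e-300)), 5),
    peak = as.integer(ifelse(is.na(pk$summit), -1L, pk$summit - pk$start))
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Export an insertion track as a pair of per-strand bedGraph files
#'
#' @param track a `fatac_track`.
#' @param prefix output path prefix; files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written.
#' @return named character vector of the two paths.
#' @export
write_bedgraph_pair <- function(track, prefix) {
  paths <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
  td <- tidy(track)
  for (s in c("plus", "minus")) {
    sub <- td[td$strand == (if (s == "plus") "+" else "-"), ]
    readr::write_tsv(
      tibble(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1L,
             count = sub$count),
      paths[[s]], col_names = FALSE
    )
  }
  invisible(paths)
}

#' Write simulator outputs as a fixture directory
#'
#' Emits FASTA (genome), GFF3 (genes), BEDPE (fragments), BED6 (truth
#' footprints; score 1 = bound, 0 = unbound) and a JSON truth/metadata
#' record. All files round-trip through the package's readers.
#'
#' @param genome a `fatac_genome`.
#' @param fragments fragment tibble.
#' @param truth a `fatac_truth`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(genome, fragments, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    bedpe = file.path(out_dir, "fragments.bedpe"),
    truth_bed = file.path(out_dir, "truth_footprints.bed"),
    truth_json = file.path(out_dir, "truth.json")
  )
  tryCatch({
    write_fasta(genome, paths[["fasta"]])
    write_gff3(genome$genes, paths[["gff3"]])
    write_bedpe(fragments, paths[["bedpe"]])
    fp <- truth$footprints
    write_bed(tibble(
      chrom = fp$chrom, start = fp$start, end = fp$end,
      name = fp$motif, score = as.numeric(fp$bound), strand = fp$strand
    ), paths[["truth_bed"]])
    jsonlite::write_json(
      list(
        condition = truth$condition,
        n_fragments = nrow(fragments),
        n_planted = nrow(fp),
        n_bound = sum(fp$bound),
        chrom_lengths = as.list(genome$chrom_lengths),
        nucleosome_dyads = truth$nucleosome_dyads
      ),
      paths[["truth_json"]], auto_unbox = TRUE, digits = NA
    )
  }, error = function(e) {
    abort(paste0("failed writing fixtures under ", out_dir, ": ",
                 conditionMessage(e)))
  })
  paths
}
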