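#' Known Aspergillus transcription-factor motifs shipped with the package
#'
#' Loads the plain-text consensus file under `inst/extdata/known_motifs.txt`.
#' Only the AmyR and PrtT spellings are literature-anchored for A. niger;
#' the remaining entries are widely used fungal consensus motifs included as
#' a documented extension point (see the file header for provenance notes).
#'
#' @return tibble with `motif` and `consensus`.
#' @export
known_motifs <- function() {
  path <- system.file("extdata", "known_motifs.txt", package = "fatac")
  readr::read_tsv(path, comment = "#", col_types = "cc")
}

#' Scan sequences or genome intervals for an IUPAC consensus motif
#'
#' Exact IUPAC matching (zero mismatches) on both strands, via
#' `Biostrings::vmatchPattern(fixed = FALSE)`. A palindromic site matching
#' both strands at the same interval is reported once, on the + strand.
#'
#' @param genome a `fatac_genome`, or a named character vector of sequences.
#' @param motif motif id (looked up in [known_motifs()]) or an IUPAC
#'   consensus string; gap shorthand like `CGG-N8-MGG` is accepted.
#' @param intervals optional tibble (chrom, start, end): restrict the scan
#'   to these intervals; reported coordinates stay genomic. An `interval_id`
#'   column, when present, is propagated.
#' @return tibble of class `fatac_instances`: chrom, start, end, strand,
#'   motif, match_seq (plus `interval_id` when scanning intervals).
#' @export
scan_motif <- function(genome, motif, intervals = NULL) {
  seqs <- if (inherits(genome, "fatac_genome")) genome$seq else genome
  cons_in <- motif
  km <- tryCatch(known_motifs(), error = function(e) NULL)
  if (!is.null(km) && motif %in% km$motif) {
    cons_in <- km$consensus[km$motif == motif][1]
    motif_id <- motif
  } else {
    motif_id <- motif
  }
  cons <- normalize_consensus(cons_in)

  if (!is.null(intervals)) {
    ids <- if ("interval_id" %in% names(intervals)) {
      intervals$interval_id
    } else {
      sprintf("iv%05d", seq_len(nrow(intervals)))
    }
    sub <- setNames(
      vapply(seq_len(nrow(intervals)), function(i) {
        substr(seqs[[intervals$chrom[i]]], intervals$start[i] + 1L, intervals$end[i])
      }, character(1)),
      ids
    )
    hits <- scan_seqs(sub, cons, motif_id)
    if (nrow(hits) == 0) {
      return(structure(
        tibble(chrom = character(), start = integer(), end = integer(),
               strand = character(), motif = character(), match_seq = character(),
               interval_id = character()),
        class = c("fatac_instances", "tbl_df", "tbl", "data.frame")
      ))
    }
    key <- match(hits$chrom, ids)
    hits <- mutate(hits,
      interval_id = .data$chrom,
      start = .data$start + intervals$start[key],
      end = .data$end + intervals$start[key],
      chrom = intervals$chrom[key]
    )
    return(structure(hits, class = c("fatac_instances", class(tibble()))))
  }
  structure(scan_seqs(seqs, cons, motif_id),
            class = c("fatac_instances", class(tibble())))
}

scan_seqs <- function(seqs, cons, motif_id) {
  dna <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::vmatchPattern(cons, dna, fixed = FALSE)
  rc <- revcomp(cons)
  rev_ <- Biostrings::vmatchPattern(rc, dna, fixed = FALSE)
  rows <- list()
  for (i in seq_along(dna)) {
    nm <- names(dna)[i]
    f <- fwd[[i]]
    if (length(f) > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = nm, start = BiocGenerics::start(f) - 1L,
        end = BiocGenerics::end(f), strand = "+"
      )
    }
    r <- rev_[[i]]
    if (length(r) > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = nm, start = BiocGenerics::start(r) - 1L,
        end = BiocGenerics::end(r), strand = "-"
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), motif = character(), match_seq = character()))
  }
  out <- bind_rows(rows)
  # palindromic double hit -> report once on +
  out <- out |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE)
  out$motif <- motif_id
  out$match_seq <- vapply(seq_len(nrow(out)), function(k) {
    substr(seqs[[out$chrom[k]]], out$start[k] + 1L, out$end[k])
  }, character(1))
  arrange(out, .data$chrom, .data$start)
}

#' Motif enrichment in target vs background intervals
#'
#' Interval-level (hit/no-hit) enrichment: the hypergeometric upper-tail
#' p-value asks whether intervals containing at least one motif instance are
#' over-represented among the targets, with the targets + background as the
#' universe. Fold enrichment is the ratio of per-bp hit densities. A motif
#' "passes" under the published rule when fold > `min_fold` and
#' p < `p_threshold`.
#'
#' @param target_intervals,background_intervals interval tibbles
#'   (chrom, start, end).
#' @param motif motif id or IUPAC consensus.
#' @param genome a `fatac_genome` (or named sequence vector).
#' @param min_fold fold cutoff (default 5).
#' @param p_threshold p-value cutoff (default 1e-12).
#' @return tibble: motif, hits_target, hits_background, n_target,
#'   n_background, fold_enrichment, p, passes.
#' @export
motif_enrichment <- function(target_intervals, background_intervals, motif,
                             genome, min_fold = 5, p_threshold = 1e-12) {
  if (nrow(background_intervals) == 0) abort("empty background interval set")
  t_ids <- sprintf("t%06d", seq_len(nrow(target_intervals)))
  b_ids <- sprintf("b%06d", seq_len(nrow(background_intervals)))
  ti <- mutate(target_intervals, interval_id = t_ids)
  bi <- mutate(background_intervals, interval_id = b_ids)
  ht <- scan_motif(genome, motif, intervals = ti)
  hb <- scan_motif(genome, motif, intervals = bi)
  hit_t <- length(unique(ht$interval_id))
  hit_b <- length(unique(hb$interval_id))
  bp_t <- sum(target_intervals$end - target_intervals$start)
  bp_b <- sum(background_intervals$end - background_intervals$start)
  dens_t <- nrow(ht) / bp_t
  dens_b <- nrow(hb) / bp_b
  fold <- if (nrow(ht) == 0) 0 else if (nrow(hb) == 0) Inf else dens_t / dens_b
  # hypergeometric upper tail on interval-level hits
  p <- phyper(hit_t - 1, hit_t + hit_b,
              nrow(ti) + nrow(bi) - hit_t - hit_b, nrow(ti),
              lower.tail = FALSE)
  tibble(
    motif = motif,
    hits_target = hit_t, hits_background = hit_b,
    n_target = nrow(ti), n_background = nrow(bi),
    fold_enrichment = fold, p = p,
    passes = is.finite(fold) && fold > min_fold && p < p_threshold ||
      is.infinite(fold) && p < p_threshold
  )
}

#' Assign motif instances to target genes via promoter windows
#'
#' An instance is assigned to gene G when its midpoint lies within
#' `promoter_bp` upstream of G's TSS (gene-strand aware). An instance
#' between two divergent genes can be assigned to both.
#'
#' @param instances motif-instance tibble (chrom, start, end).
#' @param genes gene annotation tibble.
#' @param promoter_bp promoter window (default 1000).
#' @return tibble: one row per (instance, gene) assignment, with gene_id and
#'   the instance columns.
#' @export
instances_to_targets <- function(instances, genes, promoter_bp = 1000L) {
  if (nrow(instances) == 0) {
    return(mutate(instances, gene_id = character(0)))
  }
  rows <- purrr::map(seq_len(nrow(instances)), function(i) {
    mid <- (instances$start[i] + instances$end[i]) %/% 2L
    g <- genes[genes$chrom == instances$chrom[i], ]
    if (nrow(g) == 0) return(NULL)
    hit <- ifelse(g$strand == "+",
                  mid >= g$tss - promoter_bp & mid < g$tss,
                  mid > g$tss & mid <= g$tss + promoter_bp)
    if (!any(hit)) return(NULL)
    bind_cols(instances[rep(i, sum(hit)), ], tibble(gene_id = g$gene_id[hit]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- bind_cols(instances[0, ], tibble(gene_id = character(0)))
  }
  out
}

#' Intersect motif target genes with differential expression
#'
#' Flags differentially expressed genes with the standard rule
#' |log2FC| >= 1 and p < 0.05 (restricted to the requested direction), and
#' reports the overlap of the motif's target genes with the DEG set along
#' with a hypergeometric enrichment p-value over the expression-table
#' universe.
#'
#' @param target_genes character vector of gene ids (e.g. from
#'   [instances_to_targets()]).
#' @param expression tibble with gene_id, log2FC, p.
#' @param direction `"up"` or `"down"`.
#' @param lfc_min,p_max DEG thresholds (defaults 1 and 0.05).
#' @return tibble: n_targets, n_deg, overlap, universe, p_hyper.
#' @export
integrate_expression <- function(target_genes, expression,
                                 direction = c("up", "down"),
                                 lfc_min = 1, p_max = 0.05) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "log2FC", "p") %in% names(expression)))
  deg <- expression$gene_id[
    abs(expression$log2FC) >= lfc_min & expression$p < p_max &
      (if (direction == "up") expression$log2FC > 0 else expression$log2FC < 0)
  ]
  universe <- unique(expression$gene_id)
  targets <- intersect(unique(target_genes), universe)
  ov <- length(intersect(targets, deg))
  p <- phyper(ov - 1, length(deg), length(universe) - length(deg),
              length(targets), lower.tail = FALSE)
  tibble(
    n_targets = length(targets), n_deg = length(deg), overlap = ov,
    universe = length(universe), p_hyper = p
  )
}

#' Sample length-matched background intervals
#'
#' Draws background intervals with the same widths as the targets from
#' donor regions (typically peaks minus footprints), for use in
#' [motif_enrichment()].
#'
#' @param target_intervals intervals to match (chrom, start, end).
#' @param donor_intervals regions to sample from.
#' @param n number of background intervals (default: 10x targets).
#' @param seed RNG seed.
#' @return interval tibble.
#' @export
sample_background <- function(target_intervals, donor_intervals,
                              n = 10L * nrow(target_intervals), seed = 1) {
  widths <- target_intervals$end - target_intervals$start
  dw <- donor_intervals$end - donor_intervals$start
  with_seed(seed, {
    out <- list()
    tries <- 0L
    while (length(out) < n && tries < 50L * n) {
      tries <- tries + 1L
      w <- sample(widths, 1)
      j <- sample.int(nrow(donor_intervals), 1, prob = dw)
      if (dw[j] < w) next
      s <- donor_intervals$start[j] + sample.int(dw[j] - w + 1L, 1) - 1L
      out[[length(out) + 1L]] <- tibble(
        chrom = donor_intervals$chrom[j], start = s, end = s + w
      )
    }
    if (length(out) < n) abort("could not sample enough background intervals")
    bind_rows(out)
  })
}

#' Subtract footprint intervals from peaks
#'
#' @param peaks,footprints interval tibbles.
#' @return tibble of peak sub-intervals not covered by footprints.
#' @export
peaks_minus_footprints <- function(peaks, footprints) {
  gp <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  if (nrow(footprints) == 0) {
    d <- gp
  } else {
    gf <- GenomicRanges::GRanges(footprints$chrom,
                                 IRanges::IRanges(footprints$start + 1L, footprints$end))
    d <- GenomicRanges::setdiff(gp, gf)
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(d)),
    start = BiocGenerics::start(d) - 1L,
    end = BiocGenerics::end(d)
  )
}
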