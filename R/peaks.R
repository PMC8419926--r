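#' Call accessible-chromatin peaks with a local-Poisson sliding window scan
#'
#' Fixed-width windows are slid along each chromosome and the combined
#' (both-strand) insertion count in each window is tested against a Poisson
#' null whose rate is the most conservative of the genome-wide insertion
#' rate and the local rates in 5 kb and 10 kb neighbourhoods (the dynamic
#' local-lambda idea of standard ATAC/ChIP peak callers). Window p-values
#' are BH-adjusted genome-wide; significant windows closer than `merge_gap`
#' are merged, peaks shorter than `min_width` discarded, and each peak's
#' summit placed at the maximum of the 50 bp-smoothed insertion density.
#'
#' @param track a `fatac_track`.
#' @param window window width in bp (default 200, the typical accessible-
#'   region core).
#' @param step window step in bp (default 50).
#' @param min_qvalue BH q-value cutoff for significant windows (default 0.05).
#' @param merge_gap merge significant windows separated by gaps of at most
#'   this many bp (default 100).
#' @param min_width discard merged peaks shorter than this (default 100).
#' @return tibble of class `fatac_peaks`: peak_id, chrom, start, end, summit,
#'   count, enrichment (fold over local background), p, q. Intervals are
#'   0-based half-open and non-overlapping.
#' @export
call_peaks <- function(track, window = 200L, step = 50L, min_qvalue = 0.05,
                       merge_gap = 100L, min_width = 100L) {
  empty <- tibble(
    peak_id = character(), chrom = character(), start = integer(),
    end = integer(), summit = integer(), count = integer(),
    enrichment = numeric(), p = numeric(), q = numeric()
  )
  if (track$total_events == 0) return(structure(empty, class = c("fatac_peaks", class(empty))))
  genome_rate <- track$total_events / sum(track$chrom_lengths)

  win_tbl <- list()
  for (ch in names(track$counts)) {
    L <- track$chrom_lengths[[ch]]
    if (L < window) next
    v <- track$counts[[ch]]$plus + track$counts[[ch]]$minus
    cs <- c(0, cumsum(v))
    starts <- seq(0L, L - window, by = step)
    x <- cs[starts + window + 1L] - cs[starts + 1L]
    centers <- starts + window %/% 2L
    local_rate <- function(halfw) {
      a <- pmax(0L, centers - halfw)
      b <- pmin(L, centers + halfw)
      (cs[b + 1L] - cs[a + 1L]) / (b - a)
    }
    lam_rate <- pmax(genome_rate, local_rate(2500L), local_rate(5000L))
    lam <- window * lam_rate
    p <- ppois(x - 1, lam, lower.tail = FALSE)
    win_tbl[[ch]] <- tibble(chrom = ch, start = starts, x = x, p = p,
                            lam_rate = lam_rate)
  }
  wins <- bind_rows(win_tbl)
  if (nrow(wins) == 0) return(structure(empty, class = c("fatac_peaks", class(empty))))
  wins$q <- p.adjust(wins$p, method = "BH")
  sig <- wins[wins$q <= min_qvalue, ]
  if (nrow(sig) == 0) return(structure(empty, class = c("fatac_peaks", class(empty))))

  peaks <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    s <- s[order(s$start), ]
    ivs <- merge_intervals(s$start, s$start + window, merge_gap)
    v <- track$counts[[ch]]$plus + track$counts[[ch]]$minus
    cs <- c(0, cumsum(v))
    sm <- as.numeric(stats::filter(v, rep(1 / 50, 50), sides = 2))
    sm[is.na(sm)] <- 0
    for (k in seq_len(nrow(ivs))) {
      a <- ivs$start[k]; b <- ivs$end[k]
      if (b - a < min_width) next
      cnt <- cs[b + 1L] - cs[a + 1L]
      summit <- a + which.max(sm[(a + 1L):b]) - 1L
      member <- s$start >= a & s$start + window <= b
      pmin_ <- min(s$p[member])
      qmin_ <- min(s$q[member])
      lam_loc <- max(s$lam_rate[member])
      peaks[[length(peaks) + 1L]] <- tibble(
        chrom = ch, start = a, end = b, summit = as.integer(summit),
        count = as.integer(cnt),
        enrichment = (cnt / (b - a)) / lam_loc,
        p = pmin_, q = qmin_
      )
    }
  }
  out <- bind_rows(peaks)
  if (nrow(out) == 0) return(structure(empty, class = c("fatac_peaks", class(empty))))
  out <- arrange(out, .data$chrom, .data$start)
  out <- mutate(out, peak_id = sprintf("peak%05d", row_number()), .before = 1)
  structure(out, class = c("fatac_peaks", class(out)))
}

# merge half-open intervals allowing gaps <= gap; inputs sorted by start
merge_intervals <- function(start, end, gap = 0L) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] - out_e <= gap) {
      out_e <- max(out_e, end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- start[i]; out_e <- end[i]
    }
  }
  tibble(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' Assign peaks to genomic feature categories
#'
#' Each peak is categorised by its summit with precedence
#' promoter > TTS > exon > intron > intergenic, where the promoter is the
#' `promoter_bp` window upstream of a TSS (gene-strand aware) and the TTS
#' category a `+/- tts_bp` window around a transcription termination site.
#' The nearest gene is the one minimising |summit - TSS|; the reported
#' distance is signed along the gene (negative = upstream).
#'
#' @param peaks `fatac_peaks` tibble (needs chrom, summit, peak_id).
#' @param genes gene annotation tibble.
#' @param promoter_bp promoter window upstream of the TSS (default 1000).
#' @param tts_bp half-width of the TTS window (default 300).
#' @return tibble: peak_id, category, nearest_gene, distance_to_tss.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 1000L, tts_bp = 300L) {
  if (nrow(peaks) == 0) {
    return(tibble(peak_id = character(), category = character(),
                  nearest_gene = character(), distance_to_tss = integer()))
  }
  purrr::pmap(list(peaks$peak_id, peaks$chrom, peaks$summit), function(id, ch, s) {
    g <- genes[genes$chrom == ch, ]
    cat_ <- "intergenic"
    if (nrow(g) > 0) {
      in_prom <- ifelse(g$strand == "+",
                        s >= g$tss - promoter_bp & s <= g$tss,
                        s >= g$tss & s <= g$tss + promoter_bp)
      in_tts <- abs(s - g$tts) <= tts_bp
      in_gene <- s >= g$start & s < g$end
      in_exon <- purrr::map2_lgl(g$exons, in_gene, function(ex, ing) {
        ing && any(s >= ex$start & s < ex$end)
      })
      cat_ <- if (any(in_prom)) "promoter"
      else if (any(in_tts)) "TTS"
      else if (any(in_exon)) "exon"
      else if (any(in_gene)) "intron"
      else "intergenic"
    }
    if (nrow(g) == 0) {
      return(tibble(peak_id = id, category = cat_,
                    nearest_gene = NA_character_, distance_to_tss = NA_integer_))
    }
    i <- which.min(abs(s - g$tss))
    d <- if (g$strand[i] == "+") s - g$tss[i] else g$tss[i] - s
    tibble(peak_id = id, category = cat_, nearest_gene = g$gene_id[i],
           distance_to_tss = as.integer(d))
  }) |> bind_rows()
}

#' Compare two peak sets (Venn summary)
#'
#' A peak is "common" when it overlaps at least one peak of the other set by
#' `min_overlap_bp` or more. Common counts are reported on each side (they
#' can differ when overlaps are not one-to-one); a flag marks that case.
#'
#' @param peaks_a,peaks_b peak tibbles (chrom, start, end).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list of class `fatac_venn`: n_a, n_b, common_a, common_b,
#'   a_specific, b_specific, asymmetric.
#' @export
overlap_sets <- function(peaks_a, peaks_b, min_overlap_bp = 1L) {
  common_a <- count_overlapping(peaks_a, peaks_b, min_overlap_bp)
  common_b <- count_overlapping(peaks_b, peaks_a, min_overlap_bp)
  structure(
    list(
      n_a = nrow(peaks_a), n_b = nrow(peaks_b),
      common_a = common_a, common_b = common_b,
      a_specific = nrow(peaks_a) - common_a,
      b_specific = nrow(peaks_b) - common_b,
      asymmetric = common_a != common_b
    ),
    class = "fatac_venn"
  )
}

count_overlapping <- function(x, y, min_overlap_bp) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
  # sets with disjoint chromosome names are a legitimate zero-overlap case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gx, gy, minoverlap = as.integer(min_overlap_bp))
  )
  length(unique(S4Vectors::queryHits(hits)))
}

#' @export
print.fatac_venn <- function(x, ...) {
  cat("<fatac_venn> |A| = ", x$n_a, ", |B| = ", x$n_b,
      ", common (A side) = ", x$common_a, ", common (B side) = ", x$common_b,
      "\n  A-specific = ", x$a_specific, ", B-specific = ", x$b_specific,
      if (x$asymmetric) "  [common counts differ between sides]" else "",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy fatac_venn
#' @export
tidy.fatac_venn <- function(x, ...) {
  tibble(
    n_a = x$n_a, n_b = x$n_b, common_a = x$common_a, common_b = x$common_b,
    a_specific = x$a_specific, b_specific = x$b_specific
  )
}

#' Overlap of ChIP-seq peaks with ATAC-seq peaks
#'
#' @param chip_peaks,atac_peaks peak tibbles (chrom, start, end).
#' @param min_overlap_bp minimum overlap in bp.
#' @return tibble: n_chip, n_overlapping, percentage (rounded to 2 decimals).
#' @export
chip_atac_overlap <- function(chip_peaks, atac_peaks, min_overlap_bp = 1L) {
  if (nrow(chip_peaks) == 0) abort("empty ChIP peak set")
  n_ov <- count_overlapping(chip_peaks, atac_peaks, min_overlap_bp)
  tibble(
    n_chip = nrow(chip_peaks),
    n_overlapping = n_ov,
    percentage = round(100 * n_ov / nrow(chip_peaks), 2)
  )
}

#' Build a consensus peak set from several samples
#'
#' Union of the per-sample peaks, merged (gap 0).
#'
#' @param peak_sets list of peak tibbles.
#' @return tibble with peak_id, chrom, start, end.
#' @export
consensus_peaks <- function(peak_sets) {
  all_p <- bind_rows(lapply(peak_sets, function(p) p[, c("chrom", "start", "end")]))
  out <- all_p |>
    group_by(.data$chrom) |>
    group_modify(~ merge_intervals(.x$start, .x$end, gap = 0L)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
  mutate(out, peak_id = sprintf("consensus%05d", row_number()), .before = 1)
}

#' Count insertions per consensus peak per sample
#'
#' @param tracks named list of `fatac_track` objects.
#' @param peaks consensus peak tibble.
#' @return integer matrix, peaks x samples, rownames = peak ids.
#' @export
count_peak_matrix <- function(tracks, peaks) {
  m <- vapply(tracks, function(t) {
    vapply(seq_len(nrow(peaks)), function(i) {
      track_window_count(t, peaks$chrom[i], peaks$start[i], peaks$end[i])
    }, numeric(1))
  }, numeric(nrow(peaks)))
  m <- matrix(as.integer(m), nrow = nrow(peaks),
              dimnames = list(peaks$peak_id, names(tracks)))
  m
}
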