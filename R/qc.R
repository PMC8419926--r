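#' Fragment-length histogram
#'
#' Counts fragments at each length from 1 to `max_length` bp; longer
#' fragments are pooled into the last bin, so the counts always sum to the
#' fragment count.
#'
#' @param fragments fragment tibble.
#' @param max_length largest length bin (default 1000).
#' @return tibble with `length` (1..max_length) and `count`.
#' @export
length_histogram <- function(fragments, max_length = 1000L) {
  len <- pmin(pmax(fragments$length, 1L), max_length)
  tibble(
    length = seq_len(max_length),
    count = tabulate(len, nbins = max_length)
  )
}

#' Estimate nucleosome periodicity from a fragment-length histogram
#'
#' ATAC-seq libraries from chromatin show fragment-length modes at integer
#' multiples of the nucleosome repeat length. The histogram is smoothed,
#' detrended by subtracting a 301-bin moving average (removing the overall
#' exponential decay), and the lag of maximal autocorrelation within
#' `search_range` is reported as the period. The confidence score is the
#' prominence of that autocorrelation peak relative to the spread of the
#' autocorrelation over the search range; estimates with confidence below
#' `min_confidence` (or from fewer than 100 fragments) are flagged
#' unreliable.
#'
#' Only lengths of at least `min_length` bp enter the autocorrelation: the
#' periodicity is a property of the nucleosome-protected fragment classes,
#' and the large sub-nucleosomal peak would otherwise contribute a spurious
#' lag at the NFR-to-mononucleosome spacing.
#'
#' @param histogram tibble from [length_histogram()].
#' @param search_range candidate period range in bp (default 120-300).
#' @param min_confidence reliability threshold on the prominence z-score.
#' @param min_length smallest fragment length entering the autocorrelation
#'   (default 100, the upper edge of the nucleosome-free class).
#' @return list of class `fatac_period`: `period`, `confidence`, `reliable`,
#'   `acf` (tibble of lag and autocorrelation over the search range).
#' @export
estimate_period <- function(histogram, search_range = c(120L, 300L),
                            min_confidence = 3, min_length = 100L) {
  counts <- histogram$count[histogram$length >= min_length]
  if (sum(counts) < 100) {
    return(structure(
      list(period = NA_integer_, confidence = NA_real_, reliable = FALSE,
           acf = tibble(lag = integer(), acf = numeric())),
      class = "fatac_period"
    ))
  }
  lags <- search_range[1]:search_range[2]
  smooth_detrend_acf <- function(cnt) {
    y <- as.numeric(stats::filter(cnt, rep(1 / 5, 5), sides = 2))
    y[is.na(y)] <- cnt[is.na(y)]
    trend <- as.numeric(stats::filter(y, rep(1 / 301, 301), sides = 2))
    # extend the trend to the edges so detrending covers the whole histogram
    first_ok <- which(!is.na(trend))[1]
    last_ok <- max(which(!is.na(trend)))
    trend[seq_len(first_ok - 1)] <- trend[first_ok]
    trend[(last_ok + 1):length(trend)] <- trend[last_ok]
    d <- y - trend
    d <- d - mean(d)
    n <- length(d)
    # unbiased normalisation (divide by the number of overlapping terms)
    # avoids the taper that would otherwise bias the peak towards small lags
    vapply(lags, function(l) {
      (sum(d[1:(n - l)] * d[(l + 1):n]) / (n - l)) / (sum(d^2) / n)
    }, numeric(1))
  }
  ac <- smooth_detrend_acf(counts)
  i_max <- which.max(ac)
  # prominence: the observed peak as a z-score against maximal
  # autocorrelations of shuffled (aperiodic) versions of the histogram,
  # each passed through the same smoothing and detrending
  null_max <- with_seed(20240601L, {
    vapply(seq_len(50L), function(b) {
      max(smooth_detrend_acf(counts[sample.int(length(counts))]))
    }, numeric(1))
  })
  conf <- (ac[i_max] - mean(null_max)) / max(sd(null_max), 1e-12)
  structure(
    list(
      period = as.integer(lags[i_max]),
      confidence = conf,
      reliable = conf >= min_confidence,
      acf = tibble(lag = lags, acf = ac)
    ),
    class = "fatac_period"
  )
}

#' @export
print.fatac_period <- function(x, ...) {
  if (is.na(x$period)) {
    cat("<fatac_period> undefined (too few fragments)\n")
  } else {
    cat("<fatac_period> ", x$period, " bp (confidence ",
        format(x$confidence, digits = 3),
        if (x$reliable) ", reliable" else ", UNRELIABLE", ")\n", sep = "")
  }
  invisible(x)
}

#' @method tidy fatac_period
#' @export
tidy.fatac_period <- function(x, ...) x$acf

#' @method glance fatac_period
#' @export
glance.fatac_period <- function(x, ...) {
  tibble(period = x$period, confidence = x$confidence, reliable = x$reliable)
}

#' Insertion counts around transcription start sites
#'
#' Builds the gene-by-offset matrix underlying TSS enrichment heatmaps and
#' mean profiles. Offsets are oriented along the gene (negative = upstream
#' for both strands); insertions from both strands are pooled. When
#' `size_class` is given, fragments are classified with
#' [classify_fragments()] and only the requested class contributes.
#' Insertions falling in the flanks of two genes count in both rows.
#'
#' @param fragments fragment tibble.
#' @param genes gene annotation tibble (needs chrom, tss, strand, gene_id).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param flank half-width of the window around the TSS (bp, default 1000).
#' @param bin offset bin width in bp (default 10).
#' @param size_class optional `"NFR"`, `"mono"` or `"oligo"` filter.
#' @param shift_plus,shift_minus read-shift convention.
#' @return list of class `fatac_tss_matrix`: `matrix` (genes x offset bins),
#'   `profile` (tibble of offset and mean count per gene), `genes_used`.
#' @export
tss_matrix <- function(fragments, genes, chrom_lengths, flank = 1000L,
                       bin = 10L, size_class = NULL,
                       shift_plus = 5L, shift_minus = -5L) {
  if (nrow(genes) == 0) abort("annotation is empty")
  if (!is.null(size_class)) {
    fragments <- classify_fragments(fragments)
    fragments <- fragments[fragments$size_class == size_class, ]
  }
  ev <- insertion_events(fragments, shift_plus, shift_minus, chrom_lengths)
  usable <- genes[genes$tss - flank >= 0 &
                    genes$tss + flank < unname(chrom_lengths[genes$chrom]), ]
  n_bins <- (2L * flank) %/% bin
  offsets <- seq(-flank, flank - bin, by = bin) + bin / 2
  mat <- matrix(0L, nrow = nrow(usable), ncol = n_bins,
                dimnames = list(usable$gene_id, NULL))
  ev_by_chrom <- split(ev$pos, ev$chrom)
  for (i in seq_len(nrow(usable))) {
    pos <- ev_by_chrom[[usable$chrom[i]]]
    if (is.null(pos)) next
    off <- pos - usable$tss[i]
    if (usable$strand[i] == "-") off <- -off
    off <- off[off >= -flank & off < flank]
    if (length(off) == 0) next
    mat[i, ] <- tabulate((off + flank) %/% bin + 1L, nbins = n_bins)
  }
  structure(
    list(
      matrix = mat,
      profile = tibble(offset = offsets, mean_count = colMeans(mat)),
      genes_used = usable$gene_id,
      flank = flank, bin = bin, size_class = size_class %||% "all"
    ),
    class = "fatac_tss_matrix"
  )
}

#' @export
print.fatac_tss_matrix <- function(x, ...) {
  cat("<fatac_tss_matrix> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " bins (", x$bin, " bp), class ", x$size_class, "\n", sep = "")
  invisible(x)
}

#' @method tidy fatac_tss_matrix
#' @export
tidy.fatac_tss_matrix <- function(x, ...) x$profile

#' Between-sample correlation of binned insertion counts
#'
#' Genome-wide insertion counts are summed in fixed-size bins per sample and
#' correlated (Spearman by default), the standard replicate-concordance
#' diagnostic for ATAC-seq libraries.
#'
#' @param tracks named list of `fatac_track` objects on the same genome.
#' @param bin_size bin width in bp (default 1 kb).
#' @param method correlation method (default `"spearman"`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(tracks, bin_size = 1000L, method = "spearman") {
  stopifnot(length(tracks) >= 2)
  lens <- tracks[[1]]$chrom_lengths
  for (t in tracks) {
    if (!identical(t$chrom_lengths, lens)) abort("tracks are on different genomes")
  }
  binned <- vapply(tracks, function(t) {
    unlist(lapply(names(lens), function(ch) {
      v <- t$counts[[ch]]$plus + t$counts[[ch]]$minus
      idx <- (seq_along(v) - 1L) %/% bin_size
      as.numeric(rowsum(v, idx))
    }), use.names = FALSE)
  }, numeric(sum((unname(lens) - 1L) %/% bin_size + 1L)))
  m <- cor(binned, method = method)
  diag(m) <- 1
  m
}
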