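#' Load aligned paired-end fragments
#'
#' Reads fragments from a BEDPE file, a coordinate-sorted paired-end BAM, or
#' a data frame that already holds fragment intervals. One fragment is
#' emitted per template, spanning from the leftmost aligned base to the
#' rightmost. Secondary and supplementary alignments are ignored; BAM pairs
#' below the mapping-quality floor or not properly paired are skipped (their
#' count is attached as the `n_skipped` attribute).
#'
#' @param x path to a `.bedpe`/`.bed` file, path to a `.bam` file, or a data
#'   frame with columns chrom/start/end.
#' @param mapq_floor minimum mapping quality for BAM records (default 30).
#' @return tibble with columns `chrom`, `start`, `end`, `length`
#'   (0-based half-open).
#' @export
fragments_from_alignments <- function(x, mapq_floor = 30) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    out <- as_tibble(x[, c("chrom", "start", "end")])
  } else if (grepl("\\.bam$", x, ignore.case = TRUE)) {
    out <- fragments_from_bam(x, mapq_floor)
  } else {
    pe <- read_bedpe(x)
    out <- tibble(
      chrom = pe$chrom1,
      start = pmin(pe$start1, pe$start2),
      end = pmax(pe$end1, pe$end2)
    )
    if (any(pe$chrom1 != pe$chrom2)) {
      n_skip <- sum(pe$chrom1 != pe$chrom2)
      out <- out[pe$chrom1 == pe$chrom2, ]
      attr(out, "n_skipped") <- n_skip
    }
  }
  out <- mutate(out,
    chrom = as.character(.data$chrom),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    length = .data$end - .data$start
  )
  if (any(out$length <= 0)) abort("fragments must satisfy start < end")
  out
}

fragments_from_bam <- function(path, mapq_floor) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "isize", "mapq"),
    mapqFilter = as.integer(mapq_floor)
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  # keep the leftmost read of each template (TLEN > 0 by convention), so one
  # record per fragment: template spans [pos - 1, pos - 1 + isize)
  keep <- !is.na(res$isize) & res$isize > 0
  tibble(
    chrom = as.character(res$rname)[keep],
    start = as.integer(res$pos[keep] - 1L),
    end = as.integer(res$pos[keep] - 1L + res$isize[keep])
  )
}

#' Remove duplicate fragments
#'
#' Fragments sharing an identical (chrom, start, end) key are collapsed to a
#' single representative; input order of first occurrences is preserved.
#'
#' @param fragments fragment tibble.
#' @return deduplicated tibble; attribute `n_duplicates` holds the number of
#'   removed records.
#' @export
deduplicate <- function(fragments) {
  key_dup <- duplicated(fragments[, c("chrom", "start", "end")])
  out <- fragments[!key_dup, ]
  attr(out, "n_duplicates") <- sum(key_dup)
  out
}

#' Convert fragments to strand-resolved Tn5 insertion events
#'
#' Each fragment end marks a Tn5 cut. Because the transposase introduces two
#' cuts 9 bp apart, plus-strand read starts are shifted +5 and minus-strand
#' read ends -5 to centre events on the insertion midpoint: the + event lands
#' at `start + shift_plus`, the - event at `end - 1 + shift_minus`. Events
#' shifted outside chromosome bounds are dropped and tallied.
#'
#' @param fragments fragment tibble.
#' @param shift_plus,shift_minus bp shifts (defaults +5 / -5; the ENCODE
#'   +4/-5 convention can be configured here).
#' @param chrom_lengths optional named vector for bounds checking.
#' @return tibble with `chrom`, `pos` (0-based), `strand`; attribute
#'   `n_dropped` counts out-of-bounds events.
#' @export
insertion_events <- function(fragments, shift_plus = 5L, shift_minus = -5L,
                             chrom_lengths = NULL) {
  ev <- bind_rows(
    tibble(chrom = fragments$chrom,
           pos = as.integer(fragments$start + shift_plus), strand = "+"),
    tibble(chrom = fragments$chrom,
           pos = as.integer(fragments$end - 1L + shift_minus), strand = "-")
  )
  n_dropped <- 0L
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[ev$chrom])
    ok <- ev$pos >= 0L & ev$pos < lim & !is.na(lim)
    n_dropped <- sum(!ok)
    ev <- ev[ok, ]
  } else {
    ok <- ev$pos >= 0L
    n_dropped <- sum(!ok)
    ev <- ev[ok, ]
  }
  attr(ev, "n_dropped") <- n_dropped
  ev
}

#' Classify fragments by length into nucleosome-occupancy classes
#'
#' Sub-100 bp fragments are nucleosome-free (NFR), 180-247 bp fragments
#' mononucleosomal, longer fragments oligonucleosomal. Lengths in
#' \[100, 180) are labelled `ambiguous` and excluded from class-specific
#' analyses.
#'
#' @param fragments fragment tibble with a `length` column.
#' @param bounds named numeric vector `c(nfr_max=100, mono_min=180, mono_max=247)`.
#' @return input tibble with a `size_class` column; attribute `class_counts`.
#' @export
classify_fragments <- function(fragments,
                               bounds = c(nfr_max = 100, mono_min = 180, mono_max = 247)) {
  stopifnot(all(c("nfr_max", "mono_min", "mono_max") %in% names(bounds)))
  if (!(bounds["nfr_max"] <= bounds["mono_min"] && bounds["mono_min"] <= bounds["mono_max"])) {
    abort("size-class bounds overlap: require nfr_max <= mono_min <= mono_max")
  }
  len <- fragments$length
  cls <- dplyr::case_when(
    len < bounds["nfr_max"] ~ "NFR",
    len >= bounds["mono_min"] & len <= bounds["mono_max"] ~ "mono",
    len > bounds["mono_max"] ~ "oligo",
    TRUE ~ "ambiguous"
  )
  out <- mutate(fragments, size_class = cls)
  attr(out, "class_counts") <- table(factor(cls, levels = c("NFR", "ambiguous", "mono", "oligo")))
  out
}

#' Build a per-base, per-strand insertion-count track
#'
#' @param events event tibble from [insertion_events()].
#' @param genome a `fatac_genome`, or a named vector of chromosome lengths.
#' @return object of class `fatac_track`: per chromosome two integer count
#'   vectors (`plus`, `minus`) of chromosome length, plus `total_events`.
#' @export
build_track <- function(events, genome) {
  lens <- if (inherits(genome, "fatac_genome")) genome$chrom_lengths else genome
  stopifnot(!is.null(names(lens)))
  missing <- setdiff(unique(events$chrom), names(lens))
  if (length(missing) > 0) {
    abort(paste0("events on chromosomes absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  counts <- lapply(names(lens), function(ch) {
    sub <- events[events$chrom == ch, ]
    list(
      plus = tabulate(sub$pos[sub$strand == "+"] + 1L, nbins = lens[[ch]]),
      minus = tabulate(sub$pos[sub$strand == "-"] + 1L, nbins = lens[[ch]])
    )
  })
  names(counts) <- names(lens)
  structure(
    list(counts = counts, chrom_lengths = lens, total_events = nrow(events)),
    class = "fatac_track"
  )
}

#' @export
print.fatac_track <- function(x, ...) {
  cat("<fatac_track> ", length(x$counts), " chromosome(s), ",
      format(x$total_events, big.mark = ","), " insertion events\n", sep = "")
  invisible(x)
}

#' Tidy an insertion track into a sparse tibble
#'
#' @param x a `fatac_track`.
#' @param ... unused.
#' @return tibble with `chrom`, `pos` (0-based), `strand`, `count` for all
#'   non-zero positions.
#' @method tidy fatac_track
#' @export
tidy.fatac_track <- function(x, ...) {
  rows <- lapply(names(x$counts), function(ch) {
    bind_rows(lapply(c("plus", "minus"), function(s) {
      v <- x$counts[[ch]][[s]]
      nz <- which(v > 0L)
      tibble(chrom = ch, pos = nz - 1L,
             strand = if (s == "plus") "+" else "-", count = v[nz])
    }))
  })
  arrange(bind_rows(rows), .data$chrom, .data$pos, .data$strand)
}

# counts within a 0-based half-open window, one strand ("plus"/"minus") or
# both when strand is NULL
track_window_count <- function(track, chrom, start, end, strand = NULL) {
  v <- track$counts[[chrom]]
  idx <- (start + 1L):end
  if (is.null(strand)) sum(v$plus[idx]) + sum(v$minus[idx]) else sum(v[[strand]][idx])
}

#' Convert fragments directly into an insertion track
#'
#' Convenience wrapper: deduplicate, shift, bounds-check, count.
#'
#' @inheritParams insertion_events
#' @param genome `fatac_genome` or named chromosome-length vector.
#' @param dedup collapse duplicate fragments first (default TRUE).
#' @return a `fatac_track`.
#' @export
track_from_fragments <- function(fragments, genome, shift_plus = 5L,
                                 shift_minus = -5L, dedup = TRUE) {
  lens <- if (inherits(genome, "fatac_genome")) genome$chrom_lengths else genome
  if (dedup) fragments <- deduplicate(fragments)
  ev <- insertion_events(fragments, shift_plus, shift_minus, chrom_lengths = lens)
  build_track(ev, lens)
}
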