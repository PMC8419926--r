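#' Footprint detection parameters
#'
#' @param sizes candidate footprint widths in bp; must be odd and >= 5
#'   (default 11 to 31 in steps of 2).
#' @param shoulder flanking shoulder width in bp (default 35); must be at
#'   least half the largest candidate size.
#' @param threshold log10 p-value threshold; only candidates scoring at or
#'   below it are emitted (default -10).
#' @param fdr_mode when TRUE, [detect_footprints()] additionally chooses a
#'   threshold from a strand-and-position-shuffled track so that the
#'   shuffled yield is at most 1% of the real yield, and applies the
#'   stricter of the two thresholds.
#' @return list of class `fatac_fp_params`.
#' @export
footprint_params <- function(sizes = seq(11L, 31L, by = 2L), shoulder = 35L,
                             threshold = -10, fdr_mode = FALSE) {
  if (any(sizes %% 2 == 0) || any(sizes < 5)) abort("candidate sizes must be odd and >= 5")
  if (shoulder < max(sizes) / 2) abort("shoulder must be >= max size / 2")
  structure(
    list(sizes = as.integer(sizes), shoulder = as.integer(shoulder),
         threshold = threshold, fdr_mode = fdr_mode),
    class = "fatac_fp_params"
  )
}

#' Score one footprint candidate (strand-aware binomial depletion)
#'
#' The footprint window `FP = [center - size/2, center + size/2)` is flanked
#' by an upstream shoulder `US` and a downstream shoulder `DS` of width
#' `shoulder`. Plus-strand cuts accumulate on the 5' side of a bound
#' protein, so the forward component asks whether the + strand cuts inside
#' FP are depleted relative to `US + FP`: a binomial lower tail with
#' `n = x(US,+) + x(FP,+)` and `p0 = |FP| / (|FP| + |US|)`. The reverse
#' component mirrors this with DS and - strand cuts. The combined score is
#' `log10 max(p_forward, p_reverse)` — both strands must be depleted, which
#' is what distinguishes protein-bound footprints from Tn5 sequence
#' preference.
#'
#' @param track a `fatac_track`.
#' @param chrom chromosome.
#' @param center 0-based centre position.
#' @param size odd footprint width (bp).
#' @param shoulder shoulder width (bp).
#' @return tibble: p_forward, p_reverse, score.
#' @export
score_candidate <- function(track, chrom, center, size, shoulder = 35L) {
  half <- size %/% 2L
  fp_s <- center - half
  fp_e <- center + half + 1L
  us_s <- fp_s - shoulder
  ds_e <- fp_e + shoulder
  L <- track$chrom_lengths[[chrom]]
  if (us_s < 0 || ds_e > L) abort("candidate window exceeds chromosome bounds")
  x_fp_p <- track_window_count(track, chrom, fp_s, fp_e, "plus")
  x_us_p <- track_window_count(track, chrom, us_s, fp_s, "plus")
  x_fp_m <- track_window_count(track, chrom, fp_s, fp_e, "minus")
  x_ds_m <- track_window_count(track, chrom, fp_e, ds_e, "minus")
  p0 <- size / (size + shoulder)
  pf <- pbinom(x_fp_p, x_fp_p + x_us_p, p0)
  pr <- pbinom(x_fp_m, x_fp_m + x_ds_m, p0)
  tibble(p_forward = pf, p_reverse = pr, score = log10(max(pf, pr)))
}

#' Detect transcription-factor footprints inside peaks
#'
#' Every base of every peak is scored at every candidate size with the
#' strand-aware binomial depletion statistic of [score_candidate()]; the
#' best (most negative) score per position is retained, and non-overlapping
#' footprints are selected greedily in ascending score order until the
#' threshold is reached. Candidates whose footprint-plus-shoulder window
#' extends beyond the peak are skipped. Ties are broken towards the smaller
#' size, then the leftmost position.
#'
#' @param track a `fatac_track`.
#' @param peaks `fatac_peaks` tibble.
#' @param params a `fatac_fp_params` (default [footprint_params()]).
#' @param seed seed for the shuffled-track threshold when `fdr_mode` is on.
#' @return tibble of class `fatac_footprints`: chrom, start, end, center,
#'   size, score, p_forward, p_reverse, peak_id.
#' @export
detect_footprints <- function(track, peaks, params = footprint_params(),
                              seed = 1) {
  thr <- params$threshold
  if (isTRUE(params$fdr_mode)) {
    shuffled <- shuffle_track(track, peaks, seed = seed)
    real <- detect_footprints_core(track, peaks, params$sizes, params$shoulder, 0)
    null <- detect_footprints_core(shuffled, peaks, params$sizes, params$shoulder, 0)
    thr_cands <- sort(unique(real$score), decreasing = TRUE)
    for (t in thr_cands) {
      if (sum(null$score <= t) <= 0.01 * max(1L, sum(real$score <= t))) {
        thr <- min(thr, t)
        break
      }
    }
    out <- real[real$score <= thr, ]
    return(structure(out, class = c("fatac_footprints", class(out))))
  }
  out <- detect_footprints_core(track, peaks, params$sizes, params$shoulder, thr)
  structure(out, class = c("fatac_footprints", class(out)))
}

detect_footprints_core <- function(track, peaks, sizes, shoulder, threshold) {
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    pa <- peaks$start[i]; pb <- peaks$end[i]
    vp <- track$counts[[ch]]$plus
    vm <- track$counts[[ch]]$minus
    csp <- c(0, cumsum(vp[(pa + 1L):pb]))
    csm <- c(0, cumsum(vm[(pa + 1L):pb]))
    plen <- pb - pa
    best_score <- rep(Inf, plen)
    best_size <- rep(NA_integer_, plen)
    best_pf <- rep(NA_real_, plen)
    best_pr <- rep(NA_real_, plen)
    for (size in sizes) {
      half <- size %/% 2L
      # centres (peak-local, 1-based) whose FP +/- shoulder stays in the peak
      lo <- shoulder + half + 1L
      hi <- plen - shoulder - half
      if (hi < lo) next
      cen <- lo:hi
      fp_s <- cen - half; fp_e <- cen + half # inclusive 1-based
      x_fp_p <- csp[fp_e + 1L] - csp[fp_s]
      x_us_p <- csp[fp_s] - csp[fp_s - shoulder]
      x_fp_m <- csm[fp_e + 1L] - csm[fp_s]
      x_ds_m <- csm[fp_e + shoulder + 1L] - csm[fp_e + 1L]
      p0 <- size / (size + shoulder)
      pf <- pbinom(x_fp_p, x_fp_p + x_us_p, p0)
      pr <- pbinom(x_fp_m, x_fp_m + x_ds_m, p0)
      sc <- log10(pmax(pf, pr))
      upd <- sc < best_score[cen]
      idx <- cen[upd]
      best_score[idx] <- sc[upd]
      best_size[idx] <- size
      best_pf[idx] <- pf[upd]
      best_pr[idx] <- pr[upd]
    }
    cand <- which(best_score <= threshold)
    if (length(cand) == 0) next
    ord <- cand[order(best_score[cand], best_size[cand], cand)]
    occupied <- logical(plen)
    for (c_ in ord) {
      half <- best_size[c_] %/% 2L
      span <- (c_ - half):(c_ + half)
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      res[[length(res) + 1L]] <- tibble(
        chrom = ch,
        start = pa + c_ - 1L - half,
        end = pa + c_ + half,
        center = pa + c_ - 1L,
        size = best_size[c_],
        score = best_score[c_],
        p_forward = best_pf[c_],
        p_reverse = best_pr[c_],
        peak_id = peaks$peak_id[i]
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      center = integer(), size = integer(), score = numeric(),
      p_forward = numeric(), p_reverse = numeric(), peak_id = character()
    ))
  }
  arrange(bind_rows(res), .data$chrom, .data$start)
}

# permute positions and strands of the counts inside each peak (empirical
# null that preserves per-peak totals)
shuffle_track <- function(track, peaks, seed = 1) {
  with_seed(seed, {
    out <- track
    for (i in seq_len(nrow(peaks))) {
      ch <- peaks$chrom[i]
      idx <- (peaks$start[i] + 1L):peaks$end[i]
      both <- c(out$counts[[ch]]$plus[idx], out$counts[[ch]]$minus[idx])
      both <- both[sample.int(length(both))]
      n <- length(idx)
      out$counts[[ch]]$plus[idx] <- both[seq_len(n)]
      out$counts[[ch]]$minus[idx] <- both[n + seq_len(n)]
    }
    out
  })
}

#' Signed distances from footprints to the nearest TSS
#'
#' @param footprints footprint tibble (chrom, start, end).
#' @param genes gene annotation tibble.
#' @return tibble with `distance` (footprint midpoint minus nearest TSS,
#'   gene-strand signed; negative = upstream) and `nearest_gene`.
#' @export
footprint_tss_distances <- function(footprints, genes) {
  if (nrow(footprints) == 0) {
    return(tibble(distance = integer(), nearest_gene = character()))
  }
  purrr::pmap(list(footprints$chrom, footprints$start, footprints$end),
              function(ch, s, e) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) {
      return(tibble(distance = NA_integer_, nearest_gene = NA_character_))
    }
    mid <- (s + e) %/% 2L
    i <- which.min(abs(mid - g$tss))
    d <- if (g$strand[i] == "+") mid - g$tss[i] else g$tss[i] - mid
    tibble(distance = as.integer(d), nearest_gene = g$gene_id[i])
  }) |> bind_rows()
}

#' Pad footprint intervals
#'
#' Grows each interval by `pad` bp on both sides (the standard widening
#' applied before de novo motif discovery), clipped to chromosome bounds.
#'
#' @param footprints footprint tibble (chrom, start, end).
#' @param pad bp to add on each side (default 10).
#' @param chrom_lengths optional named vector for clipping.
#' @return tibble with padded `start`/`end`.
#' @export
extend_footprints <- function(footprints, pad = 10L, chrom_lengths = NULL) {
  out <- mutate(footprints,
    start = pmax(0L, .data$start - as.integer(pad)),
    end = .data$end + as.integer(pad)
  )
  if (!is.null(chrom_lengths)) {
    out <- mutate(out, end = pmin(.data$end, unname(chrom_lengths[.data$chrom])))
  }
  out
}
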