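#' Simulation configuration for synthetic ATAC-seq libraries
#'
#' Collects the parameters of the fragment generator. Defaults emulate the
#' statistical structure of fungal ATAC-seq libraries: a fragment-length
#' mixture with a sub-nucleosomal exponential class and Gaussian modes at
#' multiples of the nucleosome repeat length, promoter nucleosome-free
#' regions (NFRs) enriched for Tn5 insertion, nucleosomes on a jittered
#' lattice elsewhere, and planted transcription-factor footprints that block
#' insertion and impose an oriented strand bias when bound.
#'
#' @param n_fragments number of fragments to emit (exact; rejection sampling
#'   tops up to this count).
#' @param nfr_fraction mixture weight of the sub-100 bp fragment class.
#' @param nucleosome_period nucleosome repeat length in bp.
#' @param mono_length_mean,mono_length_sd mononucleosomal fragment-length
#'   Gaussian; the k-nucleosome mode sits at `k * mono_length_mean` with sd
#'   `mono_length_sd * sqrt(k)`, k = 1..3.
#' @param nuc_mode_weights relative weights of the 1-, 2- and 3-nucleosome
#'   modes (normalised internally over the non-NFR mass).
#' @param sub_length_scale exponential scale (bp) of the sub-nucleosomal
#'   class, truncated below 100 bp.
#' @param footprint_spec tibble with columns `motif`, `occupancy` (in
#'   \[0,1\]) and `kappa` (strand-bias strength, >= 0) keyed by the motif ids
#'   planted in the genome with [make_genome()].
#' @param nfr_halfwidth promoter NFR half-width around the TSS (bp).
#' @param nfr_enrichment insertion-weight fold enrichment inside promoter NFRs.
#' @param nuc_core nucleosome core width protected from insertion (bp).
#' @param nuc_suppression multiplicative insertion weight inside nucleosome
#'   cores (0 = full protection).
#' @param nuc_jitter_sd sd of the jitter applied to the nucleosome lattice (bp).
#' @param protect_pad bp added on each side of a bound motif to form the
#'   protected footprint (a bound TF shields more than its core motif).
#' @param bias_halfwidth width (bp) of each motif flank over which the
#'   strand bias `exp(kappa)` is applied.
#' @param bias_ratio attenuation of the 3'-flank bias relative to the
#'   5'-flank bias (odds `exp(kappa * bias_ratio)` for the - strand 3' of a
#'   bound motif, vs `exp(kappa)` for the + strand 5' of it). A bound
#'   TF-DNA complex is structurally asymmetric, so the two faces perturb
#'   Tn5 integration unequally; a value below 1 breaks the
#'   reverse-complement mirror symmetry that naked DNA obeys, which is the
#'   signal the asymmetry statistic S detects (at `bias_ratio = 1` the two
#'   flank biases are exact mirror images and S stays at its null value).
#' @param background_insertion_rate relative baseline insertion weight.
#' @param duplication_rate fraction of emitted fragments that are PCR-style
#'   duplicates of other emitted fragments.
#' @param min_fragment_length smallest fragment length generated (bp).
#' @param seed integer seed fixing all randomness.
#' @return a list of class `fatac_sim_config`.
#' @export
simulation_config <- function(n_fragments = 1e5,
                              nfr_fraction = 0.55,
                              nucleosome_period = 200,
                              mono_length_mean = 200,
                              mono_length_sd = 20,
                              nuc_mode_weights = c(0.55, 0.29, 0.16),
                              sub_length_scale = 40,
                              footprint_spec = NULL,
                              nfr_halfwidth = 150,
                              nfr_enrichment = 8,
                              nuc_core = 147,
                              nuc_suppression = 0.15,
                              nuc_jitter_sd = 10,
                              protect_pad = 7,
                              bias_halfwidth = 75,
                              bias_ratio = 0.5,
                              background_insertion_rate = 1,
                              duplication_rate = 0,
                              min_fragment_length = 25,
                              seed = 1) {
  stopifnot(
    n_fragments >= 1,
    nfr_fraction >= 0, nfr_fraction <= 1,
    background_insertion_rate >= 0,
    nfr_enrichment > 0, nuc_suppression >= 0,
    duplication_rate >= 0, duplication_rate < 1
  )
  if (!is.null(footprint_spec)) {
    stopifnot(all(c("motif", "occupancy", "kappa") %in% names(footprint_spec)))
    if (any(footprint_spec$occupancy < 0 | footprint_spec$occupancy > 1)) {
      abort("occupancy must lie in [0, 1]")
    }
    if (any(footprint_spec$kappa < 0)) abort("kappa must be >= 0")
  }
  structure(
    list(
      n_fragments = as.integer(n_fragments),
      nfr_fraction = nfr_fraction,
      nucleosome_period = nucleosome_period,
      mono_length_mean = mono_length_mean,
      mono_length_sd = mono_length_sd,
      nuc_mode_weights = nuc_mode_weights / sum(nuc_mode_weights),
      sub_length_scale = sub_length_scale,
      footprint_spec = footprint_spec,
      nfr_halfwidth = nfr_halfwidth,
      nfr_enrichment = nfr_enrichment,
      nuc_core = nuc_core,
      nuc_suppression = nuc_suppression,
      nuc_jitter_sd = nuc_jitter_sd,
      protect_pad = protect_pad,
      bias_halfwidth = bias_halfwidth,
      bias_ratio = bias_ratio,
      background_insertion_rate = background_insertion_rate,
      duplication_rate = duplication_rate,
      min_fragment_length = min_fragment_length,
      seed = seed
    ),
    class = "fatac_sim_config"
  )
}

#' Simulate an ATAC-seq fragment library for one experimental condition
#'
#' Generates paired-cut fragments whose Tn5 insertion centres follow the
#' accessibility landscape of the requested condition:
#'
#' * `"naked"` — deproteinised DNA: insertion centres uniform, no nucleosome
#'   or footprint protection; strand profiles around any motif are
#'   mirror-symmetric in expectation.
#' * `"WT"` — chromatin: insertions suppressed inside nucleosome cores and
#'   inside bound footprints (per-instance Bernoulli(occupancy)); promoter
#'   NFRs enriched; at bound motifs insertions on the 5' flank are
#'   preferentially assigned to the + strand and on the 3' flank to the -
#'   strand with odds `exp(kappa)` (motif-oriented).
#' * `"TF-deleted:<motif>"` — identical to WT except the named motif's
#'   occupancy is forced to 0.
#'
#' Fragments are emitted so that the standard +5/-5 read shift recovers the
#' simulated insertion centres exactly: a fragment with cut centres `p1 < p2`
#' spans `[p1 - 5, p2 + 6)`.
#'
#' @param genome a `fatac_genome` from [make_genome()].
#' @param config a `fatac_sim_config` from [simulation_config()].
#' @param condition `"WT"`, `"naked"`, or `"TF-deleted:<motif id>"`.
#' @param seed overrides `config$seed` when given.
#' @return list with `fragments` (tibble: chrom, start, end, length) and
#'   `truth` (class `fatac_truth`: planted footprints with bound flags,
#'   nucleosome dyads, condition label).
#' @export
simulate_condition <- function(genome, config, condition = "WT", seed = NULL) {
  stopifnot(inherits(genome, "fatac_genome"), inherits(config, "fatac_sim_config"))
  cond <- parse_condition(condition, genome)
  seed <- seed %||% config$seed
  with_seed(seed, {
    landscape <- build_landscape(genome, config, cond)
    fragments <- sample_fragments(genome, config, landscape)
    if (config$duplication_rate > 0) {
      n_dup <- floor(config$duplication_rate * nrow(fragments))
      if (n_dup > 0) {
        idx_out <- sample.int(nrow(fragments), n_dup)
        idx_src <- sample.int(nrow(fragments), n_dup, replace = TRUE)
        fragments[idx_out, ] <- fragments[idx_src, ]
      }
    }
    fragments <- arrange(fragments, .data$chrom, .data$start, .data$end)
    truth <- structure(
      list(
        footprints = landscape$truth_footprints,
        nucleosome_dyads = landscape$dyads,
        condition = condition
      ),
      class = "fatac_truth"
    )
    list(fragments = fragments, truth = truth)
  })
}

parse_condition <- function(condition, genome) {
  stopifnot(is.character(condition), length(condition) == 1L)
  if (condition == "naked") return(list(kind = "naked", deleted = NULL))
  if (condition == "WT") return(list(kind = "WT", deleted = NULL))
  if (grepl("^TF-deleted:", condition)) {
    m <- sub("^TF-deleted:", "", condition)
    known <- unique(genome$motif_instances$motif)
    if (!m %in% known) abort(paste0("unknown motif in condition: ", m))
    return(list(kind = "WT", deleted = m))
  }
  abort(paste0("unknown condition label: ", condition,
               " (expected WT, naked, or TF-deleted:<motif>)"))
}

# Build, per chromosome, strand- and class-specific insertion weight vectors
# (1-based indexing over chromosome positions), plus ground truth.
build_landscape <- function(genome, config, cond) {
  chroms <- names(genome$seq)
  lens <- genome$chrom_lengths
  naked <- cond$kind == "naked"

  # per-instance bound states
  fp <- genome$motif_instances
  if (nrow(fp) > 0) {
    spec <- config$footprint_spec
    if (is.null(spec)) {
      spec <- tibble(motif = unique(fp$motif), occupancy = 0.9, kappa = 2)
    }
    fp <- left_join(fp, spec, by = "motif")
    fp$occupancy[is.na(fp$occupancy)] <- 0
    fp$kappa[is.na(fp$kappa)] <- 0
    if (!is.null(cond$deleted)) fp$occupancy[fp$motif == cond$deleted] <- 0
    fp$bound <- if (naked) rep(FALSE, nrow(fp)) else runif(nrow(fp)) < fp$occupancy
  } else {
    fp <- mutate(fp, occupancy = numeric(0), kappa = numeric(0), bound = logical(0))
  }

  dyads_all <- list()
  weights <- setNames(vector("list", length(chroms)), chroms)
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    L <- lens[[ci]]
    base <- rep(config$background_insertion_rate, L)
    nfr_zone <- logical(L)

    gsub_genes <- genome$genes[genome$genes$chrom == chrom, ]
    if (!naked && nrow(gsub_genes) > 0) {
      for (tss in gsub_genes$tss) {
        a <- max(1L, tss + 1L - config$nfr_halfwidth)
        b <- min(L, tss + 1L + config$nfr_halfwidth)
        nfr_zone[a:b] <- TRUE
      }
    }

    # nucleosome lattice outside NFRs
    dyads <- integer(0)
    if (!naked) {
      lattice <- seq(config$nucleosome_period %/% 2, L,
                     by = config$nucleosome_period)
      lattice <- as.integer(round(lattice + rnorm(length(lattice), 0, config$nuc_jitter_sd)))
      half_core <- config$nuc_core %/% 2
      lattice <- lattice[lattice - half_core >= 1 & lattice + half_core <= L]
      keep <- !nfr_zone[lattice]
      dyads <- lattice[keep]
      if (length(dyads) > 0) {
        core_idx <- unlist(lapply(dyads, function(d) (d - half_core):(d + half_core)))
        base[core_idx] <- base[core_idx] * config$nuc_suppression
      }
      dyads_all[[chrom]] <- tibble(chrom = chrom, pos = as.integer(dyads - 1L))
    }

    w_nfr <- base
    w_nuc <- base
    if (!naked) {
      w_nfr[nfr_zone] <- w_nfr[nfr_zone] * config$nfr_enrichment
      # nucleosomal-length fragments need a nucleosome: their cuts are
      # depleted inside NFRs just as inside cores
      w_nuc[nfr_zone] <- w_nuc[nfr_zone] * config$nuc_suppression
    }

    bias_plus <- rep(1, L)
    bias_minus <- rep(1, L)
    fsub <- fp[fp$chrom == chrom & fp$bound, , drop = FALSE]
    if (!naked && nrow(fsub) > 0) {
      for (i in seq_len(nrow(fsub))) {
        s <- fsub$start[i]; e <- fsub$end[i]
        ps <- max(1L, s + 1L - config$protect_pad)
        pe <- min(L, e + config$protect_pad)
        w_nfr[ps:pe] <- 0
        w_nuc[ps:pe] <- 0
        k <- fsub$kappa[i]
        if (k > 0) {
          left <- max(1L, ps - config$bias_halfwidth):(ps - 1L)
          right <- (pe + 1L):min(L, pe + config$bias_halfwidth)
          # Tn5 integration is enhanced at the protein-DNA boundary in a
          # strand-specific way: insertions on the motif's 5' flank favour
          # the oriented + strand with odds exp(k), and on the 3' flank the
          # oriented - strand with attenuated odds exp(k * bias_ratio). The
          # favoured strand's weight is multiplied by the odds factor while
          # the opposite strand stays at baseline, giving bound sites the
          # flanking enrichment spikes seen in real footprint profiles. The
          # attenuation makes the two flank perturbations non-mirror-image
          # (the bound complex is structurally asymmetric), which is the
          # departure from reverse-complement symmetry the asymmetry
          # statistic measures. In genomic coordinates the + strand is
          # favoured on the left flank: with full odds for a + match (its
          # 5' side) and attenuated odds for a - match (its 3' side).
          o_left <- exp(if (fsub$strand[i] == "+") k else k * config$bias_ratio)
          o_right <- exp(if (fsub$strand[i] == "+") k * config$bias_ratio else k)
          bias_plus[left] <- bias_plus[left] * o_left
          bias_minus[right] <- bias_minus[right] * o_right
        }
      }
    }

    # the strand-biased edge spikes are carried by sub-nucleosomal
    # fragments; nucleosomal-length fragments are indifferent to TF binding
    weights[[chrom]] <- list(
      nfr_plus = w_nfr * bias_plus,
      nfr_minus = w_nfr * bias_minus,
      nuc_plus = w_nuc,
      nuc_minus = w_nuc
    )
  }

  # the planted footprint is the protected region: the motif plus the
  # protect_pad the bound factor shields on each side
  truth_fp <- fp[, c("chrom", "start", "end", "strand", "motif", "bound")]
  if (nrow(truth_fp) > 0) {
    truth_fp$motif_start <- truth_fp$start
    truth_fp$motif_end <- truth_fp$end
    truth_fp$start <- pmax(0L, as.integer(truth_fp$start - config$protect_pad))
    truth_fp$end <- as.integer(truth_fp$end + config$protect_pad)
  } else {
    truth_fp$motif_start <- integer(0)
    truth_fp$motif_end <- integer(0)
  }
  list(
    weights = weights,
    truth_footprints = as_tibble(truth_fp),
    dyads = if (length(dyads_all)) bind_rows(dyads_all) else
      tibble(chrom = character(), pos = integer())
  )
}

# Fragment-length draws per mixture class.
draw_lengths <- function(class, n, config) {
  if (n == 0) return(integer(0))
  lo <- config$min_fragment_length
  if (class == 1L) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rexp(2L * n, rate = 1 / config$sub_length_scale)
      x <- x[x >= lo & x < 100]
      out <- c(out, x)
    }
    return(as.integer(round(out[seq_len(n)])))
  }
  k <- class - 1L
  x <- rnorm(n, k * config$mono_length_mean, config$mono_length_sd * sqrt(k))
  as.integer(round(pmax(lo, x)))
}

sample_fragments <- function(genome, config, landscape) {
  chroms <- names(genome$seq)
  lens <- genome$chrom_lengths
  class_w <- c(config$nfr_fraction, (1 - config$nfr_fraction) * config$nuc_mode_weights)
  n_class <- as.integer(stats::rmultinom(1, config$n_fragments, class_w))

  out <- list()
  for (cl in seq_along(n_class)) {
    m_total <- n_class[cl]
    if (m_total == 0) next
    kind <- if (cl == 1L) "nfr" else "nuc"
    wp_tot <- vapply(chroms, function(ch) sum(landscape$weights[[ch]][[paste0(kind, "_plus")]]),
                     numeric(1))
    if (sum(wp_tot) <= 0) abort("degenerate insertion landscape: zero total weight")
    m_chrom <- as.integer(stats::rmultinom(1, m_total, wp_tot / sum(wp_tot)))
    for (ci in seq_along(chroms)) {
      m <- m_chrom[ci]
      if (m == 0) next
      chrom <- chroms[ci]
      L <- lens[[ci]]
      wp <- landscape$weights[[chrom]][[paste0(kind, "_plus")]]
      wm <- landscape$weights[[chrom]][[paste0(kind, "_minus")]]
      wm_max <- max(wm)
      acc_s <- integer(0); acc_e <- integer(0)
      while (length(acc_s) < m) {
        need <- m - length(acc_s)
        k_draw <- max(100L, ceiling(need * 2.5))
        p1 <- sample.int(L, k_draw, replace = TRUE, prob = wp)
        len <- draw_lengths(cl, k_draw, config)
        p2 <- p1 + len - 11L
        ok <- p2 > p1 & p1 >= 6L & p2 <= L - 6L
        ok[ok] <- runif(sum(ok)) < wm[p2[ok]] / wm_max
        if (any(ok)) {
          acc_s <- c(acc_s, p1[ok])
          acc_e <- c(acc_e, p2[ok])
        }
      }
      sel <- seq_len(m)
      # fragment [p1-5, p2+6) in 0-based coordinates; internal p are 1-based
      start0 <- acc_s[sel] - 1L - 5L
      end0 <- acc_e[sel] - 1L + 6L
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = as.integer(start0), end = as.integer(end0)
      )
    }
  }
  frags <- bind_rows(out)
  mutate(frags, length = .data$end - .data$start)
}

#' @export
print.fatac_truth <- function(x, ...) {
  cat("<fatac_truth> condition ", x$condition, ": ",
      nrow(x$footprints), " planted footprints (",
      sum(x$footprints$bound), " bound), ",
      nrow(x$nucleosome_dyads), " nucleosome dyads\n", sep = "")
  invisible(x)
}
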