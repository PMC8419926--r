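# Shared fixtures, built once per test run and memoised. The "study"
# fixture reproduces the package's reference simulation conditions: a
# 200 kb two-chromosome genome with 120 genes, 300 planted target-motif
# instances (occupancy 0.9, kappa 2) plus 60 never-bound decoy instances,
# and 1e5 fragments per condition.

.fx <- new.env(parent = emptyenv())

study_motifs <- function() {
  tibble::tibble(
    motif = c("PrtT", "decoy"),
    consensus = c("CCGHCGG", "GATCNNGCTA"),
    n_instances = c(300L, 60L)
  )
}

study_footprint_spec <- function() {
  tibble::tibble(
    motif = c("PrtT", "decoy"),
    occupancy = c(0.9, 0),
    kappa = c(2, 0)
  )
}

study_genome <- function(seed = 11) {
  key <- paste0("genome", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- make_genome(
      2, 100000, 120, seed = seed,
      gene_length_range = c(500, 1000), min_gene_gap = 500,
      motifs = study_motifs()
    )
  }
  .fx[[key]]
}

study_config <- function(n_fragments = 1e5, seed = 5) {
  simulation_config(
    n_fragments = n_fragments, seed = seed,
    footprint_spec = study_footprint_spec()
  )
}

# simulated fragments + insertion track for one condition, memoised
study_condition <- function(condition = "WT", seed = 5, n_fragments = 1e5) {
  key <- paste0(condition, seed, n_fragments)
  if (is.null(.fx[[key]])) {
    g <- study_genome()
    sim <- simulate_condition(g, study_config(n_fragments, seed), condition)
    sim$track <- track_from_fragments(sim$fragments, g)
    .fx[[key]] <- sim
  }
  .fx[[key]]
}

target_instances <- function() {
  g <- study_genome()
  g$motif_instances[g$motif_instances$motif == "PrtT", ]
}

# fraction of intervals in `a` overlapped by at least one interval in `b`
fraction_overlapped <- function(a, b) {
  if (nrow(a) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  mean(hit)
}

# --- independent oracles -------------------------------------------------

# all-pairs interval overlap counting (quadratic reference implementation)
brute_overlap_count <- function(x, y, min_overlap = 1L) {
  n <- 0L
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] == y$chrom[j] &&
          min(x$end[i], y$end[j]) - max(x$start[i], y$start[j]) >= min_overlap) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

# binomial lower tail by direct summation of the pmf
brute_binom_tail <- function(x, n, p) {
  if (n == 0) return(1)
  k <- 0:x
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# textbook BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# hypergeometric upper tail P(X >= x) by summation over the support
brute_hyper_upper <- function(x, white, black, draws) {
  kk <- max(0, x):min(white, draws)
  sum(exp(lchoose(white, kk) + lchoose(black, draws - kk) -
            lchoose(white + black, draws)))
}

# regex-based IUPAC motif scan of a named character vector of sequences,
# both strands, palindromic double hits reported once on +
regex_scan_oracle <- function(seqs, consensus) {
  pat <- fatac:::iupac_to_regex(consensus)
  w <- nchar(fatac::normalize_consensus(consensus))
  rc_seq <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  # overlapping matches via lookahead
  find_all <- function(s) {
    m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  rows <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    for (st in find_all(s)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = nm, start = st - 1L, end = st - 1L + w, strand = "+"
      )
    }
    for (st in find_all(rc_seq(s))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = nm, start = L - (st - 1L) - w, end = L - (st - 1L),
        strand = "-"
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$chrom, out$start, out$strand), ]
  out[!duplicated(out[, c("chrom", "start", "end")]), ]
}
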