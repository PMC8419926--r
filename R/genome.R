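#' Generate a synthetic fungal genome with gene annotation
#'
#' Builds a compact random genome (i.i.d. uniform base composition) with
#' non-overlapping protein-coding genes and, optionally, motif instances
#' planted into promoter regions so that downstream footprinting and motif
#' scanning can be scored against ground truth. Gene density and sizes are
#' chosen to resemble compact filamentous-fungus genomes.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector of chromosome lengths (bp), recycled to
#'   `n_chrom`; each must be at least 10 kb.
#' @param n_genes total number of genes to place across the genome.
#' @param seed integer seed; fixes all randomness.
#' @param motifs optional tibble with columns `motif`, `consensus`,
#'   `n_instances`: IUPAC consensus instances to write into the sequence.
#'   Instances are planted preferentially inside promoter nucleosome-free
#'   regions (upstream of TSSs), falling back to intergenic space.
#' @param gene_length_range min/max gene body length in bp.
#' @param min_gene_gap minimum gap between adjacent genes (bp), leaving room
#'   for promoters.
#' @return An object of class `fatac_genome`: a list with `seq` (named
#'   character vector of chromosome sequences), `chrom_lengths`, `genes`
#'   (tibble: gene_id, chrom, start, end, strand, tss, tts, exons list-col of
#'   half-open interval tibbles) and `motif_instances` (tibble: chrom, start,
#'   end, strand, motif, consensus). All coordinates are 0-based half-open.
#' @export
make_genome <- function(n_chrom = 2,
                        lengths = 150000,
                        n_genes = 100,
                        seed = 1,
                        motifs = NULL,
                        gene_length_range = c(600, 1500),
                        min_gene_gap = 600) {
  stopifnot(n_chrom >= 1, n_genes >= 0)
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(lengths < 10000)) abort("chromosome lengths must be >= 10 kb")
  with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    seqs <- setNames(vapply(lengths, function(L) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)), chroms)

    genes <- place_genes(chroms, lengths, n_genes, gene_length_range, min_gene_gap)

    instances <- tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), motif = character(), consensus = character()
    )
    if (!is.null(motifs) && nrow(motifs) > 0) {
      planted <- plant_motifs(seqs, genes, motifs)
      seqs <- planted$seqs
      instances <- planted$instances
    }

    structure(
      list(
        seq = seqs,
        chrom_lengths = setNames(lengths, chroms),
        genes = genes,
        motif_instances = instances
      ),
      class = "fatac_genome"
    )
  })
}

place_genes <- function(chroms, lengths, n_genes, gene_length_range, min_gene_gap) {
  if (n_genes == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), tss = integer(), tts = integer(),
      exons = list()
    ))
  }
  # capacity check: each gene consumes at most max length + gap
  slot <- max(gene_length_range) + min_gene_gap
  capacity <- sum(pmax(0, (lengths - min_gene_gap) %/% slot))
  if (n_genes > capacity) {
    abort(sprintf("cannot place %d non-overlapping genes (capacity %d)", n_genes, capacity))
  }
  slots_by_chrom <- rep(seq_along(chroms), pmax(0, (lengths - min_gene_gap) %/% slot))
  slots_by_chrom <- slots_by_chrom[sample.int(length(slots_by_chrom))]
  per_chrom <- table(factor(slots_by_chrom[seq_len(n_genes)], levels = seq_along(chroms)))
  rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    k <- as.integer(per_chrom[ci])
    if (k == 0) next
    L <- lengths[ci]
    # jittered regular layout keeps placement feasible and deterministic
    anchors <- floor(seq(min_gene_gap, L - slot, length.out = k))
    for (a in anchors) {
      gid <- gid + 1L
      glen <- as.integer(round(runif(1, gene_length_range[1], gene_length_range[2])))
      start <- as.integer(a + sample.int(max(1L, min_gene_gap %/% 4L), 1))
      end <- min(start + glen, L - 100L)
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") start else end - 1L
      tts <- if (strand == "+") end - 1L else start
      rows[[gid]] <- tibble(
        gene_id = sprintf("gene%04d", gid), chrom = chroms[ci],
        start = start, end = as.integer(end), strand = strand,
        tss = as.integer(tss), tts = as.integer(tts),
        exons = list(make_exons(start, as.integer(end)))
      )
    }
  }
  bind_rows(rows)
}

make_exons <- function(start, end) {
  n_ex <- sample(1:3, 1)
  if (n_ex == 1) return(tibble(start = start, end = end))
  # split gene body at interior points, introns = 50-100 bp around cuts
  body <- end - start
  cuts <- sort(sample(seq(100L, body - 100L, by = 10L), n_ex - 1))
  ex_start <- c(start, start + cuts + sample(50:100, n_ex - 1, replace = TRUE))
  ex_end <- c(start + cuts, end)
  keep <- ex_start < ex_end
  tibble(start = as.integer(ex_start[keep]), end = as.integer(ex_end[keep]))
}

# Write concrete motif instances into the sequence. Sites are placed in
# promoter NFRs (offsets ~ -40..-120 bp upstream of a TSS) first, then in
# intergenic space, never overlapping one another.
plant_motifs <- function(seqs, genes, motifs) {
  stopifnot(all(c("motif", "consensus", "n_instances") %in% names(motifs)))
  occupied <- list()
  is_free <- function(chrom, s, e) {
    occ <- occupied[[chrom]]
    if (is.null(occ)) return(TRUE)
    all(overlap_width(s, e, occ$s, occ$e) == 0)
  }
  mark <- function(chrom, s, e) {
    occupied[[chrom]] <<- bind_rows(occupied[[chrom]], tibble(s = s, e = e))
  }

  # candidate promoter slots: three per gene (two upstream, one just
  # downstream of the TSS), placed centrally enough in the promoter NFR
  # (TSS +/- 150) that a footprint's shoulders stay inside it
  promoter_slots <- if (nrow(genes) > 0) {
    bind_rows(lapply(c(45L, 100L, -60L), function(off) {
      mutate(genes,
        center = ifelse(.data$strand == "+", .data$tss - off, .data$tss + off)
      )[, c("chrom", "center")]
    }))
  } else {
    tibble(chrom = character(), center = integer())
  }
  promoter_slots <- promoter_slots[sample.int(nrow(promoter_slots)), ]
  slot_i <- 1L

  out <- list()
  for (mi in seq_len(nrow(motifs))) {
    cons <- normalize_consensus(motifs$consensus[mi])
    w <- nchar(cons)
    placed <- 0L
    tries <- 0L
    while (placed < motifs$n_instances[mi]) {
      tries <- tries + 1L
      if (tries > motifs$n_instances[mi] * 50L) {
        abort(sprintf("could not place %d instances of motif %s",
                      motifs$n_instances[mi], motifs$motif[mi]))
      }
      if (slot_i <= nrow(promoter_slots)) {
        chrom <- promoter_slots$chrom[slot_i]
        center <- promoter_slots$center[slot_i]
        slot_i <- slot_i + 1L
      } else {
        chrom <- sample(names(seqs), 1)
        center <- sample.int(nchar(seqs[[chrom]]) - 400L, 1) + 200L
      }
      s <- as.integer(center - w %/% 2)
      e <- s + w
      if (s < 100L || e > nchar(seqs[[chrom]]) - 100L) next
      if (!is_free(chrom, s - 20L, e + 20L)) next
      strand <- sample(c("+", "-"), 1)
      site <- sample_consensus_sequence(cons)
      written <- if (strand == "+") site else revcomp(site)
      substr(seqs[[chrom]], s + 1L, e) <- written
      mark(chrom, s - 20L, e + 20L)
      placed <- placed + 1L
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = s, end = as.integer(e), strand = strand,
        motif = motifs$motif[mi], consensus = cons
      )
    }
  }
  list(seqs = seqs, instances = bind_rows(out))
}

#' Extract genome sequence for an interval
#'
#' @param genome a `fatac_genome`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return character scalar (plus-strand sequence).
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "fatac_genome"))
  if (!chrom %in% names(genome$seq)) abort(paste0("unknown chromosome: ", chrom))
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' @export
print.fatac_genome <- function(x, ...) {
  cat("<fatac_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp, ",
      nrow(x$genes), " genes, ", nrow(x$motif_instances),
      " planted motif instances\n", sep = "")
  invisible(x)
}
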