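test_that("consensus normalisation handles gaps and alternatives", {
  expect_equal(normalize_consensus("CGG-N8-MGG"), "CGGNNNNNNNNMGG")
  expect_equal(normalize_consensus("CGGN8(C/A)GG"), "CGGNNNNNNNNMGG")
  expect_equal(normalize_consensus("ccghcgg"), "CCGHCGG")
  expect_error(normalize_consensus("CCGXGG"), "non-IUPAC")
})

test_that("IUPAC matching honours degenerate codes", {
  seqs <- c(s1 = "AACCGACGGTT")
  hits <- scan_motif(seqs, "CCGHCGG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$match_seq, "CCGACGG")
  # H excludes G on the forward strand (a reverse-strand match via D = A/G/T
  # is legitimate and reported separately)
  h2 <- scan_motif(c(s1 = "AACCGGCGGTT"), "CCGHCGG")
  expect_false(any(h2$strand == "+"))
})

test_that("scanning equals the regex oracle on a random sequence", {
  set.seed(19)
  seqs <- c(chrA = paste0(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = ""))
  for (cons in c("CCGHCGG", "SYGGRG", "CACGTG")) {
    hits <- scan_motif(seqs, cons)
    oracle <- regex_scan_oracle(seqs, cons)
    expect_equal(hits$start, oracle$start, info = cons)
    expect_equal(hits$end, oracle$end, info = cons)
    expect_equal(hits$strand, oracle$strand, info = cons)
  }
})

test_that("scanning is strand-consistent under reverse complement", {
  set.seed(23)
  s <- paste0(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  fwd <- scan_motif(c(chr = s), "CCGHCGG")
  rev_ <- scan_motif(c(chr = fatac:::revcomp(s)), "CCGHCGG")
  L <- nchar(s)
  reflected <- tibble::tibble(start = L - rev_$end, end = L - rev_$start,
                              strand = ifelse(rev_$strand == "+", "-", "+"))
  reflected <- reflected[order(reflected$start), ]
  # palindromic double-reports aside, the instance intervals must agree
  expect_equal(fwd$start, reflected$start)
  expect_equal(fwd$end, reflected$end)
})

test_that("palindromic sites are reported once, on the plus strand", {
  seqs <- c(s = "TTTCACGTGTTT")
  hits <- scan_motif(seqs, "CACGTG") # its own reverse complement
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
})

test_that("interval-restricted scans report genomic coordinates", {
  g <- make_genome(1, 20000, 0, seed = 31,
                   motifs = tibble::tibble(motif = "PrtT", consensus = "CCGHCGG",
                                           n_instances = 5L))
  iv <- tibble::tibble(chrom = g$motif_instances$chrom,
                       start = g$motif_instances$start - 30L,
                       end = g$motif_instances$end + 30L)
  hits <- scan_motif(g, "PrtT", intervals = iv)
  for (i in seq_len(nrow(g$motif_instances))) {
    expect_true(any(hits$start == g$motif_instances$start[i]))
  }
  expect_true(all(c("interval_id", "match_seq") %in% names(hits)))
})

test_that("motif enrichment behaves at its fixed points and matches phyper oracle", {
  g <- make_genome(1, 60000, 0, seed = 41,
                   motifs = tibble::tibble(motif = "PrtT", consensus = "CCGHCGG",
                                           n_instances = 40L))
  inst <- g$motif_instances
  targets <- tibble::tibble(chrom = inst$chrom[1:20],
                            start = inst$start[1:20] - 40L,
                            end = inst$end[1:20] + 40L)
  # target = background -> fold 1, not passing
  e0 <- motif_enrichment(targets, targets, "CCGHCGG", g)
  expect_equal(e0$fold_enrichment, 1)
  expect_false(e0$passes)
  # motif-rich targets vs motif-poor background
  set.seed(2)
  bg <- tibble::tibble(chrom = "chr1",
                       start = sample(30000:58000, 200, TRUE))
  bg$end <- bg$start + 87L
  e1 <- motif_enrichment(targets, bg, "CCGHCGG", g, p_threshold = 1e-6)
  expect_true(e1$fold_enrichment > 5)
  expect_true(e1$passes)
  oracle_p <- brute_hyper_upper(e1$hits_target,
                                e1$hits_target + e1$hits_background,
                                e1$n_target + e1$n_background -
                                  e1$hits_target - e1$hits_background,
                                e1$n_target)
  expect_equal(e1$p, oracle_p, tolerance = 1e-10)
  # zero hits anywhere -> fold 0, flagged not passing
  e2 <- motif_enrichment(targets, bg, "TTTTAAAATTTTAAAA", g)
  expect_equal(e2$fold_enrichment, 0)
  expect_false(e2$passes)
  expect_error(motif_enrichment(targets, bg[0, ], "CCGHCGG", g), "background")
})

test_that("hypergeometric tails match exact summation over small supports", {
  for (cfg in list(c(3, 10, 20, 8), c(0, 5, 15, 5), c(7, 12, 30, 10))) {
    expect_equal(phyper(cfg[1] - 1, cfg[2], cfg[3], cfg[4], lower.tail = FALSE),
                 brute_hyper_upper(cfg[1], cfg[2], cfg[3], cfg[4]),
                 tolerance = 1e-12)
  }
})

test_that("promoter assignment respects the gene-strand window", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(5000L, 12000L), end = c(6000L, 13000L), strand = c("+", "-"),
    tss = c(5000L, 12999L), tts = c(5999L, 12000L),
    exons = list(tibble::tibble(start = 5000L, end = 6000L),
                 tibble::tibble(start = 12000L, end = 13000L))
  )
  inst <- tibble::tibble(chrom = "chr1",
                         start = c(4496L, 3496L, 13496L),
                         end = c(4504L, 3504L, 13504L),
                         strand = "+", motif = "m")
  asg <- instances_to_targets(inst, genes)
  # 500 bp upstream of gp assigned; 1500 bp upstream unassigned;
  # 500 bp upstream of the - strand gene (genomically right of its TSS)
  expect_equal(sort(asg$gene_id), c("gm", "gp"))
  expect_equal(asg$start[asg$gene_id == "gp"], 4496L)
  expect_equal(asg$start[asg$gene_id == "gm"], 13496L)
})

test_that("promoter assignment equals a brute-force window scan", {
  g <- study_genome()
  set.seed(51)
  inst <- tibble::tibble(chrom = sample(names(g$chrom_lengths), 300, TRUE),
                         start = sample(500:99000, 300))
  inst$end <- inst$start + 8L
  inst$strand <- "+"
  asg <- instances_to_targets(inst, g$genes)
  oracle <- list()
  for (i in seq_len(nrow(inst))) {
    mid <- (inst$start[i] + inst$end[i]) %/% 2L
    gg <- g$genes[g$genes$chrom == inst$chrom[i], ]
    for (j in seq_len(nrow(gg))) {
      ok <- if (gg$strand[j] == "+") {
        mid >= gg$tss[j] - 1000 && mid < gg$tss[j]
      } else {
        mid > gg$tss[j] && mid <= gg$tss[j] + 1000
      }
      if (ok) oracle[[length(oracle) + 1L]] <- paste(i, gg$gene_id[j])
    }
  }
  got <- paste(match(asg$start, inst$start), asg$gene_id)
  expect_setequal(got, unlist(oracle))
})

test_that("expression integration applies the DEG rule and hypergeometric overlap", {
  expr <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    log2FC = c(rep(2, 20), rep(-2, 20), rep(0.5, 30), rep(1.5, 30)),
    p = c(rep(0.01, 20), rep(0.01, 20), rep(0.01, 30), rep(0.5, 30))
  )
  # DEG(up) = first 20 only: |lfc| >= 1 & p < 0.05 & lfc > 0
  nested <- integrate_expression(expr$gene_id[1:10], expr, "up")
  expect_equal(nested$overlap, 10)
  expect_equal(nested$n_deg, 20)
  disjoint <- integrate_expression(expr$gene_id[41:50], expr, "up")
  expect_equal(disjoint$overlap, 0)
  down <- integrate_expression(expr$gene_id[21:30], expr, "down")
  expect_equal(down$overlap, 10)
  # overlap p matches the exact summation oracle
  expect_equal(nested$p_hyper, brute_hyper_upper(10, 20, 80, 10), tolerance = 1e-12)
})

test_that("planted target/DEG enrichment is detected reliably", {
  set.seed(61)
  hits <- replicate(100, {
    universe <- sprintf("g%04d", 1:5000)
    deg <- sample(universe, 500)
    # targets: 20% drawn from DEGs, 80% from the rest
    targets <- c(sample(deg, 40), sample(setdiff(universe, deg), 160))
    expr <- tibble::tibble(gene_id = universe,
                           log2FC = ifelse(universe %in% deg, 2, 0),
                           p = ifelse(universe %in% deg, 0.001, 0.9))
    integrate_expression(targets, expr, "up")$p_hyper < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the shipped known-motif set parses and scans", {
  km <- known_motifs()
  expect_true(all(c("AmyR", "PrtT", "CreA", "PacC", "Ebox") %in% km$motif))
  for (cons in km$consensus) expect_silent(normalize_consensus(cons))
})

test_that("background sampling matches target widths and donor space", {
  g <- study_genome()
  targets <- tibble::tibble(chrom = "chr1", start = c(1000L, 5000L),
                            end = c(1030L, 5080L))
  donors <- tibble::tibble(chrom = "chr2", start = c(0L, 50000L),
                           end = c(20000L, 90000L))
  bg <- sample_background(targets, donors, n = 50, seed = 3)
  expect_equal(nrow(bg), 50)
  expect_true(all(bg$end - bg$start %in% c(30L, 80L)))
  expect_true(all(bg$chrom == "chr2"))
  # peaks minus footprints removes covered bases
  pk <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  fp <- tibble::tibble(chrom = "chr1", start = 400L, end = 500L)
  res <- peaks_minus_footprints(pk, fp)
  expect_equal(res$start, c(0L, 500L))
  expect_equal(res$end, c(400L, 1000L))
})
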