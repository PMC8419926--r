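make_uniform_track <- function(rate = 0.2, len = 100000L, seed = 1) {
  set.seed(seed)
  n <- rpois(1, 2 * rate * len)
  ev <- tibble::tibble(chrom = "chr1", pos = sample(0:(len - 1L), n, TRUE),
                       strand = sample(c("+", "-"), n, TRUE))
  build_track(ev, c(chr1 = len))
}

test_that("a uniform track yields no significant peaks", {
  tr <- make_uniform_track(rate = 0.2)
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 0)
  empty <- build_track(tibble::tibble(chrom = character(), pos = integer(),
                                      strand = character()), c(chr1 = 100000L))
  expect_equal(nrow(call_peaks(empty)), 0)
})

test_that("an isolated hot region becomes exactly one covering peak", {
  set.seed(4)
  ev <- tibble::tibble(chrom = "chr1",
                       pos = sample(50000:50199, 50, TRUE),
                       strand = sample(c("+", "-"), 50, TRUE))
  tr <- build_track(ev, c(chr1 = 100000L))
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 50000)
  expect_gte(pk$end, 50200)
  expect_true(pk$summit >= 50000 && pk$summit < 50200)
  expect_true(all(pk$q >= pk$p))
})

test_that("peak calling is translation-invariant for step-multiple shifts", {
  sim <- study_condition("WT")
  g <- study_genome()
  ev <- insertion_events(deduplicate(sim$fragments), chrom_lengths = g$chrom_lengths)
  ev1 <- ev[ev$chrom == "chr1", ]
  tr1 <- build_track(ev1, c(chr1 = 110000L))
  ev2 <- dplyr::mutate(ev1, pos = pos + 500L)
  tr2 <- build_track(ev2, c(chr1 = 110000L))
  pk1 <- call_peaks(tr1)
  pk2 <- call_peaks(tr2)
  expect_equal(nrow(pk1), nrow(pk2))
  expect_equal(pk2$start, pk1$start + 500L)
  expect_equal(pk2$end, pk1$end + 500L)
  expect_equal(pk2$summit, pk1$summit + 500L)
})

test_that("WT simulation recovers planted accessible promoters", {
  sim <- study_condition("WT")
  g <- study_genome()
  pk <- call_peaks(sim$track)
  promoters <- tibble::tibble(chrom = g$genes$chrom,
                              start = pmax(0L, g$genes$tss - 150L),
                              end = g$genes$tss + 150L)
  expect_gte(fraction_overlapped(promoters, pk), 0.9)
  # peaks are non-overlapping after merging
  by_chrom <- split(pk, pk$chrom)
  for (s in by_chrom) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("peak summits are annotated with the documented precedence", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(2000L, 6000L), end = c(4000L, 8000L),
    strand = c("+", "+"),
    tss = c(2000L, 6000L), tts = c(3999L, 7999L),
    exons = list(tibble::tibble(start = c(2000L, 3000L), end = c(2500L, 4000L)),
                 tibble::tibble(start = 6000L, end = 8000L))
  )
  pk <- tibble::tibble(
    peak_id = sprintf("p%d", 1:5), chrom = "chr1",
    summit = c(1600L,  # 400 bp upstream of gA -> promoter
               5100L,  # inside gA's 3' region? no: intergenic, 900bp upstream of gB -> promoter
               2700L,  # inside gA intron, but within TTS window? no; intron
               2200L,  # gA exon1 -> exon... but also < 1 kb downstream? promoter rule is upstream-only
               9000L), # past gB end: within 1001 bp of gB TTS? distance 1001 -> intergenic
    start = 0L, end = 10000L
  )
  ann <- annotate_peaks(pk, genes)
  expect_equal(ann$category[1], "promoter")
  expect_equal(ann$category[2], "promoter") # precedence over exon/intergenic
  expect_equal(ann$category[3], "intron")
  expect_equal(ann$category[4], "exon")
  expect_equal(ann$category[5], "intergenic")
  expect_equal(ann$nearest_gene[1], "gA")
  expect_equal(ann$distance_to_tss[1], -400L)
})

test_that("annotation categories match a brute-force membership oracle", {
  g <- study_genome()
  set.seed(13)
  pk <- tibble::tibble(
    peak_id = sprintf("r%03d", 1:200),
    chrom = sample(names(g$chrom_lengths), 200, TRUE),
    summit = sample(1000:99000, 200, TRUE)
  )
  pk$start <- pk$summit - 50L; pk$end <- pk$summit + 50L
  ann <- annotate_peaks(pk, g$genes)
  oracle_category <- function(ch, s) {
    gg <- g$genes[g$genes$chrom == ch, ]
    in_prom <- any(ifelse(gg$strand == "+", s >= gg$tss - 1000 & s <= gg$tss,
                          s >= gg$tss & s <= gg$tss + 1000))
    if (in_prom) return("promoter")
    if (any(abs(s - gg$tts) <= 300)) return("TTS")
    for (i in seq_len(nrow(gg))) {
      if (s >= gg$start[i] && s < gg$end[i]) {
        ex <- gg$exons[[i]]
        if (any(s >= ex$start & s < ex$end)) return("exon")
        return("intron")
      }
    }
    "intergenic"
  }
  expected <- vapply(seq_len(nrow(pk)),
                     function(i) oracle_category(pk$chrom[i], pk$summit[i]),
                     character(1))
  expect_equal(ann$category, expected)
})

test_that("peak-set comparison reproduces the published strain arithmetic", {
  # construct interval sets realising the reported totals: 6524 shared
  # regions, plus strain-specific ones
  n_common <- 6524L; n_a_only <- 773L; n_b_only <- 1173L
  starts <- seq(0L, by = 400L, length.out = n_common + n_a_only + n_b_only)
  common <- tibble::tibble(chrom = "chr1", start = starts[1:n_common])
  a_only <- tibble::tibble(chrom = "chr1",
                           start = starts[n_common + seq_len(n_a_only)])
  b_only <- tibble::tibble(chrom = "chr1",
                           start = starts[n_common + n_a_only + seq_len(n_b_only)])
  peaks_a <- dplyr::bind_rows(common, a_only) |> dplyr::mutate(end = start + 200L)
  peaks_b <- dplyr::bind_rows(dplyr::mutate(common, start = start + 50L), b_only) |>
    dplyr::mutate(end = start + 200L)
  v <- overlap_sets(peaks_a, peaks_b)
  expect_equal(v$n_a, 7297L)
  expect_equal(v$n_b, 7697L)
  expect_equal(v$common_a, 6524L)
  expect_equal(v$a_specific, 773L)
  expect_equal(v$b_specific, 1173L)
})

test_that("disjoint and random peak sets match the all-pairs oracle", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1100L))
  b <- tibble::tibble(chrom = "chr1", start = c(500L, 5000L), end = c(600L, 5100L))
  v <- overlap_sets(a, b)
  expect_equal(v$common_a, 0L)
  expect_equal(v$a_specific, 2L)
  expect_equal(v$b_specific, 2L)
  set.seed(77)
  ra <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 120, TRUE),
                       start = sample(0:20000, 120, TRUE))
  ra$end <- ra$start + sample(50:500, 120, TRUE)
  rb <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 90, TRUE),
                       start = sample(0:20000, 90, TRUE))
  rb$end <- rb$start + sample(50:500, 90, TRUE)
  for (mo in c(1L, 25L)) {
    v <- overlap_sets(ra, rb, min_overlap_bp = mo)
    expect_equal(v$common_a, brute_overlap_count(ra, rb, mo))
    expect_equal(v$common_b, brute_overlap_count(rb, ra, mo))
  }
})

test_that("ChIP/ATAC overlap percentages match the published rounding", {
  chip <- tibble::tibble(chrom = "chr1",
                         start = seq(0L, by = 1000L, length.out = 161L))
  chip$end <- chip$start + 300L
  atac97 <- dplyr::mutate(chip[1:97, ], start = start + 100L, end = end + 100L)
  # 97/161 = 60.2484...%: rounds to 60.25; agreement to the reported
  # precision (0.01) is what matters
  expect_lte(abs(chip_atac_overlap(chip, atac97)$percentage - 60.24), 0.01)
  atac112 <- dplyr::mutate(chip[1:112, ], start = start + 100L, end = end + 100L)
  expect_equal(chip_atac_overlap(chip, atac112)$percentage, 69.57)
  none <- tibble::tibble(chrom = "chr2", start = 0L, end = 10L)
  expect_equal(chip_atac_overlap(chip, none)$percentage, 0)
  expect_error(chip_atac_overlap(chip[0, ], atac97), "empty")
})

test_that("BH adjustment matches the textbook step-up on a four-value example", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  expect_equal(brute_bh(p), rep(0.04, 4))
  set.seed(3)
  pr <- runif(50)
  expect_equal(p.adjust(pr, method = "BH"), brute_bh(pr))
})

test_that("identical groups give null fold changes and FDR near 1", {
  v1 <- 90L + 3L * seq_len(50)
  v2 <- v1 + 13L
  m <- cbind(a1 = v1, a2 = v2, b1 = v1, b2 = v2)
  da <- differential_accessibility(m, c("a1", "a2"), c("b1", "b2"))
  expect_true(all(abs(da$log2FC) < 1e-8))
  expect_true(all(da$FDR > 0.9))
})

test_that("type-I error is controlled under the negative-binomial null", {
  set.seed(42)
  rates <- replicate(30, {
    mu <- exp(rnorm(2000, log(200), 0.7))
    m <- matrix(rnbinom(2000 * 4, mu = mu, size = 25), 2000, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    mean(differential_accessibility(m, c("s1", "s2"), c("s3", "s4"))$p < 0.05)
  })
  expect_lte(mean(rates), 0.07)
})

test_that("planted 4x accessibility changes are recovered with correct sign", {
  set.seed(43)
  mu <- exp(rnorm(2000, log(200), 0.7))
  fc <- rep(1, 2000); fc[1:100] <- 4
  m <- cbind(matrix(rnbinom(2000 * 2, mu = mu * fc, size = 25), 2000, 2),
             matrix(rnbinom(2000 * 2, mu = mu, size = 25), 2000, 2))
  colnames(m) <- paste0("s", 1:4)
  da <- differential_accessibility(m, c("s1", "s2"), c("s3", "s4"))
  hits <- sum(da$FDR[1:100] < 0.05 & da$log2FC[1:100] > 0)
  expect_gte(hits, 80)
  expect_true(all(is.finite(da$log2FC)))
  g <- glance(da)
  expect_equal(g$model, "nb")
})

test_that("the NB test agrees with an independent exact-count analysis (edgeR)", {
  set.seed(44)
  mu <- exp(rnorm(500, log(200), 0.5))
  fc <- rep(1, 500); fc[1:25] <- 4
  m <- cbind(matrix(rnbinom(500 * 2, mu = mu * fc, size = 25), 500, 2),
             matrix(rnbinom(500 * 2, mu = mu, size = 25), 500, 2))
  colnames(m) <- paste0("s", 1:4)
  rownames(m) <- sprintf("pk%03d", 1:500)
  da <- differential_accessibility(m, c("s1", "s2"), c("s3", "s4"))
  y <- edgeR::DGEList(m, group = c(1, 1, 2, 2))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)
  # strong concordance in both ranking and sign
  expect_gt(cor(-log10(da$p), -log10(et$table$PValue), method = "spearman"), 0.7)
  expect_gt(cor(da$log2FC, -et$table$logFC), 0.95)
})

test_that("consensus peaks and count matrices are consistent", {
  sets <- list(
    tibble::tibble(chrom = "chr1", start = c(100L, 600L), end = c(300L, 800L)),
    tibble::tibble(chrom = "chr1", start = c(250L, 2000L), end = c(450L, 2200L))
  )
  cons <- consensus_peaks(sets)
  expect_equal(cons$start, c(100L, 600L, 2000L))
  expect_equal(cons$end, c(450L, 800L, 2200L))
  tr <- make_uniform_track(rate = 0.1, len = 5000L, seed = 2)
  cm <- count_peak_matrix(list(s1 = tr, s2 = tr), cons)
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(cm[, "s1"], cm[, "s2"])
  expect_equal(unname(cm["consensus00001", "s1"]),
               as.integer(fatac:::track_window_count(tr, "chr1", 100L, 450L)))
})
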