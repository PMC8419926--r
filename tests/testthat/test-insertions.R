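test_that("BEDPE records collapse to template-spanning fragments", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr1\t100\t150\tchr1\t300\t350\tfrag1\t.\t+\t-",
    "chr2\t10\t60\tchr2\t20\t70\tfrag2\t.\t+\t-"
  ), path)
  fr <- fragments_from_alignments(path)
  expect_equal(fr$chrom, c("chr1", "chr2"))
  expect_equal(fr$start, c(100L, 10L))
  expect_equal(fr$end, c(350L, 70L))
  expect_equal(fr$length, c(250L, 60L))
})

test_that("fragment counts match an independent line count", {
  sim <- local({
    g <- make_genome(1, 20000, 5, seed = 2)
    simulate_condition(g, simulation_config(n_fragments = 1000, seed = 4), "naked")
  })
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(sim$fragments, path)
  expect_equal(nrow(fragments_from_alignments(path)), length(readLines(path)))
  expect_equal(nrow(fragments_from_alignments(path)), 1000)
})

test_that("BAM input yields the same fragments as the equivalent BEDPE", {
  # construct a small SAM by hand, convert with Rsamtools, and compare
  frags <- tibble::tibble(chrom = "chr1",
                          start = c(100L, 480L, 2000L),
                          end = c(350L, 700L, 2185L))
  sam <- withr::local_tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:20000")
  for (i in seq_len(nrow(frags))) {
    s <- frags$start[i]; e <- frags$end[i]
    rl <- 50L
    lines <- c(lines,
      sprintf("r%d\t99\tchr1\t%d\t60\t50M\t=\t%d\t%d\t*\t*", i, s + 1L, e - rl + 1L, e - s),
      sprintf("r%d\t147\tchr1\t%d\t60\t50M\t=\t%d\t%d\t*\t*", i, e - rl + 1L, s + 1L, -(e - s)))
  }
  # interleave in coordinate order
  writeLines(lines[c(1, 2, order(frags$start + rep(c(0, 0.5), each = 3)) * 2 + rep(1:2, 3))], sam)
  sam_sorted <- withr::local_tempfile(fileext = ".sam")
  hdr <- grep("^@", lines, value = TRUE)
  body <- setdiff(lines, hdr)
  body <- body[order(as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 4)))]
  writeLines(c(hdr, body), sam_sorted)
  bam <- Rsamtools::asBam(sam_sorted, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  fr <- fragments_from_alignments(bam)
  fr <- fr[order(fr$start), ]
  expect_equal(fr$start, frags$start)
  expect_equal(fr$end, frags$end)
})

test_that("empty input gives an empty fragment set", {
  fr <- fragments_from_alignments(tibble::tibble(chrom = character(),
                                                 start = integer(), end = integer()))
  expect_equal(nrow(fr), 0)
  ev <- insertion_events(fr)
  expect_equal(nrow(ev), 0)
})

test_that("deduplication collapses identical (chrom,start,end) keys", {
  fr <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr1"),
                       start = c(5L, 5L, 5L, 9L), end = c(50L, 50L, 50L, 60L))
  dd <- deduplicate(fr)
  expect_equal(nrow(dd), 2)
  expect_equal(attr(dd, "n_duplicates"), 2L)
  # identity on duplicate-free input
  fr2 <- tibble::tibble(chrom = "chr1", start = 1:5 * 10L, end = 1:5 * 10L + 40L)
  expect_equal(nrow(deduplicate(fr2)), 5)
})

test_that("dedup count equals the distinct-key count of a random multiset", {
  set.seed(31)
  keys <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                         start = sample(1000L, 200, TRUE))
  keys$end <- keys$start + sample(30:300, 200, TRUE)
  multi <- keys[sample.int(200, 1000, replace = TRUE), ]
  dd <- deduplicate(multi)
  oracle <- length(unique(paste(multi$chrom, multi$start, multi$end)))
  expect_equal(nrow(dd), oracle)
})

test_that("insertion events follow the +5/-5 shift rule", {
  fr <- tibble::tibble(chrom = "chr1", start = 100L, end = 350L, length = 250L)
  ev <- insertion_events(fr)
  expect_equal(ev$pos[ev$strand == "+"], 105L)
  expect_equal(ev$pos[ev$strand == "-"], 344L)
  # boundary arithmetic: events remain in bounds and are retained
  fr2 <- tibble::tibble(chrom = "chr1", start = 2L, end = 9997L, length = 9995L)
  ev2 <- insertion_events(fr2, chrom_lengths = c(chr1 = 10000L))
  expect_equal(sort(ev2$pos), c(7L, 9991L))
  expect_equal(attr(ev2, "n_dropped"), 0L)
  # shifting out of bounds drops and tallies
  fr3 <- tibble::tibble(chrom = "chr1", start = 9998L, end = 10000L, length = 2L)
  ev3 <- insertion_events(fr3, chrom_lengths = c(chr1 = 10000L))
  expect_equal(attr(ev3, "n_dropped"), 1L) # + event at 10003 dropped
  # the alternative ENCODE convention is configurable
  ev4 <- insertion_events(fr, shift_plus = 4L, shift_minus = -5L)
  expect_equal(ev4$pos[ev4$strand == "+"], 104L)
})

test_that("event conservation: 2 x fragments = events + dropped", {
  sim <- study_condition("WT")
  g <- study_genome()
  dd <- deduplicate(sim$fragments)
  ev <- insertion_events(dd, chrom_lengths = g$chrom_lengths)
  expect_equal(2L * nrow(dd), nrow(ev) + attr(ev, "n_dropped"))
  tr <- build_track(ev, g)
  expect_equal(tr$total_events, nrow(ev))
  expect_equal(sum(vapply(tr$counts, function(x) sum(x$plus) + sum(x$minus), numeric(1))),
               nrow(ev))
})

test_that("unshifting events recovers the original cut coordinates", {
  fr <- tibble::tibble(chrom = "chr1", start = c(100L, 250L), end = c(300L, 500L),
                       length = c(200L, 250L))
  ev <- insertion_events(fr)
  plus <- ev[ev$strand == "+", ]
  minus <- ev[ev$strand == "-", ]
  expect_equal(sort(plus$pos - 5L), sort(fr$start))
  expect_equal(sort(minus$pos + 5L + 1L), sort(fr$end))
})

test_that("size classes follow the published cutoffs exactly", {
  fr <- tibble::tibble(chrom = "chr1", start = 0L,
                       end = c(99L, 100L, 180L, 247L, 248L),
                       length = c(99L, 100L, 180L, 247L, 248L))
  cl <- classify_fragments(fr)
  expect_equal(cl$size_class, c("NFR", "ambiguous", "mono", "mono", "oligo"))
  expect_error(classify_fragments(fr, bounds = c(nfr_max = 200, mono_min = 180,
                                                 mono_max = 247)),
               "bounds overlap")
})

test_that("class proportions recover configured mixture weights within 3 sigma", {
  set.seed(8)
  n <- 1e5
  w <- c(NFR = 0.5, mono = 0.3, oligo = 0.2)
  len <- c(sample(30:99, w["NFR"] * n, TRUE),
           sample(180:247, w["mono"] * n, TRUE),
           sample(248:600, w["oligo"] * n, TRUE))
  fr <- tibble::tibble(chrom = "chr1", start = 0L, end = len, length = len)
  cl <- classify_fragments(fr)
  tab <- table(cl$size_class) / n
  for (k in names(w)) {
    se <- sqrt(w[[k]] * (1 - w[[k]]) / n)
    expect_lt(abs(tab[[k]] - w[[k]]), 3 * se)
  }
})

test_that("track counts are exact and validated", {
  ev <- tibble::tibble(chrom = rep("chr1", 3), pos = rep(42L, 3),
                       strand = rep("+", 3))
  tr <- build_track(ev, c(chr1 = 100L))
  expect_equal(tr$counts$chr1$plus[43], 3L)
  expect_equal(sum(tr$counts$chr1$plus), 3L)
  empty <- build_track(ev[0, ], c(chr1 = 100L))
  expect_equal(empty$total_events, 0L)
  expect_error(build_track(tibble::tibble(chrom = "chrX", pos = 1L, strand = "+"),
                           c(chr1 = 100L)), "absent")
  # conservation on a large random event set
  set.seed(5)
  ev2 <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 1e5, TRUE),
                        pos = sample(0:9999, 1e5, TRUE),
                        strand = sample(c("+", "-"), 1e5, TRUE))
  tr2 <- build_track(ev2, c(chr1 = 10000L, chr2 = 10000L))
  expect_equal(sum(vapply(tr2$counts, function(x) sum(x$plus) + sum(x$minus),
                          numeric(1))), 1e5)
  td <- tidy(tr2)
  expect_equal(sum(td$count), 1e5)
})

test_that("strand balance holds on a naked-DNA simulation", {
  sim <- study_condition("naked", seed = 3, n_fragments = 50000)
  g <- study_genome()
  ev <- insertion_events(sim$fragments, chrom_lengths = g$chrom_lengths)
  n_plus <- sum(ev$strand == "+")
  n_minus <- sum(ev$strand == "-")
  expect_lt(abs(n_plus - n_minus) / nrow(ev), 0.01)
})
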