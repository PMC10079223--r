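test_that("peak calling reproduces the worked merge/threshold fixtures", {
  cfg <- detection_config("K")
  bins <- scored_bins("c1", c(0, 15, 30, 60), c(15, 30, 45, 75), "+",
                      c(20, 16, 10, 30))
  peaks <- call_peaks(bins, cfg)
  expect_equal(peaks$start, 60L)
  expect_equal(peaks$end, 75L)
  expect_equal(peaks$score, 30)

  expect_equal(nrow(call_peaks(scored_bins("c1", c(0, 15), c(15, 30), "+", 0), cfg)), 0)

  bins2 <- scored_bins("c1", c(0, 15, 45), c(15, 30, 60), "+", c(26, 40, 25))
  peaks2 <- call_peaks(bins2, cfg)
  expect_equal(peaks2$start, c(0L, 45L))
  expect_equal(peaks2$end, c(30L, 60L))
  expect_equal(peaks2$score, c(40, 25))

  # KPDS condition raises the call threshold to 35
  expect_equal(call_peaks(bins2, detection_config("KPDS"))$score, 40)

  expect_error(call_peaks(scored_bins("c1", c(15, 0), c(30, 15), "+", c(20, 20)), cfg),
               "sorted")
  expect_error(detection_config("K", merge_threshold = 30), "below")
})

test_that("peak calling matches the brute-force oracle on random tracks", {
  set.seed(11)
  cfg <- detection_config("K")
  for (i in 1:200) {
    bins <- random_bin_track()
    got <- call_peaks(bins, cfg)
    want <- oracle_call_peaks(bins, cfg$merge_threshold, cfg$call_threshold)
    expect_equal(got[, c("chrom", "start", "end", "score", "strand")], want,
                 ignore_attr = TRUE)
  }
  # and with a nonzero merge gap
  cfg2 <- detection_config("K", max_gap = 15)
  for (i in 1:50) {
    bins <- random_bin_track()
    got <- call_peaks(bins, cfg2)
    want <- oracle_call_peaks(bins, cfg2$merge_threshold, cfg2$call_threshold,
                              max_gap = 15)
    expect_equal(got[, c("chrom", "start", "end", "score", "strand")], want,
                 ignore_attr = TRUE)
  }
})

test_that("peaks are unions of input bins scored by a member bin", {
  set.seed(12)
  cfg <- detection_config("K")
  for (i in 1:50) {
    bins <- random_bin_track()
    peaks <- call_peaks(bins, cfg)
    for (j in seq_len(nrow(peaks))) {
      members <- bins[bins$start >= peaks$start[j] & bins$end <= peaks$end[j], ]
      expect_true(peaks$score[j] %in% members$score)
      expect_true((peaks$end[j] - peaks$start[j]) %% 15 == 0)
      expect_gte(peaks$score[j], cfg$call_threshold)
    }
  }
})

test_that("raising the call threshold never adds peaks; lowering the merge threshold never splits them", {
  set.seed(13)
  for (i in 1:30) {
    bins <- random_bin_track()
    lo <- call_peaks(bins, detection_config("K", call_threshold = 25))
    hi <- call_peaks(bins, detection_config("K", call_threshold = 35))
    expect_lte(nrow(hi), nrow(lo))
    # every high-threshold peak appears identically at the lower threshold
    if (nrow(hi) > 0)
      expect_true(all(paste(hi$start, hi$end) %in% paste(lo$start, lo$end)))

    merged_hi <- call_peaks(bins, detection_config("K", merge_threshold = 14.4))
    merged_lo <- call_peaks(bins, detection_config("K", merge_threshold = 5))
    # each peak under the higher merge threshold lies within one peak under the lower
    for (j in seq_len(nrow(merged_hi))) {
      containing <- merged_lo$start <= merged_hi$start[j] &
        merged_lo$end >= merged_hi$end[j]
      expect_equal(sum(containing), 1L)
    }
  }
})

test_that("nucleotide labels use union semantics and clip to the region", {
  pk <- function(s, e) data.frame(chrom = "c1", start = s, end = e,
                                  name = "p", score = 50, strand = "+",
                                  stringsAsFactors = FALSE)
  lab <- nucleotide_labels(pk(10, 20), list("c1", 0, 30))
  expect_equal(which(lab == 1), 11:20)

  two <- rbind(pk(0, 10), pk(5, 15))
  lab2 <- nucleotide_labels(two, list("c1", 0, 30))
  expect_equal(sum(lab2), 15)

  expect_equal(nucleotide_labels(pk(0, 10)[0, ], list("c1", 0, 30)), integer(30))
  # out-of-region peaks are clipped
  expect_equal(sum(nucleotide_labels(pk(25, 45), list("c1", 0, 30))), 5)
})

test_that("detection metrics match brute-force set arithmetic", {
  expect_equal(detection_metrics(c(1, 1, 0), c(1, 1, 0)),
               list(precision = 1, recall = 1, jaccard = 1))

  # truth (0,30), prediction (15,45) on a 60 nt region
  truth <- as.integer(seq_len(60) <= 30)
  pred <- as.integer(seq_len(60) > 15 & seq_len(60) <= 45)
  expect_equal(detection_metrics(pred, truth),
               list(precision = 0.5, recall = 0.5, jaccard = 1 / 3))

  m <- detection_metrics(integer(10), c(rep(1L, 4), rep(0L, 6)))
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_equal(m$jaccard, 0)
  expect_error(detection_metrics(1:3, 1:4), "length")

  set.seed(14)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    pred <- as.integer(runif(n) < 0.4)
    truth <- as.integer(runif(n) < 0.4)
    want <- oracle_metrics(which(pred == 1), which(truth == 1))
    expect_equal(detection_metrics(pred, truth), want)
  }
})

test_that("PQ matching agrees with an independent regex engine", {
  hits <- find_pq("GGGAGGGAGGGAGGG")
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end), c(0L, 15L))

  expect_equal(nrow(find_pq("AAAA")), 0)
  expect_error(find_pq("ACGT", loop_max = 0), "loop_max")

  set.seed(15)
  for (i in 1:300) {
    s <- random_dna(sample(30:150, 1), c("A", "C", "G", "G", "T", "N"))
    got <- find_pq(s)[, c("start", "end")]
    want <- oracle_pq_spans(s)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # PQ-planted sequences
  for (i in 1:100) {
    bg <- random_dna(120, c("A", "T", "C"))
    motif <- "GGGAGGGTGGGAGGG"
    s <- plant_motif(bg, motif, sample(0:100, 1))
    got <- find_pq(s)[, c("start", "end")]
    want <- oracle_pq_spans(s)
    expect_equal(got, want, ignore_attr = TRUE)
    expect_gte(nrow(got), 1)
  }
})

test_that("genome PQ scanning mirrors coordinates across strands", {
  set.seed(16)
  for (i in 1:20) {
    bg <- random_dna(150, c("A", "T", "C"))
    s <- plant_motif(bg, "GGGTAGGGCAGGGTTGGG", sample(10:110, 1))
    g_fwd <- genome_store(c(c1 = s))
    g_rev <- genome_store(c(c1 = reverse_complement(s)))
    fwd <- find_pq(g_fwd)
    rev_ <- find_pq(g_rev)
    L <- nchar(s)
    # reflecting the reverse-genome hits recovers the forward hits
    reflected <- data.frame(start = L - rev_$end, end = L - rev_$start,
                            strand = ifelse(rev_$strand == "+", "-", "+"))
    reflected <- reflected[order(reflected$start, reflected$strand), ]
    orig <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand")]
    expect_equal(orig, reflected, ignore_attr = TRUE)
  }
})

test_that("the KRAS promoter sequence contains an extended-form PQ", {
  hits <- find_pq(kras_promoter_sequence(), form = "extended")
  expect_gte(nrow(hits), 1)
})

test_that("PQ-only selection enforces isolation and pairs the max bin score", {
  bg <- strrep("ATTA", 150)  # 600 nt, PQ-free background
  motif <- "GGGAGGGTGGGAGGG"

  # single isolated PQ with one overlapping scored bin
  g1 <- genome_store(c(c1 = plant_motif(bg, motif, 300)))
  bins1 <- scored_bins("c1", 300, 315, "+", 40)
  sel1 <- pq_only_selection(g1, bins1)
  expect_equal(nrow(sel1), 1)
  expect_equal(sel1$score, 40)

  # two PQs 50 nt apart exclude each other
  s2 <- plant_motif(plant_motif(bg, motif, 200), motif, 265)
  g2 <- genome_store(c(c1 = s2))
  bins2 <- scored_bins("c1", c(200, 265), c(215, 280), "+", c(40, 50))
  expect_equal(nrow(pq_only_selection(g2, bins2)), 0)

  # isolated PQ overlapping bins scoring 20 and 35 pairs with 35
  bins3 <- scored_bins("c1", c(300, 308), c(315, 323), "+", c(20, 35))
  expect_equal(pq_only_selection(g1, bins3)$score, 35)

  # a PQ with no measured bin is dropped
  bins4 <- scored_bins("c1", 0, 15, "+", 40)
  expect_equal(nrow(pq_only_selection(g1, bins4)), 0)
})

test_that("merge-threshold calibration recovers the generating threshold", {
  set.seed(17)
  bins <- random_bin_track(n_max = 150)
  reference <- g4scan:::merge_scored_bins(bins, 14.4, 0)
  cal <- calibrate_merge_threshold(bins, reference,
                                   thresholds = seq(10, 20, by = 0.2))
  # the generating threshold achieves perfect agreement
  expect_equal(cal$grid$jaccard[abs(cal$grid$threshold - 14.4) < 1e-9], 1.0)
  got <- g4scan:::merge_scored_bins(bins, cal$best, 0)
  expect_equal(got[, c("start", "end", "score")],
               reference[, c("start", "end", "score")], ignore_attr = TRUE)
})
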