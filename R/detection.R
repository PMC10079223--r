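#' Peak-calling configuration
#'
#' Mirrors the G4-seq peak-production procedure: bins scoring strictly above
#' `merge_threshold` (14.4 by default, the value that reproduces the
#' published peak lists from the published bins) are merged when book-ended,
#' each merged region is assigned its maximum member score, and regions below
#' the condition-specific `call_threshold` (25 for K+, 35 for K+ with the
#' stabilizer PDS) are discarded.
#'
#' @param condition `"K"` or `"KPDS"`; sets the default call threshold.
#' @param merge_threshold Bins must score strictly above this to enter a peak.
#' @param call_threshold Minimum peak score kept (boundary inclusive).
#' @param max_gap Maximum gap in nt between merged bins (0 = book-ended only).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(condition = c("K", "KPDS"), merge_threshold = 14.4,
                             call_threshold = NULL, max_gap = 0L) {
  condition <- match.arg(condition)
  if (is.null(call_threshold))
    call_threshold <- if (condition == "K") 25 else 35
  if (!(merge_threshold < call_threshold))
    stopf("merge_threshold (%g) must be below call_threshold (%g)",
          merge_threshold, call_threshold)
  stopifnot(max_gap >= 0)
  structure(list(condition = condition, merge_threshold = merge_threshold,
                 call_threshold = call_threshold, max_gap = as.integer(max_gap)),
            class = "detection_config")
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

# merge above-threshold bins into max-scored regions (no call filter)
merge_scored_bins <- function(bins, merge_threshold, max_gap) {
  if (anyNA(bins$score)) stopf("call_peaks: bins with missing scores")
  out <- list()
  for (key in unique(paste(bins$chrom, bins$strand))) {
    sel <- bins[paste(bins$chrom, bins$strand) == key, , drop = FALSE]
    if (is.unsorted(sel$start, strictly = TRUE))
      stopf("call_peaks: bins must be sorted by start within %s", key)
    sel <- sel[sel$score > merge_threshold, , drop = FALSE]
    if (nrow(sel) == 0) next
    gap_break <- c(TRUE, sel$start[-1] - sel$end[-nrow(sel)] > max_gap)
    run <- cumsum(gap_break)
    out[[key]] <- data.frame(
      chrom = sel$chrom[1],
      start = as.integer(tapply(sel$start, run, min)),
      end = as.integer(tapply(sel$end, run, max)),
      score = as.numeric(tapply(sel$score, run, max)),
      strand = sel$strand[1],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_peaks())
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$chrom, merged$start, merged$strand), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Call G4 peaks from a per-bin score track
#'
#' Implements the merge/threshold procedure: (1) keep bins scoring strictly
#' above `merge_threshold`; (2) merge runs of kept bins separated by at most
#' `max_gap` nt (book-ended bins merge at the default gap 0); (3) score each
#' region with the maximum member-bin score; (4) keep regions whose score is
#' at least `call_threshold`. Strands are processed independently. Input must
#' be position-sorted within each chromosome and strand; unsorted input is an
#' error rather than silently reordered.
#'
#' @param bins Scored-bin data frame (scores present).
#' @param config A [detection_config()].
#' @return Peak data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
call_peaks <- function(bins, config = detection_config("K")) {
  stopifnot(inherits(config, "detection_config"))
  if (nrow(bins) == 0) return(empty_peaks())
  merged <- merge_scored_bins(bins, config$merge_threshold, config$max_gap)
  peaks <- merged[merged$score >= config$call_threshold, , drop = FALSE]
  if (nrow(peaks) == 0) return(empty_peaks())
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Per-nucleotide binary labels from a peak set
#'
#' Position i of the returned vector is 1 when at least one peak covers it
#' (union semantics); peaks extending beyond the region are clipped.
#'
#' @param peaks Peak data frame.
#' @param region A list or vector `(chrom, start, end)`; only peaks on that
#'   chromosome contribute. If `strand` is supplied as a fourth element, only
#'   matching-strand peaks contribute.
#' @return Integer 0/1 vector of length `end - start`.
#' @export
nucleotide_labels <- function(peaks, region) {
  chrom <- as.character(region[[1]])
  start <- as.integer(region[[2]]); end <- as.integer(region[[3]])
  strand <- if (length(region) >= 4) as.character(region[[4]]) else NULL
  labels <- integer(end - start)
  if (nrow(peaks) == 0) return(labels)
  sel <- peaks$chrom == chrom
  if (!is.null(strand)) sel <- sel & peaks$strand == strand
  for (i in which(sel)) {
    s <- max(peaks$start[i], start); e <- min(peaks$end[i], end)
    if (e > s) labels[(s - start + 1L):(e - start)] <- 1L
  }
  labels
}

#' Nucleotide-level detection metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and Jaccard `TP/(TP+FP+FN)`
#' over binary label vectors. A ratio with a zero denominator is reported as
#' `NA`, not as 0.
#'
#' @param predicted_labels,true_labels Equal-length 0/1 vectors.
#' @return Named list with `precision`, `recall`, `jaccard`.
#' @export
detection_metrics <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) != length(true_labels))
    stopf("label vectors differ in length")
  p <- predicted_labels != 0; t_ <- true_labels != 0
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(tp, tp + fp),
       recall = ratio(tp, tp + fn),
       jaccard = ratio(tp, tp + fp + fn))
}

pq_regex <- function(g_min, loop_max)
  sprintf("G{%d,}(?:[ACGT]{1,%d}G{%d,}){3}", g_min, loop_max, g_min)

find_pq_one <- function(sequence, pattern, form) {
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(), form = character(),
                      match = character(), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
             form = form, match = substring(sequence, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

#' Find putative quadruplex (PQ) motifs
#'
#' Matches the canonical motif `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+` (loops over
#' A,C,G,T) or the extended variant with loops up to 12 nt. Matches are
#' leftmost, greedy-maximal and non-overlapping; N never matches a tract or a
#' loop. When given a genome store, both strands of every chromosome are
#' scanned and minus-strand coordinates are mapped back to the plus strand.
#'
#' @param x A nucleotide string or a `genome_store`.
#' @param form `"canonical"` (loops 1-7) or `"extended"` (loops 1-12).
#' @param g_min Minimum G-tract length (default 3).
#' @param loop_max Maximum loop length; defaults to 7 or 12 by `form`.
#' @return Data frame with columns `chrom` (NA for plain sequences), `start`,
#'   `end` (0-based half-open, plus-strand coordinates), `strand`, `form`,
#'   `match` (the matched text, measured-strand orientation).
#' @export
find_pq <- function(x, form = c("canonical", "extended"), g_min = 3L,
                    loop_max = NULL) {
  form <- match.arg(form)
  if (is.null(loop_max)) loop_max <- if (form == "canonical") 7L else 12L
  if (loop_max < 1) stopf("loop_max must be at least 1")
  pattern <- pq_regex(g_min, loop_max)
  if (inherits(x, "genome_store")) {
    res <- lapply(names(x$sequences), function(cm) {
      s <- x$sequences[[cm]]
      L <- nchar(s)
      plus <- find_pq_one(s, pattern, form)
      minus <- find_pq_one(reverse_complement(s), pattern, form)
      plus$chrom <- rep(cm, nrow(plus))
      plus$strand <- rep("+", nrow(plus))
      minus$chrom <- rep(cm, nrow(minus))
      minus$strand <- rep("-", nrow(minus))
      if (nrow(minus) > 0) {
        rc_start <- minus$start
        minus$start <- L - minus$end
        minus$end <- L - rc_start
      }
      rbind(plus, minus)
    })
    out <- do.call(rbind, res)
    if (is.null(out) || nrow(out) == 0)
      return(data.frame(chrom = character(), start = integer(), end = integer(),
                        strand = character(), form = character(),
                        match = character(), stringsAsFactors = FALSE))
    out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    return(out[, c("chrom", "start", "end", "strand", "form", "match")])
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("[^ACGTN]", x)) stopf("find_pq: sequence contains invalid characters")
  out <- find_pq_one(x, pattern, form)
  out$chrom <- rep(NA_character_, nrow(out))
  out$strand <- rep("+", nrow(out))
  out[, c("chrom", "start", "end", "strand", "form", "match")]
}

#' Select isolated, measured PQs and their mismatch scores
#'
#' Retains extended-form PQs whose upstream and downstream flanks of
#' `flank_len` nt contain no other PQ (on either strand) and which overlap at
#' least one same-strand bin with a measured score; each kept PQ is paired
#' with the maximum measured score among its overlapping bins.
#'
#' @param genome A `genome_store`.
#' @param bins Scored-bin data frame with measured scores.
#' @param flank_len Exclusion flank length in nt (default 100).
#' @return Data frame of retained PQs with an added `score` column.
#' @export
pq_only_selection <- function(genome, bins, flank_len = 100L) {
  pqs <- find_pq(genome, form = "extended")
  if (nrow(pqs) == 0) return(cbind(pqs, score = numeric(0)))
  keep <- logical(nrow(pqs))
  score <- rep(NA_real_, nrow(pqs))
  for (i in seq_len(nrow(pqs))) {
    same_chrom <- which(pqs$chrom == pqs$chrom[i])
    others <- setdiff(same_chrom, i)
    flank_hit <- any(pqs$start[others] < pqs$end[i] + flank_len &
                     pqs$end[others] > pqs$start[i] - flank_len)
    if (flank_hit) next
    hit <- bins$chrom == pqs$chrom[i] & bins$strand == pqs$strand[i] &
      !is.na(bins$score) & bins$start < pqs$end[i] & bins$end > pqs$start[i]
    if (!any(hit)) next
    keep[i] <- TRUE
    score[i] <- max(bins$score[hit])
  }
  out <- pqs[keep, , drop = FALSE]
  out$score <- score[keep]
  rownames(out) <- NULL
  out
}

#' Calibrate the merge threshold against a published peak set
#'
#' Grid-searches the bin-level merge threshold so that merging the given
#' bins best reproduces a reference peak list, measured by nucleotide-level
#' Jaccard agreement (computed per chromosome and strand over the spanned
#' extent, then pooled).
#'
#' @param bins Scored-bin data frame.
#' @param reference_peaks Peak data frame to reproduce.
#' @param thresholds Candidate merge thresholds.
#' @param max_gap Merge gap passed through to the merge step.
#' @return List with `best` (threshold maximizing Jaccard) and `grid` (data
#'   frame of threshold/jaccard pairs).
#' @export
calibrate_merge_threshold <- function(bins, reference_peaks,
                                      thresholds = seq(5, 30, by = 0.2),
                                      max_gap = 0L) {
  keys <- unique(rbind(bins[, c("chrom", "strand")],
                       reference_peaks[, c("chrom", "strand")]))
  extent <- function(df, cm, st) {
    sel <- df$chrom == cm & df$strand == st
    if (!any(sel)) c(NA_integer_, NA_integer_)
    else c(min(df$start[sel]), max(df$end[sel]))
  }
  jac <- vapply(thresholds, function(th) {
    merged <- merge_scored_bins(bins, th, max_gap)
    tp <- fp <- fn <- 0L
    for (r in seq_len(nrow(keys))) {
      cm <- keys$chrom[r]; st <- keys$strand[r]
      ex <- range(c(extent(bins, cm, st), extent(reference_peaks, cm, st)),
                  na.rm = TRUE)
      region <- list(cm, ex[1], ex[2], st)
      p <- nucleotide_labels(merged, region)
      t_ <- nucleotide_labels(reference_peaks, region)
      tp <- tp + sum(p & t_); fp <- fp + sum(p & !t_); fn <- fn + sum(!p & t_)
    }
    if (tp + fp + fn == 0) return(NA_real_)
    tp / (tp + fp + fn)
  }, numeric(1))
  grid <- data.frame(threshold = thresholds, jaccard = jac)
  list(best = thresholds[which.max(jac)], grid = grid)
}
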