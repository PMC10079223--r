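# Shared fixtures and independent oracles. Expensive fixtures (a small
# trained model) are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
  path
}

# a small simulated dataset + trained model shared across interpretation /
# scanning tests (30 kb, 2 chromosomes, 32 kernels)
fixture_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- simulate_dataset(sim_config(genome_length = 30000L,
                                                n_chrom = 2L, seed = 5L))
  .fixtures$ds
}

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    ds <- fixture_dataset()
    spec <- model_spec(20, 25, n_kernels = 32, dense_units = 16)
    tc <- train_config(learning_rate = 0.01, batch_size = 128, epochs = 3,
                       seed = 5)
    stream <- make_batch_stream(ds$genome, ds$track, spec, tc)
    .fixtures$model <- train_model(build_model(spec, 5), stream, tc)
  }
  .fixtures$model
}

# ---- independent oracles ----------------------------------------------------

# brute-force peak caller: filter -> union of bins -> per-component max -> filter
oracle_call_peaks <- function(bins, merge_threshold, call_threshold, max_gap = 0) {
  out <- list()
  for (cm in unique(bins$chrom)) for (st in unique(bins$strand)) {
    sel <- bins[bins$chrom == cm & bins$strand == st, , drop = FALSE]
    sel <- sel[sel$score > merge_threshold, , drop = FALSE]
    if (nrow(sel) == 0) next
    sel <- sel[order(sel$start), , drop = FALSE]
    comp <- list()
    for (i in seq_len(nrow(sel))) {
      placed <- FALSE
      if (length(comp) > 0) {
        last <- comp[[length(comp)]]
        if (sel$start[i] - last$end <= max_gap) {
          last$end <- max(last$end, sel$end[i])
          last$score <- max(last$score, sel$score[i])
          comp[[length(comp)]] <- last
          placed <- TRUE
        }
      }
      if (!placed)
        comp[[length(comp) + 1L]] <- list(start = sel$start[i],
                                          end = sel$end[i],
                                          score = sel$score[i])
    }
    for (cp in comp) {
      if (cp$score >= call_threshold)
        out[[length(out) + 1L]] <- data.frame(chrom = cm, start = cp$start,
                                              end = cp$end, score = cp$score,
                                              strand = st,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random sorted single-chromosome bin track on the 15 nt grid
random_bin_track <- function(n_max = 200, score_max = 60) {
  n_slots <- n_max + sample(0:50, 1)
  keep <- sort(sample(n_slots, sample(1:n_max, 1)))
  starts <- (keep - 1L) * 15L
  scored_bins("c1", starts, starts + 15L, "+",
              round(runif(length(keep), 0, score_max), 2))
}

# brute-force nucleotide set arithmetic for detection metrics
oracle_metrics <- function(pred_set, true_set) {
  tp <- length(intersect(pred_set, true_set))
  fp <- length(setdiff(pred_set, true_set))
  fn <- length(setdiff(true_set, pred_set))
  list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       jaccard = if (tp + fp + fn == 0) NA_real_ else tp / (tp + fp + fn))
}

# PQ matching oracle on the ICU regex engine (independent of the PCRE path)
oracle_pq_spans <- function(sequence, g_min = 3, loop_max = 7) {
  pattern <- sprintf("G{%d,}(?:[ACGT]{1,%d}G{%d,}){3}", g_min, loop_max, g_min)
  loc <- stringr::str_locate_all(sequence, pattern)[[1]]
  data.frame(start = loc[, 1] - 1L, end = loc[, 2])
}

# plant a canonical PQ into a background string at a 0-based offset
plant_motif <- function(background, motif, at) {
  paste0(substr(background, 1, at),
         motif,
         substr(background, at + nchar(motif) + 1, nchar(background)))
}
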