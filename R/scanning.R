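#' Score a probe sequence by its maximum-scoring window
#'
#' Implements the microarray-probe protocol: the probe is padded on both
#' sides with `flank_len` N positions (encoded as uniform 0.25 rows, adding
#' no sequence information), every window of the model's input length is
#' enumerated at stride 1, and the maximum predicted score is returned with
#' the 0-based offset of the winning window into the padded sequence (ties
#' resolved to the smallest offset).
#'
#' @param model A `g4_model`.
#' @param probe Nucleotide string (length >= 1).
#' @param flank_len Pad length per side in nt (default 100).
#' @return List with `score`, `offset` and `n_windows`.
#' @export
score_probe <- function(model, probe, flank_len = 100L) {
  stopifnot(is.character(probe), length(probe) == 1L, nchar(probe) >= 1)
  input_len <- model_input_length(model)
  padded <- paste0(strrep("N", flank_len), probe, strrep("N", flank_len))
  padded_len <- nchar(padded)
  if (input_len > padded_len)
    stopf("model input length (%d) exceeds padded probe length (%d)",
          input_len, padded_len)
  offsets <- 0:(padded_len - input_len)
  windows <- substring(padded, offsets + 1L, offsets + input_len)
  scores <- predict_sequences(model, windows)
  best <- which.max(scores)
  list(score = scores[best], offset = offsets[best],
       n_windows = length(offsets))
}

#' Scan a genome into a predicted score track
#'
#' Emits one prediction per `bin_size` nt bin at the given stride on the
#' requested strands; windows at chromosome edges are N-padded by the
#' extraction step. Output is ordered by (chrom, start, strand).
#'
#' @param model A `g4_model`.
#' @param genome A `genome_store`.
#' @param bin_size Central bin length (default 15, the native G4-seq grid).
#' @param stride Step between bin starts (default `bin_size`; use 1 for a
#'   dense scan).
#' @param strands Strands to scan.
#' @param batch_size Prediction batch size.
#' @return Data frame of bins with columns `chrom`, `start`, `end`, `strand`
#'   and predicted `score` (unclipped).
#' @export
scan_genome <- function(model, genome, bin_size = 15L, stride = bin_size,
                        strands = c("+", "-"), batch_size = 512L) {
  stopifnot(stride >= 1)
  lens <- chrom_lengths(genome)
  per_chrom <- lapply(names(lens), function(cm) {
    if (lens[[cm]] < bin_size) return(NULL)
    starts <- seq(0L, lens[[cm]] - bin_size, by = stride)
    do.call(rbind, lapply(strands, function(st)
      data.frame(chrom = cm, start = as.integer(starts),
                 end = as.integer(starts + bin_size), strand = st,
                 score = NA_real_, stringsAsFactors = FALSE)))
  })
  bins <- do.call(rbind, per_chrom)
  if (is.null(bins))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  bins <- bins[order(bins$chrom, bins$start, bins$strand), , drop = FALSE]
  rownames(bins) <- NULL
  pred <- predict_bins(model, genome, bins, batch_size = batch_size)
  bins$score <- pred$predicted
  bins
}

#' Locate the maximum-scoring sub-sequence of a sequence
#'
#' Enumerates every `bin_len` nt sub-sequence, builds its flanked model
#' window from the surrounding sequence (N-padded beyond the sequence ends),
#' and returns the argmax offset (0-based, ties to the smallest offset).
#'
#' @param model A `g4_model`.
#' @param sequence Nucleotide string of length >= `bin_len`.
#' @param bin_len Sub-sequence length (default 15).
#' @return List with `offset`, `score`, the winning `window` string, and a
#'   data frame `all` of every (offset, score) pair.
#' @export
max_scoring_subsequence <- function(model, sequence, bin_len = 15L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < bin_len)
    stopf("sequence is shorter than the %d nt sub-sequence length", bin_len)
  fl <- spec_flanks(model$spec)
  padded <- paste0(strrep("N", fl[1]), sequence, strrep("N", fl[2]))
  offsets <- 0:(nchar(sequence) - bin_len)
  windows <- substring(padded, offsets + 1L, offsets + fl[1] + bin_len + fl[2])
  scores <- predict_sequences(model, windows)
  best <- which.max(scores)
  list(offset = offsets[best], score = scores[best], window = windows[best],
       all = data.frame(offset = offsets, score = scores))
}
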