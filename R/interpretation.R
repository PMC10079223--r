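#' Probability-pattern builders
#'
#' The interpretation procedures probe the model with per-position nucleotide
#' distributions rather than literal sequences: `pattern_fixed()` emits
#' one-hot rows, `pattern_uniform()` the neutral (0.25, 0.25, 0.25, 0.25)
#' rows, and `pattern_biased()` puts probability `p` on one base and
#' `(1 - p) / 3` on each other base, so `pattern_biased(base, 0.25)` equals
#' `pattern_uniform()` exactly.
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param p Probability assigned to `base`.
#' @param n Number of rows to emit.
#' @return Numeric matrix `(n x 4)` in channel order A, C, G, T; rows sum to 1.
#' @export
pattern_fixed <- function(base, n = 1L) {
  i <- match(base, BASES)
  if (is.na(i)) stopf("base must be one of A, C, G, T")
  m <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
  m[, i] <- 1
  m
}

#' @rdname pattern_fixed
#' @export
pattern_uniform <- function(n = 1L) {
  matrix(0.25, n, 4L, dimnames = list(NULL, BASES))
}

#' @rdname pattern_fixed
#' @export
pattern_biased <- function(base, p, n = 1L) {
  i <- match(base, BASES)
  if (is.na(i)) stopf("base must be one of A, C, G, T")
  stopifnot(p >= 0, p <= 1)
  m <- matrix((1 - p) / 3, n, 4L, dimnames = list(NULL, BASES))
  m[, i] <- p
  m
}

#' Four-tract quadruplex probability pattern
#'
#' Builds the pattern G-tract, loop, G-tract, loop, G-tract, loop, G-tract
#' with one-hot G tracts and uniform-probability loops; loop lengths of
#' (1, 1, 1) give the canonical 15 nt wild type GGGNGGGNGGGNGGG.
#'
#' @param loop_lens Integer vector of the three loop lengths.
#' @param tract_len G-tract length (default 3).
#' @return Probability matrix of the motif.
#' @export
quadruplex_pattern <- function(loop_lens = c(1L, 1L, 1L), tract_len = 3L) {
  stopifnot(length(loop_lens) == 3L, all(loop_lens >= 1))
  rbind(pattern_fixed("G", tract_len),
        pattern_uniform(loop_lens[1]),
        pattern_fixed("G", tract_len),
        pattern_uniform(loop_lens[2]),
        pattern_fixed("G", tract_len),
        pattern_uniform(loop_lens[3]),
        pattern_fixed("G", tract_len))
}

# Center a motif pattern inside the model input with uniform flank rows.
# When exact centering is impossible the motif sits one position to the left.
center_pattern <- function(motif, input_len) {
  m <- nrow(motif)
  if (m > input_len)
    stopf("motif (%d nt) exceeds the model input length (%d nt)", m, input_len)
  pad_left <- (input_len - m) %/% 2L
  pad_right <- input_len - m - pad_left
  rows <- motif
  if (pad_left > 0) rows <- rbind(pattern_uniform(pad_left), rows)
  if (pad_right > 0) rows <- rbind(rows, pattern_uniform(pad_right))
  attr(rows, "motif_offset") <- pad_left
  rows
}

predict_pattern_batch <- function(model, patterns) {
  len <- nrow(patterns[[1]])
  X <- array(0, dim = c(length(patterns), len, 4L))
  for (i in seq_along(patterns)) X[i, , ] <- patterns[[i]]
  predict_encoded(model, X)
}

#' Loop-length scan of a quadruplex pattern
#'
#' Varies the length of one loop of the four-tract pattern (the other loops
#' held at `other_loop_len`, default 1) and predicts a score per length; the
#' motif is centered in the model input with uniform flanks.
#'
#' @param model A `g4_model`.
#' @param loop_index Which loop to vary (1, 2 or 3).
#' @param lengths Loop lengths to scan (default 1-12).
#' @param other_loop_len Length of the non-varied loops.
#' @return Data frame with columns `length` and `score`.
#' @export
loop_length_scan <- function(model, loop_index, lengths = 1:12,
                             other_loop_len = 1L) {
  stopifnot(loop_index %in% 1:3)
  input_len <- model_input_length(model)
  patterns <- lapply(lengths, function(l) {
    loops <- rep(other_loop_len, 3L)
    loops[loop_index] <- l
    center_pattern(quadruplex_pattern(loops), input_len)
  })
  data.frame(length = lengths,
             score = predict_pattern_batch(model, patterns))
}

#' G-tract mutation scan
#'
#' For the wild type GGGNGGGNGGGNGGG (N = uniform row) centered in the model
#' input, substitutes each of the 12 tract guanines with each alternative
#' base and reports `delta = wild-type score - mutant score`, so mutations
#' that destabilize the quadruplex yield positive deltas.
#'
#' @param model A `g4_model`.
#' @return A 12 x 3 matrix of deltas; rows are motif positions of the
#'   guanines, columns the alternative bases A, C, T. The wild-type score is
#'   attached as attribute `wt_score`.
#' @export
gtract_mutation_scan <- function(model) {
  input_len <- model_input_length(model)
  wt <- center_pattern(quadruplex_pattern(), input_len)
  offset <- attr(wt, "motif_offset")
  g_positions <- offset + c(1:3, 5:7, 9:11, 13:15)
  alts <- c("A", "C", "T")
  patterns <- list(wt)
  for (pos in g_positions) for (b in alts) {
    mut <- wt
    mut[pos, ] <- pattern_fixed(b)
    patterns[[length(patterns) + 1L]] <- mut
  }
  scores <- predict_pattern_batch(model, patterns)
  wt_score <- scores[1]
  deltas <- matrix(wt_score - scores[-1], nrow = 12L, ncol = 3L, byrow = TRUE,
                   dimnames = list(g_positions - offset, alts))
  attr(deltas, "wt_score") <- wt_score
  deltas
}

#' Flank nucleotide-composition scan
#'
#' With the canonical quadruplex pattern fixed in the central bin, sets one
#' 20 nt flank bin to `pattern_biased(base, p)` rows (all other flank
#' positions uniform) and predicts a score for every `p` in `p_grid`. Flank
#' bins are indexed from the central bin outwards, so `bin_index = 1` is
#' adjacent to the central 15 nt bin.
#'
#' @param model A `g4_model` whose flank length is divisible by `bin_nt`.
#' @param base Base whose probability is varied.
#' @param side `"upstream"` or `"downstream"`.
#' @param bin_index Which flank bin to vary (1 = adjacent).
#' @param p_grid Probabilities to scan.
#' @param bin_nt Flank bin width (default 20).
#' @return Data frame with columns `p` and `score`.
#' @export
flank_composition_scan <- function(model, base, side = c("upstream", "downstream"),
                                   bin_index = 1L, p_grid = seq(0, 1, by = 0.1),
                                   bin_nt = 20L) {
  side <- match.arg(side)
  spec <- model$spec
  if (spec$flank_side != "both")
    stopf("flank_composition_scan requires a two-sided model")
  L <- spec$flank_len
  if (L %% bin_nt != 0)
    stopf("flank length (%d) is not divisible into %d nt bins", L, bin_nt)
  n_bins <- L %/% bin_nt
  if (!(bin_index %in% seq_len(n_bins)))
    stopf("bin_index must be in 1..%d", n_bins)
  input_len <- model_input_length(model)
  wt <- center_pattern(quadruplex_pattern(), input_len)
  rows <- if (side == "upstream") {
    (L - bin_nt * bin_index + 1L):(L - bin_nt * (bin_index - 1L))
  } else {
    (L + spec$bin_len + bin_nt * (bin_index - 1L) + 1L):(L + spec$bin_len + bin_nt * bin_index)
  }
  patterns <- lapply(p_grid, function(p) {
    x <- wt
    x[rows, ] <- pattern_biased(base, p, bin_nt)
    x
  })
  data.frame(p = p_grid, score = predict_pattern_batch(model, patterns))
}

#' Mutation map of a sequence
#'
#' Substitutes every position of `sequence` with each of the four bases and
#' reports `delta = wild-type score - mutant score`; cells at the wild-type
#' base are exactly 0 by construction. If the sequence is shorter than the
#' model input it is embedded in the supplied context (or N-padded, centered)
#' first; deltas are reported for the sequence positions only.
#'
#' @param model A `g4_model`.
#' @param sequence Nucleotide string.
#' @param upstream,downstream Optional context strings flanking `sequence`.
#' @return Numeric matrix `(nchar(sequence) x 4)` of deltas with columns
#'   A, C, G, T and attribute `wt_score`.
#' @export
mutation_map <- function(model, sequence, upstream = NULL, downstream = NULL) {
  input_len <- model_input_length(model)
  n <- nchar(sequence)
  if (is.null(upstream) && is.null(downstream)) {
    pad <- input_len - n
    if (pad < 0) stopf("sequence longer than the model input")
    upstream <- strrep("N", pad %/% 2L)
    downstream <- strrep("N", pad - pad %/% 2L)
  } else {
    upstream <- upstream %||% ""
    downstream <- downstream %||% ""
  }
  full <- paste0(upstream, sequence, downstream)
  if (nchar(full) != input_len)
    stopf("sequence plus context is %d nt; model expects %d", nchar(full), input_len)
  offset <- nchar(upstream)
  wt_mat <- encode_sequence(full)
  wt_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  patterns <- list(wt_mat)
  for (i in seq_len(n)) for (b in BASES) {
    if (!is.na(match(wt_chars[i], BASES)) && b == wt_chars[i]) next
    mut <- wt_mat
    mut[offset + i, ] <- pattern_fixed(b)
    patterns[[length(patterns) + 1L]] <- mut
  }
  scores <- predict_pattern_batch(model, patterns)
  wt_score <- scores[1]
  deltas <- matrix(0, n, 4L, dimnames = list(wt_chars, BASES))
  j <- 1L
  for (i in seq_len(n)) for (b in BASES) {
    if (!is.na(match(wt_chars[i], BASES)) && b == wt_chars[i]) next
    j <- j + 1L
    deltas[i, b] <- wt_score - scores[j]
  }
  attr(deltas, "wt_score") <- wt_score
  deltas
}

#' Integrated-gradients attribution with a uniform baseline
#'
#' Computes per-position, per-channel attributions
#' `(x - baseline) * mean gradient` along the straight path from the
#' all-0.25 baseline (equal probability for every nucleotide) to the input,
#' discretized with a midpoint Riemann sum of `steps` points. The per-position
#' aggregate is the channel sum. The completeness residual
#' `|sum(attributions) - (f(x) - f(baseline))|` is reported in the metadata.
#'
#' @param model Any model providing [predict_encoded()] and
#'   [input_gradient()] methods.
#' @param x Encoded input matrix `(len x 4)`.
#' @param steps Number of midpoint integration steps (default 128).
#' @param baseline Baseline matrix; defaults to all 0.25.
#' @param chunk_size Gradient batch size along the path.
#' @return An object of class `attribution_track`: list with `attribution`
#'   (len x 4 matrix), `aggregate` (length-len vector) and `metadata`.
#' @export
integrated_gradients <- function(model, x, steps = 128L, baseline = NULL,
                                 chunk_size = 128L) {
  stopifnot(is.matrix(x), ncol(x) == 4L, steps >= 1)
  len <- nrow(x)
  if (is.null(baseline)) baseline <- matrix(0.25, len, 4L)
  stopifnot(identical(dim(baseline), dim(x)))
  diff <- x - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  grad_sum <- matrix(0, len, 4L)
  for (at in seq(1L, steps, by = chunk_size)) {
    idx <- at:min(at + chunk_size - 1L, steps)
    pts <- array(0, dim = c(length(idx), len, 4L))
    for (j in seq_along(idx)) pts[j, , ] <- baseline + alphas[idx[j]] * diff
    g <- input_gradient(model, pts)
    for (j in seq_along(idx)) grad_sum <- grad_sum + matrix(g[j, , ], len, 4L)
  }
  attribution <- diff * (grad_sum / steps)
  fx <- predict_encoded(model, x)
  fb <- predict_encoded(model, baseline)
  residual <- abs(sum(attribution) - (fx - fb))
  structure(list(attribution = attribution,
                 aggregate = rowSums(attribution),
                 metadata = list(steps = as.integer(steps), f_input = fx,
                                 f_baseline = fb, completeness_residual = residual)),
            class = "attribution_track")
}

#' @export
print.attribution_track <- function(x, ...) {
  cat(sprintf("<attribution_track> %d positions, %d steps, completeness residual %.3g (f(x)-f(b) = %.3g)\n",
              length(x$aggregate), x$metadata$steps,
              x$metadata$completeness_residual,
              x$metadata$f_input - x$metadata$f_baseline))
  invisible(x)
}

#' The 35 nt KRAS promoter G4 sequence used for attribution demos
#' @return A nucleotide string.
#' @export
kras_promoter_sequence <- function() "AGGGCGGTGTGGGAAGAGGGAAGAGGGGGAGGCAG"

#' Attribution of the best-scoring KRAS promoter window
#'
#' Runs [max_scoring_subsequence()] over the 35 nt KRAS promoter G4 sequence
#' (flanks N-padded to the model's input length), then computes integrated
#' gradients for the winning window. The returned table (position, base,
#' attribution) is directly consumable by a sequence-logo plotter, with
#' letter height proportional to the per-position aggregate.
#'
#' @param model A trained `g4_model`.
#' @param steps Integration steps for [integrated_gradients()].
#' @return List with `offset` (of the winning 15 nt sub-sequence within the
#'   KRAS sequence), `score`, `window`, the `attribution_track`, and a tidy
#'   per-position data frame `table`.
#' @export
kras_attribution <- function(model, steps = 128L) {
  kras <- kras_promoter_sequence()
  best <- max_scoring_subsequence(model, kras)
  x <- encode_sequence(best$window)
  ig <- integrated_gradients(model, x, steps = steps)
  chars <- strsplit(best$window, "", fixed = TRUE)[[1]]
  table <- data.frame(position = seq_along(chars), base = chars,
                      attribution = ig$aggregate)
  list(offset = best$offset, score = best$score, window = best$window,
       ig = ig, table = table)
}
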