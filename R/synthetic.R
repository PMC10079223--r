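#' Simulation configuration for synthetic genomes and score tracks
#'
#' The simulator emulates the structure of a G4-seq experiment at desk
#' scale: a random background genome with planted quadruplex motifs and a
#' per-bin score track in [0, 100] whose value depends on the central bin
#' and, weighted by `flank_effect`, on the flanking sequence, plus additive
#' Gaussian noise.
#'
#' @param genome_length Total genome length in nt.
#' @param n_chrom Number of equally sized chromosomes.
#' @param gc_fraction Background GC fraction.
#' @param pq_rate Planted quadruplex motifs per kb.
#' @param flank_effect Weight alpha of the flank contribution to the score.
#' @param noise_sd Standard deviation sigma of the additive score noise.
#' @param flank_len Flank length used when generating track scores.
#' @param seed Integer seed; the same seed reproduces genome and track.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_chrom = 4L,
                       gc_fraction = 0.4, pq_rate = 2, flank_effect = 0.5,
                       noise_sd = 5, flank_len = 20L, seed = 1L) {
  stopifnot(genome_length >= n_chrom, gc_fraction > 0, gc_fraction < 1,
            pq_rate >= 0, flank_effect >= 0, noise_sd >= 0, flank_len >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 n_chrom = as.integer(n_chrom), gc_fraction = gc_fraction,
                 pq_rate = pq_rate, flank_effect = flank_effect,
                 noise_sd = noise_sd, flank_len = as.integer(flank_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_pq_motif <- function() {
  tracts <- sample(3:5, 4L, replace = TRUE)
  loops <- sample(1:7, 3L, replace = TRUE)
  parts <- character(7)
  parts[c(1, 3, 5, 7)] <- strrep("G", tracts)
  parts[c(2, 4, 6)] <- vapply(loops, function(l)
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  paste(parts, collapse = "")
}

#' Simulate a genome with planted quadruplex motifs
#'
#' Background bases are drawn i.i.d. at the configured GC fraction; PQ
#' motifs (random G-tract lengths 3-5, loops 1-7 over A/C/T) are planted at
#' `pq_rate` per kb at non-overlapping positions (30 nt minimum separation,
#' clear of chromosome edges), on a random strand. The plant log records
#' every insertion.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `genome_store`) and `plants` (data frame
#'   with columns `chrom`, `start`, `end`, `strand`, `motif`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chrom_len <- config$genome_length %/% config$n_chrom
    p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
           G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
    seqs <- character(config$n_chrom)
    names(seqs) <- paste0("chr", seq_len(config$n_chrom))
    plants <- list()
    margin <- 30L
    for (ci in seq_len(config$n_chrom)) {
      chars <- sample(BASES, chrom_len, replace = TRUE, prob = p)
      n_target <- round(config$pq_rate * chrom_len / 1000)
      if (n_target > 0) {
        occupied <- matrix(integer(0), ncol = 2)
        placed <- 0L
        attempts <- 0L
        max_attempts <- 200L * n_target
        while (placed < n_target) {
          attempts <- attempts + 1L
          if (attempts > max_attempts)
            stopf("pq_rate %.2f is too high to place %d non-overlapping motifs",
                  config$pq_rate, n_target)
          motif <- random_pq_motif()
          w <- nchar(motif)
          start <- sample.int(chrom_len - w - 2L * margin, 1L) + margin
          if (nrow(occupied) > 0 &&
              any(occupied[, 1] < start + w + margin &
                  occupied[, 2] > start - margin)) next
          strand <- sample(c("+", "-"), 1L)
          inserted <- if (strand == "+") motif else reverse_complement(motif)
          chars[(start + 1L):(start + w)] <-
            strsplit(inserted, "", fixed = TRUE)[[1]]
          occupied <- rbind(occupied, c(start, start + w))
          placed <- placed + 1L
          plants[[length(plants) + 1L]] <-
            data.frame(chrom = names(seqs)[ci], start = start,
                       end = start + w, strand = strand, motif = motif,
                       stringsAsFactors = FALSE)
        }
      }
      seqs[ci] <- paste(chars, collapse = "")
    }
    plants <- if (length(plants) == 0)
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif = character(),
                 stringsAsFactors = FALSE)
      else do.call(rbind, plants)
    plants <- plants[order(plants$chrom, plants$start), , drop = FALSE]
    rownames(plants) <- NULL
    list(genome = genome_store(seqs), plants = plants)
  })
}

# signed run values: +min(len, 4) within G-runs, -min(len, 4) within C-runs
run_values <- function(chars) {
  r <- rle(chars)
  vals <- ifelse(r$values == "G", pmin(r$lengths, 4),
                 ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  rep(vals, r$lengths)
}

#' Ground-truth surrogate score of a flanked window
#'
#' A transparent, fixed scoring function used as the simulator's ground
#' truth (deliberately not the learned model): each position takes the
#' signed capped run value `+min(run, 4)` inside a G-run and `-min(run, 4)`
#' inside a C-run (0 elsewhere, N included); the raw score is the mean over
#' the central `bin_len` positions plus `alpha` times the mean over the flank
#' positions, squashed to `100 / (1 + exp(-1.5 * (raw - 1)))`. The constants
#' are frozen so documented example values stay stable.
#'
#' @param window Nucleotide string(s): central bin plus symmetric flanks.
#' @param alpha Flank weight.
#' @param bin_len Central bin length (default 15).
#' @return Numeric vector of scores in (0, 100).
#' @export
surrogate_score <- function(window, alpha = 0.5, bin_len = 15L) {
  vapply(window, function(w) {
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < bin_len || (n - bin_len) %% 2L != 0L)
      stopf("window length %d incompatible with symmetric flanks around %d nt",
            n, bin_len)
    fl <- (n - bin_len) %/% 2L
    v <- run_values(chars)
    central <- mean(v[(fl + 1L):(fl + bin_len)])
    flank <- if (fl == 0L) 0 else mean(v[c(seq_len(fl), (fl + bin_len + 1L):n)])
    raw <- central + alpha * flank
    100 / (1 + exp(-1.5 * (raw - 1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Simulate a per-bin mismatch-score track
#'
#' Scores every non-overlapping `bin_len` nt bin on both strands:
#' `clip(surrogate_score(window) + Normal(0, noise_sd), 0, 100)`, where the
#' window is the bin plus `flank_len` nt flanks extracted strand-aware (and
#' N-padded at chromosome edges).
#'
#' @param genome A `genome_store`.
#' @param flank_len Flank length used by the surrogate.
#' @param alpha Flank weight of the surrogate.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed for the noise.
#' @param bin_len Bin length (default 15).
#' @return A sorted scored-bin data frame.
#' @export
simulate_track <- function(genome, flank_len = 20L, alpha = 0.5, noise_sd = 5,
                           seed = 1L, bin_len = 15L) {
  lens <- chrom_lengths(genome)
  per_chrom <- lapply(names(lens), function(cm) {
    if (lens[[cm]] < bin_len) return(NULL)
    starts <- seq(0L, lens[[cm]] - bin_len, by = bin_len)
    do.call(rbind, lapply(c("+", "-"), function(st)
      data.frame(chrom = cm, start = as.integer(starts),
                 end = as.integer(starts + bin_len), strand = st,
                 stringsAsFactors = FALSE)))
  })
  bins <- do.call(rbind, per_chrom)
  windows <- extract_windows(genome, bins, flank_len)
  score <- surrogate_score(windows, alpha = alpha, bin_len = bin_len)
  if (noise_sd > 0)
    score <- with_seed(seed, score + stats::rnorm(length(score), 0, noise_sd))
  bins$score <- pmin(pmax(score, 0), 100)
  sort_bins(scored_bins(bins$chrom, bins$start, bins$end, bins$strand,
                        bins$score))
}

#' Simulate a full dataset (genome, plant log, noisy and noiseless tracks)
#'
#' Convenience wrapper bundling [simulate_genome()] and [simulate_track()]
#' under one configuration; `track` carries the configured noise, `truth`
#' is the noiseless surrogate track.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `plants`, `track`, `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_genome(config)
  track <- simulate_track(sim$genome, flank_len = config$flank_len,
                          alpha = config$flank_effect,
                          noise_sd = config$noise_sd, seed = config$seed + 1L)
  truth <- simulate_track(sim$genome, flank_len = config$flank_len,
                          alpha = config$flank_effect, noise_sd = 0)
  list(genome = sim$genome, plants = sim$plants, track = track, truth = truth)
}
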