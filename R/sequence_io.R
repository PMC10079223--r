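#' In-memory genome store
#'
#' A light container holding chromosome sequences as upper-case character
#' strings over the alphabet A, C, G, T, N. Sequence extraction, scanning and
#' simulation all operate on this store, so a genome is read from disk once.
#'
#' @param sequences Named character vector of nucleotide strings.
#' @return An object of class `genome_store`.
#' @export
genome_store <- function(sequences) {
  if (length(sequences) == 0) stopf("genome must contain at least one sequence")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) || any(names(sequences) == ""))
    stopf("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    warnf("%d sequence(s) contain ambiguity codes; mapping to N", sum(bad))
    sequences[bad] <- gsub("[^ACGTN]", "N", sequences[bad])
  }
  structure(list(sequences = sequences), class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  lens <- chrom_lengths(x)
  cat(sprintf("<genome_store> %d sequence(s), %s nt total\n",
              length(lens), format(sum(lens), big.mark = ",")))
  for (nm in utils::head(names(lens), 10))
    cat(sprintf("  %s: %d nt\n", nm, lens[[nm]]))
  if (length(lens) > 10) cat(sprintf("  ... and %d more\n", length(lens) - 10))
  invisible(x)
}

#' Chromosome lengths of a genome store
#' @param genome A `genome_store`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_store"))
  vapply(genome$sequences, nchar, integer(1))
}

#' Read a genome from a FASTA file
#'
#' Sequences are upper-cased and any IUPAC ambiguity code other than N is
#' collapsed to N (with a warning), since the model treats only N specially
#' (uniform base probability).
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return A [genome_store()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stopf("no FASTA records found in %s", path)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_store(seqs)
}

#' Write a genome store to FASTA
#' @param genome A `genome_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_store"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

get_chrom <- function(genome, chrom) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stopf("unknown chromosome: %s", chrom)
  s
}

#' Reverse complement of DNA sequences
#'
#' A<->T, C<->G, N is self-complementary; vectorized over its input.
#'
#' @param sequence Character vector over the alphabet A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  if (any(grepl("[^ACGTN]", sequence)))
    stopf("reverse_complement: sequence contains characters outside A,C,G,T,N")
  comp <- chartr("ACGTN", "TGCAN", sequence)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# channel order is fixed to A,C,G,T throughout the package
BASES <- c("A", "C", "G", "T")

ENCODE_ROWS <- rbind(diag(4), rep(0.25, 4))
rownames(ENCODE_ROWS) <- c(BASES, "N")
colnames(ENCODE_ROWS) <- BASES

#' Encode a DNA sequence as a per-position probability matrix
#'
#' Unambiguous bases become one-hot rows in channel order A, C, G, T; N
#' becomes the uniform row (0.25, 0.25, 0.25, 0.25). Every row sums to 1.
#'
#' @param sequence A single nucleotide string over A, C, G, T, N.
#' @return Numeric matrix with one row per position and columns A, C, G, T.
#' @export
encode_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, c(BASES, "N"))
  if (anyNA(idx)) stopf("encode_sequence: invalid character(s): %s",
                        paste(unique(chars[is.na(idx)]), collapse = ", "))
  m <- ENCODE_ROWS[idx, , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Encode equal-length sequences into an (n, len, 4) array; i varies fastest.
encode_batch <- function(seqs) {
  n <- length(seqs)
  len <- nchar(seqs[[1]])
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  idx <- match(chars, c(BASES, "N"))
  if (anyNA(idx)) stopf("encode_batch: invalid character(s) in input sequences")
  a <- array(ENCODE_ROWS[idx, , drop = FALSE], dim = c(len, n, 4))
  aperm(a, c(2, 1, 3))
}

#' Extract a flanked sequence window from a genome
#'
#' Returns the plus-strand substring `[start - flank_up, end + flank_down)`
#' with positions beyond the chromosome ends filled with N; for strand `"-"`
#' the reverse complement is returned so the caller always receives the
#' measured strand 5'->3' (on the minus strand "upstream" is therefore the
#' plus-strand right side).
#'
#' @param genome A `genome_store`.
#' @param chrom,start,end Bin coordinates, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param flank_up,flank_down Flank lengths in nt (on the measured strand);
#'   `flank_down` defaults to `flank_up`.
#' @return A nucleotide string of length `(end - start) + flank_up + flank_down`.
#' @export
extract_window <- function(genome, chrom, start, end, strand = "+",
                           flank_up = 0, flank_down = flank_up) {
  seqs <- extract_windows(genome,
                          data.frame(chrom = chrom, start = start, end = end,
                                     strand = strand, stringsAsFactors = FALSE),
                          flank_up, flank_down)
  seqs[[1]]
}

# vectorized window extraction over a bins data frame
extract_windows <- function(genome, bins, flank_up, flank_down = flank_up) {
  stopifnot(inherits(genome, "genome_store"))
  unknown <- setdiff(unique(bins$chrom), names(genome$sequences))
  if (length(unknown) > 0)
    stopf("unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  minus <- bins$strand == "-"
  # flanks are given on the measured strand; map them to plus-strand offsets
  left <- ifelse(minus, flank_down, flank_up)
  right <- ifelse(minus, flank_up, flank_down)
  s <- bins$start - left
  e <- bins$end + right
  out <- character(nrow(bins))
  lens <- chrom_lengths(genome)
  for (cm in unique(bins$chrom)) {
    rows <- which(bins$chrom == cm)
    chrom_seq <- genome$sequences[[cm]]
    L <- lens[[cm]]
    cs <- pmax(s[rows], 0L)
    ce <- pmin(e[rows], L)
    core <- substring(chrom_seq, cs + 1L, ce)
    npad_l <- pmax(0L, -s[rows])
    npad_r <- pmax(0L, e[rows] - L)
    out[rows] <- paste0(strrep("N", npad_l), core, strrep("N", npad_r))
  }
  if (any(minus)) out[minus] <- reverse_complement(out[minus])
  out
}

#' Build a scored-bin table
#'
#' Bins are genomic intervals (0-based half-open; native G4-seq bins are
#' 15 nt) carrying a mismatch score in percent (0-100) or `NA` when the assay
#' reported none.
#'
#' @param chrom,start,end,strand,score Parallel vectors of bin fields.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`, `score`.
#' @export
scored_bins <- function(chrom, start, end, strand = "+", score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stopf("scored_bins: end must exceed start")
  if (!all(df$strand %in% c("+", "-"))) stopf("scored_bins: strand must be '+' or '-'")
  ok <- is.na(df$score) | (df$score >= 0 & df$score <= 100)
  if (!all(ok)) stopf("scored_bins: scores must lie in [0, 100] or be NA")
  df
}

sort_bins <- function(bins) bins[order(bins$chrom, bins$start, bins$strand), , drop = FALSE]

#' Read a per-bin score track
#'
#' Accepts 4-column bedGraph rows (`chrom start end score`) or 6-column BED
#' rows (`chrom start end name score strand`); in the BED dialect the strand
#' column overrides the `strand` argument. Scores that fail to parse as
#' numbers (e.g. `NA`, `.`) become missing-score bins. Rows are returned
#' sorted by (chrom, start).
#'
#' @param path Input path.
#' @param strand Strand assigned to 4-column rows (default `"+"`).
#' @return A scored-bin data frame (see [scored_bins()]).
#' @export
read_score_track <- function(path, strand = "+") {
  if (!file.exists(path)) stopf("score track not found: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  if (length(keep) == 0)
    return(scored_bins(character(), integer(), integer(), character(), numeric()))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  ncol <- lengths(fields)
  if (!all(ncol %in% c(4L, 6L)))
    stopf("malformed row at line %d: expected 4 or 6 columns, got %d",
          keep[which(!ncol %in% c(4L, 6L))[1]], ncol[which(!ncol %in% c(4L, 6L))[1]])
  get_col <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stopf("malformed row at line %d: non-integer coordinates", keep[bad])
  }
  score_str <- ifelse(ncol == 4L, get_col(4), vapply(fields, function(f) f[5], character(1)))
  score <- suppressWarnings(as.numeric(score_str))
  strand_col <- rep(strand, length(keep))
  six <- ncol == 6L
  if (any(six)) strand_col[six] <- vapply(fields[six], `[`, character(1), 6)
  if (any(end - start != 15L))
    warnf("%d bin(s) are not 15 nt long; kept as-is", sum(end - start != 15L))
  sort_bins(scored_bins(chrom, start, end, strand_col, score))
}

#' Write a score track as BED6
#'
#' Scores are serialized with 4 decimal places (missing scores as `NA`), so a
#' write/read round trip preserves every field.
#'
#' @param bins Scored-bin data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(bins, path) {
  score <- ifelse(is.na(bins$score), "NA", sprintf("%.4f", bins$score))
  rows <- sprintf("%s\t%d\t%d\tbin\t%s\t%s", bins$chrom, bins$start, bins$end,
                  score, bins$strand)
  writeLines(rows, path)
  invisible(path)
}

#' Write peaks as BED6
#'
#' Emits `chrom start end name score strand` rows (0-based half-open) with
#' scores fixed to 4 decimal places; an empty peak set yields an empty file.
#'
#' @param peaks Peak data frame (as produced by [call_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$strand), , drop = FALSE]
  name <- if ("name" %in% names(peaks)) peaks$name else
    sprintf("peak_%d", seq_len(nrow(peaks)))
  rows <- sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", peaks$chrom, peaks$start,
                  peaks$end, name, peaks$score, peaks$strand)
  writeLines(rows, path)
  invisible(path)
}

#' Read a BED6 peak file
#' @param path Input path.
#' @return Peak data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 6)) stopf("read_peaks: expected BED6 rows")
  data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    name = vapply(fields, `[`, character(1), 4),
    score = as.numeric(vapply(fields, `[`, character(1), 5)),
    strand = vapply(fields, `[`, character(1), 6),
    stringsAsFactors = FALSE
  )
}
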