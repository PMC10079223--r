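#' Model architecture specification
#'
#' The regressor sees a central 15 nt bin padded by flanking sequence: a
#' valid (no padding) 1D convolution with rectified-linear activation, global
#' max-pooling over positions, a rectified dense layer, and a single linear
#' output neuron emitting the predicted mismatch score in percent.
#'
#' @param flank_len Flank length L in nt (per side for `flank_side = "both"`).
#' @param kernel_size Convolution kernel width k in nt.
#' @param n_kernels Number of convolution kernels (default 256).
#' @param dense_units Width of the dense layer (default 32).
#' @param bin_len Central bin length (native G4-seq bins are 15 nt).
#' @param flank_side `"both"`, `"upstream"` or `"downstream"`; the one-sided
#'   variants keep a flank on a single side of the central bin, giving input
#'   length `bin_len + flank_len` instead of `bin_len + 2 * flank_len`.
#' @return An object of class `model_spec` with derived field `input_len`.
#' @export
model_spec <- function(flank_len, kernel_size, n_kernels = 256L,
                       dense_units = 32L, bin_len = 15L,
                       flank_side = c("both", "upstream", "downstream")) {
  flank_side <- match.arg(flank_side)
  stopifnot(is.numeric(flank_len), flank_len >= 0, flank_len == round(flank_len))
  stopifnot(is_count(kernel_size), is_count(n_kernels), is_count(dense_units),
            is_count(bin_len))
  input_len <- as.integer(bin_len + if (flank_side == "both") 2 * flank_len else flank_len)
  if (kernel_size > input_len)
    stopf("kernel_size (%d) exceeds input length (%d)", kernel_size, input_len)
  structure(list(flank_len = as.integer(flank_len),
                 kernel_size = as.integer(kernel_size),
                 n_kernels = as.integer(n_kernels),
                 dense_units = as.integer(dense_units),
                 bin_len = as.integer(bin_len),
                 flank_side = flank_side,
                 input_len = input_len),
            class = "model_spec")
}

# flank lengths (upstream, downstream) implied by a spec
spec_flanks <- function(spec) {
  switch(spec$flank_side,
         both = c(spec$flank_len, spec$flank_len),
         upstream = c(spec$flank_len, 0L),
         downstream = c(0L, spec$flank_len))
}

#' Training configuration
#'
#' Defaults follow the published protocol: mean-squared-error loss minimized
#' by Adam at learning rate 0.001 with batch size 256 for one epoch.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Samples per minibatch.
#' @param epochs Passes over the data.
#' @param seed Integer seed governing weight initialization-independent
#'   shuffling of the sample stream.
#' @param clip_norm Global gradient-norm ceiling per update (guards against
#'   occasional violent steps from heavy-tailed score batches).
#' @param verbose Log the running loss during training.
#' @param log_every Batch interval between log lines.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 256L, epochs = 1L,
                         seed = 1L, clip_norm = 5, verbose = FALSE,
                         log_every = 50L) {
  stopifnot(learning_rate > 0, is_count(batch_size), is_count(epochs),
            is_count(log_every), clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip_norm = clip_norm,
                 verbose = isTRUE(verbose), log_every = as.integer(log_every)),
            class = "train_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained mismatch-score model
#'
#' Weights are drawn from a seeded Glorot-uniform initializer; biases start
#' at zero. Two builds with the same spec and seed are identical.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `g4_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  k4 <- 4L * spec$kernel_size
  F_ <- spec$n_kernels
  D <- spec$dense_units
  with_seed(seed, {
    W1 <- glorot(k4, F_)
    W2 <- glorot(F_, D)
    # the output layer starts near zero so initial predictions sit at the
    # (standardized) target mean; this avoids the violent first correction
    # that can silence every rectifier in the dense layer for good
    W3 <- glorot(D, 1L) * 0.01
  })
  structure(list(spec = spec,
                 W1 = W1, b1 = numeric(F_),
                 W2 = W2, b2 = numeric(D),
                 W3 = W3, b3 = 0,
                 y_center = 0, y_scale = 1,
                 meta = list(init_seed = as.integer(seed), trained_batches = 0L,
                             train_seed = NA_integer_, data_fingerprint = NA_character_)),
            class = "g4_model")
}

#' @export
print.g4_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<g4_model> input %d nt (flank %d, %s), %d kernels x %d nt, %d dense units\n",
              s$input_len, s$flank_len, s$flank_side, s$n_kernels,
              s$kernel_size, s$dense_units))
  cat(sprintf("  %s parameters, trained on %d batches\n",
              format(parameter_count(s), big.mark = ","), x$meta$trained_batches))
  invisible(x)
}

#' Closed-form parameter count of the architecture
#'
#' `4*k*F + F` convolution weights and biases, `F*D + D` dense, `D + 1`
#' output, for kernel size k, F kernels and D dense units.
#'
#' @param spec A [model_spec()].
#' @return Integer number of trainable parameters.
#' @export
parameter_count <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$kernel_size; F_ <- spec$n_kernels; D <- spec$dense_units
  as.integer(4 * k * F_ + F_ + F_ * D + D + D + 1)
}

# number of parameters actually held by a built model (audit helper)
#' Count the weights stored in a built model
#' @param model A `g4_model`.
#' @return Integer total length of all weight and bias arrays.
#' @export
count_model_weights <- function(model) {
  stopifnot(inherits(model, "g4_model"))
  sum(vapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")], length, integer(1)))
}

# ---- forward / backward -----------------------------------------------------
# Input batches are (n, len, 4) arrays; internally the convolution is an
# im2col matrix product so all heavy lifting goes through BLAS.

conv_im2col <- function(X, k) {
  d <- dim(X); n <- d[1]; len <- d[2]
  P <- len - k + 1L
  colsidx <- matrix(0L, P, 4L * k)
  for (p in seq_len(P))
    colsidx[p, ] <- as.vector(outer(p:(p + k - 1L), (0:3) * len, `+`))
  Xm <- X; dim(Xm) <- c(n, len * 4L)
  B <- Xm[, as.vector(t(colsidx)), drop = FALSE]
  dim(B) <- c(n, 4L * k, P)
  Bmat <- matrix(aperm(B, c(1, 3, 2)), n * P, 4L * k)
  list(Bmat = Bmat, P = P, colsidx = colsidx, n = n, len = len)
}

model_forward <- function(model, X, want_cache = FALSE) {
  n <- dim(X)[1]
  k <- model$spec$kernel_size
  ic <- conv_im2col(X, k)
  P <- ic$P
  F_ <- model$spec$n_kernels
  H <- ic$Bmat %*% model$W1
  H <- H + rep(model$b1, each = n * P)
  mask1 <- H > 0
  H[!mask1] <- 0
  Harr <- H; dim(Harr) <- c(n, P, F_)
  pooled <- matrix(Harr[, 1, ], n, F_)
  amax <- matrix(1L, n, F_)
  if (P > 1) for (p in 2:P) {
    hp <- matrix(Harr[, p, ], n, F_)
    upd <- hp > pooled
    if (any(upd)) {
      pooled[upd] <- hp[upd]
      amax[upd] <- p
    }
  }
  Zpre <- pooled %*% model$W2 + rep(model$b2, each = n)
  maskZ <- Zpre > 0
  Z <- Zpre; Z[!maskZ] <- 0
  raw <- drop(Z %*% model$W3) + model$b3
  if (!want_cache) return(list(raw = raw))
  list(raw = raw, ic = ic, mask1 = mask1, amax = amax, pooled = pooled,
       maskZ = maskZ, Z = Z, n = n, P = P, F_ = F_)
}

# Backpropagate d(loss)/d(raw output) to parameter and/or input gradients.
model_backward <- function(model, cache, draw, want_input = FALSE,
                           want_params = TRUE) {
  n <- cache$n; P <- cache$P; F_ <- cache$F_
  dZ <- outer(draw, drop(model$W3))
  dZ[!cache$maskZ] <- 0
  dpooled <- dZ %*% t(model$W2)
  dH <- matrix(0, n * P, F_)
  rows <- rep(seq_len(n), F_) + (as.vector(cache$amax) - 1L) * n
  cols <- rep(seq_len(F_), each = n)
  dH[cbind(rows, cols)] <- as.vector(dpooled)
  dH[!cache$mask1] <- 0
  out <- list()
  if (want_params) {
    out$grads <- list(
      W1 = crossprod(cache$ic$Bmat, dH), b1 = colSums(dH),
      W2 = crossprod(cache$pooled, dZ), b2 = colSums(dZ),
      W3 = crossprod(cache$Z, draw), b3 = sum(draw))
  }
  if (want_input) {
    dBmat <- dH %*% t(model$W1)
    k4 <- 4L * model$spec$kernel_size
    len <- cache$ic$len
    dBarr <- dBmat; dim(dBarr) <- c(n, P, k4)
    dXm <- matrix(0, n, len * 4L)
    for (p in seq_len(P)) {
      ci <- cache$ic$colsidx[p, ]
      dXm[, ci] <- dXm[, ci] + matrix(dBarr[, p, ], n, k4)
    }
    out$dX <- array(dXm, c(n, len, 4L))
  }
  out
}

as_input_array <- function(x, input_len) {
  if (is.matrix(x)) {
    if (nrow(x) != input_len || ncol(x) != 4L)
      stopf("input has %d positions; model expects %d x 4", nrow(x), input_len)
    dim(x) <- c(1L, input_len, 4L)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != input_len || dim(x)[3] != 4L)
      stopf("input batch has %d positions; model expects %d x 4", dim(x)[2], input_len)
    return(x)
  }
  stopf("input must be a (len x 4) matrix or an (n, len, 4) array")
}

#' Predict scores for encoded inputs
#'
#' Accepts a single `(len x 4)` probability matrix or an `(n, len, 4)` batch
#' array. Outputs are unclipped: the linear output neuron may exceed
#' `[0, 100]`.
#'
#' @param model A fitted or freshly built model.
#' @param x Encoded input(s); rows must sum to 1.
#' @param ... Unused.
#' @return Numeric vector of predicted mismatch scores (percent).
#' @export
predict_encoded <- function(model, x, ...) UseMethod("predict_encoded")

#' @export
predict_encoded.g4_model <- function(model, x, ...) {
  X <- as_input_array(x, model$spec$input_len)
  model_forward(model, X)$raw * model$y_scale + model$y_center
}

#' Gradient of the model output with respect to an encoded input
#'
#' @param model A model supporting differentiation.
#' @param x Encoded input matrix `(len x 4)` or batch array `(n, len, 4)`.
#' @param ... Unused.
#' @return Gradient with the same shape as `x`.
#' @export
input_gradient <- function(model, x, ...) UseMethod("input_gradient")

#' @export
input_gradient.g4_model <- function(model, x, ...) {
  single <- is.matrix(x)
  X <- as_input_array(x, model$spec$input_len)
  n <- dim(X)[1]
  cache <- model_forward(model, X, want_cache = TRUE)
  dX <- model_backward(model, cache, rep(model$y_scale, n),
                       want_input = TRUE, want_params = FALSE)$dX
  if (single) matrix(dX[1, , ], dim(dX)[2], 4L) else dX
}

#' Input length expected by a model
#' @param model A model object.
#' @return Integer sequence length.
#' @export
model_input_length <- function(model) UseMethod("model_input_length")

#' @export
model_input_length.g4_model <- function(model) model$spec$input_len

#' Linear sequence model
#'
#' A transparent surrogate `f(x) = sum(w * x) + b` over encoded inputs, used
#' to validate attribution methods against their closed forms.
#'
#' @param w Weight matrix `(len x 4)`.
#' @param b Scalar intercept.
#' @return An object of class `linear_seq_model`.
#' @export
linear_seq_model <- function(w, b = 0) {
  stopifnot(is.matrix(w), ncol(w) == 4L, length(b) == 1L)
  structure(list(w = w, b = b), class = "linear_seq_model")
}

#' @export
predict_encoded.linear_seq_model <- function(model, x, ...) {
  X <- as_input_array(x, nrow(model$w))
  n <- dim(X)[1]
  Xm <- matrix(X, n, length(model$w))
  drop(Xm %*% as.vector(model$w)) + model$b
}

#' @export
input_gradient.linear_seq_model <- function(model, x, ...) {
  if (is.matrix(x)) return(model$w)
  n <- dim(as_input_array(x, nrow(model$w)))[1]
  g <- array(0, dim = c(n, nrow(model$w), 4L))
  for (i in seq_len(n)) g[i, , ] <- model$w
  g
}

#' @export
model_input_length.linear_seq_model <- function(model) nrow(model$w)

# ---- streaming batches ------------------------------------------------------

#' Streaming batch extractor
#'
#' Windows are cut from the genome and one-hot encoded on demand, one batch
#' at a time, so memory use never grows beyond the genome plus one batch.
#' Bins with missing scores are skipped (counted in `$n_skipped`). The
#' shuffle order is a deterministic function of `config$seed` and the epoch.
#'
#' @param genome A `genome_store`.
#' @param bins Scored-bin data frame; missing-score bins are dropped.
#' @param spec A [model_spec()] (fixes window length and flank sides).
#' @param config A [train_config()] (fixes batch size and shuffle seed).
#' @return A `batch_stream` object with fields `next_batch()` (returns
#'   `list(x, y)` or `NULL` at end of epoch), `reset(epoch)`, `n_batches`,
#'   `n_samples` and `n_skipped`.
#' @export
make_batch_stream <- function(genome, bins, spec, config) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  missing_score <- is.na(bins$score)
  if (any(missing_score))
    warnf("skipping %d bin(s) with missing scores", sum(missing_score))
  bins <- bins[!missing_score, , drop = FALSE]
  if (nrow(bins) == 0) stopf("no scored bins to stream")
  n <- nrow(bins)
  bs <- config$batch_size
  fl <- spec_flanks(spec)
  env <- new.env(parent = emptyenv())
  env$order <- with_seed(config$seed, sample.int(n))
  env$pos <- 0L
  env$n_samples <- n
  env$n_skipped <- sum(missing_score)
  env$n_batches <- as.integer(ceiling(n / bs))
  env$scores <- bins$score
  env$reset <- function(epoch = 1L) {
    env$order <- with_seed(config$seed + epoch - 1L, sample.int(n))
    env$pos <- 0L
    invisible(NULL)
  }
  env$next_batch <- function() {
    if (env$pos >= n) return(NULL)
    take <- env$order[(env$pos + 1L):min(env$pos + bs, n)]
    env$pos <- env$pos + length(take)
    b <- bins[take, , drop = FALSE]
    windows <- extract_windows(genome, b, fl[1], fl[2])
    list(x = encode_batch(windows), y = b$score)
  }
  class(env) <- "batch_stream"
  env
}

adam_init <- function(model) {
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3")
  list(m = lapply(model[nm], function(w) w * 0),
       v = lapply(model[nm], function(w) w * 0), t = 0L)
}

adam_step <- function(model, state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    if (nm == "b3") model[[nm]] <- model[[nm]] - sum(upd)
    else model[[nm]] <- model[[nm]] - upd
  }
  list(model = model, state = state)
}

#' Train a mismatch-score model on a batch stream
#'
#' Minimizes mean squared error with Adam. Targets are standardized
#' internally (to the stream's mean and standard deviation) so convergence is
#' insensitive to the 0-100 score scale; predictions are mapped back to
#' percent, which leaves Pearson-based evaluation unaffected.
#'
#' @param model A `g4_model` from [build_model()].
#' @param stream A [make_batch_stream()] object.
#' @param config A [train_config()]; `epochs` passes are run, reshuffling the
#'   stream each epoch.
#' @return The trained model.
#' @export
train_model <- function(model, stream, config) {
  stopifnot(inherits(model, "g4_model"), inherits(stream, "batch_stream"),
            inherits(config, "train_config"))
  y_all <- stream$scores
  y_center <- mean(y_all)
  y_sd <- stats::sd(y_all)
  y_scale <- if (is.na(y_sd) || y_sd < 1e-8) 1 else y_sd
  state <- adam_init(model)
  batch_idx <- 0L
  for (epoch in seq_len(config$epochs)) {
    stream$reset(epoch)
    running <- 0; running_n <- 0L
    repeat {
      batch <- stream$next_batch()
      if (is.null(batch)) break
      batch_idx <- batch_idx + 1L
      nb <- length(batch$y)
      t_std <- (batch$y - y_center) / y_scale
      cache <- model_forward(model, batch$x, want_cache = TRUE)
      resid <- cache$raw - t_std
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stopf("non-finite training loss at batch %d", batch_idx)
      draw <- 2 * resid / nb
      grads <- model_backward(model, cache, draw)$grads
      clip <- config$clip_norm %||% Inf
      if (is.finite(clip)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gnorm > clip) grads <- lapply(grads, function(g) g * (clip / gnorm))
      }
      st <- adam_step(model, state, grads, config$learning_rate)
      model <- st$model; state <- st$state
      running <- running + loss * nb; running_n <- running_n + nb
      if (config$verbose && batch_idx %% config$log_every == 0L)
        message(sprintf("epoch %d batch %d: mse (standardized) %.4f",
                        epoch, batch_idx, running / running_n))
    }
  }
  model$y_center <- y_center
  model$y_scale <- y_scale
  model$meta$trained_batches <- model$meta$trained_batches + batch_idx
  model$meta$train_seed <- config$seed
  model$meta$data_fingerprint <- sprintf("n=%d;mean=%.6g;sd=%.6g",
                                         stream$n_samples, y_center, y_sd)
  model
}

#' Predict mismatch scores for genomic bins
#'
#' Extracts each bin's flanked window (reverse-complemented for minus-strand
#' bins), encodes it and applies the model in batches. Input order is
#' preserved; outputs are unclipped.
#'
#' @param model A `g4_model`.
#' @param genome A `genome_store`.
#' @param bins Scored-bin data frame (scores may be missing; they are ignored).
#' @param batch_size Prediction batch size.
#' @return `bins` with an added `predicted` column.
#' @export
predict_bins <- function(model, genome, bins, batch_size = 512L) {
  stopifnot(inherits(model, "g4_model"))
  fl <- spec_flanks(model$spec)
  n <- nrow(bins)
  pred <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    windows <- extract_windows(genome, bins[idx, , drop = FALSE], fl[1], fl[2])
    pred[idx] <- predict_encoded(model, encode_batch(windows))
  }
  bins$predicted <- pred
  bins
}

#' Predict scores for raw sequences
#'
#' Sequences must already have the model's input length (central bin plus
#' flanks).
#'
#' @param model A `g4_model`.
#' @param sequences Character vector of equal-length sequences.
#' @param batch_size Prediction batch size.
#' @return Numeric vector of predicted scores.
#' @export
predict_sequences <- function(model, sequences, batch_size = 512L) {
  len <- model_input_length(model)
  if (any(nchar(sequences) != len))
    stopf("all sequences must have the model input length (%d nt)", len)
  n <- length(sequences)
  pred <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    pred[idx] <- predict_encoded(model, encode_batch(sequences[idx]))
  }
  pred
}

#' Pearson correlation between predicted and measured scores
#'
#' Pairs with a missing value on either side are removed first.
#'
#' @param predicted,measured Equal-length numeric vectors.
#' @return The product-moment correlation coefficient.
#' @export
evaluate_pearson <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stopf("predicted and measured lengths differ")
  keep <- !(is.na(predicted) | is.na(measured))
  x <- predicted[keep]; y <- measured[keep]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' Score-balanced evaluation by stratified resampling
#'
#' The measured-score range is split into `n_bins` uniform intervals;
#' `n_per_bin` samples are drawn from each without replacement and the
#' Pearson correlation computed on the pooled draw, repeated `iterations`
#' times. This removes the dominance of the low-score background in
#' genome-wide tracks.
#'
#' @param predicted,measured Equal-length numeric vectors (missing pairs
#'   dropped).
#' @param n_bins Number of uniform score strata.
#' @param n_per_bin Samples drawn per stratum.
#' @param iterations Resampling repetitions.
#' @param seed Integer seed.
#' @return List with `mean_r`, `sd_r` and the per-iteration vector `r`.
#' @export
balanced_evaluation <- function(predicted, measured, n_bins = 3L,
                                n_per_bin = 1000L, iterations = 1000L,
                                seed = 1L) {
  keep <- !(is.na(predicted) | is.na(measured))
  predicted <- predicted[keep]; measured <- measured[keep]
  breaks <- seq(min(measured), max(measured), length.out = n_bins + 1L)
  grp <- findInterval(measured, breaks, rightmost.closed = TRUE)
  grp[grp > n_bins] <- n_bins
  occ <- tabulate(grp, n_bins)
  if (any(occ < n_per_bin))
    stopf("underfilled score bin(s): occupancies %s < n_per_bin = %d",
          paste(occ, collapse = ", "), n_per_bin)
  idx_by_bin <- split(seq_along(measured), grp)
  r <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    take <- unlist(lapply(idx_by_bin, sample, size = n_per_bin), use.names = FALSE)
    stats::cor(predicted[take], measured[take])
  }, numeric(1)))
  list(mean_r = mean(r), sd_r = stats::sd(r), r = r)
}

#' Leave-chromosome-out split
#'
#' @param bins Scored-bin data frame.
#' @param test_chroms Chromosomes held out for testing.
#' @param validation_chroms Chromosomes held out for validation (optional).
#' @return List of data frames `train`, `validation`, `test`.
#' @export
split_by_chromosome <- function(bins, test_chroms, validation_chroms = character()) {
  overlap <- intersect(test_chroms, validation_chroms)
  if (length(overlap) > 0)
    stopf("chromosome(s) in both test and validation: %s", paste(overlap, collapse = ", "))
  list(train = bins[!(bins$chrom %in% c(test_chroms, validation_chroms)), , drop = FALSE],
       validation = bins[bins$chrom %in% validation_chroms, , drop = FALSE],
       test = bins[bins$chrom %in% test_chroms, , drop = FALSE])
}

CHECKPOINT_FORMAT <- "g4scan_model"
CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' The checkpoint holds a versioned header, the architecture spec, the
#' target-calibration constants and the raw weight arrays; [load_model()]
#' restores a bit-identical predictor.
#'
#' @param model A `g4_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "g4_model"))
  payload <- list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
                  spec = unclass(model$spec),
                  weights = model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                  calibration = c(y_center = model$y_center, y_scale = model$y_scale),
                  meta = model$meta)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_model()].
#' @return A `g4_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stopf("not a readable checkpoint: %s", path))
  if (!is.list(payload) || !identical(payload$format, CHECKPOINT_FORMAT))
    stopf("file is not a %s checkpoint", CHECKPOINT_FORMAT)
  if (!identical(payload$version, CHECKPOINT_VERSION))
    stopf("checkpoint version %s is not supported (expected %d)",
          paste(payload$version, collapse = ""), CHECKPOINT_VERSION)
  spec <- do.call(model_spec, payload$spec[c("flank_len", "kernel_size",
                                             "n_kernels", "dense_units",
                                             "bin_len", "flank_side")])
  model <- c(list(spec = spec), payload$weights,
             list(y_center = unname(payload$calibration["y_center"]),
                  y_scale = unname(payload$calibration["y_scale"]),
                  meta = payload$meta))
  class(model) <- "g4_model"
  model
}

#' Architecture sweep grid
#'
#' Enumerates the flank-length / kernel-size combinations of the published
#' sweep protocol: flank lengths from 0 to 140 nt in 20 nt increments and,
#' for each flank length L, kernel sizes from 5 to 2L + 15 in increments of
#' 10.
#'
#' @param flank_lens Flank lengths to cover.
#' @param kernel_min,kernel_step Start and increment of the kernel-size range.
#' @return Data frame with columns `flank_len` and `kernel_size`.
#' @export
architecture_grid <- function(flank_lens = seq(0L, 140L, by = 20L),
                              kernel_min = 5L, kernel_step = 10L) {
  do.call(rbind, lapply(flank_lens, function(L) {
    ks <- seq(kernel_min, 2L * L + 15L, by = kernel_step)
    data.frame(flank_len = L, kernel_size = ks)
  }))
}

#' Run a flank/kernel architecture sweep
#'
#' Trains one model per grid row on the training bins and records the
#' validation Pearson correlation, yielding the (L, k, r) triples used to
#' pick an architecture.
#'
#' @param genome A `genome_store`.
#' @param bins Scored-bin data frame.
#' @param grid Data frame from [architecture_grid()] (or any subset).
#' @param config A [train_config()].
#' @param validation_chroms Chromosomes held out for validation.
#' @param ... Passed to [model_spec()] (e.g. `n_kernels`).
#' @return `grid` with an added `r` column.
#' @export
run_architecture_sweep <- function(genome, bins, grid, config,
                                   validation_chroms, ...) {
  split <- split_by_chromosome(bins, character(), validation_chroms)
  r <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- model_spec(grid$flank_len[i], grid$kernel_size[i], ...)
    model <- build_model(spec, seed = config$seed)
    stream <- make_batch_stream(genome, split$train, spec, config)
    model <- train_model(model, stream, config)
    val <- predict_bins(model, genome, split$validation)
    evaluate_pearson(val$predicted, val$score)
  }, numeric(1))
  grid$r <- r
  grid
}
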