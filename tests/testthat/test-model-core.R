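test_that("parameter count closed form matches enumerated weights", {
  spec <- model_spec(100, 95)
  expect_equal(parameter_count(spec), 105793L)
  expect_equal(count_model_weights(build_model(spec, 1)), 105793L)

  expect_equal(parameter_count(model_spec(0, 5, n_kernels = 1, dense_units = 1)), 25L)

  set.seed(7)
  for (i in 1:20) {
    L <- sample(0:30, 1)
    spec <- model_spec(L, sample(seq_len(15 + 2 * L), 1),
                       n_kernels = sample(1:64, 1),
                       dense_units = sample(1:32, 1))
    expect_equal(count_model_weights(build_model(spec, i)), parameter_count(spec))
  }

  # doubling the kernel count doubles the conv and dense-input terms
  s1 <- model_spec(10, 9, n_kernels = 8, dense_units = 4)
  s2 <- model_spec(10, 9, n_kernels = 16, dense_units = 4)
  conv_dense <- function(s) 4 * s$kernel_size * s$n_kernels + s$n_kernels +
    s$n_kernels * s$dense_units
  expect_equal(conv_dense(s2), 2 * conv_dense(s1))
})

test_that("spec validation rejects kernels wider than the input", {
  expect_error(model_spec(0, 16), "exceeds")
  expect_equal(model_spec(100, 95)$input_len, 215L)
  expect_equal(model_spec(0, 15)$input_len, 15L)
  expect_equal(model_spec(100, 95, flank_side = "upstream")$input_len, 115L)
})

test_that("model building is deterministic under a fixed seed", {
  spec <- model_spec(5, 9, n_kernels = 8, dense_units = 4)
  x <- encode_sequence(random_dna(spec$input_len))
  m1 <- build_model(spec, 42)
  m2 <- build_model(spec, 42)
  expect_identical(predict_encoded(m1, x), predict_encoded(m2, x))
  m3 <- build_model(spec, 43)
  expect_false(identical(predict_encoded(m1, x), predict_encoded(m3, x)))
})

test_that("batch streams cover every scored bin once in seeded order", {
  g <- genome_store(c(c1 = random_dna(400)))
  starts <- seq(0L, 135L, by = 15L)  # 10 bins
  bins <- scored_bins("c1", starts, starts + 15L, "+", seq(5, 50, by = 5))
  spec <- model_spec(5, 9, n_kernels = 4, dense_units = 2)
  cfg <- train_config(batch_size = 4, seed = 9)
  st <- make_batch_stream(g, bins, spec, cfg)
  sizes <- integer(); ys <- numeric()
  repeat {
    b <- st$next_batch()
    if (is.null(b)) break
    sizes <- c(sizes, length(b$y)); ys <- c(ys, b$y)
  }
  expect_equal(sizes, c(4L, 4L, 2L))
  expect_setequal(ys, bins$score)

  st$reset(1)
  first_again <- st$next_batch()
  st2 <- make_batch_stream(g, bins, spec, cfg)
  expect_identical(first_again$y, st2$next_batch()$y)

  # larger stream: the concatenated scores are a permutation of the input
  big_starts <- seq(0L, by = 15L, length.out = 1000L)
  gbig <- genome_store(c(c1 = random_dna(15 * 1000 + 50)))
  big <- scored_bins("c1", big_starts, big_starts + 15L, "+",
                     round(runif(1000, 0, 100), 3))
  stb <- make_batch_stream(gbig, big, spec, train_config(batch_size = 64, seed = 2))
  all_y <- numeric()
  repeat {
    b <- stb$next_batch(); if (is.null(b)) break
    all_y <- c(all_y, b$y)
  }
  expect_equal(sort(all_y), sort(big$score))

  bins$score[3] <- NA
  expect_warning(st3 <- make_batch_stream(g, bins, spec, cfg), "missing scores")
  expect_equal(st3$n_skipped, 1L)
  expect_equal(st3$n_samples, 9L)
})

test_that("training recovers a constant target and is deterministic", {
  g <- genome_store(c(c1 = random_dna(800), c2 = random_dna(800)))
  tr <- simulate_track(g, flank_len = 5, noise_sd = 0)
  tr$score <- 30
  spec <- model_spec(5, 9, n_kernels = 8, dense_units = 4)
  cfg <- train_config(learning_rate = 0.01, batch_size = 32, epochs = 3, seed = 1)
  split <- split_by_chromosome(tr, "c2")
  st <- make_batch_stream(g, split$train, spec, cfg)
  m <- train_model(build_model(spec, 1), st, cfg)
  held <- predict_bins(m, g, split$test)
  expect_true(all(abs(held$predicted - 30) <= 2))

  m2 <- train_model(build_model(spec, 1), st, cfg)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$b3, m2$b3)
})

test_that("bin prediction preserves order, strand semantics and batching", {
  ds <- fixture_dataset()
  m <- fixture_model()
  bins <- ds$track[sample(nrow(ds$track), 100), ]
  p <- predict_bins(m, ds$genome, bins, batch_size = 32)
  expect_equal(p[, c("chrom", "start", "end", "strand")],
               bins[, c("chrom", "start", "end", "strand")])

  # batch prediction equals looped single-window prediction
  fl <- c(m$spec$flank_len, m$spec$flank_len)
  singles <- vapply(seq_len(20), function(i) {
    w <- extract_window(ds$genome, bins$chrom[i], bins$start[i], bins$end[i],
                        bins$strand[i], flank_up = fl[1])
    predict_encoded(m, encode_sequence(w))
  }, numeric(1))
  expect_equal(p$predicted[1:20], singles, tolerance = 1e-10)

  # duplicate bins give identical scores
  dup <- rbind(bins[1, ], bins[1, ])
  pd <- predict_bins(m, ds$genome, dup)
  expect_identical(pd$predicted[1], pd$predicted[2])

  # a minus-strand bin equals direct prediction on the reverse-complemented window
  mb <- bins[bins$strand == "-", ][1, ]
  plus_window <- extract_window(ds$genome, mb$chrom, mb$start, mb$end, "+",
                                flank_up = m$spec$flank_len)
  expect_equal(predict_bins(m, ds$genome, mb)$predicted,
               predict_encoded(m, encode_sequence(reverse_complement(plus_window))))

  expect_error(predict_bins(m, ds$genome, scored_bins("nope", 0, 15)),
               "unknown chromosome")
})

test_that("pearson evaluation handles affine maps, sign and degenerate input", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(evaluate_pearson(2 * y + 5, y), 1.0)
  expect_equal(evaluate_pearson(-y, y), -1.0)
  expect_error(evaluate_pearson(rep(1, 5), y[1:5]), "zero variance")
  expect_error(evaluate_pearson(y, y[-1]), "differ")
  expect_error(evaluate_pearson(c(1, 2), c(1, 2)), "at least 3")

  # frozen 20-pair fixture against the direct sum formula
  set.seed(8)
  a <- runif(20); b <- a + rnorm(20, 0, 0.3)
  n <- 20
  r_formula <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  expect_equal(evaluate_pearson(a, b), r_formula, tolerance = 1e-12)
})

test_that("balanced evaluation is exact on identity and checks occupancy", {
  set.seed(9)
  y <- runif(600, 0, 100)
  be <- balanced_evaluation(y, y, n_per_bin = 20, iterations = 20, seed = 1)
  expect_equal(be$mean_r, 1.0)
  expect_equal(be$sd_r, 0.0)

  expect_error(balanced_evaluation(y, y, n_per_bin = 10000, iterations = 5),
               "underfilled")

  # two different sampling seeds agree within 3 combined standard errors
  x <- y + rnorm(600, 0, 20)
  b1 <- balanced_evaluation(x, y, n_per_bin = 20, iterations = 50, seed = 1)
  b2 <- balanced_evaluation(x, y, n_per_bin = 20, iterations = 50, seed = 2)
  se <- sqrt(b1$sd_r^2 / 50 + b2$sd_r^2 / 50)
  expect_lt(abs(b1$mean_r - b2$mean_r), 3 * se)
})

test_that("checkpoints round-trip bit-exactly and reject bad input", {
  m <- fixture_model()
  path <- tempfile(fileext = ".g4")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(10)
  for (i in 1:10) {
    x <- encode_sequence(random_dna(m$spec$input_len, c("A", "C", "G", "T", "N")))
    expect_identical(predict_encoded(m, x), predict_encoded(m2, x))
  }

  # reloaded model rejects wrong-length input
  expect_error(predict_encoded(m2, encode_sequence(random_dna(215))), "expects")

  bad <- tempfile()
  writeLines("this is not a checkpoint", bad)
  expect_error(load_model(bad), "checkpoint")
  saveRDS(list(format = "g4scan_model", version = 99L), path)
  expect_error(load_model(path), "version")
})

test_that("architecture sweep grid follows the published protocol", {
  grid <- architecture_grid()
  expect_equal(sort(unique(grid$flank_len)), seq(0, 140, by = 20))
  for (L in unique(grid$flank_len)) {
    ks <- grid$kernel_size[grid$flank_len == L]
    expect_equal(ks, seq(5, 2 * L + 15, by = 10))
    expect_true(all(ks <= 15 + 2 * L))
  }
})

test_that("a tiny sweep trains per grid row and records validation r", {
  g <- genome_store(c(c1 = random_dna(3000), c2 = random_dna(3000)))
  tr <- simulate_track(g, flank_len = 5, alpha = 0.5, noise_sd = 2, seed = 3)
  grid <- data.frame(flank_len = c(0L, 5L), kernel_size = c(5L, 9L))
  cfg <- train_config(learning_rate = 0.01, batch_size = 64, epochs = 1, seed = 3)
  res <- run_architecture_sweep(g, tr, grid, cfg, validation_chroms = "c2",
                                n_kernels = 8, dense_units = 4)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$r)))
  expect_true(all(res$r >= -1 & res$r <= 1))
})

test_that("one-sided flank models accept their reduced input length", {
  spec_up <- model_spec(20, 15, n_kernels = 4, dense_units = 2,
                        flank_side = "upstream")
  m <- build_model(spec_up, 1)
  expect_equal(model_input_length(m), 35L)
  g <- genome_store(c(c1 = random_dna(200)))
  p <- predict_bins(m, g, scored_bins("c1", 60, 75))
  expect_true(is.finite(p$predicted))
  # upstream-only window: flank precedes the bin on the measured strand
  w <- extract_window(g, "c1", 60, 75, "+", flank_up = 20, flank_down = 0)
  expect_equal(p$predicted, predict_encoded(m, encode_sequence(w)))
})
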