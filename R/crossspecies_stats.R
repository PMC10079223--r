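#' Cross-dataset training and prediction matrix
#'
#' Trains one model per dataset (all with the same architecture and training
#' configuration) and fills a square Pearson-correlation matrix with rows as
#' training datasets and columns as evaluation datasets. Exactly one training
#' run is performed per dataset. When `eval_chroms` is given, evaluation is
#' restricted to those chromosomes and training excludes them; otherwise each
#' dataset is evaluated on all of its bins and the diagonal is flagged as
#' self-evaluated via the `self_evaluation` attribute.
#'
#' @param datasets Named list; each element is `list(genome = , bins = )`.
#' @param spec A [model_spec()] shared by all models.
#' @param config A [train_config()] shared by all trainings.
#' @param eval_chroms Optional chromosome names held out for evaluation.
#' @return Square numeric matrix of Pearson correlations with attributes
#'   `self_evaluation` (logical) and `failed` (character vector of training
#'   dataset names whose row is all NA).
#' @export
cross_species_matrix <- function(datasets, spec, config, eval_chroms = NULL) {
  if (length(datasets) < 2) stopf("need at least two datasets")
  if (is.null(names(datasets)) || anyDuplicated(names(datasets)))
    stopf("datasets must be uniquely named")
  nms <- names(datasets)
  models <- vector("list", length(datasets))
  names(models) <- nms
  failed <- character()
  for (nm in nms) {
    d <- datasets[[nm]]
    train_bins <- if (is.null(eval_chroms)) d$bins
      else d$bins[!(d$bins$chrom %in% eval_chroms), , drop = FALSE]
    models[[nm]] <- tryCatch({
      model <- build_model(spec, seed = config$seed)
      stream <- make_batch_stream(d$genome, train_bins, spec, config)
      train_model(model, stream, config)
    }, error = function(e) {
      warnf("training failed for dataset %s: %s", nm, conditionMessage(e))
      NULL
    })
    if (is.null(models[[nm]])) failed <- c(failed, nm)
  }
  mat <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (tr in nms) {
    if (is.null(models[[tr]])) next
    for (ev in nms) {
      d <- datasets[[ev]]
      eval_bins <- if (is.null(eval_chroms)) d$bins
        else d$bins[d$bins$chrom %in% eval_chroms, , drop = FALSE]
      eval_bins <- eval_bins[!is.na(eval_bins$score), , drop = FALSE]
      pred <- predict_bins(models[[tr]], d$genome, eval_bins)
      mat[tr, ev] <- tryCatch(evaluate_pearson(pred$predicted, pred$score),
                              error = function(e) NA_real_)
    }
  }
  attr(mat, "self_evaluation") <- is.null(eval_chroms)
  attr(mat, "failed") <- failed
  mat
}

#' Genome and experiment properties
#'
#' Computes the descriptors used to relate cross-dataset model performance to
#' properties of the training data: genome size, GC content (N excluded from
#' the denominator), extended-PQ count on both strands (loops 1-12), PQ
#' density per nt, and the fraction of measured bins scoring below 5 percent.
#' Single-nucleotide coverage is experiment metadata and is passed through.
#'
#' @param genome A `genome_store`.
#' @param bins Scored-bin data frame with measured scores.
#' @param snv_coverage Caller-supplied coverage value (optional).
#' @return Named list of properties.
#' @export
genome_properties <- function(genome, bins = NULL, snv_coverage = NA_real_) {
  stopifnot(inherits(genome, "genome_store"))
  lens <- chrom_lengths(genome)
  genome_size <- sum(lens)
  if (genome_size == 0) stopf("empty genome")
  counts <- Reduce(`+`, lapply(genome$sequences, function(s) {
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c(BASES, "N")))
    as.numeric(tab)
  }))
  names(counts) <- c(BASES, "N")
  acgt <- sum(counts[BASES])
  gc_content <- if (acgt == 0) NA_real_ else (counts["G"] + counts["C"]) / acgt
  n_pqs <- nrow(find_pq(genome, form = "extended"))
  low_score_freq <- if (is.null(bins) || all(is.na(bins$score))) NA_real_
    else mean(bins$score[!is.na(bins$score)] < 5)
  list(genome_size = genome_size,
       gc_content = unname(gc_content),
       n_pqs = n_pqs,
       pq_density = n_pqs / genome_size,
       low_score_freq = low_score_freq,
       snv_coverage = snv_coverage)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Uses average ranks for ties and the asymptotic two-sided test. A constant
#' vector makes the correlation undefined; both values are then reported as
#' `NA`.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Harmonic mean p-value
#'
#' Combines (possibly dependent) p-values by the unweighted harmonic mean,
#' `n / sum(1 / p)`. The result always lies between `min(p)` and `max(p)`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
harmonic_mean_pvalue <- function(p_values) {
  if (length(p_values) == 0) stopf("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  length(p_values) / sum(1 / p_values)
}

#' Significance tier label for a combined p-value
#'
#' Report labels only: `ns`, `**` (<= 0.009), `***` (<= 0.001), `****`
#' (<= 0.0001).
#'
#' @param p A p-value.
#' @return A character label.
#' @export
significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.009) "**" else "ns"
}

#' Correlate cross-dataset performance with dataset properties
#'
#' For each property column, Spearman-correlates the property value of the
#' training datasets with each evaluation dataset's performance column of the
#' cross-dataset matrix, then combines the per-column p-values by the
#' harmonic mean.
#'
#' @param perf_matrix Matrix from [cross_species_matrix()].
#' @param properties Data frame of properties, one row per dataset in matrix
#'   row order.
#' @param exclude_self Drop the diagonal entry from each column's correlation
#'   (the usual choice when the diagonal is self-evaluated).
#' @return Data frame with one row per property: `property`, `combined_p`,
#'   `tier`, `mean_rho`.
#' @export
property_performance_report <- function(perf_matrix, properties,
                                        exclude_self = TRUE) {
  stopifnot(nrow(properties) == nrow(perf_matrix))
  res <- lapply(names(properties), function(prop) {
    vals <- properties[[prop]]
    if (!is.numeric(vals)) return(NULL)
    cors <- lapply(seq_len(ncol(perf_matrix)), function(j) {
      rows <- seq_len(nrow(perf_matrix))
      if (exclude_self) rows <- rows[rows != j]
      spearman_correlation(vals[rows], perf_matrix[rows, j])
    })
    ps <- vapply(cors, `[[`, numeric(1), "p_value")
    rhos <- vapply(cors, `[[`, numeric(1), "rho")
    ps <- ps[!is.na(ps)]
    # asymptotic p-values underflow to 0 for perfect rank agreement at tiny n
    ps <- pmax(ps, .Machine$double.xmin)
    combined <- if (length(ps) == 0) NA_real_ else harmonic_mean_pvalue(ps)
    data.frame(property = prop, combined_p = combined,
               tier = significance_tier(combined),
               mean_rho = mean(rhos, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
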