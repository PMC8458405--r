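#' Simulate a synthetic expression cohort with one protruded biomarker
#'
#' Simulates log2-scale expression for `n_genes` independent genes over
#' `n_samples` samples: each gene draws a baseline mean from Normal(0, 1) and
#' per-sample residuals from Normal(0, 1). A fraction `pos_fraction` of
#' samples (rounded to the nearest count, drawn uniformly) is made positive
#' by adding Normal(`mu_protrude`, `protrude_sd`) noise to the biomarker
#' gene's values in those samples. Only the biomarker row differs between
#' positive and negative samples in expectation.
#'
#' @param n_genes number of genes, default 1000.
#' @param n_samples number of samples, default 100.
#' @param mu_protrude mean of the protruding Gaussian noise (log2 units).
#' @param pos_fraction fraction of positive samples in `[0, 1]`.
#' @param protrude_sd SD of the protruding noise, default 1.6.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param biomarker row index of the protruded gene, default 1.
#' @return An object of class `synthetic_cohort`: `matrix` (genes x samples),
#'   `biomarker_id`, `positive_samples` (sample IDs), `labels` (named
#'   logical), and the simulation parameters.
#' @export
simulate_cohort <- function(n_genes = 1000L, n_samples = 100L,
                            mu_protrude = 5, pos_fraction = 0.2,
                            protrude_sd = 1.6, seed = 0L, biomarker = 1L) {
  stopifnot(pos_fraction >= 0, pos_fraction <= 1, n_genes >= 2L,
            n_samples >= 1L, biomarker >= 1L, biomarker <= n_genes)
  with_seed(seed, {
    gene_means <- rnorm(n_genes)
    mat <- gene_means + matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    n_pos <- round(pos_fraction * n_samples)
    pos <- sort(sample.int(n_samples, n_pos))
    if (n_pos > 0) {
      mat[biomarker, pos] <- mat[biomarker, pos] +
        rnorm(n_pos, mu_protrude, protrude_sd)
    }
    dimnames(mat) <- list(sprintf("g%04d", seq_len(n_genes)),
                          sprintf("s%03d", seq_len(n_samples)))
    labels <- stats::setNames(seq_len(n_samples) %in% pos, colnames(mat))
    structure(list(matrix = mat,
                   biomarker_id = rownames(mat)[biomarker],
                   positive_samples = colnames(mat)[pos],
                   labels = labels,
                   mu_protrude = mu_protrude, protrude_sd = protrude_sd,
                   pos_fraction = pos_fraction, seed = seed),
              class = "synthetic_cohort")
  })
}

#' Univariate IQR-rule outlier calls
#'
#' Calls a sample an outlier when the marker's value strictly exceeds
#' Q3 + `multiplier` * IQR of the marker's cohort distribution (type-7
#' quartiles). Needs at least 4 non-missing values; degenerate (constant)
#' vectors yield no calls.
#'
#' @param values numeric vector of one marker's values across samples.
#' @param multiplier IQR multiplier, default 1.5.
#' @return Logical vector of calls (FALSE where the value is missing).
#' @export
univariate_iqr_call <- function(values, multiplier = 1.5) {
  ok <- !is.na(values)
  calls <- rep(FALSE, length(values))
  names(calls) <- names(values)
  if (sum(ok) < 4L) return(calls)
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  if (iqr == 0 && length(unique(values[ok])) == 1L) return(calls)
  calls[ok] <- values[ok] > q[2L] + multiplier * iqr
  calls
}

#' Univariate standard-score outlier calls
#'
#' Calls a sample an outlier when its standardized value
#' (value - mean) / SD strictly exceeds `z_cut`. Zero-SD vectors yield no
#' calls.
#'
#' @param values numeric vector of one marker's values across samples.
#' @param z_cut standard-score cutoff, default 2.
#' @return Logical vector of calls (FALSE where the value is missing).
#' @export
univariate_zscore_call <- function(values, z_cut = 2) {
  ok <- !is.na(values)
  calls <- rep(FALSE, length(values))
  names(calls) <- names(values)
  if (sum(ok) < 3L) return(calls)
  s <- sd(values[ok])
  if (is.na(s) || s == 0) return(calls)
  calls[ok] <- (values[ok] - mean(values[ok])) / s > z_cut
  calls
}

#' Precision, recall, selectivity, and F measure of a call set
#'
#' @param calls logical vector of positive calls.
#' @param labels logical vector of true labels, same length; at least one
#'   must be TRUE.
#' @return Named numeric vector: `precision` (`NA` when nothing is called),
#'   `recall`, `selectivity`, `f` (the harmonic mean of precision and recall;
#'   0 when no true positive is recovered).
#' @export
evaluate_calls <- function(calls, labels) {
  stopifnot(length(calls) == length(labels),
            is.logical(calls), is.logical(labels),
            !anyNA(calls), !anyNA(labels))
  if (!any(labels)) {
    stop("no positive labels: recall is undefined", call. = FALSE)
  }
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  tn <- sum(!calls & !labels)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- tp / (tp + fn)
  selectivity <- tn / (tn + fp)
  c(precision = precision, recall = recall, selectivity = selectivity,
    f = f_measure(precision, recall))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in `[0, 1]`; `F = 2pr / (p + r)`, defined
#'   as 0 when `p + r = 0` (or precision is undefined).
#' @return The F measure.
#' @export
f_measure <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Sensitivity/selectivity operating curve over score thresholds
#'
#' Sweeps the calling threshold over the sorted unique score values (plus one
#' threshold below the minimum, at which everything is called and recall is
#' 1) and reports sensitivity, selectivity, precision, and F at each level.
#' Calls are `score > threshold`, so at the maximum score nothing is called.
#'
#' @param scores numeric scores, finite wherever labeled.
#' @param labels logical true labels.
#' @param native_threshold optional method-native threshold; when given, the
#'   returned object carries an `native` attribute with the operating point
#'   at that threshold.
#' @return data.frame with columns `threshold`, `sensitivity`, `selectivity`,
#'   `precision`, `f`.
#' @export
sliding_threshold_curve <- function(scores, labels, native_threshold = NULL) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- labels[ok]
  thr <- sort(unique(scores))
  thr <- c(thr[1L] - 1, thr)
  rows <- lapply(thr, function(t) {
    ev <- evaluate_calls(scores > t, labels)
    data.frame(threshold = t, sensitivity = ev[["recall"]],
               selectivity = ev[["selectivity"]],
               precision = ev[["precision"]], f = ev[["f"]])
  })
  curve <- do.call(rbind, rows)
  if (!is.null(native_threshold)) {
    ev <- evaluate_calls(scores > native_threshold, labels)
    attr(curve, "native") <- data.frame(threshold = native_threshold,
                                        sensitivity = ev[["recall"]],
                                        selectivity = ev[["selectivity"]],
                                        precision = ev[["precision"]],
                                        f = ev[["f"]])
  }
  curve
}

# Parse a benchmark method spec like "oppti:k=4", "oppti:k=1", "iqr",
# "zscore" into list(name, k).
parse_method <- function(spec) {
  if (grepl("^oppti(:k=[0-9]+)?$", spec)) {
    k <- if (grepl(":", spec, fixed = TRUE)) {
      as.integer(sub("^oppti:k=", "", spec))
    } else 6L
    list(label = spec, type = "oppti", k = k)
  } else if (spec == "iqr") {
    list(label = spec, type = "iqr", k = NA_integer_)
  } else if (spec == "zscore") {
    list(label = spec, type = "zscore", k = NA_integer_)
  } else {
    stop("unknown benchmark method: ", spec,
         " (use oppti:k=<int>, iqr, or zscore)", call. = FALSE)
  }
}

# Run one method on one subsampled cohort; returns the biomarker's calls at
# the method's native threshold.
run_method_calls <- function(method, mat, biomarker, iqr_multiplier, z_cut) {
  if (method$type == "oppti") {
    norm <- mad_normalize(mat)
    overlap <- min(10L, max(3L, ncol(mat) - 2L))
    res <- oppti_detect(norm, oppti_config(k = method$k,
                                           min_pairwise_overlap = overlap))
    res$calls[biomarker, ]
  } else if (method$type == "iqr") {
    univariate_iqr_call(mat[biomarker, ], multiplier = iqr_multiplier)
  } else {
    univariate_zscore_call(mat[biomarker, ], z_cut = z_cut)
  }
}

#' Benchmark outlier-detection methods on synthetic cohorts
#'
#' For every scenario (a `mu_protrude` / `pos_fraction` pair) and subsample
#' size, draws `n_resamples` balanced subsamples with replacement — positives
#' and negatives resampled separately so the subsample keeps the positive
#' fraction exactly — from a cohort that is freshly simulated for each
#' resample, runs every method on the same subsample, and scores the F
#' measure of the biomarker's calls at each method's native threshold. The
#' per-scenario summary is the bootstrap-aggregated mean.
#'
#' @param scenarios data.frame with columns `mu_protrude` and `pos_fraction`.
#' @param sizes subsample sizes, default `c(10, 20, 40, 60, 80, 100)`.
#' @param n_resamples resamples per (scenario, size), default 100.
#' @param methods character vector of method specs: `"oppti:k=<int>"`,
#'   `"iqr"`, `"zscore"`.
#' @param seed integer master seed; per-resample child seeds are derived from
#'   it so all methods see identical data.
#' @param n_genes,n_samples simulated cohort dimensions, defaults 1000 x 100.
#' @param protrude_sd SD of the protruding noise, default 1.6.
#' @param iqr_multiplier cutoff for the IQR comparator, default 1.5.
#' @param z_cut cutoff for the standard-score comparator, default 2.
#' @return An object of class `benchmark_result`: a data.frame with one row
#'   per (scenario, size, method) and columns `mu_protrude`, `pos_fraction`,
#'   `size`, `method`, `mean_f`, `mean_precision`, `mean_recall`,
#'   `mean_selectivity`, `n_resamples`, `n_failed`; the per-resample F values
#'   are in the `details` attribute.
#' @export
run_benchmark <- function(scenarios = data.frame(mu_protrude = 5, pos_fraction = 0.2),
                          sizes = c(10L, 20L, 40L, 60L, 80L, 100L),
                          n_resamples = 100L,
                          methods = c("oppti:k=4", "oppti:k=1", "iqr", "zscore"),
                          seed = 0L,
                          n_genes = 1000L, n_samples = 100L,
                          protrude_sd = 1.6,
                          iqr_multiplier = 1.5, z_cut = 2) {
  stopifnot(is.data.frame(scenarios),
            all(c("mu_protrude", "pos_fraction") %in% names(scenarios)),
            n_resamples >= 1L)
  parsed <- lapply(methods, parse_method)
  n_cells <- nrow(scenarios) * length(sizes) * n_resamples
  seeds <- derive_seeds(seed, 2L * n_cells)
  summary_rows <- list()
  details <- list()
  cell <- 0L
  for (sc in seq_len(nrow(scenarios))) {
    mu <- scenarios$mu_protrude[sc]
    pf <- scenarios$pos_fraction[sc]
    for (size in sizes) {
      fmat <- matrix(NA_real_, n_resamples, length(methods),
                     dimnames = list(NULL, methods))
      pmat <- rmat <- smat <- fmat
      for (r in seq_len(n_resamples)) {
        cell <- cell + 1L
        sim <- simulate_cohort(n_genes = n_genes, n_samples = n_samples,
                               mu_protrude = mu, pos_fraction = pf,
                               protrude_sd = protrude_sd,
                               seed = seeds[2L * cell - 1L])
        sub <- balanced_undersample(sim, size, seed = seeds[2L * cell])
        for (mi in seq_along(parsed)) {
          ev <- tryCatch(
            evaluate_calls(
              run_method_calls(parsed[[mi]], sub$matrix, sim$biomarker_id,
                               iqr_multiplier, z_cut),
              sub$labels),
            error = function(e) NULL)
          if (!is.null(ev)) {
            fmat[r, mi] <- ev[["f"]]
            pmat[r, mi] <- ev[["precision"]]
            rmat[r, mi] <- ev[["recall"]]
            smat[r, mi] <- ev[["selectivity"]]
          }
        }
      }
      for (mi in seq_along(methods)) {
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          mu_protrude = mu, pos_fraction = pf, size = size,
          method = methods[mi],
          mean_f = mean(fmat[, mi], na.rm = TRUE),
          mean_precision = mean(pmat[, mi], na.rm = TRUE),
          mean_recall = mean(rmat[, mi], na.rm = TRUE),
          mean_selectivity = mean(smat[, mi], na.rm = TRUE),
          n_resamples = sum(!is.na(fmat[, mi])),
          n_failed = sum(is.na(fmat[, mi])),
          stringsAsFactors = FALSE)
      }
      details[[sprintf("mu%g_pf%g_n%d", mu, pf, size)]] <- fmat
    }
  }
  out <- do.call(rbind, summary_rows)
  attr(out, "details") <- details
  class(out) <- c("benchmark_result", class(out))
  out
}

# Balanced undersampling with replacement: resample positives and negatives
# separately so the subsample keeps round(pos_fraction * size) positives.
balanced_undersample <- function(sim, size, seed) {
  with_seed(seed, {
    pos <- which(sim$labels)
    neg <- which(!sim$labels)
    n_pos <- round(sim$pos_fraction * size)
    n_neg <- size - n_pos
    take <- c(if (n_pos > 0) sample(pos, n_pos, replace = TRUE),
              if (n_neg > 0) sample(neg, n_neg, replace = TRUE))
    mat <- sim$matrix[, take, drop = FALSE]
    colnames(mat) <- make.unique(colnames(mat), sep = "_r")
    labels <- stats::setNames(sim$labels[take], colnames(mat))
    list(matrix = mat, labels = labels)
  })
}
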