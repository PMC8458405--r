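#' Permutation significance of per-marker overexpression enrichment
#'
#' Assesses whether a marker is called overexpressed in more samples than
#' expected by chance. Each iteration shuffles every sample's dysregulation
#' scores across markers (the threshold tau is held fixed) and records the
#' resulting per-marker overexpression counts; the counts from all
#' `iterations_per_sample * n_samples` iterations and all markers are pooled
#' into one empirical null. The p-value of a marker with observed count x is
#' the fraction of pooled null counts strictly greater than x, floored at
#' 1 / pool size, and BH-adjusted across markers.
#'
#' Because the shuffle permutes each sample's score multiset, the total call
#' count per iteration equals the observed total exactly.
#'
#' @param result an `oppti_result`, or any list with a `scores` matrix and a
#'   scalar `threshold`.
#' @param iterations_per_sample iterations per cohort sample (default 100,
#'   giving N = 100 x n_samples total iterations).
#' @param seed integer seed for the shuffles.
#' @return A data.frame with columns `marker`, `observed_count`, `rate`,
#'   `p_value`, `fdr`; attributes `n_iterations`, `pool_size`,
#'   `null_distribution` (frequency of null counts 0, 1, ...), and
#'   `excluded` (markers with all-missing scores, reported separately).
#' @export
permutation_pvalues <- function(result, iterations_per_sample = 100L, seed = 0L) {
  scores <- result$scores
  tau <- result$threshold
  if (is.null(tau) || is.na(tau)) stop("threshold is missing", call. = FALSE)
  stopifnot(is.matrix(scores), iterations_per_sample >= 1L)
  n <- ncol(scores)
  p <- nrow(scores)
  calls <- !is.na(scores) & scores > tau
  excluded <- rownames(scores)[rowSums(!is.na(scores)) == 0L]
  n_iter <- as.integer(iterations_per_sample) * n
  per_sample <- colSums(calls)
  active <- which(per_sample > 0L)
  # Shuffling a sample's scores across the p markers sends its calls to a
  # uniform random subset of marker positions; only those subsets matter.
  dist <- numeric(n + 1L)  # frequency of null counts 0..n over all markers
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      if (length(active)) {
        idx <- unlist(lapply(per_sample[active],
                             function(cs) sample.int(p, cs)),
                      use.names = FALSE)
        counts <- tabulate(idx, p)
      } else {
        counts <- integer(p)
      }
      tb <- tabulate(counts + 1L, n + 1L)
      dist <- dist + tb
    }
  })
  pool_size <- n_iter * p
  # gt[c + 1] = number of pooled null counts strictly greater than c
  gt <- rev(cumsum(rev(dist)))
  gt <- c(gt[-1L], 0)
  obs <- rowSums(calls)
  pvals <- pmax(gt[obs + 1L] / pool_size, 1 / pool_size)
  keep <- !(rownames(scores) %in% excluded)
  out <- data.frame(marker = rownames(scores)[keep],
                    observed_count = obs[keep],
                    rate = obs[keep] / n,
                    p_value = pvals[keep],
                    fdr = bh_fdr(pvals[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_iterations") <- n_iter
  attr(out, "pool_size") <- pool_size
  attr(out, "null_distribution") <- dist
  attr(out, "excluded") <- excluded
  if (length(excluded)) {
    message("excluded ", length(excluded), " marker(s) with all-missing scores")
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Standard BH step-up adjustment (via [stats::p.adjust()]) preserving input
#' order; `NA` p-values are excluded from the adjustment and returned as `NA`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

check_rate_table <- function(rates, arg = "rates") {
  if (!is.matrix(rates) || !is.numeric(rates)) {
    stop("`", arg, "` must be a numeric markers x cohorts matrix", call. = FALSE)
  }
  v <- rates[!is.na(rates)]
  if (any(v < 0 | v > 1)) {
    stop("`", arg, "` entries must be rates in [0, 1]", call. = FALSE)
  }
  invisible(rates)
}

#' Flag markers with pan-cancer overexpression
#'
#' A marker is pan-cancer when its overexpression rate strictly exceeds
#' `min_rate` in at least `min_cohorts` cohorts (over 10 percent of cases in
#' at least five cohorts by default).
#'
#' @param rates markers x cohorts matrix of rates in `[0, 1]`.
#' @param min_rate strict lower bound on the rate, default 0.10.
#' @param min_cohorts minimum number of qualifying cohorts, default 5.
#' @return Named logical vector over markers.
#' @export
classify_pan_cancer <- function(rates, min_rate = 0.10, min_cohorts = 5L) {
  check_rate_table(rates)
  rowSums(rates > min_rate, na.rm = TRUE) >= min_cohorts
}

#' Flag cancer-specific overexpression
#'
#' A (marker, cohort) pair is cancer-specific when the rate strictly exceeds
#' `min_rate` and is at least `fold` times the mean rate across all other
#' cohorts.
#'
#' @param rates markers x cohorts matrix of rates.
#' @param min_rate strict lower bound on the rate, default 0.10.
#' @param fold required fold over the other cohorts' mean, default 2.
#' @return Logical matrix, same shape as `rates`.
#' @export
classify_cancer_specific <- function(rates, min_rate = 0.10, fold = 2) {
  check_rate_table(rates)
  if (ncol(rates) < 2L) {
    stop("cancer-specific classification needs at least 2 cohorts", call. = FALSE)
  }
  flags <- matrix(FALSE, nrow(rates), ncol(rates), dimnames = dimnames(rates))
  for (j in seq_len(ncol(rates))) {
    other_mean <- rowMeans(rates[, -j, drop = FALSE], na.rm = TRUE)
    r <- rates[, j]
    flags[, j] <- !is.na(r) & !is.na(other_mean) &
      r > min_rate & r >= fold * other_mean
  }
  flags
}

#' Flag markers whose protein rate dwarfs another data level's rate
#'
#' Compares protein overexpression rates against rates at another level
#' (DNA alteration or mRNA overexpression): a pair is flagged when the
#' protein rate is at least `min_protein_rate` and at least `fold` times the
#' other level's rate. A zero other-level rate flags whenever the protein
#' rate clears the floor.
#'
#' @param protein_rates markers x cohorts matrix of protein overexpression
#'   rates.
#' @param other_rates matching matrix of rates at the other level.
#' @param min_protein_rate inclusive floor on the protein rate, default 0.10.
#' @param fold required fold over the other level, default 3.
#' @return Logical matrix, same shape as the inputs.
#' @export
fold_comparison <- function(protein_rates, other_rates,
                            min_protein_rate = 0.10, fold = 3) {
  check_rate_table(protein_rates, "protein_rates")
  check_rate_table(other_rates, "other_rates")
  if (!identical(dim(protein_rates), dim(other_rates)) ||
      !identical(dimnames(protein_rates), dimnames(other_rates))) {
    stop("protein and other rate tables must share marker/cohort axes",
         call. = FALSE)
  }
  !is.na(protein_rates) & !is.na(other_rates) &
    protein_rates >= min_protein_rate & protein_rates >= fold * other_rates
}
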