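#' Pathway upregulation score for one sample
#'
#' One-sided two-sample Kolmogorov-Smirnov test asking whether the sample's
#' pathway-member values are stochastically greater than its non-member
#' values; the activity score is -log(p) (natural log). At least 3 non-missing
#' values are required on each side. The p-value is computed exactly when
#' both sides have at most `exact_max` values, asymptotically otherwise.
#'
#' @param sample_values named numeric vector of one sample's values over all
#'   markers.
#' @param members character vector of pathway member marker IDs.
#' @param exact_max exact-p size switch, default 25 per side.
#' @return A list with `ks_p` and `score`; both `NA` (with a `reason`) when
#'   either side has fewer than 3 values.
#' @export
pathway_score <- function(sample_values, members, exact_max = 25L) {
  stopifnot(!is.null(names(sample_values)))
  is_member <- names(sample_values) %in% members
  mv <- sample_values[is_member]
  ov <- sample_values[!is_member]
  mv <- mv[!is.na(mv)]
  ov <- ov[!is.na(ov)]
  if (length(mv) < 3L || length(ov) < 3L) {
    return(list(ks_p = NA_real_, score = NA_real_,
                reason = "fewer than 3 non-missing values on one side"))
  }
  exact <- length(mv) <= exact_max && length(ov) <= exact_max
  # alternative = "less": the member CDF lies below the non-member CDF,
  # i.e. member values are stochastically greater (upregulation).
  p <- suppressWarnings(
    ks.test(mv, ov, alternative = "less", exact = exact)$p.value)
  list(ks_p = p, score = -log(p), reason = NA_character_)
}

#' Per-sample pathway activity across a cohort
#'
#' Applies [pathway_score()] to every (sample, pathway) pair. A sample is
#' active for a pathway when its score reaches -log(0.05), i.e. p <= 0.05
#' (boundary inclusive); the cohort fraction is the mean of the active flags
#' over samples with a computable score. Pathways with fewer than
#' `min_members` members present in the matrix are skipped with a warning.
#'
#' @param m expression matrix (markers x samples).
#' @param sets named list of pathway member ID vectors, e.g. from
#'   [read_gene_sets()].
#' @param min_members minimum members present in the matrix, default 3.
#' @return An object of class `pathway_activity`: `activity` (long
#'   data.frame: sample, pathway, ks_p, score, active), `fractions`
#'   (data.frame: pathway, cohort_fraction, n_samples), and `skipped`.
#' @export
cohort_pathway_fractions <- function(m, sets, min_members = 3L) {
  check_expression_matrix(m)
  stopifnot(is.list(sets), !is.null(names(sets)))
  present <- lapply(sets, intersect, rownames(m))
  skipped <- names(sets)[lengths(present) < min_members]
  if (length(skipped)) {
    warning("skipping pathway(s) with < ", min_members,
            " members present: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  keep <- setdiff(names(sets), skipped)
  rows <- vector("list", length(keep) * ncol(m))
  r <- 0L
  for (pw in keep) {
    for (s in seq_len(ncol(m))) {
      ps <- pathway_score(m[, s], present[[pw]])
      r <- r + 1L
      rows[[r]] <- data.frame(sample = colnames(m)[s], pathway = pw,
                              ks_p = ps$ks_p, score = ps$score,
                              active = !is.na(ps$ks_p) & ps$ks_p <= 0.05,
                              stringsAsFactors = FALSE)
    }
  }
  activity <- do.call(rbind, rows[seq_len(r)])
  if (is.null(activity)) {
    activity <- data.frame(sample = character(0), pathway = character(0),
                           ks_p = numeric(0), score = numeric(0),
                           active = logical(0))
  }
  fractions <- do.call(rbind, lapply(keep, function(pw) {
    a <- activity[activity$pathway == pw & !is.na(activity$ks_p), ]
    data.frame(pathway = pw,
               cohort_fraction = if (nrow(a)) mean(a$active) else NA_real_,
               n_samples = nrow(a), stringsAsFactors = FALSE)
  }))
  if (is.null(fractions)) {
    fractions <- data.frame(pathway = character(0), cohort_fraction = numeric(0),
                            n_samples = integer(0))
  }
  structure(list(activity = activity, fractions = fractions, skipped = skipped),
            class = "pathway_activity")
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat("pathway_activity:", length(unique(x$activity$pathway)), "pathways x",
      length(unique(x$activity$sample)), "samples\n")
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' Correlate markers with pathway activity scores
#'
#' Pearson correlation (two-sided t-test) between each marker's per-sample
#' values and each pathway's per-sample activity scores, BH-adjusted across
#' all tested (marker, pathway) pairs. Pairs with fewer than `min_pairs`
#' complete observations or zero variance on either side get `NA` statistics
#' and are excluded from the adjustment.
#'
#' @param marker_values markers x samples matrix (expression, dysregulation
#'   scores, or phosphosite values).
#' @param pathway_scores pathways x samples matrix of activity scores sharing
#'   the sample axis.
#' @param min_pairs minimum complete pairs, default 10.
#' @return data.frame with columns `marker`, `pathway`, `n`, `r`, `p`, `q`,
#'   `significant` (q < 0.05 and r > 0) and `suggestive` (q < 0.15 and r > 0).
#' @export
marker_pathway_correlation <- function(marker_values, pathway_scores,
                                       min_pairs = 10L) {
  stopifnot(is.matrix(marker_values), is.matrix(pathway_scores))
  shared <- intersect(colnames(marker_values), colnames(pathway_scores))
  if (length(shared) < min_pairs) {
    stop("fewer than ", min_pairs, " shared samples between markers and ",
         "pathway scores", call. = FALSE)
  }
  mv <- marker_values[, shared, drop = FALSE]
  ps <- pathway_scores[, shared, drop = FALSE]
  grid <- expand.grid(marker = rownames(mv), pathway = rownames(ps),
                      stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(grid)), function(i) {
    x <- mv[grid$marker[i], ]
    y <- ps[grid$pathway[i], ]
    complete <- !is.na(x) & !is.na(y)
    n <- sum(complete)
    if (n < min_pairs || var(x[complete]) == 0 || var(y[complete]) == 0) {
      return(c(n = n, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x[complete], y[complete], method = "pearson")
    c(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  stats <- do.call(rbind, stats)
  out <- data.frame(grid, stats, row.names = NULL)
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < 0.05 & out$r > 0
  out$suggestive <- !is.na(out$q) & out$q < 0.15 & out$r > 0
  out
}
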