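#' Read a tab-separated expression matrix
#'
#' Reads a markers-by-samples table of log-scale relative abundances. The
#' first column holds marker IDs, the header row holds sample IDs. Cells that
#' are empty or match one of `missing_tokens` become `NA`; any other
#' non-numeric cell is a parse error naming its row and column.
#'
#' @param path path to a tab-separated file.
#' @param missing_tokens character tokens treated as missing values.
#' @param source_level what the rows quantify: `"protein"`, `"phosphosite"`,
#'   or `"mrna"`. Stored as an attribute; it does not change parsing.
#' @return A numeric matrix with marker rownames, sample colnames, `NA` for
#'   missing entries, and a `source_level` attribute.
#' @export
read_expression_matrix <- function(path,
                                   missing_tokens = c("NA", "NaN", ""),
                                   source_level = c("protein", "phosphosite", "mrna")) {
  source_level <- match.arg(source_level)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "",
                    comment.char = "")
  if (ncol(dat) < 2L) {
    stop("malformed header in ", path,
         ": expected a marker-ID column followed by sample columns", call. = FALSE)
  }
  ids <- dat[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate marker IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(dat)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in header of ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(dat[, -1L, drop = FALSE])
  miss <- matrix(raw %in% missing_tokens, nrow = nrow(raw))
  num <- suppressWarnings(as.numeric(raw))
  bad <- (is.na(num) | is.infinite(num)) & !miss
  if (any(bad)) {
    i <- which(bad)[1L]
    r <- (i - 1L) %% nrow(raw) + 1L
    c <- (i - 1L) %/% nrow(raw) + 1L
    stop("non-numeric cell \"", raw[r, c], "\" at marker ", ids[r],
         ", sample ", samples[c], " in ", path, call. = FALSE)
  }
  m <- matrix(num, nrow = nrow(raw), dimnames = list(ids, samples))
  m[miss] <- NA_real_
  attr(m, "source_level") <- source_level
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: marker IDs in the first column
#' (header `ID`), samples across, missing entries written as `NA`.
#'
#' @param m numeric matrix with marker rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  check_expression_matrix(m)
  ch <- matrix(sprintf("%.17g", m), nrow(m))  # full precision: exact round trip
  ch[is.na(m)] <- "NA"
  dimnames(ch) <- dimnames(m)
  out <- data.frame(ID = rownames(m), ch, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Drop markers with too many missing values
#'
#' Removes markers whose fraction of missing samples is at least
#' `max_missing_fraction` (markers with high fractions, at least 20 percent
#' by default, of missing values are filtered out). Marker order and the
#' sample set are preserved.
#'
#' @param m expression matrix.
#' @param max_missing_fraction markers with missing fraction `>=` this cutoff
#'   are dropped; default 0.20.
#' @return The filtered matrix.
#' @export
filter_missing <- function(m, max_missing_fraction = 0.20) {
  check_expression_matrix(m)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(m))
  keep <- frac < max_missing_fraction
  if (!any(keep)) {
    stop("no markers survive the missingness filter at cutoff ",
         max_missing_fraction, "; consider relaxing the threshold", call. = FALSE)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "source_level") <- attr(m, "source_level")
  out
}

#' Normalize every sample to unit median absolute deviation
#'
#' Divides each sample (column) by its raw MAD — the median of absolute
#' deviations from the column median, with no consistency constant — so every
#' sample ends with MAD exactly 1. Values are rescaled only; columns are not
#' centered. Missing entries stay missing.
#'
#' @param m expression matrix.
#' @return The rescaled matrix.
#' @export
mad_normalize <- function(m) {
  check_expression_matrix(m)
  mads <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[!is.na(v)]
    if (length(unique(v)) < 2L) {
      stop("sample ", colnames(m)[j],
           " has fewer than 2 distinct non-missing values", call. = FALSE)
    }
    median(abs(v - median(v)))
  }, numeric(1))
  zero <- mads == 0
  if (any(zero)) {
    stop("degenerate sample(s) with MAD == 0: ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  out <- sweep(m, 2L, mads, "/")
  attr(out, "source_level") <- attr(m, "source_level")
  out
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are dropped with a warning; duplicate set names are
#' an error.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors (one per set) with a
#'   `description` attribute holding the per-set description strings.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT parse error in ", path, ": line ", which(short)[1L],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate members deduplicated in set(s): ",
            paste(nms[dup], collapse = ", "), call. = FALSE)
    sets <- lapply(sets, unique)
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "description") <- desc
  sets
}

#' Read a plain-text marker list
#'
#' One marker ID per line; blank lines are skipped and duplicates dropped.
#'
#' @param path path to a text file.
#' @return Character vector of unique marker IDs.
#' @export
read_marker_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
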