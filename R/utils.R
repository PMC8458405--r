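#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic child seeds (kept below .Machine$integer.max) derived from one
# parent seed; used so every stochastic stage draws from its own stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Validate an expression matrix: numeric matrix, unique row/column names,
# entries finite or NA.
check_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`", arg, "` must be a numeric matrix (markers x samples)", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("`", arg, "` must have marker rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate marker IDs in `", arg, "`: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample IDs in `", arg, "`: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.infinite(m))) {
    stop("`", arg, "` contains non-finite values; entries must be finite or NA",
         call. = FALSE)
  }
  invisible(m)
}
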