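# Fixtures are built in code; no data files.

named_matrix <- function(p, n, data, prefix = "g") {
  matrix(data, p, n, dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                                     sprintf("s%03d", seq_len(n))))
}

# i.i.d. Gaussian cohort with per-marker means (no co-expression).
iid_cohort <- function(p, n, seed = 1) {
  with_seed(seed, {
    named_matrix(p, n, rnorm(p) + rnorm(p * n))
  })
}

# Co-expressed cohort: one latent factor per block drives all markers, so
# neighbor inference genuinely tracks each marker's observed values.
factor_cohort <- function(p, n, seed = 1, n_factors = 4, noise_sd = 0.4) {
  with_seed(seed, {
    z <- matrix(rnorm(n_factors * n), n_factors, n)
    load <- matrix(0, p, n_factors)
    block <- rep_len(seq_len(n_factors), p)
    load[cbind(seq_len(p), block)] <- runif(p, 0.7, 1.3)
    named_matrix(p, n, load %*% z + rnorm(p * n, sd = noise_sd))
  })
}

# Independent brute-force type-7 quantile (linear interpolation between
# order statistics), used as the quartile oracle.
bf_quantile <- function(v, prob) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

# Independent reference BH step-up used as the FDR oracle.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
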