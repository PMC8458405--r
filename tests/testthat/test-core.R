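test_that("trim_high_outliers masks values 1.5 IQR above Q3 and leaves the input intact", {
  m <- named_matrix(3, 5, c(0, 1, 2,  0, 1, 2,  0, 1, 2,  0, 1, 2,  10, 1, 2))
  # row 1 is [0,0,0,0,10]: Q3 = 0, IQR = 0, cutoff 0; 10 is masked
  out <- trim_high_outliers(m)
  expect_true(is.na(out[1, 5]))
  expect_equal(sum(is.na(out)), 1L)
  expect_equal(m[1, 5], 10)  # original untouched
  # constant row: nothing masked (must also strictly exceed Q3)
  expect_false(anyNA(out[2, ]))
  # row with nothing above its cutoff comes back unchanged
  expect_equal(out[3, ], m[3, ])

  short <- named_matrix(2, 5, c(1, 1, 2, 2, 3, 3, 4, NA, 100, NA))
  expect_warning(out2 <- trim_high_outliers(short), "untrimmed")
  expect_equal(out2[2, ], short[2, ])  # only 3 non-missing: passed through
  expect_true(is.na(out2[1, 5]))       # full row still trimmed
})

test_that("trimming masks exactly the values flagged by a brute-force quartile oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    v <- round(rnorm(n, sd = sample(1:3, 1)), 2)  # rounding creates ties
    m <- named_matrix(1, n, v)
    out <- suppressWarnings(trim_high_outliers(m))
    q1 <- bf_quantile(v, 0.25); q3 <- bf_quantile(v, 0.75)
    expected <- v >= q3 + 1.5 * (q3 - q1) & v > q3
    expect_identical(unname(is.na(out[1, ])), expected)
  }
})

test_that("neighbor selection ranks by signed correlation with stable ties", {
  n <- 40
  base <- factor_cohort(1, n, seed = 5)
  t0 <- base[1, ]
  mk <- function(r_target, seed) {
    # construct a vector with roughly the requested correlation to t0
    with_seed(seed, r_target * scale(t0)[, 1] +
                sqrt(max(0, 1 - r_target^2)) * rnorm(n))
  }
  m <- rbind(target = t0, n1 = mk(0.9, 1), n2 = mk(0.5, 2),
             n3 = mk(-0.8, 3), n4 = mk(0.1, 4))
  colnames(m) <- sprintf("s%03d", 1:n)
  model <- build_neighbor_model(m, oppti_config(k = 2, min_pairwise_overlap = 5),
                                targets = "target")
  # oracle: rank the empirical signed correlations directly
  r <- cor(t0, t(m[-1, ]))[1, ]
  expect_identical(model$neighbors$target, names(sort(-r))[1:2])
  expect_equal(model$weights$target, unname(sort(r, decreasing = TRUE)[1:2]^2),
               tolerance = 1e-10)

  # an exact duplicate ranks first with weight 1
  m2 <- rbind(m, dup = t0)
  model2 <- build_neighbor_model(m2, oppti_config(k = 2, min_pairwise_overlap = 5),
                                 targets = "target")
  expect_identical(model2$neighbors$target[1], "dup")
  expect_equal(model2$weights$target[1], 1, tolerance = 1e-12)

  # exact ties (identical neighbor rows) broken by marker input order
  m3 <- rbind(target = t0, a = 2 * t0, b = 2 * t0, c = -t0)
  colnames(m3) <- colnames(m)
  model3 <- build_neighbor_model(m3, oppti_config(k = 2, min_pairwise_overlap = 5),
                                 targets = "target")
  expect_identical(model3$neighbors$target, c("a", "b"))
})

test_that("pairwise correlations match cor(use = 'pairwise.complete.obs')", {
  m <- iid_cohort(40, 25, seed = 8)
  m[sample(length(m), 150)] <- NA
  pc <- oppti:::pairwise_cor(m)
  ref <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  expect_equal(pc$r, ref, tolerance = 1e-12)
  expect_identical(is.na(pc$r), is.na(ref))
})

test_that("background inference is the weight-renormalized neighbor average", {
  m <- named_matrix(3, 3, c(2, 4, 9,   2, 4, 9,   2, NA, 9), prefix = "g")
  model <- structure(list(
    neighbors = list(g003 = c("g001", "g002")),
    weights = list(g003 = c(0.81, 0.09)),
    usable = c(g003 = TRUE), reason = c(g003 = ""), k = 2L),
    class = "oppti_neighbor_model")
  inf <- infer_background(m, model)
  expect_equal(inf["g003", 1], (2 * 0.81 + 4 * 0.09) / 0.90)  # 2.2
  expect_equal(inf["g003", 2], (2 * 0.81 + 4 * 0.09) / 0.90)
  # one neighbor missing in sample 3: renormalize onto the other
  expect_equal(inf["g003", 3], 2)

  # k = 1 with a perfect duplicate reproduces the neighbor exactly
  m2 <- rbind(m, g004 = m["g001", ])
  model2 <- structure(list(
    neighbors = list(g004 = "g001"), weights = list(g004 = 1),
    usable = c(g004 = TRUE), reason = c(g004 = ""), k = 1L),
    class = "oppti_neighbor_model")
  expect_equal(infer_background(m2, model2)["g004", ], m2["g001", ])
})

test_that("deviation scores are signed perpendicular distances to the OLS line", {
  # observed == inferred: line y = x, all scores zero
  v <- c(0, 1, 2, 3, 4)
  ds <- deviation_scores(v, v)
  expect_equal(unname(ds$scores), rep(0, 5))

  obs <- c(0.1, 0.9, 2.0, 3.1, 8.0)
  inf <- c(0, 1, 2, 3, 4)
  ds2 <- deviation_scores(obs, inf)
  # brute-force oracle: lm fit + point-to-line distance formula
  fit <- lm(obs ~ inf)
  a <- coef(fit)[[2]]; b <- -1; cc <- coef(fit)[[1]]
  d <- (a * inf + b * obs + cc) / sqrt(a^2 + b^2)
  signed <- abs(d) * sign(obs - (a * inf + cc))
  expect_equal(unname(ds2$scores), unname(signed), tolerance = 1e-12)
  expect_equal(which.max(ds2$scores), 5L)
  expect_gt(ds2$scores[5], 0)

  # translation invariance and scale equivariance
  ds3 <- deviation_scores(obs + 7, inf)
  expect_equal(ds3$scores, ds2$scores, tolerance = 1e-12)
  ds4 <- deviation_scores(3 * obs, 3 * inf)
  expect_equal(ds4$scores, 3 * ds2$scores, tolerance = 1e-12)

  # missingness propagates; < 3 complete pairs disables the marker
  ds5 <- deviation_scores(c(obs, NA), c(inf, 2))
  expect_true(is.na(ds5$scores[6]))
  ds6 <- deviation_scores(c(1, 2, NA), c(1, 2, 3))
  expect_false(ds6$ok)
  expect_true(all(is.na(ds6$scores)))

  # zero-variance inferred vector falls back to median-centered residuals
  expect_warning(ds7 <- deviation_scores(v, rep(1, 5)), "zero variance")
  expect_equal(unname(ds7$scores), v - median(v))
})

test_that("background selection excludes shifted markers and sets the 95th-percentile tau", {
  # all markers perfectly inferred: tau is the 95th percentile of the scores
  m <- iid_cohort(100, 100, seed = 2)
  scores <- with_seed(7, named_matrix(100, 100, rnorm(10000)))
  bg <- background_threshold(m, m, scores, oppti_config())
  expect_setequal(bg$background_markers, rownames(m))
  expect_equal(bg$threshold, quantile(scores, 0.95, type = 7, names = FALSE))
  expect_equal(bg$threshold, qnorm(0.95), tolerance = 0.05)  # ~1.645
  expect_lte(mean(scores > bg$threshold), 0.05)

  # a marker whose observations sit +5 above its inference is excluded
  inferred <- m
  m_shift <- m
  m_shift[1, ] <- m[1, ] + 5
  bg2 <- background_threshold(m_shift, inferred, scores, oppti_config())
  expect_false(rownames(m)[1] %in% bg2$background_markers)

  # empty background is a hard error
  m_all <- m + 5
  expect_error(background_threshold(m_all, m, scores, oppti_config()),
               "no background markers")
})

test_that("a fully duplicated cohort yields zero scores and zero calls at k = 1", {
  half <- factor_cohort(25, 30, seed = 6)
  m <- rbind(half, `rownames<-`(half, paste0(rownames(half), "_copy")))
  res <- oppti_detect(m, oppti_config(k = 1, min_pairwise_overlap = 5))
  expect_equal(max(abs(res$scores), na.rm = TRUE), 0)
  expect_equal(sum(res$calls), 0L)
})

test_that("detect recovers a marker protruded in a subset of samples", {
  sim <- simulate_cohort(n_genes = 300, n_samples = 60, mu_protrude = 5,
                         pos_fraction = 0.2, seed = 13)
  m <- mad_normalize(sim$matrix)
  res <- oppti_detect(m, oppti_config(k = 4))
  ev <- evaluate_calls(res$calls[sim$biomarker_id, ], sim$labels)
  expect_gt(ev[["f"]], 0.8)
  # calls are exactly scores > tau, and missing scores are never calls
  expect_identical(res$calls,
                   !is.na(res$scores) & res$scores > res$threshold)
  # determinism
  res2 <- oppti_detect(m, oppti_config(k = 4))
  expect_identical(res$scores, res2$scores)
})

test_that("per-marker scores are invariant to shifting one marker's observations", {
  m <- factor_cohort(30, 40, seed = 21)
  res <- oppti_detect(m, oppti_config(k = 3, min_pairwise_overlap = 5))
  m2 <- m
  m2["g001", ] <- m2["g001", ] + 100
  # neighbors of g001 are unchanged (correlation is shift-invariant), and the
  # line's intercept absorbs the shift, so g001's scores are unchanged
  res2 <- oppti_detect(m2, oppti_config(k = 3, min_pairwise_overlap = 5))
  expect_equal(res2$scores["g001", ], res$scores["g001", ], tolerance = 1e-8)
})
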