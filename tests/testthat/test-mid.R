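test_that("pooled MID averages normalized vectors and reports dispersion", {
  p <- pooled_mid(list(c(0.9, 0.1), c(0.8, 0.2)))
  expect_equal(p$mean, c(0.85, 0.15))
  expect_equal(p$sd, c(0.0707, 0.0707), tolerance = 1e-3)

  single <- pooled_mid(list(c(1, 0)))
  expect_equal(single$mean, c(1, 0))
  expect_equal(single$sd, c(0, 0))

  expect_error(pooled_mid(list(c(0.5, 0.5), c(0.3, 0.3, 0.4))), "length")
})

test_that("correction matrix is the shifted-kernel lower triangle", {
  expect_equal(correction_matrix(c(1, 0, 0)), diag(3))
  expect_equal(correction_matrix(c(0.9, 0.1)),
               matrix(c(0.9, 0.1, 0, 0.9), 2, 2))
  C <- correction_matrix(c(0.5, 0.3, 0.2))
  expect_equal(C[, 3], c(0, 0, 0.5))     # truncated column, no renormalization
  expect_equal(C[, 1], c(0.5, 0.3, 0.2))
})

test_that("correcting an MID against itself returns the unit vector", {
  set.seed(19)
  for (i in 1:50) {
    u <- r_simplex(sample(2:8, 1))
    res <- correct_mid(u, u)
    e0 <- c(1, rep(0, length(u) - 1))
    expect_lt(max(abs(res$corrected - e0)), 1e-8)
    expect_lt(res$residual, 1e-8)
  }
})

test_that("deconvolution inverts a hand-built forward convolution", {
  f_true <- c(0.6, 0, 0.4)
  u <- c(0.9, 0.1, 0)
  m <- oracle_convolve(f_true, u)[1:3]
  m <- m / sum(m)
  res <- correct_mid(m, u)
  expect_lt(max(abs(res$corrected - f_true)), 1e-8)
  expect_lt(res$residual, 1e-8)

  # unequal lengths are zero-padded to the longer
  res2 <- correct_mid(c(0.7, 0.3), c(0.85, 0.1, 0.05))
  expect_length(res2$corrected, 3)
  expect_equal(sum(res2$corrected), 1, tolerance = 1e-12)
})

test_that("random convolutions are recovered when no tail mass is lost", {
  set.seed(29)
  for (i in 1:40) {
    Lf <- sample(2:4, 1); Lu <- sample(2:4, 1)
    f <- r_simplex(Lf); u <- r_simplex(Lu)
    full <- oracle_convolve(f, u)
    L <- Lf + Lu - 1L
    m <- full[1:L]                     # no truncation: full length retained
    res <- correct_mid(m / sum(m), c(u, rep(0, L - Lu)))
    expect_lt(max(abs(res$corrected - c(f, rep(0, L - Lf)))), 1e-6)
  }
})

test_that("corrected vectors stay on the probability simplex", {
  set.seed(31)
  for (i in 1:30) {
    L <- sample(2:6, 1)
    res <- correct_mid(r_simplex(L), r_simplex(L))
    expect_true(all(res$corrected >= 0))
    expect_equal(sum(res$corrected), 1, tolerance = 1e-9)
  }
})

test_that("MID estimation recovers a known label distribution under noise", {
  f_true <- c(0.5, 0.2, 0.3)
  cpd <- sim_compound("test", "C4H6O4", rt = 100, base_abundance = 1e6,
                      true_label_dist = f_true)
  cfg <- sim_config(list(cpd), n_replicates = 3, intensity_cv = 0.05,
                    mz_jitter_ppm = 1, rt_jitter_s = 0.5, seed = 101)
  sim <- simulate_experiment(cfg)
  params <- detection_params(ppm_tol = 5, rt_window = 10, n_max = 5)
  g <- detect_groups(sim$features, sim$samples, tracer_def("13C"), params, "A")
  est <- estimate_mids(g, sim$features, sim$samples)
  expect_length(est, 1)
  e <- est[[1]]
  expect_lt(max(abs(e$corrected[1:3] - f_true)), 0.05)
  expect_equal(e$enrichment, 1 - e$corrected[1], tolerance = 1e-12)
  expect_gt(e$quantification, 0)
  expect_equal(e$n_labeled_used, 3)
})

test_that("a condition with no labeling shows near-zero enrichment", {
  cpd <- sim_compound("null", "C6H12O6", rt = 100, base_abundance = 1e6,
                      true_label_dist = 1)   # no tracer incorporation
  cfg <- sim_config(list(cpd), n_replicates = 3, intensity_cv = 0.05,
                    mz_jitter_ppm = 1, seed = 7)
  sim <- simulate_experiment(cfg)
  # force-build the group (detection would rightly reject it) and estimate
  cf <- sim$truth$compound_features
  g <- data.frame(group_id = "G1", base_feature_id = cf$feature_id[cf$n == 0],
                  condition = "A", n = cf$n, feature_id = cf$feature_id,
                  mz = cf$mz_theoretical, rt = 100, p_value = NA_real_,
                  stringsAsFactors = FALSE)
  est <- estimate_mids(g, sim$features, sim$samples)
  expect_lte(est[[1]]$enrichment, 0.02)
})

test_that("single-member groups degenerate to M0 = 1", {
  ft <- feature_table(data.frame(feature_id = "B", mz = 200, rt = 100,
                                 L1 = 10, L2 = 12, U1 = 9, U2 = 11,
                                 stringsAsFactors = FALSE))
  ss <- sample_sheet(data.frame(
    sample_id = c("L1", "L2", "U1", "U2"), experiment = "E1", condition = "A",
    tracer_state = rep(c("labeled", "unlabeled"), each = 2),
    replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE))
  g <- data.frame(group_id = "G1", base_feature_id = "B", condition = "A",
                  n = 0L, feature_id = "B", mz = 200, rt = 100,
                  p_value = NA_real_, stringsAsFactors = FALSE)
  e <- estimate_mids(g, ft, ss)[[1]]
  expect_equal(e$corrected, 1)
  expect_equal(e$enrichment, 0)
  expect_equal(e$residual, 0)
})

test_that("labeling filters apply in order and report the failing rule", {
  base <- list(group_id = "G1", base_feature_id = "F1", condition = "A",
               raw_labeled = c(0.6, 0.4), raw_unlabeled = c(0.98, 0.02),
               corrected = c(0.7, 0.3), corrected_sd = c(0, 0),
               residual = 0.001, enrichment = 0.3, quantification = 1e5,
               quantification_sd = 0, n_labeled_used = 3, n_labeled_total = 3)
  params <- mid_filter_params(min_labeled_enrichment = 0.10,
                              max_unlabeled_labeling = 0.05,
                              max_residual = 0.05)
  ok <- filter_mids(structure(list(base), class = "mid_estimates"), params)
  expect_length(ok$kept, 1)
  expect_equal(nrow(ok$rejected), 0)

  low <- base; low$enrichment <- 0.05; low$corrected <- c(0.95, 0.05)
  rej <- filter_mids(structure(list(low), class = "mid_estimates"), params)
  expect_equal(rej$rejected$reason, "min_labeled_enrichment")

  dirty <- base; dirty$raw_unlabeled <- c(0.88, 0.12)
  rej2 <- filter_mids(structure(list(dirty), class = "mid_estimates"), params)
  expect_equal(rej2$rejected$reason, "max_unlabeled_labeling")

  slow <- base; slow$residual <- 0.2
  rej3 <- filter_mids(structure(list(slow), class = "mid_estimates"), params)
  expect_equal(rej3$rejected$reason, "max_residual")
})

test_that("the natural-tail allowance spares large unlabeled molecules", {
  # 12-carbon compound: natural unlabeled labeling 1 - 0.9893^12 ~ 0.121,
  # M1 alone ~ 12 * 0.0107 * 0.9893^11 ~ 0.117
  m1 <- 12 * 0.0107 * 0.9893^11
  est <- list(group_id = "G1", base_feature_id = "F1", condition = "A",
              raw_labeled = c(0.5, 0.4, 0.1),
              raw_unlabeled = c(1 - m1, m1, 0),
              corrected = c(0.6, 0.3, 0.1), corrected_sd = c(0, 0, 0),
              residual = 0.001, enrichment = 0.4, quantification = 1e5,
              quantification_sd = 0, n_labeled_used = 3, n_labeled_total = 3)
  ann <- data.frame(feature_id = "F1", compound_name = "sucrose",
                    formula = "C12H22O11", adduct = "[M+H]+", ppm_error = 0.5,
                    source = "ms1", score = NA_real_, stringsAsFactors = FALSE)
  params <- mid_filter_params(max_unlabeled_labeling = 0.05,
                              natural_tail_allowance = TRUE)
  with_allow <- filter_mids(structure(list(est), class = "mid_estimates"),
                            params, annotations = ann)
  expect_length(with_allow$kept, 1)
  without <- filter_mids(structure(list(est), class = "mid_estimates"),
                         params, annotations = NULL)
  expect_equal(without$rejected$reason, "max_unlabeled_labeling")
})

test_that("tightening the enrichment filter never grows the kept set", {
  run <- benchmark_run()
  prev <- Inf
  for (thr in c(0, 0.1, 0.3, 0.5, 0.9)) {
    kept <- length(filter_mids(run$est,
                               mid_filter_params(min_labeled_enrichment = thr,
                                                 max_unlabeled_labeling = 1,
                                                 max_residual = 1))$kept)
    expect_lte(kept, prev)
    prev <- kept
  }
})
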