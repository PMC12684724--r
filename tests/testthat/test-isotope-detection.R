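tr13 <- tracer_def("13C")

test_that("candidate members obey the ppm window around base + n*delta", {
  ft <- feature_table(data.frame(
    feature_id = c("B", "M1good", "M1bad"),
    mz = c(181.0707, 182.0740, 182.0780), rt = c(100, 101, 100),
    S1 = c(1, 1, 1), stringsAsFactors = FALSE))
  params <- detection_params(ppm_tol = 5, rt_window = 10, n_max = 3)
  mem <- candidate_members(ft, "B", tr13, params)
  # oracle: |182.0740 - (181.0707 + 1.0033548)| / 182.074 = 0.3 ppm -> in;
  #         182.0780 is ~22 ppm off -> out
  expect_equal(mem$feature_id, c("B", "M1good"))
  expect_equal(mem$n, c(0L, 1L))

  # two candidates within tolerance for one n: the closer m/z is kept
  ft2 <- feature_table(data.frame(
    feature_id = c("B", "near", "nearer"),
    mz = c(181.0707, 182.07445, 182.07410), rt = 100, S1 = 1,
    stringsAsFactors = FALSE))
  mem2 <- candidate_members(ft2, "B", tr13, params)
  expect_equal(mem2$feature_id[mem2$n == 1], "nearer")
  expect_equal(attr(mem2, "n_ambiguous"), 1L)

  # rt outside the window excludes a mass match
  ft3 <- feature_table(data.frame(
    feature_id = c("B", "M1"), mz = c(181.0707, 182.0740), rt = c(100, 140),
    S1 = 1, stringsAsFactors = FALSE))
  expect_equal(nrow(candidate_members(ft3, "B", tr13, params)), 1)
})

test_that("relative intensities normalize per sample and drop empty samples", {
  ft <- feature_table(data.frame(
    feature_id = c("B", "M1"), mz = c(200, 201.0034), rt = 100,
    S1 = c(900, 100), S2 = c(80, 20), S3 = c(NA_real_, NA_real_),
    stringsAsFactors = FALSE))
  mem <- data.frame(n = 0:1, feature_id = c("B", "M1"),
                    stringsAsFactors = FALSE)
  rel <- per_sample_relative_intensities(mem, ft, c("S1", "S2", "S3"))
  expect_equal(rownames(rel), c("S1", "S2"))   # S3 all-absent -> dropped
  expect_equal(unname(rel["S1", ]), c(0.9, 0.1))
  expect_equal(unname(rowSums(rel)), c(1, 1))

  # single-member group gives (1.0)
  rel1 <- per_sample_relative_intensities(mem[1, ], ft, c("S1", "S2"))
  expect_equal(unname(rel1[, 1]), c(1, 1))

  # gap position (NA feature_id) contributes zero without truncation
  mem_gap <- data.frame(n = 0:2, feature_id = c("B", NA, "M1"),
                        stringsAsFactors = FALSE)
  relg <- per_sample_relative_intensities(mem_gap, ft, "S1")
  expect_equal(unname(relg[1, ]), c(0.9, 0, 0.1))
})

test_that("Welch test reproduces the textbook example and t.test", {
  # hand-computed: mean diff 0.7, s^2 = 0.005 each, se = sqrt(0.005),
  # t = 9.899, Welch-Satterthwaite df = 2, p = 0.01005
  w <- welch_t_test(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(w$t, 9.899, tolerance = 1e-3)
  expect_equal(w$df, 2, tolerance = 1e-3)
  expect_equal(w$p, 0.01005, tolerance = 1e-3)

  # degenerate branches
  expect_equal(welch_t_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(welch_t_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$p, 1)
  dg <- welch_t_test(c(0.4, 0.4), c(0.2, 0.2))
  expect_equal(dg$p, 0)
  expect_true(dg$degenerate)

  # agreement with stats::t.test on random non-degenerate draws
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 0.5)
    w <- welch_t_test(a, b)
    tt <- stats::t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand-computed step-down", {
  expect_equal(adjust_pvalues_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues_bh(1.0), 1.0)
  p <- c(0.04, 0.001, 0.2)
  expect_equal(adjust_pvalues_bh(p), adjust_pvalues_bh(p))
  expect_equal(order(adjust_pvalues_bh(p)), order(p))  # order preserved
})

test_that("an enriched isotopologue pair is detected and a null pair is not", {
  pair <- make_pair_experiment(frac_labeled = c(0.6, 0.4),
                               frac_unlabeled = c(0.99, 0.01),
                               cv = 0.05, seed = 17)
  params <- detection_params(ppm_tol = 5, rt_window = 10, n_max = 3,
                             alpha = 0.05)
  g <- detect_groups(pair$features, pair$samples, tr13, params, "A")
  expect_equal(unique(g$base_feature_id), "P0")
  expect_lte(g$p_value[g$n == 1], 0.05)

  # oracle: the reported p equals a direct Welch test on the same
  # per-sample relative intensities
  mem <- data.frame(n = 0:1, feature_id = c("P0", "P1"),
                    stringsAsFactors = FALSE)
  rel_l <- per_sample_relative_intensities(mem, pair$features,
                                           paste0("L", 1:3))
  rel_u <- per_sample_relative_intensities(mem, pair$features,
                                           paste0("U", 1:3))
  expect_equal(g$p_value[g$n == 1],
               welch_t_test(rel_l[, 2], rel_u[, 2])$p, tolerance = 1e-12)

  null_pair <- make_pair_experiment(frac_labeled = c(0.99, 0.01),
                                    frac_unlabeled = c(0.99, 0.01),
                                    cv = 0.05, seed = 17)
  g0 <- detect_groups(null_pair$features, null_pair$samples, tr13, params, "A")
  expect_equal(nrow(g0), 0)
})

test_that("detection needs enough replicates and respects the noise floor", {
  pair <- make_pair_experiment(c(0.6, 0.4), c(0.99, 0.01), n_rep = 1)
  params <- detection_params()
  expect_error(detect_groups(pair$features, pair$samples, tr13, params, "A"),
               "condition 'A'")

  pair2 <- make_pair_experiment(c(0.6, 0.4), c(0.99, 0.01), seed = 2)
  high_floor <- detection_params(noise_floor = 1e9)
  g <- detect_groups(pair2$features, pair2$samples, tr13, high_floor, "A")
  expect_equal(nrow(g), 0)
})

test_that("detection is invariant to rescaling a single sample", {
  pair <- make_pair_experiment(c(0.55, 0.45), c(0.99, 0.01), seed = 23)
  params <- detection_params(n_max = 3)
  g1 <- detect_groups(pair$features, pair$samples, tr13, params, "A")
  scaled <- as.data.frame(pair$features)
  scaled$L2 <- scaled$L2 * 40
  g2 <- detect_groups(feature_table(scaled), pair$samples, tr13, params, "A")
  expect_equal(g1$p_value, g2$p_value, tolerance = 1e-12)
  expect_equal(g1$feature_id, g2$feature_id)
})

test_that("benchmark groups satisfy the ppm invariant and consume features", {
  run <- benchmark_run()
  g <- run$groups
  # no feature in two groups
  expect_false(any(duplicated(g$feature_id)))
  # every member m/z within the window against base + n*delta
  for (gid in unique(g$group_id)) {
    sub <- g[g$group_id == gid, ]
    base_mz <- sub$mz[sub$n == 0]
    target <- base_mz + sub$n * tr13$delta_mass
    expect_true(all(abs(sub$mz - target) <= 5e-6 * target))
  }
})

test_that("the FDR option only ever shrinks the detected set", {
  run <- benchmark_run()
  params_fdr <- run$params
  params_fdr$fdr <- TRUE
  g_fdr <- detect_groups(run$sim$features, run$sim$samples, tr13,
                         params_fdr, "A")
  expect_true(all(unique(g_fdr$group_id) %in% unique(run$groups$group_id)))
  expect_true(all(!is.na(g_fdr$p_adjusted[!is.na(g_fdr$p_value)])))
})
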