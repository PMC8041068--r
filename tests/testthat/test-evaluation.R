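test_that("false positive rate follows its definition exactly", {
  # no detections anywhere
  expect_equal(false_positive_rate(rep(list(integer(0)), 10), 98L, 10, 1000), 0)
  # 45 false positives over 100 replicates of 9999 zero-effect markers
  det <- rep(list(integer(0)), 100)
  for (r in 1:45) det[[r]] <- c(98L, 200L + r)   # one TP + one FP each
  expect_equal(false_positive_rate(det, 98L, 100, 10000),
               1000 * 45 / (100 * 9999))
  # saturation: all markers significant in one replicate of m = 10, 1 QTN
  expect_equal(false_positive_rate(list(1:10), 4L, 1, 10), 1000)
  # zero-effect denominator of zero is an error
  expect_error(false_positive_rate(list(1L), 1L, 1, 1), "zero-effect")
})

test_that("effect accuracy summarises detecting replicates only", {
  est <- matrix(c(0.7, 0.8, NA, 0.75), 4, 1)
  out <- effect_accuracy(est, truth = 0.75)
  expect_equal(out$n_detected, 3)
  expect_equal(out$mean_effect, 0.75)
  # two-point oracle: estimates (0.7, 0.8) against truth 0.75
  out2 <- effect_accuracy(matrix(c(0.7, 0.8), 2, 1), truth = 0.75)
  expect_equal(out2$mse, 0.0025 + 0.0025)
  # perfect estimation
  out3 <- effect_accuracy(matrix(rep(0.5, 5), 5, 1), truth = 0.5)
  expect_equal(out3$sd_effect, 0)
  expect_equal(out3$mse, 0)
  # never detected: missing, not zero
  out4 <- effect_accuracy(matrix(NA_real_, 3, 1), truth = 1)
  expect_equal(out4$n_detected, 0)
  expect_true(is.na(out4$mean_effect))
})

test_that("the error sum satisfies the moment identity", {
  set.seed(19)
  e <- rnorm(100, 0.73, 0.09)
  truth <- 0.7398
  out <- effect_accuracy(matrix(e, ncol = 1), truth = truth)
  # sum of squared errors = (n-1) sd^2 + n bias^2, exactly
  expect_equal(out$mse,
               99 * out$sd_effect^2 + 100 * (out$mean_effect - truth)^2,
               tolerance = 1e-10)
  # the identity applied to the published single-QTN summary (mean 0.734,
  # SD 0.091, truth 0.7398 over 100 replicates) reproduces its error sum
  # of ~0.817 to within rounding, confirming the sum-of-squares reading
  expect_equal(100 * (0.091^2 + (0.7398 - 0.734)^2), 0.817, tolerance = 0.02)
})

test_that("experiments are reproducible and summarise per-QTN detection", {
  cfg <- sim_config(150, 300, qtn_positions = c(20L, 77L),
                    qtn_effects = c(1.6, 0), polygenic_variance = 2,
                    base_seed = 1L)
  s1 <- run_experiment(cfg, n_reps = 5, seed = 1)
  s2 <- run_experiment(cfg, n_reps = 5, seed = 1)
  expect_identical(s1$per_qtn, s2$per_qtn)
  expect_identical(s1$fpr_permille, s2$fpr_permille)
  expect_equal(s1$per_qtn$position, c(20L, 77L))
  # the strong QTN is found, the zero-effect one is not
  expect_gte(s1$per_qtn$power[1], 80)
  expect_equal(s1$per_qtn$power[2], 0)
  expect_true(is.na(s1$per_qtn$mean_effect[2]))
  expect_equal(nrow(s1$estimates), 5)
})

test_that("power does not increase with the polygenic background", {
  base <- list(n_individuals = 400L, n_markers = 1000L,
               qtn_positions = 60L, qtn_effects = 0.45)
  p <- vapply(c(2, 10), function(bg) {
    cfg <- do.call(sim_config, c(base, list(polygenic_variance = bg)))
    run_experiment(cfg, n_reps = 12, seed = 5)$per_qtn$power
  }, 0)
  expect_gte(p[1], p[2])
})

test_that("experiment summaries export one row per QTN plus the FPR", {
  cfg <- sim_config(120, 250, qtn_positions = 33L, qtn_effects = 1.8,
                    polygenic_variance = 2)
  s <- run_experiment(cfg, n_reps = 3, seed = 2)
  path <- file.path(tempdir(), "exp.tsv")
  write_experiment_tsv(s, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("position", "true_effect", "power", "mean_effect",
                    "sd_effect", "mse", "fpr_permille") %in% names(tab)))
})
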