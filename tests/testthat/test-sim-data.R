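test_that("sim_config validates its invariants", {
  expect_error(sim_config(0, 10), "positive")
  expect_error(sim_config(10, 10, maf_low = 0), "maf")
  expect_error(sim_config(10, 10, maf_low = 0.3, maf_high = 0.2), "maf")
  expect_error(sim_config(10, 10, maf_high = 0.6), "maf")
  expect_error(sim_config(10, 10, residual_variance = 0), "residual_variance")
  expect_error(sim_config(10, 10, polygenic_variance = -1), "polygenic")
  expect_error(sim_config(10, 10, qtn_positions = 1L, qtn_effects = c(1, 2)),
               "equal length")
  expect_error(sim_config(10, 10, qtn_positions = c(2L, 2L),
                          qtn_effects = c(1, 1)), "distinct")
  expect_error(sim_config(10, 10, qtn_positions = 11L, qtn_effects = 1),
               "range")
})

test_that("generated genotypes have the configured shape, coding and MAFs", {
  cfg <- sim_config(200, 50)
  g <- generate_genotypes(cfg, 1)
  expect_equal(dim(g$X), c(200L, 50L))
  expect_true(all(g$X %in% c(-1, 1)))
  expect_true(all(g$maf > 0.1 & g$maf < 0.5))
  # reproducibility: same (config, seed) regenerates bit-identical data
  expect_identical(g, generate_genotypes(cfg, 1))
  expect_false(identical(g$X, generate_genotypes(cfg, 2)$X))
  # realized per-marker allele frequencies track the drawn MAFs
  freq <- colMeans(g$X == -1)
  se <- sqrt(g$maf * (1 - g$maf) / 200)
  expect_true(all(abs(freq - g$maf) < 4 * se + 1e-12))
})

test_that("symmetric allele frequencies give centered unit-variance markers", {
  cfg <- sim_config(4000, 40, maf_low = 0.5, maf_high = 0.5)
  g <- generate_genotypes(cfg, 5)
  expect_true(all(abs(colMeans(g$X)) < 4 / sqrt(4000)))
  expect_true(all(abs(apply(g$X, 2, var) - 1) < 0.01))
})

test_that("three-class genotypes match Hardy-Weinberg frequencies", {
  q <- 0.3
  cfg <- sim_config(1e5, 1, maf_low = q, maf_high = q,
                    genotype_coding = "hwe_three_class")
  g <- generate_genotypes(cfg, 9)
  counts <- table(factor(g$X[, 1], levels = c(-1, 0, 1)))
  gof <- chisq.test(counts, p = c(q^2, 2 * q * (1 - q), (1 - q)^2))
  expect_gt(gof$p.value, 0.001)
})

test_that("phenotype follows the additive polygenic model", {
  cfg <- sim_config(50, 20, residual_variance = 1e-12,
                    polygenic_variance = 0, grand_mean = 7)
  g <- generate_genotypes(cfg, 1)
  K <- compute_kinship(g)
  ph <- generate_phenotype(g, K, cfg, 2)
  # no variance sources: y collapses to the grand mean
  expect_equal(unname(ph$y), rep(7, 50), tolerance = 1e-5)
  expect_equal(ph$truth$u, rep(0, 50))

  # non-symmetric K rejected
  Kbad <- K; Kbad[1, 2] <- Kbad[1, 2] + 1
  expect_error(generate_phenotype(g, Kbad, cfg, 1), "symmetric")
  # non-PSD K rejected with a decomposition diagnostic
  cfg2 <- sim_config(50, 20, polygenic_variance = 2)
  Kneg <- K - diag(2, 50)
  expect_error(generate_phenotype(g, Kneg, cfg2, 1), "positive semi-definite")
})

test_that("polygenic draws have the configured variance", {
  cfg <- sim_config(300, 200, polygenic_variance = 2, residual_variance = 10)
  g <- generate_genotypes(cfg, 3)
  K <- compute_kinship(g)
  u <- unlist(lapply(1:300, function(r) generate_phenotype(g, K, cfg, r)$truth$u))
  # Var(u_i) = sigma_g^2 * K_ii, mean diag K = 1
  expect_equal(var(u), 2, tolerance = 0.1)
})

test_that("phenotype variance decomposes into QTN, polygenic and residual parts", {
  cfg <- sim_config(300, 400, qtn_positions = c(11L, 57L),
                    qtn_effects = c(0.9, -0.7),
                    polygenic_variance = 5, residual_variance = 4)
  g <- generate_genotypes(cfg, 7)
  K <- compute_kinship(g)
  Y <- vapply(seq_len(250), function(r) generate_phenotype(g, K, cfg, r)$y,
              numeric(300))
  gval <- drop(g$X[, cfg$qtn_positions] %*% cfg$qtn_effects)
  expected <- var(gval) + 5 * mean(diag(K)) + 4
  expect_equal(var(as.vector(Y)), expected, tolerance = 0.05 * expected)
})

test_that("random QTN designs hit the requested joint variance contribution", {
  g <- generate_genotypes(sim_config(500, 800), 4)
  des <- random_qtn_design(100, 0.5, g, seed = 11, residual_variance = 10)
  expect_length(unique(des$positions), 100)
  v <- apply(g$X[, des$positions], 2, var)
  h2 <- sum(des$effects^2 * v) / (sum(des$effects^2 * v) + 10)
  expect_equal(h2, 0.5, tolerance = 1e-6)

  # zero-heritability limit: effects vanish
  des0 <- random_qtn_design(1, 1e-9, g, seed = 2)
  expect_lt(abs(des0$effects), 1e-3)
  # equal shares on equal-variance markers give equal magnitudes
  Xeq <- cbind(rep(c(-1, 1), 50), rep(c(1, -1), 50))
  des2 <- random_qtn_design(2, 0.3, Xeq, seed = 3)
  expect_equal(abs(des2$effects)[1], abs(des2$effects)[2], tolerance = 1e-12)
  # infeasible heritability rejected
  expect_error(random_qtn_design(2, 1, g, seed = 1), "total_h2")
})

test_that("simulate_dataset is reproducible and fills random layouts", {
  cfg <- sim_preset("random-qtn", background = 2)
  cfg$n_individuals <- 80L; cfg$n_markers <- 150L
  attr(cfg, "random_qtn") <- list(n_qtn = 5L, total_h2 = 0.3)
  s1 <- simulate_dataset(cfg, 1)
  s2 <- simulate_dataset(cfg, 1)
  expect_identical(s1$y, s2$y)
  expect_length(s1$config$qtn_positions, 5)
  expect_length(s1$config$qtn_effects, 5)
})
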