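test_that("simulate_genotypes: HWE draws, determinism, mean dosage bound", {
  g1 <- simulate_genotypes(10000, c(0.5, 0.1), seed = 3)
  g2 <- simulate_genotypes(10000, c(0.5, 0.1), seed = 3)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  m <- rowMeans(g1$dosages)
  expect_gt(m["snp1"], 0.96); expect_lt(m["snp1"], 1.04)
  expect_gt(m["snp2"], 0.16); expect_lt(m["snp2"], 0.24)
  expect_error(simulate_genotypes(10, c(0.6)), "maf")
})

test_that("simulate_proportions: rows sum to 100, means track concentrations", {
  conc <- c(granulocyte = 70, monoCD14 = 15, CD4T = 6, CD8T = 5, B = 3,
            NK = 1)
  p <- simulate_proportions(5000, conc, seed = 4)
  expect_true(all(abs(rowSums(p$values) - 100) < 1e-9))
  expect_true(all(abs(colMeans(p$values) - conc) < 3))
  one <- simulate_proportions(10, c(only = 5), seed = 1)
  expect_true(all(one$values == 100))
})

test_that("simulate_bulk: noiseless data is exactly the interaction model", {
  cfg <- simulation_config(n_samples = 80, n_genes = 3, n_snps = 3,
                           concentrations = c(ct1 = 10, ct2 = 5),
                           n_effect_genes = 1, effect_gamma = 0.4,
                           effect_cell_type = "ct2", noise_sd = 0, seed = 8)
  sim <- simulate_bulk(cfg)
  tr <- sim$truth
  cvals <- sim$props$values
  g <- sim$geno$dosages["snp1", ]
  fit <- fit_nnls_interaction(sim$expr$values["gene1", ], g, cvals,
                              encoding = c(FALSE, FALSE))
  expect_equal(unname(fit$beta), unname(tr$betas["gene1", ]),
               tolerance = 1e-6)
  expect_equal(unname(fit$gamma), c(0, 0.4), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("simulate_bulk: with all gamma = 0 expression is genotype-independent", {
  cfg <- simulation_config(n_samples = 600, n_genes = 5, n_snps = 5,
                           concentrations = c(ct1 = 10, ct2 = 5),
                           noise_sd = 0.1, seed = 9)
  sim <- simulate_bulk(cfg)
  for (i in 1:5) {
    y <- sim$expr$values[i, ]
    cvals <- sim$props$values
    resid <- lm.fit(cbind(1, cvals[, 1]), y)$residuals
    g <- sim$geno$dosages[i, ]
    f <- lm(resid ~ g)
    tstat <- abs(coef(summary(f))["g", "t value"])
    expect_lt(tstat, 4)
  }
})

test_that("simulate_bulk is deterministic and continuous in noise_sd", {
  cfg <- simulation_config(n_samples = 50, n_genes = 4,
                           concentrations = c(a = 5, b = 5), seed = 10)
  s1 <- simulate_bulk(cfg); s2 <- simulate_bulk(cfg)
  expect_identical(s1$expr$values, s2$expr$values)
  cfg0 <- simulation_config(n_samples = 50, n_genes = 4,
                            concentrations = c(a = 5, b = 5),
                            noise_sd = 0, seed = 10)
  cfg_eps <- simulation_config(n_samples = 50, n_genes = 4,
                               concentrations = c(a = 5, b = 5),
                               noise_sd = 1e-4, noise_mode = "absolute",
                               seed = 10)
  d <- max(abs(simulate_bulk(cfg0)$expr$values -
                 simulate_bulk(cfg_eps)$expr$values))
  expect_lt(d, 5e-4)
})

test_that("simulate_facs_training: zero noise gives near-perfect prediction", {
  f <- simulate_facs_training(n_samples = 60,
                              concentrations = c(ct1 = 10, ct2 = 6,
                                                 ct3 = 4),
                              n_background = 30, noise_sd = 0, seed = 12)
  prep <- zscale_genes(log2_plus_one(tmm_normalize(f$expr)))
  rep_ <- cross_validate(prep, f$counts, "ct1", n_iter = 5, seed = 13)
  expect_gte(rep_$mean_r, 0.99)
})

test_that("simulate_facs_training: signature-free cell types are unpredictable", {
  f <- simulate_facs_training(n_samples = 60,
                              concentrations = c(ct1 = 10, ct2 = 6),
                              n_background = 40,
                              signature_free = "orphan", seed = 14)
  expect_equal(f$truth$signature_genes$orphan, character(0))
  expect_true("orphan" %in% colnames(f$counts$values))
  prep <- zscale_genes(log2_plus_one(tmm_normalize(f$expr)))
  rep_ <- suppressWarnings(cross_validate(prep, f$counts, "orphan",
                                          n_iter = 8, seed = 15))
  expect_false(isTRUE(rep_$predictable))

  # seeds differ -> datasets differ; seeds equal -> identical
  f2 <- simulate_facs_training(n_samples = 60,
                               concentrations = c(ct1 = 10, ct2 = 6),
                               n_background = 40,
                               signature_free = "orphan", seed = 14)
  expect_identical(f$expr$values, f2$expr$values)
  f3 <- simulate_facs_training(n_samples = 60,
                               concentrations = c(ct1 = 10, ct2 = 6),
                               n_background = 40,
                               signature_free = "orphan", seed = 15)
  expect_false(identical(f$expr$values, f3$expr$values))
})

test_that("generated data satisfy downstream preconditions end to end", {
  cfg <- simulation_config(n_samples = 90, n_genes = 6, n_snps = 6,
                           concentrations = c(ct1 = 50, ct2 = 20, ct3 = 10),
                           n_effect_genes = 2, seed = 16)
  sim <- simulate_bulk(cfg)
  expect_true(all(sim$expr$values >= 0))
  expect_true(all(sim$geno$dosages >= 0 & sim$geno$dosages <= 2))
  sp <- suppressWarnings(scale_proportions(sim$props))
  res <- suppressMessages(deconvolute(sim$pairs, sim$expr, sim$geno, sp))
  expect_equal(nrow(res), 6)
  expect_true(all(res$rss_full >= 0))
})
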