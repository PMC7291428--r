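test_that("scale_proportions rescales rows to 100 and flags collinearity", {
  p <- mk_props(rbind(c(60, 20, 10, 5, 3, 2), c(30, 10, 5, 2.5, 1.5, 1)))
  sp <- scale_proportions(p)
  expect_equal(unname(sp$values[1, ]), c(60, 20, 10, 5, 3, 2))
  expect_equal(unname(sp$values[2, ]), c(60, 20, 10, 5, 3, 2))
  expect_true(all(abs(rowSums(sp$values) - 100) < 1e-6))

  set.seed(1)
  a <- runif(30, 10, 50)
  corr <- mk_props(cbind(a = a, b = 2 * a, c = runif(30, 5, 20)),
                   cell_types = c("a", "b", "c"))
  expect_warning(scale_proportions(corr), "a~b")

  zero <- mk_props(rbind(c(0, 0), c(1, 2)), cell_types = c("x", "y"))
  expect_error(scale_proportions(zero), "all-zero.*s1")
})

test_that("enumerate_encodings returns the deduplicated restricted set", {
  expect_length(enumerate_encodings(1), 2)
  expect_length(enumerate_encodings(2), 6)
  expect_length(enumerate_encodings(6), 14)
  for (k in 2:8) {
    encs <- enumerate_encodings(k)
    expect_length(encs, 2 * k + 2)
    keys <- vapply(encs, paste, "", collapse = "")
    # bit patterns are distinct for k >= 3; at k = 2 the single-deviation
    # configurations from the two majorities coincide pairwise
    if (k >= 3) expect_false(anyDuplicated(keys) > 0)
    # every member deviates from its majority in at most one term
    dev <- vapply(encs, function(e) min(sum(e), sum(!e)), 0)
    expect_true(all(dev <= 1))
    # canonical order: number of swaps is non-decreasing
    expect_true(all(diff(vapply(encs, sum, 0)) >= 0))
  }
  expect_error(enumerate_encodings(0), "positive integer")
})

test_that("fit_nnls_interaction reconstructs an exact k = 1 instance", {
  n <- 20
  cvals <- matrix(100, n, 1, dimnames = list(paste0("s", 1:n), "ct1"))
  g <- rep(c(0, 1, 2), length.out = n)
  y <- 2 * cvals[, 1] + 1 * (g * cvals[, 1])
  fit <- fit_nnls_interaction(y, g, cvals, encoding = FALSE)
  expect_equal(unname(fit$beta), 2, tolerance = 1e-9)
  expect_equal(unname(fit$gamma), 1, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-12)
  expect_error(fit_nnls_interaction(y[1:2], g[1:2], cvals[1:2, , drop = FALSE]),
               "n > 2k")
})

test_that("NNLS fits agree with a projected-gradient oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_interaction_instance(n = sample(20:60, 1),
                                        k = sample(1:3, 1), seed = seed)
    fit <- fit_nnls_interaction(inst$y, inst$g, inst$cvals, inst$encoding)
    orc <- pg_nnls(inst$X, inst$y)
    k <- ncol(inst$cvals)
    impl <- c(fit$beta, fit$gamma)
    expect_lt(max(abs(impl - orc$coefficients)), 1e-6)
    expect_lt(abs(fit$rss - orc$rss), 1e-8)
  }
})

test_that("nesting: full rss never exceeds any reduced rss", {
  for (seed in 1:25) {
    k <- sample(2:3, 1)
    inst <- random_interaction_instance(n = 40, k = k, seed = 100 + seed)
    encs <- enumerate_encodings(k)
    full <- choose_encoding(lapply(encs, function(e)
      fit_nnls_interaction(inst$y, inst$g, inst$cvals, e)))
    for (ct in seq_len(k)) {
      encs_r <- enumerate_encodings(k - 1)
      red <- choose_encoding(lapply(encs_r, function(e) {
        fe <- rep(FALSE, k); fe[setdiff(seq_len(k), ct)] <- e
        fit_nnls_interaction(inst$y, inst$g, inst$cvals, fe, drop_term = ct)
      }))
      expect_lte(full$rss, red$rss + 1e-9)
    }
  }
})

test_that("choose_encoding finds a swapped-term effect and breaks ties deterministically", {
  set.seed(7)
  n <- 200
  gm <- matrix(rgamma(n * 2, shape = rep(c(5, 5), each = n)), n, 2)
  cvals <- gm / rowSums(gm) * 100
  dimnames(cvals) <- list(paste0("s", 1:n), c("ct1", "ct2"))
  g <- rbinom(n, 2, 0.4)
  # as-is effect on term 1, swapped-coding effect on term 2
  y <- 1.2 * cvals[, 1] + 0.8 * cvals[, 2] + 0.4 * (g * cvals[, 1]) +
    0.6 * ((2 - g) * cvals[, 2]) + rnorm(n, sd = 1)
  encs <- enumerate_encodings(2)
  fits <- lapply(encs, function(e) fit_nnls_interaction(y, g, cvals, e))
  best <- choose_encoding(fits)
  expect_equal(best$encoding, c(FALSE, TRUE))
  # exhaustive check: chosen rss is the global minimum
  expect_equal(best$rss, min(vapply(fits, `[[`, 0, "rss")))

  # tie-break: identical fits -> first in canonical order (fewest swaps)
  same <- list(list(rss = 1, encoding = c(FALSE, FALSE)),
               list(rss = 1, encoding = c(TRUE, TRUE)))
  expect_equal(choose_encoding(same)$encoding, c(FALSE, FALSE))
  single <- list(list(rss = 2, encoding = TRUE))
  expect_identical(choose_encoding(single), single[[1]])
})

test_that("anova_interaction_test matches the F(1, n - 2k) tail and edge cases", {
  t0 <- anova_interaction_test(list(rss = 5), list(rss = 5), n = 50, k = 2)
  expect_equal(t0$f_stat, 0)
  expect_equal(t0$p_value, 1)

  t1 <- anova_interaction_test(list(rss = 1), list(rss = 2), n = 104, k = 2)
  expect_equal(t1$f_stat, 100)
  expect_equal(t1$p_value, pf(100, 1, 100, lower.tail = FALSE))

  # saturated fit -> p = 1
  ts <- anova_interaction_test(list(rss = 0), list(rss = 0), n = 50, k = 2)
  expect_equal(ts$p_value, 1)
  expect_error(anova_interaction_test(list(rss = 1), list(rss = 2), 4, 2),
               "n > 2k")
  expect_error(anova_interaction_test(list(rss = 3), list(rss = 1), 50, 2),
               "exceeds")
})

test_that("deconvolute attributes a constructed interaction and dedupes pairs", {
  cfg <- simulation_config(n_samples = 400, n_genes = 4, n_snps = 4,
                           concentrations = c(ct1 = 10, ct2 = 8),
                           n_effect_genes = 1, effect_gamma = 0.5,
                           effect_cell_type = "ct1", noise_sd = 0.05,
                           seed = 17)
  sim <- simulate_bulk(cfg)
  sp <- suppressWarnings(scale_proportions(sim$props))
  pairs <- rbind(sim$pairs, sim$pairs[1, ])   # duplicate row
  res <- suppressMessages(deconvolute(pairs, sim$expr, sim$geno, sp))
  expect_equal(nrow(res), 4)                  # deduplicated
  expect_lt(res$p_ct1[1], 0.01)               # true interaction found
  expect_gt(res$p_ct2[1], 0.05)               # no effect in the other type
  # betas/gammas non-negative wherever reported
  expect_true(all(res$beta_ct1 >= 0 & res$beta_ct2 >= 0))
  expect_true(all(res$gamma_ct1 >= 0 & res$gamma_ct2 >= 0))
  # null genes (2:4) should not be strongly significant
  expect_true(all(pmin(res$p_ct1[-1], res$p_ct2[-1]) > 1e-4))
})

test_that("deconvolute skips unresolvable pairs with a warning", {
  cfg <- simulation_config(n_samples = 60, n_genes = 2, n_snps = 2,
                           concentrations = c(ct1 = 10, ct2 = 8), seed = 5)
  sim <- simulate_bulk(cfg)
  sp <- suppressWarnings(scale_proportions(sim$props))
  pairs <- rbind(sim$pairs,
                 data.frame(snp_id = "snp_missing", gene_id = "gene1"))
  expect_warning(res <- suppressMessages(
    deconvolute(pairs, sim$expr, sim$geno, sp)), "skipped")
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "skipped")$snp_id, "snp_missing")
})

test_that("fdr_per_celltype applies BH within each cell type", {
  res <- data.frame(snp_id = paste0("s", 1:4), gene_id = paste0("g", 1:4),
                    p_a = c(0.01, 0.02, 0.03, 0.04),
                    p_b = c(1, 1, 1, 0.5))
  attr(res, "cell_types") <- c("a", "b")
  class(res) <- c("DeconEqtlResult", "data.frame")
  out <- fdr_per_celltype(res)
  expect_equal(out$fdr_a, c(0.04, 0.04, 0.04, 0.04))
  expect_equal(out$fdr_a, bh_oracle(res$p_a))
  expect_equal(out$fdr_b, bh_oracle(res$p_b))
  expect_true(all(out$fdr_a >= out$p_a))

  one <- res[1, ]
  attr(one, "cell_types") <- c("a", "b")
  class(one) <- c("DeconEqtlResult", "data.frame")
  expect_equal(fdr_per_celltype(one)$fdr_a, one$p_a)
})

test_that("global dosage swap leaves rss and p-values invariant", {
  cfg <- simulation_config(n_samples = 150, n_genes = 3, n_snps = 3,
                           concentrations = c(ct1 = 10, ct2 = 8, ct3 = 5),
                           n_effect_genes = 2, seed = 23)
  sim <- simulate_bulk(cfg)
  sp <- scale_proportions(sim$props)
  res1 <- suppressMessages(deconvolute(sim$pairs, sim$expr, sim$geno, sp))
  geno2 <- GenotypeDosageMatrix(2 - sim$geno$dosages)
  res2 <- suppressMessages(deconvolute(sim$pairs, sim$expr, geno2, sp))
  for (ct in c("ct1", "ct2", "ct3")) {
    expect_lt(max(abs(res1[[paste0("p_", ct)]] - res2[[paste0("p_", ct)]])),
              1e-9)
  }
  expect_lt(max(abs(res1$rss_full - res2$rss_full)), 1e-9)
})
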