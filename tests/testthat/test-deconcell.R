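# Shared fixture: scaled expression with a known sparse linear response.
dc_fixture <- function(n = 60, n_genes = 40, seed = 11) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  expr <- mk_expr(x, state = "tmm_log2")
  zscale_genes(expr)
}

test_that("noiseless single-gene response is recovered with coefficient ~ 2", {
  expr <- dc_fixture()
  y <- 2 * expr$values["g1", ] + 50
  counts <- mk_props(cbind(ct = y), samples = colnames(expr$values),
                     cell_types = "ct")
  fit <- fit_elastic_net(expr, counts, "ct", seed = 3)
  expect_true("g1" %in% names(fit$gene_coefficients))
  expect_equal(unname(fit$gene_coefficients["g1"]), 2, tolerance = 0.05)
  others <- setdiff(names(fit$gene_coefficients), "g1")
  expect_true(all(abs(fit$gene_coefficients[others]) < 1e-3))
})

test_that("pure-noise response: the empty model is within one CV-SE of the optimum", {
  expr <- dc_fixture(n = 50)
  set.seed(21)
  ok <- vapply(1:6, function(s) {
    counts <- mk_props(cbind(ct = rnorm(50, 100, 10)),
                       samples = colnames(expr$values), cell_types = "ct")
    fit <- fit_elastic_net(expr, counts, "ct", seed = s)
    fit$cv_mse_null <= fit$cv_mse + fit$cv_se_best
  }, TRUE)
  expect_gte(sum(ok), 5)  # CV finds no real signal in (almost) all seeds
})

test_that("duplicated predictors share weight; coefficient sums agree", {
  expr <- dc_fixture(n = 80, n_genes = 20, seed = 5)
  vals <- expr$values
  vals["g2", ] <- vals["g1", ]           # exact duplicate
  expr2 <- expr; expr2$values <- vals
  y <- 3 * vals["g1", ] + 100 + rnorm(80, sd = 1e-4)
  counts <- mk_props(cbind(ct = y), samples = colnames(vals),
                     cell_types = "ct")
  dup <- fit_elastic_net(expr2, counts, "ct", seed = 7, alphas = 0.5)
  single <- fit_elastic_net(expr, counts, "ct", seed = 7, alphas = 0.5)
  s_dup <- sum(dup$gene_coefficients[c("g1", "g2")], na.rm = TRUE)
  expect_equal(s_dup, unname(single$gene_coefficients["g1"]),
               tolerance = 1e-3)
})

test_that("zero-variance response errors; sample overlap is enforced", {
  expr <- dc_fixture(n = 30)
  counts <- mk_props(cbind(ct = rep(5, 30)),
                     samples = colnames(expr$values), cell_types = "ct")
  expect_error(fit_elastic_net(expr, counts, "ct"), "zero variance")
  few <- mk_props(cbind(ct = rnorm(10, 50, 5)),
                  samples = colnames(expr$values)[1:10], cell_types = "ct")
  expect_error(fit_elastic_net(expr, few, "ct"), ">= 20 shared samples")
})

test_that("cross_validate: noiseless response gives near-perfect mean R; n_iter = 1 works", {
  expr <- dc_fixture(n = 60)
  y <- 10 + 3 * expr$values["g1", ] - 0 * expr$values["g2", ] +
    2 * expr$values["g3", ]
  counts <- mk_props(cbind(ct = y - min(y) + 1),
                     samples = colnames(expr$values), cell_types = "ct")
  rep1 <- cross_validate(expr, counts, "ct", n_iter = 1, seed = 2)
  expect_length(rep1$iteration_correlations, 1)
  expect_equal(rep1$mean_r, rep1$iteration_correlations[1])

  rep10 <- cross_validate(expr, counts, "ct", n_iter = 10, seed = 2)
  expect_gte(rep10$mean_r, 0.99)
  expect_true(rep10$predictable)
  expect_gte(rep10$selection_frequency["g1"], 0.9)
})

test_that("cross_validate: shuffled response hovers near zero correlation", {
  expr <- dc_fixture(n = 60, seed = 31)
  set.seed(32)
  counts <- mk_props(cbind(ct = sample(rnorm(60, 50, 15))),
                     samples = colnames(expr$values), cell_types = "ct")
  rep_null <- suppressWarnings(
    cross_validate(expr, counts, "ct", n_iter = 20, seed = 4))
  expect_false(isTRUE(rep_null$predictable))
  if (is.finite(rep_null$mean_r)) expect_lt(abs(rep_null$mean_r), 0.2)
})

test_that("cross_validate is bit-reproducible under the same seed", {
  expr <- dc_fixture(n = 50, n_genes = 15)
  y <- 5 + expr$values["g1", ] + rnorm(50, sd = 0.2)
  counts <- mk_props(cbind(ct = y - min(y) + 1),
                     samples = colnames(expr$values), cell_types = "ct")
  a <- cross_validate(expr, counts, "ct", n_iter = 5, seed = 99)
  b <- cross_validate(expr, counts, "ct", n_iter = 5, seed = 99)
  expect_identical(a, b)
})

test_that("select_signature_genes applies an inclusive threshold and sorts", {
  rep_ <- structure(list(selection_frequency = c(gA = 0.85, gB = 0.79,
                                                 gC = 0.80, gD = 1.0)),
                    class = "CrossValidationReport")
  out <- select_signature_genes(rep_, threshold = 0.8)
  expect_equal(out, c("gD", "gA", "gC"))
  expect_false("gB" %in% out)
})

test_that("predict_proportions evaluates the linear model, clips, and handles missing genes", {
  expr <- dc_fixture(n = 25, n_genes = 10)
  mod <- structure(list(cell_type = "ct",
                        gene_coefficients = c(g1 = 0.5),
                        intercept = 10, alpha = 0.5, penalty = 0.1,
                        seed = 1, cv_mse = 0, n_samples = 25),
                   class = "SignatureModel")
  pred <- predict_proportions(mod, expr)
  expect_equal(unname(pred$values[, "ct"]),
               unname(pmax(10 + 0.5 * expr$values["g1", ], 0)))

  # negative predictions are clipped and flagged
  mod_neg <- mod; mod_neg$intercept <- -100
  pred_neg <- predict_proportions(mod_neg, expr)
  expect_true(all(pred_neg$values == 0))
  expect_true(all(attr(pred_neg, "clipped")))

  # 1 of 4 genes missing (25%) -> error; 1 of 5 (20%) -> warn + impute 0
  mod4 <- mod; mod4$gene_coefficients <- c(g1 = 1, g2 = 1, g3 = 1, zz = 1)
  expect_error(predict_proportions(mod4, expr), "missing")
  mod5 <- mod
  mod5$gene_coefficients <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1, zz = 1)
  expect_warning(pred5 <- predict_proportions(mod5, expr), "imputing")
  manual <- 10 + colSums(expr$values[c("g1", "g2", "g3", "g4"), ])
  expect_equal(unname(pred5$values[, "ct"]), unname(pmax(manual, 0)))
})

test_that("sparse 5-gene truth is recovered (scaled-down parameter recovery)", {
  # smaller version of the full recovery property checked in the acceptance
  # suite: proportion is a noiseless sparse function of 5 genes
  expr <- dc_fixture(n = 60, n_genes = 40, seed = 51)
  truth_genes <- paste0("g", 1:5)
  w <- c(2, 1.5, 1, 1, 0.8)
  y <- 50 + drop(w %*% expr$values[truth_genes, ])
  counts <- mk_props(cbind(ct = y - min(y) + 1),
                     samples = colnames(expr$values), cell_types = "ct")
  rep_ <- cross_validate(expr, counts, "ct", n_iter = 20, seed = 6)
  expect_gte(rep_$mean_r, 0.95)
  sig <- select_signature_genes(rep_, threshold = 0.8)
  expect_gte(length(intersect(sig, truth_genes)), 4)
})
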