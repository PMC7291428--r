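#' Fit an elastic-net signature model for one cell type
#'
#' Regresses a cell type's measured proportions on z-scaled log2 bulk
#' expression with an elastic-net penalty. The penalty strength is chosen by
#' internal 10-fold cross-validation (minimum mean squared prediction error),
#' jointly over a grid of mixing parameters; the final model is refit on all
#' supplied samples at the selected tuning. Zero-variance genes flagged by
#' [zscale_genes()] are excluded from training.
#'
#' @param expr an [ExpressionMatrix] in `tmm_log2_scaled` state.
#' @param counts a [CellQuantMatrix] of measured cell quantities.
#' @param cell_type column of `counts` to model.
#' @param seed integer seed controlling the CV fold assignment.
#' @param alphas mixing-parameter grid (0 = ridge, 1 = lasso).
#' @param nfolds folds for the internal CV (default 10).
#' @return a `SignatureModel`: nonzero `gene_coefficients`, `intercept`,
#'   selected `alpha` and `penalty` (lambda), `seed`, and the CV error table.
#' @export
fit_elastic_net <- function(expr, counts, cell_type, seed = 1,
                            alphas = c(0.1, 0.25, 0.5, 0.75, 0.9),
                            nfolds = 10) {
  stopifnot_state(expr, "tmm_log2_scaled")
  if (!inherits(counts, "CellQuantMatrix")) stop("expected a CellQuantMatrix")
  if (!cell_type %in% colnames(counts$values))
    stop("cell type '", cell_type, "' not in counts")
  shared <- intersect(colnames(expr$values), rownames(counts$values))
  if (length(shared) < 20)
    stop("need >= 20 shared samples, have ", length(shared))
  keep_genes <- setdiff(rownames(expr$values), expr$zero_variance_genes)
  X <- t(expr$values[keep_genes, shared, drop = FALSE])
  y <- counts$values[shared, cell_type]
  if (stats::var(y) == 0)
    stop("cell type '", cell_type, "' has zero variance")
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = length(y)))
  cvs <- lapply(alphas, function(a)
    glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                      standardize = FALSE))
  best_err <- vapply(cvs, function(cv) min(cv$cvm), numeric(1))
  bi <- which.min(best_err)
  cv <- cvs[[bi]]
  li <- which.min(cv$cvm)
  co <- as.matrix(stats::coef(cv, s = cv$lambda[li]))
  beta <- co[-1, 1]
  nz <- beta[beta != 0]
  structure(list(cell_type = cell_type,
                 gene_coefficients = nz,
                 intercept = unname(co[1, 1]),
                 alpha = alphas[bi],
                 penalty = cv$lambda[li],
                 seed = seed,
                 cv_mse = min(cv$cvm),
                 # CV diagnostics: error and spread at the optimum, and the
                 # error of the empty (max-penalty) model
                 cv_se_best = cv$cvsd[li],
                 cv_mse_null = cv$cvm[1],
                 n_samples = length(y)),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel[%s]: %d genes, alpha %.2f, lambda %.4g (n = %d)\n",
              x$cell_type, length(x$gene_coefficients), x$alpha, x$penalty,
              x$n_samples))
  invisible(x)
}

#' Repeated train/test cross-validation of cell-proportion prediction
#'
#' Repeatedly splits the samples into a training fraction and a held-out test
#' set, fits an elastic-net signature model on the training split, predicts
#' the test split and records the Spearman correlation between predicted and
#' measured proportions. A cell type is called predictable when the mean
#' correlation over all iterations reaches 0.5. Per-gene selection
#' frequencies (fraction of iterations with a nonzero coefficient) feed the
#' stable-signature rule of [select_signature_genes()].
#'
#' Iteration i uses seed `seed + i`, so reports are bit-reproducible.
#'
#' @param expr an [ExpressionMatrix] in `tmm_log2_scaled` state.
#' @param counts a [CellQuantMatrix] of measured cell quantities.
#' @param cell_type column of `counts` to assess.
#' @param n_iter number of random splits (default 100).
#' @param train_frac training fraction (default 0.7).
#' @param seed master seed.
#' @param alphas mixing grid passed to [fit_elastic_net()].
#' @return a `CrossValidationReport` with `iteration_correlations`, `mean_r`,
#'   `predictable`, and `selection_frequency`.
#' @export
cross_validate <- function(expr, counts, cell_type, n_iter = 100,
                           train_frac = 0.7, seed = 1,
                           alphas = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  shared <- intersect(colnames(expr$values), rownames(counts$values))
  n <- length(shared)
  keep_genes <- setdiff(rownames(expr$values), expr$zero_variance_genes)
  sel_count <- stats::setNames(numeric(length(keep_genes)), keep_genes)
  rs <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- seed + i
    set.seed(it_seed)
    tr <- sample(shared, max(2, round(train_frac * n)))
    te <- setdiff(shared, tr)
    expr_tr <- expr; expr_tr$values <- expr$values[, tr, drop = FALSE]
    cnt_tr <- counts; cnt_tr$values <- counts$values[tr, , drop = FALSE]
    fit <- fit_elastic_net(expr_tr, cnt_tr, cell_type, seed = it_seed,
                           alphas = alphas)
    sel_count[names(fit$gene_coefficients)] <-
      sel_count[names(fit$gene_coefficients)] + 1
    pred <- fit$intercept +
      drop(crossprod(expr$values[names(fit$gene_coefficients), te,
                                 drop = FALSE],
                     fit$gene_coefficients))
    meas <- counts$values[te, cell_type]
    if (stats::var(meas) == 0 || stats::var(pred) == 0) {
      warning("iteration ", i, ": constant measured or predicted values; ",
              "correlation recorded as NA")
      next
    }
    rs[i] <- stats::cor(pred, meas, method = "spearman")
  }
  mean_r <- mean(rs, na.rm = TRUE)
  structure(list(cell_type = cell_type,
                 iteration_correlations = rs,
                 mean_r = mean_r,
                 predictable = is.finite(mean_r) && mean_r >= 0.5,
                 selection_frequency = sel_count / n_iter,
                 n_iter = n_iter, train_frac = train_frac, seed = seed),
            class = "CrossValidationReport")
}

#' @export
print.CrossValidationReport <- function(x, ...) {
  cat(sprintf("CrossValidationReport[%s]: mean R = %.3f over %d iterations (%s)\n",
              x$cell_type, x$mean_r, x$n_iter,
              if (x$predictable) "predictable" else "not predictable"))
  invisible(x)
}

#' Stable signature genes
#'
#' Genes selected (nonzero coefficient) in at least `threshold` of the
#' cross-validation iterations, inclusive at the boundary; sorted by
#' decreasing selection frequency, ties by gene ID.
#'
#' @param report a `CrossValidationReport`.
#' @param threshold selection-frequency cutoff (default 0.8).
#' @return character vector of gene IDs (possibly empty).
#' @export
select_signature_genes <- function(report, threshold = 0.8) {
  if (!inherits(report, "CrossValidationReport"))
    stop("expected a CrossValidationReport")
  f <- report$selection_frequency
  f <- f[f >= threshold]
  names(f)[order(-f, names(f))]
}

#' Predict cell proportions for new samples
#'
#' Applies fitted signature models (intercept + sum of coefficient x scaled
#' expression) to a prepared expression matrix. If more than 20% of a model's
#' signature genes are absent the cell type errors out; up to 20% missing
#' genes are imputed at scaled expression 0 with a warning. Negative
#' predictions are clipped to 0 and flagged in `attr(, "clipped")`.
#'
#' @param models a list of `SignatureModel` objects (or a single model).
#' @param expr an [ExpressionMatrix] in `tmm_log2_scaled` state.
#' @return a [CellQuantMatrix] of kind `predicted`.
#' @export
predict_proportions <- function(models, expr) {
  stopifnot_state(expr, "tmm_log2_scaled")
  if (inherits(models, "SignatureModel")) models <- list(models)
  samples <- colnames(expr$values)
  out <- matrix(NA_real_, length(samples), length(models))
  cts <- vapply(models, `[[`, "", "cell_type")
  dimnames(out) <- list(samples, cts)
  clipped <- matrix(FALSE, length(samples), length(models),
                    dimnames = dimnames(out))
  for (m in seq_along(models)) {
    mod <- models[[m]]
    genes <- names(mod$gene_coefficients)
    present <- genes %in% rownames(expr$values)
    if (mean(!present) > 0.2)
      stop("cell type '", mod$cell_type, "': ", sum(!present), "/",
           length(genes), " signature genes missing (> 20%)")
    if (any(!present))
      warning("cell type '", mod$cell_type, "': imputing scaled expression 0 for ",
              sum(!present), " missing gene(s): ",
              paste(genes[!present], collapse = ", "))
    xv <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
    xv[genes[present], ] <- expr$values[genes[present], , drop = FALSE]
    pred <- mod$intercept + drop(crossprod(xv, mod$gene_coefficients))
    clipped[, m] <- pred < 0
    out[, m] <- pmax(pred, 0)
  }
  res <- CellQuantMatrix(out, kind = "predicted")
  attr(res, "clipped") <- clipped
  res
}
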