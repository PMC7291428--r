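#' TMM normalization of a count matrix
#'
#' Between-sample normalization by the trimmed mean of M-values. For each
#' sample a scaling factor is computed against a reference sample as the
#' weighted mean of gene-wise log2 fold changes (M-values), after trimming the
#' most extreme M-values and A-values (average abundances); weights are the
#' inverse asymptotic binomial variances of the M-values. The reference is the
#' sample whose upper-quartile count fraction is closest to the mean across
#' samples. Factors are rescaled to have geometric mean 1 and normalized
#' values are counts per million effective library size
#' (library size x factor), so one sample's normalized values do not depend
#' on the other samples' sequencing depths.
#'
#' @param counts an [ExpressionMatrix] in `raw_counts` state.
#' @param trim_m fraction of M-values trimmed from each tail (default 0.3).
#' @param trim_a fraction of A-values trimmed from each tail (default 0.05).
#' @param weighted weight M-values by inverse asymptotic binomial variance
#'   (default `TRUE`, the canonical recipe). With `FALSE` the factor is the
#'   plain trimmed mean, which makes normalization exactly invariant to
#'   rescaling a single sample's counts.
#' @return an [ExpressionMatrix] in `tmm` state; per-sample scaling factors in
#'   `$norm_factors`.
#' @export
tmm_normalize <- function(counts, trim_m = 0.3, trim_a = 0.05,
                          weighted = TRUE) {
  stopifnot_state(counts, "raw_counts")
  x <- counts$values
  if (ncol(x) < 2) stop("TMM normalization needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  f75 <- apply(x, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(x)), function(j) {
    tmm_factor_pair(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a,
                    weighted)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))   # geometric mean 1, as is conventional
  eff <- lib * fac
  # counts per million effective library: a fixed scale keeps the output of
  # one sample independent of every other sample's library size
  out <- sweep(x, 2, eff, "/") * 1e6
  names(fac) <- colnames(x)
  ExpressionMatrix(out, state = "tmm", norm_factors = fac)
}

# One TMM factor: sample obs vs reference, standard M/A trimming recipe.
tmm_factor_pair <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a,
                            weighted = TRUE) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / lib_obs
  p_r <- ref / lib_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  # identical relative composition: all M == 0, factor 1 (also guards the
  # degenerate all-weights-zero two-gene case)
  if (max(abs(m)) < 1e-10) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  f <- if (weighted) sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
       else mean(m[keep2])
  if (!is.finite(f)) return(1)
  2^f
}

#' log2(x + 1) transform
#'
#' @param expr an [ExpressionMatrix] in `tmm` (or `raw_counts`) state.
#' @param offset pseudo-count added before the log (default 1).
#' @return an [ExpressionMatrix] in `tmm_log2` state.
#' @export
log2_plus_one <- function(expr, offset = 1) {
  stopifnot_state(expr, c("tmm", "raw_counts"))
  if (any(expr$values < 0)) stop("negative values cannot be log-transformed")
  ExpressionMatrix(log2(expr$values + offset), state = "tmm_log2",
                   norm_factors = expr$norm_factors)
}

#' Gene-wise z-scaling
#'
#' Centers and scales each gene to mean 0 and unit sample variance
#' (denominator n - 1). Genes with zero variance are set to all-zero rows and
#' flagged in `$zero_variance_genes`; they are retained in the matrix but
#' excluded from signature-model training.
#'
#' @param expr an [ExpressionMatrix] in `tmm_log2` state.
#' @return an [ExpressionMatrix] in `tmm_log2_scaled` state.
#' @export
zscale_genes <- function(expr) {
  stopifnot_state(expr, c("tmm_log2", "tmm_log2_scaled"))
  x <- expr$values
  if (ncol(x) < 2) stop("z-scaling needs at least 2 samples")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  flat <- sdv < .Machine$double.eps^0.5
  sdv[flat] <- 1
  out <- (x - mu) / sdv
  out[flat, ] <- 0
  ExpressionMatrix(out, state = "tmm_log2_scaled",
                   norm_factors = expr$norm_factors,
                   zero_variance_genes = rownames(x)[flat])
}

#' Covariate correction with re-exponentiation
#'
#' Prepares expression for eQTL deconvolution: per gene, ordinary least
#' squares of log2(count + offset) on the sample covariates; the residuals
#' plus the gene's fitted mean are exponentiated (2^value) so the output is
#' positive and count-like, preserving the linear relationship between
#' expression and cell proportions that the deconvolution model assumes.
#'
#' @param expr an [ExpressionMatrix] in `raw_counts` or `tmm` state.
#' @param covs a [CovariateTable] covering all samples (or `NULL` for an
#'   intercept-only correction, which reproduces `count + offset`).
#' @param offset pseudo-count for the log transform (default 1).
#' @return an [ExpressionMatrix] in `corrected_linear` state.
#' @export
correct_and_exponentiate <- function(expr, covs = NULL, offset = 1) {
  stopifnot_state(expr, c("raw_counts", "tmm"))
  x <- expr$values
  ly <- log2(x + offset)
  samples <- colnames(x)
  if (is.null(covs)) {
    design <- matrix(1, ncol(x), 1, dimnames = list(samples, "(Intercept)"))
  } else {
    df <- align_covariates(covs, samples)
    design <- stats::model.matrix(~ ., data = df)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  # residuals for all genes at once: ly' = (I - H) t(ly)
  resid <- t(qr.resid(qrd, t(ly)))
  corrected <- 2^(resid + rowMeans(ly))
  ExpressionMatrix(corrected, state = "corrected_linear")
}
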