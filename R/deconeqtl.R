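#' Rescale cell proportions to sum to 100
#'
#' The deconvolution model assumes the selected cell types jointly account
#' for the whole-blood signal, so their proportions are rescaled per sample
#' to sum to exactly 100. Highly correlated cell-type pairs
#' (|Pearson R| >= 0.75) are reported with a warning because they make the
#' interaction terms hard to attribute.
#'
#' @param props a [CellQuantMatrix] (measured or predicted).
#' @param cell_types cell types to keep (default: all columns).
#' @param cor_warn absolute Pearson correlation triggering the collinearity
#'   warning (default 0.75).
#' @return a `ScaledProportions` object (samples x cell types, rows sum 100).
#' @export
scale_proportions <- function(props, cell_types = NULL, cor_warn = 0.75) {
  if (!inherits(props, "CellQuantMatrix")) stop("expected a CellQuantMatrix")
  v <- props$values
  if (is.null(cell_types)) cell_types <- colnames(v)
  miss <- setdiff(cell_types, colnames(v))
  if (length(miss)) stop("cell types not present: ", paste(miss, collapse = ", "))
  v <- v[, cell_types, drop = FALSE]
  if (any(v < 0)) stop("proportions must be non-negative before scaling")
  rs <- rowSums(v)
  if (any(rs <= 0))
    stop("sample(s) with all-zero selected proportions: ",
         paste(rownames(v)[rs <= 0], collapse = ", "))
  out <- v / rs * 100
  if (ncol(out) >= 2) {
    cc <- suppressWarnings(stats::cor(out))
    cc[!is.finite(cc)] <- 0
    hi <- which(abs(cc) >= cor_warn & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hi))
      warning("highly correlated cell-type pairs (|R| >= ", cor_warn, "): ",
              paste(sprintf("%s~%s (R=%.2f)", colnames(out)[hi[, 1]],
                            colnames(out)[hi[, 2]],
                            cc[hi]), collapse = "; "))
  }
  structure(list(values = out, cell_types = colnames(out),
                 sample_ids = rownames(out)),
            class = "ScaledProportions")
}

#' @export
print.ScaledProportions <- function(x, ...) {
  cat(sprintf("ScaledProportions: %d samples x %d cell types (rows sum 100)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Enumerate restricted genotype encodings
#'
#' The interaction model codes the dosage per interaction term either as-is
#' (g) or swapped (2 - g). Rather than all 2^k orientations, the search is
#' restricted to configurations where at most one term deviates from the
#' majority orientation: all-as-is, all-swapped, and each single-term
#' deviation from either majority — (2k) + 2 distinct configurations for
#' k >= 2, and 2 for k = 1 after deduplication.
#'
#' Encodings are returned in a canonical deterministic order: by number of
#' swapped terms, then lexicographically (as-is < swapped); tie-breaking in
#' [choose_encoding()] relies on this order.
#'
#' @param k number of cell types (interaction terms).
#' @return list of logical vectors, `TRUE` = swapped term.
#' @export
enumerate_encodings <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer")
  k <- as.integer(k)
  encs <- c(list(rep(FALSE, k), rep(TRUE, k)),
            lapply(seq_len(k), function(i) { e <- rep(FALSE, k); e[i] <- TRUE; e }),
            lapply(seq_len(k), function(i) { e <- rep(TRUE, k); e[i] <- FALSE; e }))
  if (k == 1) {
    # swap-one coincides with all-swapped: only 2 distinct orientations
    keys <- vapply(encs, function(e) paste(as.integer(e), collapse = ""), "")
    encs <- encs[!duplicated(keys)]
  }
  # (2k) + 2 configurations for k >= 2, per the published count; at k = 2 the
  # single-deviation configurations coincide pairwise with each other, which
  # is harmless (identical fits, deterministic tie-break)
  ord <- order(vapply(encs, sum, 0L),
               vapply(encs, function(e) paste(as.integer(e), collapse = ""), ""))
  encs[ord]
}

# Design matrix for the interaction model: [c_1..c_k, g_enc x c_1 .. g_enc x c_k]
# with no intercept and no genotype main effect; drop_term removes one
# interaction column (the reduced model).
interaction_design <- function(g, cvals, encoding, drop_term = NULL) {
  k <- ncol(cvals)
  gmat <- vapply(seq_len(k), function(j) {
    if (encoding[j]) (2 - g) * cvals[, j] else g * cvals[, j]
  }, numeric(nrow(cvals)))
  colnames(gmat) <- paste0("gxc_", colnames(cvals))
  X <- cbind(cvals, gmat)
  colnames(X)[seq_len(k)] <- paste0("c_", colnames(cvals))
  if (!is.null(drop_term)) X <- X[, -(k + drop_term), drop = FALSE]
  X
}

#' Fit the non-negative interaction model for one gene
#'
#' Fits y = sum_k beta_k c_k + sum_k gamma_k (g_enc x c_k) + e with all
#' coefficients constrained >= 0 (NNLS), no intercept and no genotype main
#' effect. The genotype main effect is omitted because the per-cell-type
#' genotype effects already sum to the whole-blood effect when proportions
#' sum to 100. `drop_term = k` omits the k-th interaction term (the reduced
#' model used by the ANOVA).
#'
#' @param y expression vector for one gene (corrected, linear scale).
#' @param g dosage vector in `[0, 2]`, sample-aligned with `y`.
#' @param cprops a `ScaledProportions` object (or samples x cell-types matrix
#'   whose rows sum to 100).
#' @param encoding logical vector of swapped flags, one per cell type (see
#'   [enumerate_encodings()]).
#' @param drop_term optional cell-type index whose interaction term is omitted.
#' @return list with `beta` (per-cell-type proportion effects), `gamma`
#'   (interaction effects; `NA` at a dropped term), `rss`, `encoding`.
#' @export
fit_nnls_interaction <- function(y, g, cprops, encoding = NULL,
                                 drop_term = NULL) {
  cvals <- if (inherits(cprops, "ScaledProportions")) cprops$values else as.matrix(cprops)
  k <- ncol(cvals)
  n <- length(y)
  if (length(g) != n || nrow(cvals) != n)
    stop("y, g and proportions must be sample-aligned")
  if (n <= 2 * k) stop("need n > 2k samples (n = ", n, ", k = ", k, ")")
  if (is.null(encoding)) encoding <- rep(FALSE, k)
  if (length(encoding) != k) stop("encoding length must equal k")
  X <- interaction_design(g, cvals, encoding, drop_term)
  fit <- nnls_solve(X, y)
  beta <- fit$coefficients[seq_len(k)]
  gamma <- rep(NA_real_, k)
  gidx <- if (is.null(drop_term)) seq_len(k) else setdiff(seq_len(k), drop_term)
  gamma[gidx] <- fit$coefficients[(k + 1):length(fit$coefficients)]
  names(beta) <- names(gamma) <- colnames(cvals)
  list(beta = beta, gamma = gamma, rss = fit$rss, encoding = encoding,
       drop_term = drop_term)
}

#' Select the best genotype encoding
#'
#' Given fits of the same model under several encodings, returns the one with
#' the smallest residual sum of squares. Exact ties are broken by fewest
#' swapped terms, then lexicographic encoding order — guaranteed by the
#' canonical order of [enumerate_encodings()] plus first-minimum selection.
#'
#' @param fits list of fit records from [fit_nnls_interaction()], in the
#'   canonical encoding order.
#' @return the winning fit record.
#' @export
choose_encoding <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  fits[[which.min(rss)]]
}

#' Nested-model ANOVA for one interaction term
#'
#' Tests whether the full model explains significantly more variance than the
#' reduced model lacking one cell type's interaction term:
#' F = (rss_reduced - rss_full) / (rss_full / (n - 2k)), with p the upper
#' tail of F(1, n - 2k). The degrees of freedom are the unconstrained-OLS
#' analogue (the reduced model removes exactly one term); a tiny negative
#' numerator arising from the 1e-9 nesting tolerance is clamped to 0, and a
#' saturated full fit (rss_full ~ 0) returns p = 1.
#'
#' @param full,reduced fit records carrying `$rss`.
#' @param n number of samples; must exceed `2 * k`.
#' @param k number of cell types in the full model.
#' @return list with `f_stat` and `p_value`.
#' @export
anova_interaction_test <- function(full, reduced, n, k) {
  if (n <= 2 * k) stop("need n > 2k samples")
  rss_f <- full$rss
  rss_r <- reduced$rss
  if (rss_f > rss_r + 1e-9)
    stop("full-model rss exceeds reduced-model rss beyond tolerance")
  num <- max(rss_r - rss_f, 0)
  if (rss_f <= 1e-12 * max(1, rss_r))
    return(list(f_stat = if (num > 0) Inf else 0, p_value = 1))
  f <- num / (rss_f / (n - 2 * k))
  list(f_stat = f, p_value = stats::pf(f, 1, n - 2 * k, lower.tail = FALSE))
}

# One gene/SNP deconvolution given aligned y, g and scaled proportions.
# Returns per-cell-type statistics. The full model searches the (2k)+2
# encodings; each reduced model independently searches the (2(k-1))+2
# encodings over its remaining terms.
decon_one <- function(y, g, cvals) {
  k <- ncol(cvals)
  n <- length(y)
  encs <- enumerate_encodings(k)
  fits <- lapply(encs, function(e) fit_nnls_interaction(y, g, cvals, e))
  best <- choose_encoding(fits)
  res <- vector("list", k)
  for (ct in seq_len(k)) {
    encs_r <- if (k > 1) enumerate_encodings(k - 1) else list(logical(0))
    fits_r <- lapply(encs_r, function(e) {
      full_e <- rep(FALSE, k)
      full_e[setdiff(seq_len(k), ct)] <- e
      fit_nnls_interaction(y, g, cvals, full_e, drop_term = ct)
    })
    best_r <- choose_encoding(fits_r)
    tst <- anova_interaction_test(best, best_r, n, k)
    res[[ct]] <- list(beta = unname(best$beta[ct]),
                      gamma = unname(best$gamma[ct]),
                      encoding = if (best$encoding[ct]) "swapped" else "as-is",
                      rss_full = best$rss,
                      rss_reduced = best_r$rss,
                      f_stat = tst$f_stat, p_value = tst$p_value)
  }
  names(res) <- colnames(cvals)
  res
}

#' Deconvolute bulk eQTLs into cell-type interaction eQTLs
#'
#' For every (SNP, gene) pair: fit the full non-negative interaction model
#' over the restricted encoding set, fit per cell type the reduced model
#' (own encoding search), and test each cell type's interaction by
#' full-vs-reduced ANOVA. Samples are intersected across the expression,
#' genotype and proportion inputs.
#'
#' @param pairs data.frame with columns `snp_id`, `gene_id` (duplicates are
#'   dropped).
#' @param expr an [ExpressionMatrix] in `corrected_linear` state.
#' @param geno a [GenotypeDosageMatrix].
#' @param props a `ScaledProportions` object from [scale_proportions()].
#' @return a data.frame of class `DeconEqtlResult`: one row per (SNP, gene)
#'   with per-cell-type columns `beta_<ct>`, `gamma_<ct>`, `encoding_<ct>`,
#'   `f_<ct>`, `p_<ct>`, plus `rss_full`. Unresolvable or zero-variance pairs
#'   are skipped with a warning; the skip table is attached as
#'   `attr(, "skipped")`.
#' @export
deconvolute <- function(pairs, expr, geno, props) {
  stopifnot_state(expr, "corrected_linear")
  if (!inherits(geno, "GenotypeDosageMatrix")) stop("expected a GenotypeDosageMatrix")
  if (!inherits(props, "ScaledProportions"))
    stop("proportions must come from scale_proportions()")
  pairs <- unique(as.data.frame(pairs)[, c("snp_id", "gene_id")])
  samples <- Reduce(intersect, list(colnames(expr$values),
                                    colnames(geno$dosages),
                                    props$sample_ids))
  if (length(samples) <= 2 * ncol(props$values))
    stop("too few shared samples (", length(samples), ") for k = ",
         ncol(props$values), " cell types")
  message(sprintf("deconvolute: %d shared samples, %d pairs, %d cell types",
                  length(samples), nrow(pairs), ncol(props$values)))
  ev <- expr$values[, samples, drop = FALSE]
  gv <- geno$dosages[, samples, drop = FALSE]
  cvals <- props$values[samples, , drop = FALSE]
  cts <- colnames(cvals)
  rows <- vector("list", nrow(pairs))
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$snp_id[i]; gid <- pairs$gene_id[i]
    reason <- NULL
    if (!gid %in% rownames(ev)) reason <- "gene not in expression"
    else if (!sid %in% rownames(gv)) reason <- "snp not in genotypes"
    else if (stats::var(gv[sid, ]) == 0) reason <- "zero-variance dosage"
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1]] <- data.frame(snp_id = sid, gene_id = gid,
                                                   reason = reason)
      next
    }
    st <- decon_one(ev[gid, ], gv[sid, ], cvals)
    row <- list(snp_id = sid, gene_id = gid,
                rss_full = st[[1]]$rss_full)
    for (ct in cts) {
      row[[paste0("beta_", ct)]] <- st[[ct]]$beta
      row[[paste0("gamma_", ct)]] <- st[[ct]]$gamma
      row[[paste0("encoding_", ct)]] <- st[[ct]]$encoding
      row[[paste0("f_", ct)]] <- st[[ct]]$f_stat
      row[[paste0("p_", ct)]] <- st[[ct]]$p_value
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no testable (SNP, gene) pairs")
  out <- do.call(rbind, rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  if (!is.null(skipped))
    warning(nrow(skipped), " pair(s) skipped; see attr(result, 'skipped')")
  attr(out, "cell_types") <- cts
  attr(out, "skipped") <- skipped
  class(out) <- c("DeconEqtlResult", "data.frame")
  out
}

#' Per-cell-type FDR control
#'
#' Benjamini-Hochberg adjustment applied separately to each cell type's
#' p-value column — each cell type is corrected for the same number of tests,
#' namely all tested (SNP, gene) pairs.
#'
#' @param results a `DeconEqtlResult` data.frame from [deconvolute()].
#' @return the same data.frame with `fdr_<ct>` columns added.
#' @export
fdr_per_celltype <- function(results) {
  cts <- attr(results, "cell_types")
  if (is.null(cts))
    cts <- sub("^p_", "", grep("^p_", names(results), value = TRUE))
  if (!nrow(results)) stop("empty result set")
  for (ct in cts)
    results[[paste0("fdr_", ct)]] <-
      stats::p.adjust(results[[paste0("p_", ct)]], method = "BH")
  results
}
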