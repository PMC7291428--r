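#' Single-cell-type interaction model (comparator)
#'
#' Ordinary least squares of expression on genotype, one cell type's
#' proportion and their interaction: y = I + b1 G + b2 c + b3 (c x G) + e.
#' The interaction p-value is the two-sided t-test on b3. This is the
#' classical single-cell-type interaction approach used as a comparator for
#' the non-negative multi-cell-type deconvolution model.
#'
#' @param y expression vector (same corrected linear preparation as the
#'   deconvolution model).
#' @param g dosage vector in `[0, 2]`.
#' @param c_prop one cell type's proportion vector.
#' @param snp_id,gene_id,cell_type identifiers carried into the result.
#' @return a `WestraResult`: intercept, `beta_g`, `beta_c`, `beta_inter`,
#'   `p_inter`, and `p_after_restriction` (initially equal to `p_inter`).
#' @export
fit_westra <- function(y, g, c_prop, snp_id = NA, gene_id = NA,
                       cell_type = NA) {
  n <- length(y)
  if (n < 5) stop("need at least 5 samples")
  if (length(g) != n || length(c_prop) != n)
    stop("y, g and c_prop must be sample-aligned")
  X <- cbind(`(Intercept)` = 1, g = g, c = c_prop, gxc = g * c_prop)
  if (qr(X)$rank < ncol(X))
    stop("collinear design (constant genotype or proportion?)")
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - 4
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * rss / df)
  tstat <- cf["gxc"] / se[4]
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(snp_id = snp_id, gene_id = gene_id, cell_type = cell_type,
                 intercept = unname(cf[1]), beta_g = unname(cf["g"]),
                 beta_c = unname(cf["c"]), beta_inter = unname(cf["gxc"]),
                 se_inter = unname(se[4]),
                 p_inter = unname(p), p_after_restriction = unname(p)),
            class = "WestraResult")
}

#' Sign restriction on the interaction p-value
#'
#' The comparator method nulls out interactions whose direction relative to
#' the genotype main effect is deemed implausible for the cell type:
#' under `opposite_signs_null` (neutrophils/granulocytes) the p-value is set
#' to 1 when `beta_inter * beta_g < 0`; under `same_signs_null` (CD4+ T
#' cells, monocytes and, by default, the remaining cell types) when
#' `beta_inter * beta_g > 0`. A zero product leaves the p-value untouched
#' (both inequalities are strict). The rule never decreases a p-value.
#'
#' @param res a `WestraResult`.
#' @param rule `"opposite_signs_null"` or `"same_signs_null"`.
#' @return the `WestraResult` with `p_after_restriction` updated.
#' @export
apply_sign_restriction <- function(res,
                                   rule = c("opposite_signs_null",
                                            "same_signs_null")) {
  rule <- match.arg(rule)
  if (!inherits(res, "WestraResult")) stop("expected a WestraResult")
  prod <- res$beta_inter * res$beta_g
  nulled <- (rule == "opposite_signs_null" && prod < 0) ||
    (rule == "same_signs_null" && prod > 0)
  res$p_after_restriction <- if (nulled) 1 else res$p_inter
  res
}

#' Default per-cell-type sign-restriction rules
#'
#' Granulocytes/neutrophils use `opposite_signs_null`; all other cell types
#' default to `same_signs_null`. Override by passing a named vector to the
#' caller.
#'
#' @param cell_types character vector of cell-type names.
#' @return named character vector of rules.
#' @export
default_sign_rules <- function(cell_types) {
  rules <- ifelse(grepl("gran|neut", cell_types, ignore.case = TRUE),
                  "opposite_signs_null", "same_signs_null")
  stats::setNames(rules, cell_types)
}

#' Run the comparator model over many (SNP, gene) pairs
#'
#' @param pairs data.frame with `snp_id`, `gene_id` columns.
#' @param expr an [ExpressionMatrix] in `corrected_linear` state.
#' @param geno a [GenotypeDosageMatrix].
#' @param props a [CellQuantMatrix] or `ScaledProportions`.
#' @param cell_type which cell type's proportion to interact with genotype.
#' @param rule sign-restriction rule (default from [default_sign_rules()]).
#' @return data.frame, one row per testable pair.
#' @export
westra_scan <- function(pairs, expr, geno, props, cell_type, rule = NULL) {
  stopifnot_state(expr, "corrected_linear")
  pv <- if (inherits(props, "ScaledProportions")) props$values else props$values
  if (is.null(rule)) rule <- unname(default_sign_rules(cell_type))
  samples <- Reduce(intersect, list(colnames(expr$values),
                                    colnames(geno$dosages), rownames(pv)))
  pairs <- unique(as.data.frame(pairs)[, c("snp_id", "gene_id")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sid <- pairs$snp_id[i]; gid <- pairs$gene_id[i]
    if (!gid %in% rownames(expr$values) || !sid %in% rownames(geno$dosages))
      return(NULL)
    r <- fit_westra(expr$values[gid, samples], geno$dosages[sid, samples],
                    pv[samples, cell_type], snp_id = sid, gene_id = gid,
                    cell_type = cell_type)
    r <- apply_sign_restriction(r, rule)
    data.frame(snp_id = sid, gene_id = gid, cell_type = cell_type,
               intercept = r$intercept, beta_g = r$beta_g, beta_c = r$beta_c,
               beta_inter = r$beta_inter, p_inter = r$p_inter,
               p_after_restriction = r$p_after_restriction)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no testable pairs")
  do.call(rbind, rows)
}
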