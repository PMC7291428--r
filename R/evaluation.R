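#' Allelic concordance against reference effects
#'
#' Compares the direction of deconvoluted cell-type interaction eQTLs with
#' signed reference effects (purified-cell eQTLs, chromatin-mark QTLs,
#' single-cell eQTLs, or simulation truth). The direction of a deconvoluted
#' effect is the one implied by its chosen genotype encoding — the
#' interaction coefficient itself is non-negative by construction, so an
#' as-is encoding means the coded allele increases expression (+1) and a
#' swapped encoding means it decreases it (-1). Reference effects are
#' harmonized first: when the reference's coded allele differs from the
#' deconvolution's coded allele for that SNP, the reference sign is flipped.
#' Pairs with a zero effect on either side are excluded from the rate and
#' counted separately.
#'
#' @param decon data.frame with columns `snp_id`, `gene_id`, `cell_type`,
#'   `direction` (+1/-1) — see [decon_directions()] — and optionally
#'   `coded_allele`.
#' @param ref data.frame with columns `snp_id`, `gene_id`, `cell_type`,
#'   `effect` (signed), and optionally `coded_allele`.
#' @param cell_type_map optional named character vector translating decon
#'   cell-type names to reference cell-type names.
#' @return list with `n_concordant`, `n_discordant`, `n_zero_excluded`,
#'   `rate` (percent).
#' @export
allelic_concordance <- function(decon, ref, cell_type_map = NULL) {
  decon <- as.data.frame(decon); ref <- as.data.frame(ref)
  if (!is.null(cell_type_map)) {
    mapped <- cell_type_map[decon$cell_type]
    decon$cell_type <- ifelse(is.na(mapped), decon$cell_type, mapped)
  }
  key <- function(d) paste(d$snp_id, d$gene_id, d$cell_type, sep = "\r")
  m <- match(key(decon), key(ref))
  ok <- !is.na(m)
  if (!any(ok)) stop("no overlapping (SNP, gene, cell type) entries")
  d <- decon[ok, , drop = FALSE]
  r <- ref[m[ok], , drop = FALSE]
  eff <- r$effect
  if (!is.null(d$coded_allele) && !is.null(r$coded_allele)) {
    flip <- d$coded_allele != r$coded_allele
    eff[flip] <- -eff[flip]
  }
  zero <- d$direction == 0 | eff == 0
  conc <- sign(d$direction[!zero]) == sign(eff[!zero])
  list(n_concordant = sum(conc), n_discordant = sum(!conc),
       n_zero_excluded = sum(zero),
       rate = 100 * sum(conc) / max(length(conc), 1))
}

#' Extract signed effect directions from deconvolution results
#'
#' Long-format table of per-cell-type directions from a `DeconEqtlResult`:
#' +1 for an as-is encoding, -1 for swapped; direction 0 when the
#' interaction coefficient is zero (no detectable genotype effect in that
#' cell type). Optionally restricted to entries below an FDR threshold.
#'
#' @param results a `DeconEqtlResult` (after [fdr_per_celltype()] when
#'   filtering by FDR).
#' @param fdr_max optional per-cell-type FDR filter.
#' @return data.frame with `snp_id`, `gene_id`, `cell_type`, `direction`.
#' @export
decon_directions <- function(results, fdr_max = NULL) {
  cts <- attr(results, "cell_types")
  if (is.null(cts))
    cts <- sub("^p_", "", grep("^p_", names(results), value = TRUE))
  out <- lapply(cts, function(ct) {
    d <- data.frame(snp_id = results$snp_id, gene_id = results$gene_id,
                    cell_type = ct,
                    direction = ifelse(results[[paste0("gamma_", ct)]] <= 0, 0,
                                       ifelse(results[[paste0("encoding_", ct)]] ==
                                                "swapped", -1, 1)))
    if (!is.null(fdr_max)) {
      fc <- results[[paste0("fdr_", ct)]]
      if (is.null(fc)) stop("run fdr_per_celltype() before filtering by FDR")
      d <- d[fc <= fdr_max, , drop = FALSE]
    }
    d
  })
  do.call(rbind, out)
}

#' Fisher test comparing two concordance tables
#'
#' Two-sided Fisher exact test on the 2x2 table of concordant/discordant
#' counts from two comparisons, Bonferroni-multiplied by `correction_m` and
#' capped at 1.
#'
#' @param a,b lists with `n_concordant`, `n_discordant` (e.g. from
#'   [allelic_concordance()]).
#' @param correction_m Bonferroni multiplier (default 1).
#' @return corrected p-value.
#' @export
concordance_fisher <- function(a, b, correction_m = 1) {
  tab <- matrix(c(a$n_concordant, a$n_discordant,
                  b$n_concordant, b$n_discordant), 2, 2)
  if (any(colSums(tab) == 0)) stop("empty concordance table")
  p <- stats::fisher.test(tab)$p.value
  min(p * correction_m, 1)
}

#' Compare effect-size distributions between two groups
#'
#' @param group_a,group_b numeric vectors (absolute effect sizes).
#' @param test `"wilcoxon_ranksum"` (two-sided rank-sum), `"t_test"`
#'   (Welch), or `"f_variance"` (variance-ratio F test).
#' @return two-sided p-value.
#' @export
effect_size_comparison <- function(group_a, group_b,
                                   test = c("wilcoxon_ranksum", "t_test",
                                            "f_variance")) {
  test <- match.arg(test)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (test %in% c("t_test", "f_variance") &&
      (stats::var(group_a) == 0 || stats::var(group_b) == 0))
    stop("constant group: ", test, " undefined")
  switch(test,
         wilcoxon_ranksum = stats::wilcox.test(group_a, group_b,
                                               exact = NULL)$p.value,
         t_test = stats::t.test(group_a, group_b)$p.value,
         f_variance = stats::var.test(group_a, group_b)$p.value)
}

#' Fisher enrichment of one gene set in another
#'
#' Cross-tabulates membership of `set_a` and `set_b` within `universe` and
#' applies a two-sided Fisher exact test.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `odds_ratio` (conditional MLE; may be 0 or `Inf`),
#'   `p`, and the 2x2 `table`.
#' @export
enrichment_fisher <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad))
    stop("sets must be subsets of the universe; offending: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
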