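#' SNP quality filters
#'
#' Retains SNPs with minor allele frequency >= `maf_min`, call rate meeting
#' `call_rate_req` and a Hardy-Weinberg equilibrium p-value >= `hwe_p_min`
#' (both boundaries inclusive). HWE is a 1-df chi-square test on hard-call
#' genotype counts; fractional (imputed) dosages are rounded to the nearest
#' integer genotype for the counts, with a warning when more than 5% of
#' dosages lie further than 0.1 from an integer.
#'
#' @param geno a [GenotypeDosageMatrix] (may contain `NA` only if
#'   `call_rate_req < 1`).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-4).
#' @param call_rate_req required call rate (default 1).
#' @return character vector of retained SNP IDs; per-SNP statistics in
#'   `attr(, "stats")`.
#' @export
snp_filters <- function(geno, maf_min = 0.01, hwe_p_min = 1e-4,
                        call_rate_req = 1.0) {
  d <- geno$dosages
  hard <- round(d)
  frac_off <- mean(abs(d - hard) > 0.1, na.rm = TRUE)
  if (is.finite(frac_off) && frac_off > 0.05)
    warning(sprintf("%.1f%% of dosages deviate > 0.1 from hard calls; HWE uses rounded genotypes",
                    100 * frac_off))
  stats_df <- data.frame(snp_id = rownames(d),
                         call_rate = rowMeans(!is.na(d)),
                         maf = NA_real_, hwe_p = NA_real_)
  for (i in seq_len(nrow(d))) {
    gi <- hard[i, !is.na(hard[i, ])]
    n <- length(gi)
    if (!n) next
    p_alt <- sum(gi) / (2 * n)
    stats_df$maf[i] <- min(p_alt, 1 - p_alt)
    n_aa <- sum(gi == 0); n_ab <- sum(gi == 1); n_bb <- sum(gi == 2)
    stats_df$hwe_p[i] <- hwe_chisq_p(n_aa, n_ab, n_bb)
  }
  keep <- stats_df$call_rate >= call_rate_req &
    !is.na(stats_df$maf) & stats_df$maf >= maf_min &
    !is.na(stats_df$hwe_p) & stats_df$hwe_p >= hwe_p_min
  out <- stats_df$snp_id[keep]
  attr(out, "stats") <- stats_df
  out
}

# 1-df chi-square HWE test on genotype counts.
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  p <- (2 * n_bb + n_ab) / (2 * n)
  q <- 1 - p
  exp_cnt <- n * c(q^2, 2 * p * q, p^2)
  obs <- c(n_aa, n_ab, n_bb)
  if (any(exp_cnt == 0)) return(1)  # monomorphic: trivially in HWE
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Feature position table
#'
#' 1-based inclusive coordinates (documented explicitly: not BED's 0-based
#' half-open convention). For SNPs, `start == end`.
#'
#' @param feature_id,chromosome,start,end vectors of equal length.
#' @return a validated data.frame of class `FeaturePositions`.
#' @export
FeaturePositions <- function(feature_id, chromosome, start, end = start) {
  df <- data.frame(feature_id = as.character(feature_id),
                   chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$chromosome))) stop("empty chromosome name")
  if (any(df$start > df$end)) stop("start must be <= end")
  if (anyDuplicated(df$feature_id)) stop("duplicated feature IDs")
  class(df) <- c("FeaturePositions", "data.frame")
  df
}

#' Candidate cis SNP-gene pairs
#'
#' Pairs every SNP with every gene on the same chromosome whose center
#' (floor of the span midpoint) lies within `window` base pairs of the SNP,
#' boundary inclusive.
#'
#' @param snps,genes `FeaturePositions` tables.
#' @param window window half-width in bp (default 250000).
#' @return data.frame with `snp_id`, `gene_id`, `distance`.
#' @export
cis_pairs <- function(snps, genes, window = 250000) {
  genes <- as.data.frame(genes)
  snps <- as.data.frame(snps)
  genes$center <- floor((genes$start + genes$end) / 2)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    same <- snps[snps$chromosome == genes$chromosome[i], , drop = FALSE]
    if (!nrow(same)) return(NULL)
    dist <- abs(same$start - genes$center[i])
    hit <- dist <= window
    if (!any(hit)) return(NULL)
    data.frame(snp_id = same$feature_id[hit], gene_id = genes$feature_id[i],
               distance = dist[hit], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$snp_id), , drop = FALSE]
}

#' Minimal cis-eQTL mapping
#'
#' Simple per-pair linear regression of expression on dosage, BH FDR over
#' all tested pairs, and per gene the smallest-p significant SNP as the
#' "top effect". This is a deliberately minimal stand-in for a production
#' eQTL pipeline, sufficient to generate top-effect lists on synthetic data.
#'
#' @param expr an [ExpressionMatrix] (any state; typically corrected).
#' @param geno a [GenotypeDosageMatrix], pre-filtered with [snp_filters()].
#' @param pairs data.frame with `snp_id`, `gene_id`.
#' @param fdr_alpha significance threshold on BH FDR (default 0.05).
#' @return list with `pairs` (beta, t, p, fdr per pair) and `top_effects`
#'   (one row per gene with a significant eQTL).
#' @export
map_cis_eqtls <- function(expr, geno, pairs, fdr_alpha = 0.05) {
  samples <- intersect(colnames(expr$values), colnames(geno$dosages))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  pairs <- unique(as.data.frame(pairs)[, c("snp_id", "gene_id")])
  keep <- pairs$gene_id %in% rownames(expr$values) &
    pairs$snp_id %in% rownames(geno$dosages)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) stop("no testable pairs")
  n <- length(samples)
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    y <- expr$values[pairs$gene_id[i], samples]
    g <- geno$dosages[pairs$snp_id[i], samples]
    vg <- stats::var(g)
    if (vg == 0) return(c(NA, NA, NA))
    beta <- stats::cov(g, y) / vg
    a <- mean(y) - beta * mean(g)
    rss <- sum((y - a - beta * g)^2)
    se <- sqrt(rss / (n - 2) / ((n - 1) * vg))
    t <- beta / se
    c(beta, t, 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
  }, numeric(3))
  pairs$beta <- res[1, ]; pairs$t <- res[2, ]; pairs$p <- res[3, ]
  pairs <- pairs[!is.na(pairs$p), , drop = FALSE]
  pairs$fdr <- stats::p.adjust(pairs$p, method = "BH")
  sig <- pairs[pairs$fdr <= fdr_alpha, , drop = FALSE]
  top <- if (nrow(sig)) {
    sig <- sig[order(sig$gene_id, sig$p, sig$snp_id), , drop = FALSE]
    sig[!duplicated(sig$gene_id), , drop = FALSE]
  } else sig
  list(pairs = pairs, top_effects = top)
}
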