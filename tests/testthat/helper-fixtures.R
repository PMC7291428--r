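# Small in-code fixtures shared across test files.

mk_expr <- function(values, state = "raw_counts", genes = NULL,
                    samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% rownames(values) %||%
    paste0("g", seq_len(nrow(values)))
  colnames(values) <- samples %||% colnames(values) %||%
    paste0("s", seq_len(ncol(values)))
  ExpressionMatrix(values, state = state)
}

mk_props <- function(values, kind = "measured", samples = NULL,
                     cell_types = NULL) {
  values <- as.matrix(values)
  rownames(values) <- samples %||% rownames(values) %||%
    paste0("s", seq_len(nrow(values)))
  colnames(values) <- cell_types %||% colnames(values) %||%
    paste0("ct", seq_len(ncol(values)))
  CellQuantMatrix(values, kind = kind)
}

mk_geno <- function(values, snps = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- snps %||% rownames(values) %||%
    paste0("snp", seq_len(nrow(values)))
  colnames(values) <- samples %||% colnames(values) %||%
    paste0("s", seq_len(ncol(values)))
  GenotypeDosageMatrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random small interaction-model instance; returns the pieces plus the
# hand-built design matrix for oracle solvers.
random_interaction_instance <- function(n, k, seed) {
  set.seed(seed)
  conc <- stats::runif(k, 1, 10)
  gm <- matrix(stats::rgamma(n * k, shape = rep(conc, each = n)), n, k)
  cvals <- gm / rowSums(gm) * 100
  colnames(cvals) <- paste0("ct", seq_len(k))
  rownames(cvals) <- paste0("s", seq_len(n))
  g <- stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5))
  y <- stats::rnorm(n, mean = drop(cvals %*% stats::runif(k, 0.5, 1.5)),
                    sd = stats::runif(1, 0.5, 5))
  enc <- stats::runif(k) < 0.3
  if (sum(enc) > 1 && sum(!enc) > 1) enc[] <- FALSE  # keep it a legal encoding
  X <- cbind(cvals, vapply(seq_len(k), function(j)
    (if (enc[j]) 2 - g else g) * cvals[, j], numeric(n)))
  list(y = y, g = g, cvals = cvals, encoding = enc, X = X)
}
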