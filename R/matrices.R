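#' Expression matrix container
#'
#' A light S3 container for a genes x samples expression matrix that records
#' its normalization state so downstream consumers can verify they receive the
#' preparation they expect (`"tmm_log2_scaled"` for cell-proportion modelling,
#' `"corrected_linear"` for eQTL deconvolution).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Dimnames
#'   are taken as gene and sample identifiers and must be unique.
#' @param state one of `"raw_counts"`, `"tmm"`, `"tmm_log2"`,
#'   `"tmm_log2_scaled"`, `"corrected_linear"`.
#' @param norm_factors optional per-sample TMM scaling factors.
#' @param zero_variance_genes optional character vector of genes flagged as
#'   constant during scaling (kept in the matrix, excluded from training).
#' @return an `ExpressionMatrix` object.
#' @export
ExpressionMatrix <- function(values, state = "raw_counts",
                             norm_factors = NULL,
                             zero_variance_genes = character(0)) {
  states <- c("raw_counts", "tmm", "tmm_log2", "tmm_log2_scaled",
              "corrected_linear")
  state <- match.arg(state, states)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (state %in% c("raw_counts", "tmm", "corrected_linear") &&
      any(values < 0))
    stop("state '", state, "' requires non-negative values")
  structure(list(values = values, state = state,
                 norm_factors = norm_factors,
                 zero_variance_genes = zero_variance_genes),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  if (length(x$zero_variance_genes))
    cat(sprintf("  %d zero-variance genes flagged\n",
                length(x$zero_variance_genes)))
  invisible(x)
}

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

stopifnot_state <- function(expr, state) {
  if (!inherits(expr, "ExpressionMatrix"))
    stop("expected an ExpressionMatrix")
  if (!expr$state %in% state)
    stop("expected expression state ", paste(state, collapse = "/"),
         ", got '", expr$state, "'")
  invisible(expr)
}

#' Cell quantification matrix container
#'
#' Samples x cell types matrix of measured (FACS-like counts or percentages)
#' or predicted cell proportions.
#'
#' @param values numeric matrix, samples in rows, cell types in columns, with
#'   dimnames.
#' @param kind `"measured"` or `"predicted"`.
#' @return a `CellQuantMatrix` object.
#' @export
CellQuantMatrix <- function(values, kind = c("measured", "predicted")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("cell quantities must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("cell quantification matrix requires sample rownames and cell-type colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicated sample or cell-type IDs")
  if (anyNA(values)) stop("cell quantification matrix contains missing values")
  if (kind == "measured" && any(values < 0))
    stop("measured cell quantities must be non-negative")
  structure(list(values = values, kind = kind), class = "CellQuantMatrix")
}

#' @export
print.CellQuantMatrix <- function(x, ...) {
  cat(sprintf("CellQuantMatrix: %d samples x %d cell types [%s]\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Genotype dosage matrix container
#'
#' SNPs x samples dosages on the usual 0..2 scale (hard calls or imputed).
#'
#' @param dosages numeric matrix, SNPs in rows, samples in columns, with
#'   dimnames; all values in `[0, 2]`.
#' @return a `GenotypeDosageMatrix` object.
#' @export
GenotypeDosageMatrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix requires SNP rownames and sample colnames")
  if (anyDuplicated(rownames(dosages)) || anyDuplicated(colnames(dosages)))
    stop("duplicated SNP or sample IDs")
  if (anyNA(dosages)) stop("dosage matrix contains missing values")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  structure(list(dosages = dosages), class = "GenotypeDosageMatrix")
}

#' @export
print.GenotypeDosageMatrix <- function(x, ...) {
  cat(sprintf("GenotypeDosageMatrix: %d SNPs x %d samples\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Covariate table container
#'
#' Per-sample covariates (cohort, age, sex, technical metrics, ...) used for
#' expression correction on the eQTL path. Categorical columns may be
#' character or factor; they are dummy-encoded at model time.
#'
#' @param df data.frame with a `sample_id` column (or rownames) and one column
#'   per covariate.
#' @return a `CovariateTable` object.
#' @export
CovariateTable <- function(df) {
  df <- as.data.frame(df)
  if ("sample_id" %in% names(df)) {
    ids <- as.character(df$sample_id)
    df <- df[setdiff(names(df), "sample_id")]
  } else if (!is.null(rownames(df))) {
    ids <- rownames(df)
  } else stop("covariate table requires a sample_id column or rownames")
  if (anyDuplicated(ids)) stop("duplicated sample IDs in covariate table")
  rownames(df) <- ids
  structure(list(sample_ids = ids, covariates = df), class = "CovariateTable")
}

#' @export
print.CovariateTable <- function(x, ...) {
  cat(sprintf("CovariateTable: %d samples x %d covariates (%s)\n",
              length(x$sample_ids), ncol(x$covariates),
              paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

# Align a covariate table to an expression matrix's samples; reject missing.
align_covariates <- function(covs, samples) {
  miss <- setdiff(samples, covs$sample_ids)
  if (length(miss))
    stop("samples without covariates: ", paste(miss, collapse = ", "))
  df <- covs$covariates[match(samples, covs$sample_ids), , drop = FALSE]
  if (anyNA(df))
    stop("missing covariate values after alignment for columns: ",
         paste(names(df)[vapply(df, anyNA, logical(1))], collapse = ", "))
  rownames(df) <- samples
  df
}
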