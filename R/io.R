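#' Read a typed matrix from TSV
#'
#' Canonical tabular layout: first column the row identifier, header row the
#' column identifiers, tab-separated numeric body, '.' decimal separator,
#' gzip-transparent. Orientation and validation depend on `kind`:
#' `expression` (genes x samples), `genotype` (SNPs x samples, values in
#' `[0, 2]`), `proportions` (samples x cell types), `covariates` (samples x
#' covariates, mixed types allowed). Missing values are rejected for all
#' numeric kinds.
#'
#' @param path TSV file path.
#' @param kind one of `"expression"`, `"genotype"`, `"proportions"`,
#'   `"covariates"`.
#' @param state expression state recorded on the returned
#'   [ExpressionMatrix] (default `"raw_counts"`).
#' @param prop_kind `"measured"` or `"predicted"` for proportions.
#' @return the matching container object.
#' @export
read_matrix <- function(path, kind = c("expression", "genotype",
                                       "proportions", "covariates"),
                        state = "raw_counts",
                        prop_kind = c("measured", "predicted")) {
  kind <- match.arg(kind)
  prop_kind <- match.arg(prop_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (ncol(dt) < 2) stop("malformed table (need id column + data): ", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicated IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- dt[, -1, drop = FALSE]
  if (kind == "covariates") {
    rownames(body) <- ids
    return(CovariateTable(body))
  }
  # an all-NA column is type-guessed as logical; treat it as numeric NA so
  # the missing-value check reports it properly
  body[] <- lapply(body, function(col) if (is.logical(col)) as.numeric(col)
                   else col)
  bad <- which(!vapply(body, is.numeric, TRUE))
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(body)[bad], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  na_rows <- which(rowSums(is.na(m)) > 0)
  if (length(na_rows))
    stop("missing values in ", path, " (first at data row ", na_rows[1], ")")
  switch(kind,
         expression = ExpressionMatrix(m, state = state),
         genotype = GenotypeDosageMatrix(m),
         proportions = CellQuantMatrix(m, kind = prop_kind))
}

#' Write a matrix container to TSV
#'
#' Inverse of [read_matrix()]: first column the row identifier (named by
#' `id_col`), then one column per sample/cell type/covariate.
#'
#' @param x an [ExpressionMatrix], [CellQuantMatrix],
#'   [GenotypeDosageMatrix], `ScaledProportions`, data.frame or matrix.
#' @param path output path.
#' @param id_col name for the identifier column.
#' @export
write_matrix <- function(x, path, id_col = NULL) {
  m <- if (inherits(x, "ExpressionMatrix")) x$values
  else if (inherits(x, "CellQuantMatrix")) x$values
  else if (inherits(x, "ScaledProportions")) x$values
  else if (inherits(x, "GenotypeDosageMatrix")) x$dosages
  else x
  if (is.null(id_col))
    id_col <- if (inherits(x, "ExpressionMatrix")) "gene_id"
  else if (inherits(x, "GenotypeDosageMatrix")) "snp_id"
  else if (inherits(x, c("CellQuantMatrix", "ScaledProportions"))) "sample_id"
  else "id"
  if (is.data.frame(m)) {
    data.table::fwrite(m, path, sep = "\t")
    return(invisible(path))
  }
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Extracts the DS (dosage) FORMAT field when present; otherwise falls back
#' to GT hard calls coded as the count of alternate alleles (0/1/2).
#' Requires the VariantAnnotation package.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [GenotypeDosageMatrix].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    d <- gen$DS
    mode(d) <- "numeric"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    d <- matrix(vapply(gt, function(s) {
      if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  } else stop("VCF has neither DS nor GT genotype fields")
  GenotypeDosageMatrix(d)
}

#' Save / load signature models
#'
#' One JSON bundle holding, per cell type, the nonzero gene coefficients and
#' training metadata (mixing parameter, penalty, seed, CV error).
#'
#' @param models list of `SignatureModel` objects.
#' @param path JSON file path.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "SignatureModel")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(cell_type = m$cell_type,
         intercept = m$intercept,
         alpha = m$alpha, penalty = m$penalty, seed = m$seed,
         cv_mse = m$cv_mse, n_samples = m$n_samples,
         genes = names(m$gene_coefficients),
         coefficients = unname(m$gene_coefficients))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @return `read_models()`: a list of `SignatureModel` objects.
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(m) {
    structure(list(cell_type = m$cell_type,
                   gene_coefficients = stats::setNames(
                     as.numeric(m$coefficients), unlist(m$genes)),
                   intercept = m$intercept, alpha = m$alpha,
                   penalty = m$penalty, seed = m$seed, cv_mse = m$cv_mse,
                   n_samples = m$n_samples),
              class = "SignatureModel")
  })
}
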