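#' Simulation configuration
#'
#' Bundles the stated world of the synthetic generator: Hardy-Weinberg
#' genotypes at a given MAF, Dirichlet cell proportions with a
#' granulocyte-dominant default panel (granulocytes are roughly 70% of
#' circulating white blood cells), per-cell-type proportion effects of order
#' 1, optional cell-type-restricted genotype interaction effects, and
#' Gaussian noise on the linear scale (matching the least-squares model).
#'
#' @param n_samples number of individuals (default 500).
#' @param n_genes number of genes (default 100).
#' @param n_snps number of SNPs (default `n_genes`; gene i is paired with
#'   SNP `(i - 1) %% n_snps + 1`).
#' @param concentrations named Dirichlet concentration vector; names are the
#'   cell-type panel. Default: the six-type blood panel
#'   `c(granulocyte = 70, monoCD14 = 15, CD4T = 6, CD8T = 5, B = 3, NK = 1)`.
#' @param maf minor allele frequency, recycled over SNPs (default 0.3).
#' @param betas optional `n_genes x k` matrix of per-cell-type proportion
#'   effects; default drawn U(0.5, 1.5) from the seed.
#' @param effects optional data.frame `gene`, `snp`, `cell_type`, `gamma`
#'   giving genotype interaction effects (negative gamma means the effect
#'   runs through the swapped encoding with magnitude `|gamma|`).
#' @param n_effect_genes shorthand when `effects` is `NULL`: this many genes
#'   (from the first) get `effect_gamma` in cycling cell types; default 0.
#' @param effect_gamma interaction effect size for the shorthand (default
#'   0.5).
#' @param effect_cell_type optional single cell type for the shorthand
#'   (default: cycle over the panel).
#' @param noise_sd noise level (default 0.1).
#' @param noise_mode `"relative"` (default; `noise_sd` is a fraction of each
#'   gene's noiseless signal standard deviation) or `"absolute"`.
#' @param seed master seed (all draws derive from it).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 500, n_genes = 100,
                              n_snps = n_genes,
                              concentrations = c(granulocyte = 70,
                                                 monoCD14 = 15, CD4T = 6,
                                                 CD8T = 5, B = 3, NK = 1),
                              maf = 0.3, betas = NULL, effects = NULL,
                              n_effect_genes = 0, effect_gamma = 0.5,
                              effect_cell_type = NULL,
                              noise_sd = 0.1,
                              noise_mode = c("relative", "absolute"),
                              seed = 1) {
  noise_mode <- match.arg(noise_mode)
  if (is.null(names(concentrations)))
    names(concentrations) <- paste0("ct", seq_along(concentrations))
  if (any(concentrations <= 0)) stop("Dirichlet concentrations must be > 0")
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  k <- length(concentrations)
  cts <- names(concentrations)
  if (is.null(effects) && n_effect_genes > 0) {
    idx <- seq_len(min(n_effect_genes, n_genes))
    ct <- if (is.null(effect_cell_type)) cts[(idx - 1) %% k + 1]
          else rep(effect_cell_type, length(idx))
    effects <- data.frame(gene = paste0("gene", idx),
                          snp = paste0("snp", (idx - 1) %% n_snps + 1),
                          cell_type = ct, gamma = effect_gamma)
  }
  structure(list(n_samples = n_samples, n_genes = n_genes, n_snps = n_snps,
                 concentrations = concentrations, cell_types = cts,
                 maf = maf, betas = betas, effects = effects,
                 noise_sd = noise_sd, noise_mode = noise_mode,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Hard-call dosages drawn Binomial(2, maf) per SNP, independent across
#' samples (no LD).
#'
#' @param n number of samples.
#' @param maf_vector per-SNP minor allele frequencies in (0, 0.5].
#' @param seed integer seed.
#' @return a [GenotypeDosageMatrix] (SNPs x samples).
#' @export
simulate_genotypes <- function(n, maf_vector, seed = 1) {
  if (any(maf_vector <= 0 | maf_vector > 0.5))
    stop("maf must lie in (0, 0.5]")
  set.seed(seed)
  d <- t(vapply(maf_vector, function(m) stats::rbinom(n, 2, m),
                numeric(n)))
  dimnames(d) <- list(paste0("snp", seq_along(maf_vector)),
                      paste0("sample", seq_len(n)))
  GenotypeDosageMatrix(d)
}

#' Simulate Dirichlet cell proportions
#'
#' Dirichlet draws scaled to percentages (rows sum to exactly 100). The
#' concentration vector sets both the mean composition and how strongly the
#' cell types covary (compositional closure makes the dominant type
#' anti-correlated with the rest).
#'
#' @param n number of samples.
#' @param concentrations positive named concentration vector.
#' @param seed integer seed.
#' @return a [CellQuantMatrix] (measured kind, samples x cell types).
#' @export
simulate_proportions <- function(n, concentrations, seed = 1) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (is.null(names(concentrations)))
    names(concentrations) <- paste0("ct", seq_along(concentrations))
  set.seed(seed)
  k <- length(concentrations)
  gm <- matrix(stats::rgamma(n * k, shape = rep(concentrations, each = n)),
               n, k)
  pr <- gm / rowSums(gm) * 100
  dimnames(pr) <- list(paste0("sample", seq_len(n)), names(concentrations))
  CellQuantMatrix(pr, kind = "measured")
}

#' Simulate bulk expression with cell-type-restricted genotype effects
#'
#' Generates, per gene, the proportion-weighted mixture
#' `y_j = sum_k c_jk beta_k + sum_k gamma_k g_enc,j c_jk + e_j` on the
#' corrected linear scale — exactly the data-generating form the
#' deconvolution model assumes — plus Gaussian noise. Negative implied
#' expression is clipped at 0 with a logged count.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` ([ExpressionMatrix], `corrected_linear`), `geno`
#'   ([GenotypeDosageMatrix]), `props` ([CellQuantMatrix], measured),
#'   `pairs` (the gene-SNP map), and `truth` (a `SyntheticTruth` list:
#'   realized betas, gammas, encodings, proportions, noise, seed).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_samples; k <- length(config$cell_types)
  geno <- simulate_genotypes(n, config$maf, seed = config$seed + 11L)
  props <- simulate_proportions(n, config$concentrations,
                                seed = config$seed + 29L)
  cvals <- props$values
  genes <- paste0("gene", seq_len(config$n_genes))
  snp_of <- paste0("snp", (seq_len(config$n_genes) - 1L) %% config$n_snps + 1L)
  set.seed(config$seed + 47L)
  betas <- config$betas
  if (is.null(betas))
    betas <- matrix(stats::runif(config$n_genes * k, 0.5, 1.5),
                    config$n_genes, k)
  dimnames(betas) <- list(genes, config$cell_types)
  gammas <- matrix(0, config$n_genes, k, dimnames = dimnames(betas))
  swapped <- matrix(FALSE, config$n_genes, k, dimnames = dimnames(betas))
  if (!is.null(config$effects)) {
    ef <- config$effects
    for (i in seq_len(nrow(ef))) {
      gammas[ef$gene[i], ef$cell_type[i]] <- abs(ef$gamma[i])
      swapped[ef$gene[i], ef$cell_type[i]] <- ef$gamma[i] < 0
      if (snp_of[match(ef$gene[i], genes)] != ef$snp[i])
        snp_of[match(ef$gene[i], genes)] <- ef$snp[i]
    }
  }
  set.seed(config$seed + 63L)
  vals <- matrix(NA_real_, config$n_genes, n,
                 dimnames = list(genes, rownames(cvals)))
  n_clipped <- 0L
  for (i in seq_len(config$n_genes)) {
    g <- geno$dosages[snp_of[i], ]
    y0 <- drop(cvals %*% betas[i, ])
    for (j in seq_len(k)) {
      if (gammas[i, j] == 0) next
      ge <- if (swapped[i, j]) 2 - g else g
      y0 <- y0 + gammas[i, j] * ge * cvals[, j]
    }
    sd_i <- if (config$noise_mode == "relative") {
      s <- stats::sd(y0)
      config$noise_sd * (if (s > 0) s else max(mean(y0), 1))
    } else config$noise_sd
    y <- y0 + stats::rnorm(n, sd = sd_i)
    n_clipped <- n_clipped + sum(y < 0)
    vals[i, ] <- pmax(y, 0)
  }
  if (n_clipped > 0)
    message("simulate_bulk: clipped ", n_clipped,
            " negative expression values at 0")
  truth <- structure(list(betas = betas, gammas = gammas, swapped = swapped,
                          proportions = cvals, snp_of = stats::setNames(snp_of, genes),
                          noise_sd = config$noise_sd,
                          noise_mode = config$noise_mode,
                          seed = config$seed),
                     class = "SyntheticTruth")
  list(expr = ExpressionMatrix(vals, state = "corrected_linear"),
       geno = geno, props = props,
       pairs = data.frame(snp_id = snp_of, gene_id = genes,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a paired FACS-training dataset
#'
#' Emulates a cohort with both bulk RNA-seq counts and flow-cytometric cell
#' quantification. Each mixture cell type is given a sparse set of signature
#' genes whose bulk counts increase with the cell type's proportion;
#' remaining genes are background with constant expected counts.
#' Multiplicative lognormal noise (`noise_sd` on the log2 scale) models
#' measurement variability; `noise_sd = 0` gives exact counts. Cell types
#' listed in `signature_free` are measured subpopulations with no bulk
#' transcriptional footprint: their "proportions" are drawn independently of
#' the mixture (emulating rare FACS subpopulations that bulk expression
#' cannot predict).
#'
#' @param n_samples number of samples (default 120).
#' @param concentrations Dirichlet concentrations for the mixture cell types
#'   (default: the six-type blood panel).
#' @param n_signature signature genes per mixture cell type, recycled
#'   (default 5; a 0 entry makes that cell type signature-free as well).
#' @param n_background background genes (default 100).
#' @param signature_free names of extra measured cell types with independent
#'   proportions and no signature (default none).
#' @param depth library-depth scale for expected counts (default 1000).
#' @param noise_sd log2-scale multiplicative noise sd (default 0.05).
#' @param facs_noise_sd absolute Gaussian noise on measured percentages
#'   (default 0: measured = true proportions).
#' @param seed integer seed.
#' @return list with `expr` ([ExpressionMatrix], `raw_counts`), `counts`
#'   ([CellQuantMatrix], measured), and `truth` (signature gene sets, slopes,
#'   true proportions, seed).
#' @export
simulate_facs_training <- function(n_samples = 120,
                                   concentrations = c(granulocyte = 70,
                                                      monoCD14 = 15,
                                                      CD4T = 6, CD8T = 5,
                                                      B = 3, NK = 1),
                                   n_signature = 5, n_background = 100,
                                   signature_free = character(0),
                                   depth = 1000, noise_sd = 0.05,
                                   facs_noise_sd = 0, seed = 1) {
  props <- simulate_proportions(n_samples, concentrations, seed = seed + 101L)
  cvals <- props$values
  cts <- colnames(cvals)
  n_signature <- rep_len(n_signature, length(cts))
  set.seed(seed + 137L)
  sig_genes <- list(); mu_rows <- list(); slopes <- list()
  for (ki in seq_along(cts)) {
    if (n_signature[ki] == 0) { sig_genes[[cts[ki]]] <- character(0); next }
    gnames <- sprintf("sig_%s_%d", cts[ki], seq_len(n_signature[ki]))
    sl <- stats::runif(n_signature[ki], 2, 5)
    base <- stats::runif(n_signature[ki], 0.02, 0.1)
    mu <- depth * (outer(base, rep(1, n_samples)) +
                     outer(sl, cvals[, ki] / 100))
    rownames(mu) <- gnames
    sig_genes[[cts[ki]]] <- gnames
    slopes[[cts[ki]]] <- stats::setNames(sl, gnames)
    mu_rows[[length(mu_rows) + 1]] <- mu
  }
  if (n_background > 0) {
    bnames <- sprintf("bg_%d", seq_len(n_background))
    bbase <- stats::runif(n_background, 0.2, 2)
    mu <- depth * outer(bbase, rep(1, n_samples))
    rownames(mu) <- bnames
    mu_rows[[length(mu_rows) + 1]] <- mu
  }
  mu_all <- do.call(rbind, mu_rows)
  colnames(mu_all) <- rownames(cvals)
  set.seed(seed + 151L)
  counts <- if (noise_sd > 0)
    mu_all * 2^matrix(stats::rnorm(length(mu_all), sd = noise_sd),
                      nrow(mu_all))
  else mu_all
  measured <- cvals
  if (length(signature_free)) {
    set.seed(seed + 163L)
    extra <- vapply(signature_free, function(ct)
      100 * stats::rbeta(n_samples, 2, 50), numeric(n_samples))
    colnames(extra) <- signature_free
    measured <- cbind(measured, extra)
    sig_genes[signature_free] <- replicate(length(signature_free),
                                           character(0), simplify = FALSE)
  }
  if (facs_noise_sd > 0) {
    set.seed(seed + 177L)
    measured <- pmax(measured + matrix(stats::rnorm(length(measured),
                                                    sd = facs_noise_sd),
                                       nrow(measured)), 0)
  }
  list(expr = ExpressionMatrix(counts, state = "raw_counts"),
       counts = CellQuantMatrix(measured, kind = "measured"),
       truth = list(signature_genes = sig_genes, slopes = slopes,
                    proportions = cvals, noise_sd = noise_sd, seed = seed))
}
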