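#' Write a complete simulated dataset to disk
#'
#' Generates one coherent synthetic world and writes every artifact the
#' pipeline consumes as plain TSV/JSON: a training cohort with paired bulk
#' counts and measured cell proportions, a larger bulk cohort whose
#' expression contains both the same signature genes (so trained models can
#' predict its cell proportions) and eQTL genes following the
#' genotype-by-proportion interaction model, genotype dosages, SNP/gene
#' positions (SNPs placed at their gene's center) and the ground truth.
#'
#' @param outdir output directory (created if needed).
#' @param config a [simulation_config()] for the bulk/eQTL cohort.
#' @param n_train training-cohort size (default 120).
#' @param n_signature signature genes per cell type (default 5).
#' @param n_background background genes (default 100).
#' @param facs_noise_sd,train_noise_sd noise settings for the training
#'   cohort (defaults 0 and 0.05).
#' @return invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(outdir, config = simulation_config(),
                             n_train = 120, n_signature = 5,
                             n_background = 100, facs_noise_sd = 0,
                             train_noise_sd = 0.05) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  facs <- simulate_facs_training(n_samples = n_train,
                                 concentrations = config$concentrations,
                                 n_signature = n_signature,
                                 n_background = n_background,
                                 noise_sd = train_noise_sd,
                                 facs_noise_sd = facs_noise_sd,
                                 seed = seed + 1000L)
  bulk <- simulate_bulk(config)
  # signature/background genes for the bulk cohort: same slopes and bases as
  # the training world, driven by the bulk cohort's own proportions
  set.seed(seed + 137L + 1000L)   # replay the training gene parameters
  cts <- config$cell_types
  cvals <- bulk$props$values
  nb <- nrow(cvals)
  sig_rows <- list()
  for (ki in seq_along(cts)) {
    nsig <- rep_len(n_signature, length(cts))[ki]
    if (nsig == 0) next
    gnames <- sprintf("sig_%s_%d", cts[ki], seq_len(nsig))
    sl <- stats::runif(nsig, 2, 5)
    base <- stats::runif(nsig, 0.02, 0.1)
    mu <- 1000 * (outer(base, rep(1, nb)) + outer(sl, cvals[, ki] / 100))
    rownames(mu) <- gnames
    sig_rows[[length(sig_rows) + 1]] <- mu
  }
  if (n_background > 0) {
    bnames <- sprintf("bg_%d", seq_len(n_background))
    bbase <- stats::runif(n_background, 0.2, 2)
    mu <- 1000 * outer(bbase, rep(1, nb))
    rownames(mu) <- bnames
    sig_rows[[length(sig_rows) + 1]] <- mu
  }
  set.seed(seed + 2000L)
  sig_mat <- do.call(rbind, sig_rows)
  colnames(sig_mat) <- rownames(cvals)
  if (train_noise_sd > 0)
    sig_mat <- sig_mat * 2^matrix(stats::rnorm(length(sig_mat),
                                               sd = train_noise_sd),
                                  nrow(sig_mat))
  bulk_mat <- rbind(sig_mat, bulk$expr$values)
  # positions: gene i centered at i * 600 kb on chr1, its SNP at the center
  genes <- bulk$pairs$gene_id
  centers <- seq_along(genes) * 600000L
  gene_pos <- data.frame(feature_id = genes, chromosome = "1",
                         start = centers - 500L, end = centers + 500L)
  snp_ids <- rownames(bulk$geno$dosages)
  first_gene_of_snp <- vapply(snp_ids, function(s)
    centers[match(s, bulk$pairs$snp_id)], numeric(1))
  first_gene_of_snp[is.na(first_gene_of_snp)] <- 0
  snp_pos <- data.frame(feature_id = snp_ids, chromosome = "1",
                        start = as.integer(first_gene_of_snp),
                        end = as.integer(first_gene_of_snp))
  paths <- list(
    facs_expr = file.path(outdir, "facs_expr.tsv"),
    facs_counts = file.path(outdir, "facs_counts.tsv"),
    bulk_expr = file.path(outdir, "bulk_expr.tsv"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    gene_pos = file.path(outdir, "gene_pos.tsv"),
    snp_pos = file.path(outdir, "snp_pos.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_matrix(facs$expr, paths$facs_expr)
  write_matrix(facs$counts, paths$facs_counts)
  write_matrix(ExpressionMatrix(bulk_mat, state = "raw_counts"),
               paths$bulk_expr)
  write_matrix(bulk$geno, paths$genotypes)
  write_matrix(gene_pos, paths$gene_pos)
  write_matrix(snp_pos, paths$snp_pos)
  tr <- bulk$truth
  nz <- which(tr$gammas != 0, arr.ind = TRUE)
  truth_json <- list(seed = seed,
                     cell_types = cts,
                     noise_sd = tr$noise_sd, noise_mode = tr$noise_mode,
                     effects = if (nrow(nz)) data.frame(
                       gene_id = rownames(tr$gammas)[nz[, 1]],
                       snp_id = unname(tr$snp_of[rownames(tr$gammas)[nz[, 1]]]),
                       cell_type = colnames(tr$gammas)[nz[, 2]],
                       gamma = tr$gammas[nz],
                       direction = ifelse(tr$swapped[nz], -1, 1))
                     else list())
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Run the full deconvolution pipeline
#'
#' Orchestrates the five stages — expression preparation, cell-proportion
#' model training and prediction, cis-eQTL mapping, eQTL deconvolution, and
#' evaluation against ground truth when available — over a simulated (or
#' equivalently laid out real) input directory. Every artifact is written to
#' `outdir` together with a manifest recording inputs, parameters, seed,
#' package version and per-stage status; the manifest contains no
#' timestamps, so reruns with the same seed are byte-identical.
#'
#' @param indir input directory with `facs_expr.tsv`, `facs_counts.tsv`,
#'   `bulk_expr.tsv`, `genotypes.tsv`, `snp_pos.tsv`, `gene_pos.tsv` and
#'   optionally `truth.json`.
#' @param outdir output directory.
#' @param seed master seed for the stochastic stages.
#' @param cell_types cell types to model (default: all columns of the
#'   training counts).
#' @param cv_iterations cross-validation iterations per cell type during
#'   training (default 0 = skip the repeated CV report and only fit the
#'   final models; the published procedure uses 100).
#' @param maf_min,hwe_p_min,window,fdr_alpha cis-mapping parameters with the
#'   standard defaults (0.01, 1e-4, 250 kb, 0.05).
#' @param signature_threshold stable-signature selection frequency cutoff
#'   (default 0.8), used when `cv_iterations > 0`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(indir, outdir, seed = 42, cell_types = NULL,
                         cv_iterations = 0, maf_min = 0.01,
                         hwe_p_min = 1e-4, window = 250000,
                         fdr_alpha = 0.05, signature_threshold = 0.8) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    inputs = list(indir = indir),
    parameters = list(seed = seed, cv_iterations = cv_iterations,
                      maf_min = maf_min, hwe_p_min = hwe_p_min,
                      window = window, fdr_alpha = fdr_alpha,
                      signature_threshold = signature_threshold),
    version = as.character(utils::packageVersion("decon2")),
    stages = list())
  finish <- function(stage, status) {
    manifest$stages[[stage]] <<- status
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, fn) {
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) { finish(stage, paste("failed:",
                                                             conditionMessage(e)))
                     stop("stage '", stage, "' failed: ",
                          conditionMessage(e), call. = FALSE) })
    if (ok) finish(stage, "completed")
  }

  env <- new.env()
  run_stage("prep", function() {
    facs_raw <- read_matrix(file.path(indir, "facs_expr.tsv"), "expression")
    bulk_raw <- read_matrix(file.path(indir, "bulk_expr.tsv"), "expression")
    env$facs_scaled <- zscale_genes(log2_plus_one(tmm_normalize(facs_raw)))
    env$bulk_scaled <- zscale_genes(log2_plus_one(tmm_normalize(bulk_raw)))
    env$bulk_corrected <- correct_and_exponentiate(bulk_raw, covs = NULL)
    write_matrix(env$facs_scaled, file.path(outdir, "prep_facs_scaled.tsv"))
    write_matrix(env$bulk_scaled, file.path(outdir, "prep_bulk_scaled.tsv"))
    write_matrix(env$bulk_corrected, file.path(outdir, "prep_bulk_corrected.tsv"))
  })

  run_stage("cell", function() {
    counts <- read_matrix(file.path(indir, "facs_counts.tsv"), "proportions")
    cts <- if (is.null(cell_types)) colnames(counts$values) else cell_types
    models <- list(); reports <- list()
    for (i in seq_along(cts)) {
      ct <- cts[i]
      models[[ct]] <- fit_elastic_net(env$facs_scaled, counts, ct,
                                      seed = seed + i)
      if (cv_iterations > 0)
        reports[[ct]] <- cross_validate(env$facs_scaled, counts, ct,
                                        n_iter = cv_iterations,
                                        seed = seed + 100 * i)
    }
    env$models <- models
    write_models(models, file.path(outdir, "models.json"))
    if (length(reports)) {
      cv_df <- data.frame(cell_type = names(reports),
                          mean_r = vapply(reports, `[[`, 0, "mean_r"),
                          predictable = vapply(reports, `[[`, TRUE,
                                               "predictable"))
      cv_df$n_signature_genes <- vapply(reports, function(r)
        length(select_signature_genes(r, signature_threshold)), 0L)
      write_matrix(cv_df, file.path(outdir, "crossval.tsv"))
    }
    env$predicted <- predict_proportions(models, env$bulk_scaled)
    write_matrix(env$predicted, file.path(outdir, "predicted_proportions.tsv"))
  })

  run_stage("cis", function() {
    geno <- read_matrix(file.path(indir, "genotypes.tsv"), "genotype")
    snp_pos <- data.table::fread(file.path(indir, "snp_pos.tsv"),
                                 data.table = FALSE)
    gene_pos <- data.table::fread(file.path(indir, "gene_pos.tsv"),
                                  data.table = FALSE)
    keep <- snp_filters(geno, maf_min = maf_min, hwe_p_min = hwe_p_min)
    geno$dosages <- geno$dosages[keep, , drop = FALSE]
    env$geno <- geno
    pairs <- cis_pairs(FeaturePositions(snp_pos[[1]], snp_pos[[2]],
                                        snp_pos[[3]], snp_pos[[4]]),
                       FeaturePositions(gene_pos[[1]], gene_pos[[2]],
                                        gene_pos[[3]], gene_pos[[4]]),
                       window = window)
    mapped <- map_cis_eqtls(env$bulk_corrected, geno, pairs,
                            fdr_alpha = fdr_alpha)
    env$top_effects <- mapped$top_effects
    write_matrix(mapped$pairs, file.path(outdir, "cis_all_pairs.tsv"))
    write_matrix(mapped$top_effects, file.path(outdir, "cis_top_effects.tsv"))
  })

  run_stage("eqtl", function() {
    if (!nrow(env$top_effects)) stop("no significant cis top effects")
    sp <- scale_proportions(env$predicted)
    res <- suppressMessages(deconvolute(env$top_effects, env$bulk_corrected,
                                        env$geno, sp))
    res <- fdr_per_celltype(res)
    env$decon <- res
    write_matrix(as.data.frame(res), file.path(outdir, "decon_results.tsv"))
  })

  run_stage("eval", function() {
    truth_path <- file.path(indir, "truth.json")
    report <- data.frame(cell_type = character(0), n_concordant = integer(0),
                         n_discordant = integer(0), rate = numeric(0))
    if (file.exists(truth_path)) {
      truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      eff <- truth$effects
      if (is.data.frame(eff) && nrow(eff)) {
        ref <- data.frame(snp_id = eff$snp_id, gene_id = eff$gene_id,
                          cell_type = eff$cell_type,
                          effect = eff$gamma * eff$direction)
        dirs <- decon_directions(env$decon)
        dirs <- dirs[paste(dirs$snp_id, dirs$gene_id, dirs$cell_type) %in%
                       paste(ref$snp_id, ref$gene_id, ref$cell_type), ,
                     drop = FALSE]
        if (nrow(dirs)) {
          cc <- allelic_concordance(dirs, ref)
          report <- data.frame(cell_type = "all",
                               n_concordant = cc$n_concordant,
                               n_discordant = cc$n_discordant,
                               rate = cc$rate)
        }
      }
    }
    write_matrix(report, file.path(outdir, "eval_concordance.tsv"))
  })

  invisible(manifest)
}
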