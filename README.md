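# decon2

Cell-type context for bulk blood transcriptomics: predict circulating
immune-cell proportions from whole-blood RNA-seq, then decompose bulk
cis-eQTL effects into cell-type interaction (CTi) eQTLs.

Whole-blood eQTL studies average over a mixture of immune cell populations,
hiding which cell type carries a regulatory effect. This package implements
a two-stage framework for recovering that context without cell sorting:

1. **Decon-cell** — elastic-net signature-gene models mapping TMM-normalized,
   log2, z-scaled bulk expression to measured (FACS) cell proportions, with
   repeated 70/30 cross-validation (100 iterations). A cell type is
   *predictable* when mean Spearman R ≥ 0.5; its *stable signature genes*
   are those selected in ≥ 80% of iterations.
2. **Decon-eQTL** — for each whole-blood eQTL (SNP, gene), fit the
   non-negative interaction model

   *y* = Σₖ βₖ·cₖ + Σₖ γₖ·g₍ₖ₎·cₖ + e

   by NNLS (no intercept, no genotype main effect; proportions cₖ rescaled
   to sum to 100 per sample). Allelic direction lives in the per-term
   genotype encoding g₍ₖ₎ ∈ {g, 2−g}, searched over the (2k)+2
   configurations with at most one term deviating from the majority. Each
   cell type's interaction is tested by full-vs-reduced ANOVA
   (F(1, n−2k)) with per-cell-type Benjamini–Hochberg FDR.

Also included: the covariate-correct-and-re-exponentiate expression
preparation, a minimal cis-eQTL mapper (MAF ≥ 0.01, call rate 1, HWE
p ≥ 1e-4, 250 kb window, FDR ≤ 0.05 top effects), the single-cell-type
interaction comparator (OLS + sign-restriction rule), validation statistics
(allelic concordance, Fisher tests, effect-size comparisons), and a fully
seeded synthetic-data generator with exported ground truth.

## Worked example

Simulate 500 individuals, six blood cell types (granulocyte-dominant
Dirichlet proportions), six genes of which three carry a cell-type-specific
interaction effect (γ = 0.5), then deconvolute:

```r
library(decon2)

cfg <- simulation_config(n_samples = 500, n_genes = 6, n_snps = 6,
                         n_effect_genes = 3, effect_gamma = 0.5, seed = 7)
sim <- simulate_bulk(cfg)
sp  <- scale_proportions(sim$props)
res <- fdr_per_celltype(deconvolute(sim$pairs, sim$expr, sim$geno, sp))
```

Per-cell-type interaction p-values (three shown) and the smallest FDR per
pair, as printed by the code above:

```
       pair    p_gran    p_mono    p_CD4T   fdr_min
 snp1/gene1 4.70e-207  5.88e-01  7.44e-01 2.82e-206
 snp2/gene2  1.11e-01 2.15e-217  5.07e-01 1.29e-216
 snp3/gene3  6.74e-01  4.68e-01 4.72e-267 2.83e-266
 snp4/gene4  4.49e-02  6.11e-01  1.09e-01  1.35e-01
 snp5/gene5  8.68e-01  1.00e+00  8.28e-01  8.28e-01
 snp6/gene6  8.52e-01  1.00e+00  1.62e-01  2.53e-01
```

The three simulated effects (gene1→granulocyte, gene2→monocyte,
gene3→CD4+ T, per `cfg$effects`) are each attributed to the correct cell
type at overwhelming significance, while the three null genes stay above
FDR 0.05 everywhere. Each row's `encoding_<ct>` column (not shown) records
whether the effect runs with the coded allele (`as-is`) or against it
(`swapped`) — with non-negative coefficients, that is where the allelic
direction lives.

## Command line

```sh
exec/decon2 simulate --out simdir --seed 1
exec/decon2 run --in simdir --out results --seed 42
exec/decon2 prep --counts expr.tsv --mode cell --out prep.tsv
exec/decon2 cell train --expr prep.tsv --counts facs.tsv --out models.json --seed 42
exec/decon2 eqtl --expr corrected.tsv --geno dosages.tsv --props predicted.tsv \
            --pairs top_effects.tsv --out decon_results.tsv
```

`run` executes prep → cell → cis → eqtl → eval and writes a manifest
(inputs, parameters, seed, per-stage status, no timestamps); reruns with the
same seed are byte-identical.

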