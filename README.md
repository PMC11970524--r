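# regRemodel

Comparative multi-omics analysis of how embryonic **diapause** — a
reversible state of suspended development — evolved in the African
turquoise killifish through **regulatory remodeling of ancient gene
duplicates**. The package is aimed at researchers in evolutionary and
regulatory genomics who want to run, adapt or audit this style of
analysis: paralog specialization calling, cross-species chromatin
conservation, binding-site evolution, transposable-element enrichment,
knockout program shifts and diapause lipidomics — each stage validated on
seeded synthetic data with planted ground truth.

## What it computes

**Paralog age and specialization.** Paralog pairs are binned by
duplication age (very ancient > 473.3 mya, ancient 111–473.3 mya,
recent/very recent ≤ 111 mya; families with > 20 partners filtered). A
pair is *diapause-specialized* when one gene is significantly up in a
diapause time point vs a development stage (BH FDR < 0.05) and its partner
is significantly down or has higher median expression in development than
in diapause. Age-bin enrichment of specialized pairs is tested against the
genome-wide expectation with an observed/expected ratio

    ratio(bin) = [ spec(bin) / spec(total) ] / [ n(bin) / n(total) ]

assessed over 10,000 half-subsample bootstraps and a 2×2 Pearson
chi-square (specialized × in-bin).

**Cross-species peak conservation.** Peaks are projected between genomes
through a colinear gapless alignment-block map (BED-convention, split
projections flagged), tagged conserved per species at relaxed / strict
(≥ 25% coverage) / very strict (≥ 50%) stringency, and classified
ancient/very ancient, recent, or very recent — with the outgroup exception
(present in zebrafish/medaka but absent in other African killifish still
counts as ancient). Includes the two-method diapause-specific peak rule,
nearest-TSS gene assignment and promoter/exon/intron/distal annotation.

**Binding-site evolution.** PWMs are scored as summed log-odds
`Σ log(p_i / 0.25)` against a uniform background with a stored detection
threshold, scanned on both strands. Focal sites are assessed per species as
conserved / not conserved / excluded (identical motif within a nearby
window) / alignment-absent, and classified mutation- vs TE-derived with the
four-way TE–motif co-conservation grid.

**TE enrichment.** Exact binomial tests of family containment in target
peaks against three backgrounds (genome, all chromatin, control loci
shifted 10 kb downstream), BH across families.

**Knockout program shifts.** Dual-control DEGs (FDR < 0.1 vs both scramble
and wildtype, concordant sign), then Spearman correlation between knockout
fold changes and the control diapause-vs-development program:
no-effect / enhanced / reversed. Two-way ANOVA (role × genotype) tests
whether knockout reduces paralog specialization.

**Lipidomics.** Lipid-name parsing, median normalization excluding TG/DG,
Welch + BH diapause-specific lipid calls, very-long-chain flags (≥ 22
carbon chains), class sums and fatty-acid composition with SFA/MUFA/PUFA
grouping.

## Worked example

Simulate a paralog universe with planted specialization (enriched twofold
in the very-ancient bin), run the classifier and the enrichment test:

```r
library(regRemodel)

u     <- genParalogUniverse(n_pairs = 1000, expression_noise_sd = 0.3, seed = 42)
pairs <- filterParalogFamilies(u$pairs)
de    <- differentialExpressionStandin(u$expression, u$design)
calls <- classifySpecialization(pairs, de, u$expression, u$design)
sum(calls$specialized)
#> [1] 208

bins <- assignAgeBin(pairs$duplication_age_mya)
enr  <- binEnrichment(bins, calls$specialized, n_boot = 2000, seed = 42)
enr$summary[, c("bin", "n_pairs_in_bin", "n_specialized_in_bin",
                "enrichment_ratio", "chi2_p")]
#>                  bin n_pairs_in_bin n_specialized_in_bin enrichment_ratio   chi2_p
#> 1       VERY_ANCIENT            200                   81            1.947 1.66e-14
#> 2            ANCIENT            300                   46            0.737 5.30e-03
#> 3 RECENT_VERY_RECENT            500                   81            0.779 3.38e-04

mean(calls$specialized == u$truth$specialized)
#> [1] 0.992
```

208 of 1000 pairs are called specialized (the generator planted 200, at a
log2 effect of 4 with replicate noise 0.3). The very-ancient bin holds its
planted ~2× excess of specialized pairs (ratio 1.95, chi-square
p ≈ 2e-14), while the other bins are correspondingly depleted — the same
observed/expected logic used on the real paralog tables. At zero noise the
classifier recovers the planted labels exactly (`truth recovery = 1`).

The full pipeline (simulate → validate → all six stages → manifest with
input/output hashes) runs with:

```r
manifest <- runPipeline(defaultPipelineConfig(outdir = "run1", seed = 1))
```

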