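# lofscape

Loss-of-function phenotype classification and regulatory integration for
tumor transcriptomes.

## The problem

In pancreatic ductal adenocarcinoma (and other tumors), loss of function
(LoF) of a lineage transcription factor such as HNF1A — or of a chromatin
regulator such as KDM6A that sustains its program — leaves a recognizable
footprint: coordinated downregulation of the factor's direct target genes.
Many tumors show this footprint without carrying any mutation in the factor
itself, so a purely genetic definition misses them. `lofscape` implements
an expression-based definition and the regulatory-genomics layer needed to
connect it to transcription-factor binding, chromatin state, motifs, and
tissue-microarray protein staining.

It is aimed at computational biologists who have a gene-by-sample
expression matrix, a LoF gene signature, and (optionally) ChIP-seq peaks,
coverage tracks, and clinical staining scores, and who want the complete
classification and enrichment chain with testable, deterministic behavior.

## The method

**Single-sample preranked GSEA classification.** For each tumor sample
*s*, genes are ranked by differential expression against the cohort:

    score(g) = log2( (x[g,s] + c) / (median_t x[g,t] + c) )

with pseudocount *c* = 1. The LoF gene set *S* is scored on this ranked
list with the weighted running-sum enrichment statistic: walking down the
ranks, the sum gains `|score_i|^w / Σ_S |score|^w` at set members (*w* = 1)
and loses `1/(N − |S|)` elsewhere; the enrichment score ES is the signed
extremum. A gene-tag permutation null (random gene sets of size |S|,
default 10,000 draws) yields the normalized score
`NES = ES / mean |same-sign null ES|` and the add-one nominal p-value
`p = (b + 1)/(m + 1)`. Samples are labeled:

| label    | rule                 | interpretation                      |
|----------|----------------------|-------------------------------------|
| LoF      | NES < 0 and p < 0.05 | coordinated target downregulation   |
| Control1 | NES < 0 and p ≥ 0.05 | weak, non-significant depletion     |
| Control2 | NES ≥ 0              | no depletion                        |

**Regulatory integration.** Active-chromatin peaks within 1 kb of a TSS
are promoters, all others enhancers; peaks are assigned to their closest
gene (leftmost start on ties). Fisher's exact test measures enrichment of
TF-bound genes among downregulated genes within an expressed-gene
background (log2 basemean > 2.5). Coverage tracks are aggregated in 10-bp
bins around peak centers, and a PWM scanner with a one-tailed binomial
test quantifies known-motif enrichment in ±250-bp windows.

**IHC scoring.** Tissue-microarray cores get an immunoreactive score
IRS = intensity (0–3) × percent-positive category (0–4), averaged per
case, grouped negative/weak/moderate/strong, and tested against tumor
grade by chi-square (undetermined-grade cases excluded).

Every input can be simulated with known ground truth (`gen_cohort`,
`gen_regulatory_landscape`, `gen_motif_sequences`, `gen_tma_cases`), so
the full pipeline is testable without any external download.

## Worked example

```r
library(lofscape)

# a 120-sample cohort; 20% of samples downregulate a 100-gene LoF set
# by 1 log2 unit (sd 0.5); mutations at 19% penetrance vs 2% background
sim <- gen_cohort(cohort_sim_config(seed = 7))
classes <- classify_cohort(sim$matrix, sim$truth$set_gene_ids,
                           n_perm = 1000, seed = 7)
table(classes$label)
#> Control2      LoF
#>       96       24

head(classes[classes$label == "LoF", ], 3)
#>  sample_id label       nes   p_nominal
#>       S006   LoF -3.410731 0.001443001
#>       S008   LoF -3.523055 0.001647446
#>       S012   LoF -3.153270 0.001519757

assoc <- mutation_association(classes, sim$mutations)
assoc$table
#>             LoF_mutant not_mutant
#> LoF_class            6         18
#> other_class          2         94
round(assoc$odds_ratio, 2); signif(assoc$p_value, 3)
#> [1] 15.67
#> [1] 0.000771
```

All 24 truly simulated LoF samples are recovered (sensitivity 1.0,
specificity 1.0 against the generator's ground truth), and the LoF class
is strongly enriched for LoF mutations — the same phenotype/genotype
association logic the classifier is designed to expose on real cohorts.

A command-line entry point wraps the same functions:

```sh
Rscript inst/cli/lofscape.R simulate cohort --out sim/ --seed 7
Rscript inst/cli/lofscape.R classify --matrix sim/matrix.tsv \
    --gmt sim/set.gmt --out sim/cls --nperm 1000 --seed 7 \
    --mutations sim/mutations.tsv
```

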