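# promotif

Regulatory-genomics toolkit for asking, of any set of co-expressed genes:
**which transcription factors plausibly drive them, and is their binding
conserved across species?** The package grew out of the analysis style used
for stress- and virus-responsive genes in *Drosophila* (including
domesticated retroelement genes whose promoters carry kayak/Stat92E-class
motifs), but every stage is generic:

* strand-aware promoter extraction around transcription starts
  (−1000..+100 bp by default) and random reference-set sampling;
* TRANSFAC-format PWM parsing and log2-odds scanning of both strands, with
  per-matrix score thresholds calibrated to a maximum site frequency
  (1 site per 2000 bp by default) on the reference set;
* binding-site enrichment per (matrix, cluster): a one-sided Fisher exact
  test on promoter hit counts, a binomial test on collapsed site frequency,
  and an **adjusted fold enrichment** — the lower bound of the 99%
  confidence interval of the promoter-table odds ratio
  (Haldane–Anscombe-corrected), maximised over the calibrated threshold
  grid. A matrix is called significantly enriched when AFE > 1 and the
  per-cluster Benjamini–Hochberg FDR of the binomial test is below 0.05;
* differential-expression calling (Welch tests, BH adjustment, strict
  fold-change > 2 rule), rank-correlation co-expression networks, and an
  MCODE-style complex-detection algorithm (k-core vertex weights, greedy
  seeded expansion, haircut and fluff post-processing);
* motif mapping into multiple alignments of ortholog promoters, with
  per-species presence calls and a positional-conservation flag based on
  merged alignment-column windows;
* qPCR relative expression by the 2^dCt method against three reference
  genes, with exact Mann–Whitney group comparisons;
* synthetic-data generators that produce every one of these inputs with
  planted, logged ground truth.

The core statistic, for a 2×2 promoter table (a, b; c, d) = (targets with a
site, without; references with, without):

    AFE = exp( ln OR⁺ − z₀.₉₉₅ · SE ),   OR⁺ = (a+½)(d+½) / (b+½)(c+½),
    SE  = sqrt( 1/(a+½) + 1/(b+½) + 1/(c+½) + 1/(d+½) )

maximised over all score thresholds whose reference site frequency respects
the 1/2000 bp⁻¹ cap.

## Worked example

Plant one motif into half of 200 synthetic target promoters, leave 5000
reference promoters as background, and ask which of six matrices is
enriched:

```r
library(promotif)
library(tibble)

mats <- lapply(1:6, function(i) random_pwm(8, sprintf("SIM_%02d", i),
                                           seed = 100 + i))
targets <- plant_motifs(
  gen_background_promoters(200, 1100, seed = 1, prefix = "clu"),
  mats[[2]], plant_probability = 0.5, seed = 2)$promoters
refs <- gen_background_promoters(5000, 1100, seed = 3, prefix = "ref")

report <- enrich_report(
  clusters = tibble(gene_id = targets$gene_id, cluster = "stress"),
  matrices = mats, promoters = targets, references = refs)
tidy(report)[, c("matrix_id", "cluster", "a", "c", "binom_p",
                 "afe", "fdr", "significant")]
#> # A tibble: 6 × 8
#>   matrix_id cluster     a     c   binom_p   afe      fdr significant
#>   <chr>     <chr>   <dbl> <dbl>     <dbl> <dbl>    <dbl> <lgl>
#> 1 SIM_01    stress      6   179 0.591     0.316 0.820    FALSE
#> 2 SIM_02    stress     20   174 0.0000411 1.67  0.000247 TRUE
#> 3 SIM_03    stress      6   168 0.684     0.336 0.820    FALSE
#> 4 SIM_04    stress      3   204 0.989     0.102 0.989    FALSE
#> 5 SIM_05    stress     13   159 0.0179    1.03  0.0537   FALSE
#> 6 SIM_06    stress      9   172 0.276     0.576 0.552    FALSE
```

Reading the table: `a` of 200 target promoters and `c` of 5000 reference
promoters carry at least one site at the maximising threshold. The planted
matrix `SIM_02` has 20 hit-bearing target promoters against a background
rate of 174/5000, an adjusted fold enrichment of 1.67 (its 99% CI lower
bound stays above 1) and a binomial FDR of 2.5 × 10⁻⁴ — the only
significant call. `SIM_05` drifts close (AFE 1.03) but fails the FDR gate;
that is the decision rule doing its job. `autoplot(report)` draws the
matrix-by-cluster AFE heatmap with significant entries outlined.

Downstream stages work the same way from tibbles:
`call_de()` → `build_network()` → `mcode_complexes()` →
`select_anchor_cluster()` for co-expression clusters, and
`read_alignment()` → `conservation_matrix()` for cross-species motif
presence. See the methods vignette (`vignettes/promotif-methods.Rmd`) for
the models, parameter meanings and design choices.

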