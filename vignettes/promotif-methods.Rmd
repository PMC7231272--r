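---
title: "Methods: promoter motif enrichment, co-expression clustering and motif conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif enrichment, co-expression clustering and motif conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotif)
```

# The question the package answers

Given a set of co-expressed genes — for example, genes that respond together
to stress or viral infection in *Drosophila* — which transcription factors
plausibly regulate them, and is the candidate regulation evolutionarily
conserved? promotif implements the full desk pipeline for this question:
promoter extraction, PWM scanning, binding-site enrichment statistics,
co-expression clustering, cross-species motif conservation, and the qPCR
arithmetic used to validate candidate genes experimentally. A synthetic-data
module generates every input with planted ground truth, so each stage, and
the pipeline end to end, is testable without any external download.

# Promoter windows

Promoters are fixed windows around annotated transcription starts, by
default 1000 bp upstream to 100 bp downstream (1100 bp in total; the TSS
base itself counts as downstream position 1, so a window covers exactly
`upstream + downstream` bases). Coordinates are 0-based and half-open
internally; for a minus-strand gene the window `[tss - downstream + 1,
tss + upstream + 1)` is reverse-complemented so that position 0 of every
returned sequence is its most-upstream base. Windows running off a
chromosome end are clipped with a warning rather than dropped. Bases other
than A/C/G/T are kept as `N`; no scan window may overlap an `N`, which is
deterministic and conservative.

The enrichment background is a uniform random sample of promoters
(`sample_reference()`, default 5000 genes), drawn without replacement and,
by default, excluding the analysed cluster genes so foreground never
contaminates background.

# PWM scoring and threshold calibration

A motif is a position count matrix (TRANSFAC flat format, `read_transfac()`).
Scoring is log2-odds with a total pseudocount of 1 distributed in proportion
to the background:

$$s_{i,b} = \log_2 \frac{(c_{i,b} + \pi_b)/(\sum_{b'} c_{i,b'} + 1)}{\pi_b}$$

with background $\pi$ uniform by default. A window's score is the column
sum, in bits; both strands are always scanned, and a minus-strand hit is
reported at the leftmost forward-strand base of its window. The scoring
formula is fixed and documented here because commercial scanning platforms
do not publish theirs; determinism and testability take precedence over
fidelity to an unpublished internal.

Score thresholds are not p-value based. Each matrix's threshold is
calibrated empirically on the reference promoter set as the smallest
observed window score whose total hit count per scanned bp stays below a
frequency cap, 1 site per 2000 bp by default. Frequency counts hits on both
strands over the single-strand length. For site-frequency statistics
(the binomial test below), overlapping hits are first collapsed per strand
by greedy best-score selection, so one strong site never counts once per
overlapping window; raw (uncollapsed) counts are used only for the
calibration cap itself, where the distinction is immaterial because the cap
constrains the same quantity on both sides of the comparison.

The scanning kernel is a short C++ routine (Rcpp): it encodes each promoter
set once, scores every window on both strands in a single pass, and retains
only the per-promoter maxima plus the top tail of scores needed for
calibration and the threshold sweep. This is the same engineering choice
the field's sequence packages make for inner loops.

# Enrichment statistics

For each (matrix, gene set) pair, against the reference set:

* **Fisher test** on promoter counts: the 2x2 table is (target promoters
  with at least one site, without; reference promoters with, without), and
  the p-value is the one-sided hypergeometric tail in the enrichment
  direction. One-sided is a deliberate reading of the decision rule: the
  question is enrichment, not depletion (a flag can flip this).
* **Binomial test** on site frequency: the null per-bp rate is the
  collapsed reference site count over reference bp; the p-value is
  $P(X \ge s_t)$ for $X \sim \mathrm{Bin}(B_t, \lambda)$. When the
  reference has no sites at all, $\lambda$ is floored at $1/(2B_r)$ to keep
  the test finite and conservative.
* **Adjusted fold enrichment (AFE)**: the odds ratio of the promoter table,
  corrected downward to the lower bound of its 99% Wald confidence interval
  on the log scale, with Haldane–Anscombe +0.5 in every cell:
  $\mathrm{AFE} = \exp(\ln \mathrm{OR}^+ - z_{0.995}\,\mathrm{SE})$,
  $\mathrm{SE} = \sqrt{\sum 1/(\text{cell}+0.5)}$. AFE > 1 means the
  enrichment direction survives the correction. "Fold enrichment" is an
  odds ratio here, not a rate ratio, matching the statistic's own
  description as a corrected odds ratio.
* **Threshold sweep**: AFE is maximised over the grid of candidate
  thresholds — the distinct reference window scores that respect the
  frequency cap — and the Fisher and binomial tests are evaluated at the
  maximising threshold, ties resolving to the stricter threshold.
* **Decision rule**: within each cluster, binomial p-values are adjusted
  across matrices by Benjamini–Hochberg, and a matrix is called
  significantly enriched iff AFE > 1 **and** FDR < 0.05. The FDR family is
  all matrices within one cluster (the report is read column-wise); this is
  a documented choice, configurable in principle, since the family is not
  dictated by the statistic itself. The Fisher p is reported but not gated
  on: the rule names the binomial test.

Maximising AFE over thresholds is mildly anti-conservative, which is why
the gate demands the 99%-CI lower bound to clear 1 *and* the FDR test. The
null-calibration benchmark (equal planting in target and reference sets,
200 seeded runs) measures the realised false-call rate of the whole
procedure at about 2%, inside the nominal 5%.

# Differential expression and co-expression clustering

`call_de()` performs a per-gene Welch t-test on log2 expression with an
optional variance-shrinkage weight that pools gene variances toward their
mean (off by default; the pipeline's decisions do not depend on it).
Zero-variance genes are decided by the exact mean difference. Genes are
flagged DE by adjusted p < 0.05 and fold change *strictly* greater than 2
(|log2FC| > 1); a gene sitting exactly at 2-fold is not called.

The co-expression graph is deliberately simple: an edge joins two genes
when their Spearman correlation across samples has absolute value at least
0.7. A composite multi-evidence association network would require external
databases; a rank-correlation graph preserves the topology-in/clusters-out
contract at desk scale and is labelled as such.

Clustering is an MCODE-style algorithm implemented from scratch:

* **Vertex weights**: each vertex is weighted by the highest k-core
  (k >= 2) of its closed neighbourhood — weight = core number x core
  density. Requiring k >= 2 makes pendant vertices, star leaves and other
  singly-connected structures weightless, which is consistent with the
  haircut step's multiply-connected philosophy; a K5 vertex weighs 4.
* **Expansion**: complexes grow greedily from the heaviest unassigned
  seeds. A neighbour joins when its weight is within the node score cutoff
  (default 0.2) of the seed weight **and** it connects to at least half the
  current members (minimum two edges; one edge only for the very first
  addition). A pure weight rule cannot separate two equally dense regions
  joined by a spurious bridge — in a barbell of two K5s every vertex has
  identical weight, so any weight threshold crosses the bridge — whereas
  the half-connectivity condition keeps the growing complex a dense 2-core
  and never crosses single- or double-edge bridges. Candidates are
  re-examined to a fixpoint, making the result independent of edge-list
  order.
* **Post-processing**, per complex in discovery order: haircut (iteratively
  remove members with fewer than two within-complex edges) runs before the
  complex claims its vertices, so pruned vertices remain available to later
  complexes; fluff then adds still-unassigned neighbours whose closed
  neighbourhood is denser than 0.5 and that attach to at least a quarter of
  the complex (minimum two edges); haircut runs once more so a fluffed-in
  pendant is pruned again. The attachment requirement on fluff is this
  package's addition: closed-neighbourhood density alone admits any member
  of a *different* dense module that happens to touch the complex by one
  spurious edge, which dilutes recovered modules. Fluffed vertices may
  belong to several complexes; core assignment is exclusive.
* Complexes are scored density x size and reported in descending score;
  complexes with fewer than two surviving members are dropped. Defaults
  (haircut on, fluff on, node score cutoff 0.2, fluff density 0.5) follow
  the reported MCODE settings for this analysis.

# Cross-species motif conservation

`read_alignment()` ingests aligned FASTA or Clustal (a small built-in
parser handles minimal Clustal files) and builds, per species, the map from
ungapped promoter positions to alignment columns. Hits scanned on each
species' ungapped promoter are mapped to inclusive column intervals; gaps
inside a motif in *other* rows simply widen nothing in this species' map.
Hit windows are merged across species when their column intervals overlap
or fall within a tolerance (10 columns by default — an explicit,
configurable operationalisation of "same localisation", which would
otherwise be a judgement by eye). A motif is *positionally conserved* when
a single merged window contains hits from every species that has the motif
at all. Per-matrix thresholds default to the calibrated thresholds from the
scanning stage. An optional phylogenetic tree only orders report rows; no
tree inference, bootstrap or ancestral reconstruction is attempted.

# qPCR relative expression

Relative expression uses the 2^dCt method against three reference genes:
per sample, the reference Ct is the arithmetic mean of the three reference
Cts (equivalently, the geometric mean of their expressions), and a target's
relative expression is `2^(ref_ct - ct)`. The multi-reference convention is
the standard one; it is recorded in the output's metadata attribute because
other conventions exist. Group comparisons are two-sided Mann–Whitney U
tests at alpha 0.01 on biological replicates: exact by full enumeration up
to 8 replicates per group, and a tie- and continuity-corrected normal
approximation beyond that.

# The synthetic-data generators

Every input has a generator with planted, exhaustively logged ground truth:

* **Background promoters** are i.i.d. draws from a base composition,
  uniform by default — the nucleotide background real fly promoters would
  impose is unknown to this package and deliberately not claimed.
* **Motif planting** selects promoters with a given probability and writes
  sites sampled column-wise from the PWM at non-overlapping uniform
  offsets (greedy rejection, 1000 attempts), reverse-complementing
  minus-strand placements. The plant log records every site exactly once,
  so recovery is checkable by string search.
* **Expression matrices** are baseline + condition-block effects +
  Gaussian noise, with an optional shared per-sample latent factor per
  module (`module_cor`). Condition effects alone cannot produce high rank
  correlation within a module: with 4 of 12 samples affected, the rank
  correlation of a noiseless block design is capped near 0.67, because
  ranks within each condition are driven entirely by noise. The latent
  factor is the standard way to plant a target pairwise correlation
  (loading $c = \sigma\sqrt{r/(1-r)}$); it also reproduces a property of
  real co-expression data that independent noise does not — correlated
  sampling error, where a whole module's realised correlation rises or
  falls together from sample to sample.
* **Ortholog promoters** share one ancestral scaffold, independently
  substituted per species at a configurable per-base rate (default 0.05),
  with consensus sites written at one homologous offset per motif in the
  scripted species. Substitution-only evolution means the set is natively
  aligned; gap machinery is exercised in tests by inserting gaps
  programmatically. No indel process is simulated.
* **Ct tables** follow `base_ct - log2(fold change) + noise`, so fold
  changes are exact cycle shifts; reference genes are constrained to fold
  change 1 everywhere.

All generators derive per-operation child seeds from a single integer seed,
so any stage can be re-run independently and still reproduce a full
pipeline run. Identical configuration and seed give byte-identical output.

# Benchmarks, problem sizes, and what they show

The acceptance suite and `scripts/acceptance.R` exercise the pipeline at
these scales, chosen as a realistic desk-scale version of the intended
analysis:

* *Enrichment recovery*: one 8-bp matrix planted at probability 0.5 in 200
  target promoters versus 0.02 in 5000 reference promoters (1100 bp,
  uniform background), among 19 unplanted matrices; 100 seeded runs. The
  planted matrix is recovered (AFE > 1, FDR < 0.05) in effectively all
  runs, with unplanted false calls well under 1%.
* *Null calibration*: equal planting on both sides, 200 runs; realised
  significant-call rate ~2%.
* *Module recovery*: two 20-gene modules at within-module correlation 0.8
  across 12 samples, 100 seeds, recovery judged by Jaccard >= 0.8 per
  module. Measured recovery sits at 85–90%. The shortfall is a property of
  the data regime, not the algorithm: at 12 samples the *realised*
  correlation graph occasionally collapses (a module's within-edge density
  can fall to ~0.1 when its latent factor draws a low-spread realisation)
  or two modules' factors correlate strongly by chance (cross-module edge
  densities above 0.5 occur), and no clustering algorithm recovers those
  realisations. This failure mode — whole modules dropping out together —
  is invisible in per-edge error rates and is exactly what more samples
  buy in a real design.
* *Conservation*: a 7-species scripted gain/loss pattern (one motif in all
  species, one in a 3-species group) is recovered exactly, 50/50 seeds.
* *DE rule, qPCR*: boundary exactness (a gene at exactly 2-fold is never
  called), noiseless recall, null false-call rates, and exact noiseless
  2^dCt round trips.

Because all of this runs on synthetic data, passing shows the statistics,
algorithms and bookkeeping are correct under the stated models; it does not
validate the biological assumptions of any particular real dataset
(microarray normalisation artifacts, probe effects, alignment quality, and
non-uniform promoter composition are all outside the generators' scope).

# Known limitations

* The scoring formula and the empirical frequency calibration approximate,
  but cannot reproduce, proprietary scanning platforms; absolute AFE values
  from real TRANSFAC matrices will differ even when the decision rule
  agrees.
* The correlation network is not a composite association network; graphs
  built from it should be read as co-expression only.
* The MCODE expansion's connectivity requirement makes complexes cleaner
  than classic MCODE on noisy graphs but can under-grow very sparse true
  complexes; fluff compensates only for well-attached stragglers.
* Exact Mann–Whitney enumeration is limited to 8 replicates per group;
  beyond that the normal approximation is used.
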