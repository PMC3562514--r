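---
title: "Predicting miRNA differential expression and targets from mRNA data"
author: "mirhostpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA differential expression and targets from mRNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhostpred)
```

## The biological model

Most human microRNAs are intragenic: their primary transcripts sit
inside (mostly in the introns of) protein-coding *host genes* and are
transcribed with them. Two consequences drive everything this package
does:

1. a mature miRNA's expression is **positively correlated** with its
   host gene's mRNA expression, and
2. because miRNAs direct degradation of their target mRNAs, a miRNA's
   expression is **anti-correlated** with its targets' expression.

Paired miRNA+mRNA expression studies are rare, while mRNA-only studies
are abundant. `mirhostpred` therefore predicts a miRNA *pseudo-expression
matrix* from an mRNA matrix via the host-gene relationship (1), calls
differentially expressed miRNAs on it, and then uses relationship (2)
to nominate the mRNAs most anti-correlated with each predicted miRNA as
putative targets. Predicted targets are functionally annotated by
gene-set over-representation, and can be validated energetically by a
sliding-window duplex free-energy scan of target 3'UTRs against the
mature miRNA sequence.

## Pre-processing and the permutation cutoff

Input is a log2-scale expression matrix (the scale RMA produces; the
package does not process raw arrays) plus a design table mapping
samples to groups. `row_stats()` computes a per-feature signed log2
fold change `fc = mean(group2) - mean(group1)` and a p-value from a
Welch t-test (default), Student t-test, or one-way ANOVA. Multi-column
ANOVA designs are collapsed to one grouping with `interaction()`; a
factorial decomposition is deliberately out of scope.

Rather than a fixed alpha, the significance threshold is derived from
the data: `permutation_cutoff()` re-runs the row test on label-shuffled
designs (group sizes preserved) and takes the smallest p-value seen.
Anything in the real analysis below that value is stronger than the
best score pure chance produced. With `n_perm = 1` (the default,
matching the original single-randomization design) the cutoff on null
data has expectation `1/(m+1)` for `m` independent rows — the expected
minimum of `m` uniform p-values. Note this oracle assumes exactly
uniform null p-values: Student's t delivers that under Gaussian noise,
while Welch's Satterthwaite approximation is slightly conservative in
the far tail, so the calibration experiments in this package use the
Student test.

Degenerate rows are handled explicitly: zero variance everywhere with
equal means gives `p = 1, fc = 0` (and a logged count); zero variance
with distinct means gives `p = 0`.

## The miRNA-host mapping

The mapping table connects each precursor miRNA to the transcripts it
overlaps, carrying three attributes per edge: relative strand
(sense/antisense), overlap class (intron, exon, 3'UTR, 5'UTR), and
evidence status (experimental vs predicted, binarized from the raw
annotation source label, which is preserved). Tables can be read from
CSV (`read_mapping()`) or built from genomic coordinates
(`build_mapping()`, 1-based inclusive intervals). When a locus spans a
feature boundary the class is resolved by the priority
utr3 > utr5 > exon > intron; the priority favors the classes retained
in mature mRNA, which the predictors treat specially. In genome-wide
mappings the intronic sense-strand class dominates (our synthetic
generator defaults to 92% intronic, 83% sense, mirroring that reality).

## Predictor I: the scaling function

For each mature miRNA with mapped host rows, the pseudo-expression in a
sample is the mean over hosts of expression times an edge weight

\[ \omega_i = |FC_i| \cdot (1 - p_i) \cdot k_{sense} \cdot k_{overlap}
   \cdot k_{evidence} \]

with fixed coefficients `k_sense` (1.2 sense / 0.8 antisense),
`k_overlap` (2 intron / 0.8 otherwise) and `k_evidence` (1.2
experimental / 0.8 predicted). Introns are promoted because splicing
releases them to the miRNA-maturation machinery, while exonic and UTR
overlaps travel with the mature mRNA. The mean is deliberately **not**
normalized by the weight sum — that is the predictor's stated form; it
can overestimate fold changes of highly expressed hosts, and a
normalized variant is available via `normalize = TRUE`.

## Predictor II: the per-miRNA linear model

Where a paired training dataset exists, per-miRNA regression
coefficients are fitted by least squares. Because a miRNA can have 1-32
host transcripts, the model cannot regress on a variable-length vector;
instead one regression row is built per (miRNA, transcript, sample) and
per-transcript predictions are aggregated by the **median** per miRNA
and sample. The default formula (variant `standard`) regresses miRNA
expression on host expression `e`, `|FC|`, `(1 - p)` and all their
interactions, with a miRNA-identity factor interacting with every term.
That factor structure is mathematically identical to independent
per-miRNA regressions, which is how it is computed (and verified
against the global factor fit in the test suite). Variant `full` adds
the categorical edge attributes; `minimal` keeps only `e`. By default
rows are pre-filtered to sense-strand intronic edges — the
configuration with the best reported predictive power — and the
evidence covariate is dropped.

Rows are split 2/3 train / 1/3 test at random (seeded); the fit
records the held-out Pearson correlation between median-aggregated
predictions and observations. Aliased columns within a miRNA's block
(common when a miRNA has few hosts, making `|FC|` collinear with the
intercept) are dropped and logged.

## Consensus and target extraction

Each predictor's pseudo-matrix goes through the same
`row_stats()` + `permutation_cutoff()` machinery; the direction of a
call is the sign of the pseudo fold change. `consensus()` takes the
union, flagging each miRNA `scaling`, `linear` or `both`. An empty
union terminates the pipeline (exit status 3 in the CLI): with no
significant miRNA there is nothing to correlate.

`correlate()` then computes the full correlation matrix between
consensus pseudo-expression rows and the significant mRNA rows
(Pearson default; Spearman uses average ranks, Kendall is tau-b).
`get_ht()` keeps entries at or below a negative cutoff, default
**-0.8**, chosen for reliable general performance; relaxing it (e.g.
-0.6) broadens the candidate list at the cost of noise. Undefined
correlations from zero-variance rows are recorded as missing and never
pass the filter. Probe-level hits are aggregated to genes with a
support count (the number of (probeset, mature miRNA) entries backing
each pair), and `direction_of_regulation()` labels each interaction
`repression_gained` (miRNA up, gene down) or `repression_lifted`
(miRNA down, gene up); concordant signs are kept but flagged
inconsistent.

## Over-representation testing

Predicted target genes are tested against gene-set collections (GMT
files; GO/KEGG/disease-ontology content is supplied by the user — no
ontology-graph propagation is performed). The statistic is the
hypergeometric upper tail `P(X >= k)` with the universe defaulting to
all genes on the input matrix after annotation translation. Raw
p-values are reported alongside a Benjamini-Hochberg adjustment; the
adjustment cannot change rankings. The same tail underlies
`fisher_overlap_test()`, the one-sided 2x2 Fisher exact test used to
score the overlap between two prediction sets.

## The energy-walk validation

The energetic plausibility of predicted miRNA-target pairs is assessed
by scanning each target's 3'UTR with 25-nt windows advancing 5 nt
(trailing partial windows dropped — an interpretation choice, stated
here because the original protocol leaves it open). Each window is
joined to the mature miRNA through an 8-base unpairable linker and the
minimum free energy of the joined molecule is recorded; the lowest
window marks the putative binding site (leftmost window on ties). For
genes with several UTR isoforms the longest is scanned (ties to the
lexicographically smallest transcript id), and UTRs under 100 nt are
discarded. The historical description of the isoform rule says "5'UTR"
in one place; since the scan targets 3'UTRs this is implemented for
3'UTRs.

The default energy backend is an internal nearest-neighbor
hybridization dynamic program (Rcpp): Watson-Crick and GU-wobble
doublet stacking at approximate Turner 37°C values, base-dependent
dangling-end terms, size-specific bulge and interior-loop initiation
with a capped Ninio asymmetry penalty and terminal-mismatch
stabilization, a duplex-initiation cost and terminal-AU penalties.
Intra-strand pairing is excluded by construction, so the unpairable
linker is honored trivially and the open chain fixes the energy scale
at 0 (results are always <= 0). This is a documented approximation to
a full folding engine: against ViennaRNA's hybridization-only
`RNAduplex` it rank-correlates at about 0.84 (Spearman, 200 random
window/miRNA pairs); against `RNAfold` on the linker-joined molecule
agreement is lower (~0.7) because `RNAfold` also folds intramolecular
hairpins. Both external engines are available as backends
(`"rnaduplex"`, `"rnafold"`) when the binaries are on the PATH.

Following the source protocol's own conclusion, no fixed -20 kcal/mol
site cutoff is applied; instead whole minimum-energy distributions are
compared. Two null models accompany each matched set: permuting the
gene-label vector over the same sequences (`randomize_labels()`; a
derangement is not enforced) and substituting targets with other genes'
UTRs drawn without replacement from a pool, falling back to
uniform-random synthetic sequences when the pool is exhausted
(`randomize_sequences()`). `compare_energy_distributions()` runs all
pairwise Welch two-sample t-tests. On fixtures with planted
complementary sites the matched distribution sits far below both
randomizations while the two randomizations agree — the expected
signature of genuine binding sites.

## The synthetic-data generator

`make_paired_dataset()` emulates the statistical structure the pipeline
exploits, with Gaussian noise on the log2 scale throughout:

- host genes: baseline U(6, 10) plus a two-group log2 shift (`effect`,
  default 1 — a two-fold change) for the hosts of differential miRNAs
  (`diff_fraction`, default 0.5), plus N(0, `noise_sd`) with
  `noise_sd = 0.2` by default;
- miRNAs: `a_j + b_j * mean(hosts_j) + noise`, with `a_j ~ U(0, 2)` and
  `b_j ~ U(0.8, 1.2)`;
- planted targets (2 per miRNA): anti-correlated with the realized
  miRNA row at population correlation `target_strength` (default
  0.95); with `noise_sd = 0` the construction degenerates to exact
  linearity and correlation -1;
- decoys: independent noise around their own baselines.

The default geometry (30 samples, 20 miRNAs, 500 genes, one host per
miRNA) keeps a full pipeline run in seconds; the parameter-recovery
experiments use 100 samples and 20 miRNAs, and the target-recovery
experiments 30 samples and 10 miRNAs over 20 generator seeds. One host
per miRNA makes the planted slope `b_j` exactly the per-transcript
regression slope, which is what the recovery experiments check
(multi-host generation is available via `hosts_per_mirna`).

What the generator does **not** emulate: probe-level noise structure,
correlated gene modules beyond the planted ones, batch effects,
mapping errors, or the heavy-tailed expression distributions of real
arrays. Passing tests therefore demonstrate correctness of the
machinery under the stated statistical model, not field performance on
real data.

`make_sequences()` plants exact reverse-complement binding sites at
recorded positions in otherwise uniform-random UTRs (length >= 100 so
the UTR filter passes); `make_genesets()` plants one enriched term
drawing half its members from a designated query; `make_mapping()`
emits schema-valid edge tables at the genome-realistic class mix. All
generators are pure functions of their parameters and seed.

## Numerical and design choices

- **Fold-change scale**: matrices are log2; predictors consume
  `|FC|`. Log2 matches RMA-style pre-processing.
- **ANOVA fold change**: max minus min group mean (nonnegative); the
  extreme-pair convention leaves the sign undefined.
- **Permutation design**: label shuffles preserve group sizes;
  degenerate shuffles (a group emptied below 2) are redrawn.
- **Duplicate edges** for one (miRNA, probeset) pair are tolerated;
  the support count absorbs them at the interaction-summary stage.
- **Ties**: Spearman uses average ranks; Kendall is tau-b; the energy
  scan reports the leftmost minimal window; UTR isoform ties go to the
  smallest transcript id.
- **Higher-order predictors** (GLMs, neural networks, genetic
  algorithms) are deliberately not implemented; they were reported to
  add no significant power over the per-miRNA linear model.
- **Seeds**: every stochastic stage takes an explicit seed and is
  bit-reproducible; the pipeline manifest records it.

## Known limitations

- The method only sees intragenic miRNAs with expressed, mapped hosts;
  intergenic miRNAs with independent promoters are invisible.
- Pseudo-expression inherits host-gene regulation wholesale: miRNA
  maturation and post-transcriptional regulation are ignored, so
  false positives are expected where a host is expressed but the miRNA
  is not matured.
- The internal energy backend approximates a full nearest-neighbor
  folding engine; absolute kcal/mol values should not be compared
  across backends, only ranks and distribution contrasts.
- The enrichment stage treats gene sets as flat lists; no ontology
  topology is used.
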