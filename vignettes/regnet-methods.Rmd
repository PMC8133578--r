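---
title: "Statistical methods for validated TF-target network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for validated TF-target network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnet)
```

## The problem

High-throughput assays validate transcription factor (TF) to target-gene
relationships in two fundamentally different ways: *binding* evidence
(ChIP-seq in vivo, DAP-seq in vitro — the TF physically occupies a site
near the gene) and *regulation* evidence (perturbing the TF changes the
gene's expression, as in protoplast TF-perturbation assays or mutant
transcriptomes). Neither kind alone defines a functional regulatory edge:
binding is pervasive but mostly non-functional, while regulation may be
indirect. `regnet` stores both kinds of evidence in one queryable
compendium and provides the statistics needed to integrate them: overlap
enrichment, cis-motif enrichment, multi-set (Sungear) statistics,
precision/recall evaluation of predicted networks, and Network Walking.

This vignette documents the models, their assumptions, the tunable
parameters and the numerical choices. Every empirical statement here is
computed by the test suite or the acceptance script; nothing is quoted
from external data.

## The query language

Queries are boolean expressions over *terms*. A term is a TF identifier
(or the keywords `all` / `all_expression`) with optional bracket filters:

```
AT4G24020[EXPERIMENT_TYPE=Expression] and not AT4G24020[TECHNOLOGY/METHOD=ChIPseq]
```

Metadata filters (`EXPERIMENT_TYPE`, `TECHNOLOGY/METHOD`, `TISSUE/SAMPLE`,
any upper-cased key) select experiments; edge filters (`log2fc`, `pvalue`,
`EDGE_TYPE`) select individual edges, so `TF[log2fc > 0]` isolates
TF-induced targets. Precedence is `not` > `and` > `or`; values with spaces
or colons are double-quoted.

Design choices that the grammar's source examples leave open:

* **`and` across distinct TFs.** Conjunction keeps per-TF grouping and
  restricts each TF's target set to the targets present for every
  conjunct. The same-TF case — the only one the source material
  demonstrates — reduces to plain intersection.
* **Bare `not`.** Complementation needs a universe; a bare `not` (and the
  all-negated conjunction `not A and not B`, evaluated by De Morgan)
  requires an explicit background gene list and errors without one.
* **Unknown subjects** return an empty result with a warning rather than
  an error, so panel-wide batch queries do not abort.

Constraints are applied after evaluation: a *target-genes* list and the
*background* restrict targets, *filter-TFs* restricts the TF set (this is
how walk results feed back into new queries), and a *target-network*
restricts (TF, target) pairs to the edges of a predicted network.

## Overlap enrichment

All overlap tests are exact Fisher tests on 2×2 tables laid out against a
user-controlled background universe *N*: upper tail
\(P(X \ge a)\) for enrichment, lower tail \(P(X \le a)\) for depletion,
with \(X\) hypergeometric on the observed margins. Bonferroni correction
uses the family actually tested: all (analysis × list) cells for
target-list enrichment, all \(k(k-1)\) off-diagonal cells for the
pairwise gene-set grid (upper-tail p above the diagonal, lower-tail
below), and one family per call for motif enrichment, so queried analyses
and user gene lists can be corrected independently. Overlaps are counted
at gene level: several experiments validating the same (TF, target) pair
contribute one gene. Genes outside the background are removed from both
sides before testing (with a warning), and target-list results also
report *specificity* (percent of the TF's targets inside the list) and
*influence* (percent of the list covered by the TF's targets).

## Motif scanning and cis-enrichment

Motifs are position weight matrices (MEME format). Every position on both
strands is scored as \(\sum_j \log_2(p_{b_j,j}/q_{b_j})\) against a
zero-order background \(q\) (defaulting to the scanned sequence's base
frequencies, the usual genome-scan convention). The reported p-value is
*exact*: the null score distribution is computed by dynamic programming
over per-column score distributions discretised at a granularity of
10^-3^ bits (a FIMO-style scaled-integer scheme). Both the window score
and the distribution use the same integer discretisation, so the DP is
exact for the discretised score model; the test suite certifies it against
exhaustive 4^w^ word enumeration. Windows containing `N` are skipped
rather than scored as mismatches. Hits are reported when
`p < p_threshold` (default 10^-4^). A pseudocount (default 10^-4^) is
added to PWM cells before log-ratios; a zero cell with no pseudocount is
an error rather than a silent -Inf.

Overlapping matches of the *same* motif — common for repetitive motifs —
are pruned greedily in ascending p-value order (ties: leftmost start,
then forward strand), keeping a hit only when it overlaps no previously
kept hit. Matches of different motifs are never pruned against each
other.

Retained hits are tallied per gene region: `promoter2000/1000/500`
(immediately 5' of the TSS on the gene's strand, clipped at the
chromosome start), `utr5`, `cds`, `intron`, `exon`, `utr3` and `cdna`
(the transcribed span), with multi-transcript genes using per-region
unions. A hit in a region shared by several genes counts for all of
them; a hit spanning several intervals of one region counts once. The
TSS convention follows the internal 0-based half-open coordinates: for a
`-` strand gene the TSS is the exclusive span end (one past the 5'-most
base), which makes `promoter500 = [tss, tss+500)` on that strand.

Enrichment of a motif in a target-gene set is occurrence-level: the table
compares occurrences of the motif versus all other motifs, inside versus
outside the target set, within one region. The source description is
ambiguous between occurrence-level and gene-level contingency;
occurrence-level is implemented because it matches the stated background
("all individual cis-binding motifs within that gene region"). Cluster
level tests aggregate member-motif counts first.

## Sungear statistics

For \(n\) gene lists of sizes \(x_1 \dots x_n\) with \(x = \sum_i x_i\)
(a gene in three lists contributes three — the definition deliberately
does not deduplicate), each non-empty subset \(S\) of lists owns the
node of genes belonging to *exactly* the lists in \(S\), with expectation

\[ e_S = x \cdot \prod_{i \in S} \frac{x_i}{x} \cdot
        \prod_{i \notin S}\left(1 - \frac{x_i}{x}\right). \]

These expectations sum to \(x\) over all \(2^n\) subsets. The observed
node size is compared to \(e_S\) by an exact binomial test with \(x\)
trials and success probability \(e_S/x\). Sidedness is not specified by
the source method, so the two-sided minimum-likelihood p-value is
reported together with an explicit direction flag (enriched/depleted);
likelihood ties use the conventional \(1+10^{-7}\) relative tolerance.
Bonferroni corrects over observed nodes only (not all \(2^n - 1\)
possible ones). The layout places list anchors at the n-th roots of
unity and nodes at the centroid of their member anchors; coincident
centroids (e.g. complementary axis pairs) are jittered deterministically
from a hash of the membership key.

## Precision/recall evaluation and pruning

A predicted network is a ranked edge list (TF, target, score). Against a
gold standard built from validated query results (gene-level pairs,
restricted to the background), the *evaluable* edges are those whose TF
has any gold data and whose target is in the background. They are sorted
by descending score, ties broken lexicographically by (TF, target) for
determinism. At rank \(r\), precision is \(TP_r/r\) and recall
\(TP_r/P\), with \(P\) the number of gold positives occurring among the
evaluable candidate pairs. AUPR uses step (right-continuous)
integration, \(\sum precision(r)\,\Delta recall\) — equivalently the mean
precision at the positive ranks.

Significance comes from permuting scores uniformly among evaluable edges
and recomputing the AUPR, with the add-one estimator
\(p = (1 + \#\{AUPR_{null} \ge AUPR_{obs}\})/(1 + n_{perm})\); the null
mean and the percent improvement over it are reported alongside. Note
that the null mean exceeds the positive prevalence \(P/n\) at finite
sample sizes (the mean precision of a random ranking is biased upward by
the harmonic terms at early ranks); the test suite therefore checks
concentration of the null mean around prevalence at the scale of the
null distribution's spread rather than exact equality.

Pruning maps a precision cutoff to a score threshold: the score at the
*deepest* rank whose precision still attains the cutoff. The threshold is
then applied to **all** predicted edges, evaluable or not, so TFs
without validation data survive in the refined network. Raising the
cutoff never enlarges the surviving set.

## Open chromatin and peak-to-gene assignment

Binding edges carrying a peak interval can be filtered to those
overlapping (by at least one base, half-open semantics) an open-chromatin
interval set (DHS/ATAC). Edges without peak coordinates — regulation
edges — pass through unchanged with a logged count: the filter targets
binding evidence only. The filter is idempotent. Peak-to-gene assignment
uses closest-base distance (0 when overlapping) with a 2 kb default,
matching the common peak-annotation rule; a peak within range of several
genes is assigned to all of them.

## Network Walking

Starting from a focus TF (TF1), its regulated targets are split into
*direct* (regulated and bound) and *indirect* (regulated but not bound) —
always a partition. A second query (typically `all_expression`) is then
evaluated with the TF filter set to the direct targets and the target
filter to the indirect targets, yielding the intermediate TF2s and their
edges into TF1's indirect targets. "Bound" defaults to ChIP-derived
evidence (`TECHNOLOGY/METHOD=ChIPseq`) and is configurable (e.g. to
include DAP-seq). Coverage is the percent of *all* indirect targets
reached by at least one TF2 — the union across TF2s, with the full
indirect set as denominator; both choices are deliberate and the
denominator is not restricted to genes expressed in the TF2 assays.
Per-TF2 enrichment of its full target set in the indirect list supplies
the influence/specificity ranking of intermediates.

## The synthetic compendium

`generate_compendium()` produces a complete, deterministic test world:
genome (FASTA), annotation (GFF3), edge and metadata tables, MEME motifs,
a cluster map, gene lists, a DHS interval set and a ranked predicted
network. The defaults are the package's study conditions, chosen once to
mirror the qualitative regime of real TF validation panels:

* 2,000 genes on one chromosome (600 bp gene slots with 2,400 bp
  intergenic gaps, so 2 kb promoters never collide), 5 TFs;
* 40 regulated targets per TF, half induced / half repressed, with
  log2 fold-changes ~ ±|N(2, 0.5)| and log-uniform p-values;
* `beta = 0.75` of regulated targets are also bound, while the
  bound-but-unregulated pool is sized so that exactly 25% of bound genes
  are regulated — the empirical asymmetry that regulated genes are
  largely bound but bound genes are rarely regulated;
* 200 bp binding peaks placed 300–900 bp upstream of the target TSS,
  always within the 2 kb assignment rule; a DHS set covering 60% of
  peaks;
* an 8-bp consensus site (`TGACGTCA`) planted in the `promoter500`
  window of 90% of the first TF's regulated targets (exact consensus,
  not PWM-sampled, so scanner sensitivity on plants is provably 1 at any
  sane threshold), plus an unplanted control motif;
* two of the TFs planted as direct (regulated + bound) targets of the
  first TF, each regulating 40% of its indirect targets, so Network
  Walking has a real path to find;
* a predicted network scoring gold edges 1 and 160 decoys per TF 0, plus
  `N(0, sigma = 0.1)` noise — strong but noisy planted signal.

All randomness flows from one seed; the same seed yields byte-identical
files. What the generator does *not* emulate: realistic sequence
composition, overlapping genes, multi-exon diversity, assay-specific
biases, or compendium-scale edge counts — so green tests certify the
statistical machinery, not performance on any real genome.

Problem sizes in the test suite (2,000-gene default fixture; a 300-gene
fixture for genome-wide scans; enumeration oracles at margins ≤ 30,
motif widths ≤ 8, ≤ 12-hit overlap instances, ≤ 200 binomial trials;
999–1,000 permutations) are the package's chosen balance of coverage
against runtime.

## Numerical conventions

* All internal coordinates are 0-based half-open; GFF3 (1-based
  inclusive) and BED are converted at the boundary, once.
* Fisher tails use the hypergeometric distribution directly
  (`phyper`), never a normal approximation; the suite certifies
  agreement with full enumeration to 10^-10^.
* Score discretisation granularity (10^-3^ bits) and the PWM pseudocount
  (10^-4^) are `scan_params()` arguments.
* Deterministic tie-breaks everywhere randomness is not wanted:
  lexicographic (TF, target) for equal scores, (p, start, strand) for
  overlap removal, membership-key hashing for layout jitter.
* Duplicate edges collapse with a warning; an edge referencing an
  unknown analysis, a CDS outside its gene span, or a p-value outside
  [0,1] is an error.

## Known limitations

* The exact p-value DP assumes a zero-order background; higher-order
  Markov backgrounds are out of scope.
* Occurrence-level motif contingency treats occurrences as independent;
  heavily repetitive regions can inflate counts even after same-motif
  overlap removal.
* Sungear's \(x = \sum x_i\) definition double-counts shared genes by
  design; expectations are exact for that definition, not for the
  deduplicated union.
* The permutation null permutes scores only; it conditions on the
  predicted edge set and does not model uncertainty in network
  structure.
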