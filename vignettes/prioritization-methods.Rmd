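---
title: "Methods: multi-evidence prioritization of cancer-associated RNA-binding proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence prioritization of cancer-associated RNA-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpprio)
```

## The problem

RNA-binding proteins (RBPs) regulate every post-transcriptional step of
gene expression, yet few have established roles in breast cancer.
`rbpprio` implements an integrative desk-scale strategy for nominating
candidate breast-cancer RBPs by requiring convergent evidence from four
independent data modalities:

1. **Genomic alteration burden** — the gene sits in the first quartile of
   per-gene event counts under the *progression* alteration profile
   (amplification, mRNA upregulation, fusion, mutation). The mirrored
   *suppression* profile uses deep deletion, mRNA downregulation, fusion
   and mutation; fusions and mutations are ambiguous with respect to
   direction and deliberately contribute to both profiles.
2. **Protein–protein interactions** — at least one high-confidence
   interaction (experimental or database evidence channel, score ≥ 0.9,
   inclusive) with a known breast-cancer protein.
3. **Immunohistochemistry** — at least one ordinal level of expression
   gain in tumor versus normal tissue (consensus over tumor samples).
4. **Tumor dependency** — essential in at least one loss-of-function
   screen (RNAi or CRISPR), i.e. a member of the union essential set.

Genes meeting all four criteria are *prioritized*; genes meeting the
first three but not essential ex vivo are reported as the *near-miss*
set. The prioritized genes then seed a disease-gene network (one-hop
neighborhood in a weighted functional network, filtered to RBPs and
cancer driver genes), in which dense complexes are detected with a
from-scratch MCODE implementation and annotated against a catalog of
known protein complexes.

## Statistical and algorithmic components

### Burden normalization and rank comparison

Per-patient burden for a gene set is the number of alteration events
hitting the set divided by the set size, making sets of different sizes
comparable; per-group (subtype or stage) burden divides total events by
the number of patients in the group. Gene sets and clinical groups are
compared with a Mann–Whitney rank test. The U statistic counts pairs
$(x_i, y_j)$ with $x_i > y_j$, ties counted one half. For tie-free
samples with both sizes ≤ 8 the two-sided p-value is exact (doubled
smaller tail of the enumeration distribution of U); otherwise a normal
approximation with tie correction and a 0.5 continuity correction toward
the mean is used. The exact branch is verified in the tests against
brute-force enumeration of all $\binom{n_1+n_2}{n_1}$ labelings, and the
approximate branch against the standard implementation in base R.

### First-quartile selection

"Most altered" genes are those whose event count reaches the 75th
percentile of the per-gene count distribution, computed with linear
interpolation between order statistics (R's default quantile type 7) and
with boundary ties included. The rule is deterministic under ties and
always returns at least a quarter of the genes. Counts, not
patient-corrected frequencies, feed the quantile: event counts are what
an alteration-type profile table reports, and the per-gene denominator
would be constant anyway within one cohort.

### IHC consensus and shift classes

Expression is measured on the closed 4-level ordinal scale
not_detected < low < medium < high. The tumor consensus is the modal
level of the tumor samples; among tied modes the **higher** level is
returned. A deterministic tie rule is required to replace a manual
frequency-based consensus; breaking ties upward is applied symmetrically
in both tissues, so it cannot systematically inflate tumor−normal
shifts, but it remains a convention and is flagged here. The shift is
`delta = tumor − normal`: |delta| ≥ 2 is called up-/downregulated
("twofold variation level" read as two ordinal levels, consistent with
the one-level definition of moderate change), |delta| = 1 moderate, 0
unchanged. Genes lacking either tissue measurement are excluded and
reported, not silently dropped.

### Essentiality calling

Dependency screens report a per-(cell line, gene) depletion score where
strongly negative means the line depends on the gene. A gene is called
essential when its **mean** score across the considered lines is ≤ −0.5
(inclusive). The threshold is stated as a magnitude in the depleting
direction: published top essential genes have mean scores around −1.3 to
−1.8, so a literal "greater than 0.5" reading would contradict every
listed example. Means over lines (rather than per-line dependent
fractions) match how screen portals summarize gene-level dependency.
Lowering the threshold magnitude never removes genes (tested). Per
molecular subtype, the same caller runs on that subtype's cell lines;
a gene is *exclusive* to a subtype when essential there and nowhere
else, which makes exclusive sets pairwise disjoint by construction.

### MCODE

The complex finder is a faithful re-implementation of the
molecular-complex-detection algorithm on an unweighted simple graph
(edge weights from the functional network are retained for reporting
only; the published algorithm is topological):

* **Vertex weight** = $k \cdot \mathrm{density}(K)$ where $K$ is the
  highest $k$-core of the closed neighborhood of the vertex and density
  is $2|E| / (|V|(|V|-1))$; isolated vertices weigh 0.
* **Expansion**: unvisited vertices are taken as seeds in descending
  weight order (ties broken lexicographically — determinism matters for
  testing); breadth-first expansion admits unvisited neighbors with
  weight ≥ seed weight × (1 − node score cutoff), the published
  "vertex weight percentage" semantics. Every vertex joins at most one
  complex, so complexes are vertex-disjoint and each induces a connected
  subgraph.
* **Haircut** (off by default) removes degree-1 members; **fluff**
  (0 = off) admits neighbors whose closed-neighborhood density exceeds
  the fluff threshold. The defaults — cutoff 0.1, fluff 0, no haircut —
  are the standard "level 3" parameterization.

Vertex weights are validated in the tests against an independent
exhaustive k-core peeling oracle on ~1,000 random graphs of up to 8
nodes, and the expansion rule against hand-traced examples (a K5 with a
pendant vertex yields exactly the K5). Predicted complexes are annotated
with the catalog entry sharing the most members (ties: higher coverage,
then lexicographic name).

### Disease-network construction

The network around the prioritized seeds is the subgraph induced on
(seeds ∪ one-hop neighbors of seeds) ∩ (RBPs ∪ cancer driver genes ∪
seeds). The one-hop induced-subgraph reading is the reproducible
interpretation of a disease-gene network query; seeds absent from the
functional network are reported and kept as isolated vertices so the
caller can see them.

## What the simulator emulates

The generator produces every input table with planted ground truth, so
the whole pipeline has a checkable answer:

* **Cohort** (default 200 patients, 280 genes: 200 RBP + 40 BC + 40
  non-cancer): each (sample, gene, category) is an independent Bernoulli
  draw at rate `background rate × category weight`, category weights
  defaulting to the mix dominated by mRNA upregulation (68.7%) and
  amplification (15.4%) observed in breast tumors. Planted progressors
  get a 10× boost on amplification/mRNA-up; planted suppressors on deep
  deletion/mRNA-down. Subtype and stage annotations default to uniform
  proportions — a simulation has no cohort to inherit them from — and a
  per-subtype rate multiplier lets tests plant subtype burden contrasts.
* **IHC**: one normal level per gene (background distribution weighted
  toward medium) and 12 tumor samples; background samples jitter ±1
  level with probability 0.15 each way, planted progressors shift +2/+3
  per sample (clamped to the scale; their normal level is seeded at
  not_detected/low so the shift survives clamping), suppressors mirror
  this downward. The truncated discrete shift keeps levels valid without
  rejection sampling.
* **Dependency screens**: two 30-line screens; background scores
  Normal(0, 0.2), planted essentials Normal(−1.5, 0.2) — magnitudes
  chosen to echo the score range of published top essential genes. With
  30 lines the standard error is ≈ 0.037, so planted sensitivity is ~1
  and the background false-positive rate is ≈ 0 at the −0.5 threshold
  (verified over 50 seeds).
* **Networks**: every planted gene receives one experimental-channel PPI
  edge with score ≥ 0.9 to a BC protein; background PPI edges score
  Uniform(0.4, 0.95) on mixed channels. The functional network is an
  Erdős–Rényi background at p = 0.05 over the 280-gene universe plus a
  planted 12-clique containing the 5 planted progressors; the complex
  catalog lists the clique under the name "Spliceosome" plus decoys.
* **Catalog**: all 40 BC genes as breast drivers plus 20 RBPs as drivers
  of other cancer types, with sampled roles.

Each table draws from its own RNG stream derived from the master seed by
a fixed label, so adding a table never perturbs the others, and
identical configs give byte-identical outputs.

**What the simulator does not emulate** — and hence what passing tests
do *not* show about real data: mutational signatures, copy-number
segmentation and within-gene event correlation; batch effects and
antibody variability; realistic network topology (degree heterogeneity,
community structure) beyond a clique-in-noise; version skew across
database releases. Recovery results on planted structure demonstrate
correctness of the machinery, not expected performance on real cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default configuration
(200 patients, 280 genes, two 30-line screens, ~2,000-edge functional
network) over 20 seeds for recovery checks and 50 seeds for the
essentiality error-rate check; a full pipeline run takes well under a
second, which makes many-seed replication the natural design. Degenerate
inputs are handled explicitly: empty alteration tables yield zero-count
maps, an empty PPI table empties criterion 2 but the pipeline completes,
zero-variance rank comparisons return p = 1, and empty complex catalogs
annotate to nothing with a warning.

## Known limitations

* The modal-with-upward-tie-break consensus is one defensible reading of
  a manual frequency-based consensus; real curated calls may differ on
  balanced level distributions.
* The PPI confidence filter treats the score column as a per-row
  combined confidence; channel-specific sub-score recombination is out
  of scope.
* The near-miss definition is the strict conjunction
  c1 ∧ c2 ∧ c3 ∧ ¬c4; looser readings ("not needed for tumor survival ex
  vivo") would also exclude genes never assayed in either screen.
* The suppression-direction criteria mirror the progression ones
  (suppression alteration profile, same PPI criterion, IHC shift ≤ −1,
  same essentiality criterion); this mapping is an interpretation, since
  only the progression direction is enumerated in the motivating
  analysis strategy.
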