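# rbpprio

Multi-evidence prioritization of cancer-associated RNA-binding proteins
(RBPs), for computational biologists studying post-transcriptional
regulation in breast cancer.

Most RBPs have no established role in breast tumorigenesis. `rbpprio`
nominates candidates by demanding convergent evidence from four
independent modalities, then asks what the candidates do together in a
functional network:

1. **c1 — alteration burden**: the gene lies in the first quartile of
   per-gene event counts under the progression alteration profile
   (amplification ∪ mRNA-up ∪ fusion ∪ mutation); selection at the
   interpolated 75th percentile with boundary ties included.
2. **c2 — PPI**: ≥ 1 interaction with a known breast-cancer protein on
   the experimental or database channel with confidence score ≥ 0.9.
3. **c3 — IHC**: ≥ 1 ordinal level of expression gain in tumor versus
   normal tissue, where tumor expression is the modal consensus of the
   tumor samples on the scale not_detected < low < medium < high.
4. **c4 — dependency**: essential in either loss-of-function screen,
   i.e. mean dependency score ≤ −0.5 across the screen's cell lines.

Genes with all four flags are *prioritized*; genes with c1 ∧ c2 ∧ c3 but
not c4 form the *near-miss* set. Prioritized genes seed a disease-gene
network (one-hop neighborhood filtered to RBPs and cancer driver genes),
where dense complexes are found with a from-scratch MCODE implementation
— vertex weight = k × density of the highest k-core of the closed
neighborhood; seeded breadth-first expansion at the vertex-weight
percentage cutoff (defaults: cutoff 0.1, fluff 0, no haircut) — and
annotated against a protein-complex catalog by maximum member overlap.

A synthetic-cohort generator with planted ground truth (known progressor
genes, known dense complex) produces every input table the pipeline
consumes, so the whole strategy can be exercised and validated without
external database downloads. See the methods vignette
(`vignettes/prioritization-methods.Rmd`) for the model, parameter
defaults and design decisions.

## Worked example

```r
library(rbpprio)
report <- run_pipeline(run_config(seed = 42))
print(report)
#> rbpprio pipeline run (seed 42, version 1.0.0)
#>   alterations: 1312 events in 200 samples
#>   criteria (progression): quartile 71 | PPI 15 | IHC up 7 | essential 5
#>   prioritized (5): RBP0021, RBP0039, RBP0123, RBP0191, RBP0192
#>   near-miss: 0 genes
#>   top complex: 12 nodes / 66 edges, best match Spliceosome (12 matched, coverage 1.00)
#>   recovery: prioritized Jaccard 1.000, top-complex Jaccard 1.000
```

Reading the output: the simulated 200-patient cohort produced 1312
alteration events; 71 RBPs sit in the top burden quartile, 15 have a
high-confidence breast-cancer interaction, 7 shift up in tumor IHC and 5
are essential in at least one screen. Exactly the 5 genes passing all
four criteria are returned, and they are precisely the planted
progressors (Jaccard 1.0). The MCODE top complex recovers the planted
12-gene clique, annotated to the "Spliceosome" catalog entry with full
coverage.

Individual stages are exported and composable: `simulate_all()`,
`count_per_gene()` / `first_quartile_genes()` / `mann_whitney()`,
`ihc_shift_table()`, `filter_edges()` / `extract_bipartite()`,
`call_essential()` / `combine_screens()` / `essential_by_subtype()`,
`build_evidence()` / `prioritize_intersect()`,
`build_disease_network()` / `mcode_find_complexes()` /
`annotate_complex()`. A thin CLI wrapper lives at
`scripts/run_pipeline.R`.

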