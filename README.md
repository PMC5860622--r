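# interologr

Predicts protein–protein interaction (PPI) networks for a species with no
experimentally measured interactome — the motivating case is the planarian
*Schmidtea mediterranea* — by transferring interactions from a reference
human network through sequence homology (*interolog* mapping). It is aimed
at researchers with assembled transcriptomes who want network context
(candidate interactions, pathways, functional neighborhoods) for their
contigs.

## Method at a glance

For each contig *t* the pipeline resolves at most one human homolog
*h(t)* from three evidence channels — BLAST (forward/reverse, with best
reciprocal hits), EggNOG profile-HMM hits, and a Needleman–Wunsch
*meta-alignment* over PFAM domain architectures (match +30 scaled by
model coverage, mismatch −30, gap −5) — via a strict five-rule cascade.
Every candidate pair (*t₁*, *t₂*) with
d(h(t₁), h(t₂)) ∈ {1, 2} in the reference interactome receives a
19-feature vector:

* `path_length` — shortest path between the homologs (−1 if disconnected),
* `dom_int_score` — number of transcript domain pairs catalogued as
  physically interacting (3did-style),
* `nto_mf`, `nto_bp`, `nto_cc` — GO normalized term overlap per aspect,
  NTO(A, B) = |anc(A) ∩ anc(B)| / min(|anc(A)|, |anc(B)|),
* per-transcript alignment measures: BLAST/EggNOG E-values, BLAST query
  coverage, meta-alignment score, and BRH booleans for the three channels.

A random forest (1000 trees, per-tree 5:1 downsampling of non-interacting
pairs) scores each pair; out-of-bag votes give unbiased performance
estimates and pairs with vote fraction ≥ 0.6 form the predicted network.
Networks are exported as a property graph (bulk-import CSVs + JSON) with a
confidence-scored pathway finder and expression overlays.

A seeded synthetic-data generator (`make_world()`) produces complete
fixture worlds — scale-free reference graph, domain catalog, GO DAG,
two species of contigs with planted true homologies and interactions —
so the whole pipeline is testable offline with known ground truth.

## Worked example

```r
library(interologr)

# end-to-end on one synthetic world: generate fixtures, resolve homologs,
# train, predict the query-species network, score against planted truth
b <- synthetic_benchmark(seed = 1)
b$auc_full                 # 0.9999723
b$auc_without_path         # 0.7248205
round(b$recovery$enrichment, 1)   # 76.9
nrow(b$network$edges)      # 367

# published per-dataset summary statistics as reference data
tab <- published_network_summaries()
round(spearman(tab$total_contigs, tab$contigs_in_interactome), 3)  # 0.873
```

The first block reads: on a planted world the full 19-feature forest
separates interacting from non-interacting training pairs almost
perfectly out-of-bag (AUC 0.99997), removing the dominant path-length
feature drops the AUC to ~0.72, and the predicted query network is ~77×
enriched for the
planted interolog pairs relative to a random edge set of the same size.
The last line reproduces the published rank correlation between dataset
size and predicted-interactome size across the 11 planarian
transcriptomes.

A thin command-line wrapper over the same functions is installed at
`inst/cli/interologr.R` (subcommands `synth`, `resolve`, `benchmark`).

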