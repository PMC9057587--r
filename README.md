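# epimapr — sort-seq epitope mapping from yeast-display selections

`epimapr` is an R package and analysis workflow for mapping antibody
epitopes by yeast surface display and sort-seq. A randomly mutagenized
antigen library is FACS-sorted for clones that still display antigen but no
longer bind an antibody Fab; after two rounds of selection the selected and
unselected populations are fragment-sequenced, and the positions whose
mutations became enriched mark the epitope. The package covers every
computational stage of that experiment — and ships a full simulator of the
wet-lab side, so the pipeline is testable end to end without any external
data.

## The statistic at the core

For library *j*, each accepted read contributes one observation per fully
covered codon: with *k<sub>i</sub>* reads carrying a nonsynonymous
substitution at native position *i* and *n<sub>i</sub>* reads covering
codon *i*, the mutation frequency is *f<sub>ij</sub> = k<sub>i</sub> /
n<sub>i</sub>*. Libraries are normalized by the median of geometric mean
ratios: over positions positive in all *m* libraries,

    g_i = (prod_j f_ij)^(1/m),   s_j = median_i (f_ij / g_i),
    f~_ij = f_ij / s_j

and each selected library is scored against its own median,

    e_ij = log2( f~_ij / median_i' f~_i'j ),

with positions called at **e ≥ 2** (inclusive; at least 4× the median
mutation frequency). Called positions that are structurally incapable of
being an epitope — relative solvent accessibility below 0.15 or engaged in
a disulfide bond, judged from a PDB/mmCIF structure or a precomputed
per-residue table — are excluded from the final epitope set, with the
reason recorded.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over the package functions. `Rscript analysis/01_simulate.R` through
`04_filter.R` prints:

```
mutagenized: 50000 clones, 2.00 nt substitutions/clone, 91.1% displayed
selected after 2 rounds: 100.0% of clones carry a mutation at a binding-relevant position
sequenced: 444 reads per library
selected: 444/444 reads accepted; 104/111 positions retained (median n = 214); top f at 62
unselected: 444/444 reads accepted; 107/111 positions retained (median n = 210); top f at 126
frequency matrix: 104 positions x 2 libraries (7 dropped for coverage)
size factors: selected=0.956, unselected=1.046
called at log2 enrichment >= 2: {45, 62, 75, 98, 110, 111, 112}
epitope set: {62, 75, 110, 111, 112}
excluded: 45 (buried, rsa=0.02); 98 (disulfide, rsa=0.72)
```

Reading this: the simulator planted epitope positions {62, 75, 110, 111,
112} plus two decoys (45 and 98) that enrich under selection but are
annotated buried / disulfide-bonded. After two selection rounds essentially
every clone in the selected pool carries a relevant mutation; the counter
accepts all 444 fragments per library and retains positions with ≥ 20
covering reads; normalization finds near-unit size factors (the libraries
were sequenced to the same depth); the enrichment rule calls all seven
enriched positions; the structural filter then removes exactly the two
decoys, leaving the planted epitope.

The same run is available as one call:

```r
library(epimapr)
res <- run_pipeline(list(seed = 7, outdir = "results/run",
  simulate = list(decoy_buried = 45L, decoy_disulfide = 98L)))
res$epitope          # per-position keep/exclude table with reasons
res$recovery         # sensitivity/precision vs the planted truth
```

`Rscript analysis/05_evaluate.R` repeats the study over 10 seeds and writes
`results/recovery_summary.tsv` (mean post-filter sensitivity 1.000,
precision 0.950, decoys excluded in 10/10 seeds).

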