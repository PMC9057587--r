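---
title: "Sort-seq epitope mapping: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq epitope mapping: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

# The experiment being modeled

Yeast surface display epitope mapping locates the residues of an antigen
that an antibody depends on for binding. The antigen — here an IgV-domain
fragment displayed via a cell-wall fusion, numbered by its native residues
(22..132 in the motivating application) — is randomly mutagenized by
low-rate error-prone PCR. FACS then sorts cells that still *display* the
antigen (expression-tag positive) but have *lost* binding to the antibody
Fab. Clones whose mutation disrupts the epitope pass this gate; clones with
neutral mutations mostly do not. After two rounds of sorting and expansion,
plasmids are fragmented and sequenced alongside an unselected reference
library. Positions whose mutation frequency is strongly enriched in the
selected pool mark the epitope — except for positions whose mutations
destabilize the fold rather than the interface, which is why candidate
positions that are buried in the core or locked in a disulfide bond are
excluded at the end.

# The statistic

For each library, every accepted read contributes one observation per fully
covered codon. With $k_i$ reads carrying a nonsynonymous substitution at
native position $i$ and $n_i$ reads covering codon $i$, the mutation
frequency is $f_i = k_i / n_i$. Reads are the sampling unit because
fragments cannot be phased back to clones; this per-read frequency is the
only estimator available from fragment data.

Libraries are made comparable by median-of-ratios normalization applied to
frequencies: over positions with $f_{ij} > 0$ in all $m$ libraries,

$$ g_i = \Big(\prod_{j=1}^{m} f_{ij}\Big)^{1/m}, \qquad
   s_j = \mathrm{median}_i \; f_{ij} / g_i, \qquad
   \tilde f_{ij} = f_{ij} / s_j. $$

Each selected library is scored against its own median:

$$ e_{ij} = \log_2 \frac{\tilde f_{ij}}{\mathrm{median}_{i'} \tilde f_{i'j}}, $$

and position $i$ is called a loss-of-binding candidate when
$e_{ij} \ge 2$ — an inclusive threshold, i.e. at least four times the
within-sample median mutation frequency. The log2 ratio to the unselected
reference, $\log_2(\tilde f_{ij}/\tilde f_{i,\mathrm{ref}})$, is computed
and reported alongside but is deliberately *not* used for calling: the
within-sample median baseline is the literal reading of the calling rule
this pipeline implements, and reporting both lets a user inspect any
disagreement between the two readings rather than having the package decide
silently. Positions with $\tilde f_{ij}=0$ score $-\infty$ and can never be
called.

Finally, called positions are annotated with relative solvent accessibility
(RSA) and disulfide status — from a structure or a precomputed table — and
removed when RSA $<$ 0.15 or when disulfide-bonded.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `lambda_nt` | 2 | nt substitutions/clone | realized rate of a low-rate error-prone PCR protocol; vendors quote 0–4.5 mutations/kb per cycle, and 1–3 per ~330-nt amplicon is typical |
| `rounds` | 2 | — | two sort/expand cycles |
| `p_hit`, `p_bg` | 0.9, 0.005 | capture prob./round | a clean FACS gate: high capture of true binding-loss clones, ~0.5% leakage |
| `q_effect` | 0.8 | probability | not every substitution at an epitope position abolishes binding; conservative changes often do not |
| `coverage` | 200 | reads/ORF position | MiSeq-scale depth for a one-gene amplicon |
| `read_length` | 150 | nt | standard short-read length |
| `error_rate` | 0.001 | per base | post-filter Illumina substitution error |
| `k` | 15 | nt | anchor length; a 15-mer is effectively unique in a 333-nt ORF |
| `max_mismatch` | 10 | per read | admits heavily mutated clones (Poisson(2) load plus sequencing error) while rejecting foreign sequence |
| `min_coverage` | 20 | reads | positions with fewer covering reads are too noisy to score |
| `threshold` | 2 | log2 units | the calling rule: ≥ 4× the median frequency |
| `rsa_min` | 0.15 | — | common buried/exposed boundary for relative accessibility |
| `probe_radius` | 1.4 | Å | water probe |
| `n_sphere_points` | 960 | — | Shrake–Rupley sampling density; see convergence below |
| `sg_cutoff` | 2.3 | Å | disulfide SG–SG distance; the canonical bond is ≈ 2.05 Å |

# What the simulator emulates — and what it does not

`mutagenize_library()` draws Poisson(`lambda_nt`) substitutions per clone,
uniform over the ORF without replacement, uniform over the three
alternative bases; amino-acid substitutions follow by codon translation,
and a clone gaining a stop codon is flagged non-displayed (it cannot
present antigen, so it can never be captured). `select_library()` draws
each epitope-position substitution's effect once per clone — a phenotype is
a property of the genotype, so it persists across rounds — then applies
per-round Bernoulli capture (`p_hit` for binding-loss clones, `p_bg`
otherwise, 0 for non-displayed clones) and resamples with replacement to a
constant population size, modeling expansion. `sequence_library()` emits
`round(coverage × ORF length / read length)` reads with uniform
forward-strand offsets, iid substitution errors, constant base quality,
and truth tags (source clone, offset) in the read names.

Deliberately **not** modeled: PCR amplification bias, the mutagenesis
kit's codon spectrum, indels, paired ends, reverse-strand reads (the
counter supports reverse-complement search, the simulator never needs it),
expression-level variation among displayed clones, and vector-flanking
sequence. The last omission has a visible consequence: because every read
lies wholly inside the ORF, codons near the ORF ends are covered by few
reads, and their frequency estimates are noisy. Passing tests on this
generator show the statistical machinery recovers a planted signal under
realistic noise; they do not certify performance on real data with
amplification artifacts, indels, or uneven fragmentation.

# Numerical and policy choices

* **Size factors on frequencies, not counts.** Normalization operates on
  the per-position frequencies, which is what the libraries report;
  positions with a zero in any library are excluded from the size-factor
  median (their geometric mean vanishes) but stay in the scored set. No
  pseudocount by default; `pseudocount` is exposed for users who want
  all-zero positions rescued at the cost of shrinking large ratios.
* **Medians.** An even number of values yields the arithmetic mean of the
  two central values, everywhere (size factors, enrichment baseline).
* **Alignment is ungapped and exact-anchored.** The first read k-mer with a
  unique exact ORF match fixes the offset; ambiguity or absence of anchors,
  out-of-bounds placement, or more than `max_mismatch` mismatches reject
  the read (rejections are counted and logged, never silently dropped).
  Indel-containing reads are expected to be rejected; substitutions
  dominate error-prone PCR libraries.
* **Codon calling.** Only fully covered codons are evaluated; a codon
  containing N is uncallable and contributes to neither $k_i$ nor $n_i$;
  synonymous changes contribute nothing. A per-substitution
  (position × alternative amino acid) table is emitted for inspection but
  never used for calling.
* **SASA.** Shrake–Rupley sampling with a near-uniform Fibonacci lattice of
  960 points per atom, probe 1.4 Å, van der Waals radii C 1.70, N 1.55,
  O 1.52, S 1.80 Å. Doubling the point count changes per-residue values by
  under 1% on the bundled fixtures, and single- and two-sphere
  configurations reproduce closed-form areas to within 1–2%. RSA uses the
  Tien et al. (2013) theoretical maxima.
* **Disulfides.** SG–SG pairs at ≤ 2.3 Å, resolved nearest-first so each
  cysteine joins at most one partner.
* **Structure parsing policy.** First model kept (with a warning), waters
  and hydrogens dropped, alternate locations resolved by highest occupancy
  then alphabetically. Numbering is mapped by identity when author numbers
  match the construct, otherwise by the best ungapped offset requiring
  ≥ 90% identity over the overlap.
* **Filter policy.** Called positions lacking annotation are kept and
  flagged `unfiltered` by default (configurable to drop): silently
  discarding a strong signal because a residue is missing from a structure
  would be worse than reporting it with a caveat. Every exclusion records
  its reason, and the output carries the RSA values so users can see which
  exclusions depend on the `rsa_min` choice.
* **Seed fan-out.** One run seed maps to fixed per-stage seeds via
  `(seed × 1009 + stage index) mod (2^31 − 1)`, so any stage can be
  reproduced in isolation and two runs with the same config are
  byte-identical.

# Problem sizes used in validation

The recovery study simulates a 111-aa construct, 50,000 clones, two
selection rounds and 200× coverage (444 reads per library), repeated over
10 seeds — the scale at which a single benchtop MiSeq experiment would
operate, and small enough that the entire study runs in well under a
minute per seed. Oracle checks use 100 random 50 × 4 frequency matrices;
SASA fixtures are single atoms, pairs, and an idealized extended
Gly-Gly-Gly tripeptide.

# Known limitations

* Precision of the call set is limited by coverage at the ORF edges: with
  uniform within-ORF fragment offsets, terminal codons are covered by far
  fewer reads, and 2–3 mutant reads there can clear the 4×-median bar by
  chance. In the 10-seed study this costs about 0–1 false call per run
  (mean post-filter precision ≈ 0.95). Real tagmentation of a plasmid
  yields reads spanning the ORF boundaries and would not show this edge
  effect.
* No variance model or multiple-testing control: calling is a fixed
  fold-change rule, as specified, so its false-positive rate scales with
  sequencing depth rather than being controlled.
* The per-read frequency estimator cannot separate two mutations on one
  clone from two clones with one mutation each; hitchhiker passengers of
  selected clones inflate non-epitope frequencies slightly (the
  normalization median absorbs most of this).
* The structural filter is only as good as its annotation; the burial
  threshold (RSA < 0.15) and disulfide cutoff (2.3 Å) are field-standard
  but not universal, and both are surfaced in the output table.
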