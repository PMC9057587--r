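#!/usr/bin/env Rscript

# Stage 1: simulate a yeast-display sort-seq experiment.
#
# A random 111-aa antigen construct (native numbering 22..132) is
# mutagenized by error-prone PCR (50,000 clones, ~2 nt substitutions each),
# put through two rounds of FACS selection that enrich clones which still
# display antigen but have lost Fab binding, and fragment-sequenced at 200x
# alongside the unselected library. Five epitope positions are planted
# (62, 75, 110, 111, 112), plus two "decoy" positions that enrich under
# selection but are annotated buried (45) or disulfide-bonded (98) — the
# structural filter must remove them later.

suppressMessages(library(epimapr))

outdir <- "results/mapping_run"
seed <- 7L
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ref <- random_reference(n_aa = 111L, first_residue = 22L,
                        seed = seed, cys_positions = 98L)
write_reference(ref, file.path(outdir, "ref.fasta"))

epitope <- c(62L, 75L, 110L, 111L, 112L)
decoy_buried <- 45L
decoy_disulfide <- 98L

params <- selection_params(c(epitope, decoy_buried, decoy_disulfide),
                           q_effect = 0.8, p_hit = 0.9, p_bg = 0.005,
                           rounds = 2L)
lib <- mutagenize_library(ref, n_clones = 50000L, lambda_nt = 2,
                          seed = seed + 1L)
message(sprintf("mutagenized: %d clones, %.2f nt substitutions/clone, %.1f%% displayed",
                length(lib$members), nrow(lib$nt_subs) / length(lib$members),
                100 * mean(lib$displayed)))

sel <- select_library(lib, params, seed = seed + 2L)
loss <- unique(lib$aa_subs$clone[lib$aa_subs$position %in%
                                   params$epitope_positions])
message(sprintf("selected after %d rounds: %.1f%% of clones carry a mutation at a binding-relevant position",
                params$rounds, 100 * mean(sel$members %in% loss)))

reads_sel <- sequence_library(sel, coverage = 200, read_length = 150L,
                              error_rate = 0.001, seed = seed + 3L)
reads_uns <- sequence_library(lib, coverage = 200, read_length = 150L,
                              error_rate = 0.001, seed = seed + 4L)
write_fastq(reads_sel, file.path(outdir, "selected.fastq"))
write_fastq(reads_uns, file.path(outdir, "unselected.fastq"))
message(sprintf("sequenced: %d reads per library", nrow(reads_sel)))

write_truth(ground_truth(epitope, params, lambda_nt = 2, seed = seed,
                         decoy_positions = c(decoy_buried, decoy_disulfide)),
            file.path(outdir, "truth.tsv"))
write_annotation(synthetic_annotation(ref, epitope,
                                      buried_positions = decoy_buried,
                                      disulfide_positions = decoy_disulfide,
                                      seed = seed + 5L),
                 file.path(outdir, "annotation.tsv"))
message("wrote ref.fasta, selected.fastq, unselected.fastq, truth.tsv, annotation.tsv")
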