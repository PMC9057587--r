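#!/usr/bin/env Rscript

# Stage 4: structural filtering. Called positions that are buried
# (relative solvent accessibility < 0.15) or involved in a disulfide bond
# are excluded from the putative epitope. Here the per-residue annotation
# table from the simulation stands in for a structure; with a real PDB,
# annotate_structure() computes RSA (Shrake-Rupley SASA over Tien et al.
# maxima) and SG-SG disulfides directly.

suppressMessages(library(epimapr))

outdir <- "results/mapping_run"
etab <- read_enrichment(file.path(outdir, "enrichment.tsv"))
ann <- read_annotation(file.path(outdir, "annotation.tsv"))

called <- called_positions(etab, "selected")
sel <- etab[etab$library == "selected", ]
epi <- filter_epitope(called, ann,
                      scores = setNames(sel$e_log2, sel$position),
                      rsa_min = 0.15)
write.table(epi, file.path(outdir, "epitope.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("epitope set: {%s}", paste(epi$position[epi$kept],
                                           collapse = ", ")))
removed <- epi[!epi$kept, ]
if (nrow(removed))
  message(sprintf("excluded: %s",
                  paste(sprintf("%d (%s, rsa=%.2f)", removed$position,
                                removed$reason, removed$rsa),
                        collapse = "; ")))
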