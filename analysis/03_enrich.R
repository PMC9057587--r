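#!/usr/bin/env Rscript

# Stage 3: normalize mutation frequencies across libraries by the median of
# geometric mean ratios and score each position as log2 enrichment over the
# within-sample median; positions at log2 enrichment >= 2 (i.e. at least 4x
# the median mutation frequency) are candidate loss-of-binding positions.

suppressMessages(library(epimapr))

outdir <- "results/mapping_run"
counts <- list(read_counts(file.path(outdir, "counts_selected.tsv")),
               read_counts(file.path(outdir, "counts_unselected.tsv")))

F <- frequency_matrix(counts, reference = "unselected")
message(sprintf("frequency matrix: %d positions x %d libraries (%d dropped for coverage)",
                nrow(F), ncol(F), length(attr(F, "dropped"))))

etab <- enrichment_table(F, threshold = 2)
write_enrichment(etab, file.path(outdir, "enrichment.tsv"))

s <- attr(etab, "size_factors")
message(sprintf("size factors: %s",
                paste(sprintf("%s=%.3f", names(s), s), collapse = ", ")))
called <- called_positions(etab, "selected")
message(sprintf("called at log2 enrichment >= 2: {%s}",
                paste(called, collapse = ", ")))
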