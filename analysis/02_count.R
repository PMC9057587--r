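#!/usr/bin/env Rscript

# Stage 2: map fragment reads to the reference ORF and count amino-acid
# mutations per position. Reads are placed by exact 15-mer anchoring with
# ungapped extension; only fully covered, N-free codons are evaluated, and
# frequencies are per-read: f_i = (reads with a nonsynonymous call at i) /
# (reads covering codon i).

suppressMessages(library(epimapr))

outdir <- "results/mapping_run"
ref <- read_reference(file.path(outdir, "ref.fasta"))

for (libname in c("selected", "unselected")) {
  reads <- read_fastq(file.path(outdir, paste0(libname, ".fastq")))
  res <- count_library(reads, ref, libname, k = 15L, max_mismatch = 10L,
                       min_coverage = 20L)
  write_counts(res$counts, file.path(outdir, paste0("counts_", libname, ".tsv")))
  write.table(res$substitutions,
              file.path(outdir, paste0("substitutions_", libname, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- res$counts$flag == ""
  message(sprintf("%s: %d/%d reads accepted; %d/%d positions retained (median n = %d); top f at %d",
                  libname, res$n_accepted, res$n_reads, sum(ok), nrow(res$counts),
                  round(median(res$counts$n[ok])),
                  res$counts$position[which.max(res$counts$f)]))
}
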