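ref <- toy_reference()  # MAETGWKDLFHR, native 22..33, 36-nt ORF

test_that("anchor alignment places, rejects, and reports mismatches", {
  # exact substring at a known offset
  sub <- substr(ref$nt_orf, 13, 30)
  aln <- anchor_align(sub, ref, k = 9)
  expect_true(aln$accepted)
  expect_equal(aln$orf_offset, 12L)
  expect_length(aln$mismatch_indices, 0L)

  # random bases sharing no k-mer: rejected with reason "no anchor"
  bad <- anchor_align(strrep("A", 18), ref, k = 9)
  expect_false(bad$accepted)
  expect_equal(bad$reason, "no anchor")

  # one substitution round-trips to its known ORF index
  mut <- sub
  substr(mut, 4, 4) <- if (substr(mut, 4, 4) == "A") "C" else "A"
  aln2 <- anchor_align(mut, ref, k = 9, max_mismatch = 10)
  expect_true(aln2$accepted)
  expect_equal(aln2$orf_offset, 12L)
  expect_equal(aln2$mismatch_indices, 15L)

  # mismatch budget enforced
  aln3 <- anchor_align(mut, ref, k = 9, max_mismatch = 0)
  expect_false(aln3$accepted)
  expect_equal(aln3$reason, "too many mismatches")

  # reverse-complement search only when enabled
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  expect_false(anchor_align(rc, ref, k = 9)$accepted)
  aln4 <- anchor_align(rc, ref, k = 9, search_rc = TRUE)
  expect_true(aln4$accepted)
  expect_equal(aln4$orf_offset, 12L)
  expect_equal(aln4$strand, "-")
})

test_that("ambiguous anchors are rejected, not guessed", {
  # a construct with an exact internal repeat makes every k-mer of a
  # repeat-only read multi-mapping
  rep_ref <- reference_construct("rep", paste0("ATGGCTGAAACC",
                                               "GCTGAAACCTGG"), 1L)
  read <- "GCTGAAACC"
  out <- anchor_align(read, rep_ref, k = 9)
  expect_false(out$accepted)
  expect_equal(out$reason, "ambiguous anchor")
})

test_that("codon calls are amino-acid level with N codons uncallable", {
  # full-length read, one base change GCT->GAT at aa index 1 (native 23)
  read <- ref$nt_orf
  substr(read, 5, 5) <- "A"
  aln <- anchor_align(read, ref, k = 9)
  res <- call_aa_mutations(aln, read, ref)
  expect_equal(res$calls,
               data.frame(position = 23L, ref_aa = "A", alt_aa = "D"))
  expect_equal(res$covered, 22:33)

  # synonymous change GCT->GCC emits nothing
  syn <- ref$nt_orf
  substr(syn, 6, 6) <- "C"
  res2 <- call_aa_mutations(anchor_align(syn, ref, k = 9), syn, ref)
  expect_equal(nrow(res2$calls), 0L)
  expect_equal(res2$covered, 22:33)

  # partial codons at read edges are not evaluated
  part <- substr(ref$nt_orf, 5, 26)  # covers codons 2..7 fully (native 24..29)
  res3 <- call_aa_mutations(anchor_align(part, ref, k = 9), part, ref)
  expect_equal(res3$covered, 24:29)

  # an N makes its codon uncallable for both calls and coverage
  nread <- ref$nt_orf
  substr(nread, 5, 5) <- "N"
  res4 <- call_aa_mutations(anchor_align(nread, ref, k = 9), nread, ref)
  expect_equal(res4$covered, c(22L, 24:33))
  expect_equal(nrow(res4$calls), 0L)
})

test_that("tabulation computes f = k/n with flags and conservation", {
  # 10 reads cover all positions; 2 carry the same nonsynonymous change
  mut <- ref$nt_orf
  substr(mut, 5, 5) <- "A"
  reads <- data.frame(id = sprintf("r%d", 1:10),
                      seq = c(rep(mut, 2), rep(ref$nt_orf, 8)))
  res <- count_library(reads, ref, "toy", k = 9, min_coverage = 5)
  tab <- res$counts
  expect_equal(tab$k[tab$position == 23], 2L)
  expect_equal(tab$n[tab$position == 23], 10L)
  expect_equal(tab$f[tab$position == 23], 0.2)
  expect_true(all(tab$f[tab$position != 23] == 0))
  expect_true(all(tab$flag == ""))

  # conservation: sum of k equals total nonsynonymous calls emitted
  expect_equal(sum(tab$k), sum(res$substitutions$reads))

  # low/no coverage flags
  short <- data.frame(id = "r1", seq = substr(ref$nt_orf, 1, 18))
  res2 <- count_library(short, ref, "toy", k = 9, min_coverage = 2)
  tab2 <- res2$counts
  expect_true(all(tab2$flag[tab2$n == 0] == "no_coverage"))
  expect_true(all(tab2$flag[tab2$n == 1] == "low_coverage"))
  expect_true(all(is.na(tab2$f[tab2$n == 0])))

  expect_error(count_library(reads[0, ], ref, "toy"), "empty read set")
})

test_that("noiseless one-clone library recovers its mutation exactly", {
  # clone carrying A->D at native 23; coverage 100, no sequencing error
  nt_subs <- data.frame(clone = 1L, pos0 = 4L, ref = "C", alt = "A")
  aa_subs <- data.frame(clone = 1L, position = 23L,
                        ref_aa = "A", alt_aa = "D")
  lib <- epimapr:::new_clone_library(ref, nt_subs, aa_subs, TRUE, 1L)
  reads <- sequence_library(lib, coverage = 100, read_length = 18,
                            error_rate = 0, seed = 1)
  res <- count_library(reads, ref, "one", k = 9, min_coverage = 1)
  tab <- res$counts
  expect_equal(tab$f[tab$position == 23], 1)
  expect_true(all(tab$f[tab$position != 23 & tab$n > 0] == 0))
})

test_that("read-level frequencies match a brute-force truth-tagged oracle", {
  # noiseless reads tagged with their source clone: f_i must equal the
  # fraction of covering reads drawn from clones mutated at i
  big <- random_reference(40, 22, seed = 8)
  lib <- mutagenize_library(big, 200, lambda_nt = 2, seed = 9)
  reads <- sequence_library(lib, coverage = 40, read_length = 60,
                            error_rate = 0, seed = 10)
  res <- count_library(reads, big, "lib", k = 15, max_mismatch = 10,
                       min_coverage = 1)
  tab <- res$counts
  # a noiseless read is mappable iff it contains a clean (mutation-free)
  # anchor-length window; derived from the truth tags, not the aligner
  mappable <- vapply(seq_len(nrow(reads)), function(i) {
    mut <- lib$nt_subs$pos0[lib$nt_subs$clone == reads$clone[i]]
    inside <- sort(mut[mut >= reads$offset[i] &
                         mut <= reads$offset[i] + 59]) - reads$offset[i]
    gaps <- diff(c(-1L, inside, 60L)) - 1L
    max(gaps) >= 15L
  }, TRUE)
  expect_equal(res$n_accepted, sum(mappable))
  # brute force over the truth-tagged mappable read set
  for (pos in seq(22, 61, by = 7)) {
    codon0 <- pos - 22L
    span <- c(3 * codon0, 3 * codon0 + 2)
    covering <- which(mappable & reads$offset <= span[1] &
                        reads$offset + 60 - 1 >= span[2])
    mut_clones <- unique(lib$aa_subs$clone[lib$aa_subs$position == pos])
    k_oracle <- sum(reads$clone[covering] %in% mut_clones)
    expect_equal(tab$k[tab$position == pos], k_oracle)
    expect_equal(tab$n[tab$position == pos], length(covering))
  }
})

test_that("raising min_coverage never adds positions downstream", {
  big <- random_reference(40, 22, seed = 8)
  lib <- mutagenize_library(big, 200, lambda_nt = 2, seed = 9)
  reads <- sequence_library(lib, coverage = 10, read_length = 60,
                            error_rate = 0.001, seed = 12)
  kept <- lapply(c(1, 5, 20), function(mc) {
    tab <- count_library(reads, big, "lib", min_coverage = mc)$counts
    tab$position[tab$flag == ""]
  })
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("count tables round-trip through TSV", {
  reads <- data.frame(id = "r1", seq = substr(toy_reference()$nt_orf, 1, 18))
  tab <- count_library(reads, toy_reference(), "toy", k = 9,
                       min_coverage = 1)$counts
  path <- tempfile(fileext = ".tsv")
  write_counts(tab, path)
  back <- read_counts(path)
  expect_equal(back, tab)
})
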