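#' Reference antigen construct
#'
#' A displayed antigen construct is a nucleotide ORF together with its
#' amino-acid translation and the native residue number of the first amino
#' acid, so that position `i` (0-based in the protein) carries native number
#' `first_residue + i`. The default simulated construct mirrors a displayed
#' IgV-domain fragment spanning native residues 22 to 132 (111 amino acids).
#'
#' @param name identifier for the construct.
#' @param nt_orf nucleotide ORF (A/C/G/T), length a multiple of 3.
#' @param first_residue native residue number of the first amino acid.
#' @return An object of class `reference_construct` with fields `name`,
#'   `nt_orf`, `aa_seq`, `first_residue`.
#' @examples
#' ref <- reference_construct("toy", "ATGGCTGAA", first_residue = 22)
#' ref$aa_seq           # "MAE"
#' native_positions(ref) # 22 23 24
#' @export
reference_construct <- function(name, nt_orf, first_residue = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(nt_orf), length(nt_orf) == 1L)
  nt_orf <- toupper(nt_orf)
  if (nchar(nt_orf) %% 3L != 0L)
    stop("ORF length must be a multiple of 3, got ", nchar(nt_orf))
  if (grepl("[^ACGT]", nt_orf))
    stop("ORF must contain only A/C/G/T")
  aa <- translate_orf(nt_orf)
  if (grepl("\\*", aa))
    stop("ORF translation contains a stop codon; the construct must be ",
         "a displayed open reading frame")
  structure(
    list(name = name, nt_orf = nt_orf, aa_seq = aa,
         first_residue = as.integer(first_residue)),
    class = "reference_construct")
}

#' @export
print.reference_construct <- function(x, ...) {
  n <- nchar(x$aa_seq)
  cat(sprintf("reference_construct '%s': %d aa (native %d..%d), %d nt ORF\n",
              x$name, n, x$first_residue, x$first_residue + n - 1L,
              nchar(x$nt_orf)))
  invisible(x)
}

#' Translate a nucleotide ORF under the standard genetic code
#'
#' Codons containing ambiguous bases translate to `X`.
#'
#' @param nt nucleotide string, length a multiple of 3.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_orf <- function(nt) {
  stopifnot(nchar(nt) %% 3L == 0L)
  if (nchar(nt) == 0L) return("")
  codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Native residue numbers covered by a construct
#' @param ref a [reference_construct()].
#' @return integer vector of native positions, in order.
#' @export
native_positions <- function(ref) {
  ref$first_residue + seq_len(nchar(ref$aa_seq)) - 1L
}

#' Generate a random synthetic reference construct
#'
#' Draws codons uniformly from the 61 sense codons; positions listed in
#' `cys_positions` (native numbering) are forced to cysteine (TGT) so that
#' disulfide annotations in downstream synthetic fixtures stay coherent with
#' the sequence.
#'
#' @param n_aa protein length (default 111, an IgV-domain-sized fragment).
#' @param first_residue native number of the first residue (default 22).
#' @param seed RNG seed.
#' @param cys_positions native positions forced to cysteine.
#' @param name construct name.
#' @return a [reference_construct()].
#' @export
random_reference <- function(n_aa = 111L, first_residue = 22L, seed = 1L,
                             cys_positions = integer(), name = "synthetic") {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(seed)
  codons <- sample(sense, n_aa, replace = TRUE)
  if (length(cys_positions)) {
    idx <- cys_positions - first_residue + 1L
    if (any(idx < 1L | idx > n_aa))
      stop("cys_positions outside construct range")
    codons[idx] <- "TGT"
  }
  reference_construct(name, paste0(codons, collapse = ""), first_residue)
}

#' Write / read a reference construct as FASTA
#'
#' The FASTA holds two records, `<name>|nt|first_residue=<n>` (the ORF) and
#' `<name>|aa|first_residue=<n>` (its translation, a consistency check on
#' read-back).
#'
#' @param ref a [reference_construct()].
#' @param path output file.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns the reconstructed [reference_construct()].
#' @export
write_reference <- function(ref, path) {
  hdr <- sprintf("%s|%%s|first_residue=%d", ref$name, ref$first_residue)
  nt <- Biostrings::DNAStringSet(ref$nt_orf)
  names(nt) <- sprintf(hdr, "nt")
  Biostrings::writeXStringSet(nt, path, format = "fasta")
  aa <- Biostrings::AAStringSet(ref$aa_seq)
  names(aa) <- sprintf(hdr, "aa")
  Biostrings::writeXStringSet(aa, path, format = "fasta", append = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(recs), "|", fixed = TRUE)
  kinds <- vapply(parts, `[`, "", 2L)
  i_nt <- which(kinds == "nt")
  if (length(i_nt) != 1L)
    stop("reference FASTA must contain exactly one '|nt|' record")
  fr <- sub("^first_residue=", "", vapply(parts, `[`, "", 3L)[i_nt])
  ref <- reference_construct(
    name = vapply(parts, `[`, "", 1L)[i_nt],
    nt_orf = as.character(recs[[i_nt]]),
    first_residue = as.integer(fr))
  i_aa <- which(kinds == "aa")
  if (length(i_aa) == 1L && as.character(recs[[i_aa]]) != ref$aa_seq)
    stop("aa record in ", path, " does not match the ORF translation")
  ref
}
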