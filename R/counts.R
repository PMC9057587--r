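#' Read mapping and codon-aware mutation counting
#'
#' Fragment reads are placed on the reference ORF by exact k-mer anchoring
#' with ungapped extension (error-prone PCR libraries carry substitutions,
#' not indels), amino-acid substitutions are called codon by codon, and
#' per-position mutation frequencies are tabulated with reads as the
#' sampling units: `f_i = k_i / n_i` where `n_i` counts accepted reads fully
#' covering codon `i` with a callable codon there and `k_i` those carrying a
#' nonsynonymous call.
#'
#' @name read_processing
NULL

#' Build an exact k-mer index of the reference ORF
#'
#' @param ref a [reference_construct()].
#' @param k anchor length (default 15).
#' @return a named list mapping each k-mer to its 0-based start offsets.
#' @export
kmer_index <- function(ref, k = 15L) {
  L <- nchar(ref$nt_orf)
  stopifnot(k >= 1L, k <= L)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(ref$nt_orf, starts, starts + k - 1L)
  idx <- split(starts - 1L, kmers)
  attr(idx, "k") <- as.integer(k)
  idx
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

align_forward <- function(seq, ref, index, k, max_mismatch) {
  L <- nchar(ref$nt_orf)
  len <- nchar(seq)
  saw_ambiguous <- FALSE
  for (a in 0:(len - k)) {
    kmer <- substr(seq, a + 1L, a + k)
    hits <- index[[kmer]]
    if (is.null(hits)) next
    if (length(hits) > 1L) { saw_ambiguous <- TRUE; next }
    offset <- hits - a
    if (offset < 0L || offset + len > L)
      return(list(accepted = FALSE, reason = "out of bounds"))
    refsub <- substr(ref$nt_orf, offset + 1L, offset + len)
    mm <- which(strsplit(seq, "", fixed = TRUE)[[1L]] !=
                  strsplit(refsub, "", fixed = TRUE)[[1L]])
    if (length(mm) > max_mismatch)
      return(list(accepted = FALSE, reason = "too many mismatches"))
    return(list(accepted = TRUE, orf_offset = offset, matched_length = len,
                mismatch_indices = offset + mm - 1L))
  }
  list(accepted = FALSE,
       reason = if (saw_ambiguous) "ambiguous anchor" else "no anchor")
}

#' Align one read to the reference ORF by exact k-mer anchoring
#'
#' Scans read k-mers left to right for the first with a unique exact match in
#' the ORF, then extends ungapped over the full read. The read is rejected
#' when no k-mer matches ("no anchor"), when only multi-mapping k-mers match
#' ("ambiguous anchor"), when the implied placement leaves the ORF
#' ("out of bounds"), or when mismatches exceed `max_mismatch`. With
#' `search_rc = TRUE` the reverse complement is tried when the forward
#' orientation is rejected.
#'
#' @param seq read sequence (character).
#' @param ref a [reference_construct()].
#' @param k anchor length.
#' @param max_mismatch maximum mismatches tolerated over the read.
#' @param search_rc also try the reverse complement.
#' @param index optional precomputed [kmer_index()] (must match `k`).
#' @return a list: `accepted` (logical); when accepted, `orf_offset`
#'   (0-based), `matched_length`, `mismatch_indices` (0-based ORF indices),
#'   `strand`; when rejected, `reason`.
#' @export
anchor_align <- function(seq, ref, k = 15L, max_mismatch = 10L,
                         search_rc = FALSE, index = NULL) {
  stopifnot(k <= nchar(seq))
  if (is.null(index)) index <- kmer_index(ref, k)
  fwd <- align_forward(seq, ref, index, k, max_mismatch)
  if (fwd$accepted) { fwd$strand <- "+"; return(fwd) }
  if (search_rc) {
    rc <- align_forward(revcomp(seq), ref, index, k, max_mismatch)
    if (rc$accepted) { rc$strand <- "-"; return(rc) }
  }
  fwd
}

#' Call amino-acid substitutions from an accepted alignment
#'
#' Only codons fully covered by the read are evaluated. A call is emitted iff
#' the translated read codon differs from the reference amino acid
#' (synonymous changes emit nothing); codons containing an ambiguous base (N)
#' are uncallable and excluded from both calls and coverage.
#'
#' @param aln an accepted alignment from [anchor_align()].
#' @param seq the read sequence in reference orientation (reverse-complement
#'   the read first for minus-strand alignments).
#' @param ref a [reference_construct()].
#' @return a list with `calls` (data.frame `position`, `ref_aa`, `alt_aa`)
#'   and `covered` (native positions whose codon was callable).
#' @export
call_aa_mutations <- function(aln, seq, ref) {
  stopifnot(isTRUE(aln$accepted))
  off <- aln$orf_offset
  len <- aln$matched_length
  c0 <- as.integer(ceiling(off / 3))        # first fully covered codon
  c1 <- (off + len) %/% 3L - 1L             # last fully covered codon
  empty <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character())
  if (c1 < c0) return(list(calls = empty, covered = integer()))
  codons <- c0:c1
  read_cod <- substring(seq, 3L * codons - off + 1L, 3L * codons - off + 3L)
  callable <- !grepl("[^ACGT]", read_cod)
  codons <- codons[callable]
  if (!length(codons)) return(list(calls = empty, covered = integer()))
  read_cod <- read_cod[callable]
  alt_aa <- unname(Biostrings::GENETIC_CODE[read_cod])
  ref_aa <- strsplit(ref$aa_seq, "", fixed = TRUE)[[1L]][codons + 1L]
  pos <- ref$first_residue + codons
  hit <- alt_aa != ref_aa
  list(calls = data.frame(position = pos[hit], ref_aa = ref_aa[hit],
                          alt_aa = alt_aa[hit]),
       covered = pos)
}

#' Count per-position mutation frequencies for one library
#'
#' Aligns every read, calls amino-acid substitutions, and tabulates `k_i`
#' (reads with a nonsynonymous call at native position `i`), `n_i` (reads
#' whose span fully covers a callable codon `i`) and `f_i = k_i / n_i`.
#' Positions with `n_i < min_coverage` are flagged `low_coverage` and
#' excluded downstream; `f_i` is `NA` where `n_i = 0`. Multiple substitutions
#' on one read are counted independently at each position.
#'
#' @param reads a `read_set` or data.frame with columns `id`, `seq` (e.g.
#'   from [read_fastq()]).
#' @param ref a [reference_construct()].
#' @param library_id library label carried into downstream tables.
#' @param k,max_mismatch,search_rc alignment policy, see [anchor_align()].
#' @param min_coverage minimum covering reads for a position to be retained.
#' @return a list with
#'   `counts`: data.frame (class `position_counts`) with columns `library`,
#'   `position`, `ref_aa`, `k`, `n`, `f`, `flag`;
#'   `substitutions`: auxiliary per-substitution table (`position`, `ref_aa`,
#'   `alt_aa`, `reads`), reported but not used for calling;
#'   `n_reads`, `n_accepted`, `rejections` (reason table).
#' @export
count_library <- function(reads, ref, library_id, k = 15L, max_mismatch = 10L,
                          search_rc = FALSE, min_coverage = 20L) {
  if (nrow(reads) == 0L) stop("empty read set for library ", library_id)
  index <- kmer_index(ref, k)
  pos_all <- native_positions(ref)
  n_i <- k_i <- stats::setNames(integer(length(pos_all)), pos_all)
  sub_list <- vector("list", nrow(reads))
  reject <- character()
  n_acc <- 0L
  for (i in seq_len(nrow(reads))) {
    aln <- anchor_align(reads$seq[i], ref, k = k, max_mismatch = max_mismatch,
                        search_rc = search_rc, index = index)
    if (!aln$accepted) { reject <- c(reject, aln$reason); next }
    n_acc <- n_acc + 1L
    s <- if (identical(aln$strand, "-")) revcomp(reads$seq[i]) else reads$seq[i]
    res <- call_aa_mutations(aln, s, ref)
    cov <- as.character(res$covered)
    n_i[cov] <- n_i[cov] + 1L
    if (nrow(res$calls)) {
      hit <- as.character(res$calls$position)
      k_i[hit] <- k_i[hit] + 1L
      sub_list[[i]] <- res$calls
    }
  }
  f <- ifelse(n_i > 0L, k_i / n_i, NA_real_)
  flag <- ifelse(n_i == 0L, "no_coverage",
                 ifelse(n_i < min_coverage, "low_coverage", ""))
  counts <- data.frame(
    library = library_id, position = pos_all,
    ref_aa = strsplit(ref$aa_seq, "", fixed = TRUE)[[1L]],
    k = unname(k_i), n = unname(n_i), f = unname(f), flag = unname(flag))
  rownames(counts) <- NULL
  class(counts) <- c("position_counts", "data.frame")
  subs <- do.call(rbind, sub_list)
  substitutions <- if (is.null(subs)) {
    data.frame(position = integer(), ref_aa = character(),
               alt_aa = character(), reads = integer())
  } else {
    agg <- stats::aggregate(list(reads = rep(1L, nrow(subs))),
                            subs[c("position", "ref_aa", "alt_aa")], sum)
    agg[order(agg$position, agg$alt_aa), , drop = FALSE]
  }
  rej <- if (length(reject)) as.data.frame(table(reason = reject),
                                           stringsAsFactors = FALSE)
         else data.frame(reason = character(), Freq = integer())
  list(counts = counts, substitutions = substitutions,
       n_reads = nrow(reads), n_accepted = n_acc, rejections = rej)
}

#' Write / read a position-count table as TSV
#' @param counts a `position_counts` data.frame from [count_library()].
#' @param path TSV path.
#' @return `write_counts` returns `path` invisibly; `read_counts` the table.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(library = "character",
                                          position = "integer",
                                          ref_aa = "character",
                                          k = "integer", n = "integer",
                                          f = "numeric", flag = "character"))
  tab$flag[is.na(tab$flag)] <- ""
  class(tab) <- c("position_counts", "data.frame")
  tab
}
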