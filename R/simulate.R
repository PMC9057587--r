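#' Synthetic sort-seq library simulation
#'
#' These functions emulate the wet-lab arc of a yeast-display epitope-mapping
#' experiment at desk scale: error-prone PCR mutagenesis of the antigen ORF,
#' FACS selection of clones that still display antigen but have lost Fab
#' binding, expansion between rounds, and fragment sequencing of the selected
#' and unselected populations.
#'
#' A `clone_library` stores one row per nucleotide substitution in
#' `nt_subs` (`clone`, `pos0` 0-based ORF index, `ref`, `alt`), the derived
#' amino-acid substitutions in `aa_subs` (`clone`, `position` native
#' numbering, `ref_aa`, `alt_aa`; stop gains appear as `alt_aa = "*"`),
#' the per-genotype `displayed` flag (FALSE when any substitution creates a
#' stop codon), and `members`, the multiset of genotype ids making up the
#' current population (repeats appear after expansion).
#'
#' @name clone_library
NULL

new_clone_library <- function(ref, nt_subs, aa_subs, displayed, members) {
  structure(list(ref = ref, nt_subs = nt_subs, aa_subs = aa_subs,
                 displayed = displayed, members = members),
            class = "clone_library")
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf(paste0("clone_library on '%s': %d clones (%d genotypes), ",
                     "%d nt substitutions, %d aa substitutions, ",
                     "%.1f%% displayed\n"),
              x$ref$name, length(x$members), length(x$displayed),
              nrow(x$nt_subs), nrow(x$aa_subs),
              100 * mean(x$displayed[x$members])))
  invisible(x)
}

# Derive amino-acid substitutions and display status from nucleotide
# substitutions by mutating and translating each affected codon.
derive_aa_subs <- function(ref, nt_subs, n_clones) {
  displayed <- rep(TRUE, n_clones)
  if (nrow(nt_subs) == 0L) {
    aa_subs <- data.frame(clone = integer(), position = integer(),
                          ref_aa = character(), alt_aa = character())
    return(list(aa_subs = aa_subs, displayed = displayed))
  }
  codon0 <- nt_subs$pos0 %/% 3L
  within <- nt_subs$pos0 %% 3L
  key <- nt_subs$clone * (nchar(ref$nt_orf) %/% 3L) + codon0
  u <- !duplicated(key)
  uclone <- nt_subs$clone[u]
  ucodon <- codon0[u]
  ref_codon <- substring(ref$nt_orf, 3L * ucodon + 1L, 3L * ucodon + 3L)
  cod <- matrix(c(substr(ref_codon, 1L, 1L), substr(ref_codon, 2L, 2L),
                  substr(ref_codon, 3L, 3L)), ncol = 3L)
  m <- match(key, key[u])
  cod[cbind(m, within + 1L)] <- nt_subs$alt
  mut_codon <- paste0(cod[, 1L], cod[, 2L], cod[, 3L])
  alt_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  nonsyn <- alt_aa != ref_aa
  aa_subs <- data.frame(clone = uclone[nonsyn],
                        position = ref$first_residue + ucodon[nonsyn],
                        ref_aa = ref_aa[nonsyn], alt_aa = alt_aa[nonsyn])
  stopped <- unique(aa_subs$clone[aa_subs$alt_aa == "*"])
  displayed[stopped] <- FALSE
  list(aa_subs = aa_subs, displayed = displayed)
}

#' Mutagenize a display library by error-prone PCR
#'
#' Each clone receives a Poisson(`lambda_nt`) number of nucleotide
#' substitutions at ORF positions drawn uniformly without replacement; the
#' alternative base is uniform over the three non-reference bases. Amino-acid
#' substitutions and display status are derived by codon translation; clones
#' acquiring a stop codon are flagged non-displayed.
#'
#' @param ref a [reference_construct()].
#' @param n_clones library size.
#' @param lambda_nt mean nucleotide substitutions per clone (a low-rate
#'   error-prone PCR protocol typically realizes 1-3).
#' @param seed RNG seed; identical inputs give identical libraries.
#' @return a [clone_library].
#' @export
mutagenize_library <- function(ref, n_clones, lambda_nt = 2, seed = 1L) {
  stopifnot(inherits(ref, "reference_construct"), n_clones >= 1L,
            lambda_nt >= 0)
  orf_len <- nchar(ref$nt_orf)
  if (lambda_nt > orf_len)
    stop("lambda_nt (", lambda_nt, ") exceeds ORF length (", orf_len,
         "); cannot place substitutions without replacement")
  set.seed(seed)
  n_subs <- stats::rpois(n_clones, lambda_nt)
  n_subs <- pmin(n_subs, orf_len)
  hit <- which(n_subs > 0L)
  pos_list <- lapply(n_subs[hit], function(k) sample.int(orf_len, k) - 1L)
  pos0 <- unlist(pos_list, use.names = FALSE)
  clone <- rep(hit, n_subs[hit])
  if (is.null(pos0)) pos0 <- integer()
  orf_chars <- strsplit(ref$nt_orf, "", fixed = TRUE)[[1L]]
  ref_base <- orf_chars[pos0 + 1L]
  bases <- c("A", "C", "G", "T")
  # uniform over the 3 non-reference bases
  shift <- sample.int(3L, length(pos0), replace = TRUE)
  alt_base <- bases[(match(ref_base, bases) - 1L + shift) %% 4L + 1L]
  nt_subs <- data.frame(clone = clone, pos0 = pos0,
                        ref = ref_base, alt = alt_base)
  o <- order(nt_subs$clone, nt_subs$pos0)
  nt_subs <- nt_subs[o, , drop = FALSE]
  rownames(nt_subs) <- NULL
  d <- derive_aa_subs(ref, nt_subs, n_clones)
  new_clone_library(ref, nt_subs, d$aa_subs, d$displayed, seq_len(n_clones))
}

#' Selection parameters for the sort-seq gate
#'
#' The FACS gate keeps singlets with positive antigen expression and negative
#' Fab binding. A displayed clone is "binding-loss" when at least one of its
#' nonsynonymous substitutions at an epitope position registers an effect
#' (drawn once per substitution with probability `q_effect`; a clone's
#' phenotype is a property of its genotype and persists across rounds).
#' Each round captures binding-loss clones with probability `p_hit` and
#' binding-retained clones with probability `p_bg`; non-displayed clones are
#' never captured.
#'
#' @param epitope_positions native positions whose mutation can abolish
#'   binding.
#' @param q_effect probability that an epitope-position substitution
#'   abolishes binding.
#' @param p_hit per-round gate-capture probability of a binding-loss clone.
#' @param p_bg per-round gate-capture probability of a binding-retained
#'   clone (gate leakage).
#' @param rounds number of selection rounds (default 2).
#' @return an object of class `selection_params`.
#' @export
selection_params <- function(epitope_positions, q_effect = 0.8,
                             p_hit = 0.9, p_bg = 0.005, rounds = 2L) {
  stopifnot(q_effect >= 0, q_effect <= 1,
            p_bg >= 0, p_bg <= p_hit, p_hit <= 1, rounds >= 1L)
  structure(list(epitope_positions = sort(unique(as.integer(epitope_positions))),
                 q_effect = q_effect, p_hit = p_hit, p_bg = p_bg,
                 rounds = as.integer(rounds)),
            class = "selection_params")
}

#' Simulate FACS rounds selecting loss-of-binding clones
#'
#' Applies `params$rounds` sequential gate/expand cycles: per-clone capture
#' Bernoulli draws, followed by resampling the captured pool with replacement
#' to `target_size` (expansion between rounds). A round capturing no clone
#' is an error ("selection extinguished library").
#'
#' @param lib a [clone_library].
#' @param params a [selection_params()].
#' @param target_size population size after each expansion.
#' @param seed RNG seed.
#' @return the selected [clone_library] (same genotype tables, new members).
#' @export
select_library <- function(lib, params, target_size = length(lib$members),
                           seed = 1L) {
  stopifnot(inherits(lib, "clone_library"),
            inherits(params, "selection_params"),
            length(lib$members) > 0L, target_size >= 1L)
  set.seed(seed)
  # phenotype per genotype: effect drawn once per epitope substitution
  epi <- lib$aa_subs[lib$aa_subs$position %in% params$epitope_positions &
                       lib$aa_subs$alt_aa != "*", , drop = FALSE]
  loss <- rep(FALSE, length(lib$displayed))
  if (nrow(epi) > 0L) {
    eff <- stats::runif(nrow(epi)) < params$q_effect
    loss[unique(epi$clone[eff])] <- TRUE
  }
  loss <- loss & lib$displayed
  members <- lib$members
  for (r in seq_len(params$rounds)) {
    p <- ifelse(lib$displayed[members],
                ifelse(loss[members], params$p_hit, params$p_bg), 0)
    captured <- members[stats::runif(length(members)) < p]
    if (length(captured) == 0L)
      stop("selection extinguished library at round ", r,
           ": no clone passed the gate")
    members <- captured[sample.int(length(captured), target_size,
                                   replace = TRUE)]
  }
  new_clone_library(lib$ref, lib$nt_subs, lib$aa_subs, lib$displayed, members)
}

# Mutated ORF strings for the given genotype ids.
mutant_orfs <- function(lib, genotypes) {
  orf_chars <- strsplit(lib$ref$nt_orf, "", fixed = TRUE)[[1L]]
  vapply(genotypes, function(g) {
    rows <- lib$nt_subs[lib$nt_subs$clone == g, , drop = FALSE]
    ch <- orf_chars
    ch[rows$pos0 + 1L] <- rows$alt
    paste0(ch, collapse = "")
  }, "")
}

#' Simulate fragment sequencing of a library
#'
#' Emulates tagmentation-style fragmentation followed by short-read
#' sequencing: `round(coverage * orf_length / read_length)` reads, each drawn
#' from a clone chosen uniformly from the population, with a uniform
#' forward-strand start offset and iid substitution errors at `error_rate`.
#' Base qualities are constant ("I"). The read identifier records the source
#' genotype and offset for debugging (`r<i>|clone=<g>|offset=<o>`).
#'
#' @param lib a [clone_library].
#' @param coverage mean reads per ORF position.
#' @param read_length read length in bases (must not exceed the ORF length).
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed.
#' @return a data.frame of class `read_set` with columns `id`, `seq`,
#'   `clone`, `offset` (0-based).
#' @export
sequence_library <- function(lib, coverage = 200, read_length = 150L,
                             error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(lib, "clone_library"), coverage > 0,
            error_rate >= 0, error_rate < 1)
  if (length(lib$members) == 0L) stop("cannot sequence an empty library")
  orf_len <- nchar(lib$ref$nt_orf)
  if (read_length > orf_len)
    stop("read_length (", read_length, ") exceeds ORF length (", orf_len, ")")
  n_reads <- round(coverage * orf_len / read_length)
  set.seed(seed)
  clone <- lib$members[sample.int(length(lib$members), n_reads,
                                  replace = TRUE)]
  offset <- sample.int(orf_len - read_length + 1L, n_reads,
                       replace = TRUE) - 1L
  orfs <- mutant_orfs(lib, sort(unique(clone)))
  names(orfs) <- sort(unique(clone))
  seqs <- substring(orfs[as.character(clone)], offset + 1L,
                    offset + read_length)
  # sequencing errors: iid per base
  n_err <- stats::rbinom(n_reads, read_length, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- sample.int(read_length, n_err[i])
    shift <- sample.int(3L, n_err[i], replace = TRUE)
    ch[at] <- bases[(match(ch[at], bases) - 1L + shift) %% 4L + 1L]
    seqs[i] <- paste0(ch, collapse = "")
  }
  out <- data.frame(
    id = sprintf("r%06d|clone=%d|offset=%d", seq_len(n_reads), clone, offset),
    seq = unname(seqs), clone = clone, offset = offset)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write / read a read set as FASTQ
#'
#' Qualities are constant "I" (Q40); quality-aware filtering is outside the
#' simulator's scope.
#'
#' @param reads a `read_set` from [sequence_library()].
#' @param path FASTQ file path.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   data.frame with columns `id`, `seq`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), row.names = NULL)
}

#' Ground truth of a synthetic run
#'
#' Records the planted epitope positions, decoy positions (forced to enrich
#' but structurally excludable), selection parameters, mutation rate and seed
#' of a simulation, round-trippable through a two-column TSV.
#'
#' @param epitope_positions planted epitope positions (native numbering).
#' @param params a [selection_params()].
#' @param lambda_nt mutation rate used.
#' @param seed simulation seed.
#' @param decoy_positions positions enriched by selection but expected to be
#'   removed by the structural filter.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(epitope_positions, params, lambda_nt, seed,
                         decoy_positions = integer()) {
  structure(list(epitope_positions = sort(unique(as.integer(epitope_positions))),
                 decoy_positions = sort(unique(as.integer(decoy_positions))),
                 q_effect = params$q_effect, p_hit = params$p_hit,
                 p_bg = params$p_bg, rounds = params$rounds,
                 lambda_nt = lambda_nt, seed = as.integer(seed)),
            class = "ground_truth")
}

truth_fields <- c("epitope_positions", "decoy_positions", "q_effect",
                  "p_hit", "p_bg", "rounds", "lambda_nt", "seed")

#' Write / read the ground-truth TSV
#'
#' @param truth a [ground_truth()].
#' @param path TSV path (columns `field`, `value`; position lists
#'   comma-joined, sorted ascending).
#' @return `write_truth` returns `path` invisibly; `read_truth` the
#'   reconstructed [ground_truth()]. A missing field on read-back is a
#'   schema error.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  val <- vapply(truth_fields, function(f)
    paste(truth[[f]], collapse = ","), "")
  utils::write.table(data.frame(field = truth_fields, value = val),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  missing <- setdiff(truth_fields, tab$field)
  if (length(missing))
    stop("ground-truth file ", path, " is missing field(s): ",
         paste(missing, collapse = ", "))
  get <- function(f) tab$value[match(f, tab$field)]
  num <- function(f) as.numeric(get(f))
  ints <- function(f) {
    v <- get(f)
    if (v == "") integer() else as.integer(strsplit(v, ",")[[1L]])
  }
  params <- selection_params(ints("epitope_positions"),
                             q_effect = num("q_effect"), p_hit = num("p_hit"),
                             p_bg = num("p_bg"), rounds = num("rounds"))
  ground_truth(ints("epitope_positions"), params, num("lambda_nt"),
               as.integer(num("seed")), decoy_positions = ints("decoy_positions"))
}
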