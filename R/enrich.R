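#' Cross-library normalization and enrichment calling
#'
#' Per-position mutation frequencies from the selected and unselected
#' libraries are normalized by the median of geometric mean ratios (the
#' median-of-ratios size-factor estimator applied to frequencies), scored as
#' log2 enrichment relative to the within-sample median frequency, and
#' called at an inclusive threshold (default 2).
#'
#' @name enrichment
NULL

#' Assemble a frequency matrix from per-library count tables
#'
#' Retains positions whose frequency is defined (covered at or above the
#' count tables' `min_coverage`) in every library; one library must carry
#' the `reference` (unselected) role.
#'
#' @param count_tables list of `position_counts` data.frames (one per
#'   library, see [count_library()]).
#' @param reference library id of the unselected reference.
#' @return a numeric matrix (positions x libraries, rownames = native
#'   positions) with attributes `reference` and `dropped` (positions removed
#'   for missing coverage in at least one library).
#' @export
frequency_matrix <- function(count_tables, reference) {
  stopifnot(length(count_tables) >= 2L)
  ids <- vapply(count_tables, function(tab) tab$library[1L], "")
  if (anyDuplicated(ids)) stop("duplicate library ids")
  if (!reference %in% ids)
    stop("reference library '", reference, "' not among: ",
         paste(ids, collapse = ", "))
  pos <- sort(Reduce(intersect, lapply(count_tables, function(tab)
    tab$position[tab$flag == "" & !is.na(tab$f)])))
  all_pos <- sort(unique(unlist(lapply(count_tables, `[[`, "position"))))
  if (!length(pos)) stop("no position has defined frequency in all libraries")
  F <- vapply(count_tables, function(tab) tab$f[match(pos, tab$position)],
              numeric(length(pos)))
  F <- matrix(F, nrow = length(pos),
              dimnames = list(pos, ids))
  attr(F, "reference") <- reference
  attr(F, "dropped") <- setdiff(all_pos, pos)
  F
}

#' Size factors by the median of geometric mean ratios
#'
#' For each position `i` with strictly positive frequency in all `m`
#' libraries, the geometric mean `g_i = (prod_j f_ij)^(1/m)` is formed; the
#' size factor of library `j` is the median over those positions of
#' `f_ij / g_i`. Positions with any zero are excluded here (their geometric
#' mean would vanish) but are retained for scoring.
#'
#' @param F positions x libraries frequency matrix ([frequency_matrix()]).
#' @return named positive numeric vector of size factors, one per library.
#' @export
size_factors <- function(F) {
  stopifnot(is.matrix(F), ncol(F) >= 2L)
  if (any(!is.finite(F)) || any(F < 0))
    stop("frequency matrix must be finite and non-negative")
  pos_ok <- rowSums(F > 0) == ncol(F)
  if (!any(pos_ok))
    stop("normalization undefined: no position has positive frequency ",
         "in every library")
  Fp <- F[pos_ok, , drop = FALSE]
  g <- exp(rowMeans(log(Fp)))             # geometric mean, log-space for
  s <- apply(Fp / g, 2L, stats::median)   # stability; median of ratios
  stats::setNames(s, colnames(F))
}

#' Normalize frequencies by size factors
#'
#' @param F frequency matrix.
#' @param s size factors from [size_factors()] (names must match columns).
#' @return matrix of normalized frequencies `f_ij / s_j`.
#' @export
normalize_frequencies <- function(F, s) {
  if (length(s) != ncol(F) || !all(colnames(F) == names(s)))
    stop("size factors do not match the frequency matrix columns")
  sweep(F, 2L, s, "/")
}

#' Log2 enrichment relative to the within-sample median
#'
#' `e_ij = log2(fnorm_ij / median_i' fnorm_i'j)`, the median taken over all
#' retained positions of library `j` (even counts: mean of the two central
#' values). Positions with zero normalized frequency score `-Inf` and are
#' never called.
#'
#' @param fnorm normalized frequency matrix.
#' @param library column (library id) to score.
#' @return named numeric vector of scores per position.
#' @export
enrichment_scores <- function(fnorm, library) {
  x <- fnorm[, library]
  if (sum(x > 0) < 3L)
    stop("library '", library, "' has fewer than 3 positions with ",
         "positive normalized frequency")
  med <- stats::median(x)
  if (med <= 0) stop("degenerate sample: median normalized frequency is 0")
  log2(x / med)
}

#' Call positions at a log2-enrichment threshold
#'
#' The threshold is inclusive: a score exactly equal to `threshold` is
#' called.
#'
#' @param e named score vector from [enrichment_scores()].
#' @param threshold log2 enrichment cutoff (default 2, i.e. 4x the median).
#' @return sorted integer vector of called native positions.
#' @export
call_positions <- function(e, threshold = 2) {
  stopifnot(!any(is.na(e)))
  sort(as.integer(names(e)[e >= threshold]))
}

#' Log2 ratio to the unselected reference (auxiliary)
#'
#' Reported alongside the within-sample score but not used for calling.
#' Entries where the reference frequency is zero are `NA` (flagged, not
#' computed).
#'
#' @param fnorm normalized frequency matrix.
#' @param library selected library id.
#' @param reference reference library id.
#' @return named numeric vector `log2(fnorm_ij / fnorm_ir)`.
#' @export
reference_delta <- function(fnorm, library, reference) {
  fr <- fnorm[, reference]
  ifelse(fr > 0, log2(fnorm[, library] / fr), NA_real_)
}

#' Full enrichment table across selected libraries
#'
#' Runs [size_factors()], [normalize_frequencies()], [enrichment_scores()],
#' [call_positions()] and [reference_delta()] and assembles the long-format
#' result, one row per (position, selected library).
#'
#' @param F frequency matrix from [frequency_matrix()] (its `reference`
#'   attribute names the unselected library).
#' @param threshold calling threshold, see [call_positions()].
#' @param pseudocount added to every frequency before normalization
#'   (default 0; a small pseudocount rescues all-zero positions for the
#'   size-factor step at the cost of shrinking large ratios).
#' @return data.frame of class `enrichment_table` with columns `position`,
#'   `library`, `f`, `size_factor`, `f_norm`, `e_log2`, `ref_delta`,
#'   `called`; size factors for all libraries in attribute `size_factors`.
#' @export
enrichment_table <- function(F, threshold = 2, pseudocount = 0) {
  reference <- attr(F, "reference")
  if (is.null(reference)) stop("frequency matrix lacks a reference attribute")
  stopifnot(pseudocount >= 0)
  Fp <- F + pseudocount
  s <- size_factors(Fp)
  fnorm <- normalize_frequencies(Fp, s)
  selected <- setdiff(colnames(F), reference)
  rows <- lapply(selected, function(j) {
    e <- enrichment_scores(fnorm, j)
    called <- call_positions(e, threshold)
    data.frame(position = as.integer(rownames(F)), library = j,
               f = F[, j], size_factor = s[[j]], f_norm = fnorm[, j],
               e_log2 = e, ref_delta = reference_delta(fnorm, j, reference),
               called = as.integer(rownames(F)) %in% called)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "size_factors") <- s
  attr(out, "reference") <- reference
  attr(out, "threshold") <- threshold
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Called positions of an enrichment table
#' @param etab an `enrichment_table`.
#' @param library optional library id (default: union over libraries).
#' @return sorted integer vector of called positions.
#' @export
called_positions <- function(etab, library = NULL) {
  if (!is.null(library)) etab <- etab[etab$library == library, , drop = FALSE]
  sort(unique(etab$position[etab$called]))
}

#' Write / read an enrichment table as TSV
#' @param etab an `enrichment_table`.
#' @param path TSV path; metadata (reference, threshold, size factors) go in
#'   `#`-prefixed header lines.
#' @return `write_enrichment` returns `path` invisibly; `read_enrichment`
#'   the table with attributes restored.
#' @export
write_enrichment <- function(etab, path) {
  s <- attr(etab, "size_factors")
  hdr <- c(sprintf("# reference=%s", attr(etab, "reference")),
           sprintf("# threshold=%.17g", attr(etab, "threshold")),
           sprintf("# size_factor %s=%.17g", names(s), s))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(etab, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           sep = "\t", header = TRUE)
  sf_lines <- grep("^# size_factor ", meta, value = TRUE)
  sf <- as.numeric(sub(".*=", "", sf_lines))
  names(sf) <- sub("^# size_factor (\\S+)=.*", "\\1", sf_lines)
  attr(tab, "size_factors") <- sf
  attr(tab, "reference") <- sub("^# reference=", "",
                                grep("^# reference=", meta, value = TRUE))
  attr(tab, "threshold") <- as.numeric(sub("^# threshold=", "",
                                           grep("^# threshold=", meta,
                                                value = TRUE)))
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
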