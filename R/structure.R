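#' Structural annotation and epitope filtering
#'
#' Called positions are filtered against an atomic structure (or a
#' precomputed residue annotation table): positions that are buried
#' (relative solvent accessibility below `rsa_min`) or involved in a
#' disulfide bond are excluded from the putative epitope. SASA is computed
#' by Shrake-Rupley sphere sampling; RSA normalizes by the Tien et al.
#' (2013) theoretical maximum ASA per residue type.
#'
#' @name structure_filter
NULL

# van der Waals radii (Angstrom) by element
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

# Tien et al. (2013) theoretical maximum ASA (Angstrom^2) by residue type
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
             GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
             LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
             SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

element_of <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  # fall back to the atom name: first alphabetic character
  el[miss] <- substr(gsub("[^A-Za-z]", "", toupper(elety[miss])), 1L, 1L)
  el
}

#' Parse an atomic structure (PDB or mmCIF)
#'
#' Keeps the first model only (warning when more are present), drops
#' hydrogens and waters, and resolves alternate locations by highest
#' occupancy, ties broken alphabetically by altloc code.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @return a data.frame of class `structure_model` with columns `chain`,
#'   `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`, `o`.
#' @export
parse_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = TRUE,
                         rm.alt = FALSE),
    error = function(e) stop("cannot parse structure file ", path, ": ",
                             conditionMessage(e)))
  if (!is.null(dim(pdb$xyz)) && nrow(pdb$xyz) > 1L)
    warning("structure has ", nrow(pdb$xyz), " models; keeping model 1")
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  at$element <- element_of(at$elesy, at$elety)
  at <- at[at$element != "H" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("empty model in ", path,
                           " after dropping hydrogens and waters")
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  # altloc: highest occupancy, then alphabetical
  ord <- order(at$chain, at$resno, at$elety, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  dup <- duplicated(at[c("chain", "resno", "insert", "elety")])
  at <- at[!dup, , drop = FALSE]
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = trimws(at$elety), element = at$element,
                    x = at$x, y = at$y, z = at$z, o = at$o)
  if (any(!is.finite(as.matrix(out[c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  rownames(out) <- NULL
  class(out) <- c("structure_model", "data.frame")
  out
}

# Near-uniform points on the unit sphere (Fibonacci / golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]),
                                         collapse = ", "),
            "; using carbon radius 1.7 A")
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Distributes `n_points` near-uniform test points on each atom's
#' solvent-expanded sphere (radius `r_vdw + probe_radius`); a point is
#' accessible when it lies outside every other atom's expanded sphere. The
#' atom's SASA is `4*pi*(r+probe)^2` times the accessible fraction.
#'
#' @param xyz numeric matrix (atoms x 3) of coordinates in Angstrom.
#' @param radii per-atom van der Waals radii.
#' @param probe_radius solvent probe radius (default 1.4 A, water).
#' @param n_points test points per atom (default 960).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
shrake_rupley <- function(xyz, radii, probe_radius = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, length(radii) == nrow(xyz), probe_radius >= 0)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  R <- radii + probe_radius
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) { area[i] <- 4 * pi * R[i]^2; next }
    p <- pts * R[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      free <- free & dj > R[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  area
}

#' Per-residue SASA of a structure model
#'
#' @param model a `structure_model` from [parse_structure()].
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_points Shrake-Rupley test points per atom.
#' @return data.frame with `chain`, `resno`, `resid`, `sasa` (sum over the
#'   residue's atoms).
#' @export
residue_sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  stopifnot(nrow(model) > 0L)
  atom_area <- shrake_rupley(model[c("x", "y", "z")],
                             vdw_radius(model$element),
                             probe_radius, n_points)
  key <- paste(model$chain, model$resno)
  u <- !duplicated(key)
  out <- data.frame(chain = model$chain[u], resno = model$resno[u],
                    resid = model$resid[u],
                    sasa = as.numeric(rowsum(atom_area, key)[unique(key), ]))
  rownames(out) <- NULL
  out
}

#' Relative solvent accessibility
#'
#' `rsa = sasa / max_asa(residue type)`; residues of a type absent from the
#' table get `NA` with a warning and are excluded from burial decisions.
#'
#' @param res_sasa data.frame from [residue_sasa()].
#' @param max_asa named maximum-ASA table (default: Tien et al. 2013
#'   theoretical values).
#' @return `res_sasa` with an `rsa` column appended.
#' @export
relative_sasa <- function(res_sasa, max_asa = MAX_ASA) {
  mx <- max_asa[res_sasa$resid]
  if (anyNA(mx))
    warning("no max-ASA value for residue type(s) ",
            paste(unique(res_sasa$resid[is.na(mx)]), collapse = ", "),
            "; rsa undefined there")
  res_sasa$rsa <- res_sasa$sasa / unname(mx)
  res_sasa
}

#' Detect disulfide bonds from SG-SG distances
#'
#' Pairs distinct cysteine SG atoms at distance <= `sg_cutoff` (the canonical
#' S-S bond is about 2.05 A). Each SG joins at most one partner; candidate
#' pairs are resolved nearest-first.
#'
#' @param model a `structure_model`.
#' @param sg_cutoff maximum SG-SG distance in Angstrom (default 2.3).
#' @return data.frame with one row per bond: `chain1`, `resno1`, `chain2`,
#'   `resno2`, `distance`.
#' @export
detect_disulfides <- function(model, sg_cutoff = 2.3) {
  sg <- model[model$resid == "CYS" & model$elety == "SG", , drop = FALSE]
  empty <- data.frame(chain1 = character(), resno1 = integer(),
                      chain2 = character(), resno2 = integer(),
                      distance = numeric())
  if (nrow(sg) < 2L) return(empty)
  d <- as.matrix(stats::dist(sg[c("x", "y", "z")]))
  cand <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (used[i] || used[j]) next
    if (sg$chain[i] == sg$chain[j] && sg$resno[i] == sg$resno[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = sg$chain[i], resno1 = sg$resno[i],
      chain2 = sg$chain[j], resno2 = sg$resno[j], distance = d[i, j])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map construct native numbering onto structure residue numbers
#'
#' When the chain's author residue numbers already equal the construct's
#' native numbers with matching amino acids, the identity map is used.
#' Otherwise the single ungapped offset maximizing sequence identity over
#' the overlap is chosen; it must reach at least `min_identity`. Construct
#' positions without a matching residue are flagged unmapped.
#'
#' @param ref a [reference_construct()].
#' @param model a `structure_model`.
#' @param chain chain identifier in the structure.
#' @param min_identity minimum fraction of matching amino acids over the
#'   overlap (default 0.9).
#' @return data.frame of class `numbering_map`: `position` (native),
#'   `chain`, `resno` (NA when unmapped), `mapped`.
#' @export
map_numbering <- function(ref, model, chain, min_identity = 0.9) {
  at <- model[model$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not present in the model")
  resno <- sort(unique(at$resno))
  res_aa <- AA3TO1[at$resid[match(resno, at$resno)]]
  res_aa[is.na(res_aa)] <- "X"
  pos <- native_positions(ref)
  ref_aa <- strsplit(ref$aa_seq, "", fixed = TRUE)[[1L]]
  score_offset <- function(off) {
    hit <- match(pos + off, resno)
    ok <- !is.na(hit)
    if (!any(ok)) return(c(identity = 0, overlap = 0))
    c(identity = mean(ref_aa[ok] == res_aa[hit[ok]]), overlap = sum(ok))
  }
  id0 <- score_offset(0L)
  offset <- 0L
  if (!(id0["overlap"] > 0 && id0["identity"] >= min_identity &&
        id0["identity"] == 1)) {
    offsets <- (min(resno) - max(pos)):(max(resno) - min(pos))
    sc <- t(vapply(offsets, score_offset, c(identity = 0, overlap = 0)))
    best <- which.max(sc[, "identity"] * (sc[, "overlap"] > 0))
    if (sc[best, "overlap"] == 0 || sc[best, "identity"] < min_identity)
      stop("numbering map failed: no ungapped offset reaches ",
           min_identity * 100, "% identity")
    offset <- offsets[best]
  }
  hit <- match(pos + offset, resno)
  mapped <- !is.na(hit) & ref_aa == res_aa[ifelse(is.na(hit), 1L, hit)]
  out <- data.frame(position = pos, chain = chain,
                    resno = ifelse(mapped, resno[hit], NA_integer_),
                    mapped = mapped)
  attr(out, "offset") <- offset
  class(out) <- c("numbering_map", "data.frame")
  out
}

#' Annotate construct residues from a structure
#'
#' Combines [residue_sasa()], [relative_sasa()], [detect_disulfides()] and
#' [map_numbering()] into a per-position annotation table in construct
#' native numbering. SASA is computed on the full model (all chains) so that
#' packing against other chains counts as burial.
#'
#' @param ref a [reference_construct()].
#' @param model a `structure_model`.
#' @param chain chain carrying the construct.
#' @param probe_radius,n_points see [residue_sasa()].
#' @param sg_cutoff see [detect_disulfides()].
#' @return annotation data.frame: `position`, `rsa`, `disulfide` (mapped
#'   positions only).
#' @export
annotate_structure <- function(ref, model, chain, probe_radius = 1.4,
                               n_points = 960L, sg_cutoff = 2.3) {
  nm <- map_numbering(ref, model, chain)
  rs <- relative_sasa(residue_sasa(model, probe_radius, n_points))
  ss <- detect_disulfides(model, sg_cutoff)
  ss_res <- c(paste(ss$chain1, ss$resno1), paste(ss$chain2, ss$resno2))
  ok <- nm$mapped
  key <- paste(chain, nm$resno[ok])
  idx <- match(key, paste(rs$chain, rs$resno))
  data.frame(position = nm$position[ok], rsa = rs$rsa[idx],
             disulfide = key %in% ss_res)
}

#' Read / write a per-residue annotation table
#'
#' The TSV carries `position` (native numbering), `rsa` and `disulfide`
#' (TRUE/FALSE) and can replace a structure entirely.
#'
#' @param annotation data.frame with columns `position`, `rsa`, `disulfide`.
#' @param path TSV path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   the validated table.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(all(c("position", "rsa", "disulfide") %in% names(annotation)))
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("position", "rsa", "disulfide")
  if (!all(need %in% names(tab)))
    stop("annotation table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  stopifnot(is.numeric(tab$rsa), is.logical(tab$disulfide))
  if (anyDuplicated(tab$position)) stop("duplicate positions in ", path)
  tab
}

#' Filter called positions by burial and disulfide involvement
#'
#' Removes called positions with `disulfide = TRUE` or `rsa < rsa_min`.
#' Positions absent from the annotation are kept with flag `unfiltered`
#' (set `drop_unannotated = TRUE` to drop them instead). The exclusion
#' reason is recorded for every removed position.
#'
#' @param called integer vector of called native positions.
#' @param annotation data.frame (`position`, `rsa`, `disulfide`), from
#'   [annotate_structure()] or [read_annotation()].
#' @param scores optional named score vector carried into the output.
#' @param rsa_min burial threshold on relative solvent accessibility
#'   (default 0.15).
#' @param drop_unannotated drop positions lacking annotation instead of
#'   keeping them flagged.
#' @return data.frame of class `epitope_set`: `position`, `e_log2`, `rsa`,
#'   `disulfide`, `kept`, `reason`. The epitope set is `position[kept]`.
#' @export
filter_epitope <- function(called, annotation, scores = NULL, rsa_min = 0.15,
                           drop_unannotated = FALSE) {
  called <- sort(unique(as.integer(called)))
  idx <- match(called, annotation$position)
  rsa <- annotation$rsa[idx]
  ss <- annotation$disulfide[idx]
  known <- !is.na(idx) & !is.na(rsa)
  reason <- character(length(called))
  reason[!known] <- if (drop_unannotated) "unannotated" else "unfiltered"
  reason[known & ss] <- "disulfide"
  reason[known & !ss & rsa < rsa_min] <- "buried"
  kept <- !(reason %in% c("disulfide", "buried", "unannotated"))
  out <- data.frame(
    position = called,
    e_log2 = if (is.null(scores)) rep(NA_real_, length(called))
             else unname(scores[as.character(called)]),
    rsa = rsa, disulfide = ifelse(known, ss, NA), kept = kept,
    reason = reason)
  # filter soundness: no kept position may be buried or disulfide-bonded
  stopifnot(!any(out$kept & !is.na(out$rsa) & out$rsa < rsa_min),
            !any(out$kept & !is.na(out$disulfide) & out$disulfide))
  class(out) <- c("epitope_set", "data.frame")
  out
}

#' Write a structure copy with enrichment scores in the B-factor column
#'
#' Convenience output for visualization: every atom of a mapped residue gets
#' its position's score (clamped below at 0); other atoms get 0.
#'
#' @param model a `structure_model`.
#' @param scores named per-position score vector.
#' @param nmap a `numbering_map` from [map_numbering()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_score_pdb <- function(model, scores, nmap, path) {
  b <- rep(0, nrow(model))
  ok <- nmap$mapped & as.character(nmap$position) %in% names(scores)
  for (r in which(ok)) {
    sel <- model$chain == nmap$chain[r] & model$resno == nmap$resno[r]
    b[sel] <- max(0, scores[[as.character(nmap$position[r])]])
  }
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)),
    ifelse(nchar(model$elety) < 4L, paste0(" ", model$elety), model$elety),
    model$resid, model$chain, model$resno, model$x, model$y, model$z,
    model$o, pmin(b, 99.99), model$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
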