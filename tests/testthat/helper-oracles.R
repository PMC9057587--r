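# Independent brute-force oracles and coordinate fixtures used across the
# suite. These deliberately share no code with the implementation: explicit
# loops, naive medians, closed forms.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# median of per-position ratios to the across-library geometric mean
oracle_size_factors <- function(F) {
  m <- ncol(F)
  keep <- integer()
  for (i in seq_len(nrow(F)))
    if (all(F[i, ] > 0)) keep <- c(keep, i)
  g <- numeric(length(keep))
  for (t in seq_along(keep)) {
    p <- 1
    for (j in seq_len(m)) p <- p * F[keep[t], j]
    g[t] <- p^(1 / m)
  }
  s <- numeric(m)
  for (j in seq_len(m)) {
    r <- numeric(length(keep))
    for (t in seq_along(keep)) r[t] <- F[keep[t], j] / g[t]
    s[j] <- oracle_median(r)
  }
  names(s) <- colnames(F)
  s
}

oracle_enrichment_scores <- function(fnorm, j) {
  x <- fnorm[, j]
  med <- oracle_median(x)
  e <- numeric(length(x))
  for (i in seq_along(x)) e[i] <- log2(x[i] / med)
  names(e) <- rownames(fnorm)
  e
}

oracle_reference_delta <- function(fnorm, j, r) {
  out <- numeric(nrow(fnorm))
  for (i in seq_len(nrow(fnorm)))
    out[i] <- if (fnorm[i, r] > 0) log2(fnorm[i, j] / fnorm[i, r])
              else NA_real_
  names(out) <- rownames(fnorm)
  out
}

random_freq_matrix <- function(n_pos = 50L, n_lib = 4L) {
  F <- matrix(stats::runif(n_pos * n_lib, 1e-4, 0.5), n_pos, n_lib,
              dimnames = list(seq(22L, length.out = n_pos),
                              paste0("lib", seq_len(n_lib))))
  attr(F, "reference") <- "lib1"
  F
}

# accessible area of each of two equal spheres of expanded radius R whose
# centers are d apart (d < 2R): full sphere minus the spherical cap of
# height h = R - d/2 swallowed by the partner
cap_closed_form <- function(R, d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)

make_structure_model <- function(elety, resno, xyz, resid = "GLY",
                                 chain = "A") {
  m <- data.frame(chain = chain, resno = resno,
                  resid = rep_len(resid, length(elety)), elety = elety,
                  element = substr(elety, 1L, 1L),
                  x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1)
  class(m) <- c("structure_model", "data.frame")
  m
}

pdb_atom_line <- function(i, elety, resid, chain, resno, x, y, z,
                          element = substr(elety, 1L, 1L), occ = 1,
                          alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, elety, alt, resid, chain, resno, x, y, z, occ, 0, element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# idealized fully extended Gly-Gly-Gly backbone (phi = psi = omega = 180),
# laid out in the xy-plane with standard bond lengths and angles
ggg_extended_model <- function() {
  rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                           sin(th) * v[1] + cos(th) * v[2])
  blen <- c(1.458, 1.525, 1.329)             # N-CA, CA-C, C-N
  bang <- c(111, 117, 121) * pi / 180        # N-CA-C, CA-C-N, C-N-CA
  atoms <- list()
  p <- c(0, 0); dir <- c(1, 0); sgn <- 1
  for (res in 1:3) {
    atoms[[length(atoms) + 1L]] <- list("N", res, p)
    for (b in 1:3) {
      if (res == 3L && b == 3L) break
      p2 <- p + blen[b] * dir
      nm <- c("CA", "C", "N")[b]
      if (nm != "N") atoms[[length(atoms) + 1L]] <- list(nm, res, p2)
      if (nm == "C") {
        odir <- rot(dir, -sgn * (pi - 121 * pi / 180))
        atoms[[length(atoms) + 1L]] <- list("O", res, p2 + 1.231 * odir)
      }
      dir <- rot(dir, sgn * (pi - bang[b]))
      sgn <- -sgn
      p <- p2
    }
  }
  elety <- vapply(atoms, function(a) a[[1]], "")
  resno <- vapply(atoms, function(a) a[[2]], 0)
  xy <- t(vapply(atoms, function(a) a[[3]], c(0, 0)))
  make_structure_model(elety, resno, cbind(xy, 0))
}

# small fixed construct used across read-processing tests:
# 12 aa, native numbering from 22
toy_reference <- function() {
  reference_construct(
    "toy",
    paste0("ATGGCTGAAACCGGTTGGAAAGATCTGTTCCACCGT",
           collapse = ""),
    first_residue = 22L)
}
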