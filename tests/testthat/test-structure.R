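test_that("structure parsing applies model, water, hydrogen, altloc policy", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.3, 2.4, 0),
    pdb_atom_line(5, "H", "ALA", "A", 1, -0.5, 0.5, 0, element = "H"),
    pdb_atom_line(6, "O", "HOH", "A", 90, 8, 8, 8))
  path <- write_toy_pdb(lines)
  m <- parse_structure(path)
  # hydrogens and waters dropped
  expect_equal(nrow(m), 4L)
  expect_false(any(m$element == "H"))
  expect_false(any(m$resid == "HOH"))

  # two models: first kept with a warning
  path2 <- write_toy_pdb(c("MODEL     1", lines[1:4], "ENDMDL",
                           "MODEL     2", lines[1:4], "ENDMDL"))
  expect_warning(m2 <- parse_structure(path2), "models")
  expect_equal(nrow(m2), 4L)

  # altloc: highest occupancy wins
  alt <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
                         alt = "A"),
           pdb_atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.6,
                         alt = "B"))
  m3 <- parse_structure(write_toy_pdb(alt))
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$x, 5)

  # garbage in, error out
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(parse_structure(bad))
})

test_that("SASA matches isolated-sphere and spherical-cap closed forms", {
  probe <- 1.4
  # isolated carbon: 4 pi (1.7 + 1.4)^2
  a <- shrake_rupley(matrix(0, 1, 3), 1.7, probe, 960)
  iso <- 4 * pi * 3.1^2
  expect_lt(abs(a - iso) / iso, 0.01)

  # two atoms beyond 2(r + probe): both isolated
  a2 <- shrake_rupley(rbind(c(0, 0, 0), c(7, 0, 0)), c(1.7, 1.7), probe, 960)
  expect_true(all(abs(a2 - iso) / iso < 0.01))

  # overlapping expanded spheres: analytic cap-area oracle within 2%
  for (d in c(2.5, 3.0, 4.0, 5.0)) {
    av <- shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7),
                        probe, 960)
    cf <- cap_closed_form(3.1, d)
    expect_lt(max(abs(av - cf)) / cf, 0.02)
  }
})

test_that("occlusion monotonicity: adding an atom never raises SASA", {
  set.seed(14)
  xyz <- matrix(stats::runif(30, 0, 6), 10, 3)
  r <- rep(1.7, 10)
  base <- shrake_rupley(xyz, r)
  grown <- shrake_rupley(rbind(xyz, c(3, 3, 3)), c(r, 1.7))
  expect_true(all(grown[1:10] <= base + 1e-9))
})

test_that("SASA converges in the number of sphere points", {
  m <- ggg_extended_model()
  s1 <- residue_sasa(m, n_points = 960)$sasa
  s2 <- residue_sasa(m, n_points = 1920)$sasa
  expect_true(all(abs(s2 - s1) / s1 < 0.01))
})

test_that("extended Gly-Gly-Gly central residue has near-maximal RSA", {
  rs <- relative_sasa(residue_sasa(ggg_extended_model()))
  central <- rs$rsa[rs$resno == 2]
  expect_gte(central, 0.8)
  expect_lte(central, 1.2)
})

test_that("relative SASA handles zeros and unknown residue types", {
  rs <- data.frame(chain = "A", resno = 1:2, resid = c("GLY", "UNK"),
                   sasa = c(0, 50))
  expect_warning(out <- relative_sasa(rs), "UNK")
  expect_equal(out$rsa[1], 0)
  expect_true(is.na(out$rsa[2]))
})

test_that("disulfide detection is cutoff-exact with greedy pairing", {
  sg <- function(i, resno, x) pdb_atom_line(i, "SG", "CYS", "A", resno,
                                            x, 0, 0, element = "S")
  # 2.05 A apart: bonded
  m1 <- parse_structure(write_toy_pdb(c(sg(1, 1, 0), sg(2, 2, 2.05))))
  b1 <- detect_disulfides(m1)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$distance, 2.05)

  # 4.0 A apart: not bonded
  m2 <- parse_structure(write_toy_pdb(c(sg(1, 1, 0), sg(2, 2, 4.0))))
  expect_equal(nrow(detect_disulfides(m2)), 0L)

  # triangle of three SG atoms with pairwise distances 2.0 / 2.1 / 2.2:
  # nearest-first greedy pairs only the 2.0 A pair, third CYS unpaired
  sg2 <- function(i, resno, x, y) pdb_atom_line(i, "SG", "CYS", "A", resno,
                                                x, y, 0, element = "S")
  x3 <- (2.2^2 - 2.1^2 + 4) / 4
  y3 <- sqrt(2.2^2 - x3^2)
  m3 <- parse_structure(write_toy_pdb(c(sg2(1, 1, 0, 0), sg2(2, 2, 2.0, 0),
                                        sg2(3, 3, x3, y3))))
  b3 <- detect_disulfides(m3)
  expect_equal(nrow(b3), 1L)
  expect_equal(sort(c(b3$resno1, b3$resno2)), c(1L, 2L))
  # brute-force check: of the three one-pair matchings under the 2.3 A
  # cutoff, (1,2) at 2.0 A is strictly nearest, so greedy must choose it
  d <- as.matrix(dist(m3[c("x", "y", "z")]))
  cand <- list(c(1, 2), c(2, 3), c(1, 3))
  cand <- Filter(function(p) d[p[1], p[2]] <= 2.3, cand)
  dists <- vapply(cand, function(p) d[p[1], p[2]], 0)
  expect_equal(cand[[which.min(dists)]], c(1, 2))
})

test_that("disulfide pairs are invariant under atom order permutation", {
  sg <- function(i, resno, x) pdb_atom_line(i, "SG", "CYS", "A", resno,
                                            x, 0, 0, element = "S")
  m <- parse_structure(write_toy_pdb(c(sg(1, 1, 0), sg(2, 2, 2.0),
                                       sg(3, 3, 4.1), sg(4, 4, 6.2))))
  b <- detect_disulfides(m)
  mp <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  bp <- detect_disulfides(mp)
  norm <- function(b) {
    key <- apply(cbind(pmin(b$resno1, b$resno2),
                       pmax(b$resno1, b$resno2)), 1, paste, collapse = "-")
    sort(key)
  }
  expect_equal(norm(bp), norm(b))
})

test_that("numbering map handles identity, offsets, and failure", {
  ref <- random_reference(20, 22, seed = 6)
  aa <- strsplit(ref$aa_seq, "")[[1]]
  aa3 <- names(epimapr:::AA3TO1)[match(aa, epimapr:::AA3TO1)]
  mk_model <- function(resno) {
    make_structure_model(rep("CA", 20), resno,
                         cbind(seq(0, by = 3.8, length.out = 20), 0, 0),
                         resid = aa3)
  }
  # identity numbering
  nm <- map_numbering(ref, mk_model(22:41), "A")
  expect_true(all(nm$mapped))
  expect_equal(nm$resno, 22:41)
  expect_equal(attr(nm, "offset"), 0L)

  # renumbered +100: offset recovered
  nm2 <- map_numbering(ref, mk_model(122:141), "A")
  expect_equal(attr(nm2, "offset"), 100L)
  expect_true(all(nm2$mapped))

  # scrambled sequence: mapping error
  bad <- mk_model(22:41)
  bad$resid <- sample(names(epimapr:::MAX_ASA), 20, replace = TRUE)
  expect_error(map_numbering(ref, bad, "A"), "numbering map failed")
  expect_error(map_numbering(ref, mk_model(22:41), "B"), "chain 'B'")
})

test_that("epitope filtering applies the burial and disulfide rules", {
  ann <- data.frame(position = c(30, 50, 61),
                    rsa = c(0.4, 0.05, 0.3),
                    disulfide = c(FALSE, FALSE, TRUE))
  out <- filter_epitope(c(30, 50, 61), ann)
  expect_equal(out$position[out$kept], 30)
  expect_equal(out$reason[out$position == 50], "buried")
  expect_equal(out$reason[out$position == 61], "disulfide")

  # empty call set
  expect_equal(nrow(filter_epitope(integer(), ann)), 0L)

  # unannotated positions kept flagged, or dropped on request
  out2 <- filter_epitope(c(30, 99), ann)
  expect_true(out2$kept[out2$position == 99])
  expect_equal(out2$reason[out2$position == 99], "unfiltered")
  out3 <- filter_epitope(c(30, 99), ann, drop_unannotated = TRUE)
  expect_false(out3$kept[out3$position == 99])

  # soundness: kept members never buried or disulfide-bonded
  set.seed(15)
  for (i in 1:20) {
    ann_r <- data.frame(position = 22:61,
                        rsa = stats::runif(40, 0, 0.6),
                        disulfide = stats::runif(40) < 0.2)
    out_r <- filter_epitope(sample(22:61, 12), ann_r, rsa_min = 0.15)
    kept <- out_r[out_r$kept, ]
    expect_false(any(kept$rsa < 0.15 | kept$disulfide))
  }
})

test_that("structure-derived annotation composes into native numbering", {
  ref <- random_reference(3, 22, seed = 2)
  aa <- strsplit(ref$aa_seq, "")[[1]]
  aa3 <- names(epimapr:::AA3TO1)[match(aa, epimapr:::AA3TO1)]
  model <- make_structure_model(rep("CA", 3), 22:24,
                                cbind(c(0, 3.8, 7.6), 0, 0), resid = aa3)
  ann <- annotate_structure(ref, model, "A")
  expect_equal(ann$position, 22:24)
  expect_true(all(ann$rsa > 0))
  expect_false(any(ann$disulfide))
})
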