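# Structure model: parsing, typing, chirality, mirror transform, sequence
# notation.

test_that("residue kinds are assigned from names and atom content", {
  g <- single_nucleotide("G")
  atoms <- rbind(
    g$atoms[, c("elety", "x", "y", "z", "elesy", "chain", "resno", "resid")],
    data.frame(elety = "O", x = 10, y = 0, z = 0, elesy = "O",
               chain = "S", resno = 100, resid = "HOH"),
    data.frame(elety = "MG", x = 14, y = 0, z = 0, elesy = "MG",
               chain = "S", resno = 200, resid = "MG"))
  s <- structure_model(atoms)
  rt <- aptastruct:::residue_table(s)
  expect_equal(nrow(rt), 3)
  expect_setequal(rt$kind, c("ribonucleotide", "water", "metal_ion"))
  # deoxy typing by O2' absence even under a ribo residue name
  g2 <- single_nucleotide("G", deoxy = TRUE)
  g2$atoms$resid <- "G"
  s2 <- structure_model(g2$atoms)
  expect_equal(unique(s2$atoms$kind), "deoxyribonucleotide")
})

test_that("unknown residues are typed 'other' with a warning, not an error", {
  atoms <- data.frame(elety = c("C1", "N1"), x = c(0, 1.5), y = 0, z = 0,
                      elesy = c("C", "N"), chain = "X", resno = 1, resid = "XYZ")
  expect_warning(s <- structure_model(atoms), "XYZ")
  expect_equal(unique(s$atoms$kind), "other")
})

test_that("PDB and mmCIF round trips preserve atoms and coordinates to 0.001 A", {
  d <- make_duplex(4)
  for (ext in c(".pdb", ".cif")) {
    f <- tempfile(fileext = ext)
    write_structure(d, f)
    d2 <- suppressWarnings(read_structure(f))
    expect_equal(nrow(d2$atoms), nrow(d$atoms))
    expect_equal(aptastruct:::residue_table(d2)$resno,
                 aptastruct:::residue_table(d)$resno)
    dev <- max(abs(as.matrix(d2$atoms[, c("x", "y", "z")]) -
                     as.matrix(d$atoms[, c("x", "y", "z")])))
    expect_lt(dev, 0.001)
    # second round trip is exact at the stored precision
    f2 <- tempfile(fileext = ext)
    write_structure(d2, f2)
    d3 <- suppressWarnings(read_structure(f2))
    expect_identical(as.matrix(d3$atoms[, c("x", "y", "z")]),
                     as.matrix(d2$atoms[, c("x", "y", "z")]))
  }
})

test_that("gzip-compressed files are read transparently", {
  d <- make_duplex(2)
  f <- tempfile(fileext = ".pdb")
  write_structure(d, f)
  fg <- paste0(f, ".gz")
  con <- gzfile(fg, "wb")
  writeLines(readLines(f), con)
  close(con)
  expect_equal(nrow(read_structure(fg)$atoms), nrow(d$atoms))
})

test_that("unparseable input raises a format error naming the file", {
  f <- tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", f)
  expect_error(read_structure(f), "failed to parse")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("altloc policy keeps the highest-occupancy conformer by default", {
  g <- single_nucleotide("G")
  a1 <- g$atoms
  a1$alt <- "A"; a1$o <- 0.4
  a2 <- g$atoms
  a2$alt <- "B"; a2$o <- 0.6; a2$x <- a2$x + 1
  a2$eleno <- a2$eleno + nrow(a1)
  f <- tempfile(fileext = ".pdb")
  write_structure(structure_model(rbind(a1, a2)), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), nrow(g$atoms))
  expect_true(all(s$atoms$alt == "B"))
  s_all <- read_structure(f, keep_altloc = TRUE)
  expect_equal(nrow(s_all$atoms), 2 * nrow(g$atoms))
})

test_that("mirror_structure is an exact involution and isometry that flips chirality", {
  d <- make_duplex(3)
  m <- mirror_structure(d)
  mm <- mirror_structure(m)
  expect_identical(d$atoms$x, mm$atoms$x)
  expect_identical(d$atoms$y, mm$atoms$y)
  expect_identical(d$atoms$z, mm$atoms$z)
  expect_identical(d$atoms$chirality, mm$atoms$chirality)
  # exact isometry
  expect_identical(dist_matrix(d), dist_matrix(m))
  # chirality verdicts flip, both as stored flags and as recomputed geometry
  expect_true(all(detect_chirality(d)$chirality == "D"))
  expect_true(all(detect_chirality(m)$chirality == "L"))
  expect_true(all(aptastruct:::assign_chirality(m$atoms)[
    m$atoms$kind %in% c("ribonucleotide", "deoxyribonucleotide")] == "L"))
  # any torsion is negated in the as-deposited frame
  chi_d <- glycosidic_chi(d, frame = "as-deposited")$chi
  chi_m <- glycosidic_chi(m, frame = "as-deposited")$chi
  expect_equal(chi_m, -chi_d, tolerance = 1e-12)
})

test_that("mixed L-RNA/L-DNA sequence notation parses with deoxy positions", {
  nox_d20 <- "5'-GCGAUG(dU)GGUGGU(dG)(dA)AGGGUUGUUGGG(dU)G(dU)CGACGCA(dC)GC-3'"
  sq <- parse_mixed_sequence(nox_d20)
  expect_equal(nrow(sq), 40)
  expect_equal(sq$position[sq$is_deoxy], c(7, 14, 15, 28, 30, 38))
  expect_equal(paste(sq$base[1:6], collapse = ""), "GCGAUG")
  nox_d19 <- "5'-GCCUGAUGUGGUGGUGAAGGGUUGUUGGGUGUCGACGCACAGGC-3'"
  sq19 <- parse_mixed_sequence(nox_d19)
  expect_equal(nrow(sq19), 44)
  expect_false(any(sq19$is_deoxy))
  expect_equal(nrow(parse_mixed_sequence("")), 0)
  expect_error(parse_mixed_sequence("GC(dU"), "unbalanced")
  expect_error(parse_mixed_sequence("GCX"), "offset 3")
  expect_error(parse_mixed_sequence("G(dX)C"), "illegal token")
})

test_that("structure summary reports chains, kinds and chirality", {
  d <- make_duplex(4, chirality = "L")
  sm <- structure_summary(d)
  expect_equal(sm$n_chains, 2)
  expect_equal(sm$n_residues, 8)
  expect_equal(sm$chains$A$chirality$L, 4)
  expect_silent(jsonlite::toJSON(sm, auto_unbox = TRUE))
})
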