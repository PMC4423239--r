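# Glycosidic torsion, syn/anti classification, pseudorotation and pucker
# naming, including the mirrored-to-D convention for L nucleotides.

test_that("glycosidic chi reproduces the constructed torsion and negates under mirror", {
  for (target in c(60, -160, 10, 179)) {
    s <- single_nucleotide("G", chi = target)
    expect_equal(glycosidic_chi(s)$chi, target, tolerance = 1e-6)
  }
  s <- single_nucleotide("U", chi = 60)
  expect_equal(glycosidic_chi(s)$chi, 60, tolerance = 1e-6)
  m <- mirror_structure(s)
  # raw frame: reflection negates the torsion
  expect_equal(glycosidic_chi(m, frame = "as-deposited")$chi, -60,
               tolerance = 1e-6)
  # mirrored-to-D frame: L residue reported with standard-convention chi
  expect_equal(glycosidic_chi(m)$chi, 60, tolerance = 1e-6)
})

test_that("chi with a missing defining atom yields a named no-value result", {
  s <- single_nucleotide("G")
  s2 <- structure_model(s$atoms[s$atoms$elety != "N9", ])
  res <- glycosidic_chi(s2)
  expect_true(is.na(res$chi))
  expect_equal(res$missing_atom, "N9")
})

test_that("syn/anti classification uses |chi| <= 90 and is sign-invariant", {
  expect_equal(classify_glycosidic(0), "syn")
  expect_equal(classify_glycosidic(180), "anti")
  expect_equal(classify_glycosidic(90), "syn")
  expect_equal(classify_glycosidic(-90.001), "anti")
  chis <- seq(-179, 179, by = 7)
  expect_identical(classify_glycosidic(chis), classify_glycosidic(-chis))
})

test_that("pseudorotation recovers constructed canonical puckers", {
  cases <- list(c(18, "3'-endo"), c(162, "2'-endo"), c(54, "4'-exo"),
                c(342, "2'-exo"), c(90, "O4'-endo"))
  for (cs in cases) {
    s <- single_nucleotide("G", phase = as.numeric(cs[1]))
    ps <- pseudorotation(s)
    expect_equal(ps$phase, as.numeric(cs[1]), tolerance = 1e-4)
    expect_equal(ps$pucker, cs[2])
  }
})

test_that("near-planar rings are reported planar/indeterminate", {
  expect_equal(pucker_name(100, amplitude = 3), "planar/indeterminate")
  expect_equal(pucker_name(100, amplitude = 6), "O4'-endo")
})

test_that("pucker naming agrees with the exhaustive sector oracle on 1000 seeded phases", {
  wheel <- data.frame(center = seq(18, 342, by = 36),
                      name = c("3'-endo", "4'-exo", "O4'-endo", "1'-exo",
                               "2'-endo", "3'-exo", "4'-endo", "O4'-exo",
                               "1'-endo", "2'-exo"))
  oracle <- function(p) {
    d <- pmin(abs(p - wheel$center) %% 360, 360 - abs(p - wheel$center) %% 360)
    wheel$name[which.max(-d)]
  }
  ps <- aptastruct:::with_seed(42, stats::runif(1000, 0, 360))
  got <- vapply(ps, pucker_name, "", amplitude = 38)
  want <- vapply(ps, oracle, "")
  expect_identical(got, want)
})

test_that("ring construction and pseudorotation are mutually consistent around the wheel", {
  for (p in seq(9, 351, by = 36)) {   # one probe per sector, off-center
    ring <- aptastruct:::build_sugar_ring(p, 38.5)
    res <- data.frame(elety = rownames(ring), x = ring[, 1], y = ring[, 2],
                      z = ring[, 3])
    pr <- pseudorotation_phase(aptastruct:::endocyclic_torsions(res))
    expect_equal(pr$phase, p, tolerance = 1e-4)
    expect_equal(pr$amplitude, 38.5, tolerance = 1e-4)
  }
})

test_that("ideal A-form duplex annotates all-anti, all 3'-endo in both chiralities", {
  for (ch in c("D", "L")) {
    d <- make_duplex(8, chirality = ch)
    ac <- annotate_conformation(d)
    expect_true(all(ac$glycosidic_class == "anti"))
    expect_true(all(ac$pucker == "3'-endo"))
  }
})

test_that("pucker names are mirror-invariant under the mirrored-to-D convention", {
  d <- make_duplex(5)
  m <- mirror_structure(d)
  expect_identical(pseudorotation(d)$pucker, pseudorotation(m)$pucker)
  expect_identical(annotate_conformation(d)$glycosidic_class,
                   annotate_conformation(m)$glycosidic_class)
})

test_that("annotation flags near-boundary calls as ambiguous", {
  s <- single_nucleotide("G", chi = 88)   # within 5 degrees of the syn/anti edge
  ac <- annotate_conformation(s)
  expect_true(ac$chi_ambiguous)
  s2 <- single_nucleotide("G", chi = 45, phase = 35)  # near 3'-endo/4'-exo edge
  ac2 <- annotate_conformation(s2)
  expect_true(ac2$pucker_ambiguous)
  expect_false(annotate_conformation(single_nucleotide("G"))$pucker_ambiguous)
})
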