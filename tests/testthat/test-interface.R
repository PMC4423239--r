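# SASA, buried surface area, footprints.

test_that("single-atom SASA matches the analytic sphere within 1% at 960 points", {
  s <- make_sphere_cluster(1, seed = 1)
  res <- sasa(s, probe = 1.4, n_points = 960)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(res$total - analytic) / analytic, 0.01)
  expect_equal(res$total, sum(res$per_atom))
})

test_that("SASA of far-apart atoms is additive", {
  atoms <- data.frame(elety = "C", x = c(0, 100), y = 0, z = 0, elesy = "C",
                      chain = c("A", "B"), resno = 1:2, resid = "ALA")
  s <- structure_model(atoms)
  expect_equal(sasa(s)$total, 2 * 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
})

test_that("a fully enclosed atom has zero accessible area", {
  shell <- aptastruct:::sphere_lattice(40) * 2.0
  atoms <- data.frame(elety = "C",
                      x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                      z = c(0, shell[, 3]), elesy = "C", chain = "A",
                      resno = seq_len(41), resid = "ALA")
  s <- structure_model(atoms)
  res <- sasa(s)
  expect_equal(res$per_atom[1], 0)
})

test_that("lattice SASA agrees with a dense quadrature on seeded clusters within 2%", {
  for (seed in c(7, 11)) {
    cl <- make_sphere_cluster(20, seed = seed)
    a <- sasa(cl, n_points = 960)$total
    b <- sasa(cl, n_points = 10000)$total
    expect_lt(abs(a - b) / b, 0.02)
  }
})

test_that("SASA is deterministic and rigid-motion and mirror invariant", {
  cl <- make_sphere_cluster(15, seed = 3)
  a <- sasa(cl)$total
  expect_identical(a, sasa(cl)$total)
  expect_equal(sasa(random_rigid(cl, 9))$total, a, tolerance = 1e-6 * a)
  expect_equal(sasa(mirror_structure(cl))$total, a, tolerance = 1e-6 * a)
})

test_that("unknown elements fall back to the default radius with a warning", {
  atoms <- data.frame(elety = "Q1", x = 0, y = 0, z = 0, elesy = "Q",
                      chain = "A", resno = 1, resid = "ALA")
  s <- structure_model(atoms)
  expect_warning(res <- sasa(s), "unknown element")
  expect_equal(res$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01 * res$total)
})

test_that("two-sphere BSA equals the analytic spherical-cap loss", {
  d <- 2.0
  atoms <- data.frame(elety = "C", x = c(0, d), y = 0, z = 0, elesy = "C",
                      chain = c("A", "B"), resno = 1:2, resid = "ALA")
  s <- structure_model(atoms)
  rep <- buried_surface(s, list(chain = "A"), list(chain = "B"))
  rr <- 1.70 + 1.4
  cap <- 2 * pi * rr * (rr - d / 2)       # area lost per sphere
  expect_lt(abs(rep$bsa_total - 2 * cap) / (2 * cap), 0.01)
})

test_that("BSA is exactly symmetric and exactly zero for separated chains", {
  d <- make_duplex(4)
  ab <- buried_surface(d, list(chain = "A"), list(chain = "B"))
  ba <- buried_surface(d, list(chain = "B"), list(chain = "A"))
  expect_identical(ab$bsa_total, ba$bsa_total)
  expect_gt(ab$bsa_total, 0)
  atoms <- data.frame(elety = "C", x = c(0, 50), y = 0, z = 0, elesy = "C",
                      chain = c("A", "B"), resno = 1:2, resid = "ALA")
  s <- structure_model(atoms)
  expect_identical(buried_surface(s, list(chain = "A"), list(chain = "B"))$bsa_total, 0)
})

test_that("BSA never increases as the partners are pulled apart", {
  base <- make_duplex(3)
  ia <- select_atoms(base, chain = "A")
  prev <- Inf
  for (shift in c(0, 2, 4, 8, 16)) {
    s <- base
    s$atoms$x[ia] <- s$atoms$x[ia] + shift
    b <- buried_surface(s, list(chain = "A"), list(chain = "B"))$bsa_total
    expect_lte(b, prev + 1e-9)
    prev <- b
  }
})

test_that("BSA is invariant under mirror and overlapping selections error", {
  d <- make_duplex(3)
  a <- buried_surface(d, list(chain = "A"), list(chain = "B"))$bsa_total
  m <- buried_surface(mirror_structure(d), list(chain = "A"),
                      list(chain = "B"))$bsa_total
  expect_equal(m, a, tolerance = 1e-6 * a)
  expect_error(buried_surface(d, list(chain = "A"), list(chain = c("A", "B"))),
               "overlap")
})

test_that("footprints contain the contacting residues with positive buried area", {
  d <- make_duplex(6)
  rep <- buried_surface(d, list(chain = "A"), list(chain = "B"))
  expect_true(all(rep$footprint_a$delta_sasa > 0 |
                    rep$footprint_a$key %in%
                      aptastruct:::res_key(d$atoms[c(rep$contacts$i, rep$contacts$j), ])))
  expect_gt(nrow(rep$footprint_a), 0)
  expect_gt(nrow(rep$hbonds), 0)   # the WC hydrogen bonds cross the interface
})

test_that("footprint overlap metrics are symmetric with Jaccard in [0,1]", {
  a <- c("K701", "D705", "R708")
  expect_equal(footprint_overlap(a, a)$jaccard, 1)
  expect_equal(footprint_overlap(a, c("X1", "X2"))$jaccard, 0)
  ov1 <- footprint_overlap(a, c("K701", "X1"))
  ov2 <- footprint_overlap(c("K701", "X1"), a)
  expect_equal(ov1$jaccard, ov2$jaccard)
  expect_equal(ov1$jaccard, 1 / 4)
})
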