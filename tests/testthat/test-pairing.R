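# Hydrogen bonds, base pairing, stacking, G-tetrads and quadruplex assembly.

test_that("hydrogen bonds respect the distance cutoff", {
  expect_equal(nrow(detect_hbonds(two_waters(2.8))), 1)
  expect_equal(nrow(detect_hbonds(two_waters(5.0))), 0)
  expect_error(detect_hbonds(two_waters(2.8), cutoff = 10), "2.4")
  expect_equal(nrow(detect_hbonds(two_waters(2.8), selection = integer(0))), 0)
})

test_that("canonical G-C pair shows exactly the three Watson-Crick hydrogen bonds", {
  s <- base_pair_structure("G", "C")
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), 3)
  pairs <- sort(paste(hb$atom_i, hb$atom_j))
  expect_setequal(pairs, c("N1 N3", "N2 O2", "O6 N4"))
  # A-U: the two canonical bonds
  hb_au <- detect_hbonds(base_pair_structure("A", "U"))
  expect_equal(nrow(hb_au), 2)
})

test_that("an 8-bp ideal duplex yields exactly 8 Watson-Crick pairs", {
  d <- make_duplex(8)
  bp <- detect_base_pairs(d)
  expect_equal(nrow(bp), 8)
  expect_true(all(bp$pair_class == "watson_crick"))
  # every strand-1 residue paired with its antiparallel complement
  expect_equal(sort(bp$resno_a + bp$resno_b - 9), rep(0, 8))
})

test_that("G-U wobble pairs are classed non_watson_crick", {
  # shift a U against G at the wobble geometry: build from a G-C pose, then
  # swap the partner for U displaced along the pair axis
  d <- make_duplex(6, sequence = c("G", "U", "G", "U", "G", "U"))
  bp <- detect_base_pairs(d)
  # constructed pairs are G-C and A-U (complement), so all WC here; check
  # the classifier directly on a synthetic wobble-like hbond pattern
  hb <- data.frame(atom_a = c("O6", "N1"), atom_b = c("N3", "O2"),
                   distance = c(2.85, 2.85))
  expect_equal(aptastruct:::classify_pair("G", "U", hb), "non_watson_crick")
})

test_that("base-pair detection is mirror-invariant", {
  d <- make_duplex(6)
  m <- mirror_structure(d)
  bp_d <- detect_base_pairs(d)
  bp_m <- detect_base_pairs(m)
  expect_identical(bp_d[, c("res_a", "res_b", "n_hbonds", "pair_class")],
                   bp_m[, c("res_a", "res_b", "n_hbonds", "pair_class")])
})

test_that("stacking detection finds every consecutive intrastrand step and respects cutoffs", {
  d <- make_duplex(8)
  st <- detect_stacking(d)
  for (ch in c("A", "B")) {
    for (i in 1:7) {
      hit <- any((st$chain_a == ch & st$chain_b == ch &
                    st$resno_a == i & st$resno_b == i + 1) |
                   (st$chain_a == ch & st$chain_b == ch &
                      st$resno_a == i + 1 & st$resno_b == i))
      expect_true(hit, label = paste("stacked step", ch, i))
    }
  }
  # two bases 10 A apart are not stacked
  s1 <- single_nucleotide("A")
  a2 <- s1$atoms
  a2$z <- a2$z + 10
  a2$resno <- 2
  far <- structure_model(rbind(s1$atoms, a2))
  expect_equal(nrow(detect_stacking(far)), 0)
})

test_that("tetrad detection finds constructed tetrads and nothing in duplexes", {
  q2 <- make_tetrad_stack(2, twist = 45, rise = 3.3, ion = "CA")
  tt <- detect_tetrads(q2)
  expect_length(tt, 2)
  expect_setequal(tt[[1]]$resnos, if (1 %in% tt[[1]]$resnos) 1:4 else 5:8)
  # directed Hoogsteen cycle closes: each tetrad has 4 distinct guanines
  for (t in tt) expect_length(unique(t$residues), 4)
  q1 <- make_tetrad_stack(1, ion = "none")
  expect_length(detect_tetrads(q1), 1)
  expect_length(detect_tetrads(make_duplex(8)), 0)
})

test_that("quadruplex assembly measures the constructed twist within 0.5 degrees", {
  for (tw in c(30, 45)) {
    q <- make_tetrad_stack(2, twist = tw, rise = 3.3, ion = "none")
    qq <- assemble_quadruplex(q, detect_tetrads(q))
    expect_equal(qq$n_tetrads, 2)
    expect_equal(mean(qq$twist_angles), tw, tolerance = 0.5 / tw)
    expect_true(all(qq$twist_angles >= 0 & qq$twist_angles <= 90))
  }
})

test_that("quadruplex channel ion is reported and coordination is 8 guanine O6", {
  q <- make_tetrad_stack(2, twist = 45, rise = 3.3, ion = "CA", ion_dist = 2.48)
  qq <- assemble_quadruplex(q, detect_tetrads(q))
  expect_equal(nrow(qq$channel_ions), 1)
  cs <- coordination_sphere(q, which(q$atoms$kind == "metal_ion"))
  expect_equal(cs$coordination_number, 8)
  expect_true(all(cs$ligands$class == "base_O"))
  expect_true(all(cs$ligands$elety == "O6"))
})

test_that("assembling fewer than two tetrads errors; unstackable tetrads give an empty quadruplex", {
  q1 <- make_tetrad_stack(1, ion = "none")
  expect_error(assemble_quadruplex(q1, detect_tetrads(q1)), ">= 2")
  # two tetrads far apart do not stack
  qfar <- make_tetrad_stack(2, twist = 45, rise = 30, ion = "none")
  qq <- assemble_quadruplex(qfar, detect_tetrads(qfar))
  expect_equal(qq$n_tetrads, 0)
})

test_that("pair and tetrad counts are invariant over seeded random rigid placements", {
  d <- make_duplex(4)
  q <- make_tetrad_stack(2, twist = 45, rise = 3.3, ion = "none")
  for (seed in 1:20) {
    dr <- random_rigid(d, seed)
    qr <- random_rigid(q, seed + 1000)
    expect_equal(nrow(detect_base_pairs(dr)), 4)
    expect_length(detect_tetrads(qr), 2)
  }
})
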