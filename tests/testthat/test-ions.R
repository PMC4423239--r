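# Ion coordination spheres and species scoring.

test_that("ideal octahedral Mg site: CN 6, exact mean, zero spread, assigned Mg", {
  s <- make_ion_site("MG", 6, 2.08, jitter_sd = 0)
  cs <- coordination_sphere(s, 1)
  expect_equal(cs$coordination_number, 6)
  expect_equal(cs$mean_distance, 2.08, tolerance = 1e-12)
  expect_equal(cs$sd_distance, 0, tolerance = 1e-12)
  expect_true(all(cs$ligands$class == "water"))
  sc <- score_ion_identity(cs)
  expect_equal(sc$assigned_species, "Mg")
})

test_that("species scores are the documented z-scores (direct arithmetic)", {
  s <- make_ion_site("CA", 7, 2.47)
  sc <- score_ion_identity(coordination_sphere(s, 1))
  z <- function(mu, sig) abs(2.47 - mu) / sig
  expect_equal(sc$scores$score[sc$scores$species == "Ca"], z(2.43, 0.11),
               tolerance = 1e-9)
  expect_equal(sc$scores$score[sc$scores$species == "Na"], z(2.38, 0.10),
               tolerance = 1e-9)
  expect_equal(sc$scores$score[sc$scores$species == "K"], z(2.81, 0.10),
               tolerance = 1e-9)
  # K is rejected at more than 3 sigma; Ca is the best CN-compatible species
  expect_gt(sc$scores$score[sc$scores$species == "K"], 3)
  expect_equal(sc$best_species, "Ca")
  # ... but Ca-vs-Na cannot be resolved on distance alone
  expect_equal(sc$assigned_species, "ambiguous")
  expect_equal(sc$runner_up, "Na")
})

test_that("K and Mg sites are assigned unambiguously at their canonical distances", {
  sk <- make_ion_site("K", 7, 2.81, jitter_sd = 0.05, seed = 1)
  sck <- score_ion_identity(coordination_sphere(sk, 1))
  expect_equal(sck$assigned_species, "K")
  smg <- make_ion_site("MG", 6, 2.08, jitter_sd = 0.05, seed = 2)
  expect_equal(score_ion_identity(coordination_sphere(smg, 1))$assigned_species, "Mg")
})

test_that("score is minimized exactly at the species mean distance", {
  tbl <- species_table()
  for (i in seq_len(nrow(tbl))) {
    s <- make_ion_site(toupper(tbl$species[i]), tbl$cn_min[i], tbl$mu[i])
    sc <- score_ion_identity(coordination_sphere(s, 1))
    expect_equal(sc$scores$score[sc$scores$species == tbl$species[i]], 0,
                 tolerance = 1e-9)
    expect_equal(sc$best_species, tbl$species[i])
  }
})

test_that("classifier recovers generating species for Mg and K on seeded noisy sites", {
  lab <- c(MG = "Mg", CA = "Ca", K = "K", "NA" = "Na")
  recover <- function(species, cn, mu, sigma, n = 40) {
    hits <- 0
    for (seed in seq_len(n)) {
      s <- make_ion_site(species, cn, mu, jitter_sd = sigma, seed = seed)
      sc <- score_ion_identity(coordination_sphere(s, 1))
      hits <- hits + (sc$best_species == lab[[species]])
    }
    hits / n
  }
  expect_gte(recover("MG", 6, 2.08, 0.06), 0.95)
  expect_gte(recover("K", 7, 2.81, 0.10), 0.95)
})

test_that("coordination spheres are invariant under mirror and rigid motion", {
  q <- make_tetrad_stack(2, twist = 45, ion = "CA", ion_dist = 2.48)
  ion <- which(q$atoms$kind == "metal_ion")
  ref <- coordination_sphere(q, ion)
  mir <- coordination_sphere(mirror_structure(q), ion)
  expect_equal(mir$coordination_number, ref$coordination_number)
  expect_equal(mir$mean_distance, ref$mean_distance, tolerance = 1e-12)
  rot <- random_rigid(q, 5)
  rr <- coordination_sphere(rot, ion)
  expect_equal(rr$mean_distance, ref$mean_distance, tolerance = 1e-9)
})

test_that("ion survey attributes ions to polymer chains and flags isolated ions", {
  q <- make_tetrad_stack(2, twist = 45, ion = "CA", ion_dist = 2.48)
  # add an isolated ion far from everything
  extra <- data.frame(elety = "MG", x = 60, y = 0, z = 0, o = 1, b = 0,
                      alt = "", insert = "", elesy = "MG", chain = "Z",
                      resno = 99L, resid = "MG", kind = "metal_ion",
                      chirality = "not_applicable",
                      eleno = max(q$atoms$eleno) + 1L)
  q$atoms <- rbind(q$atoms, extra)
  sv <- suppressWarnings(survey_ions(q))
  expect_equal(nrow(sv$table), 2)
  expect_equal(sv$table$attributed_chain[sv$table$ion_name == "CA"], "Q")
  expect_true(is.na(sv$table$attributed_chain[sv$table$ion_name == "MG"]))
  expect_equal(sv$table$coordination_number[sv$table$ion_name == "MG"], 0)
})

test_that("colinearity of an ion triple is the deviation from the best-fit line", {
  X <- rbind(c(0, 0, 0), c(5, 0.2, 0), c(10, 0, 0.1))
  dev <- aptastruct:::line_deviation(X)
  expect_lt(dev, 0.25)
  expect_gt(aptastruct:::line_deviation(rbind(c(0, 0, 0), c(5, 5, 0), c(10, 0, 0))), 2)
})

test_that("cutoff and ligand-count preconditions are enforced", {
  s <- make_ion_site("MG", 6, 2.08)
  expect_error(coordination_sphere(s, 1, cutoff = 5), "\\[2.0, 3.5\\]")
  expect_error(coordination_sphere(s, 2), "not typed metal_ion")
  far <- make_ion_site("MG", 6, 2.08)
  far$atoms$x[-1] <- far$atoms$x[-1] + 50
  expect_warning(cs <- coordination_sphere(far, 1), "no ligand")
  expect_error(score_ion_identity(cs), "at least 3")
})
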