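# SPR kinetics: simulation, closed-form limits, global fitting, competition.

test_that("kinetic model validates parameters and derives Kd = kd/ka exactly", {
  m <- kinetic_model(1e6, 1e-3, 100)
  expect_identical(m$Kd, 1e-3 / 1e6)
  expect_error(kinetic_model(-1, 1e-3, 100), "positive")
  expect_error(kinetic_model(1e6, 1e-3, 100, kt = 0), "positive")
})

test_that("saturation and zero-concentration limits behave", {
  m <- kinetic_model(1e6, 1e-9, 80)   # negligible dissociation
  sg <- simulate_sensorgram(m, 1e-6, t_assoc = 400, t_dissoc = 0)
  expect_true(all(diff(sg$response) >= -1e-5))  # monotone up to solver tolerance
  expect_equal(sg$response[nrow(sg)], 80, tolerance = 1e-3)
  expect_true(all(sg$response <= 80 + 1e-9))
  z <- simulate_sensorgram(m, 0)
  expect_true(all(abs(z$response) < 1e-9))
  expect_equal(sg$response[1], 0)
  expect_error(simulate_sensorgram(m, 1e-9, dt = 0), "positive")
})

test_that("transport-free limit matches the closed-form Langmuir solution", {
  m <- kinetic_model(1e6, 1e-3, 100, kt = 1e12)
  for (conc in c(5e-9, 5e-8, 5e-7)) {
    sg <- simulate_sensorgram(m, conc)
    cf <- langmuir_closed_form(m, conc, sg$time)
    expect_lt(max(abs(sg$response - cf)), 0.1)
  }
})

test_that("dissociation is non-increasing and plateaus match Req for fast transport", {
  m <- kinetic_model(1e6, 1e-3, 100, kt = 1e9)
  for (conc in c(1e-9, 1e-8)) {
    sg <- simulate_sensorgram(m, conc, t_assoc = 20000, t_dissoc = 100)
    diss <- sg$response[sg$phase == "dissociation"]
    expect_true(all(diff(diss) <= 1e-9))
    req <- m$Rmax * conc / (conc + m$Kd)
    plateau <- max(sg$response)
    expect_lt(abs(plateau - req) / req, 0.005)
  }
})

test_that("mass transport slows the initial association phase", {
  fast <- kinetic_model(1e6, 1e-3, 100, kt = 1e12)
  slow <- kinetic_model(1e6, 1e-3, 100, kt = 1e6)
  c0 <- 1e-7
  r_fast <- simulate_sensorgram(fast, c0, t_assoc = 60, t_dissoc = 0)
  r_slow <- simulate_sensorgram(slow, c0, t_assoc = 60, t_dissoc = 0)
  expect_lt(r_slow$response[20], r_fast$response[20])
})

test_that("noiseless global fit recovers the generating parameters within 1%", {
  truth <- kinetic_model(1e6, 1e-3, 100, kt = 1e7)
  sims <- make_sensorgram_set(truth, c(500, 250, 125, 62.5, 31.3) * 1e-9, dt = 1)
  fit <- fit_kinetics(sims, kt = 1e7)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$ka - truth$ka) / truth$ka, 0.01)
  expect_lt(abs(fit$estimates$kd - truth$kd) / truth$kd, 0.01)
  expect_lt(abs(fit$estimates$Rmax - truth$Rmax) / truth$Rmax, 0.01)
  expect_identical(fit$estimates$Kd, fit$estimates$kd / fit$estimates$ka)
})

test_that("seeded noisy series are byte-deterministic and fits stay within 10%", {
  truth <- kinetic_model(1e6, 1e-3, 100, kt = 1e7)
  concs <- c(500, 125, 31.3, 7.8) * 1e-9
  s1 <- make_sensorgram_set(truth, concs, noise_sd = 2, seed = 77, dt = 2)
  s2 <- make_sensorgram_set(truth, concs, noise_sd = 2, seed = 77, dt = 2)
  expect_identical(s1, s2)
  kds <- vapply(1:3, function(seed) {
    sims <- make_sensorgram_set(truth, concs, noise_sd = 2, seed = seed, dt = 2)
    fit_kinetics(sims, kt = 1e7)$estimates$Kd
  }, numeric(1))
  expect_true(all(abs(kds - truth$Kd) / truth$Kd < 0.10))
})

test_that("competition curve hits its limits and matches the equilibrium quadratic", {
  chip <- kinetic_model(1e6, 1e-3, 100, kt = 1e7)
  kd_sol <- 1.4e-9
  A <- 1.4e-9   # total aptamer equal to the solution Kd
  B <- seq(0, 200e-9, length.out = 9)
  cc <- simulate_competition(chip, kd_sol, A, B)
  expect_equal(cc$signal_fraction[1], 1)
  expect_true(all(diff(cc$signal_fraction) <= 1e-9))
  expect_lt(cc$signal_fraction[nrow(cc)], 0.05)
  expect_true(all(cc$signal_fraction >= 0 & cc$signal_fraction <= 1 + 1e-12))
  # algebraic oracle: free concentration solves A_free (A_free + B_free ...) via
  # the closed-form quadratic; verify against an independent numeric root
  for (b in c(1e-9, 5e-9, 5e-8)) {
    f <- function(af) af + (af * b) / (kd_sol + af) - A
    af_num <- stats::uniroot(f, c(0, A), tol = 1e-18)$root
    expect_equal(free_fraction_quadratic(A, b, kd_sol), af_num,
                 tolerance = 1e-6)
  }
  # the half-depletion point: with B = Kd + A/2, exactly half the aptamer is free
  b_half <- kd_sol + A / 2
  expect_equal(free_fraction_quadratic(A, b_half, kd_sol), A / 2,
               tolerance = 1e-12)
  expect_error(simulate_competition(chip, kd_sol, -1e-9, B), "non-negative")
})

test_that("sensorgram CSV round trip preserves the series", {
  truth <- kinetic_model(1e5, 1e-2, 50)
  sims <- make_sensorgram_set(truth, c(1e-7, 1e-8), dt = 5)
  f <- tempfile(fileext = ".csv")
  write_sensorgrams(sims, f)
  back <- read_sensorgrams(f)
  expect_length(back, 2)
  total_in <- sum(vapply(sims, nrow, 1L))
  total_out <- sum(vapply(back, nrow, 1L))
  expect_equal(total_out, total_in)
  expect_equal(unname(sort(vapply(back, function(sg) sg$conc[1], 1))),
               c(1e-8, 1e-7))
})
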