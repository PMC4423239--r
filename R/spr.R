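# Surface plasmon resonance: simulation and global fitting of sensorgrams
# under the 1:1 Langmuir binding model with mass-transport limitation, and
# the competitive (solution-equilibrium) assay format.
#
# Model: dR/dt = ka * Cs * (Rmax - R) - kd * R, with the analyte
# concentration at the sensor surface given by the two-compartment
# quasi-steady-state balance Cs = (kt * C + kd * R) / (kt + ka * (Rmax - R)).
# During dissociation the bulk concentration C is zero, so dissociation is
# rebinding-limited when transport is slow.

#' Construct a 1:1 Langmuir mass-transport kinetic model
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax surface capacity, RU.
#' @param kt mass-transport coefficient, RU/(M s); default 1e7, the
#'   conventional initial value for this assay format.
#' @return object of class `KineticModel` with derived `Kd = kd/ka` (M).
#' @export
kinetic_model <- function(ka, kd, Rmax, kt = 1e7) {
  stopifnot(is.finite(ka), is.finite(kd), is.finite(Rmax), is.finite(kt))
  if (ka <= 0 || kd <= 0 || Rmax <= 0 || kt <= 0) {
    stop("ka, kd, Rmax and kt must all be positive")
  }
  structure(list(ka = ka, kd = kd, Rmax = Rmax, kt = kt, Kd = kd / ka),
            class = "KineticModel")
}

#' @export
print.KineticModel <- function(x, ...) {
  cat(sprintf("KineticModel: ka %.3g 1/(M s), kd %.3g 1/s, Rmax %.3g RU, kt %.3g, Kd %.3g M\n",
              x$ka, x$kd, x$Rmax, x$kt, x$Kd))
  invisible(x)
}

spr_derivative <- function(t, state, parms) {
  R <- state[1]
  C <- if (t <= parms$t_assoc) parms$conc else 0
  cs <- (parms$kt * C + parms$kd * R) / (parms$kt + parms$ka * (parms$Rmax - R))
  list(parms$ka * cs * (parms$Rmax - R) - parms$kd * R)
}

#' Simulate a sensorgram
#'
#' Integrates the transport-coupled 1:1 Langmuir model over an association
#' phase (analyte at `conc`) followed by a dissociation phase (analyte zero)
#' with the stiff-capable `lsoda` integrator (absolute tolerance 1e-6 RU).
#' The response starts at zero and never exceeds `Rmax`.
#'
#' @param model a `KineticModel`.
#' @param conc analyte concentration, M.
#' @param t_assoc,t_dissoc phase durations, s (defaults 240/240, the standard
#'   direct-binding protocol).
#' @param dt sampling interval, s (> 0).
#' @return data.frame (class `Sensorgram`): `time`, `response`, `conc`,
#'   `phase`; attributes `model`, `t_assoc`, `t_dissoc`.
#' @export
simulate_sensorgram <- function(model, conc, t_assoc = 240, t_dissoc = 240,
                                dt = 0.5) {
  stopifnot(inherits(model, "KineticModel"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (conc < 0) stop("analyte concentration must be non-negative")
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  if (abs(times[length(times)] - (t_assoc + t_dissoc)) > 1e-9) {
    times <- c(times, t_assoc + t_dissoc)
  }
  parms <- list(ka = model$ka, kd = model$kd, Rmax = model$Rmax,
                kt = model$kt, conc = conc, t_assoc = t_assoc)
  # integrate the two phases separately so the discontinuity at t_assoc is a
  # clean initial condition, not an event inside a step
  ta <- times[times <= t_assoc]
  td <- times[times > t_assoc]
  outa <- deSolve::lsoda(c(R = 0), unique(c(ta, t_assoc)), spr_derivative,
                         parms, atol = 1e-6, rtol = 1e-8)
  Ra <- outa[match(ta, outa[, 1]), 2]
  Rend <- outa[nrow(outa), 2]
  if (length(td)) {
    outd <- deSolve::lsoda(c(R = Rend), unique(c(t_assoc, td)), spr_derivative,
                           parms, atol = 1e-6, rtol = 1e-8)
    Rd <- outd[match(td, outd[, 1]), 2]
  } else Rd <- numeric(0)
  resp <- pmin(c(Ra, Rd), model$Rmax)
  out <- data.frame(time = c(ta, td), response = resp,
                    conc = conc,
                    phase = c(rep("association", length(ta)),
                              rep("dissociation", length(td))))
  attr(out, "model") <- model
  attr(out, "t_assoc") <- t_assoc
  attr(out, "t_dissoc") <- t_dissoc
  class(out) <- c("Sensorgram", "data.frame")
  out
}

#' Closed-form transport-free 1:1 Langmuir response
#'
#' The analytic solution in the absence of mass-transport limitation:
#' association `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = Rmax C / (C + Kd)`, then exponential dissociation from the
#' association end point. Used as an independent oracle for the simulator in
#' its transport-free limit.
#'
#' @inheritParams simulate_sensorgram
#' @param times time grid, s.
#' @return numeric response vector (RU).
#' @export
langmuir_closed_form <- function(model, conc, times, t_assoc = 240) {
  req <- model$Rmax * conc / (conc + model$Kd)
  kobs <- model$ka * conc + model$kd
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(times <= t_assoc,
         req * (1 - exp(-kobs * times)),
         r_end * exp(-model$kd * (times - t_assoc)))
}

#' Generate a noisy sensorgram concentration series
#'
#' Simulates one sensorgram per concentration and adds seeded i.i.d.
#' Gaussian noise per time point. Byte-deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param model a `KineticModel`.
#' @param concs analyte concentrations, M.
#' @param noise_sd Gaussian noise standard deviation, RU (0 = noiseless).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param t_assoc,t_dissoc,dt protocol constants.
#' @return list of `Sensorgram`s.
#' @export
make_sensorgram_set <- function(model, concs, noise_sd = 0, seed = NULL,
                                t_assoc = 240, t_dissoc = 240, dt = 0.5) {
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required for noisy data")
  sims <- lapply(concs, function(cc)
    simulate_sensorgram(model, cc, t_assoc, t_dissoc, dt))
  if (noise_sd > 0) {
    sims <- with_seed(seed, lapply(sims, function(sg) {
      sg$response <- sg$response + stats::rnorm(nrow(sg), 0, noise_sd)
      sg
    }))
  }
  sims
}

#' Globally fit a sensorgram concentration series
#'
#' Nonlinear least squares (Levenberg-Marquardt) sharing `ka`, `kd` and
#' `Rmax` across all curves of a concentration series; `kt` is fixed by
#' default (the standard analysis convention) or fitted when `fix_kt =
#' FALSE`. Parameters are fitted on the log scale to enforce positivity.
#' Non-convergence is flagged in the result, never raised as an error.
#'
#' @param sensorgrams list of `Sensorgram`s (one per concentration).
#' @param kt mass-transport coefficient used (fixed) or as starting value.
#' @param fix_kt keep `kt` fixed (default `TRUE`).
#' @param start optional named list with starting `ka`, `kd`, `Rmax`.
#' @return object of class `FitResult`: `estimates` (a `KineticModel`),
#'   `std_errors`, `rss`, `converged`, `message`.
#' @export
fit_kinetics <- function(sensorgrams, kt = 1e7, fix_kt = TRUE, start = NULL) {
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 1)
  concs <- vapply(sensorgrams, function(sg) sg$conc[1], numeric(1))
  t_as <- vapply(sensorgrams, function(sg) attr(sg, "t_assoc"), numeric(1))
  rmax0 <- max(vapply(sensorgrams, function(sg) max(sg$response), numeric(1)))
  if (is.null(start)) {
    start <- list(ka = 1e5, kd = 1e-2, Rmax = rmax0 * 1.2)
  }
  p0 <- log(c(ka = start$ka, kd = start$kd, Rmax = start$Rmax))
  if (!fix_kt) p0 <- c(p0, kt = log(kt))
  obs <- unlist(lapply(sensorgrams, function(sg) sg$response))
  residual <- function(p) {
    ka <- exp(p[["ka"]]); kd <- exp(p[["kd"]]); Rmax <- exp(p[["Rmax"]])
    ktv <- if (fix_kt) kt else exp(p[["kt"]])
    pred <- tryCatch(
      unlist(lapply(seq_along(sensorgrams), function(i) {
        sg <- sensorgrams[[i]]
        m <- kinetic_model(ka, kd, Rmax, ktv)
        dtm <- diff(sg$time)
        sim <- simulate_sensorgram(m, concs[i], t_assoc = t_as[i],
                                   t_dissoc = max(sg$time) - t_as[i],
                                   dt = min(dtm))
        stats::approx(sim$time, sim$response, xout = sg$time, rule = 2)$y
      })),
      error = function(e) rep(1e6, length(obs)))
    pred - obs
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = residual,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  est <- kinetic_model(exp(p[["ka"]]), exp(p[["kd"]]), exp(p[["Rmax"]]),
                       if (fix_kt) kt else exp(p[["kt"]]))
  converged <- fit$info %in% 1:4
  # delta-method standard errors on the natural scale
  se <- tryCatch({
    cv <- diag(vcov(fit))
    sqrt(cv) * exp(unlist(p))
  }, error = function(e) rep(NA_real_, length(p)))
  structure(list(estimates = est, std_errors = se,
                 rss = fit$deviance, converged = converged,
                 message = fit$message, n_iter = fit$niter),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$estimates)
  cat(sprintf("  rss %.3g, %d iterations\n", x$rss, x$n_iter))
  invisible(x)
}

#' Free-ligand concentration at 1:1 solution equilibrium
#'
#' Closed-form root of the binding quadratic for total ligand `A`, total
#' binder `B` and dissociation constant `Kd`:
#' `A_free = ((A - B - Kd) + sqrt((A - B - Kd)^2 + 4 Kd A)) / 2`.
#'
#' @param A total ligand concentration, M.
#' @param B total binder concentration, M.
#' @param Kd solution dissociation constant, M.
#' @return free ligand concentration, M.
#' @export
free_fraction_quadratic <- function(A, B, Kd) {
  ((A - B - Kd) + sqrt((A - B - Kd)^2 + 4 * Kd * A)) / 2
}

#' Simulate a competitive binding assay
#'
#' The aptamer (analyte) at fixed total concentration is pre-equilibrated in
#' solution with a dilution series of competitor (the target protein); only
#' the free aptamer binds the immobilized target on the chip. The
#' report-point signal for each competitor concentration, relative to the
#' no-competitor signal, is returned: a monotone non-increasing competition
#' curve.
#'
#' @param chip_model `KineticModel` for binding to the immobilized target.
#' @param solution_kd solution-phase dissociation constant, M.
#' @param aptamer_conc total analyte concentration, M.
#' @param competitor_concs competitor concentration series, M.
#' @param t_assoc association time before the report point, s.
#' @param dt sampling interval, s.
#' @return data.frame (class `CompetitionCurve`): competitor concentration,
#'   free analyte, report-point response and `signal_fraction`.
#' @export
simulate_competition <- function(chip_model, solution_kd, aptamer_conc,
                                 competitor_concs, t_assoc = 240, dt = 0.5) {
  stopifnot(inherits(chip_model, "KineticModel"))
  if (aptamer_conc < 0 || any(competitor_concs < 0) || solution_kd <= 0) {
    stop("concentrations must be non-negative and solution_kd positive")
  }
  a_free <- vapply(competitor_concs, function(b)
    free_fraction_quadratic(aptamer_conc, b, solution_kd), numeric(1))
  report <- function(conc) {
    sg <- simulate_sensorgram(chip_model, conc, t_assoc = t_assoc,
                              t_dissoc = 0, dt = dt)
    sg$response[nrow(sg)]
  }
  r0 <- report(aptamer_conc)
  resp <- vapply(a_free, report, numeric(1))
  out <- data.frame(competitor_conc = competitor_concs,
                    free_analyte = a_free,
                    response = resp,
                    signal_fraction = if (r0 > 0) resp / r0 else NA_real_)
  class(out) <- c("CompetitionCurve", "data.frame")
  out
}

#' Write sensorgrams to CSV
#'
#' Columns: `time_s`, `response_RU`, `conc_M`, `phase`.
#'
#' @param sensorgrams list of `Sensorgram`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensorgrams <- function(sensorgrams, path) {
  df <- do.call(rbind, lapply(sensorgrams, function(sg)
    data.frame(time_s = sg$time, response_RU = sg$response,
               conc_M = sg$conc, phase = sg$phase)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read sensorgrams from CSV
#'
#' @param path CSV path as written by [write_sensorgrams()].
#' @param t_assoc association time (s) to record on each curve.
#' @return list of `Sensorgram`s, one per concentration.
#' @export
read_sensorgrams <- function(path, t_assoc = 240) {
  df <- utils::read.csv(path)
  lapply(split(df, df$conc_M), function(dd) {
    out <- data.frame(time = dd$time_s, response = dd$response_RU,
                      conc = dd$conc_M, phase = dd$phase)
    attr(out, "t_assoc") <- t_assoc
    attr(out, "t_dissoc") <- max(dd$time_s) - t_assoc
    class(out) <- c("Sensorgram", "data.frame")
    out
  })
}
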