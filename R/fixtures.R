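# Deterministic synthetic-structure generators: ideal nucleotides with
# prescribed glycosidic torsion and sugar pucker, A-form duplexes in D and L
# chirality, stacked G-tetrads with channel ions, ion coordination sites and
# sphere clusters. Everything is built from frozen ideal base geometry plus
# analytic sugar-ring construction; randomized fixtures require a seed and
# are byte-deterministic.

# Ideal base (plus C1') heavy-atom geometry, chemical-component ideal
# coordinates expressed in a common base frame: glycosidic N at the origin,
# C1' along +x, base plane ~ xy, ring neighbour (C4 for purines, C2 for
# pyrimidines) oriented toward +y.
.BASE_TEMPLATES <- local({
  tpl <- list(
    A = list(atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
      xyz = rbind(c(1.464, 0.000, 0.000), c(0.000, 0.000, 0.000), c(-0.806, -1.099, 0.000),
                  c(-2.055, -0.734, 0.000), c(-2.130, 0.618, 0.006), c(-3.182, 1.550, 0.000),
                  c(-4.500, 1.129, -0.001), c(-2.882, 2.844, 0.000), c(-1.628, 3.254, 0.001),
                  c(-0.610, 2.419, 0.001), c(-0.812, 1.106, 0.001))),
    G = list(atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
      xyz = rbind(c(1.465, 0.000, 0.000), c(0.000, 0.000, 0.000), c(-0.806, 1.101, -0.001),
                  c(-2.054, 0.735, -0.001), c(-2.124, -0.619, 0.000), c(-3.188, -1.550, 0.001),
                  c(-4.348, -1.173, 0.001), c(-2.888, -2.867, -0.005), c(-1.589, -3.276, 0.002),
                  c(-1.314, -4.621, 0.003), c(-0.591, -2.422, 0.001), c(-0.811, -1.102, 0.000))),
    C = list(atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
      xyz = rbind(c(1.465, 0.000, 0.000), c(0.000, 0.000, 0.000), c(-0.668, -1.166, -0.001),
                  c(-0.046, -2.215, -0.001), c(-2.000, -1.196, -0.001), c(-2.702, -0.071, -0.001),
                  c(-4.077, -0.113, -0.002), c(-2.031, 1.169, -0.005), c(-0.677, 1.182, 0.002))),
    U = list(atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
      xyz = rbind(c(1.466, 0.000, 0.000), c(0.000, 0.000, 0.000), c(-0.666, 1.167, 0.004),
                  c(-0.045, 2.211, 0.002), c(-2.012, 1.195, -0.002), c(-2.716, 0.045, 0.001),
                  c(-3.933, 0.070, 0.001), c(-2.026, -1.190, 0.002), c(-0.676, -1.190, 0.001))),
    T = list(atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6", "C7"),
      xyz = rbind(c(1.434, 0.000, 0.000), c(0.000, 0.000, 0.000), c(-0.732, 1.207, 0.001),
                  c(-0.212, 2.324, 0.000), c(-2.122, 1.056, 0.001), c(-2.832, -0.135, 0.000),
                  c(-4.059, -0.196, 0.000), c(-1.993, -1.363, 0.001), c(-0.661, -1.222, 0.000),
                  c(-2.684, -2.688, 0.001))))
  # normalize handedness: glycosidic-N ring neighbour toward +y
  for (b in names(tpl)) {
    nb <- if (b %in% c("A", "G")) "C4" else "C2"
    i <- match(nb, tpl[[b]]$atoms)
    if (tpl[[b]]$xyz[i, 2] < 0) {
      tpl[[b]]$xyz[, 2] <- -tpl[[b]]$xyz[, 2]
      tpl[[b]]$xyz[, 3] <- -tpl[[b]]$xyz[, 3]
    }
  }
  tpl
})

# NeRF placement: coordinates of atom D with |CD| = bond, angle(B,C,D) =
# angle and torsion(A,B,C,D) = torsion (degrees).
place_atom <- function(A, B, C, bond, angle, tors) {
  bc <- unitv(C - B)
  n <- unitv(vcross(B - A, bc))
  m <- vcross(n, bc)
  th <- rad(angle)
  ta <- rad(tors)
  C + bond * (-cos(th) * bc + sin(th) * (cos(ta) * m + sin(ta) * n))
}

# Five-membered sugar ring (C1',C2',C3',C4',O4') with prescribed
# pseudorotation phase (degrees) and amplitude (degrees). Built from a
# pentagon with cosine out-of-plane displacements; the free construction
# phase and displacement scale are solved numerically so that the
# Altona-Sundaralingam descriptors of the returned ring match the request.
.ring_cache <- new.env(parent = emptyenv())

build_sugar_ring <- function(phase, amplitude = 38.5) {
  ckey <- sprintf("%.6f|%.6f", phase, amplitude)
  if (!is.null(.ring_cache[[ckey]])) return(.ring_cache[[ckey]])
  ring_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  rho <- 1.53 / (2 * sin(pi / 5))
  mk <- function(phi, q) {
    k <- 0:4
    th <- 2 * pi * k / 5
    z <- sqrt(2 / 5) * q * cos(phi + 4 * pi * k / 5)
    X <- cbind(rho * cos(th), rho * sin(th), z)
    rownames(X) <- ring_names
    X
  }
  measure <- function(X) {
    res <- data.frame(elety = ring_names, x = X[, 1], y = X[, 2], z = X[, 3],
                      stringsAsFactors = FALSE)
    pseudorotation_phase(endocyclic_torsions(res))
  }
  # scan the construction phase for the target P, then refine; rescale q for
  # the target amplitude (amplitude is nearly independent of phi)
  q <- 0.38
  for (iter in 1:4) {
    grid <- seq(0, 2 * pi, length.out = 721)
    pg <- vapply(grid, function(phi) measure(mk(phi, q))$phase, numeric(1))
    best <- grid[which.min(ang_diff(pg, phase))]
    f <- function(phi) {
      p <- measure(mk(phi, q))$phase
      d <- (p - phase) %% 360
      if (d > 180) d <- d - 360
      d
    }
    lo <- best - 0.02; hi <- best + 0.02
    phi <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
                    error = function(e) best)
    got <- measure(mk(phi, q))
    if (abs(got$amplitude - amplitude) < 1e-6 &&
        ang_diff(got$phase, phase) < 1e-6) break
    q <- q * amplitude / got$amplitude
  }
  .ring_cache[[ckey]] <- mk(phi, q)
  .ring_cache[[ckey]]
}

# Full heavy-atom nucleotide in a local frame with prescribed glycosidic
# torsion (chi, degrees, D-frame convention) and sugar pucker.
build_nucleotide <- function(base = "G", deoxy = FALSE, chi = -160,
                             phase = 18, amplitude = 38.5) {
  base <- toupper(base)
  stopifnot(base %in% names(.BASE_TEMPLATES))
  ring <- build_sugar_ring(phase, amplitude)
  pl <- fit_plane(ring)
  n <- pl$normal
  p <- function(nm) ring[nm, ]
  # exocyclic substituent: out-of-plane from the in-plane bisector
  subst <- function(ctr, nb1, nb2, normal, up, bond, tilt = 54.75) {
    w <- -(unitv(nb1 - ctr) + unitv(nb2 - ctr))
    w <- w - sum(w * normal) * normal
    w <- unitv(w)
    dir <- unitv(w * cos(rad(tilt)) + (if (up) 1 else -1) * normal * sin(rad(tilt)))
    ctr + bond * dir
  }
  # orient the ring normal so that placing C5' on the +n side yields the
  # natural D configuration at C4'
  c5 <- subst(p("C4'"), p("C3'"), p("O4'"), n, TRUE, 1.51)
  v <- sum(vcross(p("C3'") - p("C4'"), p("O4'") - p("C4'")) * (c5 - p("C4'")))
  if (v < 0) {
    n <- -n
    c5 <- subst(p("C4'"), p("C3'"), p("O4'"), n, TRUE, 1.51)
  }
  npos <- subst(p("C1'"), p("O4'"), p("C2'"), n, TRUE, 1.47)
  o2p <- subst(p("C2'"), p("C1'"), p("C3'"), n, FALSE, 1.41)
  o3p <- subst(p("C3'"), p("C2'"), p("C4'"), n, FALSE, 1.42)
  o5p <- place_atom(p("C3'"), p("C4'"), c5, 1.44, 110, 54)
  pp  <- place_atom(p("C4'"), c5, o5p, 1.60, 120, 180)
  op1 <- place_atom(c5, o5p, pp, 1.49, 108, 115)
  op2 <- place_atom(c5, o5p, pp, 1.49, 108, -115)
  # base placement: align the template C1'->N bond, then spin about the
  # glycosidic bond to hit the requested chi
  tpl <- .BASE_TEMPLATES[[base]]
  n_name <- if (base %in% c("A", "G")) "N9" else "N1"
  chi_ref <- if (base %in% c("A", "G")) "C4" else "C2"
  bx <- tpl$xyz
  rownames(bx) <- tpl$atoms
  bx <- sweep(bx, 2, bx[n_name, ])          # N at origin
  u_t <- unitv(bx["C1'", ])                 # template N -> C1'
  u_a <- unitv(p("C1'") - npos)             # actual N -> C1'
  ax <- vcross(u_t, u_a)
  R0 <- if (vnorm(ax) < 1e-9) diag(3)
    else rotation_about_axis(ax, deg(atan2(vnorm(ax), sum(u_t * u_a))))
  base_xyz <- sweep(bx %*% t(R0), 2, npos, "+")
  rownames(base_xyz) <- tpl$atoms
  spin <- function(X, theta) {
    Xc <- sweep(X, 2, npos)
    sweep(Xc %*% t(rotation_about_axis(p("C1'") - npos, theta)), 2, npos, "+")
  }
  chi_of <- function(X) torsion_angle(p("O4'"), p("C1'"), npos, X[chi_ref, ])
  # probe the rotation sense about the glycosidic bond, then correct exactly
  cur <- chi_of(base_xyz)
  slope <- {
    d <- chi_of(spin(base_xyz, 10)) - cur
    d <- ((d + 180) %% 360) - 180
    sign(d)
  }
  delta <- ((chi - cur + 180) %% 360) - 180
  base_xyz <- spin(base_xyz, slope * delta)
  if (ang_diff(chi_of(base_xyz), chi) > 1e-6) {
    stop("internal error: glycosidic torsion placement failed")
  }
  base_atoms <- setdiff(tpl$atoms, "C1'")
  elety <- c(rownames(ring), "C5'", if (!deoxy) "O2'", "O3'", "O5'", "P",
             "OP1", "OP2", n_name, base_atoms[base_atoms != n_name])
  xyz <- rbind(ring, c5, if (!deoxy) o2p, o3p, o5p, pp, op1, op2,
               npos, base_xyz[base_atoms[base_atoms != n_name], , drop = FALSE])
  data.frame(elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             elesy = substr(gsub("[^A-Z]", "", elety), 1, 1),
             stringsAsFactors = FALSE)
}

resid_name <- function(base, deoxy) if (deoxy) paste0("D", base) else base

# rigid placement of a built nucleotide so that its base (ring + C1') atoms
# coincide with `target` (rows named by atom)
place_nucleotide <- function(nuc, target) {
  shared <- intersect(rownames(target), nuc$elety)
  P <- as.matrix(nuc[match(shared, nuc$elety), c("x", "y", "z")])
  Q <- target[shared, , drop = FALSE]
  kk <- kabsch(P, Q)
  X <- as.matrix(nuc[, c("x", "y", "z")]) %*% kk$R
  X <- sweep(X, 2, kk$t, "+")
  nuc$x <- X[, 1]; nuc$y <- X[, 2]; nuc$z <- X[, 3]
  nuc
}

# canonical hydrogen-bonding targets (atom pair and crystallographic mean
# distance, Angstrom) used to pose Watson-Crick partners; A-U additionally
# constrains the C2...O2 separation so the single-constraint-deficient pose
# reproduces the canonical propeller-free geometry
.WC_TARGETS <- list(
  "G|C" = list(list(c("O6", "N4"), 2.91), list(c("N1", "N3"), 2.95),
               list(c("N2", "O2"), 2.86)),
  "A|U" = list(list(c("N6", "O4"), 2.95), list(c("N1", "N3"), 2.82)),
  "A|T" = list(list(c("N6", "O4"), 2.95), list(c("N1", "N3"), 2.82)))

.pose_cache <- new.env(parent = emptyenv())

# pose base 2 against base 1 (template frames) so canonical WC hydrogen
# bonds are 2.90 A and the bases are coplanar; in-plane rigid optimization
# from a deterministic multi-start
pose_wc_partner <- function(b1, b2) {
  ckey <- sprintf("wc|%s|%s", b1, b2)
  if (!is.null(.pose_cache[[ckey]])) return(.pose_cache[[ckey]])
  t1 <- .BASE_TEMPLATES[[b1]]; t2 <- .BASE_TEMPLATES[[b2]]
  X1 <- t1$xyz; rownames(X1) <- t1$atoms
  X2 <- t2$xyz; rownames(X2) <- t2$atoms
  # flip partner about the x axis (proper rotation) so its glycosidic bond
  # faces back and its WC edge faces base 1
  X2f <- X2 %*% diag(c(1, -1, -1))
  tg <- .WC_TARGETS[[paste(b1, b2, sep = "|")]]
  swap <- FALSE
  if (is.null(tg)) {
    tg <- .WC_TARGETS[[paste(b2, b1, sep = "|")]]
    swap <- TRUE
  }
  if (is.null(tg)) stop("no Watson-Crick target pattern for ", b1, "-", b2)
  obj <- function(par) {
    th <- par[1]; tx <- par[2]; ty <- par[3]
    Rz <- rotation_about_axis(c(0, 0, 1), th)
    Y <- sweep(X2f %*% t(Rz), 2, c(tx, ty, 0), "+")
    rownames(Y) <- rownames(X2)
    s <- 0
    for (pr in tg) {
      a1 <- if (!swap) pr[[1]][1] else pr[[1]][2]
      a2 <- if (!swap) pr[[1]][2] else pr[[1]][1]
      s <- s + (vnorm(X1[a1, ] - Y[a2, ]) - pr[[2]])^2
    }
    # canonical glycosidic separation selects the correct solution branch
    s + (vnorm(X1["C1'", ] - Y["C1'", ]) - 10.4)^2
  }
  best <- NULL
  for (th0 in seq(0, 330, by = 30)) {
    o <- stats::optim(c(th0, -6, 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # four distance targets over three in-plane degrees of freedom: a small
  # least-squares residual (distance deviations of a few hundredths of an
  # Angstrom) is expected
  if (best$value > 1e-2) {
    warning(sprintf("WC pose residual %.3g for %s-%s", best$value, b1, b2))
  }
  Rz <- rotation_about_axis(c(0, 0, 1), best$par[1])
  Y <- sweep(X2f %*% t(Rz), 2, c(best$par[2], best$par[3], 0), "+")
  rownames(Y) <- rownames(X2)
  .pose_cache[[ckey]] <- Y
  Y
}

wc_complement <- function(base) c(A = "U", U = "A", G = "C", C = "G", T = "A")[base]

#' Generate an ideal A-form duplex
#'
#' Builds an idealized double helix from frozen ideal base geometry: base
#' pairs are posed at canonical Watson-Crick hydrogen-bond geometry, sugars
#' (C3'-endo, anti) are attached rigidly, and pairs are stacked with the
#' A-form fiber parameters (rise 2.81 Angstrom, twist 32.7 degrees per base
#' pair). The `"L"` variant is the exact mirror of the D build and is
#' therefore left-handed.
#'
#' @param n_bp number of base pairs (>= 2).
#' @param sequence optional base letters for strand 1 (default a repeating
#'   G/A/C/U pattern); the second strand is the Watson-Crick complement.
#' @param deoxy logical vector: which strand-1 nucleotides are deoxy
#'   (complement strand stays ribo).
#' @param chirality "D" or "L".
#' @param twist,rise helical parameters (degrees, Angstrom).
#' @param x_disp displacement of the base-pair centroid from the helix axis
#'   (Angstrom).
#' @return a `StructureModel` with chains A and B (B antiparallel).
#' @export
make_duplex <- function(n_bp, sequence = NULL, deoxy = NULL,
                        chirality = c("D", "L"), twist = 32.7, rise = 2.81,
                        x_disp = 0) {
  chirality <- match.arg(chirality)
  if (n_bp < 2) stop("a duplex needs at least 2 base pairs")
  if (is.null(sequence)) sequence <- rep(c("G", "A", "C", "U"), length.out = n_bp)
  sequence <- toupper(sequence)
  stopifnot(length(sequence) == n_bp, all(sequence %in% c("A", "C", "G", "U", "T")))
  if (is.null(deoxy)) deoxy <- rep(FALSE, n_bp)
  stopifnot(length(deoxy) == n_bp)
  rows <- list()
  poses <- lapply(unique(sequence), function(b) pose_wc_partner(b, wc_complement(b)))
  names(poses) <- unique(sequence)
  # one nucleotide build per distinct (base, deoxy); placement is rigid
  get_nuc <- function(b, dx) {
    k <- sprintf("nuc|%s|%d", b, dx)
    if (is.null(.pose_cache[[k]])) .pose_cache[[k]] <- build_nucleotide(b, dx)
    .pose_cache[[k]]
  }
  for (i in seq_len(n_bp)) {
    b1 <- sequence[i]; b2 <- wc_complement(b1)
    t1 <- .BASE_TEMPLATES[[b1]]$xyz
    rownames(t1) <- .BASE_TEMPLATES[[b1]]$atoms
    t2 <- poses[[b1]]
    # center the pair unit on its two-base centroid, then displace from the
    # helix axis by x_disp
    ctr <- colMeans(rbind(t1, t2))
    Rz <- rotation_about_axis(c(0, 0, 1), (i - 1) * twist)
    shift <- c(0, 0, (i - 1) * rise)
    placei <- function(tpl) {
      Y <- sweep(tpl, 2, ctr - c(x_disp, 0, 0)) %*% t(Rz)
      sweep(Y, 2, shift, "+")
    }
    nuc1 <- place_nucleotide(get_nuc(b1, deoxy[i]), placei(t1))
    nuc2 <- place_nucleotide(get_nuc(b2, FALSE), placei(t2))
    nuc1$chain <- "A"; nuc1$resno <- i; nuc1$resid <- resid_name(b1, deoxy[i])
    nuc2$chain <- "B"; nuc2$resno <- n_bp - i + 1; nuc2$resid <- b2
    rows[[length(rows) + 1]] <- nuc1
    rows[[length(rows) + 1]] <- nuc2
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$eleno <- seq_len(nrow(atoms))
  s <- structure_model(atoms, identifier = sprintf("ideal A-form duplex (%d bp, %s)",
                                                   n_bp, chirality))
  if (chirality == "L") mirror_structure(s) else s
}

#' Helix handedness from the C1' spiral
#'
#' Estimates the helical axis (principal component of the C1' positions of
#' one strand) and reports whether the strand winds right- or left-handed:
#' the sign of the angular advance about the axis per step along the axis.
#'
#' @param s a `StructureModel`.
#' @param chain chain identifier of the strand to test.
#' @return "right-handed" or "left-handed".
#' @export
helix_handedness <- function(s, chain = "A") {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  sel <- a$chain == chain & a$elety == "C1'"
  at <- a[sel, , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  if (nrow(at) < 3) stop("need >= 3 nucleotides to measure handedness")
  X <- coords(at)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  axis <- svd(Xc)$v[, 1]
  zz <- as.vector(Xc %*% axis)
  Pr <- Xc - outer(zz, axis)
  # in-plane frame
  e1 <- unitv(Pr[1, ])
  e2 <- vcross(axis, e1)
  th <- atan2(Pr %*% e2, Pr %*% e1)
  dth <- diff(as.vector(th))
  dth <- ((dth + pi) %% (2 * pi)) - pi
  sgn <- sum(sign(dth * diff(zz)))
  if (sgn > 0) "right-handed" else "left-handed"
}

# pose one guanine of a planar G-tetrad: in-plane pose (theta, tx, ty) such
# that the Hoogsteen contacts to the 90-degree-rotated copy are at target
# distance and O6 sits at a prescribed radius from the channel axis
pose_tetrad_guanine <- function(o6_radius, hb_target = 2.90) {
  ckey <- sprintf("tet|%.4f|%.4f", o6_radius, hb_target)
  if (!is.null(.pose_cache[[ckey]])) return(.pose_cache[[ckey]])
  tpl <- .BASE_TEMPLATES[["G"]]
  X <- tpl$xyz
  rownames(X) <- tpl$atoms
  R90 <- rotation_about_axis(c(0, 0, 1), 90)
  obj <- function(par) {
    Rz <- rotation_about_axis(c(0, 0, 1), par[1])
    Y <- sweep(X %*% t(Rz), 2, c(par[2], par[3], 0), "+")
    rownames(Y) <- tpl$atoms
    Z <- Y %*% t(R90)
    rownames(Z) <- tpl$atoms
    (vnorm(Y["N1", ] - Z["O6", ]) - hb_target)^2 +
      (vnorm(Y["N2", ] - Z["N7", ]) - hb_target)^2 +
      (vnorm(Y["O6", c(1, 2)]) - o6_radius)^2
  }
  best <- NULL
  for (th0 in seq(0, 330, by = 30)) {
    for (r0 in c(3, 4.5)) {
      o <- stats::optim(c(th0, r0, 0), obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  # tightly squeezed channels (small O6 radius) cannot satisfy all three
  # targets exactly; a residual up to ~0.05 A^2 means per-target deviations
  # of a few hundredths of an Angstrom, which is inconsequential for the
  # detection cutoffs these fixtures exercise
  if (best$value > 0.05) {
    warning(sprintf("tetrad pose residual %.3g at O6 radius %.2f",
                    best$value, o6_radius))
  }
  Rz <- rotation_about_axis(c(0, 0, 1), best$par[1])
  Y <- sweep(X %*% t(Rz), 2, c(best$par[2], best$par[3], 0), "+")
  rownames(Y) <- tpl$atoms
  .pose_cache[[ckey]] <- Y
  Y
}

#' Generate an ideal stacked G-tetrad fixture
#'
#' Four guanines are posed in a plane with closed Hoogsteen hydrogen-bond
#' geometry (N1...O6 and N2...N7 at 2.9 Angstrom) by four-fold symmetry;
#' additional tetrads are stacked with the given twist and rise. An optional
#' channel ion is placed on the axis (mid-channel for stacks, in-plane for a
#' single tetrad) at the requested ion-oxygen distance, which fixes the O6
#' radius of the construction.
#'
#' @param n_tetrads number of tetrads (>= 1).
#' @param twist inter-tetrad twist, degrees.
#' @param rise inter-tetrad rise, Angstrom.
#' @param ion `NA`/`"none"` or a species residue name ("CA", "K", "NA", "MG").
#' @param ion_dist target ion-O6 distance, Angstrom.
#' @param chirality "D" or "L".
#' @return a `StructureModel` (guanines on chain Q, ion on chain I).
#' @export
make_tetrad_stack <- function(n_tetrads = 2, twist = 45, rise = 3.3,
                              ion = "CA", ion_dist = 2.48,
                              chirality = c("D", "L")) {
  chirality <- match.arg(chirality)
  if (n_tetrads < 1) stop("need at least one tetrad")
  has_ion <- !is.null(ion) && !is.na(ion) && ion != "none"
  if (has_ion) {
    ion <- toupper(ion)
    stopifnot(ion %in% .METAL_RES)
  }
  o6_radius <- if (!has_ion) 2.45
    else if (n_tetrads == 1) ion_dist
    else {
      hh <- rise / 2
      if (ion_dist <= hh) stop("ion_dist too small for the requested rise")
      sqrt(ion_dist^2 - hh^2)
    }
  pose <- pose_tetrad_guanine(o6_radius)
  if (is.null(.pose_cache[["nuc|G|0"]])) {
    .pose_cache[["nuc|G|0"]] <- build_nucleotide("G", FALSE)
  }
  gnuc <- .pose_cache[["nuc|G|0"]]
  rows <- list()
  resno <- 0
  for (t in seq_len(n_tetrads)) {
    Rt <- rotation_about_axis(c(0, 0, 1), (t - 1) * twist)
    shift <- c(0, 0, (t - 1) * rise)
    for (g in 0:3) {
      Rg <- rotation_about_axis(c(0, 0, 1), 90 * g)
      tgt <- sweep(pose %*% t(Rg) %*% t(Rt), 2, shift, "+")
      rownames(tgt) <- rownames(pose)
      nuc <- place_nucleotide(gnuc, tgt)
      resno <- resno + 1
      nuc$chain <- "Q"; nuc$resno <- resno; nuc$resid <- "G"
      rows[[length(rows) + 1]] <- nuc
    }
  }
  atoms <- do.call(rbind, rows)
  if (has_ion) {
    zion <- if (n_tetrads == 1) 0 else rise / 2
    atoms <- rbind(atoms, data.frame(
      elety = ion, x = 0, y = 0, z = zion, elesy = ion,
      chain = "I", resno = 1L, resid = ion, stringsAsFactors = FALSE))
  }
  atoms$eleno <- seq_len(nrow(atoms))
  s <- structure_model(atoms, identifier = sprintf(
    "ideal G-tetrad stack (%d x 4 G, twist %.1f)", n_tetrads, twist))
  if (chirality == "L") mirror_structure(s) else s
}

# regular coordination polyhedra (unit vectors) for CN 4-9
coordination_polyhedron <- function(cn) {
  s3 <- 1 / sqrt(3)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s3
  oct <- rbind(diag(3), -diag(3))
  tbp <- rbind(c(0, 0, 1), c(0, 0, -1),
               t(vapply(0:2, function(k) c(cos(2 * pi * k / 3), sin(2 * pi * k / 3), 0),
                        numeric(3))))
  pbp <- rbind(c(0, 0, 1), c(0, 0, -1),
               t(vapply(0:4, function(k) c(cos(2 * pi * k / 5), sin(2 * pi * k / 5), 0),
                        numeric(3))))
  sap <- {
    a <- 1 / sqrt(2)
    top <- t(vapply(0:3, function(k) c(cos(pi * k / 2), sin(pi * k / 2), 1) , numeric(3)))
    bot <- t(vapply(0:3, function(k) c(cos(pi * k / 2 + pi / 4), sin(pi * k / 2 + pi / 4), -1), numeric(3)))
    X <- rbind(top, bot)
    X / sqrt(rowSums(X^2))
  }
  ttp <- {
    z <- 0.65
    prism <- rbind(
      t(vapply(0:2, function(k) c(cos(2 * pi * k / 3), sin(2 * pi * k / 3), z), numeric(3))),
      t(vapply(0:2, function(k) c(cos(2 * pi * k / 3), sin(2 * pi * k / 3), -z), numeric(3))))
    caps <- t(vapply(0:2, function(k) c(cos(2 * pi * k / 3 + pi / 3),
                                        sin(2 * pi * k / 3 + pi / 3), 0) * 1.1, numeric(3)))
    X <- rbind(prism, caps)
    X / sqrt(rowSums(X^2))
  }
  switch(as.character(cn),
         "4" = tet, "5" = tbp, "6" = oct, "7" = pbp, "8" = sap, "9" = ttp,
         stop("coordination number must lie in 4-9"))
}

#' Generate a synthetic metal-ion coordination site
#'
#' One metal ion at the origin surrounded by `cn` water oxygens on the
#' vertices of a regular coordination polyhedron at seeded, jittered radial
#' distances.
#'
#' @param species residue name of the ion ("MG", "CA", "K", "NA").
#' @param cn coordination number (4-9).
#' @param mean_dist mean ion-oxygen distance, Angstrom.
#' @param jitter_sd radial Gaussian jitter, Angstrom (0 = exact).
#' @param seed integer seed (required when `jitter_sd > 0`).
#' @return a `StructureModel` (ion on chain M, waters on chain W).
#' @export
make_ion_site <- function(species = "MG", cn = 6, mean_dist = 2.08,
                          jitter_sd = 0, seed = NULL) {
  species <- toupper(species)
  stopifnot(species %in% .METAL_RES)
  if (cn < 4 || cn > 9) stop("coordination number must lie in 4-9")
  if (jitter_sd > 0 && is.null(seed)) stop("a seed is required for jittered sites")
  U <- coordination_polyhedron(cn)
  d <- rep(mean_dist, cn)
  if (jitter_sd > 0) d <- with_seed(seed, d + stats::rnorm(cn, 0, jitter_sd))
  X <- U * d
  atoms <- rbind(
    data.frame(elety = species, x = 0, y = 0, z = 0, elesy = species,
               chain = "M", resno = 1L, resid = species, stringsAsFactors = FALSE),
    data.frame(elety = "O", x = X[, 1], y = X[, 2], z = X[, 3], elesy = "O",
               chain = "W", resno = 100L + seq_len(cn), resid = "HOH",
               stringsAsFactors = FALSE))
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, identifier = sprintf("ideal %s site (CN %d, %.2f A)",
                                              species, cn, mean_dist))
}

#' Generate a random cluster of carbon spheres
#'
#' A seeded Gaussian cloud of carbon atoms, used to exercise surface-area
#' computations against dense-quadrature references.
#'
#' @param n_atoms number of atoms.
#' @param seed integer seed.
#' @param spread standard deviation of the Gaussian cloud, Angstrom.
#' @return a `StructureModel`.
#' @export
make_sphere_cluster <- function(n_atoms = 20, seed = 1, spread = 2.5) {
  X <- with_seed(seed, matrix(stats::rnorm(3 * n_atoms, 0, spread), ncol = 3))
  atoms <- data.frame(
    elety = "C", x = X[, 1], y = X[, 2], z = X[, 3], elesy = "C",
    chain = "X", resno = seq_len(n_atoms), resid = "ALA",
    stringsAsFactors = FALSE)
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, identifier = sprintf("sphere cluster (n=%d, seed=%d)",
                                              n_atoms, seed))
}
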