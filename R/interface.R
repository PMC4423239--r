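# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# golden-spiral point lattice), buried surface area, interface contacts and
# residue footprints.

#' Van der Waals radii used for surface computations
#'
#' Per-element radii in Angstrom: C 1.70, N 1.55, O 1.52, P 1.80, S 1.80,
#' H 1.20; common ions get their ionic/vdW radii. Unknown elements fall back
#' to 1.70 with a warning.
#'
#' @return named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20,
    SE = 1.90, MG = 1.73, CA = 2.31, K = 2.75, "NA" = 2.27, ZN = 1.39,
    MN = 1.39, FE = 1.32, LI = 1.82, RB = 3.03, CS = 3.43, SR = 2.49,
    BA = 2.68, CL = 1.75, BR = 1.85, F = 1.47, I = 1.98, OS = 2.0)
}

atom_radii <- function(atoms, radii = vdw_radii()) {
  el <- toupper(atoms$elesy)
  r <- radii[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            ": using default radius 1.70 A")
    r[unknown] <- 1.70
  }
  unname(r)
}

# Orientation-canonical coordinates: principal axes with each axis sign
# fixed by the third moment (falling back to the largest-magnitude
# coordinate). Any isometry of the input - rotation, translation or mirror -
# maps to the same canonical coordinates, which makes the lattice SASA
# exactly invariant under rigid motion and reflection instead of invariant
# only to quadrature error.
canonical_frame <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (nrow(X) < 2 || max(abs(Xc)) < 1e-9) return(Xc)
  V <- eigen(crossprod(Xc), symmetric = TRUE)$vectors  # always 3 axes
  Y <- Xc %*% V
  for (j in 1:3) {
    s3 <- sum(Y[, j]^3)
    if (abs(s3) < 1e-9) s3 <- Y[which.max(abs(Y[, j])), j]
    if (s3 < 0) Y[, j] <- -Y[, j]
  }
  Y
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic numerical SASA: each atom's expanded sphere
#' (radius + probe) is sampled on a golden-spiral lattice of `n_points`
#' points and a point is accessible when it lies outside every neighbouring
#' expanded sphere. No randomness is involved: identical inputs give
#' identical results, and coordinates are canonicalized to their principal
#' axes first, so the result is exactly invariant under rigid motion and
#' mirror reflection of the input.
#'
#' @param s a `StructureModel`.
#' @param probe probe radius in Angstrom, in \[1.0, 2.0\]; default 1.4.
#' @param n_points lattice points per atom (default 960).
#' @param selection optional atom selection.
#' @param include_waters,include_ions include waters / metal ions
#'   (default `FALSE`: the macromolecular surface).
#' @param radii named per-element radius table, default [vdw_radii()].
#' @return object of class `SasaResult`: per-atom areas, per-residue areas,
#'   total, probe radius, point count.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, selection = NULL,
                 include_waters = FALSE, include_ions = FALSE,
                 radii = vdw_radii()) {
  stopifnot(inherits(s, "StructureModel"))
  if (probe < 1.0 || probe > 2.0) stop("probe radius must lie in [1.0, 2.0] A")
  idx <- resolve_selection(s, selection)
  a <- s$atoms
  if (!include_waters) idx <- idx[a$kind[idx] != "water"]
  if (!include_ions) idx <- idx[a$kind[idx] != "metal_ion"]
  idx <- idx[toupper(a$elesy[idx]) != "H"]
  if (!length(idx)) stop("empty selection for sasa()")
  at <- a[idx, , drop = FALSE]
  X <- canonical_frame(coords(at))
  r <- atom_radii(at, radii) + probe
  n <- nrow(X)
  pts <- sphere_lattice(n_points)
  area <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    di <- sqrt((X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 +
                 (X[, 3] - X[i, 3])^2)
    nb <- which(di < r[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < r[i] + r[nb]]
    sp <- sweep(pts * r[i], 2, X[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj <- (sp[acc, 1] - X[j, 1])^2 + (sp[acc, 2] - X[j, 2])^2 +
          (sp[acc, 3] - X[j, 3])^2
        acc[acc] <- dj >= r[j]^2
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * r[i]^2 * frac
  }
  per_res <- tapply(area, res_key(at), sum)
  structure(list(
    atom_index = idx, per_atom = area,
    per_residue = data.frame(key = names(per_res), area = as.numeric(per_res),
                             stringsAsFactors = FALSE),
    total = sum(area), probe_radius = probe, sample_points = n_points),
    class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$sample_points))
  invisible(x)
}

subset_structure <- function(s, idx) {
  structure_model(s$atoms[idx, , drop = FALSE], identifier = s$identifier,
                  source_format = s$source_format)
}

#' Buried surface area and interface footprints
#'
#' Computes the two-sided buried area
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)` between two
#' disjoint selections, the cross-interface atom contacts, cross-interface
#' hydrogen bonds, and the footprint of each partner: residues losing at
#' least `footprint_dsasa` of accessible area on complexation, or having any
#' heavy atom within `contact_cutoff` of the other partner. Waters and metal
#' ions are excluded by default.
#'
#' @param s a `StructureModel`.
#' @param selection_a,selection_b disjoint atom selections.
#' @param probe probe radius (Angstrom).
#' @param n_points lattice points per atom.
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom, default 4.0).
#' @param footprint_dsasa per-residue buried-area threshold (Angstrom^2).
#' @param hbond_cutoff cross-interface hydrogen-bond cutoff (Angstrom).
#' @return object of class `InterfaceReport`: `bsa_total`, per-side SASA,
#'   `contacts`, `hbonds`, `footprint_a`, `footprint_b`.
#' @export
buried_surface <- function(s, selection_a, selection_b, probe = 1.4,
                           n_points = 960, contact_cutoff = 4.0,
                           footprint_dsasa = 1.0, hbond_cutoff = 3.5) {
  stopifnot(inherits(s, "StructureModel"))
  ia <- resolve_selection(s, selection_a)
  ib <- resolve_selection(s, selection_b)
  if (length(intersect(ia, ib))) stop("selections overlap")
  a <- s$atoms
  drop_kind <- function(ii) ii[!(a$kind[ii] %in% c("water", "metal_ion"))]
  ia <- drop_kind(ia); ib <- drop_kind(ib)
  if (!length(ia) || !length(ib)) stop("empty selection after removing waters/ions")
  sa <- sasa(subset_structure(s, ia), probe, n_points)
  sb <- sasa(subset_structure(s, ib), probe, n_points)
  sab <- sasa(subset_structure(s, c(ia, ib)), probe, n_points)
  bsa <- sa$total + sb$total - sab$total
  # per-residue delta SASA
  dsasa <- function(alone, idx_side) {
    keys_ab <- res_key(a[c(ia, ib), , drop = FALSE])
    per_ab <- tapply(sab$per_atom, keys_ab, sum)
    m <- match(alone$per_residue$key, names(per_ab))
    delta <- alone$per_residue$area - as.numeric(per_ab[m])
    data.frame(key = alone$per_residue$key, delta_sasa = delta,
               stringsAsFactors = FALSE)
  }
  da <- dsasa(sa, ia)
  db <- dsasa(sb, ib)
  # contacts
  Xa <- coords(a[ia, , drop = FALSE])
  Xb <- coords(a[ib, , drop = FALSE])
  contacts <- list()
  for (p in seq_along(ia)) {
    d2 <- (Xb[, 1] - Xa[p, 1])^2 + (Xb[, 2] - Xa[p, 2])^2 +
      (Xb[, 3] - Xa[p, 3])^2
    hit <- which(d2 <= contact_cutoff^2)
    if (length(hit)) {
      contacts[[length(contacts) + 1]] <- data.frame(
        i = ia[p], j = ib[hit], distance = sqrt(d2[hit]))
    }
  }
  contacts <- if (length(contacts)) do.call(rbind, contacts)
    else data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  # cross-interface hydrogen bonds
  hb <- detect_hbonds(s, cutoff = hbond_cutoff, selection = c(ia, ib))
  if (nrow(hb)) hb <- hb[(hb$i %in% ia) != (hb$j %in% ia), , drop = FALSE]
  key_all <- res_key(a)
  footprint <- function(dd, side_idx) {
    contact_keys <- unique(key_all[c(contacts$i, contacts$j)])
    keep <- dd$delta_sasa >= footprint_dsasa | dd$key %in% contact_keys
    fp <- dd[keep, , drop = FALSE]
    m <- match(fp$key, key_all)
    fp$chain <- a$chain[m]; fp$resno <- a$resno[m]; fp$resid <- a$resid[m]
    fp[order(fp$chain, fp$resno), , drop = FALSE]
  }
  structure(list(
    bsa_total = bsa, sasa_a = sa$total, sasa_b = sb$total,
    sasa_complex = sab$total, contacts = contacts, hbonds = hb,
    footprint_a = footprint(da, ia), footprint_b = footprint(db, ib),
    probe_radius = probe, sample_points = n_points),
    class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("InterfaceReport: BSA %.0f A^2 (A %.0f + B %.0f - AB %.0f)\n",
              x$bsa_total, x$sasa_a, x$sasa_b, x$sasa_complex))
  cat(" ", nrow(x$contacts), "atom contacts;", nrow(x$hbonds),
      "cross-interface H-bonds;",
      nrow(x$footprint_a), "+", nrow(x$footprint_b), "footprint residues\n")
  invisible(x)
}

#' Overlap metrics between two residue footprints
#'
#' @param fp_a,fp_b residue identifier vectors (any consistent labelling,
#'   e.g. author residue numbers).
#' @return list with intersection, union sizes and the Jaccard index.
#' @export
footprint_overlap <- function(fp_a, fp_b) {
  A <- unique(fp_a)
  B <- unique(fp_b)
  inter <- intersect(A, B)
  uni <- union(A, B)
  list(n_a = length(A), n_b = length(B),
       intersection = inter, n_intersection = length(inter),
       n_union = length(uni),
       jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_)
}
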