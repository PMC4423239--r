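# Nucleotide conformational descriptors: glycosidic torsion and syn/anti
# class, sugar pseudorotation phase/amplitude and pucker name.
#
# L-configured residues are always evaluated in the mirrored-to-D frame
# (equivalently: their torsions are negated), so that the standard D-frame
# nomenclature (anti, 3'-endo, ...) applies unchanged to mirror-image
# nucleic acids.

.PURINES <- c("A", "G", "I", "DA", "DG", "DI")

# canonical envelope/twist wheel: sector centers every 36 degrees
.PUCKER_WHEEL <- data.frame(
  center = seq(18, 342, by = 36),
  name = c("3'-endo", "4'-exo", "O4'-endo", "1'-exo", "2'-endo",
           "3'-exo", "4'-endo", "O4'-exo", "1'-endo", "2'-exo"),
  stringsAsFactors = FALSE)

is_purine <- function(resid) toupper(resid) %in% .PURINES

# the five endocyclic sugar torsions nu0..nu4 of one residue (degrees),
# or NULL if the ring is incomplete
endocyclic_torsions <- function(res_atoms) {
  ring <- list(c("C4'", "O4'", "C1'", "C2'"),  # nu0
               c("O4'", "C1'", "C2'", "C3'"),  # nu1
               c("C1'", "C2'", "C3'", "C4'"),  # nu2
               c("C2'", "C3'", "C4'", "O4'"),  # nu3
               c("C3'", "C4'", "O4'", "C1'"))  # nu4
  vapply(ring, function(q) {
    ps <- lapply(q, atom_xyz, res_atoms = res_atoms)
    if (any(vapply(ps, is.null, TRUE))) return(NA_real_)
    torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

#' Glycosidic torsion (chi) of every nucleotide
#'
#' chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines
#' (IUPAC). With `frame = "auto"` (default), L residues are evaluated in the
#' mirrored-to-D frame (torsion negated) so standard conventions apply;
#' `frame = "as-deposited"` reports the raw torsion.
#'
#' @param s a `StructureModel`.
#' @param frame "auto" or "as-deposited".
#' @return data.frame: chain, resno, insert, resid, chi, missing_atom.
#' @export
glycosidic_chi <- function(s, frame = c("auto", "as-deposited")) {
  frame <- match.arg(frame)
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  key <- res_key(a)
  rt <- residue_table(s)
  rt <- rt[rt$kind %in% c("ribonucleotide", "deoxyribonucleotide"), , drop = FALSE]
  out <- rt[, c("chain", "resno", "insert", "resid", "chirality")]
  out$chi <- NA_real_
  out$missing_atom <- NA_character_
  for (i in seq_len(nrow(rt))) {
    res <- a[key == rt$key[i], , drop = FALSE]
    q <- if (is_purine(rt$resid[i])) c("O4'", "C1'", "N9", "C4")
         else c("O4'", "C1'", "N1", "C2")
    ps <- lapply(q, atom_xyz, res_atoms = res)
    miss <- q[vapply(ps, is.null, TRUE)]
    if (length(miss)) {
      out$missing_atom[i] <- miss[1]
      next
    }
    chi <- torsion_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    if (frame == "auto" && rt$chirality[i] == "L") chi <- -chi
    if (chi <= -180) chi <- chi + 360
    out$chi[i] <- chi
  }
  out
}

#' Classify a glycosidic torsion as syn or anti
#'
#' syn iff |chi| <= 90 degrees; anti otherwise. The classification is
#' invariant under a sign flip of chi, hence mirror-invariant.
#'
#' @param chi glycosidic torsion(s) in degrees.
#' @return character vector "syn"/"anti" (NA propagated).
#' @export
classify_glycosidic <- function(chi) {
  ifelse(is.na(chi), NA_character_, ifelse(abs(chi) <= 90, "syn", "anti"))
}

#' Pseudorotation phase from the five endocyclic torsions
#'
#' Altona-Sundaralingam: tan P = ((nu4+nu1)-(nu3+nu0)) / (2 nu2 (sin36+sin72)),
#' with 180 degrees added when nu2 < 0; amplitude tau_m = nu2 / cos P.
#'
#' @param nu numeric length-5 vector (nu0..nu4, degrees).
#' @return list(phase, amplitude) in degrees.
#' @export
pseudorotation_phase <- function(nu) {
  stopifnot(length(nu) == 5)
  if (any(is.na(nu))) return(list(phase = NA_real_, amplitude = NA_real_))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(rad(36)) + sin(rad(72)))
  P <- deg(atan(num / den))
  if (nu[3] < 0) P <- P + 180
  P <- P %% 360
  tm <- nu[3] / cos(rad(P))
  list(phase = P, amplitude = abs(tm))
}

#' Name a sugar pucker from its pseudorotation phase
#'
#' Returns the nearest canonical envelope on the 18-degree wheel (3'-endo at
#' P=18, 4'-exo at 54, ..., 2'-exo at 342). Amplitudes below `min_amplitude`
#' give "planar/indeterminate".
#'
#' @param phase pseudorotation phase in degrees.
#' @param amplitude puckering amplitude in degrees.
#' @param min_amplitude near-planar threshold (default 5 degrees).
#' @return character pucker name.
#' @export
pucker_name <- function(phase, amplitude = 38, min_amplitude = 5) {
  if (is.na(phase) || is.na(amplitude)) return(NA_character_)
  if (amplitude < min_amplitude) return("planar/indeterminate")
  d <- ang_diff(phase, .PUCKER_WHEEL$center)
  .PUCKER_WHEEL$name[which.min(d)]
}

#' Sugar pseudorotation of every nucleotide
#'
#' Computes nu0..nu4, phase P, amplitude and the pucker name for each
#' nucleotide. L residues are evaluated in the mirrored-to-D frame so that
#' the standard pucker vocabulary applies (`frame = "auto"`).
#'
#' @inheritParams glycosidic_chi
#' @return data.frame with chain, resno, insert, resid, nu0..nu4, phase,
#'   amplitude, pucker, ambiguous (within 5 degrees of a sector edge).
#' @export
pseudorotation <- function(s, frame = c("auto", "as-deposited")) {
  frame <- match.arg(frame)
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  key <- res_key(a)
  rt <- residue_table(s)
  rt <- rt[rt$kind %in% c("ribonucleotide", "deoxyribonucleotide"), , drop = FALSE]
  out <- rt[, c("chain", "resno", "insert", "resid", "chirality")]
  nus <- matrix(NA_real_, nrow(rt), 5,
                dimnames = list(NULL, paste0("nu", 0:4)))
  out$phase <- NA_real_
  out$amplitude <- NA_real_
  out$pucker <- NA_character_
  out$ambiguous <- NA
  for (i in seq_len(nrow(rt))) {
    res <- a[key == rt$key[i], , drop = FALSE]
    nu <- endocyclic_torsions(res)
    if (frame == "auto" && rt$chirality[i] == "L") nu <- -nu
    nus[i, ] <- nu
    pr <- pseudorotation_phase(nu)
    out$phase[i] <- pr$phase
    out$amplitude[i] <- pr$amplitude
    out$pucker[i] <- pucker_name(pr$phase, pr$amplitude)
    if (!is.na(pr$phase)) {
      # distance to the nearest sector boundary (boundaries at center +- 18)
      d <- min(ang_diff(pr$phase, .PUCKER_WHEEL$center + 18))
      out$ambiguous[i] <- d < 5
    }
  }
  cbind(out, nus)
}

#' Per-nucleotide conformational annotation table
#'
#' One row per nucleotide: chirality, glycosidic chi and syn/anti class,
#' pseudorotation phase/amplitude and pucker name. Calls within 5 degrees of
#' a classification edge are flagged `ambiguous` rather than silently
#' asserted.
#'
#' @inheritParams glycosidic_chi
#' @return data.frame annotation table.
#' @export
annotate_conformation <- function(s, frame = c("auto", "as-deposited")) {
  frame <- match.arg(frame)
  chi <- glycosidic_chi(s, frame = frame)
  ps <- pseudorotation(s, frame = frame)
  out <- chi[, c("chain", "resno", "insert", "resid", "chirality", "chi")]
  out$is_deoxy <- residue_table(s)$kind[match(
    paste(out$chain, out$resno, out$insert),
    paste(residue_table(s)$chain, residue_table(s)$resno, residue_table(s)$insert))] ==
    "deoxyribonucleotide"
  out$glycosidic_class <- classify_glycosidic(out$chi)
  out$chi_ambiguous <- !is.na(out$chi) &
    (abs(abs(out$chi) - 90) < 5)
  m <- match(paste(out$chain, out$resno, out$insert),
             paste(ps$chain, ps$resno, ps$insert))
  out$phase <- ps$phase[m]
  out$amplitude <- ps$amplitude[m]
  out$pucker <- ps$pucker[m]
  out$pucker_ambiguous <- ps$ambiguous[m]
  out
}
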