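# Rigid-body superposition (Kabsch), RMSD with defined atom selections, and
# per-base rotation between conformers.

#' Optimal rigid-body superposition of two structures
#'
#' Pairs atoms across the two structures by (chain, residue number,
#' insertion code, atom name), optionally after a chain mapping, then finds
#' the least-squares optimal proper rotation (Kabsch). Reflections are never
#' applied: a mirror-image pair superposes with a visibly larger RMSD rather
#' than silently inverting. Waters, metal ions and hydrogens are excluded.
#'
#' @param s_a,s_b `StructureModel`s (moving and reference).
#' @param selection_a,selection_b optional atom selections.
#' @param chain_map optional named character vector mapping chains of `s_a`
#'   to chains of `s_b` (names = chains in `s_a`).
#' @return object of class `Superposition`: rotation `R` (3x3, det +1),
#'   translation `t`, `rmsd`, `n_atoms`, the atom `mapping`, and a count of
#'   unmatched atoms.
#' @export
superpose <- function(s_a, s_b, selection_a = NULL, selection_b = NULL,
                      chain_map = NULL) {
  stopifnot(inherits(s_a, "StructureModel"), inherits(s_b, "StructureModel"))
  ia <- resolve_selection(s_a, selection_a)
  ib <- resolve_selection(s_b, selection_b)
  aa <- s_a$atoms[ia, , drop = FALSE]
  ab <- s_b$atoms[ib, , drop = FALSE]
  drop <- function(at) at[!(at$kind %in% c("water", "metal_ion")) &
                            toupper(at$elesy) != "H", , drop = FALSE]
  aa <- drop(aa); ab <- drop(ab)
  cha <- aa$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[cha]
    cha <- ifelse(is.na(mapped), cha, mapped)
  }
  ka <- paste(cha, aa$resno, aa$insert, aa$elety, sep = "|")
  kb <- paste(ab$chain, ab$resno, ab$insert, ab$elety, sep = "|")
  common <- intersect(ka, kb)
  n_unmatched <- (nrow(aa) - length(common)) + (nrow(ab) - length(common))
  if (length(common) < 3) stop("fewer than 3 paired atoms; check selections/chain_map")
  P <- coords(aa[match(common, ka), , drop = FALSE])
  Q <- coords(ab[match(common, kb), , drop = FALSE])
  kk <- kabsch(P, Q)
  structure(list(R = kk$R, t = kk$t, rmsd = kk$rmsd,
                 n_atoms = length(common), mapping = common,
                 n_unmatched = n_unmatched), class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d atoms (%d unmatched)\n",
              x$rmsd, x$n_atoms, x$n_unmatched))
  invisible(x)
}

#' RMSD between two paired coordinate sets after optimal superposition
#'
#' @param P,Q n x 3 coordinate matrices, already paired row-wise.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(P, Q) kabsch(P, Q)$rmsd

#' Apply a superposition (or any rigid transform) to a structure
#'
#' @param s a `StructureModel`.
#' @param sp a `Superposition` (or a list with `R` and `t`).
#' @return the transformed `StructureModel`.
#' @export
transform_structure <- function(s, sp) {
  stopifnot(inherits(s, "StructureModel"))
  X <- coords(s$atoms) %*% sp$R
  X <- sweep(X, 2, sp$t, "+")
  s$atoms$x <- X[, 1]; s$atoms$y <- X[, 2]; s$atoms$z <- X[, 3]
  s
}

#' Rotation of a base between two conformers
#'
#' After a context superposition has aligned everything except the residue of
#' interest (pass it as `context`, or `NULL` if the structures are already in
#' a common frame), the base rotation is the angle of the optimal proper
#' rotation mapping the base ring atoms of conformer A onto conformer B about
#' their common centroid, in \[0, 180\] degrees.
#'
#' @param s_a,s_b `StructureModel`s containing the two conformers.
#' @param chain,resno identify the residue in both structures.
#' @param context optional `Superposition` applied to `s_a` first.
#' @param chain_b,resno_b identifiers in `s_b` if different.
#' @return rotation angle in degrees.
#' @export
base_rotation <- function(s_a, s_b, chain, resno, context = NULL,
                          chain_b = chain, resno_b = resno) {
  stopifnot(inherits(s_a, "StructureModel"), inherits(s_b, "StructureModel"))
  if (!is.null(context)) s_a <- transform_structure(s_a, context)
  ra <- s_a$atoms[select_atoms(s_a, chain = chain, resno = resno), , drop = FALSE]
  rb <- s_b$atoms[select_atoms(s_b, chain = chain_b, resno = resno_b), , drop = FALSE]
  if (!nrow(ra) || !nrow(rb)) stop("residue not found in one of the structures")
  ring <- intersect(intersect(base_ring_atoms(ra$resid[1]), ra$elety), rb$elety)
  if (length(ring) < 4) stop("fewer than 4 shared base ring atoms")
  P <- coords(ra[match(ring, ra$elety), , drop = FALSE])
  Q <- coords(rb[match(ring, rb$elety), , drop = FALSE])
  kk <- kabsch(P, Q)
  rotation_angle(kk$R)
}
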