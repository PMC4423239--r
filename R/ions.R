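# Metal-ion coordination spheres and ion-identity scoring against canonical
# metal-oxygen distance statistics.

#' Canonical metal-ligand distance statistics
#'
#' Mean and standard deviation of metal-oxygen coordination distances
#' (Angstrom) with plausible coordination-number ranges, from standard
#' crystallographic surveys: Mg 2.08 +/- 0.06 (CN 5-6), Ca 2.43 +/- 0.11
#' (CN 6-8), K 2.81 +/- 0.10 (CN 6-9), Na 2.38 +/- 0.10 (CN 5-6). Na is
#' included deliberately: Ca and Na distances overlap strongly, and the
#' distance-only classifier must report that ambiguity honestly (resolving
#' it requires anomalous-scattering evidence, which is out of scope here).
#'
#' @return data.frame with species, mu, sigma, cn_min, cn_max.
#' @export
species_table <- function() {
  data.frame(
    species = c("Mg", "Ca", "K", "Na"),
    mu = c(2.08, 2.43, 2.81, 2.38),
    sigma = c(0.06, 0.11, 0.10, 0.10),
    cn_min = c(5L, 6L, 6L, 5L),
    cn_max = c(6L, 8L, 9L, 6L),
    stringsAsFactors = FALSE)
}

ligand_class <- function(atoms, i) {
  kind <- atoms$kind[i]
  el <- toupper(atoms$elesy[i])
  ety <- atoms$elety[i]
  if (kind == "water") return("water")
  if (kind %in% c("ribonucleotide", "deoxyribonucleotide")) {
    if (ety %in% c("OP1", "OP2", "OP3", "O5'", "O3'")) return("phosphate_O")
    if (el == "O") return("base_O")
    return("base_N")
  }
  if (kind == "protein") {
    if (el == "O") return("protein_O")
    return("protein_N")
  }
  if (el == "O") return("other_O") else return("other_N")
}

#' Coordination sphere of a metal ion
#'
#' Lists every oxygen/nitrogen atom within `cutoff` of the ion, classified by
#' ligand type (water, phosphate oxygen, base oxygen/nitrogen, protein
#' oxygen/nitrogen), sorted by distance, with coordination number and
#' distance statistics.
#'
#' @param s a `StructureModel`.
#' @param ion_index atom row index of the metal ion (see [survey_ions()]).
#' @param cutoff coordination cutoff in Angstrom, in \[2.0, 3.5\];
#'   default 3.0.
#' @return object of class `IonSite`: ion identity, ligand table,
#'   coordination number, mean/sd distance.
#' @export
coordination_sphere <- function(s, ion_index, cutoff = 3.0) {
  stopifnot(inherits(s, "StructureModel"))
  if (cutoff < 2.0 || cutoff > 3.5) {
    stop("coordination cutoff must lie in [2.0, 3.5] Angstrom")
  }
  a <- s$atoms
  if (a$kind[ion_index] != "metal_ion") {
    stop("atom ", ion_index, " is not typed metal_ion")
  }
  p <- c(a$x[ion_index], a$y[ion_index], a$z[ion_index])
  el <- toupper(a$elesy)
  cand <- which(el %in% c("O", "N") & seq_len(nrow(a)) != ion_index)
  d <- sqrt((a$x[cand] - p[1])^2 + (a$y[cand] - p[2])^2 + (a$z[cand] - p[3])^2)
  keep <- d <= cutoff
  cand <- cand[keep]; d <- d[keep]
  ord <- order(d)
  cand <- cand[ord]; d <- d[ord]
  if (!length(cand)) {
    warning("ion at atom ", ion_index, " has no ligand within ", cutoff, " A")
  }
  ligands <- data.frame(
    index = cand, elety = a$elety[cand], resid = a$resid[cand],
    chain = a$chain[cand], resno = a$resno[cand], distance = d,
    class = vapply(cand, function(i) ligand_class(a, i), character(1)),
    stringsAsFactors = FALSE)
  structure(list(
    ion_index = ion_index, ion_name = a$resid[ion_index],
    ion_chain = a$chain[ion_index], ion_resno = a$resno[ion_index],
    ligands = ligands, coordination_number = nrow(ligands),
    mean_distance = if (nrow(ligands)) mean(d) else NA_real_,
    sd_distance = if (nrow(ligands) > 1) stats::sd(d) else 0,
    cutoff = cutoff), class = "IonSite")
}

#' @export
print.IonSite <- function(x, ...) {
  cat("IonSite", x$ion_name, paste0("(chain ", x$ion_chain, ", ", x$ion_resno, ")"),
      "CN", x$coordination_number,
      sprintf("mean %.2f +/- %.2f A\n", x$mean_distance, x$sd_distance))
  print(table(x$ligands$class))
  invisible(x)
}

#' Score ion identity from coordination distances
#'
#' For each candidate species the score is the absolute z-score
#' `|mean_distance - mu| / sigma` (lower is better), with a flag marking
#' coordination-number compatibility. The assignment is the lowest-scoring
#' CN-compatible species, or `"ambiguous"` when the two best scores differ
#' by less than `margin`.
#'
#' @param site an `IonSite`.
#' @param table species statistics, default [species_table()].
#' @param margin minimum score separation for an unambiguous call (default 1).
#' @return list with `scores` (data.frame) and `assigned_species`.
#' @export
score_ion_identity <- function(site, table = species_table(), margin = 1.0) {
  stopifnot(inherits(site, "IonSite"))
  if (site$coordination_number < 3) {
    stop("ion-identity scoring requires at least 3 ligands")
  }
  sc <- table
  sc$score <- abs(site$mean_distance - sc$mu) / sc$sigma
  sc$cn_compatible <- site$coordination_number >= sc$cn_min &
    site$coordination_number <= sc$cn_max
  ord <- order(sc$score)
  sc <- sc[ord, , drop = FALSE]
  cand <- sc[sc$cn_compatible, , drop = FALSE]
  pool <- if (nrow(cand)) cand else sc
  # the best CN-compatible species is the assignment candidate, but the
  # ambiguity margin is judged against every species: CN alone must not
  # manufacture certainty between overlapping distance distributions
  # (e.g. Ca versus Na)
  ambiguous <- nrow(sc) >= 2 && (sc$score[2] - sc$score[1]) < margin &&
    sc$species[1] != sc$species[2]
  assigned <- if (ambiguous) "ambiguous" else pool$species[1]
  rownames(sc) <- NULL
  list(scores = sc, assigned_species = assigned,
       best_species = pool$species[1],
       runner_up = sc$species[2])
}

#' Survey all metal ions of a structure
#'
#' Builds the coordination sphere of every metal ion, scores its identity,
#' attributes it to a polymer chain when at least two of its ligands belong
#' to that chain, and reports the colinearity of every ion triple attributed
#' to the same chain (maximum deviation from the best-fit line).
#'
#' @param s a `StructureModel`.
#' @param cutoff coordination cutoff (Angstrom).
#' @return list with `sites` (list of `IonSite`), `table` (one row per ion:
#'   CN, mean/sd distance, scores, assignment, attributed chain) and
#'   `colinearity` (per chain with >= 3 ions: best triple deviation).
#' @export
survey_ions <- function(s, cutoff = 3.0) {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  ions <- which(a$kind == "metal_ion")
  sites <- lapply(ions, function(i) coordination_sphere(s, i, cutoff))
  rows <- list()
  for (k in seq_along(sites)) {
    site <- sites[[k]]
    att <- NA_character_
    if (site$coordination_number) {
      # a ligand's chain counts only if it is a polymer atom
      pol <- site$ligands[!(site$ligands$class %in% c("water", "other_O", "other_N")), ]
      tb <- table(pol$chain)
      tb <- tb[tb >= 2]
      if (length(tb)) att <- names(tb)[which.max(tb)]
    }
    sc <- if (site$coordination_number >= 3) score_ion_identity(site)
          else list(assigned_species = NA_character_, best_species = NA_character_)
    rows[[k]] <- data.frame(
      ion_index = site$ion_index, ion_name = site$ion_name,
      chain = site$ion_chain, resno = site$ion_resno,
      coordination_number = site$coordination_number,
      mean_distance = site$mean_distance, sd_distance = site$sd_distance,
      assigned_species = sc$assigned_species,
      best_species = sc$best_species,
      attributed_chain = att, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  # colinearity of ion triples within each attributed chain
  colin <- list()
  if (nrow(tab)) {
    for (chn in unique(stats::na.omit(tab$attributed_chain))) {
      ii <- tab$ion_index[!is.na(tab$attributed_chain) & tab$attributed_chain == chn]
      if (length(ii) < 3) next
      combos <- utils::combn(ii, 3)
      best <- Inf; best_triple <- NULL
      for (cc in seq_len(ncol(combos))) {
        X <- coords(a[combos[, cc], , drop = FALSE])
        dev <- line_deviation(X)
        if (dev < best) { best <- dev; best_triple <- combos[, cc] }
      }
      colin[[chn]] <- list(ions = best_triple, max_deviation = best)
    }
  }
  list(sites = sites, table = tab, colinearity = colin)
}

# max point deviation from the best-fit (total least squares) line
line_deviation <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  dir <- svd(Xc)$v[, 1]
  perp <- Xc - outer(as.vector(Xc %*% dir), dir)
  max(sqrt(rowSums(perp^2)))
}
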