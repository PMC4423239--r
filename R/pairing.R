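# Hydrogen-bond detection, base-pair classification, base stacking,
# G-tetrad detection and G-quadruplex assembly.
#
# Heavy-atom criteria throughout: crystal structures at typical resolution
# carry no hydrogens, so donors and acceptors are identified by atom-name
# tables and proximity.

.BASE_DONORS <- list(
  A = "N6", G = c("N1", "N2"), C = "N4", U = "N3", T = "N3", I = "N1")
.BASE_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
  C = c("O2", "N3"), U = c("O2", "O4"), T = c("O2", "O4"),
  I = c("O6", "N3", "N7"))
.PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

.PROT_DONORS <- c("N", "OG", "OG1", "OH", "SG", "NZ", "NE", "NH1", "NH2",
                  "ND1", "NE2", "ND2", "NE1", "OW")
.PROT_ACCEPTORS <- c("O", "OXT", "OG", "OG1", "OH", "OD1", "OD2", "OE1",
                     "OE2", "ND1", "NE2", "SD")

base_letter <- function(resid) sub("^D", "", toupper(resid))

base_ring_atoms <- function(resid) {
  if (is_purine(resid)) .PURINE_RING else .PYRIMIDINE_RING
}

# donor/acceptor capability flags per atom row
hbond_roles <- function(atoms) {
  n <- nrow(atoms)
  donor <- logical(n)
  acceptor <- logical(n)
  el <- toupper(atoms$elesy)
  nuc <- atoms$kind %in% c("ribonucleotide", "deoxyribonucleotide")
  bl <- base_letter(atoms$resid)
  for (b in names(.BASE_DONORS)) {
    donor[nuc & bl == b & atoms$elety %in% .BASE_DONORS[[b]]] <- TRUE
    acceptor[nuc & bl == b & atoms$elety %in% .BASE_ACCEPTORS[[b]]] <- TRUE
  }
  # sugar-phosphate moiety
  donor[nuc & atoms$elety == "O2'"] <- TRUE
  acceptor[nuc & atoms$elety %in% c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2", "OP3")] <- TRUE
  prot <- atoms$kind == "protein"
  donor[prot & atoms$elety %in% .PROT_DONORS] <- TRUE
  acceptor[prot & atoms$elety %in% .PROT_ACCEPTORS] <- TRUE
  wat <- atoms$kind == "water"
  donor[wat & el == "O"] <- TRUE
  acceptor[wat & el == "O"] <- TRUE
  # permissive fallback for residues typed 'other'
  oth <- atoms$kind == "other" & el %in% c("N", "O")
  donor[oth] <- TRUE
  acceptor[oth] <- TRUE
  list(donor = donor, acceptor = acceptor)
}

# pairs covalently linked across consecutive residues (1-2/1-3 through the
# backbone linkage) that must never count as hydrogen bonds
is_linkage_pair <- function(a, i, j) {
  same_chain <- a$chain[i] == a$chain[j]
  dr <- a$resno[j] - a$resno[i]
  ei <- a$elety[i]; ej <- a$elety[j]
  (same_chain & dr == 1 &
     ((ei %in% c("O3'", "O") & ej %in% c("P", "OP1", "OP2", "O5'", "N")) |
        (ei == "C" & ej == "N"))) |
  (same_chain & dr == -1 &
     ((ej %in% c("O3'", "O") & ei %in% c("P", "OP1", "OP2", "O5'", "N")) |
        (ej == "C" & ei == "N")))
}

#' Detect hydrogen bonds between heavy atoms
#'
#' All donor-acceptor heavy-atom pairs within `cutoff`, excluding pairs
#' within the same residue and pairs covalently linked across the backbone.
#' The result is symmetric in atom order (each physical contact reported
#' once).
#'
#' @param s a `StructureModel`.
#' @param cutoff donor-acceptor distance cutoff in Angstrom, in \[2.4, 4.0\].
#' @param selection optional atom selection (indices, logical mask, or
#'   filter list for [select_atoms()]); default all atoms.
#' @return data.frame: indices, atom names, residue identifiers, distance.
#' @export
detect_hbonds <- function(s, cutoff = 3.5, selection = NULL) {
  stopifnot(inherits(s, "StructureModel"))
  if (cutoff < 2.4 || cutoff > 4.0) {
    stop("hydrogen-bond cutoff must lie in [2.4, 4.0] Angstrom")
  }
  idx <- resolve_selection(s, selection)
  if (!length(idx)) return(empty_hbonds())
  a <- s$atoms
  roles <- hbond_roles(a)
  cand <- idx[roles$donor[idx] | roles$acceptor[idx]]
  if (length(cand) < 2) return(empty_hbonds())
  X <- coords(a[cand, , drop = FALSE])
  d <- as.matrix(stats::dist(X))
  key <- res_key(a)[cand]
  out <- list()
  nn <- length(cand)
  for (p in seq_len(nn - 1)) {
    for (q in (p + 1):nn) {
      if (d[p, q] > cutoff || d[p, q] < 2.2) next
      if (key[p] == key[q]) next
      i <- cand[p]; j <- cand[q]
      ok <- (roles$donor[i] && roles$acceptor[j]) ||
        (roles$donor[j] && roles$acceptor[i])
      if (!ok) next
      if (is_linkage_pair(a, i, j)) next
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j, atom_i = a$elety[i], atom_j = a$elety[j],
        res_i = key[p], res_j = key[q], distance = d[p, q],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hbonds())
  do.call(rbind, out)
}

empty_hbonds <- function() {
  data.frame(i = integer(0), j = integer(0), atom_i = character(0),
             atom_j = character(0), res_i = character(0),
             res_j = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

# base ring plane of one residue: list(center, normal) or NULL
base_plane <- function(res_atoms) {
  ring <- base_ring_atoms(res_atoms$resid[1])
  have <- intersect(ring, res_atoms$elety)
  if (length(have) < 4) return(NULL)
  X <- coords(res_atoms[match(have, res_atoms$elety), , drop = FALSE])
  fit_plane(X)
}

# canonical Watson-Crick hydrogen-bond atom patterns, keyed by sorted bases
.WC_PATTERNS <- list(
  "C|G" = list(c("G", "O6", "C", "N4"), c("G", "N1", "C", "N3"),
               c("G", "N2", "C", "O2")),
  "A|U" = list(c("A", "N6", "U", "O4"), c("A", "N1", "U", "N3")),
  "A|T" = list(c("A", "N6", "T", "O4"), c("A", "N1", "T", "N3")))

#' Detect and classify base pairs
#'
#' A base pair requires at least two inter-base hydrogen bonds between
#' base-edge donor/acceptor atoms, near-coplanar base rings (normal angle
#' <= `coplanarity`) and a small out-of-plane offset (which excludes stacked
#' bases). Pairs whose hydrogen-bond atom pattern matches the canonical G-C
#' or A-U(T) arrangement are classed `watson_crick`; everything else
#' (including G-U wobble) is `non_watson_crick`.
#'
#' @param s a `StructureModel`.
#' @param selection optional atom selection restricting the residues
#'   considered.
#' @param cutoff hydrogen-bond heavy-atom cutoff (Angstrom).
#' @param coplanarity maximum angle between base normals (degrees).
#' @return data.frame: residue identifiers, bases, number of hydrogen bonds,
#'   pair class.
#' @export
detect_base_pairs <- function(s, selection = NULL, cutoff = 3.5,
                              coplanarity = 30) {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  key <- res_key(a)
  idx <- resolve_selection(s, selection)
  rt <- residue_table(s)
  rt <- rt[rt$kind %in% c("ribonucleotide", "deoxyribonucleotide") &
             rt$key %in% unique(key[idx]), , drop = FALSE]
  n <- nrow(rt)
  if (n < 2) return(empty_base_pairs())
  res_atoms <- lapply(rt$key, function(k) a[key == k, , drop = FALSE])
  planes <- lapply(res_atoms, base_plane)
  # base-edge hydrogen bond atoms only
  out <- list()
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      if (is.null(planes[[p]]) || is.null(planes[[q]])) next
      ctr_d <- vnorm(planes[[p]]$center - planes[[q]]$center)
      if (ctr_d > 12) next
      hb <- base_edge_hbonds(res_atoms[[p]], res_atoms[[q]], cutoff)
      if (nrow(hb) < 2) next
      if (normal_angle(planes[[p]]$normal, planes[[q]]$normal) > coplanarity) next
      nmean <- unitv(align_normals(planes[[p]]$normal, planes[[q]]$normal))
      offset <- abs(sum(nmean * (planes[[q]]$center - planes[[p]]$center)))
      if (offset > 2.0) next
      cls <- classify_pair(rt$resid[p], rt$resid[q], hb)
      out[[length(out) + 1]] <- data.frame(
        res_a = rt$key[p], res_b = rt$key[q],
        chain_a = rt$chain[p], resno_a = rt$resno[p], base_a = rt$resid[p],
        chain_b = rt$chain[q], resno_b = rt$resno[q], base_b = rt$resid[q],
        n_hbonds = nrow(hb), pair_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_base_pairs())
  do.call(rbind, out)
}

empty_base_pairs <- function() {
  data.frame(res_a = character(0), res_b = character(0),
             chain_a = character(0), resno_a = integer(0), base_a = character(0),
             chain_b = character(0), resno_b = integer(0), base_b = character(0),
             n_hbonds = integer(0), pair_class = character(0),
             stringsAsFactors = FALSE)
}

align_normals <- function(n1, n2) {
  if (sum(n1 * n2) < 0) n2 <- -n2
  n1 + n2
}

base_edge_hbonds <- function(ra, rb, cutoff) {
  la <- base_letter(ra$resid[1]); lb <- base_letter(rb$resid[1])
  da <- intersect(ra$elety, .BASE_DONORS[[la]])
  aa <- intersect(ra$elety, .BASE_ACCEPTORS[[la]])
  db <- intersect(rb$elety, .BASE_DONORS[[lb]])
  ab <- intersect(rb$elety, .BASE_ACCEPTORS[[lb]])
  res <- list()
  for (x in union(da, aa)) {
    px <- atom_xyz(ra, x)
    for (y in union(db, ab)) {
      ok <- (x %in% da && y %in% ab) || (y %in% db && x %in% aa)
      if (!ok) next
      py <- atom_xyz(rb, y)
      dd <- vnorm(px - py)
      if (dd <= cutoff && dd >= 2.2) {
        res[[length(res) + 1]] <- data.frame(atom_a = x, atom_b = y,
                                             distance = dd,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(atom_a = character(0), atom_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

classify_pair <- function(resid_a, resid_b, hb) {
  la <- base_letter(resid_a); lb <- base_letter(resid_b)
  keyp <- paste(sort(c(la, lb)), collapse = "|")
  pat <- .WC_PATTERNS[[keyp]]
  if (is.null(pat)) return("non_watson_crick")
  hits <- vapply(pat, function(pp) {
    # pp = (base1, atom1, base2, atom2); match either orientation
    any((la == pp[1] & hb$atom_a == pp[2] & lb == pp[3] & hb$atom_b == pp[4]) |
          (lb == pp[1] & hb$atom_b == pp[2] & la == pp[3] & hb$atom_a == pp[4]))
  }, logical(1))
  need <- if (keyp == "C|G") 2 else 2
  if (sum(hits) >= need) "watson_crick" else "non_watson_crick"
}

#' Detect stacked bases
#'
#' Base pairs with ring-centroid distance <= `dist_cutoff` and base-normal
#' angle <= `angle_cutoff` are reported as stacked.
#'
#' @param s a `StructureModel`.
#' @param selection optional atom selection.
#' @param dist_cutoff centroid distance cutoff (Angstrom, default 4.5).
#' @param angle_cutoff normal angle cutoff (degrees, default 30).
#' @return data.frame of stacked residue pairs with centroid distance.
#' @export
detect_stacking <- function(s, selection = NULL, dist_cutoff = 4.5,
                            angle_cutoff = 30) {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  key <- res_key(a)
  idx <- resolve_selection(s, selection)
  rt <- residue_table(s)
  rt <- rt[rt$kind %in% c("ribonucleotide", "deoxyribonucleotide") &
             rt$key %in% unique(key[idx]), , drop = FALSE]
  n <- nrow(rt)
  if (n < 2) return(data.frame())
  planes <- lapply(rt$key, function(k) base_plane(a[key == k, , drop = FALSE]))
  out <- list()
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      if (is.null(planes[[p]]) || is.null(planes[[q]])) next
      dd <- vnorm(planes[[p]]$center - planes[[q]]$center)
      if (dd > dist_cutoff) next
      if (normal_angle(planes[[p]]$normal, planes[[q]]$normal) > angle_cutoff) next
      out[[length(out) + 1]] <- data.frame(
        res_a = rt$key[p], res_b = rt$key[q],
        chain_a = rt$chain[p], resno_a = rt$resno[p], base_a = rt$resid[p],
        chain_b = rt$chain[q], resno_b = rt$resno[q], base_b = rt$resid[q],
        centroid_distance = dd, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Detect G-tetrads
#'
#' Builds the directed Hoogsteen graph over guanines (edge i -> j when
#' N1(i)...O6(j) <= `cutoff` and N2(i)...N7(j) <= `cutoff`) and reports
#' directed 4-cycles as tetrads. When cycles share guanines, tetrads are
#' chosen greedily by smallest mean hydrogen-bond distance so that each
#' guanine belongs to at most one tetrad.
#'
#' @param s a `StructureModel`.
#' @param selection optional atom selection.
#' @param cutoff Hoogsteen hydrogen-bond cutoff (Angstrom, default 3.5).
#' @return list of tetrads; each has `residues` (cyclically ordered keys),
#'   `resnos`, `chains`, `center`, `normal`, `mean_hbond`.
#' @export
detect_tetrads <- function(s, selection = NULL, cutoff = 3.5) {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atoms
  key <- res_key(a)
  idx <- resolve_selection(s, selection)
  rt <- residue_table(s)
  rt <- rt[base_letter(rt$resid) %in% c("G", "I") &
             rt$kind %in% c("ribonucleotide", "deoxyribonucleotide") &
             rt$key %in% unique(key[idx]), , drop = FALSE]
  n <- nrow(rt)
  if (n < 4) return(list())
  res_atoms <- lapply(rt$key, function(k) a[key == k, , drop = FALSE])
  getp <- function(i, nm) atom_xyz(res_atoms[[i]], nm)
  # directed Hoogsteen edges
  edge_d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    n1 <- getp(i, "N1"); n2 <- getp(i, "N2")
    if (is.null(n1) || is.null(n2)) next
    for (j in seq_len(n)) {
      if (i == j) next
      o6 <- getp(j, "O6"); n7 <- getp(j, "N7")
      if (is.null(o6) || is.null(n7)) next
      d1 <- vnorm(n1 - o6); d2 <- vnorm(n2 - n7)
      if (d1 <= cutoff && d2 <= cutoff) edge_d[i, j] <- (d1 + d2) / 2
    }
  }
  adj <- !is.na(edge_d)
  # enumerate directed 4-cycles i -> j -> k -> l -> i (i the smallest index)
  cycles <- list()
  for (i in seq_len(n)) {
    js <- which(adj[i, ])
    for (j in js[js != i]) {
      ks <- which(adj[j, ])
      for (k in ks[!(ks %in% c(i, j))]) {
        ls <- which(adj[k, ])
        for (l in ls[!(ls %in% c(i, j, k))]) {
          if (!adj[l, i]) next
          if (i != min(c(i, j, k, l))) next
          md <- mean(c(edge_d[i, j], edge_d[j, k], edge_d[k, l], edge_d[l, i]))
          sig <- paste(sort(c(i, j, k, l)), collapse = "-")
          cycles[[length(cycles) + 1]] <- list(members = c(i, j, k, l),
                                               mean_hbond = md, sig = sig)
        }
      }
    }
  }
  if (!length(cycles)) return(list())
  # dedupe cycles over the same set (keep best direction), then greedy
  # disjoint selection by mean hydrogen-bond distance
  md <- vapply(cycles, function(cc) cc$mean_hbond, numeric(1))
  cycles <- cycles[order(md)]
  used <- integer(0)
  tetrads <- list()
  for (cc in cycles) {
    if (any(cc$members %in% used)) next
    used <- c(used, cc$members)
    mem <- cc$members
    ring_xyz <- do.call(rbind, lapply(mem, function(i) {
      ring <- intersect(.PURINE_RING, res_atoms[[i]]$elety)
      coords(res_atoms[[i]][match(ring, res_atoms[[i]]$elety), , drop = FALSE])
    }))
    pl <- fit_plane(ring_xyz)
    tetrads[[length(tetrads) + 1]] <- list(
      residues = rt$key[mem],
      resnos = rt$resno[mem],
      chains = rt$chain[mem],
      bases = rt$resid[mem],
      center = pl$center,
      normal = pl$normal,
      mean_hbond = cc$mean_hbond)
  }
  tetrads
}

#' Assemble a G-quadruplex from detected tetrads
#'
#' Tetrads are stacked when their mean-plane centroids are separated by
#' 2.8-4.5 Angstrom and their normals agree within 30 degrees. The twist
#' between consecutive tetrads is the mean rotation about the stacking axis
#' that maps the C1' atoms of one tetrad onto their stacked counterparts,
#' folded into \[0, 90\] degrees. Strand orientation is taken from the
#' consensus of glycosidic (C1' -> N9) circulation senses: all alike gives
#' `parallel`, a 2+2 split `antiparallel`, a 3+1 split `mixed`.
#'
#' @param s the `StructureModel` the tetrads came from.
#' @param tetrads list of tetrads from [detect_tetrads()].
#' @param stack_window centroid separation window (Angstrom).
#' @param angle_cutoff maximum angle between tetrad normals (degrees).
#' @return list with `tetrads` (stacked order), `twist_angles`,
#'   `strand_orientation`, `channel_ions`, `loops`; or an empty quadruplex
#'   (`n_tetrads = 0`) if no stackable pair exists.
#' @export
assemble_quadruplex <- function(s, tetrads, stack_window = c(2.8, 4.5),
                                angle_cutoff = 30) {
  stopifnot(inherits(s, "StructureModel"))
  empty <- list(n_tetrads = 0L, tetrads = list(), twist_angles = numeric(0),
                strand_orientation = NA_character_, channel_ions = data.frame(),
                loops = list())
  if (length(tetrads) < 1) return(empty)
  if (length(tetrads) == 1) stop("assembling a quadruplex requires >= 2 tetrads")
  # order along the consensus normal
  nref <- tetrads[[1]]$normal
  proj <- vapply(tetrads, function(tt) sum(tt$center * nref), numeric(1))
  tetrads <- tetrads[order(proj)]
  # verify consecutive stacking
  stacked <- list(tetrads[[1]])
  for (i in 2:length(tetrads)) {
    t1 <- stacked[[length(stacked)]]
    t2 <- tetrads[[i]]
    sep <- vnorm(t2$center - t1$center)
    if (sep >= stack_window[1] && sep <= stack_window[2] &&
        normal_angle(t1$normal, t2$normal) <= angle_cutoff) {
      stacked[[length(stacked) + 1]] <- t2
    }
  }
  if (length(stacked) < 2) return(empty)
  a <- s$atoms
  key <- res_key(a)
  c1p <- function(reskey) {
    ra <- a[key == reskey, , drop = FALSE]
    atom_xyz(ra, "C1'")
  }
  n9 <- function(reskey) {
    ra <- a[key == reskey, , drop = FALSE]
    atom_xyz(ra, "N9")
  }
  twists <- numeric(0)
  for (i in seq_len(length(stacked) - 1)) {
    t1 <- stacked[[i]]; t2 <- stacked[[i + 1]]
    axis <- unitv(align_normals(t1$normal, t2$normal))
    origin <- (t1$center + t2$center) / 2
    p1 <- do.call(rbind, lapply(t1$residues, c1p))
    p2 <- do.call(rbind, lapply(t2$residues, c1p))
    projp <- function(P) {
      Pc <- sweep(P, 2, origin)
      Pc - outer(as.vector(Pc %*% axis), axis)
    }
    q1 <- projp(p1); q2 <- projp(p2)
    # counterpart = nearest projected C1'
    angs <- numeric(0)
    for (g in seq_len(nrow(q1))) {
      d <- sqrt(rowSums(sweep(q2, 2, q1[g, ])^2))
      m <- which.min(d)
      u <- unitv(q1[g, ]); v <- unitv(q2[m, ])
      ang <- abs(deg(atan2(sum(vcross(u, v) * axis), sum(u * v))))
      if (ang > 90) ang <- 180 - ang   # fold: twist is defined on [0, 90]
      angs <- c(angs, ang)
    }
    twists <- c(twists, mean(angs))
  }
  # strand orientation from glycosidic circulation sense
  senses <- integer(0)
  for (tt in stacked) {
    for (g in seq_along(tt$residues)) {
      c1 <- c1p(tt$residues[g]); n9g <- n9(tt$residues[g])
      if (is.null(c1) || is.null(n9g)) next
      senses <- c(senses,
                  sign(sum(vcross(c1 - tt$center, n9g - c1) * tt$normal)))
    }
  }
  tb <- table(factor(senses, levels = c(-1, 1)))
  orientation <- if (min(tb) == 0) "parallel"
    else if (abs(tb[[1]] - tb[[2]]) == 0) "antiparallel" else "mixed"
  # channel ions: metals close to consecutive tetrad centroids
  ions <- which(a$kind == "metal_ion")
  ch <- ions[vapply(ions, function(ii) {
    p <- c(a$x[ii], a$y[ii], a$z[ii])
    all(vapply(stacked, function(tt) vnorm(p - tt$center) <= 4.5, logical(1)))
  }, logical(1))]
  channel <- a[ch, c("eleno", "elety", "resid", "chain", "resno"), drop = FALSE]
  # loops: gaps in residue numbering between quadruplex guanines per chain
  loops <- list()
  gdf <- do.call(rbind, lapply(stacked, function(tt)
    data.frame(chain = tt$chains, resno = tt$resnos, stringsAsFactors = FALSE)))
  for (chn in unique(gdf$chain)) {
    rs <- sort(gdf$resno[gdf$chain == chn])
    gaps <- which(diff(rs) > 1)
    for (g in gaps) {
      loops[[length(loops) + 1]] <- list(chain = chn,
                                         from = rs[g] + 1, to = rs[g + 1] - 1)
    }
  }
  list(n_tetrads = length(stacked), tetrads = stacked,
       twist_angles = twists, strand_orientation = orientation,
       channel_ions = channel, loops = loops)
}
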