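# Structure model: a flat atom table (one row per atom) carrying residue
# typing and sugar chirality, read from PDB/mmCIF via bio3d.

.PROTEIN_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")
.RIBO_RES  <- c("A", "C", "G", "U", "I")
.DEOXY_RES <- c("DA", "DC", "DG", "DT", "DU", "DI")
.METAL_RES <- c("CA", "MG", "K", "NA", "ZN", "MN", "FE", "SR", "BA", "RB",
                "CS", "LI", "NI", "CU", "CO", "CD", "OS")
.WATER_RES <- c("HOH", "WAT", "DOD", "H2O")
.SUGAR_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")

# residue key used throughout: chain | author number | insertion code
res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")

#' Build a StructureModel from an atom table
#'
#' Users normally obtain a `StructureModel` from [read_structure()] or from
#' the synthetic generators ([make_duplex()], [make_tetrad_stack()], ...).
#' This constructor validates a raw atom `data.frame` (bio3d-style columns:
#' `elety`, `resid`, `chain`, `resno`, `insert`, `alt`, `x`, `y`, `z`, `o`,
#' `b`, `elesy`), assigns residue kinds and sugar chirality, and tags the
#' object.
#'
#' @param atoms data.frame of atoms.
#' @param identifier free-text identifier.
#' @param source_format "PDB", "mmCIF" or "generated".
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, identifier = "", source_format = "generated") {
  needed <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$o[is.na(atoms$o)] <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$b[is.na(atoms$b)] <- 0
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) || all(atoms$elesy == "")) {
    atoms$elesy <- guess_element(atoms$elety)
  }
  blank <- is.na(atoms$elesy) | atoms$elesy == ""
  atoms$elesy[blank] <- guess_element(atoms$elety[blank])
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$o < 0 | atoms$o > 1)) stop("occupancies must lie in [0, 1]")
  atoms$kind <- classify_residue_kinds(atoms)
  atoms$chirality <- assign_chirality(atoms)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier,
                 source_format = source_format),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  keys <- unique(res_key(a))
  cat("StructureModel", if (nzchar(x$identifier)) paste0("'", x$identifier, "'"),
      "(", x$source_format, ")\n")
  cat(" ", nrow(a), "atoms,", length(keys), "residues,",
      length(unique(a$chain)), "chains\n")
  cat("  residue kinds:",
      paste(names(table(residue_table(x)$kind)),
            table(residue_table(x)$kind), collapse = ", "), "\n")
  invisible(x)
}

# crude element from PDB atom name (digits stripped, first letter; two-letter
# metals handled by exact residue-name match upstream)
guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- nm %in% c("CA", "MG", "NA", "CL", "ZN", "MN", "FE", "BR", "RB", "CS",
                   "SR", "BA", "LI", "NI", "CU", "CO", "CD", "OS", "SE")
  out <- substr(nm, 1, 1)
  # only trust two-letter symbols when the full atom name is the symbol
  out[two & nchar(gsub("[^A-Za-z0-9']", "", elety)) == 2] <- nm[two & nchar(gsub("[^A-Za-z0-9']", "", elety)) == 2]
  out
}

# Residue-kind typing. Precedence: residue-name lookup for standard names,
# then atom-content heuristics (sugar ring present; O2' distinguishes ribo
# from deoxy; protein backbone atoms). Unknown residues are typed "other"
# with a warning.
classify_residue_kinds <- function(atoms) {
  key <- res_key(atoms)
  kinds <- character(nrow(atoms))
  unknown <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- toupper(atoms$resid[idx][1])
    anames <- atoms$elety[idx]
    kind <-
      if (rn %in% .WATER_RES) "water"
      else if (rn %in% .METAL_RES && length(idx) == 1) "metal_ion"
      else if (rn %in% .PROTEIN_RES) "protein"
      else if (rn %in% .DEOXY_RES) "deoxyribonucleotide"
      else if (rn %in% .RIBO_RES) {
        # name says ribo, but trust atom content for nonstandard deposits
        if (!("O2'" %in% anames) && all(.SUGAR_RING %in% anames))
          "deoxyribonucleotide" else "ribonucleotide"
      }
      else if (all(.SUGAR_RING %in% anames)) {
        if ("O2'" %in% anames) "ribonucleotide" else "deoxyribonucleotide"
      }
      else if (all(c("N", "CA", "C", "O") %in% anames)) "protein"
      else {
        unknown <- c(unknown, rn)
        "other"
      }
    kinds[idx] <- kind
  }
  if (length(unknown)) {
    warning("unknown residue name(s) typed 'other': ",
            paste(unique(unknown), collapse = ", "))
  }
  kinds
}

# Sugar chirality per atom row: "D", "L" or "not_applicable".
# Sign of the improper configuration at C4' (C3'-C4' x O4'-C4' . C5'-C4'):
# positive for natural D-sugars, negative for their mirror images.
assign_chirality <- function(atoms) {
  key <- res_key(atoms)
  out <- rep("not_applicable", nrow(atoms))
  nuc <- atoms$kind %in% c("ribonucleotide", "deoxyribonucleotide")
  for (k in unique(key[nuc])) {
    idx <- which(key == k)
    out[idx] <- chirality_of_residue(atoms[idx, , drop = FALSE])
  }
  out
}

chirality_of_residue <- function(res_atoms) {
  need <- c("C3'", "C4'", "O4'", "C5'")
  if (!all(need %in% res_atoms$elety)) {
    warning("residue ", res_atoms$resid[1], " ", res_atoms$resno[1],
            ": incomplete sugar, chirality not_applicable")
    return("not_applicable")
  }
  p <- function(n) {
    i <- match(n, res_atoms$elety)
    c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
  }
  v <- sum(vcross(p("C3'") - p("C4'"), p("O4'") - p("C4'")) * (p("C5'") - p("C4'")))
  if (v > 0) "D" else "L"
}

#' Detect sugar chirality of every nucleotide
#'
#' Computes the handedness of each nucleotide sugar from the improper
#' (out-of-plane) configuration at C4': natural sugars are D, their mirror
#' images L. Non-nucleotide residues and nucleotides with incomplete sugar
#' rings are reported `not_applicable` (the latter with a warning).
#'
#' @param s a `StructureModel`.
#' @return data.frame with chain, resno, insert, resid, chirality.
#' @export
detect_chirality <- function(s) {
  stopifnot(inherits(s, "StructureModel"))
  rt <- residue_table(s)
  rt[rt$kind %in% c("ribonucleotide", "deoxyribonucleotide"),
     c("chain", "resno", "insert", "resid", "chirality")]
}

# One row per residue.
residue_table <- function(s) {
  a <- s$atoms
  key <- res_key(a)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             kind = a$kind[first], chirality = a$chirality[first],
             stringsAsFactors = FALSE)
}

# named coordinate lookup within one residue's atom rows
atom_xyz <- function(res_atoms, name) {
  i <- match(name, res_atoms$elety)
  if (is.na(i)) return(NULL)
  c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Select atom indices of a structure
#'
#' @param s a `StructureModel`.
#' @param chain,resno,resid,elety,kind optional filters (vectors, OR within a
#'   filter, AND across filters).
#' @return integer vector of row indices into `s$atoms`.
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, kind = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(kind))  keep <- keep & a$kind %in% kind
  which(keep)
}

resolve_selection <- function(s, sel) {
  if (is.null(sel)) return(seq_len(nrow(s$atoms)))
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.logical(sel)) return(which(sel))
  if (is.list(sel)) return(do.call(select_atoms, c(list(s), sel)))
  stop("selection must be NULL, indices, a logical mask, or a filter list")
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses coordinates (gzip-transparent) into a `StructureModel`. Waters and
#' monoatomic metals are typed from residue names; nucleotides are typed ribo
#' versus deoxy from residue names and the presence or absence of the O2'
#' atom; anything unrecognized is kept and typed `other` with a warning.
#'
#' @param path file path (`.pdb`, `.cif`, optionally `.gz`).
#' @param format "auto" (from extension), "pdb" or "cif".
#' @param keep_altloc keep all alternate conformers. Default `FALSE`: for each
#'   (chain, residue, atom name) only the highest-occupancy conformer is kept,
#'   so downstream conformational calls are single-valued.
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_altloc = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  real <- path
  base <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    real <- tempfile(fileext = paste0(".", tools::file_ext(base)))
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    writeLines(readLines(con), real)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(real, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(real, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- parsed$atom
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("failed to parse ", path, " as ", format, ": no atom records found")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  # drop hydrogens and deuteriums
  h <- toupper(guess_element(atoms$elety)) %in% c("H", "D") &
    !(toupper(atoms$resid) %in% .METAL_RES)
  atoms <- atoms[!h, , drop = FALSE]
  if (!keep_altloc) atoms <- collapse_altlocs(atoms)
  structure_model(atoms, identifier = basename(path),
                  source_format = if (format == "pdb") "PDB" else "mmCIF")
}

# keep the highest-occupancy conformer per (chain,resno,insert,elety)
collapse_altlocs <- function(atoms) {
  id <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(id, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|")), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

#' Write a structure to PDB or mmCIF
#'
#' @param s a `StructureModel`.
#' @param path output path; format inferred from extension unless given.
#' @param format "auto", "pdb" or "cif".
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "cif")) {
  stopifnot(inherits(s, "StructureModel"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer output format from '", ext, "'"))
  }
  a <- s$atoms
  if (format == "pdb") {
    het <- a$kind %in% c("water", "metal_ion", "other")
    bio3d::write.pdb(file = path, xyz = as.vector(t(coords(a))),
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = ifelse(a$chain == "", " ", a$chain),
                     insert = a$insert, alt = ifelse(a$alt == "", NA, a$alt),
                     o = a$o, b = a$b, elesy = a$elesy)
  } else {
    write_mmcif(s, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (no R package in this stack writes mmCIF).
write_mmcif <- function(s, path) {
  a <- s$atoms
  het <- a$kind %in% c("water", "metal_ion", "other")
  chain <- ifelse(a$chain == "" | a$chain == " ", ".", a$chain)
  atomq <- ifelse(grepl("'", a$elety), paste0('"', a$elety, '"'), a$elety)
  lines <- c(
    paste0("data_", ifelse(nzchar(s$identifier),
                           gsub("[^A-Za-z0-9_-]", "_", s$identifier), "model")),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            ifelse(het, "HETATM", "ATOM"), a$eleno, a$elesy, atomq,
            ifelse(a$alt == "", ".", a$alt), a$resid, chain,
            a$resno, ifelse(a$insert == "", "?", a$insert),
            a$x, a$y, a$z, a$o, a$b,
            a$resno, a$resid, chain, atomq),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Mirror a structure through the Z plane
#'
#' Inverts the sign of the Z coordinate of every atom, which converts a
#' D-configured model into its exact L-configured mirror image (and vice
#' versa): all interatomic distances are preserved exactly and all torsion
#' angles are negated. Chirality flags are flipped L <-> D.
#'
#' @param s a `StructureModel`.
#' @return the mirrored `StructureModel`.
#' @export
mirror_structure <- function(s) {
  stopifnot(inherits(s, "StructureModel"))
  s$atoms$z <- -s$atoms$z
  flip <- s$atoms$chirality %in% c("L", "D")
  s$atoms$chirality[flip] <- ifelse(s$atoms$chirality[flip] == "L", "D", "L")
  s
}

#' Parse mixed L-RNA/L-DNA sequence notation
#'
#' Parses strings such as `"5'-GCGAUG(dU)GG...-3'"` where parenthesized
#' d-prefixed letters mark deoxyribonucleotides within an otherwise ribo
#' sequence. 5'/3' decorations, hyphens and whitespace are stripped.
#'
#' @param text the notation string.
#' @return data.frame with columns `position`, `base`, `is_deoxy`
#'   (class `MixedSequence`).
#' @export
parse_mixed_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  # normalize decorations: unicode primes, 5'-/3' markers, spaces, hyphens
  t0 <- gsub("′", "'", text)
  t0 <- gsub("[53]'", "", t0)
  t0 <- gsub("[-\\s]", "", t0, perl = TRUE)
  bases <- character(0)
  deoxy <- logical(0)
  i <- 1
  n <- nchar(t0)
  while (i <= n) {
    ch <- substr(t0, i, i)
    if (ch == "(") {
      close <- regexpr(")", substr(t0, i, n), fixed = TRUE)
      if (close < 0) stop("unbalanced parenthesis at offset ", i)
      tok <- substr(t0, i + 1, i + close - 2)
      if (!grepl("^d[ACGUT]$", tok)) {
        stop("illegal token '(", tok, ")' at offset ", i)
      }
      bases <- c(bases, substr(tok, 2, 2))
      deoxy <- c(deoxy, TRUE)
      i <- i + close
    } else if (ch %in% c("A", "C", "G", "U", "T")) {
      bases <- c(bases, ch)
      deoxy <- c(deoxy, FALSE)
      i <- i + 1
    } else {
      stop("illegal character '", ch, "' at offset ", i)
    }
  }
  out <- data.frame(position = seq_along(bases), base = bases,
                    is_deoxy = deoxy, stringsAsFactors = FALSE)
  class(out) <- c("MixedSequence", "data.frame")
  out
}

#' Summarize a structure as a plain list (JSON-ready)
#'
#' @param s a `StructureModel`.
#' @return list with identifier, format, chain/residue/atom counts and
#'   per-chain composition.
#' @export
structure_summary <- function(s) {
  stopifnot(inherits(s, "StructureModel"))
  rt <- residue_table(s)
  per_chain <- lapply(split(rt, rt$chain), function(ch) {
    list(n_residues = nrow(ch),
         kinds = as.list(table(ch$kind)),
         chirality = as.list(table(ch$chirality[ch$chirality != "not_applicable"])))
  })
  list(identifier = s$identifier, source_format = s$source_format,
       n_atoms = nrow(s$atoms), n_residues = nrow(rt),
       n_chains = length(unique(rt$chain)), chains = per_chain)
}

# Polymer-chain roles by content: nucleic chains and protein chains, used to
# select molecules when chain identifiers are unknown a priori.
chain_roles <- function(s) {
  rt <- residue_table(s)
  sp <- split(rt, rt$chain)
  data.frame(
    chain = names(sp),
    n_nuc = vapply(sp, function(x) sum(x$kind %in% c("ribonucleotide", "deoxyribonucleotide")), 0L),
    n_prot = vapply(sp, function(x) sum(x$kind == "protein"), 0L),
    stringsAsFactors = FALSE)
}
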