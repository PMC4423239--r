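# Shared fixture helpers. Everything is generated in code; nothing is read
# from disk.

# single free nucleotide as a StructureModel
single_nucleotide <- function(base = "G", deoxy = FALSE, chi = -160,
                              phase = 18, resno = 1, chain = "A") {
  nuc <- aptastruct:::build_nucleotide(base, deoxy, chi = chi, phase = phase)
  nuc$chain <- chain
  nuc$resno <- resno
  nuc$resid <- aptastruct:::resid_name(base, deoxy)
  nuc$eleno <- seq_len(nrow(nuc))
  structure_model(nuc)
}

# base-only Watson-Crick pair (no sugars), canonical geometry
base_pair_structure <- function(b1 = "G", b2 = "C") {
  t1 <- aptastruct:::.BASE_TEMPLATES[[b1]]
  X1 <- t1$xyz
  rownames(X1) <- t1$atoms
  X2 <- aptastruct:::pose_wc_partner(b1, b2)
  a1 <- data.frame(elety = rownames(X1), x = X1[, 1], y = X1[, 2], z = X1[, 3],
                   chain = "A", resno = 1, resid = b1)
  a2 <- data.frame(elety = rownames(X2), x = X2[, 1], y = X2[, 2], z = X2[, 3],
                   chain = "B", resno = 1, resid = b2)
  suppressWarnings(structure_model(rbind(a1, a2)))
}

# two waters at a given O-O distance
two_waters <- function(d) {
  atoms <- data.frame(elety = "O", x = c(0, d), y = 0, z = 0, elesy = "O",
                      chain = "W", resno = 1:2, resid = "HOH")
  structure_model(atoms)
}

# apply a seeded random rigid motion
random_rigid <- function(s, seed) {
  sp <- aptastruct:::with_seed(seed, {
    ax <- stats::rnorm(3)
    list(R = aptastruct:::rotation_about_axis(ax, stats::runif(1, 0, 360)),
         t = stats::rnorm(3, 0, 20))
  })
  transform_structure(s, sp)
}

# distance matrix of all atoms
dist_matrix <- function(s) as.matrix(stats::dist(as.matrix(s$atoms[, c("x", "y", "z")])))

# locate local copies of the deposited coordinate entries, if the user has
# provided them (they are not distributed with the package)
deposited_path <- function(accession) {
  dirs <- c(getOption("aptastruct.deposited_dir", ""),
            file.path(path.expand("~"), "aptastruct-deposited"),
            system.file("extdata", "deposited", package = "aptastruct"))
  for (d in dirs) {
    if (!nzchar(d) || !dir.exists(d)) next
    for (ext in c(".cif", ".cif.gz", ".pdb", ".pdb.gz")) {
      for (nm in c(tolower(accession), toupper(accession))) {
        p <- file.path(d, paste0(nm, ext))
        if (file.exists(p)) return(p)
      }
    }
  }
  NULL
}
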