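# Construction of idealized nucleotide coordinates from internal coordinates.
# Used to build reference fragments at prescribed conformations, both for
# unit testing and for closed-loop validation of the scoring layer.

# Place atom D given positions of A, B, C and the internal coordinates
# bond |CD|, angle B-C-D and torsion A-B-C-D (degrees). Standard NeRF.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Default internal coordinates of the idealized sugar (Angstrom, degrees).
default_internal <- function() {
  list(
    b_c4_o4 = 1.449, b_o4_c1 = 1.414, b_c1_c2 = 1.521, b_c2_c3 = 1.524,
    b_c4_c5 = 1.509, b_c5_o5 = 1.440, b_c3_o3 = 1.431, b_c2_o2 = 1.412,
    b_c1_n = 1.468, b_n_cf = 1.374, b_n_cr = 1.374,
    a_c4_o4_c1 = 109.7, a_o4_c1_c2 = 106.1, a_c1_c2_c3 = 101.8,
    a_o4_c4_c5 = 109.3, a_c4_c5_o5 = 110.6, a_c2_c3_o3 = 110.5,
    a_c1_c2_o2 = 110.6, a_o4_c1_n = 108.2,
    a_c1_n_cf = 126.4, a_c1_n_cr = 127.0
  )
}

#' Build an idealized nucleotide at a prescribed conformation
#'
#' Atoms are placed sequentially from internal coordinates, so the requested
#' torsions (chi, gamma, nu0, nu1) and any overridden bond lengths are
#' reproduced exactly by measurement; the remaining ring torsions follow from
#' the construction. This is a geometric scaffold for testing and synthetic
#' benchmarks, not a chemically optimized model.
#'
#' @param chi glycosidic torsion chi in degrees.
#' @param gamma side-chain torsion gamma (O5'-C5'-C4'-C3') in degrees.
#' @param nu0,nu1 the first two endocyclic torsions in degrees (they fix the
#'   approximate ring pucker of the open-chain construction).
#' @param sugar_type "ribose" or "deoxyribose".
#' @param base_type "purine" or "pyrimidine".
#' @param resname residue name (default chosen from base/sugar type).
#' @param chain,resno,altloc,occupancy atom-record metadata.
#' @param internal named list overriding entries of the default internal
#'   coordinates (see source), e.g. `list(b_c1_c2 = 1.52)`.
#' @return data.frame of atom records (elety, resid, chain, resno, insert,
#'   alt, occupancy, x, y, z, elesy).
#' @export
build_nucleotide <- function(chi = -120, gamma = 60, nu0 = -25, nu1 = 37,
                             sugar_type = c("ribose", "deoxyribose"),
                             base_type = c("purine", "pyrimidine"),
                             resname = NULL, chain = "A", resno = 1L,
                             altloc = "", occupancy = 1,
                             internal = list()) {
  sugar_type <- match.arg(sugar_type)
  base_type <- match.arg(base_type)
  ic <- utils::modifyList(default_internal(), internal)
  if (is.null(resname))
    resname <- switch(paste(sugar_type, base_type),
                      "ribose purine" = "A", "ribose pyrimidine" = "C",
                      "deoxyribose purine" = "DA", "deoxyribose pyrimidine" = "DC")

  xyz <- list()
  xyz[["C4'"]] <- c(0, 0, 0)
  xyz[["O4'"]] <- c(ic$b_c4_o4, 0, 0)
  # C1' in the xy-plane
  ang <- ic$a_c4_o4_c1 * pi / 180
  xyz[["C1'"]] <- xyz[["O4'"]] + ic$b_o4_c1 * c(-cos(ang), sin(ang), 0)
  xyz[["C2'"]] <- place_atom(xyz[["C4'"]], xyz[["O4'"]], xyz[["C1'"]],
                             ic$b_c1_c2, ic$a_o4_c1_c2, nu0)
  xyz[["C3'"]] <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[["C2'"]],
                             ic$b_c2_c3, ic$a_c1_c2_c3, nu1)
  # side chain: C5' exocyclic at C4', on the opposite face from C3'
  # (two candidate torsions about O4'-C4'; keep the one away from the ring)
  t_ring <- measure_torsion(xyz[["C1'"]], xyz[["O4'"]], xyz[["C4'"]],
                            xyz[["C3'"]])
  cand <- lapply(c(-120, 120), function(dt)
    place_atom(xyz[["C1'"]], xyz[["O4'"]], xyz[["C4'"]],
               ic$b_c4_c5, ic$a_o4_c4_c5, wrap180(t_ring + dt)))
  dist3 <- vapply(cand, function(p) vnorm(p - xyz[["C3'"]]), numeric(1))
  xyz[["C5'"]] <- cand[[which.max(dist3)]]
  xyz[["O5'"]] <- place_atom(xyz[["C3'"]], xyz[["C4'"]], xyz[["C5'"]],
                             ic$b_c5_o5, ic$a_c4_c5_o5, gamma)
  xyz[["O3'"]] <- place_atom(xyz[["C1'"]], xyz[["C2'"]], xyz[["C3'"]],
                             ic$b_c3_o3, ic$a_c2_c3_o3, -155)
  if (sugar_type == "ribose")
    xyz[["O2'"]] <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[["C2'"]],
                               ic$b_c2_o2, ic$a_c1_c2_o2, wrap180(nu1 + 120))
  nname <- if (base_type == "purine") "N9" else "N1"
  fwd <- if (base_type == "purine") "C4" else "C2"   # atom defining chi
  rev <- if (base_type == "purine") "C8" else "C6"
  xyz[[nname]] <- place_atom(xyz[["C4'"]], xyz[["O4'"]], xyz[["C1'"]],
                             ic$b_c1_n, ic$a_o4_c1_n, wrap180(nu0 + 120))
  # chi = O4'-C1'-N-Cfwd: place Cfwd by that torsion directly
  xyz[[fwd]] <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[[nname]],
                           ic$b_n_cf, ic$a_c1_n_cf, chi)
  xyz[[rev]] <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[[nname]],
                           ic$b_n_cr, ic$a_c1_n_cr, wrap180(chi + 180))

  nm <- names(xyz)
  data.frame(
    elety = nm,
    resid = resname,
    chain = chain,
    resno = as.integer(resno),
    insert = "",
    alt = altloc,
    occupancy = occupancy,
    x = vapply(xyz, `[`, numeric(1), 1),
    y = vapply(xyz, `[`, numeric(1), 2),
    z = vapply(xyz, `[`, numeric(1), 3),
    elesy = substr(nm, 1, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build a short idealized oligonucleotide
#'
#' Successive residues are translated apart and joined by a bridging
#' phosphorus placed on the O3'(i) -> O5'(i+1) axis, so that terminal-state
#' detection (presence of a bonded P at O3'/O5') behaves as in a real chain.
#'
#' @param n number of residues.
#' @param chain chain identifier.
#' @param free_5prime if TRUE (default) the first residue has a free 5'-OH.
#' @param ... per-residue arguments recycled across residues and passed to
#'   [build_nucleotide()] (`chi`, `gamma`, `sugar_type`, `base_type`, ...).
#' @return data.frame of atom records for the whole chain.
#' @export
build_chain <- function(n = 2, chain = "A", free_5prime = TRUE, ...) {
  args <- lapply(list(...), function(a) rep_len(a, n))
  p_row <- function(p, resid, resno) data.frame(
    elety = "P", resid = resid, chain = chain, resno = as.integer(resno),
    insert = "", alt = "", occupancy = 1, x = p[1], y = p[2], z = p[3],
    elesy = "P", stringsAsFactors = FALSE)
  at1 <- function(res, nm) unlist(res[res$elety == nm, c("x", "y", "z")],
                                  use.names = FALSE)
  residues <- list()
  phosphates <- list()
  for (i in seq_len(n)) {
    ai <- lapply(args, `[[`, i)
    ai$chain <- chain
    ai$resno <- i
    res <- do.call(build_nucleotide, ai)
    if (i > 1) {
      # place residue i so that its O5' sits 2.55 A from O3'(i-1), pointing
      # away from the previous residue, then drop the bridging P beside the
      # O3'...O5' midpoint at bonding distance (~1.6 A) from both oxygens
      prev <- residues[[i - 1]]
      o3 <- at1(prev, "O3'")
      u <- o3 - colMeans(as.matrix(prev[, c("x", "y", "z")]))
      u <- if (vnorm(u) < 1e-6) c(1, 0, 0) else u / vnorm(u)
      target_o5 <- o3 + 2.55 * u
      shift <- target_o5 - at1(res, "O5'")
      res$x <- res$x + shift[1]; res$y <- res$y + shift[2]
      res$z <- res$z + shift[3]
      w <- vcross(u, c(0, 0, 1))
      if (vnorm(w) < 1e-6) w <- vcross(u, c(0, 1, 0))
      w <- w / vnorm(w)
      pb <- (o3 + target_o5) / 2 + 0.99 * w
      phosphates[[length(phosphates) + 1L]] <- p_row(pb, res$resid[1], i)
    }
    residues[[i]] <- res
  }
  if (!free_5prime) {
    r1 <- residues[[1]]
    o5 <- at1(r1, "O5'")
    u <- o5 - at1(r1, "C5'")
    p <- o5 + 1.60 * u / vnorm(u)
    phosphates[[length(phosphates) + 1L]] <- p_row(p, r1$resid[1], 1)
  }
  atoms <- do.call(rbind, c(residues, phosphates))
  row.names(atoms) <- NULL
  atoms
}

#' Write atom records as a minimal PDB file
#'
#' @param atoms data.frame as produced by [build_nucleotide()]/[build_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name <- a$elety
    # PDB column alignment: 4-char atom-name field starting at column 13
    namefld <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    lines[i] <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, namefld, ifelse(a$alt == "", " ", a$alt), a$resid, a$chain,
      a$resno, ifelse(a$insert == "", " ", a$insert),
      a$x, a$y, a$z, a$occupancy, 0, a$elesy)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write atom records as a minimal mmCIF file
#'
#' @inheritParams write_pdb_file
#' @return `path`, invisibly.
#' @export
write_cif_file <- function(atoms, path) {
  hdr <- c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    nm <- sprintf("\"%s\"", a$elety)
    rows[i] <- sprintf(
      "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      i, a$elesy, nm, ifelse(a$alt == "", ".", a$alt), a$resid, a$chain,
      a$resno, ifelse(a$insert == "", "?", a$insert),
      a$x, a$y, a$z, a$occupancy, 0, a$resno, a$resid, a$chain, nm)
  }
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
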