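# Coordinate input and sugar-fragment extraction.

NUC_RESNAMES <- c("A", "C", "G", "U", "I", "N",
                  "DA", "DC", "DG", "DT", "DU", "DI",
                  "ADE", "CYT", "GUA", "URA", "THY",
                  "1MA", "5MC", "PSU", "7MG", "H2U", "OMC", "OMG", "M2G")

AA_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "HOH", "WAT")

#' Read a coordinate file (PDB or mmCIF)
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] that returns a
#' normalized atom table. Only the first model of a multi-model file is used.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @return data.frame with columns elety, resid, chain, resno, insert, alt,
#'   occupancy, x, y, z, elesy. Primed atom names are normalized (`*` is
#'   converted to `'`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("cif", "mmcif")) {
    # bio3d's mmCIF reader emits advisory warnings (beta notice, unparsed
    # helix/sheet records) that are irrelevant to coordinate extraction
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  }
  at <- obj$atom
  blank <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v %in% c(".", "?")] <- ""
    v
  }
  data.frame(
    elety = gsub("\\*", "'", gsub("\"", "", as.character(at$elety))),
    resid = toupper(blank(at$resid)),
    chain = blank(at$chain),
    resno = as.integer(at$resno),
    insert = blank(at$insert),
    alt = blank(at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    elesy = blank(at$elesy),
    stringsAsFactors = FALSE
  )
}

frag_id <- function(frag) {
  paste0(frag$chain, "/", frag$resid, frag$resno, frag$insert,
         if (frag$altloc != "") paste0(".", frag$altloc) else "")
}

#' Extract sugar-base fragments from a structure
#'
#' One fragment is produced per nucleotide sugar per alternative conformation.
#' A fragment requires the complete atom set C1'-C5', O4', O3', O5', the
#' glycosidic nitrogen (N9 for purines, N1 for pyrimidines) and its two base
#' neighbours; residues with missing atoms are skipped with a logged reason.
#' Hydrogens are ignored. Terminal state is decided by the absence of a
#' phosphorus atom within `p_cutoff` of O3'/O5'.
#'
#' @param x a file path, or an atom data.frame as returned by
#'   [read_structure()] or [build_chain()].
#' @param p_cutoff covalent-distance cutoff (Angstrom) for the O-P bond
#'   search used for terminal-state detection.
#' @param verbose print the extraction report.
#' @return list of `sugar_fragment` objects; attribute `report` holds counts
#'   of accepted/skipped residues and the skip reasons.
#' @export
extract_fragments <- function(x, p_cutoff = 1.8, verbose = FALSE) {
  atoms <- if (is.character(x)) read_structure(x) else as.data.frame(x)
  atoms <- atoms[atoms$elesy != "H" & !grepl("^H", atoms$elety), , drop = FALSE]
  p_xyz <- as.matrix(atoms[atoms$elety == "P", c("x", "y", "z"), drop = FALSE])

  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  frags <- list()
  skipped <- character(0)
  for (k in unique(key)) {
    res <- atoms[key == k, , drop = FALSE]
    resname <- res$resid[1]
    has_sugar <- all(c("C1'", "O4'") %in% res$elety)
    if (!(resname %in% NUC_RESNAMES)) {
      if (has_sugar && !(resname %in% AA_RESNAMES))
        skipped <- c(skipped, sprintf("%s/%s%s: unknown residue name",
                                      res$chain[1], resname, res$resno[1]))
      next
    }
    alts <- setdiff(unique(res$alt), "")
    if (length(alts) == 0) alts <- ""
    for (a in alts) {
      sel <- res[res$alt %in% c("", a), , drop = FALSE]
      # keep the altloc copy when both blank and matching-alt copies exist
      sel <- sel[!duplicated(sel$elety, fromLast = (a != "")), , drop = FALSE]
      frag <- tryCatch(
        make_fragment(sel, altloc = a, p_xyz = p_xyz, p_cutoff = p_cutoff),
        error = function(e) conditionMessage(e))
      if (is.character(frag)) {
        skipped <- c(skipped, sprintf("%s/%s%s%s: %s", sel$chain[1], resname,
                                      sel$resno[1],
                                      if (a != "") paste0(".", a) else "", frag))
      } else {
        frags[[length(frags) + 1L]] <- frag
      }
    }
  }
  report <- list(n_accepted = length(frags), n_skipped = length(skipped),
                 skipped = skipped)
  if (verbose) {
    message(sprintf("extracted %d sugar fragment(s), skipped %d",
                    report$n_accepted, report$n_skipped))
    for (s in skipped) message("  skipped ", s)
  }
  attr(frags, "report") <- report
  frags
}

make_fragment <- function(res, altloc, p_xyz, p_cutoff) {
  get1 <- function(nm) {
    i <- which(res$elety == nm)
    if (length(i) == 0) return(NULL)
    unlist(res[i[1], c("x", "y", "z")], use.names = FALSE)
  }
  base_type <- if (!is.null(get1("N9"))) "purine"
               else if (!is.null(get1("N1"))) "pyrimidine"
               else stop("no glycosidic nitrogen (N1/N9)")
  nname <- if (base_type == "purine") "N9" else "N1"
  bfwd <- if (base_type == "purine") "C4" else "C2"
  brev <- if (base_type == "purine") "C8" else "C6"
  need <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O3'", "O5'",
            nname, bfwd, brev)
  missing <- setdiff(need, res$elety)
  if (length(missing) > 0)
    stop("missing atom(s) ", paste(missing, collapse = ", "))
  sugar_type <- if ("O2'" %in% res$elety) "ribose" else "deoxyribose"
  keep <- c(need, if (sugar_type == "ribose") "O2'")
  xyz <- t(vapply(keep, get1, numeric(3)))
  colnames(xyz) <- c("x", "y", "z")

  near_p <- function(o) {
    if (nrow(p_xyz) == 0) return(FALSE)
    d2 <- (p_xyz[, 1] - o[1])^2 + (p_xyz[, 2] - o[2])^2 + (p_xyz[, 3] - o[3])^2
    any(d2 <= p_cutoff^2)
  }
  occ <- res$occupancy[match(keep, res$elety)]
  structure(list(
    chain = res$chain[1], resno = res$resno[1], insert = res$insert[1],
    resid = res$resid[1], altloc = altloc,
    sugar_type = sugar_type, base_type = base_type,
    n_name = nname, base_fwd = bfwd, base_rev = brev,
    terminal_o3 = !near_p(xyz["O3'", ]),
    terminal_o5 = !near_p(xyz["O5'", ]),
    occupancy = min(occ), multi_conf = altloc != "",
    xyz = xyz
  ), class = "sugar_fragment")
}

#' @export
print.sugar_fragment <- function(x, ...) {
  cat(sprintf("<sugar_fragment %s %s/%s%s%s %s-%s%s%s>\n",
              x$resid, x$chain, x$resno, x$insert,
              if (x$altloc != "") paste0(".", x$altloc) else "",
              x$sugar_type, x$base_type,
              if (x$terminal_o3) " 3'-terminal" else "",
              if (x$terminal_o5) " 5'-terminal" else ""))
  invisible(x)
}

# ---- measurement -----------------------------------------------------------

#' Measure all dictionary geometry of a sugar fragment
#'
#' Returns every bond length and bond angle carried by the restraint
#' dictionary, the torsions chi (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for
#' pyrimidines), gamma (O5'-C5'-C4'-C3') and nu0..nu4, and the pseudorotation
#' parameters (P, tau_m).
#'
#' @param frag a `sugar_fragment`.
#' @return list with elements `bonds`, `angles` (named numeric vectors keyed
#'   by dictionary parameter name), `torsions` (chi, gamma, nu) and `pucker`
#'   (P, tau_m).
#' @export
measure_fragment <- function(frag) {
  stopifnot(inherits(frag, "sugar_fragment"))
  X <- frag$xyz
  p <- function(nm) X[nm, ]
  N <- frag$n_name
  d <- function(a, b) bond_length(p(a), p(b))
  an <- function(a, b, c) bond_angle(p(a), p(b), p(c))
  tor <- function(a, b, c, g) measure_torsion(p(a), p(b), p(c), p(g))

  bonds <- c(
    "C1'-C2'" = d("C1'", "C2'"), "C2'-C3'" = d("C2'", "C3'"),
    "C3'-C4'" = d("C3'", "C4'"), "C4'-O4'" = d("C4'", "O4'"),
    "C1'-O4'" = d("C1'", "O4'"), "C4'-C5'" = d("C4'", "C5'"),
    "C1'-N" = d("C1'", N), "C3'-O3'" = d("C3'", "O3'"),
    "C5'-O5'" = d("C5'", "O5'"))
  if (frag$sugar_type == "ribose")
    bonds <- c(bonds, "C2'-O2'" = d("C2'", "O2'"))

  angles <- c(
    "C1'-C2'-C3'" = an("C1'", "C2'", "C3'"),
    "C2'-C3'-C4'" = an("C2'", "C3'", "C4'"),
    "C3'-C4'-O4'" = an("C3'", "C4'", "O4'"),
    "C4'-O4'-C1'" = an("C4'", "O4'", "C1'"),
    "O4'-C1'-C2'" = an("O4'", "C1'", "C2'"),
    "C2'-C3'-O3'" = an("C2'", "C3'", "O3'"),
    "C4'-C3'-O3'" = an("C4'", "C3'", "O3'"),
    "C3'-C4'-C5'" = an("C3'", "C4'", "C5'"),
    "O4'-C4'-C5'" = an("O4'", "C4'", "C5'"),
    "C4'-C5'-O5'" = an("C4'", "C5'", "O5'"),
    "N-C1'-C2'" = an(N, "C1'", "C2'"),
    "N-C1'-O4'" = an(N, "C1'", "O4'"),
    "C1'-N-C2/C4" = an("C1'", N, frag$base_fwd),
    "C1'-N-C6/C8" = an("C1'", N, frag$base_rev))
  if (frag$sugar_type == "ribose")
    angles <- c(angles,
                "C1'-C2'-O2'" = an("C1'", "C2'", "O2'"),
                "C3'-C2'-O2'" = an("C3'", "C2'", "O2'"))

  nu <- c(tor("C4'", "O4'", "C1'", "C2'"),
          tor("O4'", "C1'", "C2'", "C3'"),
          tor("C1'", "C2'", "C3'", "C4'"),
          tor("C2'", "C3'", "C4'", "O4'"),
          tor("C3'", "C4'", "O4'", "C1'"))
  chi <- tor("O4'", "C1'", N, frag$base_fwd)
  gamma <- tor("O5'", "C5'", "C4'", "C3'")
  pk <- compute_pseudorotation(nu)

  list(bonds = bonds, angles = angles,
       torsions = list(chi = chi, gamma = gamma, nu = nu),
       pucker = list(P = pk$P, tau_m = pk$tau_m, flat = pk$flat))
}

# Map a dictionary parameter name to the fragment's actual atom names.
parameter_atoms <- function(parameter, frag) {
  nm <- strsplit(parameter, "-", fixed = TRUE)[[1]]
  nm[nm == "N"] <- frag$n_name
  nm[nm == "C2/C4"] <- frag$base_fwd
  nm[nm == "C6/C8"] <- frag$base_rev
  nm
}
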