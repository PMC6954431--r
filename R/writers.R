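# Emission of restraints in the three refinement-program dialects.
# Printed precision is fixed: 3 decimals for Angstrom, 2 for degrees.

fmt_A <- function(x) sprintf("%.3f", x)
fmt_deg <- function(x) sprintf("%.2f", x)

sel_refmac <- function(r, atom) {
  s <- sprintf("chain %s resi %d ins %s atom %s",
               r$chain, r$resno, ifelse(r$insert == "", ".", r$insert), atom)
  if (r$altloc != "") s <- paste0(s, " alte ", r$altloc)
  s
}

#' Write restraints in REFMAC external-restraint keyword format
#'
#' One `exte dist`/`exte angle` line per record, with sigmas taken directly
#' from the dictionary standard deviations. Records are emitted in
#' deterministic order (chain, residue, insertion, altloc, parameter).
#'
#' @param records restraint records from [build_full_restraint_set()].
#' @param path optional output file.
#' @return character vector of output lines (invisibly when `path` is given).
#' @export
write_refmac <- function(records, path = NULL) {
  records <- order_records(records)
  lines <- c("# Conformation-dependent sugar restraints (REFMAC external)",
             "# distances in Angstrom, angles in degrees")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind == "bond") {
      lines <- c(lines, sprintf("exte dist first %s second %s value %s sigma %s",
                                sel_refmac(r, r$atom1), sel_refmac(r, r$atom2),
                                fmt_A(r$ideal), fmt_A(r$sigma)))
    } else {
      lines <- c(lines, sprintf(
        "exte angle first %s second %s third %s value %s sigma %s",
        sel_refmac(r, r$atom1), sel_refmac(r, r$atom2), sel_refmac(r, r$atom3),
        fmt_deg(r$ideal), fmt_deg(r$sigma)))
    }
  }
  finish_writer(lines, path)
}

sel_phenix <- function(r, atom) {
  s <- sprintf("chain %s and resseq %d and name %s", r$chain, r$resno, atom)
  if (r$insert != "") s <- paste0(s, " and icode ", r$insert)
  if (r$altloc != "") s <- paste0(s, " and altid ", r$altloc)
  s
}

#' Write restraints as PHENIX geometry-restraints edits
#'
#' @inheritParams write_refmac
#' @return character vector of output lines (invisibly when `path` is given).
#' @export
write_phenix <- function(records, path = NULL) {
  records <- order_records(records)
  lines <- c("refinement.geometry_restraints.edits {")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind == "bond") {
      lines <- c(lines,
        "  bond {",
        "    action = *add",
        sprintf("    atom_selection_1 = %s", sel_phenix(r, r$atom1)),
        sprintf("    atom_selection_2 = %s", sel_phenix(r, r$atom2)),
        sprintf("    distance_ideal = %s", fmt_A(r$ideal)),
        sprintf("    sigma = %s", fmt_A(r$sigma)),
        "  }")
    } else {
      lines <- c(lines,
        "  angle {",
        "    action = *add",
        sprintf("    atom_selection_1 = %s", sel_phenix(r, r$atom1)),
        sprintf("    atom_selection_2 = %s", sel_phenix(r, r$atom2)),
        sprintf("    atom_selection_3 = %s", sel_phenix(r, r$atom3)),
        sprintf("    angle_ideal = %s", fmt_deg(r$ideal)),
        sprintf("    sigma = %s", fmt_deg(r$sigma)),
        "  }")
    }
  }
  lines <- c(lines, "}")
  finish_writer(lines, path)
}

#' 1-3 distance and sigma for a SHELXL DANG restraint
#'
#' Converts a bond-angle target into the 1-3 distance by the law of cosines,
#' d13 = sqrt(b1^2 + b2^2 - 2 b1 b2 cos(theta)), with the sigma obtained by
#' first-order error propagation from the two flanking bond sigmas and the
#' angle sigma.
#'
#' @param b1,b2 flanking bond targets (Angstrom).
#' @param theta angle target (degrees).
#' @param sb1,sb2 flanking bond sigmas (Angstrom).
#' @param stheta angle sigma (degrees).
#' @return list with `d13` and `sigma` (Angstrom).
#' @export
dang_distance <- function(b1, b2, theta, sb1 = 0, sb2 = 0, stheta = 0) {
  th <- theta * pi / 180
  d13 <- sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(th))
  d_b1 <- (b1 - b2 * cos(th)) / d13
  d_b2 <- (b2 - b1 * cos(th)) / d13
  d_th <- b1 * b2 * sin(th) / d13          # per radian
  sigma <- sqrt((d_b1 * sb1)^2 + (d_b2 * sb2)^2 +
                (d_th * stheta * pi / 180)^2)
  list(d13 = d13, sigma = sigma)
}

#' Write restraints as a SHELXL instruction fragment (DFIX/DANG)
#'
#' Distances become `DFIX_n` lines and angles become `DANG_n` 1-3 distance
#' lines (the residue number is carried in the instruction suffix). The 1-3
#' target is computed by [dang_distance()] from the two flanking bond targets
#' of the same fragment. An angle whose flanking bond target is missing
#' raises an error naming the missing bond when `on_missing = "error"`, or is
#' dropped with a warning when `on_missing = "skip"` (the non-terminal
#' O3'/O5' angles fall in this class because the corresponding phosphoester
#' bonds belong to the phosphodiester dictionary, which is out of scope
#' here).
#'
#' @inheritParams write_refmac
#' @param on_missing "error" or "skip".
#' @return character vector of output lines (invisibly when `path` is given).
#' @export
write_shelxl <- function(records, path = NULL,
                         on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  records <- order_records(records)
  fragkey <- paste(records$chain, records$resno, records$insert,
                   records$altloc)
  lines <- c("REM Conformation-dependent sugar restraints (SHELXL DFIX/DANG)")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$kind == "bond") {
      lines <- c(lines, sprintf("DFIX_%d %s %s %s %s", r$resno,
                                fmt_A(r$ideal), fmt_A(r$sigma),
                                r$atom1, r$atom2))
      next
    }
    sib <- records[fragkey == fragkey[i] & records$kind == "bond", ,
                   drop = FALSE]
    find_bond <- function(a, b) {
      j <- which((sib$atom1 == a & sib$atom2 == b) |
                 (sib$atom1 == b & sib$atom2 == a))
      if (length(j) == 0) return(NULL)
      sib[j[1], ]
    }
    bnd1 <- find_bond(r$atom1, r$atom2)
    bnd2 <- find_bond(r$atom2, r$atom3)
    if (is.null(bnd1) || is.null(bnd2)) {
      missing <- paste(c(
        if (is.null(bnd1)) paste0(r$atom1, "-", r$atom2),
        if (is.null(bnd2)) paste0(r$atom2, "-", r$atom3)), collapse = ", ")
      msg <- sprintf("angle %s (%s %s%s): missing flanking bond target %s",
                     r$parameter, r$chain, r$resno, r$insert, missing)
      if (on_missing == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    dd <- dang_distance(bnd1$ideal, bnd2$ideal, r$ideal,
                        bnd1$sigma, bnd2$sigma, r$sigma)
    lines <- c(lines, sprintf("DANG_%d %s %s %s %s", r$resno,
                              fmt_A(dd$d13), fmt_A(dd$sigma),
                              r$atom1, r$atom3))
  }
  finish_writer(lines, path)
}

order_records <- function(records) {
  records[order(records$chain, records$resno, records$insert, records$altloc,
                records$kind, records$parameter), , drop = FALSE]
}

finish_writer <- function(lines, path) {
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Lenient re-parser for emitted restraint files
#'
#' Recovers the (kind, ideal, sigma) triples from any of the three emitted
#' dialects; used to verify that the writers round-trip their numbers at the
#' printed precision.
#'
#' @param lines character vector of emitted lines.
#' @param format "refmac", "phenix" or "shelxl".
#' @return data.frame with columns kind, ideal, sigma.
#' @export
parse_restraint_file <- function(lines, format = c("refmac", "phenix",
                                                   "shelxl")) {
  format <- match.arg(format)
  num <- function(x) as.numeric(x)
  out <- list()
  if (format == "refmac") {
    for (l in grep("^exte ", lines, value = TRUE)) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      out[[length(out) + 1L]] <- data.frame(
        kind = ifelse(tok[2] == "dist", "bond", "angle"),
        ideal = num(tok[which(tok == "value") + 1]),
        sigma = num(tok[which(tok == "sigma") + 1]))
    }
  } else if (format == "phenix") {
    kind <- NA
    ideal <- NA
    for (l in lines) {
      t <- trimws(l)
      if (t %in% c("bond {", "angle {")) kind <- sub(" \\{", "", t)
      if (grepl("^(distance_ideal|angle_ideal)", t))
        ideal <- num(sub(".*= ", "", t))
      if (grepl("^sigma", t)) {
        out[[length(out) + 1L]] <- data.frame(
          kind = kind, ideal = ideal, sigma = num(sub(".*= ", "", t)))
      }
    }
  } else {
    for (l in grep("^(DFIX|DANG)", lines, value = TRUE)) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      out[[length(out) + 1L]] <- data.frame(
        kind = ifelse(grepl("^DFIX", tok[1]), "bond", "angle_13"),
        ideal = num(tok[2]), sigma = num(tok[3]))
    }
  }
  do.call(rbind, out)
}

#' Generate restraints for a coordinate file (command-line entry point)
#'
#' Thin stateless driver over extract -> measure -> classify -> lookup ->
#' write. Restraints are regenerated from scratch on every invocation, so the
#' output always reflects the current conformation of the model.
#'
#' @param args character vector of command-line arguments:
#'   `--input <pdb|cif>`, `--output <file>`,
#'   `--format refmac|phenix|shelxl`, `--library this-work|parkinson`,
#'   `--quiet`.
#' @return exit status, invisibly: 0 when at least one restraint was written.
#' @export
cli_generate <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- list(input = NULL, output = NULL, format = "refmac",
              library = "this-work", quiet = FALSE)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--input", "-i")) { opt$input <- args[i + 1]; i <- i + 2 }
    else if (a %in% c("--output", "-o")) { opt$output <- args[i + 1]; i <- i + 2 }
    else if (a %in% c("--format", "-f")) { opt$format <- args[i + 1]; i <- i + 2 }
    else if (a == "--library") { opt$library <- args[i + 1]; i <- i + 2 }
    else if (a %in% c("--quiet", "-q")) { opt$quiet <- TRUE; i <- i + 1 }
    else { message("unknown argument: ", a); return(invisible(2L)) }
  }
  if (is.null(opt$input) || is.null(opt$output)) {
    message("usage: restraintgen --input model.pdb --output file ",
            "[--format refmac|phenix|shelxl] [--library this-work|parkinson]")
    return(invisible(2L))
  }
  if (!file.exists(opt$input)) {
    message("input file not found: ", opt$input)
    return(invisible(1L))
  }
  if (!opt$format %in% c("refmac", "phenix", "shelxl")) {
    message("unknown format: ", opt$format)
    return(invisible(2L))
  }
  frags <- extract_fragments(opt$input, verbose = !opt$quiet)
  if (length(frags) == 0) {
    message("no nucleic-acid sugars found in ", opt$input)
    return(invisible(1L))
  }
  dict <- load_dictionary(opt$library)
  records <- build_full_restraint_set(frags, dict)
  if (nrow(records) == 0) {
    message("no restraints generated")
    return(invisible(1L))
  }
  writer <- switch(opt$format, refmac = write_refmac, phenix = write_phenix,
                   shelxl = function(r, p) write_shelxl(r, p,
                                                        on_missing = "skip"))
  suppressWarnings(writer(records, opt$output))
  if (!opt$quiet)
    message(sprintf("wrote %d restraint records (%s) to %s",
                    nrow(records), opt$format, opt$output))
  invisible(0L)
}
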