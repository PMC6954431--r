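# Scoring a coordinate model against a restraint dictionary.

#' Score a model against a restraint dictionary
#'
#' Every applicable dictionary target is evaluated at each fragment's own
#' conformational variables (P, tau_m, chi, gamma) and compared with the
#' measured value; deviations are summarized as RMSD(bonds) and RMSD(angles).
#' Functional targets are evaluated at the fragment's own torsions, not at
#' group means — this is what a conformation-dependent library means in
#' practice. With `well_ordered_only = TRUE` (default) only full-occupancy,
#' single-conformation fragments are scored.
#'
#' @param x a file path, an atom data.frame, or a list of `sugar_fragment`s.
#' @param dict a `restraint_dictionary`.
#' @param well_ordered_only restrict to well-ordered fragments.
#' @return object of class `deviation_report`: `records` (per-record
#'   measured/ideal/|delta|), `rmsd_bonds` (Angstrom), `rmsd_angles`
#'   (degrees), `n_bonds`, `n_angles`.
#' @export
score_model <- function(x, dict = load_dictionary(),
                        well_ordered_only = TRUE) {
  frags <- if (is.list(x) && length(x) > 0 && inherits(x[[1]],
                                                       "sugar_fragment")) x
           else extract_fragments(x)
  if (length(frags) == 0) stop("no sugar fragments to score")
  rec <- build_full_restraint_set(frags, dict)
  if (well_ordered_only)
    rec <- rec[rec$occupancy >= 1 & !rec$multi_conf, , drop = FALSE]
  rec$delta <- rec$measured - rec$ideal
  rec$abs_delta <- abs(rec$delta)
  b <- rec$kind == "bond"
  rmsd <- function(d) if (length(d) == 0) NA_real_ else sqrt(mean(d^2))
  structure(list(records = rec,
                 rmsd_bonds = rmsd(rec$delta[b]),
                 rmsd_angles = rmsd(rec$delta[!b]),
                 n_bonds = sum(b), n_angles = sum(!b),
                 provenance = attr(dict, "provenance")),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "<deviation_report [%s] RMSD(bonds) = %.4f A over %d, RMSD(angles) = %.2f deg over %d>\n",
    x$provenance, x$rmsd_bonds, x$n_bonds, x$rmsd_angles, x$n_angles))
  invisible(x)
}

#' Paired comparison of two deviation reports
#'
#' Wilcoxon signed-rank tests on the paired absolute deviations of two
#' dictionaries scored on the same model, separately for bonds and angles.
#' Identical reports (all pairwise differences zero) are the degenerate
#' no-difference case and are reported with p = 1.
#'
#' @param report_a,report_b `deviation_report`s over the same records.
#' @param alternative passed to [stats::wilcox.test()] ("two.sided" default;
#'   "greater" tests whether `report_a` has larger deviations).
#' @return list with `bonds` and `angles`, each holding `p_value`, `n`,
#'   `median_diff` (median of |delta_a| - |delta_b|).
#' @export
compare_dictionaries <- function(report_a, report_b,
                                 alternative = "two.sided") {
  key <- function(r) paste(r$chain, r$resno, r$insert, r$altloc, r$parameter)
  ra <- report_a$records
  rb <- report_b$records
  if (nrow(ra) != nrow(rb) || !setequal(key(ra), key(rb)))
    stop("reports are not paired over identical parameter sets")
  rb <- rb[match(key(ra), key(rb)), , drop = FALSE]
  one <- function(kind) {
    i <- ra$kind == kind
    da <- ra$abs_delta[i]
    db <- rb$abs_delta[i]
    diffs <- da - db
    if (all(diffs == 0))
      return(list(p_value = 1, n = sum(i), median_diff = 0))
    wt <- suppressWarnings(stats::wilcox.test(da, db, paired = TRUE,
                                              alternative = alternative))
    list(p_value = wt$p.value, n = sum(i), median_diff = stats::median(diffs))
  }
  list(bonds = one("bond"), angles = one("angle"))
}

#' Write a deviation report to disk
#'
#' Emits a JSON summary and a delimited per-record |delta| table suitable for
#' histogram plotting.
#'
#' @param report a `deviation_report`.
#' @param json_path path for the JSON summary (NULL to skip).
#' @param table_path path for the tab-delimited record table (NULL to skip).
#' @return the summary list, invisibly.
#' @export
write_deviation_report <- function(report, json_path = NULL,
                                   table_path = NULL) {
  summ <- list(provenance = report$provenance,
               rmsd_bonds = report$rmsd_bonds,
               rmsd_angles = report$rmsd_angles,
               n_bonds = report$n_bonds, n_angles = report$n_angles)
  if (!is.null(json_path))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(table_path))
    utils::write.table(report$records[, c("chain", "resno", "insert",
                                          "altloc", "parameter", "kind",
                                          "measured", "ideal", "abs_delta")],
                       table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(summ)
}
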