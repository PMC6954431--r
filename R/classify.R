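# Discrete conformational classification keying the restraint dictionary.

#' Classify ring pucker from the pseudorotation phase
#'
#' C3'-endo is defined by 0 <= P <= 36 degrees and C2'-endo by
#' 144 <= P <= 190 degrees; all other phase values are "Other". The windows
#' are applied verbatim (the C2'-endo window deliberately extends past the
#' conventional 180-degree half-range).
#'
#' @param P pseudorotation phase in degrees, in [0, 360).
#' @return character vector: "C3'-endo", "C2'-endo" or "Other".
#' @export
classify_pucker <- function(P) {
  stopifnot(all(P >= 0 & P < 360))
  out <- rep("Other", length(P))
  out[P >= 0 & P <= 36] <- "C3'-endo"
  out[P >= 144 & P <= 190] <- "C2'-endo"
  out
}

#' Classify the glycosidic torsion rotamer
#'
#' syn for |chi| <= 90 degrees (boundary inclusive), anti otherwise.
#'
#' @param chi glycosidic torsion in degrees, in (-180, 180].
#' @return character vector: "syn" or "anti".
#' @export
classify_chi <- function(chi) {
  ifelse(abs(wrap180(chi)) <= 90, "syn", "anti")
}

#' Classify the side-chain torsion rotamer
#'
#' gauche+ for gamma = 60 +/- 30 degrees, gauche- for -60 +/- 30 degrees,
#' trans for 180 +/- 30 degrees (the window spans the +/-180 wrap); anything
#' else is "other".
#'
#' @param gamma side-chain torsion in degrees.
#' @return character vector: "gauche+", "gauche-", "trans" or "other".
#' @export
classify_gamma <- function(gamma) {
  g <- wrap180(gamma)
  out <- rep("other", length(g))
  out[abs(g - 60) <= 30] <- "gauche+"
  out[abs(g + 60) <= 30] <- "gauche-"
  out[abs(wrap180(g - 180)) <= 30] <- "trans"
  out
}

#' Full conformational context of a measured fragment
#'
#' Bundles the discrete labels (sugar type, base type, pucker class, chi and
#' gamma rotamers, terminal flags) with the continuous variables (P, tau_m,
#' chi, gamma) needed to evaluate functional restraint targets.
#'
#' @param frag a `sugar_fragment`.
#' @param meas optional result of [measure_fragment()] (recomputed if absent).
#' @return object of class `conformation_context`.
#' @export
classify_fragment <- function(frag, meas = NULL) {
  if (is.null(meas)) meas <- measure_fragment(frag)
  structure(list(
    sugar_type = frag$sugar_type,
    base_type = frag$base_type,
    pucker_class = classify_pucker(meas$pucker$P),
    chi_rotamer = classify_chi(meas$torsions$chi),
    gamma_rotamer = classify_gamma(meas$torsions$gamma),
    terminal_o3 = frag$terminal_o3,
    terminal_o5 = frag$terminal_o5,
    P = meas$pucker$P, tau_m = meas$pucker$tau_m,
    chi = meas$torsions$chi, gamma = meas$torsions$gamma
  ), class = "conformation_context")
}

#' Construct a conformational context directly
#'
#' Convenience constructor for dictionary queries without coordinates. The
#' discrete labels are derived from the continuous variables.
#'
#' @param sugar_type "ribose" or "deoxyribose".
#' @param base_type "purine" or "pyrimidine".
#' @param P,tau_m,chi,gamma conformational variables in degrees.
#' @param terminal_o3,terminal_o5 terminal flags.
#' @return object of class `conformation_context`.
#' @export
conformation_context <- function(sugar_type = "deoxyribose",
                                 base_type = "purine",
                                 P = 160, tau_m = 38, chi = -120, gamma = 60,
                                 terminal_o3 = FALSE, terminal_o5 = FALSE) {
  sugar_type <- match.arg(sugar_type, c("ribose", "deoxyribose"))
  base_type <- match.arg(base_type, c("purine", "pyrimidine"))
  structure(list(
    sugar_type = sugar_type, base_type = base_type,
    pucker_class = classify_pucker(P %% 360),
    chi_rotamer = classify_chi(chi),
    gamma_rotamer = classify_gamma(gamma),
    terminal_o3 = terminal_o3, terminal_o5 = terminal_o5,
    P = P %% 360, tau_m = tau_m, chi = wrap180(chi), gamma = wrap180(gamma)
  ), class = "conformation_context")
}

#' @export
print.conformation_context <- function(x, ...) {
  cat(sprintf(
    "<context %s/%s %s chi:%s gamma:%s P=%.1f tau_m=%.1f chi=%.1f gamma=%.1f%s%s>\n",
    x$sugar_type, x$base_type, x$pucker_class, x$chi_rotamer, x$gamma_rotamer,
    x$P, x$tau_m, x$chi, x$gamma,
    if (x$terminal_o3) " 3'term" else "", if (x$terminal_o5) " 5'term" else ""))
  invisible(x)
}
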