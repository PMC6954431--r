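# Synthetic fragment-geometry tables with the statistical structure the
# derivation pipeline assumes: per-group Gaussian bonds/angles, tau_m-linear
# endocyclic angles, chi-periodic glycosidic geometry, quality metadata and
# optional planted outliers. Used for closed-loop testing of the derivation
# module.

#' Generating specification for the synthetic fragment table
#'
#' A compact known dictionary (a subset of the shipped conformation-dependent
#' library) covering each functional class: a fixed bond, a pucker-split
#' bond, a gamma-split bond, a chi-periodic glycosidic bond, a tau_m-linear
#' endocyclic angle, and a chi-periodic glycosidic angle.
#'
#' @param dict dictionary supplying the generating targets.
#' @param params parameter names drawn from `dict`.
#' @return a `restraint_dictionary` subset used as generating truth.
#' @export
default_generating_spec <- function(dict = load_dictionary("this-work"),
                                    params = c("C1'-C2'", "C3'-C4'",
                                               "C4'-C5'", "C1'-N",
                                               "C3'-C4'-O4'")) {
  d <- dict[dict$parameter %in% params, , drop = FALSE]
  # The planted tau_m-linear dependence is conditioned on pucker class only:
  # sugar-type differences in the endocyclic angles are secondary and keeping
  # them out of the generating truth gives per-group sample sizes at which
  # slope recovery is statistically meaningful at the study's class counts.
  lin <- d$parameter == "C3'-C4'-O4'"
  keep <- !lin | d$sugar == "deoxyribose"
  d <- d[keep, , drop = FALSE]
  lin <- d$parameter == "C3'-C4'-O4'"
  d$sugar[lin] <- "any"
  d$n[lin] <- c("C2'-endo" = 195L, "C3'-endo" = 161L,
                "Other" = 76L)[d$pucker[lin]]
  attr(d, "provenance") <- attr(dict, "provenance")
  d
}

# Truncated-normal-by-rejection sampler (simple, adequate at these scales).
rtruncn <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic fragment-geometry table
#'
#' Draws one row per sugar-base fragment: class membership with the study's
#' sample sizes (130 R-Pu, 51 D-Pu, 84 R-Py, 167 D-Py by default), realistic
#' conformational variables (pucker mixture tied to sugar type, tau_m around
#' 38 +/- 5 degrees, anti-dominated chi, gauche+-dominated gamma), quality
#' metadata within the selection thresholds unless `frac_bad_quality > 0`,
#' and parameter values drawn from the generating dictionary targets
#' evaluated at each row's own conformation plus Gaussian noise at the
#' stored sigma. Optionally plants gross outliers.
#'
#' @param spec generating dictionary (see [default_generating_spec()]).
#' @param n_per_class named counts for the classes R-Pu, D-Pu, R-Py, D-Py.
#' @param outlier_fraction fraction of rows receiving one gross outlier.
#' @param outlier_magnitude outlier size in units of the target sigma.
#' @param frac_bad_quality fraction of extra rows violating the quality
#'   thresholds (appended, to exercise the filter).
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame fragment table: structure_id, R_factor (percent),
#'   sigma_CC (Angstrom), disordered, sugar_type, base_type, P, tau_m, chi,
#'   gamma and one column per generated parameter. Attribute `truth` stores
#'   the generating dictionary, `outlier_rows` the planted outlier rows.
#' @export
generate_synthetic_table <- function(spec = default_generating_spec(),
                                     n_per_class = c("R-Pu" = 130,
                                                     "D-Pu" = 51,
                                                     "R-Py" = 84,
                                                     "D-Py" = 167),
                                     outlier_fraction = 0,
                                     outlier_magnitude = 10,
                                     frac_bad_quality = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- rep(names(n_per_class), n_per_class)
  n <- length(cls)
  sugar <- ifelse(startsWith(cls, "R"), "ribose", "deoxyribose")
  base <- ifelse(endsWith(cls, "Pu"), "purine", "pyrimidine")

  # pucker mixture tied to sugar type (A-form-like riboses, B-form-like
  # deoxyriboses), with an "Other" tail
  pucker <- character(n)
  for (i in seq_len(n)) {
    pr <- if (sugar[i] == "ribose") c(0.62, 0.22, 0.16) else c(0.22, 0.60, 0.18)
    pucker[i] <- sample(c("C3'-endo", "C2'-endo", "Other"), 1, prob = pr)
  }
  P <- numeric(n)
  P[pucker == "C3'-endo"] <- stats::runif(sum(pucker == "C3'-endo"), 2, 34)
  P[pucker == "C2'-endo"] <- stats::runif(sum(pucker == "C2'-endo"), 146, 188)
  P[pucker == "Other"] <- stats::runif(sum(pucker == "Other"), 45, 135)
  tau_m <- rtruncn(n, 38, 5, 22, 48)

  syn <- stats::runif(n) < 0.15
  chi <- ifelse(syn, rtruncn(n, 45, 25, -20, 89),
                wrap180(rtruncn(n, -120, 25, -185, -91)))
  grot <- sample(c("gauche+", "trans", "gauche-", "other"), n, replace = TRUE,
                 prob = c(0.58, 0.25, 0.13, 0.04))
  gamma <- numeric(n)
  gamma[grot == "gauche+"] <- rtruncn(sum(grot == "gauche+"), 60, 10, 31, 89)
  gamma[grot == "trans"] <- wrap180(rtruncn(sum(grot == "trans"), 180, 10,
                                            151, 209))
  gamma[grot == "gauche-"] <- rtruncn(sum(grot == "gauche-"), -60, 10, -89, -31)
  gamma[grot == "other"] <- stats::runif(sum(grot == "other"), -15, 15)

  tab <- data.frame(
    structure_id = sprintf("SYN%04d", seq_len(n)),
    R_factor = stats::runif(n, 4.5, 8.5),
    sigma_CC = stats::runif(n, 0.004, 0.0099),
    disordered = stats::runif(n) < 0.15,
    sugar_type = sugar, base_type = base,
    P = P, tau_m = tau_m, chi = chi, gamma = gamma,
    stringsAsFactors = FALSE)

  params <- unique(spec$parameter)
  for (p in params) tab[[p]] <- NA_real_
  for (i in seq_len(n)) {
    ctx <- conformation_context(sugar_type = sugar[i], base_type = base[i],
                                P = P[i], tau_m = tau_m[i], chi = chi[i],
                                gamma = gamma[i])
    for (p in params) {
      tgt <- suppressWarnings(
        tryCatch(lookup_target(spec, p, ctx), error = function(e) NULL))
      if (is.null(tgt)) next
      ev <- evaluate_target(tgt, ctx)
      tab[[p]][i] <- stats::rnorm(1, ev$value, ev$sigma)
    }
  }

  out_rows <- integer(0)
  if (outlier_fraction > 0) {
    out_rows <- sample(n, max(1, round(outlier_fraction * n)))
    for (i in out_rows) {
      p <- sample(params, 1)
      sg <- stats::sd(tab[[p]], na.rm = TRUE)
      tab[[p]][i] <- tab[[p]][i] + sample(c(-1, 1), 1) * outlier_magnitude * sg
    }
  }

  if (frac_bad_quality > 0) {
    nb <- max(1, round(frac_bad_quality * n))
    bad <- tab[sample(n, nb, replace = TRUE), , drop = FALSE]
    bad$structure_id <- sprintf("BADQ%04d", seq_len(nb))
    half <- seq_len(nb) %% 2 == 0
    bad$R_factor[half] <- stats::runif(sum(half), 8.6, 12)
    bad$sigma_CC[!half] <- stats::runif(sum(!half), 0.01, 0.02)
    tab <- rbind(tab, bad)
    rownames(tab) <- NULL
  }

  attr(tab, "truth") <- spec
  attr(tab, "outlier_rows") <- out_rows
  tab
}

# Representative context at the centre of a dictionary row's conditioning
# cell ('any' columns fall back to deoxyribose/purine/C2'-endo/anti/gauche+).
representative_ctx <- function(row) {
  conformation_context(
    sugar_type = if (row$sugar == "any") "deoxyribose" else row$sugar,
    base_type = if (row$base == "any") "purine" else row$base,
    P = switch(row$pucker, "C3'-endo" = 18, "C2'-endo" = 165, "Other" = 90,
               165),
    tau_m = 38,
    chi = if (row$chi == "syn") 45 else -120,
    gamma = switch(row$gamma, "gauche+" = 60, "gauche-" = -60,
                   "trans" = 180, 60))
}

#' Closed-loop recovery of a known dictionary from synthetic data
#'
#' Generates a synthetic fragment table from a known generating dictionary,
#' re-derives a dictionary with [build_dictionary()], and compares the
#' recovered targets with the generating truth: fixed targets by the
#' recovery error in units of the generating group's standard error of the
#' mean (SEM = sigma/sqrt(N)), linear targets by the relative slope error,
#' and periodic targets by the relative error of the curve's max - min swing
#' over a dense chi grid.
#'
#' @param seed integer seed for the synthetic table.
#' @param spec generating dictionary.
#' @param config a `derivation_config`.
#' @param outlier_fraction passed to [generate_synthetic_table()].
#' @return list with data.frames `fixed` (truth, recovered, err, sem),
#'   `linear` (slope_truth, slope_recovered, rel_err), `periodic`
#'   (range_truth, range_recovered, rel_err, period, form), plus the derived
#'   `dict` and the generated `table`.
#' @export
closed_loop_recovery <- function(seed = 1, spec = default_generating_spec(),
                                 config = derivation_config(),
                                 outlier_fraction = 0) {
  tab <- generate_synthetic_table(spec, outlier_fraction = outlier_fraction,
                                  seed = seed)
  derived <- build_dictionary(quality_filter(tab, config), config)
  labs <- data.frame(sugar = tab$sugar_type, base = tab$base_type,
                     pucker = classify_pucker(tab$P %% 360),
                     chi = classify_chi(tab$chi),
                     gamma = classify_gamma(tab$gamma),
                     stringsAsFactors = FALSE)
  in_group <- function(row) {
    ok <- rep(TRUE, nrow(tab))
    for (f in c("sugar", "base", "pucker", "chi", "gamma"))
      if (row[[f]] != "any") ok <- ok & labs[[f]] == row[[f]]
    which(ok)
  }
  grid <- seq(-179, 180, by = 1)
  fx <- ln <- pd <- list()
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, , drop = FALSE]
    if (row$gamma == "other") next   # pooled fallback rows are not generators
    ctx <- representative_ctx(row)
    lab <- paste(row$parameter, row$sugar, row$base, row$pucker, row$chi,
                 row$gamma)
    dt <- lookup_target(derived, row$parameter, ctx)
    if (row$form == "fixed") {
      # average the derived prediction over the group's own synthetic rows,
      # so that a finer-than-truth derived grouping is N-weighted correctly
      idx <- in_group(row)
      preds <- vapply(idx, function(j) {
        cj <- conformation_context(tab$sugar_type[j], tab$base_type[j],
                                   P = tab$P[j], tau_m = tab$tau_m[j],
                                   chi = tab$chi[j], gamma = tab$gamma[j])
        suppressWarnings(
          evaluate_target(lookup_target(derived, row$parameter, cj),
                          cj)$value)
      }, numeric(1))
      rec <- mean(preds)
      fx[[length(fx) + 1L]] <- data.frame(
        group = lab, truth = row$value, recovered = rec,
        err = rec - row$value, sem = row$sigma / sqrt(row$n))
    } else if (row$form == "linear_tau") {
      dr <- derived[derived$parameter == row$parameter &
                    derived$form == "linear_tau" &
                    (row$pucker == "any" |
                     derived$pucker %in% c("any", row$pucker)), , drop = FALSE]
      rec <- if (nrow(dr) > 0) sum(dr$slope * dr$n) / sum(dr$n) else NA_real_
      ln[[length(ln) + 1L]] <- data.frame(
        group = lab, slope_truth = row$slope, slope_recovered = rec,
        rel_err = abs(rec - row$slope) / abs(row$slope),
        form = dt$form)
    } else {
      tv <- vapply(grid, function(ch)
        evaluate_target(row, list(chi = ch, tau_m = 38))$value, numeric(1))
      dv <- vapply(grid, function(ch)
        evaluate_target(dt, list(chi = ch, tau_m = 38))$value, numeric(1))
      rt <- max(tv) - min(tv)
      rd <- max(dv) - min(dv)
      pd[[length(pd) + 1L]] <- data.frame(
        group = lab, range_truth = rt, range_recovered = rd,
        rel_err = abs(rd - rt) / rt,
        period = if (!is.null(dt$period)) dt$period else NA_real_,
        form = dt$form)
    }
  }
  list(fixed = do.call(rbind, fx), linear = do.call(rbind, ln),
       periodic = do.call(rbind, pd), dict = derived, table = tab)
}
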