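# Restraint dictionary: loading, lookup and evaluation.

DICT_META_COLS <- c("parameter", "kind", "sugar", "base", "pucker", "chi",
                    "gamma", "terminal", "form")

#' Load a restraint dictionary
#'
#' Reads the delimited dictionary file shipped with the package (or a
#' user-supplied file with the same schema) and returns the entries of one
#' provenance. Where a parameter is split by the gamma rotamer, a pooled
#' `gamma = "other"` fallback row is added automatically (N-weighted mean,
#' pooled standard deviation), so that sugars whose gamma falls outside the
#' gauche+/gauche-/trans windows can still be restrained.
#'
#' @param provenance "this-work" (the conformation-dependent library) or
#'   "parkinson" (the 1996 reference compilation).
#' @param path dictionary file; defaults to the file shipped in `extdata`.
#' @return data.frame of class `restraint_dictionary`.
#' @export
load_dictionary <- function(provenance = c("this-work", "parkinson"),
                            path = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(path))
    path <- system.file("extdata", "sugar_dictionary_reconstructed.tsv",
                        package = "sugarcdl", mustWork = TRUE)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  d <- d[d$provenance == provenance, , drop = FALSE]
  if (nrow(d) == 0) stop("no dictionary entries with provenance ", provenance)
  d$curve <- vector("list", nrow(d))
  d <- rbind(d, pooled_gamma_rows(d))
  rownames(d) <- NULL
  class(d) <- c("restraint_dictionary", "data.frame")
  attr(d, "provenance") <- provenance
  d
}

# N-weighted pooling of fixed targets across gamma rotamer levels.
pooled_gamma_rows <- function(d) {
  split_rows <- d[d$gamma != "any" & d$form == "fixed", , drop = FALSE]
  if (nrow(split_rows) == 0) return(d[0, , drop = FALSE])
  key <- interaction(split_rows$parameter, split_rows$sugar, split_rows$base,
                     split_rows$pucker, split_rows$chi, split_rows$terminal,
                     drop = TRUE)
  out <- lapply(split(split_rows, key), function(g) {
    w <- g$n / sum(g$n)
    mu <- sum(w * g$value)
    # pooled variance includes between-group spread of the means
    v <- sum(w * (g$sigma^2 + g$value^2)) - mu^2
    r <- g[1, , drop = FALSE]
    r$gamma <- "other"
    r$value <- mu
    r$sigma <- sqrt(v)
    r$n <- sum(g$n)
    r
  })
  do.call(rbind, out)
}

ctx_match <- function(rows, ctx, parameter) {
  ok <- rep(TRUE, nrow(rows))
  ok <- ok & (rows$sugar == "any" | rows$sugar == ctx$sugar_type)
  ok <- ok & (rows$base == "any" | rows$base == ctx$base_type)
  ok <- ok & (rows$pucker == "any" | rows$pucker == ctx$pucker_class)
  ok <- ok & (rows$chi == "any" | rows$chi == ctx$chi_rotamer)
  ok <- ok & (rows$gamma == "any" | rows$gamma == ctx$gamma_rotamer)
  term <- if (grepl("O5'", parameter)) ctx$terminal_o5 else
          if (grepl("O3'", parameter)) ctx$terminal_o3 else FALSE
  ok & (rows$terminal == "any" | rows$terminal == ifelse(term, "yes", "no"))
}

#' Look up the restraint target for a parameter in a given context
#'
#' Resolves the unique dictionary row whose conditioning variables match the
#' context. Terminal variants of the O3'/O5' parameters are selected when the
#' corresponding terminal flag is set. A gamma rotamer outside the three
#' named windows falls back to the pooled (gamma = "other") target with a
#' warning.
#'
#' @param dict a `restraint_dictionary`.
#' @param parameter dictionary parameter name, e.g. `"C1'-N"` or
#'   `"C4'-C5'-O5'"`.
#' @param ctx a `conformation_context`.
#' @return one-row data.frame (the restraint target).
#' @export
lookup_target <- function(dict, parameter, ctx) {
  rows <- dict[dict$parameter == parameter, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unknown parameter '", parameter, "'; supported: ",
         paste(sort(unique(dict$parameter)), collapse = ", "))
  hit <- rows[ctx_match(rows, ctx, parameter), , drop = FALSE]
  if (nrow(hit) > 0 && ctx$gamma_rotamer == "other" && any(hit$gamma == "other"))
    warning("gamma rotamer outside all windows for ", parameter,
            "; using pooled target", call. = FALSE)
  if (nrow(hit) == 0)
    stop("no dictionary entry for '", parameter, "' in context ",
         paste(ctx$sugar_type, ctx$base_type, ctx$pucker_class,
               ctx$chi_rotamer, ctx$gamma_rotamer))
  if (nrow(hit) > 1) {
    # keep the most specific row (fewest 'any' wildcards)
    n_any <- rowSums(hit[, c("sugar", "base", "pucker", "chi", "gamma",
                             "terminal")] == "any")
    hit <- hit[which.min(n_any), , drop = FALSE]
  }
  hit
}

#' Evaluate a restraint target at a conformational context
#'
#' Fixed targets return their stored value; `linear_tau` targets return
#' `slope * tau_m + intercept`; `periodic_chi` targets evaluate
#' `offset + amp1*cos(2*chi + phase1) + amp2*cos(chi + phase2)` (the dominant
#' harmonic has a 180-degree period, matching the glycosidic-bond behaviour);
#' `curve` targets (produced by the derivation pipeline) interpolate a
#' tabulated periodic grid. A tau_m far outside the fitted range
#' (about 20-50 degrees) is evaluated but flagged as an extrapolation.
#'
#' @param target one-row target as returned by [lookup_target()].
#' @param ctx a `conformation_context` (or a list with `tau_m`/`chi`).
#' @return list with `value`, `sigma` and `extrapolated`.
#' @export
evaluate_target <- function(target, ctx) {
  form <- target$form
  extrap <- FALSE
  sigma <- target$sigma
  if (form == "fixed") {
    value <- target$value
  } else if (form == "linear_tau") {
    stopifnot(!is.null(ctx$tau_m))
    value <- target$slope * ctx$tau_m + target$intercept
    extrap <- ctx$tau_m < 20 || ctx$tau_m > 50
  } else if (form == "periodic_chi") {
    stopifnot(!is.null(ctx$chi))
    chi <- ctx$chi
    value <- target$offset +
      target$amp1 * cos((2 * chi + target$phase1) * pi / 180) +
      target$amp2 * cos((chi + target$phase2) * pi / 180)
  } else if (form == "curve") {
    cv <- target$curve[[1]]
    chi <- wrap180(ctx$chi)
    value <- interp_periodic(cv$x, cv$mean, chi)
    sigma <- interp_periodic(cv$x, cv$sd, chi)
  } else {
    stop("unknown target form: ", form)
  }
  list(value = value, sigma = sigma, extrapolated = extrap)
}

# Linear interpolation on a periodic grid over (-180, 180].
interp_periodic <- function(x, y, at) {
  xx <- c(x, x[1] + 360)
  yy <- c(y, y[1])
  at <- ((at - x[1]) %% 360) + x[1]
  stats::approx(xx, yy, xout = at, rule = 2)$y
}

#' Generate the full restraint record set for a list of fragments
#'
#' For each measured, classified fragment every applicable dictionary
#' parameter is looked up and evaluated at the fragment's own conformational
#' variables. Non-terminal C3'-O3' and C5'-O5' bonds belong to the
#' phosphodiester moiety and are outside this dictionary; they are skipped.
#' Parameters whose atoms are absent (O2' on deoxyribose) are skipped.
#'
#' @param fragments list of `sugar_fragment` objects.
#' @param dict a `restraint_dictionary` (default: the shipped
#'   conformation-dependent library).
#' @return data.frame with one row per (fragment, parameter): fragment
#'   identity and atom selectors, `kind`, measured value, `ideal` and `sigma`.
#' @export
build_full_restraint_set <- function(fragments, dict = load_dictionary()) {
  out <- list()
  for (frag in fragments) {
    meas <- measure_fragment(frag)
    ctx <- classify_fragment(frag, meas)
    measured <- c(meas$bonds, meas$angles)
    kinds <- c(rep("bond", length(meas$bonds)),
               rep("angle", length(meas$angles)))
    for (i in seq_along(measured)) {
      par <- names(measured)[i]
      if (par == "C3'-O3'" && !frag$terminal_o3) next
      if (par == "C5'-O5'" && !frag$terminal_o5) next
      tgt <- tryCatch(lookup_target(dict, par, ctx), error = function(e) NULL)
      if (is.null(tgt)) next
      ev <- evaluate_target(tgt, ctx)
      atoms <- parameter_atoms(par, frag)
      out[[length(out) + 1L]] <- data.frame(
        chain = frag$chain, resno = frag$resno, insert = frag$insert,
        resid = frag$resid, altloc = frag$altloc,
        parameter = par, kind = kinds[i],
        atom1 = atoms[1], atom2 = atoms[2],
        atom3 = if (length(atoms) > 2) atoms[3] else "",
        measured = unname(measured[i]),
        ideal = ev$value, sigma = ev$sigma,
        extrapolated = ev$extrapolated,
        occupancy = frag$occupancy, multi_conf = frag$multi_conf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      altloc = character(), parameter = character(),
                      kind = character(), atom1 = character(),
                      atom2 = character(), atom3 = character(),
                      measured = numeric(), ideal = numeric(),
                      sigma = numeric(), extrapolated = logical(),
                      occupancy = numeric(), multi_conf = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # deterministic ordering: chain, residue, insertion, altloc, parameter
  res[order(res$chain, res$resno, res$insert, res$altloc, res$parameter), ,
      drop = FALSE]
}
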