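# Statistical pipeline deriving a restraint dictionary from a
# fragment-geometry table: quality filtering, robust outlier rejection,
# Welch subgroup discovery, Spearman functional screening, and
# Gaussian-process / Bayesian-ridge fitting.

FRAGTABLE_META <- c("structure_id", "R_factor", "sigma_CC", "disordered",
                    "sugar_type", "base_type", "P", "tau_m", "chi", "gamma")

#' Configuration of the derivation pipeline
#'
#' @param alpha_t Welch t-test significance level.
#' @param alpha_s Spearman screen significance level.
#' @param rho_min minimum |rho| for a functional relation.
#' @param r_max maximum crystallographic R factor (percent), inclusive.
#' @param sigma_cc_max maximum mean e.s.d. of C-C bonds (Angstrom), exclusive.
#' @param z_threshold modified Z-score rejection threshold.
#' @param min_group minimum group size; smaller cells are merged.
#' @param noise_bounds white-noise standard-deviation search bounds for the
#'   Gaussian-process fit.
#' @param periods candidate periods (degrees) of the exp-sine-squared kernel.
#' @return list of class `derivation_config`.
#' @export
derivation_config <- function(alpha_t = 0.05, alpha_s = 0.05, rho_min = 0.5,
                              r_max = 8.5, sigma_cc_max = 0.01,
                              z_threshold = 3.5, min_group = 5,
                              noise_bounds = c(1e-7, 1e7),
                              periods = c(180, 360)) {
  stopifnot(alpha_t > 0, alpha_s > 0, rho_min > 0, r_max > 0,
            sigma_cc_max > 0, z_threshold > 0, all(noise_bounds > 0))
  structure(list(alpha_t = alpha_t, alpha_s = alpha_s, rho_min = rho_min,
                 r_max = r_max, sigma_cc_max = sigma_cc_max,
                 z_threshold = z_threshold, min_group = min_group,
                 noise_bounds = noise_bounds, periods = periods),
            class = "derivation_config")
}

#' Quality filter for a fragment table
#'
#' Keeps rows with `R_factor <= r_max` (inclusive) and
#' `sigma_CC < sigma_cc_max` (strict). Disordered structures are retained:
#' restricting to non-disordered structures shrinks the sample and raises the
#' standard error of the mean more than it helps.
#'
#' @param table fragment table (see [generate_synthetic_table()]).
#' @param config a `derivation_config`.
#' @return the filtered table.
#' @export
quality_filter <- function(table, config = derivation_config()) {
  if (!all(c("R_factor", "sigma_CC") %in% names(table)))
    stop("fragment table lacks quality columns R_factor/sigma_CC")
  table[table$R_factor <= config$r_max &
        table$sigma_CC < config$sigma_cc_max, , drop = FALSE]
}

#' Modified Z-scores and outlier flags
#'
#' M_i = 0.6745 (x_i - median) / median|x_j - median|; an observation is an
#' outlier when |M_i| > threshold. When the median absolute deviation is zero
#' the formula's limit is applied: any value differing from the median is
#' flagged.
#'
#' @param x numeric sample (length >= 3 for a meaningful median).
#' @param threshold rejection threshold (default 3.5).
#' @return list with `m` (scores), `outlier` (logical flags), `median`, `mad`.
#' @export
modified_zscore_outliers <- function(x, threshold = 3.5) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    m <- ifelse(x == med, 0, Inf * sign(x - med))
  } else {
    m <- 0.6745 * (x - med) / mad0
  }
  list(m = m, outlier = abs(m) > threshold, median = med, mad = mad0)
}

# Structure-level outlier removal: a structure is dropped when any of its
# parameters is an outlier within its sugar-base class.
remove_outlier_structures <- function(table, params,
                                      config = derivation_config()) {
  cls <- interaction(table$sugar_type, table$base_type, drop = TRUE)
  bad <- character(0)
  for (p in params) {
    for (lv in levels(cls)) {
      i <- which(cls == lv & is.finite(table[[p]]))
      if (length(i) < 3) next
      fl <- modified_zscore_outliers(table[[p]][i], config$z_threshold)$outlier
      bad <- union(bad, table$structure_id[i[fl]])
    }
  }
  out <- table[!(table$structure_id %in% bad), , drop = FALSE]
  attr(out, "removed_structures") <- bad
  out
}

#' Pairwise Welch tests across the levels of a grouping factor
#'
#' Two-sided Welch t-tests (no equal-variance assumption) between every pair
#' of groups. The factor is accepted when strictly more than half of the
#' testable pairs are significant at `alpha`. A zero-variance pair yields the
#' degenerate limit (p = 0 for different means, p = 1 otherwise) and is
#' flagged.
#'
#' @param groups named list of numeric samples (each of size >= 2).
#' @param alpha significance level.
#' @return list with `pairs` (data.frame: a, b, p), `accepted`, `min_p`,
#'   `n_tests`.
#' @export
welch_split <- function(groups, alpha = 0.05) {
  nm <- names(groups)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]], p = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    ga <- groups[[pairs[1, k]]]
    gb <- groups[[pairs[2, k]]]
    if (stats::var(ga) == 0 && stats::var(gb) == 0) {
      res$p[k] <- if (mean(ga) == mean(gb)) 1 else 0
      res$degenerate[k] <- TRUE
    } else {
      res$p[k] <- stats::t.test(ga, gb, var.equal = FALSE)$p.value
    }
  }
  list(pairs = res, accepted = sum(res$p < alpha) > nrow(res) / 2,
       min_p = min(res$p), n_tests = nrow(res))
}

#' Spearman screen for a functional relationship
#'
#' Passes when |rho| > rho_min and the correlation is significantly
#' different from zero at `alpha_s`. Ties are handled by average ranks.
#'
#' @param x conformational variable (degrees).
#' @param y parameter values.
#' @param config a `derivation_config`.
#' @return list of class `correlation_result`: `rho`, `p_value`, `pass`, `n`.
#' @export
spearman_screen <- function(x, y, config = derivation_config()) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 pass = abs(ct$estimate) > config$rho_min &&
                        ct$p.value < config$alpha_s,
                 n = length(x)), class = "correlation_result")
}

# ---- regression fits -------------------------------------------------------

# Bayesian ridge regression (evidence-maximizing, MacKay fixed point) for a
# single centred predictor; equivalent to a Gaussian process with a linear
# kernel.
bayes_ridge_fit <- function(x, y, max_iter = 200, tol = 1e-10) {
  xb <- mean(x); yb <- mean(y)
  xc <- x - xb; yc <- y - yb
  n <- length(y)
  sxx <- sum(xc^2); sxy <- sum(xc * yc)
  alpha <- 1e-6
  beta <- 1 / max(stats::var(yc), 1e-12)
  m <- 0
  for (it in seq_len(max_iter)) {
    A <- alpha + beta * sxx
    m_new <- beta * sxy / A
    gam <- beta * sxx / A
    rss <- sum((yc - m_new * xc)^2)
    alpha <- gam / max(m_new^2, 1e-12)
    beta <- max(n - gam, 1e-6) / max(rss, 1e-12)
    if (abs(m_new - m) < tol) { m <- m_new; break }
    m <- m_new
  }
  list(slope = m, intercept = yb - m * xb, sigma = sqrt(1 / beta),
       n = n)
}

exp_sine2_kernel <- function(d, period, lengthscale, sf2) {
  sf2 * exp(-2 * sin(pi * d / period)^2 / lengthscale^2)
}

# Gaussian-process regression with an exp-sine-squared kernel plus white
# noise. Hyperparameters (period, length-scale, signal variance, noise level)
# are selected by maximizing the log marginal likelihood over a grid; the
# noise grid spans the configured bounds and is refined around the sample
# standard deviation.
gpr_periodic_fit <- function(x, y, config = derivation_config(),
                             grid_step = 2) {
  yb <- mean(y)
  yc <- y - yb
  n <- length(y)
  sdy <- stats::sd(yc)
  lb <- config$noise_bounds
  noise <- sort(unique(pmin(pmax(
    c(10^seq(log10(lb[1]), log10(lb[2]), by = 2),
      sdy * c(0.3, 0.6, 1, 1.4)), lb[1]), lb[2])))
  cand <- expand.grid(period = config$periods, ls = c(0.7, 1.5),
                      sf = c(0.3, 1))
  D <- abs(outer(x, x, "-"))
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    K0 <- exp_sine2_kernel(D, cand$period[i], cand$ls[i],
                           cand$sf[i] * sdy^2)
    for (sn in noise) {
      K <- K0 + diag(sn^2 + 1e-12, n)
      U <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(U)) next
      a <- backsolve(U, forwardsolve(t(U), yc))
      lml <- -0.5 * sum(yc * a) - sum(log(diag(U))) - n / 2 * log(2 * pi)
      if (is.null(best) || lml > best$lml)
        best <- list(lml = lml, period = cand$period[i], ls = cand$ls[i],
                     sf2 = cand$sf[i] * sdy^2, noise = sn, U = U, a = a)
    }
  }
  if (is.null(best)) {  # non-convergent search: widest-noise fallback
    warning("GPR hyperparameter search failed; flat widest-noise fallback")
    xs <- seq(-180, 180 - grid_step, by = grid_step)
    return(list(period = max(config$periods), lml = NA,
                grid = data.frame(x = xs, mean = yb,
                                  sd = stats::sd(y)), fallback = TRUE))
  }
  xs <- seq(-180, 180 - grid_step, by = grid_step)
  Ds <- abs(outer(xs, x, "-"))
  Ks <- exp_sine2_kernel(Ds, best$period, best$ls, best$sf2)
  mu <- as.numeric(Ks %*% best$a) + yb
  V <- backsolve(best$U, t(Ks), transpose = TRUE)   # solve(t(U), t(Ks))
  pv <- best$sf2 + best$noise^2 - colSums(V^2)
  list(period = best$period, lengthscale = best$ls, noise = best$noise,
       sf2 = best$sf2, lml = best$lml,
       grid = data.frame(x = xs, mean = mu, sd = sqrt(pmax(pv, 1e-12))),
       fallback = FALSE)
}

# Least-squares cosine approximation a*cos(k*chi + b) + c of a fitted curve,
# for reporting (k = 2 for a 180-degree period, 1 for 360).
cosine_approximation <- function(grid, period) {
  k <- if (period == 180) 2 else 1
  th <- k * grid$x * pi / 180
  fit <- stats::lm(grid$mean ~ cos(th) + sin(th))
  cc <- stats::coef(fit)
  a <- sqrt(cc[2]^2 + cc[3]^2)
  b <- atan2(-cc[3], cc[2]) * 180 / pi
  c(a = unname(a), b = unname(wrap180(b)), c = unname(cc[1]))
}

#' Fit a functional restraint target
#'
#' Linear relations (on tau_m) are fitted by evidence-maximizing Bayesian
#' ridge regression; periodic relations (on chi or gamma) by Gaussian-process
#' regression with an exp-sine-squared kernel (periods 180/360 degrees)
#' plus a white-noise kernel, the model being selected by log marginal
#' likelihood. Data are mean-normalized internally and de-normalized on
#' output.
#'
#' @param x predictor values (degrees).
#' @param y parameter values (Angstrom or degrees).
#' @param kind "linear" or "periodic".
#' @param config a `derivation_config`.
#' @return for "linear": list(form, slope, intercept, sigma, n); for
#'   "periodic": list(form, period, grid, cosine (a, b, c), sigma, n, lml).
#' @export
fit_functional <- function(x, y, kind = c("linear", "periodic"),
                           config = derivation_config()) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    fit <- bayes_ridge_fit(x, y)
    return(list(form = "linear_tau", slope = fit$slope,
                intercept = fit$intercept, sigma = fit$sigma, n = fit$n))
  }
  fit <- gpr_periodic_fit(wrap180(x), y, config)
  list(form = "curve", period = fit$period, grid = fit$grid,
       cosine = cosine_approximation(fit$grid, fit$period),
       sigma = stats::median(fit$grid$sd), n = length(y), lml = fit$lml,
       fallback = isTRUE(fit$fallback))
}

# ---- dictionary construction ----------------------------------------------

FACTOR_COLS <- c(sugar = "sugar_type", base = "base_type",
                 pucker = "pucker_class", chi = "chi_rotamer",
                 gamma = "gamma_rotamer")
FUNC_VARS <- c(tau_m = "linear", chi = "periodic", gamma = "periodic")

derive_labels <- function(table) {
  table$pucker_class <- classify_pucker(table$P %% 360)
  table$chi_rotamer <- classify_chi(table$chi)
  table$gamma_rotamer <- classify_gamma(table$gamma)
  table
}

# Discrete factor search for one parameter: single accepted factor with the
# smallest p, upgraded to a two-factor combination when the majority of the
# stratified pairwise tests (cells differing in one factor while the other is
# held fixed, e.g. ribose C2'-endo vs ribose C3'-endo) are also significant.
# Stratification is what protects the search against confounding through the
# unbalanced class composition of the sample.
search_factors <- function(tab, param, config) {
  cand <- list()
  n_tests <- 0
  for (f in names(FACTOR_COLS)) {
    col <- tab[[FACTOR_COLS[[f]]]]
    keep <- col != "other"
    gr <- split(tab[[param]][keep], col[keep])
    gr <- gr[lengths(gr) >= max(2, config$min_group)]
    if (length(gr) < 2) next
    ws <- welch_split(gr, config$alpha_t)
    n_tests <- n_tests + ws$n_tests
    if (ws$accepted) cand[[f]] <- ws$min_p
  }
  if (length(cand) == 0)
    return(list(factors = character(0), n_tests = n_tests))
  ord <- names(sort(unlist(cand)))
  if (length(ord) >= 2) {
    c1 <- tab[[FACTOR_COLS[[ord[1]]]]]
    c2 <- tab[[FACTOR_COLS[[ord[2]]]]]
    keep <- c1 != "other" & c2 != "other"
    key <- paste(c1, c2, sep = "\r")[keep]
    y <- tab[[param]][keep]
    cells <- split(y, key)
    cells <- cells[lengths(cells) >= max(2, config$min_group)]
    lev <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
    p1 <- p2 <- numeric(0)   # pairs differing in factor 1 / factor 2 only
    if (length(cells) >= 2) {
      for (i in seq_len(length(cells) - 1)) {
        for (j in seq(i + 1, length(cells))) {
          d1 <- lev[i, 1] != lev[j, 1]
          d2 <- lev[i, 2] != lev[j, 2]
          if (d1 == d2) next   # must differ in exactly one factor
          ws <- welch_split(cells[c(i, j)], config$alpha_t)
          if (d1) p1 <- c(p1, ws$min_p) else p2 <- c(p2, ws$min_p)
          n_tests <- n_tests + 1
        }
      }
    }
    maj <- function(p) length(p) > 0 && sum(p < config$alpha_t) > length(p) / 2
    if (maj(p1) && maj(p2))
      return(list(factors = ord[1:2], n_tests = n_tests))
  }
  list(factors = ord[1], n_tests = n_tests)
}

#' Derive a restraint dictionary from a fragment-geometry table
#'
#' For each parameter column the pipeline (i) removes structures containing a
#' modified-Z-score outlier in any parameter, (ii) searches the discrete
#' grouping factors (sugar type, base type, pucker class, chi and gamma
#' rotamers) by pairwise Welch tests with the majority rule for factor
#' combinations, (iii) screens the continuous variables (tau_m, chi, gamma)
#' by Spearman correlation within the accepted groups (majority rule across
#' groups), and (iv) fits either a fixed mean/sigma per group, a Bayesian
#' ridge line in tau_m, or a Gaussian-process periodic curve in chi/gamma.
#' When a functional dependence on chi (or gamma) is accepted, the discrete
#' rotamer split of the same variable is dropped and the function is fitted
#' across the union of its rotamer subgroups, since the continuous form
#' subsumes the discrete one. Groups smaller than `min_group` are merged into
#' an unconditioned parent row and flagged.
#'
#' @param table fragment table (already quality-filtered; see
#'   [quality_filter()]).
#' @param config a `derivation_config`.
#' @param params parameter columns to process (default: all non-metadata
#'   columns).
#' @return a `restraint_dictionary` with provenance "derived"; attribute
#'   `report` holds per-parameter diagnostics (chosen factors, p-values, rho,
#'   model, sample sizes, number of tests).
#' @export
build_dictionary <- function(table, config = derivation_config(),
                             params = NULL) {
  table <- derive_labels(table)
  if (is.null(params))
    params <- setdiff(names(table), c(FRAGTABLE_META, "pucker_class",
                                      "chi_rotamer", "gamma_rotamer"))
  table <- remove_outlier_structures(table, params, config)
  rows <- list()
  report <- list()
  for (param in params) {
    tab <- table[is.finite(table[[param]]), , drop = FALSE]
    kind <- if (grepl("-.*-", param)) "angle" else "bond"
    fs <- search_factors(tab, param, config)
    factors <- fs$factors

    # functional screen within accepted groups (majority rule); cyclic
    # variables are additionally stratified by their own rotamer, since a
    # periodic relation is monotone only within a rotamer range
    grp_of <- function(factors) {
      if (length(factors) == 0) rep("all", nrow(tab))
      else interaction(tab[FACTOR_COLS[factors]], drop = TRUE)
    }
    func_var <- NA_character_
    func_rho <- NA_real_
    for (v in names(FUNC_VARS)) {
      strat <- switch(v, chi = "chi", gamma = "gamma", NULL)
      g <- grp_of(unique(c(factors, strat)))
      res <- lapply(split(seq_len(nrow(tab)), g), function(i) {
        if (length(i) < 10) return(NULL)
        spearman_screen(tab[[v]][i], tab[[param]][i], config)
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res) == 0) next
      npass <- sum(vapply(res, `[[`, logical(1), "pass"))
      if (npass > length(res) / 2) {
        rho <- max(abs(vapply(res, `[[`, numeric(1), "rho")))
        if (is.na(func_rho) || rho > abs(func_rho)) {
          func_var <- v
          func_rho <- rho
        }
      }
    }
    # a continuous dependence subsumes the discrete split of its own rotamer
    if (!is.na(func_var)) {
      drop_f <- switch(func_var, chi = "chi", gamma = "gamma", tau_m = NULL)
      if (!is.null(drop_f) && drop_f %in% factors) {
        factors <- setdiff(factors, drop_f)
      }
    }

    g <- grp_of(factors)
    merged <- character(0)
    for (lv in levels(factor(g))) {
      i <- which(g == lv)
      if (length(i) < config$min_group) {
        merged <- c(merged, lv)
        next
      }
      row <- empty_dict_row(param, kind)
      if (length(factors) > 0) {
        levs <- strsplit(lv, ".", fixed = TRUE)[[1]]
        for (k in seq_along(factors)) row[[factors[k]]] <- levs[k]
      }
      y <- tab[[param]][i]
      if (is.na(func_var)) {
        row$form <- "fixed"
        row$value <- mean(y)
        row$sigma <- stats::sd(y)
        row$n <- length(y)
        row$curve <- list(NULL)
      } else if (FUNC_VARS[[func_var]] == "linear") {
        fit <- fit_functional(tab[[func_var]][i], y, "linear", config)
        row$form <- "linear_tau"
        row$slope <- fit$slope
        row$intercept <- fit$intercept
        row$sigma <- fit$sigma
        row$n <- fit$n
        row$curve <- list(NULL)
      } else {
        fit <- fit_functional(tab[[func_var]][i], y, "periodic", config)
        row$form <- "curve"
        row$amp1 <- unname(fit$cosine["a"])
        row$phase1 <- unname(fit$cosine["b"])
        row$offset <- unname(fit$cosine["c"])
        row$sigma <- fit$sigma
        row$n <- fit$n
        row$curve <- list(fit$grid)
        row$period <- fit$period
      }
      rows[[length(rows) + 1L]] <- row
    }
    if (length(merged) > 0) {
      # merged parent row over the full sample, flagged
      row <- empty_dict_row(param, kind)
      row$form <- "fixed"
      row$value <- mean(tab[[param]])
      row$sigma <- stats::sd(tab[[param]])
      row$n <- nrow(tab)
      row$curve <- list(NULL)
      rows[[length(rows) + 1L]] <- row
    }
    report[[param]] <- list(factors = factors, min_p = NULL,
                            func_var = func_var, rho = func_rho,
                            n_tests = fs$n_tests, merged_cells = merged,
                            n = nrow(tab))
  }
  d <- do.call(rbind, rows)
  class(d) <- c("restraint_dictionary", "data.frame")
  attr(d, "provenance") <- "derived"
  attr(d, "report") <- report
  attr(d, "removed_structures") <- attr(table, "removed_structures")
  d
}

empty_dict_row <- function(param, kind) {
  data.frame(parameter = param, kind = kind, sugar = "any", base = "any",
             pucker = "any", chi = "any", gamma = "any", terminal = "any",
             form = "fixed", value = NA_real_, slope = NA_real_,
             intercept = NA_real_, amp1 = NA_real_, phase1 = NA_real_,
             amp2 = NA_real_, phase2 = NA_real_, offset = NA_real_,
             sigma = NA_real_, n = NA_integer_, provenance = "derived",
             basis = "derived", period = NA_real_,
             curve = I(list(NULL)), stringsAsFactors = FALSE)
}

#' Sampling diagnostics: SEM and standard deviation versus the R cutoff
#'
#' Report-only diagnostic of the quality-threshold trade-off: for each
#' candidate R-factor cutoff, the average standard error of the mean and the
#' average standard deviation of every parameter, per sugar-base class.
#'
#' @param table fragment table.
#' @param r_grid candidate R-factor cutoffs (percent).
#' @param params parameter columns (default: all non-metadata columns).
#' @return data.frame with columns r_max, class, mean_sem, mean_sd, n.
#' @export
sampling_diagnostics <- function(table, r_grid = seq(4.5, 10, by = 0.5),
                                 params = NULL) {
  if (is.null(params))
    params <- setdiff(names(table), c(FRAGTABLE_META, "pucker_class",
                                      "chi_rotamer", "gamma_rotamer"))
  cls <- interaction(table$sugar_type, table$base_type, drop = TRUE)
  out <- list()
  for (r in r_grid) {
    keep <- table$R_factor <= r
    for (lv in levels(cls)) {
      i <- which(keep & cls == lv)
      if (length(i) < 3) next
      sds <- vapply(params, function(p) stats::sd(table[[p]][i]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        r_max = r, class = lv, mean_sem = mean(sds) / sqrt(length(i)),
        mean_sd = mean(sds), n = length(i))
    }
  }
  do.call(rbind, out)
}
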