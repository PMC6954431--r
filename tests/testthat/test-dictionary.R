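dict <- load_dictionary("this-work")
park <- load_dictionary("parkinson")

test_that("terminal and non-terminal targets reproduce the published values", {
  anti_gp_term <- conformation_context(chi = -120, gamma = 60,
                                       terminal_o5 = TRUE)
  anti_gp <- conformation_context(chi = -120, gamma = 60)
  expect_equal(lookup_target(dict, "C4'-C5'-O5'", anti_gp_term)$value, 111.5)
  expect_equal(lookup_target(dict, "C4'-C5'-O5'", anti_gp)$value, 110.6)
  expect_equal(lookup_target(dict, "C5'-O5'", anti_gp_term)$value, 1.421)
})

test_that("evaluate handles the three target forms", {
  lin <- data.frame(form = "linear_tau", slope = -0.2, intercept = 110.0,
                    sigma = 1.0)
  ev <- evaluate_target(lin, list(tau_m = 35))
  expect_equal(ev$value, 103.0)
  expect_false(ev$extrapolated)
  expect_true(evaluate_target(lin, list(tau_m = 60))$extrapolated)
  fx <- data.frame(form = "fixed", value = 1.5, sigma = 0.01)
  expect_equal(evaluate_target(fx, list())$value, 1.5)
  per <- data.frame(form = "periodic_chi", amp1 = 0.01, phase1 = 0,
                    amp2 = 0, phase2 = 0, offset = 1.46, sigma = 0.01)
  expect_equal(evaluate_target(per, list(chi = 0))$value, 1.47)
  expect_equal(evaluate_target(per, list(chi = 90))$value, 1.45)
})

test_that("glycosidic bond curves have a 180-degree period with extremes near +/-90", {
  rows <- dict[dict$form == "periodic_chi" & dict$kind == "bond", ]
  expect_gt(nrow(rows), 0)
  chi <- seq(-180, 179.5, by = 0.5)
  for (i in seq_len(nrow(rows))) {
    v <- vapply(chi, function(ch)
      evaluate_target(rows[i, ], list(chi = ch))$value, numeric(1))
    v2 <- vapply(chi, function(ch)
      evaluate_target(rows[i, ], list(chi = ch + 180))$value, numeric(1))
    expect_equal(v, v2, tolerance = 1e-9)
    ext <- chi[which.min(v)]
    expect_lt(min(abs(abs(ext) - 90)), 5)   # extremes close to |chi| = 90
  }
})

test_that("glycosidic cosine amplitudes span the published envelope", {
  rows <- dict[dict$form == "periodic_chi" & dict$kind == "bond", ]
  expect_true(all(rows$amp1 >= 0.007 & rows$amp1 <= 0.018))
  expect_equal(max(2 * rows$amp1), 0.036)
})

test_that("all tau_m-linear angle targets have negative slope within the published range", {
  rows <- dict[dict$form == "linear_tau", ]
  expect_gt(nrow(rows), 10)
  expect_true(all(rows$slope < 0))
  expect_true(all(rows$slope >= -0.241 & rows$slope <= -0.088))
  expect_equal(max(abs(rows$slope)) * 20, 4.82, tolerance = 1e-9)
})

test_that("lookup is total over every conformational context", {
  combos <- expand.grid(sugar = c("ribose", "deoxyribose"),
                        base = c("purine", "pyrimidine"),
                        P = c(18, 165, 90),
                        chi = c(-120, 45),
                        gamma = c(60, -60, 180, 10),
                        t3 = c(TRUE, FALSE), t5 = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  bonds <- c("C1'-C2'", "C2'-C3'", "C3'-C4'", "C4'-O4'", "C1'-O4'",
             "C4'-C5'", "C1'-N")
  angles <- c("C1'-C2'-C3'", "C2'-C3'-C4'", "C3'-C4'-O4'", "C4'-O4'-C1'",
              "O4'-C1'-C2'", "C2'-C3'-O3'", "C4'-C3'-O3'", "C3'-C4'-C5'",
              "O4'-C4'-C5'", "C4'-C5'-O5'", "N-C1'-C2'", "N-C1'-O4'",
              "C1'-N-C2/C4", "C1'-N-C6/C8")
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    ctx <- conformation_context(cc$sugar, cc$base, P = cc$P, tau_m = 38,
                                chi = cc$chi, gamma = cc$gamma,
                                terminal_o3 = cc$t3, terminal_o5 = cc$t5)
    pars <- c(bonds, angles,
              if (cc$sugar == "ribose") c("C2'-O2'", "C1'-C2'-O2'",
                                          "C3'-C2'-O2'"),
              if (cc$t3) "C3'-O3'", if (cc$t5) "C5'-O5'")
    for (p in pars) {
      tgt <- suppressWarnings(lookup_target(dict, p, ctx))
      ev <- evaluate_target(tgt, ctx)
      expect_true(is.finite(ev$value), label = paste(p, "value", i))
      expect_gt(tgt$sigma, 0)
    }
  }
})

test_that("a gamma rotamer outside all windows falls back to the pooled target", {
  ctx <- conformation_context(chi = -120, gamma = 10)   # gamma 'other'
  expect_warning(tgt <- lookup_target(dict, "C4'-C5'", ctx), "pooled")
  g <- dict[dict$parameter == "C4'-C5'" & dict$gamma %in%
              c("gauche+", "gauche-", "trans"), ]
  expect_equal(tgt$value, sum(g$value * g$n) / sum(g$n), tolerance = 1e-9)
  expect_gt(tgt$sigma, max(0, min(g$sigma)))   # pooled spread >= within-group
})

test_that("unknown parameters raise an error listing the supported ones", {
  expect_error(lookup_target(dict, "C9'-C8'", conformation_context()),
               "supported")
})

test_that("restraint sets cover the schema and respect terminal overrides", {
  at <- build_nucleotide(sugar_type = "deoxyribose", base_type = "purine")
  frag <- extract_fragments(at)[[1]]     # isolated residue: both ends terminal
  rec <- build_full_restraint_set(list(frag), dict)
  expect_false(any(grepl("O2'", rec$parameter)))   # no O2' on deoxyribose
  expect_true(all(c("C3'-O3'", "C5'-O5'") %in% rec$parameter))
  expect_equal(rec$ideal[rec$parameter == "C5'-O5'"], 1.421)

  # same residue embedded in a chain: interior fragment loses the
  # phosphoester bonds (they belong to the phosphodiester dictionary)
  chain <- build_chain(n = 3, free_5prime = FALSE)
  frags <- extract_fragments(chain)
  interior <- frags[[2]]
  expect_false(interior$terminal_o3 || interior$terminal_o5)
  rec2 <- build_full_restraint_set(list(interior), dict)
  expect_false(any(rec2$parameter %in% c("C3'-O3'", "C5'-O5'")))
  expect_true("C2'-C3'-O3'" %in% rec2$parameter)   # angles are still restrained
})

test_that("an empty fragment list yields an empty restraint set", {
  rec <- build_full_restraint_set(list(), dict)
  expect_equal(nrow(rec), 0)
})

test_that("the reference dictionary loads and resolves the same contexts", {
  ctx <- conformation_context(chi = -120, gamma = 60, terminal_o5 = TRUE)
  expect_equal(lookup_target(park, "C5'-O5'", ctx)$value, 1.440)
  expect_true(is.finite(lookup_target(park, "C1'-N", ctx)$value))
})
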