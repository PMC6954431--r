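# A dictionary whose fixed targets equal a model's own measured geometry:
# scoring that model against it must give zero deviations.
self_dictionary <- function(frag) {
  m <- measure_fragment(frag)
  vals <- c(m$bonds, m$angles)
  kinds <- c(rep("bond", length(m$bonds)), rep("angle", length(m$angles)))
  d <- do.call(rbind, lapply(seq_along(vals), function(i)
    data.frame(parameter = names(vals)[i], kind = kinds[i], sugar = "any",
               base = "any", pucker = "any", chi = "any", gamma = "any",
               terminal = "any", form = "fixed", value = unname(vals[i]),
               slope = NA, intercept = NA, amp1 = NA, phase1 = NA, amp2 = NA,
               phase2 = NA, offset = NA, sigma = 0.01, n = 10L,
               provenance = "self", basis = "derived",
               stringsAsFactors = FALSE)))
  d$curve <- vector("list", nrow(d))
  class(d) <- c("restraint_dictionary", "data.frame")
  attr(d, "provenance") <- "self"
  d
}

test_that("a model scored against its own geometry has zero RMSD", {
  frag <- extract_fragments(build_nucleotide())[[1]]
  dict <- self_dictionary(frag)
  rep0 <- score_model(list(frag), dict)
  expect_equal(rep0$rmsd_bonds, 0, tolerance = 1e-12)
  expect_equal(rep0$rmsd_angles, 0, tolerance = 1e-12)
})

test_that("a single offset bond follows the closed-form RMSD", {
  frag <- extract_fragments(build_nucleotide())[[1]]
  dict <- self_dictionary(frag)
  i <- which(dict$parameter == "C1'-C2'")
  dict$value[i] <- dict$value[i] + 0.01
  rep1 <- score_model(list(frag), dict)
  expect_equal(rep1$rmsd_bonds, 0.01 / sqrt(rep1$n_bonds), tolerance = 1e-9)
  expect_equal(rep1$rmsd_angles, 0)
  # decomposition invariant: rmsd^2 * n = sum of squared deviations
  b <- rep1$records[rep1$records$kind == "bond", ]
  expect_equal(rep1$rmsd_bonds^2 * rep1$n_bonds, sum(b$delta^2),
               tolerance = 1e-12)
})

test_that("the well-ordered filter excludes partial-occupancy fragments", {
  frags <- extract_fragments(make_altloc_residue())
  dict <- load_dictionary()
  expect_error(score_model(frags, dict), NA)
  rep_all <- suppressWarnings(score_model(frags, dict,
                                          well_ordered_only = FALSE))
  expect_gt(nrow(rep_all$records), 0)
  rep_wo <- tryCatch(suppressWarnings(score_model(frags, dict)),
                     error = function(e) NULL)
  if (!is.null(rep_wo)) expect_lt(nrow(rep_wo$records),
                                  nrow(rep_all$records))
})

test_that("the same model scored against both libraries yields paired reports", {
  frags <- extract_fragments(make_dinucleotide())
  a <- score_model(frags, load_dictionary("this-work"))
  b <- score_model(frags, load_dictionary("parkinson"))
  expect_equal(nrow(a$records), nrow(b$records))
  cmp <- compare_dictionaries(a, b)
  expect_true(is.finite(cmp$angles$p_value))
  expect_true(all(a$records$abs_delta >= 0))
})

test_that("identical reports compare as no difference with p = 1", {
  frags <- extract_fragments(build_nucleotide())
  a <- score_model(frags, load_dictionary())
  cmp <- compare_dictionaries(a, a)
  expect_equal(cmp$bonds$p_value, 1)
  expect_equal(cmp$angles$p_value, 1)
  expect_equal(cmp$angles$median_diff, 0)
})

test_that("Wilcoxon comparison agrees with an exact enumeration oracle", {
  # paired |deltas| where b exceeds a on every pair
  set.seed(61)
  da <- runif(50, 0, 1)
  db <- da + runif(50, 0.05, 0.3)
  p <- suppressWarnings(wilcox.test(da, db, paired = TRUE)$p.value)
  expect_lt(p, 0.001)

  # exact oracle by full sign enumeration at n = 12 (no ties)
  d <- c(0.8, -0.2, 1.1, 0.5, -0.4, 0.9, 1.3, 0.7, -0.1, 0.6, 1.0, 0.35)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 12))
  Vall <- as.matrix(signs) %*% r
  p_exact <- mean(abs(Vall - sum(r) / 2) >= abs(V - sum(r) / 2))
  p_impl <- wilcox.test(d, alternative = "two.sided", exact = TRUE)$p.value
  expect_equal(p_impl, p_exact, tolerance = 1e-12)

  # one-sided direction agrees with a planted median shift
  set.seed(62)
  x <- rnorm(40); y <- x + 0.5 + rnorm(40, 0, 0.2)
  p_less <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                         alternative = "less")$p.value)
  p_greater <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                            alternative = "greater")$p.value)
  expect_lt(p_less, 0.01)
  expect_gt(p_greater, 0.5)
})

test_that("unpaired reports are rejected", {
  frags <- extract_fragments(make_dinucleotide())
  a <- score_model(frags, load_dictionary())
  b <- score_model(frags[1], load_dictionary())
  expect_error(compare_dictionaries(a, b), "paired")
})

test_that("closed-loop scoring RMSD is consistent with the generating noise", {
  cl <- closed_loop_cached(1)
  tab <- cl$table
  # residuals of the synthetic observations around the derived targets
  for (p in c("C1'-C2'", "C3'-C4'")) {
    pred <- vapply(seq_len(nrow(tab)), function(j) {
      cj <- conformation_context(tab$sugar_type[j], tab$base_type[j],
                                 P = tab$P[j], tau_m = tab$tau_m[j],
                                 chi = tab$chi[j], gamma = tab$gamma[j])
      suppressWarnings(
        evaluate_target(lookup_target(cl$dict, p, cj), cj)$value)
    }, numeric(1))
    rmsd <- sqrt(mean((tab[[p]] - pred)^2))
    sig <- mean(attr(tab, "truth")$sigma[attr(tab, "truth")$parameter == p])
    expect_lt(abs(rmsd - sig) / sig, 0.15)
  }
})

test_that("deviation reports serialize to JSON and a plot-ready table", {
  frags <- extract_fragments(make_dinucleotide())
  repo <- score_model(frags, load_dictionary())
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_deviation_report(repo, jp, tp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$rmsd_angles, repo$rmsd_angles, tolerance = 1e-9)
  tb <- read.delim(tp)
  expect_equal(nrow(tb), nrow(repo$records))
  unlink(c(jp, tp))
})
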