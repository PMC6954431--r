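cfg <- derivation_config()

test_that("quality filter applies the published thresholds with the printed strictness", {
  tab <- data.frame(structure_id = paste0("S", 1:3),
                    R_factor = c(8.0, 8.5, 9.0),
                    sigma_CC = c(0.005, 0.005, 0.005))
  expect_equal(quality_filter(tab, cfg)$structure_id, c("S1", "S2"))
  tab$R_factor <- 5
  tab$sigma_CC <- c(0.005, 0.01, 0.0099)       # 0.01 exactly is rejected
  expect_equal(quality_filter(tab, cfg)$structure_id, c("S1", "S3"))
  expect_equal(nrow(quality_filter(tab[0, ], cfg)), 0)
  expect_error(quality_filter(data.frame(x = 1), cfg), "quality columns")
})

test_that("tightening the R cutoff never increases the retained rows", {
  set.seed(5)
  tab <- generate_synthetic_table(seed = 99, frac_bad_quality = 0.3)
  counts <- vapply(seq(10, 4, by = -0.5), function(r)
    nrow(quality_filter(tab, derivation_config(r_max = r))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("modified Z-score flags the hand-computed outlier", {
  res <- modified_zscore_outliers(c(1, 2, 3, 4, 100))
  # median 3, MAD 1, M(100) = 0.6745 * 97
  expect_equal(res$median, 3)
  expect_equal(res$mad, 1)
  expect_equal(res$m[5], 0.6745 * 97)
  expect_equal(sum(res$outlier), 1)
  expect_true(res$outlier[5])
})

test_that("modified Z-score degenerate and symmetry behaviour", {
  expect_equal(sum(modified_zscore_outliers(c(5, 5, 5, 5))$outlier), 0)
  # MAD = 0 with a deviating point: the deviator is flagged (formula limit)
  res <- modified_zscore_outliers(c(5, 5, 5, 5, 6))
  expect_true(res$outlier[5])
  expect_equal(sum(res$outlier), 1)
  # odd symmetry: flags invariant under x -> -x
  set.seed(8)
  x <- c(rnorm(20), 9)
  expect_equal(modified_zscore_outliers(-x)$outlier,
               modified_zscore_outliers(x)$outlier)
})

test_that("Welch split agrees with the closed-form Welch t-test", {
  a <- c(1, 2, 3); expect_equal(welch_split(list(a = a, b = a))$pairs$p, 1)
  set.seed(42)
  g1 <- rnorm(200); g2 <- rnorm(200, 0.5)
  ws <- welch_split(list(a = g1, b = g2), 0.05)
  # independent oracle: Welch statistic and Satterthwaite df by hand
  se2 <- var(g1) / 200 + var(g2) / 200
  tstat <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((var(g1) / 200)^2 / 199 + (var(g2) / 200)^2 / 199)
  p_oracle <- 2 * pt(-abs(tstat), df)
  expect_equal(ws$pairs$p, p_oracle, tolerance = 1e-12)
  expect_true(ws$accepted)
  # degenerate zero-variance pair
  wd <- welch_split(list(a = c(1, 1), b = c(2, 2)))
  expect_true(wd$pairs$degenerate)
  expect_equal(wd$pairs$p, 0)
})

test_that("Spearman screen passes monotone relations and rejects noise", {
  x <- 1:50
  s <- spearman_screen(x, x^3, cfg)
  expect_equal(s$rho, 1)
  expect_true(s$pass)
  set.seed(13)
  s2 <- spearman_screen(rnorm(200), rnorm(200), cfg)
  expect_false(s2$pass)
  s3 <- spearman_screen(x, -0.2 * x + rnorm(50, 0, 0.1), cfg)
  expect_lt(s3$rho, -0.95)
  expect_true(s3$pass)
})

test_that("linear fits recover the generating slope", {
  set.seed(31)
  x <- runif(300, 25, 45)
  y <- -0.15 * x + 112 + rnorm(300, 0, 0.3)
  fit <- fit_functional(x, y, "linear", cfg)
  expect_equal(fit$form, "linear_tau")
  expect_lt(abs(fit$slope - (-0.15)), 0.02)
  expect_lt(abs(fit$sigma - 0.3), 0.08)
})

test_that("periodic fits recover amplitude and select the 180-degree period", {
  set.seed(32)
  chi <- runif(300, -180, 180)
  y <- 0.012 * cos(2 * chi * pi / 180) + 1.46 + rnorm(300, 0, 0.004)
  fit <- fit_functional(chi, y, "periodic", cfg)
  expect_equal(fit$period, 180)
  swing <- max(fit$grid$mean) - min(fit$grid$mean)
  expect_lt(abs(swing - 0.024) / 0.024, 0.2)
  expect_equal(unname(fit$cosine["c"]), 1.46, tolerance = 0.002)
})

test_that("a two-harmonic angle curve is recovered from well-spread torsions", {
  set.seed(33)
  chi <- runif(400, -180, 180)
  truth <- function(ch) 113.6 + 1.2 * cos((2 * ch + 10) * pi / 180) +
    0.8 * cos((ch + 25) * pi / 180)
  y <- truth(chi) + rnorm(400, 0, 1.0)
  fit <- fit_functional(chi, y, "periodic", cfg)
  expect_equal(fit$period, 360)   # asymmetric curve needs the full period
  tv <- truth(fit$grid$x)
  expect_lt(sqrt(mean((fit$grid$mean - tv)^2)), 0.5)
})

test_that("a constant signal yields a near-flat curve with sigma near the sample SD", {
  set.seed(34)
  y <- 108 + rnorm(200, 0, 1.2)
  fit <- fit_functional(runif(200, -180, 180), y, "periodic", cfg)
  expect_lt(max(fit$grid$mean) - min(fit$grid$mean), 0.8)
  expect_lt(abs(fit$sigma - 1.2) / 1.2, 0.35)
})

test_that("synthetic tables honour the study design and are reproducible", {
  tab <- generate_synthetic_table(seed = 77)
  expect_equal(nrow(tab), 432)
  expect_equal(sum(tab$sugar_type == "ribose" & tab$base_type == "purine"), 130)
  expect_equal(sum(tab$sugar_type == "deoxyribose" & tab$base_type == "purine"), 51)
  expect_equal(sum(tab$sugar_type == "ribose" & tab$base_type == "pyrimidine"), 84)
  expect_equal(sum(tab$sugar_type == "deoxyribose" & tab$base_type == "pyrimidine"), 167)
  tab2 <- generate_synthetic_table(seed = 77)
  expect_identical(tab, tab2)
  # without planted outliers the robust test flags (almost) nothing
  fl <- modified_zscore_outliers(tab[["C1'-C2'"]])$outlier
  expect_lt(mean(fl), 0.01)
})

test_that("a parameter with no planted differences yields a single-group target", {
  spec1 <- default_generating_spec(params = "C1'-C2'")
  tab <- generate_synthetic_table(spec1, seed = 55)
  dd <- build_dictionary(tab, cfg)
  rows <- dd[dd$parameter == "C1'-C2'", ]
  expect_equal(nrow(rows), 1)
  expect_equal(rows$form, "fixed")
  expect_equal(unname(unlist(rows[, c("sugar", "base", "pucker", "chi",
                                      "gamma")])),
               rep("any", 5))
})

test_that("a planted chi dependence selects the periodic form for the glycosidic bond", {
  dd <- closed_loop_cached(1)$dict
  rows <- dd[dd$parameter == "C1'-N", ]
  expect_true(all(rows$form == "curve"))
  expect_setequal(rows$base, c("purine", "pyrimidine"))
})
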