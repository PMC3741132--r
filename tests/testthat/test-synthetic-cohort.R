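# Generator parameterization, marginal recovery, coupling, planted signal.

test_that("packaged marginals carry the published summary values", {
  m <- table1_marginals()
  expect_equal(m$AD$biomarker_params$homocysteine$mean, 22.3)
  expect_equal(m$AD$biomarker_params$homocysteine$ci_half_width, 4.7)
  expect_equal(m$control$biomarker_params$homocysteine$mean, 16.2)
  expect_equal(m$AD$biomarker_params$folate$mean, 6.2)
  expect_equal(m$control$biomarker_params$folate$mean, 6.8)
  expect_equal(m$AD$biomarker_params$vitamin_b12$mean, 401.3)
  expect_equal(m$control$biomarker_params$vitamin_b12$mean, 404.9)
  expect_equal(unname(m$AD$genotype_freqs$MTHFR_C677T),
               c(28, 40, 32) / 100)
  # triples normalized to sum 1 in both groups
  for (g in names(m$AD$genotype_freqs)) {
    expect_equal(sum(m$AD$genotype_freqs[[g]]), 1)
    expect_equal(sum(m$control$genotype_freqs[[g]]), 1)
  }
})

test_that("derive_sd matches the closed form and its preconditions", {
  # frozen oracle: 4.7 * sqrt(40) / 1.959964 computed independently
  expect_equal(derive_sd(4.7, 40), 15.16630, tolerance = 1e-6)
  expect_error(derive_sd(-1, 40), "positive")
  expect_error(derive_sd(0, 40), "positive")
  expect_error(derive_sd(1.959964, 1), ">= 2")
  # linear in half-width at fixed n
  expect_equal(derive_sd(2 * 4.7, 40), 2 * derive_sd(4.7, 40))
})

test_that("generation is seed-deterministic and positive", {
  a <- generate_cohort(n_per_group = 30, seed = 123)
  b <- generate_cohort(n_per_group = 30, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(n_per_group = 30, seed = 124)
  expect_false(identical(a, c))
  big <- generate_cohort(n_per_group = 2000, seed = 3)
  for (bm in c("folate", "homocysteine", "vitamin_b12"))
    expect_true(all(big[[bm]] > 0))
})

test_that("large-sample marginals recover the printed values", {
  cohort <- generate_cohort(n_per_group = 10000, seed = 42)
  ad <- cohort[cohort$group == "AD", ]
  ct <- cohort[cohort$group == "control", ]
  expect_equal(mean(ad$homocysteine), 22.3, tolerance = 0.01)
  expect_equal(mean(ct$homocysteine), 16.2, tolerance = 0.01)
  expect_equal(mean(ad$folate), 6.2, tolerance = 0.01)
  expect_equal(mean(ad$vitamin_b12), 401.3, tolerance = 0.01)
  # genotype frequencies within 1.5 points of the printed percentages
  expect_lt(abs(100 * mean(ad$MTHFR_C677T == "TT") - 32), 1.5)
  expect_lt(abs(100 * mean(ct$MTHFR_C677T == "CC") - 38), 1.5)
  # zero-probability class never drawn
  expect_equal(sum(cohort$MTHFR_A1298C == "CC"), 0)
})

test_that("independent generation has near-zero rank correlations", {
  cohort <- generate_cohort(n_per_group = 10000, seed = 7)
  ad <- cohort[cohort$group == "AD", ]
  pairs <- combn(c("folate", "homocysteine", "vitamin_b12"), 2)
  for (j in seq_len(ncol(pairs))) {
    r <- cor(ad[[pairs[1, j]]], ad[[pairs[2, j]]], method = "spearman")
    expect_lt(abs(r), 0.03)
  }
})

test_that("requested coupling is recovered within 0.05 at n = 10,000", {
  cohort <- generate_cohort(n_per_group = 10000, seed = 11,
                            coupling = coupling_preset_literature())
  for (g in c("AD", "control")) {
    sub <- cohort[cohort$group == g, ]
    expect_equal(cor(sub$folate, sub$homocysteine, method = "spearman"),
                 -0.5, tolerance = 0.1)
    expect_lt(abs(cor(sub$folate, sub$homocysteine, method = "spearman") + 0.5),
              0.05)
    expect_lt(abs(cor(sub$folate, sub$vitamin_b12, method = "spearman") - 0.5),
              0.05)
    # uncoupled pair stays near independence
    expect_lt(abs(cor(sub$homocysteine, sub$vitamin_b12, method = "spearman")),
              0.05)
  }
})

test_that("coupling validation rejects malformed requests", {
  expect_error(coupling_spec("folate", "folate", 0.5), "distinct")
  expect_error(coupling_spec("folate", "homocysteine", 1), "\\(-1, 1\\)")
  expect_error(generate_cohort(n_per_group = 5, seed = 1,
                               coupling = coupling_spec("folate", "nope", 0.3)),
               "unknown generator dimension")
})

test_that("planted signal columns have the closed-form AUC", {
  # theoretical single-column AUC for a 3 sd shift: pnorm(3 / sqrt(2))
  ps <- planted_signal_cohort(100, 5, 25, effect = 3, seed = 21)
  expect_equal(length(ps$informative), 30)
  expect_equal(sum(ps$informative), 5)
  auc <- function(x, y) {
    r <- rank(x)
    n1 <- sum(y == "AD")
    (sum(r[y == "AD"]) - n1 * (n1 + 1) / 2) / (n1 * sum(y != "AD"))
  }
  for (j in 1:5)
    expect_gt(auc(ps$x[, j], ps$labels), 0.95)
  theory <- pnorm(3 / sqrt(2))
  emp <- mean(vapply(1:5, function(j) auc(ps$x[, j], ps$labels), numeric(1)))
  expect_equal(emp, theory, tolerance = 0.02)
  # null case: no column separates the classes strongly
  null <- planted_signal_cohort(100, 5, 25, effect = 0, seed = 22)
  aucs <- vapply(seq_len(30), function(j) auc(null$x[, j], null$labels),
                 numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.15))
})

test_that("summaries mirror the generator's inputs at large n", {
  cohort <- generate_cohort(n_per_group = 10000, seed = 13)
  s <- summarize_cohort(cohort)
  expect_equal(nrow(s), 3 + 27)
  expect_equal(s$AD_mean[s$parameter == "homocysteine"], 22.3,
               tolerance = 0.01)
  expect_equal(s$control_mean[s$parameter == "folate"], 6.8,
               tolerance = 0.01)
  # percentages per polymorphism partition to 100
  geno_rows <- s[-(1:3), ]
  for (g in unique(sub("_(wild_type|heterozygous|mutant)$", "",
                       geno_rows$parameter))) {
    trip <- geno_rows[startsWith(geno_rows$parameter, paste0(g, "_")), ]
    trip <- trip[sub(paste0("^", g, "_"), "", trip$parameter) %in%
                   c("wild_type", "heterozygous", "mutant"), ]
    expect_equal(sum(trip$AD_mean), 100, tolerance = 1e-9)
  }
  small <- summarize_cohort(generate_cohort(n_per_group = 40, seed = 1))
  expect_true(all(is.finite(small$AD_ci[1:3])))
})
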