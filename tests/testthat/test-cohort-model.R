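# Genotype coding, biomarker scaling, complement coding, matrix assembly.

test_that("panel validation enforces distinct labels and unique names", {
  expect_s3_class(mini_panel(), "ocm_panel")
  expect_error(polymorphism_panel(data.frame(
    name = "X", rsid = "rs1", wild = "AA", het = "AA", mut = "GG")),
    "pairwise distinct")
  expect_error(polymorphism_panel(data.frame(
    name = c("X", "X"), rsid = c("a", "b"),
    wild = c("AA", "CC"), het = c("AG", "CT"), mut = c("GG", "TT"))),
    "unique")
  expect_equal(nrow(default_panel()), 9)
})

test_that("genotype one-hot coding matches the worked AA/GG/AG example", {
  d <- encode_genotypes(mini_cohort(), mini_panel())
  block <- unclass(d)[, c("MTRR_A66G_wild_type", "MTRR_A66G_heterozygous",
                          "MTRR_A66G_mutant")]
  expect_equal(unname(block),
               rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)))
  expect_equal(ncol(d), 6)
  expect_true(all(attr(d, "provenance") == "genotype-indicator"))
})

test_that("coding errors name the subject and polymorphism", {
  bad <- mini_cohort()
  bad$MTRR_A66G[2] <- "AT"
  expect_error(encode_genotypes(bad, mini_panel()), "s2.*AT.*MTRR_A66G")
  bad2 <- mini_cohort()
  bad2$MTRR_A66G[1] <- NA
  expect_error(encode_genotypes(bad2, mini_panel()), "s1.*MTRR_A66G")
  expect_error(encode_genotypes(mini_cohort()[, -3], mini_panel()), "missing")
})

test_that("indicator column sums equal direct genotype tallies", {
  cohort <- generate_cohort(n_per_group = 20, seed = 11)
  panel <- default_panel()
  d <- encode_genotypes(cohort, panel)
  expect_equal(nrow(d), 40)
  for (i in seq_len(nrow(panel))) {
    labs <- c(panel$wild[i], panel$het[i], panel$mut[i])
    tally <- vapply(labs, function(l) sum(cohort[[panel$name[i]]] == l),
                    numeric(1))
    cols <- paste(panel$name[i], c("wild_type", "heterozygous", "mutant"),
                  sep = "_")
    expect_equal(unname(colSums(unclass(d)[, cols])), unname(tally))
    expect_equal(sum(tally), nrow(cohort))
  }
})

test_that("one-hot partition and decode round trip hold on generated cohorts", {
  panel <- default_panel()
  for (seed in c(1, 2, 3)) {
    cohort <- generate_cohort(n_per_group = 15, seed = seed)
    d <- encode_genotypes(cohort, panel)
    for (i in seq_len(nrow(panel))) {
      cols <- paste(panel$name[i], c("wild_type", "heterozygous", "mutant"),
                    sep = "_")
      expect_true(all(rowSums(unclass(d)[, cols]) == 1))
    }
    decoded <- decode_genotypes(d, panel)
    for (g in panel$name)
      expect_equal(decoded[[g]], cohort[[g]])
  }
})

test_that("min-max scaling maps extremes to 0/1 and inverts exactly", {
  d <- scale_biomarkers(mini_cohort(), "folate")
  expect_equal(unname(unclass(d)[, "folate"]), c(0, 0.5, 1))
  const <- mini_cohort(); const$folate <- 7
  expect_error(scale_biomarkers(const, "folate"), "constant")
  cohort <- generate_cohort(n_per_group = 25, seed = 5)
  scaled <- scale_biomarkers(cohort)
  raw <- unscale_biomarkers(scaled)
  for (b in c("folate", "homocysteine", "vitamin_b12"))
    expect_equal(unname(raw[, b]), cohort[[b]], tolerance = 1e-12)
})

test_that("complement coding doubles columns and pairs sum to 1", {
  scaled <- scale_biomarkers(mini_cohort())
  both <- add_complements(scaled)
  expect_equal(ncol(both), 6)
  expect_equal(colnames(both)[4:6],
               c("folate_LOW", "homocysteine_LOW", "vitamin_b12_LOW"))
  vals <- unclass(both)
  expect_equal(vals[, 1:3] + vals[, 4:6], matrix(1, 3, 3),
               ignore_attr = TRUE)
  expect_equal(attr(both, "provenance"),
               rep(c("scaled-biomarker", "complement-biomarker"), each = 3))
  expect_error(add_complements(matrix(c(0.5, 1.2), 1)), "\\[0, 1\\]")
})

test_that("classification matrix is 30 columns with the right provenance", {
  cohort <- generate_cohort(n_per_group = 10, seed = 2)
  x <- assemble_classification_matrix(cohort)
  expect_equal(ncol(x), 30)
  prov <- table(attr(x, "provenance"))
  expect_equal(prov[["genotype-indicator"]], 27)
  expect_equal(prov[["scaled-biomarker"]], 3)
  expect_true(all(unclass(x) >= 0 & unclass(x) <= 1))
  expect_error(assemble_classification_matrix(cohort[0, ]), "no records")
})

test_that("Auto-CM matrix is 35 columns with one-hot class indicators", {
  cohort <- generate_cohort(n_per_group = 10, seed = 2)
  x <- assemble_autocm_matrix(cohort)
  expect_equal(ncol(x), 35)
  cls <- unclass(x)[, c("AD", "control")]
  expect_true(all(rowSums(cls) == 1))
  expect_equal(unname(cls[, "AD"]),
               as.numeric(attr(x, "class_labels") == "AD"))
  expect_true(all(unclass(x) >= 0 & unclass(x) <= 1))
})

test_that("identical cohorts yield identical matrices; CSV IO round-trips", {
  cohort <- generate_cohort(n_per_group = 8, seed = 9)
  a <- assemble_classification_matrix(cohort)
  b <- assemble_classification_matrix(cohort)
  expect_identical(a, b)
  csv <- tempfile(fileext = ".csv")
  write_design(a, csv)
  back <- read_design(csv)
  expect_equal(unclass(back), unclass(a), tolerance = 1e-9)
  expect_equal(attr(back, "provenance"), attr(a, "provenance"))
  expect_equal(attr(back, "class_labels"), attr(a, "class_labels"))
  co_csv <- tempfile(fileext = ".csv")
  write_cohort(cohort, co_csv)
  expect_equal(read_cohort(co_csv), cohort, tolerance = 1e-12)
})
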