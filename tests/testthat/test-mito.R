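# Mito-nuclear concordance: clade frequencies, concordance table, exact
# habitat association test.

test_that("clade frequencies exclude unknowns and mark empty locales missing", {
  tab <- data.frame(
    individual_id = paste0("i", 1:9),
    locale = c("A", "A", "A", "A", "B", "B", "C", "C", "C"),
    habitat = c(rep("savanna", 6), rep("forest", 3)),
    mt_clade = c("F", "F", "S", "S", "unknown", "unknown", "F", "F", "unknown"))
  cf <- clade_frequencies(tab)
  expect_equal(cf$s_clade_proportion[cf$locale == "A"], 0.5)
  expect_true(is.na(cf$s_clade_proportion[cf$locale == "B"]))
  expect_identical(cf$s_clade_present[cf$locale == "B"], FALSE)
  expect_equal(cf$s_clade_proportion[cf$locale == "C"], 0)
  # presence <=> proportion > 0
  done <- !is.na(cf$s_clade_proportion)
  expect_identical(cf$s_clade_present[done], cf$s_clade_proportion[done] > 0)
})

test_that("generator forest locales have zero S-clade proportion", {
  sim <- simulate_dataset(sim_config(seed = 77))
  cf <- clade_frequencies(sim$samples)
  expect_true(all(cf$s_clade_proportion[cf$habitat == "forest"] == 0))
})

test_that("concordance table measures deviation from the diagonal", {
  clades <- data.frame(locale = c("F1", "S1", "S2"),
                       habitat = c("forest", "savanna", "savanna"),
                       n = c(10, 10, 10), n_classified = c(10, 10, 10),
                       s_clade_proportion = c(0, 0, 0.5),
                       s_clade_present = c(FALSE, FALSE, TRUE))
  means <- data.frame(locale = c("F1", "S1", "S2"),
                      habitat = c("forest", "savanna", "savanna"),
                      n = c(10, 10, 10),
                      cluster1 = c(1, 0, 0.5), cluster2 = c(0, 1, 0.5))
  ct <- concordance_table(clades, means, "cluster2")
  # concordant forest locale sits at the origin
  expect_identical(ct$deviation[ct$locale == "F1"], 0)
  # savanna locale fixed for F-clade mtDNA but pure savanna nuclear: +1,
  # the maximal mito-nuclear discordance
  expect_identical(ct$deviation[ct$locale == "S1"], 1)
  # perfectly concordant locale: 0
  expect_identical(ct$deviation[ct$locale == "S2"], 0)
  expect_error(concordance_table(clades[1:2, ], means, "cluster2"),
               "locale sets")
})

test_that("fisher_exact_2x2 matches hand enumeration and brute force", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  # the habitat-by-clade table built from 0/30 forest and 34/51 non-forest
  expect_lt(fisher_exact_2x2(0, 34, 30, 17), 1e-4)
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_error(fisher_exact_2x2(1, 2, -1, 4), "non-negative")

  # brute-force oracle via the hypergeometric density on all margins N <= 30
  brute <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    xs <- max(0, c1 - (n - r1)):min(r1, c1)
    pr <- dhyper(xs, r1, n - r1, c1)
    sum(pr[pr <= dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
  }
  set.seed(4)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d), brute(a, b, c, d),
                 tolerance = 1e-9)
    # cross-check a subsample against stats::fisher.test
    if (rep <= 40) {
      expect_equal(fisher_exact_2x2(a, b, c, d),
                   fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                   tolerance = 1e-7)
    }
  }
})

test_that("fisher p is invariant to transposition and double label swap", {
  cases <- list(c(3, 7, 9, 2), c(1, 9, 9, 1), c(12, 4, 3, 11))
  for (x in cases) {
    p <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_2x2(x[1], x[3], x[2], x[4]), p) # transpose
    expect_equal(fisher_exact_2x2(x[4], x[3], x[2], x[1]), p) # swap both
  }
})

test_that("habitat association recovers the forest exclusion pattern", {
  # generator output: S absent in forest, common in savanna
  sim <- simulate_dataset(sim_config(seed = 19))
  assoc <- habitat_association(clade_frequencies(sim$samples))
  expect_identical(assoc$table["S_present", "forest"], 0L)
  expect_lt(assoc$p, 0.01)

  # repeated seeds: significant in nearly all runs
  ps <- vapply(1:12, function(s) {
    sim <- simulate_dataset(sim_config(
      n_forest_locales = 5, n_savanna_locales = 17, n_mixed_locales = 0,
      individuals_per_locale = 10, n_loci = 2, savanna_Fclade_rate = 0.20,
      seed = s + 300))
    habitat_association(clade_frequencies(sim$samples))$p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.95)

  # all locales on one habitat side
  one_side <- data.frame(habitat = c("savanna", "savanna"),
                         s_clade_present = c(TRUE, FALSE),
                         n_classified = c(5, 5))
  expect_error(habitat_association(one_side), "habitat side")
})

test_that("discordance holds on generator output: habitat, not mtDNA,
           predicts nuclear ancestry", {
  sim <- simulate_dataset(sim_config(seed = 29))
  cf <- clade_frequencies(sim$samples)
  truthQ <- sim$truth$true_Q[, "savanna"]
  means <- vapply(cf$locale, function(lc) {
    mean(truthQ[sim$samples$individual_id[sim$samples$locale == lc]])
  }, numeric(1))
  sav <- cf$habitat == "savanna"
  # among savanna locales S-clade share varies while nuclear ancestry is
  # constant at 1, so the two are uncorrelated there
  expect_true(all(means[sav] == 1))
  expect_gt(stats::sd(cf$s_clade_proportion[sav]), 0)
  # across habitats, habitat predicts nuclear ancestry essentially exactly
  expect_true(all(means[cf$habitat == "forest"] == 0))
})
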