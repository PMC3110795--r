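# Synthetic-data generator: drift model, backcross arithmetic, maternal
# mtDNA transmission, and the structural contracts of simulate_dataset.

test_that("species frequency drift keeps the ancestral mean and validates F", {
  anc <- list(L1 = c(a = 0.5, b = 0.5))

  # F -> 0+: concentration -> infinity, pools collapse onto the ancestor
  tiny <- simulate_species_freqs(anc, 1e-6, seed = 1)
  expect_lt(max(abs(tiny$forest$L1 - 0.5)), 1e-2)
  expect_lt(max(abs(tiny$savanna$L1 - 0.5)), 1e-2)

  # Dirichlet mean is the ancestral vector (Monte-Carlo oracle)
  set.seed(2)
  draws <- replicate(1e4, simulate_species_freqs(anc, 0.3)$forest$L1[["a"]])
  # var of a Balding-Nichols frequency is p(1-p)F = 0.075; MC error ~ 0.003
  expect_lt(abs(mean(draws) - 0.5), 4 * sqrt(0.25 * 0.3 / 1e4) + 1e-3)

  expect_error(simulate_species_freqs(anc, 1.2), "divergence_F")
  expect_error(simulate_species_freqs(anc, 0), "divergence_F")
  expect_error(simulate_species_freqs(list(c(0.5, 0.4)), 0.3), "sum to 1")

  # rows always sum to 1
  fr <- simulate_species_freqs(list(c(0.2, 0.3, 0.5)), 0.9, seed = 3)
  expect_equal(sum(fr$forest[[1]]), 1)
  expect_equal(sum(fr$savanna[[1]]), 1)
})

test_that("backcross ancestry halves each generation", {
  expect_identical(simulate_backcross_fraction(0), 0.5)
  expect_identical(simulate_backcross_fraction(2), 0.125)
  expect_identical(simulate_backcross_fraction(6), 0.0078125)
  expect_lt(simulate_backcross_fraction(6), 0.01)
  expect_error(simulate_backcross_fraction(-1), "non-negative")
  expect_error(simulate_backcross_fraction(1.5), "integer")
})

test_that("mtDNA assignment enforces the forest / hybrid-lineage constraints", {
  # forest individuals always F, regardless of pedigree or seed
  for (seed in 1:5) {
    expect_identical(
      assign_mtdna(rep("forest", 50), rep("pure_forest", 50), seed = seed),
      rep("F", 50))
  }
  # hybrid lineages carry F through the maternal line in any habitat
  expect_identical(
    assign_mtdna(c("savanna", "mixed", "savanna"),
                 c("F1", "backcross_2", "backcross_5"), seed = 9),
    rep("F", 3))
  # pure savanna: F-clade share matches the configured rate (binomial oracle)
  draws <- assign_mtdna(rep("savanna", 2000), rep("pure_savanna", 2000),
                        savanna_Fclade_rate = 0.20, seed = 4)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.20) / 2000
  expect_gte(mean(draws == "F"), ci[1])
  expect_lte(mean(draws == "F"), ci[2])
  expect_error(assign_mtdna("swamp", "pure_savanna"), "habitat")
})

test_that("simulate_dataset honours its structural contracts", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_dataset(cfg)

  expect_identical(sum(!duplicated(sim$samples$locale) &
                         sim$samples$habitat == "forest"),
                   cfg$n_forest_locales)
  expect_identical(nrow(sim$samples),
                   (cfg$n_forest_locales + cfg$n_savanna_locales +
                      cfg$n_mixed_locales) * cfg$individuals_per_locale)
  # no forest individual carries S
  expect_false(any(sim$samples$mt_clade[sim$samples$habitat == "forest"] == "S"))
  # truth rows sum to 1, pedigree consistent with Q
  expect_equal(unname(rowSums(sim$truth$true_Q)), rep(1, nrow(sim$truth$true_Q)))
  hyb <- sim$truth$pedigree_class %in% c("F1") |
    startsWith(sim$truth$pedigree_class, "backcross")
  expect_identical(unname(hyb),
                   unname(sim$truth$true_Q[, "forest"] > 0 &
                            sim$truth$true_Q[, "forest"] < 1))

  # determinism: same seed, byte-identical output
  expect_identical(sim, simulate_dataset(sim_config(seed = 5)))
  # different seed differs
  expect_false(identical(sim$genotypes,
                         simulate_dataset(sim_config(seed = 6))$genotypes))
})

test_that("hybrid fraction is constructed exactly and only in mixed locales", {
  cfg <- sim_config(individuals_per_locale = 20, hybrid_fraction_mixed = 0.2,
                    seed = 8)
  sim <- simulate_dataset(cfg)
  q <- sim$truth$true_Q[, "forest"]
  frac_hybrid <- mean(q > 0 & q < 1)
  n_mixed <- sum(sim$samples$habitat == "mixed")
  expect_identical(frac_hybrid * nrow(sim$samples),
                   round(0.2 * n_mixed))
  mixed_ids <- sim$samples$individual_id[sim$samples$habitat == "mixed"]
  expect_true(all(names(q)[q > 0 & q < 1] %in% mixed_ids))
  # backcross truth follows (1/2)^(g+1) exactly
  bc <- grep("^backcross_", sim$truth$pedigree_class)
  g <- as.integer(sub("backcross_", "", sim$truth$pedigree_class[bc]))
  expect_identical(unname(q[bc]), 0.5^(g + 1))

  # no hybrids requested -> every truth row is a vertex
  sim0 <- simulate_dataset(sim_config(hybrid_fraction_mixed = 0, seed = 8))
  q0 <- sim0$truth$true_Q[, "forest"]
  expect_true(all(q0 %in% c(0, 1)))
})

test_that("empirical pure-pool frequencies converge to the species pools", {
  err_for_n <- function(n) {
    sim <- simulate_dataset(sim_config(
      n_forest_locales = 1, n_savanna_locales = 1, n_mixed_locales = 0,
      individuals_per_locale = n, n_loci = 6, missing_rate = 0, seed = 31))
    fids <- sim$samples$individual_id[sim$samples$habitat == "forest"]
    emp <- allele_freqs(sim$genotypes, fids)
    mean(vapply(seq_along(emp), function(l) {
      truth <- sim$truth$species_freqs$forest[[l]]
      e <- truth * 0
      e[names(emp[[l]])] <- emp[[l]]
      sum(abs(e - truth))
    }, numeric(1)))
  }
  errs <- vapply(c(20, 200, 2000), err_for_n, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("forest locales never receive S clade across many seeds", {
  # structural invariant, checked exhaustively over seeds with a small config
  for (seed in 1:25) {
    sim <- simulate_dataset(sim_config(
      n_forest_locales = 2, n_savanna_locales = 3, n_mixed_locales = 1,
      individuals_per_locale = 8, n_loci = 4, seed = seed))
    expect_false(any(sim$samples$mt_clade[sim$samples$habitat == "forest"] == "S"))
  }
})

test_that("sim_config rejects invalid parameters", {
  expect_error(sim_config(divergence_F = 1), "divergence_F")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(n_loci = 0), "positive")
  expect_error(sim_config(backcross_generations = -1), "backcross")
  expect_error(sim_config(alleles_per_locus = c(5, 2)), "alleles_per_locus")
})
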