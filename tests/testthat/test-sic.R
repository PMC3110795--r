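# Shannon Information Content: formula values, symmetry, concavity,
# ranking, and panel-based assignment.

test_that("SIC formula reproduces hand-evaluated and degenerate cases", {
  # identical frequencies carry no information at any m
  pr0 <- sic_profile(c(0.3, 0.7), c(0.3, 0.7))
  expect_true(all(pr0$sic_values == 0))
  expect_identical(pr0$sic_star, 0)

  # fully diagnostic biallelic locus: 1 bit at m = 0.5
  pr1 <- sic_profile(c(1, 0), c(0, 1), m_grid = 0.5)
  expect_equal(pr1$sic_values, 1)

  # hand evaluation: H(0.75, 0.25) - 0.5 * 1
  pr2 <- sic_profile(c(1, 0), c(0.5, 0.5), m_grid = 0.5)
  expect_equal(pr2$sic_values,
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 0.5,
               tolerance = 1e-10)
  expect_equal(round(pr2$sic_values, 5), 0.31128)

  # SIC -> 0 at the grid edges
  pr3 <- sic_profile(c(0.9, 0.1), c(0.2, 0.8),
                     m_grid = c(1e-6, 0.5, 1 - 1e-6))
  expect_lt(pr3$sic_values[1], 1e-5)
  expect_lt(pr3$sic_values[3], 1e-5)

  expect_error(sic_profile(c(1, 0), c(0.5, 0.5), m_grid = c(0, 0.5)), "m_grid")
  expect_error(sic_profile(c(0.6, 0.5), c(0.5, 0.5)), "sum to 1")
  expect_error(sic_profile(c(a = 1, b = 0), c(a = 0.5, c = 0.5)),
               "allele sets")
})

test_that("SIC is symmetric, concave and bounded by log2(n alleles)", {
  set.seed(12)
  grid <- seq(0.01, 0.99, by = 0.01)
  for (r in 1:15) {
    J <- sample(2:8, 1)
    p1 <- rgamma(J, 0.8); p1 <- p1 / sum(p1)
    p2 <- rgamma(J, 0.8); p2 <- p2 / sum(p2)
    a <- sic_profile(p1, p2, grid)
    b <- sic_profile(p2, p1, grid)
    # SIC(m; p1, p2) = SIC(1 - m; p2, p1) exactly
    expect_equal(a$sic_values, rev(b$sic_values), tolerance = 1e-12)
    # concavity: discrete second differences non-positive
    expect_lte(max(diff(diff(a$sic_values))), 1e-9)
    # bounds
    expect_true(all(a$sic_values >= 0))
    expect_lte(a$sic_star, log2(J))
  }
})

test_that("max_sic sits at 0.5 for symmetric pairs and shifts otherwise", {
  sym <- sic_profile(c(0.9, 0.1), c(0.1, 0.9))
  expect_identical(sym$m_star, 0.5)

  # asymmetric pair: dense-grid numerical maximization oracle
  dense <- seq(0.001, 0.999, by = 0.001)
  asym <- sic_profile(c(1, 0), c(0.5, 0.5), m_grid = dense)
  h <- function(m) {
    p <- c(m + (1 - m) * 0.5, (1 - m) * 0.5)
    -sum(p[p > 0] * log2(p[p > 0])) - (1 - m)
  }
  oracle_m <- dense[which.max(vapply(dense, h, numeric(1)))]
  expect_equal(asym$m_star, oracle_m)
  expect_false(isTRUE(all.equal(asym$m_star, 0.5)))

  # both monomorphic on the same allele
  mono <- sic_profile(c(1, 0), c(1, 0))
  expect_identical(mono$sic_star, 0)
})

test_that("rank_loci orders by sic_star with deterministic tie breaks", {
  f1 <- list(d = c(a = 1, b = 0), m = c(a = 0.8, b = 0.2),
             z = c(a = 0.5, b = 0.5))
  f2 <- list(d = c(a = 0, b = 1), m = c(a = 0.2, b = 0.8),
             z = c(a = 0.5, b = 0.5))
  rk <- rank_loci(f1, f2)
  expect_identical(rk$locus, c("d", "m", "z"))
  expect_identical(rk$sic_star[3], 0)

  # fixed difference beats monomorphic
  g1 <- list(fix = c(a = 1, b = 0), mono = c(a = 1, b = 0))
  g2 <- list(fix = c(a = 0, b = 1), mono = c(a = 1, b = 0))
  expect_identical(rank_loci(g1, g2)$locus[1], "fix")

  # equal-SIC duplicates fall back to lexicographic order
  h1 <- list(bb = c(a = 1, b = 0), aa = c(a = 1, b = 0))
  h2 <- list(bb = c(a = 0, b = 1), aa = c(a = 0, b = 1))
  expect_identical(rank_loci(h1, h2)$locus, c("aa", "bb"))

  expect_error(rank_loci(list(), list()), "empty")
})

test_that("panel evaluation is perfect on diagnostic loci and chance on
           monomorphic ones", {
  # two populations, two diagnostic loci and two monomorphic loci
  n <- 40
  diag1 <- c(rep(1L, n / 2), rep(2L, n / 2))
  mono <- rep(7L, n)
  gm <- genotype_matrix(cbind(diag1, diag1, mono, mono),
                        cbind(diag1, diag1, mono, mono),
                        sprintf("i%02d", 1:n),
                        c("d1", "d2", "m1", "m2"))
  truth <- setNames(rep(c("A", "B"), each = n / 2), gm$individual_ids)
  train <- list(
    A = list(d1 = structure(c(`1` = 1), n_calls = 20L),
             d2 = structure(c(`1` = 1), n_calls = 20L),
             m1 = structure(c(`7` = 1), n_calls = 20L),
             m2 = structure(c(`7` = 1), n_calls = 20L)),
    B = list(d1 = structure(c(`2` = 1), n_calls = 20L),
             d2 = structure(c(`2` = 1), n_calls = 20L),
             m1 = structure(c(`7` = 1), n_calls = 20L),
             m2 = structure(c(`7` = 1), n_calls = 20L)))
  expect_identical(evaluate_panel(c("d1", "d2"), train, gm, truth,
                                  seed = 1)$accuracy, 1)
  # monomorphic panel: ties broken at random -> chance level on balanced set
  accs <- vapply(1:30, function(s) {
    evaluate_panel(c("m1", "m2"), train, gm, truth, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(evaluate_panel(character(0), train, gm, truth), "empty")
})

test_that("forest-savanna SIC exceeds within-savanna SIC for most loci", {
  # the between-species comparison carries the most information
  sim <- simulate_dataset(sim_config(
    n_forest_locales = 2, n_savanna_locales = 2, n_mixed_locales = 0,
    individuals_per_locale = 40, n_loci = 10, divergence_F = 0.25, seed = 23))
  s <- sim$samples
  f_ids <- s$individual_id[s$habitat == "forest"]
  sv <- unique(s$locale[s$habitat == "savanna"])
  sv1 <- s$individual_id[s$locale == sv[1]]
  sv2 <- s$individual_id[s$locale == sv[2]]
  between <- rank_loci(allele_freqs(sim$genotypes, f_ids),
                       allele_freqs(sim$genotypes,
                                    s$individual_id[s$habitat == "savanna"]))
  within <- rank_loci(allele_freqs(sim$genotypes, sv1),
                      allele_freqs(sim$genotypes, sv2))
  m <- merge(between, within, by = "locus", suffixes = c("_bet", "_win"))
  expect_gt(mean(m$sic_star_bet > m$sic_star_win), 0.5)
})
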