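# Shared fixture builders: everything is generated in code at test time.

# Tiny literal genotype matrix.
toy_gm <- function() {
  genotype_matrix(a1 = matrix(c(1L, 1L, 2L,   3L, 3L, 3L), nrow = 3),
                  a2 = matrix(c(1L, 2L, 2L,   3L, 4L, 4L), nrow = 3),
                  individual_ids = c("i1", "i2", "i3"),
                  locus_ids = c("L1", "L2"))
}

# Random genotype matrix for round-trip property tests.
random_gm <- function(n = 10, L = 5, max_allele = 12, missing_rate = 0.1,
                      seed = 1) {
  set.seed(seed)
  a1 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  drop <- matrix(runif(n * L) < missing_rate, n, L)
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  genotype_matrix(a1, a2, sprintf("GR_%03d", seq_len(n)),
                  sprintf("p%02d", seq_len(L)))
}

# Two diverged pure pools with ground truth, no mixed locale.
two_pool_sim <- function(n_per = 30, n_loci = 12, divergence_F = 0.3,
                         seed = 1, missing_rate = 0) {
  simulate_dataset(sim_config(
    n_forest_locales = 1, n_savanna_locales = 1, n_mixed_locales = 0,
    individuals_per_locale = n_per, n_loci = n_loci,
    divergence_F = divergence_F, missing_rate = missing_rate, seed = seed))
}

# Construct one F1 genotype: one allele copy drawn from each species pool
# at every locus.
construct_f1 <- function(sim, seed = 1, id = "F1_001") {
  set.seed(seed)
  pools <- sim$truth$species_freqs
  L <- length(pools$forest)
  a1 <- integer(L); a2 <- integer(L)
  for (l in seq_len(L)) {
    pf <- pools$forest[[l]]; ps <- pools$savanna[[l]]
    a1[l] <- as.integer(names(pf))[sample.int(length(pf), 1, prob = pf)]
    a2[l] <- as.integer(names(ps))[sample.int(length(ps), 1, prob = ps)]
  }
  genotype_matrix(matrix(a1, 1), matrix(a2, 1), id, sim$genotypes$locus_ids)
}

# Orient a 2-column Q matrix so column 1 tracks forest ancestry.
orient_forest_first <- function(Q, samples) {
  forest_rows <- samples$individual_id[samples$habitat == "forest"]
  if (mean(Q[forest_rows, 1]) < 0.5) Q <- Q[, 2:1]
  Q
}
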