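# Admixture machinery: sampler contracts, label alignment, L_hat, Evanno
# delta-K, locale means. Heavy parameter-recovery experiments live in the
# acceptance suite.

test_that("admixture_spec validates its fields", {
  expect_error(admixture_spec(K = 0), "K")
  expect_error(admixture_spec(K = 2, alpha = -1), "alpha")
  expect_error(admixture_spec(K = 2, sweeps = 100, burnin = 100), "burnin")
  sp <- admixture_spec(K = 2, alpha = "infer")
  expect_true(sp$infer_alpha)
})

test_that("K = 1 yields all-ones membership and normalized posteriors", {
  sim <- two_pool_sim(n_per = 8, n_loci = 4, seed = 2)
  est <- gibbs_admixture(sim$genotypes,
                         admixture_spec(K = 1, sweeps = 60, burnin = 20))
  expect_equal(unname(est$Q[, 1]), rep(1, 16))
  expect_identical(length(est$loglik_trace), 40L)
  for (m in est$P) expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
})

test_that("sampler output is deterministic given the seed and handles missing", {
  sim <- two_pool_sim(n_per = 10, n_loci = 5, seed = 4, missing_rate = 0.15)
  sp <- admixture_spec(K = 2, sweeps = 80, burnin = 30, seed = 99)
  e1 <- gibbs_admixture(sim$genotypes, sp)
  e2 <- gibbs_admixture(sim$genotypes, sp)
  expect_identical(e1, e2)
  expect_equal(unname(rowSums(e1$Q)), rep(1, nrow(e1$Q)))
  expect_true(all(is.finite(e1$loglik_trace)))
})

test_that("no-admixture model assigns whole individuals to clusters", {
  sim <- two_pool_sim(n_per = 12, n_loci = 8, divergence_F = 0.5, seed = 6)
  est <- gibbs_admixture(sim$genotypes,
                         admixture_spec(K = 2, admixture = FALSE,
                                        sweeps = 120, burnin = 40, seed = 1))
  # posterior mean of indicator rows still sums to 1
  expect_equal(unname(rowSums(est$Q)), rep(1, nrow(est$Q)))
  # strongly diverged pools: assignments are near-certain for most individuals
  expect_gt(mean(apply(est$Q, 1, max) > 0.9), 0.8)
})

test_that("label alignment recovers permutations exactly", {
  sim <- two_pool_sim(n_per = 8, n_loci = 4, seed = 3)
  est <- gibbs_admixture(sim$genotypes,
                         admixture_spec(K = 3, sweeps = 60, burnin = 20,
                                        seed = 5))
  # identity
  self <- align_cluster_labels(est, est)
  expect_identical(attr(self, "permutation"), 1:3)
  expect_equal(self$Q, est$Q)
  # constructed swap is inverted exactly
  swapped <- est
  perm <- c(3L, 1L, 2L)
  swapped$Q <- est$Q[, perm]
  colnames(swapped$Q) <- colnames(est$Q)
  swapped$P <- lapply(est$P, function(m) {
    m2 <- m[perm, , drop = FALSE]; rownames(m2) <- rownames(m); m2
  })
  aligned <- align_cluster_labels(est, swapped)
  expect_equal(aligned$Q, est$Q)
  expect_equal(aligned$P, est$P)
  # brute force over all 6 permutations is the definition; cross-check with
  # an independent scorer
  set.seed(10)
  qa <- matrix(rgamma(30, 1), 10); qa <- qa / rowSums(qa)
  qb <- matrix(rgamma(30, 1), 10); qb <- qb / rowSums(qb)
  rownames(qa) <- rownames(qb) <- paste0("i", 1:10)
  fake <- function(q) structure(list(Q = q, P = list()),
                                class = "ancestry_estimate")
  got <- attr(align_cluster_labels(fake(qa), fake(qb)), "permutation")
  perms <- list(1:3, c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
                c(3L, 1L, 2L), c(3L, 2L, 1L))
  scores <- vapply(perms, function(p) sum(qa * qb[, p]), numeric(1))
  expect_identical(got, perms[[which.max(scores)]])
  # mismatched K errors
  expect_error(align_cluster_labels(fake(qa), fake(qa[, 1:2])), "K")
})

test_that("L_hat matches the mean-minus-half-variance estimator", {
  expect_identical(estimate_log_prob_data(c(-5, -5, -5)), -5)
  expect_identical(estimate_log_prob_data(c(-10, -12)), -12)
  expect_error(estimate_log_prob_data(numeric(0)), "at least 2")
  expect_error(estimate_log_prob_data(-3), "at least 2")
})

test_that("Evanno delta-K reproduces hand arithmetic and edge rules", {
  dk <- evanno_delta_k(list(`1` = c(-1000, -1000, -1000),
                            `2` = c(-900, -902, -904),
                            `3` = c(-880, -880, -880)))
  expect_identical(dk$delta_K[dk$K == 2], 38)
  expect_true(all(is.na(dk$delta_K[dk$K %in% c(1, 3)])))

  # exactly linear L in K per run: all interior delta-K are zero
  lin <- evanno_delta_k(list(`1` = c(-30, -31), `2` = c(-20, -21),
                             `3` = c(-10, -11), `4` = c(0, -1)))
  expect_identical(lin$delta_K[lin$K %in% 2:3], c(0, 0))

  # zero sd: infinite with warning
  expect_warning(
    z <- evanno_delta_k(list(`1` = c(-9, -9), `2` = c(-5, -5),
                             `3` = c(-4, -4))),
    "zero replicate sd")
  expect_identical(z$delta_K[z$K == 2], Inf)

  expect_error(evanno_delta_k(list(`1` = c(-1, -2), `2` = c(-1, -2))),
               "at least 3")
  expect_error(evanno_delta_k(list(`1` = c(-1, -2), `3` = c(-1, -2),
                                   `4` = c(-1, -2))), "consecutive")
  expect_error(evanno_delta_k(list(`1` = -1, `2` = -1, `3` = -1)),
               "2 replicates")
})

test_that("recovery improves with more loci on matched seeds", {
  mae_for <- function(n_loci, seed) {
    sim <- two_pool_sim(n_per = 15, n_loci = n_loci, divergence_F = 0.2,
                        seed = seed)
    est <- gibbs_admixture(sim$genotypes,
                           admixture_spec(K = 2, alpha = "infer",
                                          sweeps = 150, burnin = 50,
                                          seed = seed + 1000))
    q <- orient_forest_first(est$Q, sim$samples)
    mean(abs(q[, 1] - sim$truth$true_Q[, "forest"]))
  }
  seeds <- 1:10
  m6 <- vapply(seeds, function(s) mae_for(6, s), numeric(1))
  m24 <- vapply(seeds, function(s) mae_for(24, s), numeric(1))
  expect_lte(mean(m24), mean(m6))
})

test_that("locale means average Q rows per locale", {
  Q <- rbind(c(1, 0), c(0.8, 0.2), c(0, 1))
  rownames(Q) <- c("a1", "a2", "b1")
  tab <- data.frame(individual_id = c("a1", "a2", "b1"),
                    locale = c("A", "A", "B"),
                    habitat = c("forest", "forest", "savanna"))
  m <- mean_cluster_by_locale(Q, tab)
  expect_equal(unname(unlist(m[m$locale == "A", c("cluster1", "cluster2")])),
               c(0.9, 0.1))
  expect_equal(unname(unlist(m[m$locale == "B", c("cluster1", "cluster2")])),
               c(0, 1))
  # unknown individual named in the error
  rownames(Q)[3] <- "zz"
  expect_error(mean_cluster_by_locale(Q, tab), "zz")
})
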