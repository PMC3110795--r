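# Locus QC battery: Hardy-Weinberg exact testing by Monte-Carlo permutation,
# Brookfield null-allele estimation from homozygote excess, and a
# permutation G-test for inter-locus association.

# Log conditional probability of a genotype array given its allele counts
# (Levene / Guo-Thompson): valid for multi-allelic sparse tables.
#   log P = log n! + sum_j log a_j! - log (2n)! + h log 2 - sum log n_jk!
log_genotype_array_prob <- function(a1, a2) {
  n <- length(a1)
  alleles <- c(a1, a2)
  acounts <- table(alleles)
  gcounts <- table(paste(pmin(a1, a2), pmax(a1, a2)))
  h <- sum(a1 != a2)
  lfactorial(n) + sum(lfactorial(acounts)) - lfactorial(2 * n) +
    h * log(2) - sum(lfactorial(gcounts))
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' The test statistic is the conditional probability of the observed
#' genotype array given the allele counts (the Levene distribution used by
#' Guo-Thompson style exact tests, appropriate for multi-allelic sparse STR
#' tables). The null distribution is sampled by pooling all allele copies
#' and re-pairing them uniformly at random; the p-value is the add-one
#' corrected proportion of permuted arrays whose conditional probability is
#' at most the observed one, so `0 < p <= 1` always.
#'
#' @param x A [genotype_matrix()].
#' @param locus_id Locus to test.
#' @param n_permutations Number of random re-pairings (>= 100).
#' @param seed Optional integer seed.
#' @return The p-value.
#' @export
hwe_exact_test <- function(x, locus_id, n_permutations = 10000L, seed = NULL) {
  if (n_permutations < 100L) stop("n_permutations must be at least 100")
  l <- match(locus_id, x$locus_ids)
  if (is.na(l)) stop("locus not found: ", locus_id)
  ok <- !is.na(x$a1[, l])
  a1 <- x$a1[ok, l]; a2 <- x$a2[ok, l]
  if (length(a1) < 2L) stop("need at least 2 non-missing calls at ", locus_id)
  if (length(unique(c(a1, a2))) == 1L) return(1.0) # single possible array
  obs <- log_genotype_array_prob(a1, a2)
  pool <- c(a1, a2)
  n <- length(a1)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(pool)
      if (log_genotype_array_prob(perm[seq_len(n)], perm[n + seq_len(n)]) <=
          obs + 1e-9) {
        hits <- hits + 1L
      }
    }
    (hits + 1L) / (n_permutations + 1L)
  })
}

#' Null-allele frequency estimate from homozygote excess
#'
#' Brookfield's estimator 1: `r = (He - Ho) / (1 + He)`, floored at zero.
#' Appropriate when homozygote excess relative to Hardy-Weinberg expectation
#' is attributed to a non-amplifying (null) allele.
#'
#' @param He Expected heterozygosity in `[0, 1]`.
#' @param Ho Observed heterozygosity in `[0, 1]`.
#' @return Estimated null-allele frequency, `>= 0`.
#' @export
#' @examples
#' null_allele_estimate(He = 0.5, Ho = 0.25) # 0.16667
null_allele_estimate <- function(He, Ho) {
  if (any(He < 0 | He > 1) || any(Ho < 0 | Ho > 1)) {
    stop("He and Ho must lie in [0, 1]")
  }
  pmax(0, (He - Ho) / (1 + He))
}

#' Permutation G-test for association between two loci
#'
#' Builds the two-locus genotype contingency table over individuals
#' non-missing at both loci and computes the G statistic; the null
#' distribution comes from permuting one locus's genotype column across
#' individuals, which preserves both single-locus genotype spectra. A
#' degenerate table (a single genotype class at either locus) returns
#' `p = 1` with a warning.
#'
#' @param x A [genotype_matrix()].
#' @param locusA,locusB Locus labels.
#' @param n_permutations Number of permutations.
#' @param seed Optional integer seed.
#' @return The add-one corrected p-value.
#' @export
linkage_test <- function(x, locusA, locusB, n_permutations = 2000L,
                         seed = NULL) {
  la <- match(locusA, x$locus_ids); lb <- match(locusB, x$locus_ids)
  if (is.na(la) || is.na(lb)) stop("locus not found")
  ok <- !is.na(x$a1[, la]) & !is.na(x$a1[, lb])
  if (sum(ok) < 2L) stop("need at least 2 individuals non-missing at both loci")
  ga <- paste(x$a1[ok, la], x$a2[ok, la])
  gb <- paste(x$a1[ok, lb], x$a2[ok, lb])
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    warning("degenerate table: a locus has a single genotype class; p = 1")
    return(1.0)
  }
  g_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.numeric(tab)
    e <- as.numeric(e)
    nz <- o > 0
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  obs <- g_stat(ga, gb)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (g_stat(ga, sample(gb)) >= obs - 1e-9) hits <- hits + 1L
    }
    (hits + 1L) / (n_permutations + 1L)
  })
}

#' Per-locus QC report
#'
#' He, Ho, Hardy-Weinberg exact p, Brookfield null-allele estimate and a
#' flag column. Loci are flagged, never silently dropped: exclusion
#' decisions stay with the caller.
#'
#' @param x A [genotype_matrix()].
#' @param n_permutations Permutations for the HWE test.
#' @param seed Optional integer seed (per-locus substreams derive from it).
#' @param null_threshold Null-allele estimate above which a locus is flagged
#'   (default 0.05).
#' @param alpha HWE significance level, Bonferroni-corrected across loci
#'   (default 0.05).
#' @return data.frame: locus, n_calls, n_alleles, He, Ho, hwe_p, null_r,
#'   flagged.
#' @export
qc_report <- function(x, n_permutations = 2000L, seed = NULL,
                      null_threshold = 0.05, alpha = 0.05) {
  rows <- lapply(seq_along(x$locus_ids), function(i) {
    l <- x$locus_ids[i]
    s <- summarize_locus(x, l)
    p <- hwe_exact_test(x, l, n_permutations,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, "hwe", i))
    r <- null_allele_estimate(s$He, s$Ho)
    data.frame(locus = l, n_calls = s$n_calls, n_alleles = s$n_alleles,
               He = s$He, Ho = s$Ho, hwe_p = p, null_r = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$null_r > null_threshold |
    out$hwe_p < alpha / nrow(out)
  out
}

#' Pairwise linkage screen
#'
#' All locus pairs tested with [linkage_test()]; raw and Bonferroni-adjusted
#' p-values are reported side by side (the appropriate multiplicity
#' correction for this screen is a judgement call, so both are given).
#'
#' @inheritParams qc_report
#' @return data.frame: locusA, locusB, p, p_bonferroni.
#' @export
linkage_screen <- function(x, n_permutations = 2000L, seed = NULL) {
  L <- length(x$locus_ids)
  if (L < 2L) stop("need at least two loci")
  pairs <- utils::combn(L, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ia <- pairs[1L, j]; ib <- pairs[2L, j]
    p <- suppressWarnings(
      linkage_test(x, x$locus_ids[ia], x$locus_ids[ib], n_permutations,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "ld", j)))
    data.frame(locusA = x$locus_ids[ia], locusB = x$locus_ids[ib], p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
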