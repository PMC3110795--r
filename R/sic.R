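# Shannon Information Content of STR loci for a pair of populations:
# bits of uncertainty about an allele's population of origin removed by
# observing the allele, as a function of the admixture proportion m.

#' Shannon Information Content profile of a locus
#'
#' For a mixture that draws an allele from population 1 with probability `m`
#' and population 2 with probability `1 - m`, the information an allele
#' carries about its population of origin is the mutual information
#' `SIC(m) = H(m p1 + (1-m) p2) - [m H(p1) + (1-m) H(p2)]`, with `H` the
#' base-2 Shannon entropy and `0 log 0 := 0`. It is zero when the two
#' populations share identical frequencies, at most `log2(n alleles)`, and
#' concave in `m`; alleles that are rare in one population but common in
#' the other drive it up (the centrality property that makes SIC preferable
#' to simple frequency differentials for ranking assignment markers).
#'
#' @param p1,p2 Allele-frequency vectors of the locus in the two
#'   populations, over a shared allele set (same names / length), each
#'   summing to 1.
#' @param m_grid Admixture proportions to evaluate, strictly inside (0, 1);
#'   default 99 points at 0.01 spacing.
#' @param locus_id Optional label stored in the profile.
#' @param populations Length-2 labels of the pair.
#' @return A list of class `sic_profile`: `locus_id`, `populations`,
#'   `m_grid`, `sic_values` (bits), `m_star`, `sic_star`.
#' @export
#' @examples
#' pr <- sic_profile(c(1, 0), c(0.5, 0.5))
#' pr$sic_star
sic_profile <- function(p1, p2, m_grid = seq(0.01, 0.99, by = 0.01),
                        locus_id = NULL, populations = c("pop1", "pop2")) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stop("allele sets differ")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("allele sets differ (unequal lengths)")
  }
  check_freq_vector(p1, "p1"); check_freq_vector(p2, "p2")
  if (any(m_grid <= 0) || any(m_grid >= 1)) {
    stop("m_grid must lie strictly inside (0, 1)")
  }
  h1 <- entropy_bits(p1); h2 <- entropy_bits(p2)
  sic <- vapply(m_grid, function(m) {
    entropy_bits(m * p1 + (1 - m) * p2) - (m * h1 + (1 - m) * h2)
  }, numeric(1))
  sic <- pmax(sic, 0)
  sic[sic < 1e-12] <- 0 # snap round-off so identical profiles give exact zero
  prof <- structure(list(locus_id = locus_id, populations = populations,
                         m_grid = m_grid, sic_values = sic,
                         m_star = NA_real_, sic_star = NA_real_),
                    class = "sic_profile")
  mx <- max_sic(prof)
  prof$m_star <- mx[["m_star"]]
  prof$sic_star <- mx[["sic_star"]]
  prof
}

#' @export
print.sic_profile <- function(x, ...) {
  cat(sprintf("sic_profile%s: max %.4f bits at m = %.2f\n",
              if (is.null(x$locus_id)) "" else paste0(" [", x$locus_id, "]"),
              x$sic_star, x$m_star))
  invisible(x)
}

#' Grid maximum of a SIC profile
#'
#' The maximum need not sit at m = 0.5: a locus can be more effective at
#' detecting members of one population inside the other than vice versa.
#' Ties (within 1e-12 bits) are broken toward m = 0.5, then toward the
#' smaller m.
#'
#' @param profile A [sic_profile()].
#' @return Named numeric vector `c(m_star, sic_star)`.
#' @export
max_sic <- function(profile) {
  stopifnot(inherits(profile, "sic_profile"))
  if (!length(profile$m_grid)) stop("empty m grid")
  s <- profile$sic_values
  top <- which(s >= max(s) - 1e-12)
  ord <- top[order(abs(profile$m_grid[top] - 0.5), profile$m_grid[top])]
  i <- ord[1L]
  c(m_star = profile$m_grid[i], sic_star = s[i])
}

#' Rank loci by maximum Shannon Information Content
#'
#' Evaluates a SIC profile per locus for one population pair and orders loci
#' by descending `sic_star` (ties broken lexicographically by locus id).
#' Loci monomorphic in both populations are retained with SIC 0 so the
#' ranking covers the full panel.
#'
#' @param freqs1,freqs2 Named per-locus lists of allele-frequency vectors
#'   for the two populations (as from [allele_freqs()]); locus sets must
#'   match.
#' @param m_grid Passed to [sic_profile()].
#' @return data.frame: locus, m_star, sic_star, ordered by informativeness.
#' @export
rank_loci <- function(freqs1, freqs2, m_grid = seq(0.01, 0.99, by = 0.01)) {
  if (!length(freqs1)) stop("empty input")
  if (!setequal(names(freqs1), names(freqs2))) stop("locus sets differ")
  freqs2 <- freqs2[names(freqs1)]
  pairs <- align_freq_pair(freqs1, freqs2)
  names(pairs) <- names(freqs1)
  rows <- lapply(names(pairs), function(l) {
    a <- pairs[[l]]$a; b <- pairs[[l]]$b
    if (!length(a) || sum(a) == 0 || sum(b) == 0) {
      return(data.frame(locus = l, m_star = NA_real_, sic_star = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pr <- sic_profile(a, b, m_grid = m_grid, locus_id = l)
    data.frame(locus = l, m_star = pr$m_star, sic_star = pr$sic_star,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$sic_star, out$locus), , drop = FALSE]
}

#' Assignment accuracy of a locus panel
#'
#' Likelihood-based population assignment: each test individual is assigned
#' to the training population maximising the product over panel loci of its
#' genotype likelihood under Hardy-Weinberg within that population
#' (homozygote `p^2`, heterozygote `2 p q`). Training frequencies of zero
#' (alleles unseen in a population) are floored at `1/(2 n + 1)` with `n`
#' the number of training individuals behind that population's frequencies,
#' so novel alleles are improbable rather than impossible. Ties are broken
#' uniformly at random under `seed`.
#'
#' @param panel Character vector of locus ids to use (non-empty).
#' @param train Named list of populations, each a per-locus list of allele
#'   frequencies carrying attribute `n_calls` (as from [allele_freqs()]).
#' @param test A [genotype_matrix()] of test individuals.
#' @param true_origins Character vector (named by individual or in row
#'   order) of true population labels, matching `names(train)`.
#' @param seed Optional integer seed for tie breaking.
#' @return List: `accuracy`, `assigned` (named character vector), `n_test`.
#' @export
evaluate_panel <- function(panel, train, test, true_origins, seed = NULL) {
  if (!length(panel)) stop("empty panel")
  miss <- setdiff(panel, test$locus_ids)
  if (length(miss)) stop("panel loci absent from test data: ",
                         paste(miss, collapse = ", "))
  pops <- names(train)
  if (length(pops) < 2L) stop("need at least 2 training populations")
  if (!is.null(names(true_origins))) {
    true_origins <- true_origins[test$individual_ids]
  }
  if (length(true_origins) != n_individuals(test)) {
    stop("true_origins must cover every test individual")
  }
  bad <- setdiff(unique(true_origins), pops)
  if (length(bad)) stop("true origin label(s) not in training set: ",
                        paste(bad, collapse = ", "))

  n <- n_individuals(test)
  ll <- matrix(0, n, length(pops), dimnames = list(test$individual_ids, pops))
  for (l in panel) {
    li <- match(l, test$locus_ids)
    a1 <- test$a1[, li]; a2 <- test$a2[, li]
    for (pi in seq_along(pops)) {
      f <- train[[pi]][[l]]
      ntrain <- attr(f, "n_calls")
      if (is.null(ntrain) || !length(f)) next # no training data at locus
      floor_p <- 1 / (2 * ntrain + 1)
      look <- function(a) {
        p <- f[as.character(a)]
        p[is.na(p) | p <= 0] <- floor_p
        unname(p)
      }
      ok <- !is.na(a1)
      p1 <- look(a1[ok]); p2 <- look(a2[ok])
      het <- a1[ok] != a2[ok]
      contrib <- log(p1) + log(p2) + ifelse(het, log(2), 0)
      ll[ok, pi] <- ll[ok, pi] + contrib
    }
  }
  with_seed(seed, {
    assigned <- apply(ll, 1L, function(v) {
      top <- which(v >= max(v) - 1e-9)
      pops[if (length(top) == 1L) top else sample(top, 1L)]
    })
    list(accuracy = mean(assigned == true_origins),
         assigned = assigned,
         n_test = n)
  })
}
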