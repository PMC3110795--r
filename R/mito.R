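# Mito-nuclear concordance: per-locale mtDNA clade frequencies, the
# concordance table against nuclear cluster means, and the exact
# habitat-by-clade association test.

#' Per-locale S-clade mtDNA proportions
#'
#' Individuals with clade `unknown` are excluded from the denominator; a
#' locale with no classified individuals gets a missing (NA) proportion
#' rather than zero, since absence of data is not absence of the clade.
#'
#' @param table Sample table with `locale`, `habitat`, `mt_clade`.
#' @return data.frame: locale, habitat, n, n_classified,
#'   s_clade_proportion, s_clade_present (>= 1 classified S individual).
#' @export
clade_frequencies <- function(table) {
  table <- as_sample_table(table)
  locs <- unique(table$locale)
  rows <- lapply(locs, function(lc) {
    sub <- table[table$locale == lc, ]
    cl <- sub$mt_clade[sub$mt_clade != "unknown"]
    nS <- sum(cl == "S")
    data.frame(locale = lc, habitat = sub$habitat[1L], n = nrow(sub),
               n_classified = length(cl),
               s_clade_proportion = if (length(cl)) nS / length(cl) else NA_real_,
               s_clade_present = nS > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance of mtDNA clade and nuclear cluster proportions by locale
#'
#' Pairs each locale's S-clade mtDNA proportion with its mean savanna
#' nuclear cluster membership; under strict concordance the two would sit on
#' the diagonal. `deviation = mean_savanna_Q - s_clade_proportion`, so a
#' savanna locale fixed for introgressed F-clade mtDNA but with pure savanna
#' nuclear genotypes scores the maximal discordance `+1`.
#'
#' @param clades data.frame from [clade_frequencies()].
#' @param locale_means data.frame from [mean_cluster_by_locale()].
#' @param savanna_cluster Name or index of the Q column corresponding to the
#'   savanna cluster.
#' @return data.frame: locale, habitat, n, s_clade_proportion,
#'   mean_savanna_Q, deviation.
#' @export
concordance_table <- function(clades, locale_means, savanna_cluster) {
  if (!setequal(clades$locale, locale_means$locale)) {
    stop("locale sets differ between clade and cluster summaries")
  }
  lm <- locale_means[match(clades$locale, locale_means$locale), ]
  q <- lm[[savanna_cluster]]
  if (is.null(q)) stop("savanna_cluster column not found")
  data.frame(locale = clades$locale, habitat = clades$habitat, n = clades$n,
             s_clade_proportion = clades$s_clade_proportion,
             mean_savanna_Q = q,
             deviation = q - clades$s_clade_proportion,
             stringsAsFactors = FALSE)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact enumeration over all tables sharing the observed margins; under the
#' null the first cell follows the hypergeometric distribution. The
#' two-tailed p-value sums the probabilities of all tables whose probability
#' is at most the observed table's (with 1e-12 relative slack for
#' floating-point ties). Probabilities are computed in log space via
#' log-gamma so counts in the hundreds stay exact to machine precision.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows `(a, b)` and
#'   `(c, d)`; every row and column margin must be positive.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5) # 2/252
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("every row and column margin must be positive")
  }
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  obs <- logp[match(a, xs)]
  sum(exp(logp[logp <= obs + 1e-12 * abs(obs) + 1e-12]))
}

#' Habitat-by-clade association test across locales
#'
#' Classifies locales as tropical forest versus other-or-mixed habitat and
#' as S-clade present versus not detected, then applies
#' [fisher_exact_2x2()]. Mixed-habitat locales group with non-forest.
#' Presence means at least one classified S individual; locales with no
#' classified individuals are excluded.
#'
#' @param clades data.frame from [clade_frequencies()] (columns `habitat`,
#'   `s_clade_present`, `n_classified`).
#' @return List: `table` (2x2 matrix, rows S present/not detected, columns
#'   forest/other) and `p` (two-tailed exact p-value).
#' @export
habitat_association <- function(clades) {
  clades <- clades[clades$n_classified > 0, , drop = FALSE]
  forest <- clades$habitat == "forest"
  if (!any(forest) || all(forest)) {
    stop("need at least one locale on each habitat side")
  }
  present <- clades$s_clade_present
  tab <- matrix(c(sum(present & forest), sum(present & !forest),
                  sum(!present & forest), sum(!present & !forest)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("S_present", "S_not_detected"),
                                c("forest", "other_or_mixed")))
  p <- fisher_exact_2x2(tab[1L, 1L], tab[1L, 2L], tab[2L, 1L], tab[2L, 2L])
  list(table = tab, p = p)
}
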