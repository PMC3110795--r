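# Allele-frequency chord distances between population samples and
# neighbor-joining trees over locales.

# Align two per-locus frequency lists onto the union allele set per locus.
align_freq_pair <- function(fa, fb) {
  if (!setequal(names(fa), names(fb))) stop("locus sets differ")
  fb <- fb[names(fa)]
  lapply(names(fa), function(l) {
    pa <- fa[[l]]; pb <- fb[[l]]
    union_alleles <- sort(unique(c(names(pa), names(pb))))
    a <- stats::setNames(rep(0, length(union_alleles)), union_alleles)
    b <- a
    a[names(pa)] <- pa
    b[names(pb)] <- pb
    list(a = a, b = b)
  })
}

#' Chord distance between two allele-frequency profiles
#'
#' Per locus, `d_l = sqrt(2 * (1 - sum_j sqrt(p_Aj * p_Bj)))` — the chord
#' between the two frequency vectors on the unit sphere of square-root
#' frequencies. Loci are combined by root-mean-square:
#' `D = sqrt(mean_l d_l^2)`. Symmetric, zero iff the profiles agree at every
#' locus. The `angular = TRUE` switch applies the classical `2/pi`
#' normalisation to each per-locus chord.
#'
#' Frequencies are aligned on the union allele set per locus (absent alleles
#' count 0). Loci where either profile has no data (empty vector) are
#' dropped pairwise.
#'
#' @param freqA,freqB Named per-locus lists of named allele-frequency
#'   vectors (as from [allele_freqs()]), or bare numeric vectors for a
#'   single locus. Locus sets must match.
#' @param angular Apply the 2/pi angular normalisation (default FALSE).
#' @return The multi-locus distance.
#' @export
#' @examples
#' chord_distance(c(a = 1, b = 0), c(a = 0.5, b = 0.5)) # 0.76537
chord_distance <- function(freqA, freqB, angular = FALSE) {
  if (is.numeric(freqA)) freqA <- list(locus1 = freqA)
  if (is.numeric(freqB)) freqB <- list(locus1 = freqB)
  if (is.null(names(freqA))) names(freqA) <- paste0("locus", seq_along(freqA))
  if (is.null(names(freqB))) names(freqB) <- paste0("locus", seq_along(freqB))
  # unnamed allele vectors are matched positionally
  for (l in names(freqA)) {
    if (is.null(names(freqA[[l]])) && is.null(names(freqB[[l]])) &&
        length(freqA[[l]]) == length(freqB[[l]])) {
      names(freqA[[l]]) <- names(freqB[[l]]) <- seq_along(freqA[[l]])
    }
  }
  pairs <- align_freq_pair(freqA, freqB)
  d2 <- c()
  for (pr in pairs) {
    if (!length(pr$a) || sum(pr$a) == 0 || sum(pr$b) == 0) next # no data side
    check_freq_vector(pr$a); check_freq_vector(pr$b)
    cosv <- min(1, sum(sqrt(pr$a * pr$b)))
    if (cosv > 1 - 1e-12) cosv <- 1 # identical profiles give exactly zero
    dl <- sqrt(2 * (1 - cosv))
    if (angular) dl <- dl * 2 / pi
    d2 <- c(d2, dl^2)
  }
  if (!length(d2)) stop("no loci with data in both profiles")
  sqrt(mean(d2))
}

#' Pairwise chord-distance matrix between groups of individuals
#'
#' Computes per-group allele frequencies (non-missing calls only) and the
#' chord distance for every pair of groups.
#'
#' @param x A [genotype_matrix()].
#' @param table Sample table; `by` selects the grouping column.
#' @param by Grouping column of `table` (default `"locale"`).
#' @param angular Passed to [chord_distance()].
#' @return Symmetric matrix with zero diagonal, labelled by group.
#' @export
chord_dist_matrix <- function(x, table, by = "locale", angular = FALSE) {
  table <- as_sample_table(table)
  grp <- table[[by]][match(x$individual_ids, table$individual_id)]
  if (anyNA(grp)) stop("sample table missing some individuals")
  groups <- unique(grp)
  freqs <- lapply(groups, function(g) {
    allele_freqs(x, individuals = x$individual_ids[grp == g])
  })
  names(freqs) <- groups
  n <- length(groups)
  D <- matrix(0, n, n, dimnames = list(groups, groups))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <- chord_distance(freqs[[i]], freqs[[j]],
                                             angular = angular)
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard implementation in \pkg{ape})
#' on a symmetric non-negative distance matrix. Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero with the
#' deficit shifted onto the sister edge so path lengths through the parent
#' node are preserved. The result is an unrooted tree with branch lengths.
#'
#' @param D Symmetric numeric matrix, zero diagonal, >= 3 taxa, with
#'   dimnames (or supply `labels`).
#' @param labels Optional taxon labels overriding dimnames.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || nrow(D) < 3L) stop("need a square matrix with >= 3 taxa")
  if (any(is.na(D))) stop("distance matrix contains NA")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  }
  tree <- ape::nj(D)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tree$edge.length[sisters[1L]] <-
        tree$edge.length[sisters[1L]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Build the locale NJ tree from genotypes
#'
#' Chord-distance matrix between locales followed by neighbor joining.
#'
#' @inheritParams chord_dist_matrix
#' @return An [ape::phylo] tree with locale tip labels.
#' @export
locale_tree <- function(x, table, by = "locale", angular = FALSE) {
  D <- chord_dist_matrix(x, table, by = by, angular = angular)
  neighbor_joining(D)
}
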