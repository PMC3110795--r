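#' Factorial correspondence analysis of a genotype dosage table
#'
#' Builds the individuals-by-alleles dosage table (0/1/2 copies of each
#' allele at each locus; missing calls contribute nothing) and performs
#' correspondence analysis: the chi-square-metric singular value
#' decomposition of the standardised residual matrix
#' `(P - r c') / sqrt(r c')` under standard row/column-mass weighting.
#' Individual coordinates are principal coordinates; the inertia percentage
#' of axis i is its eigenvalue over the total inertia. Axis signs are made
#' reproducible by forcing the largest-magnitude individual coordinate on
#' each axis positive.
#'
#' @param x A [genotype_matrix()] with at least 3 individuals and 2
#'   polymorphic loci. Individuals with no non-missing calls are rejected.
#' @param n_axes Maximum number of axes to return (default all).
#' @return A list of class `str_fca`: `coords` (individuals x axes principal
#'   coordinates), `inertia_pct` (percent of total inertia per retained
#'   axis, summing to 100), `eig` (eigenvalues), `col_coords` (allele-column
#'   principal coordinates).
#' @export
fca <- function(x, n_axes = NULL) {
  if (n_individuals(x) < 3L) stop("need at least 3 individuals")
  poly <- vapply(x$locus_ids, function(l) {
    a <- c(x$a1[, match(l, x$locus_ids)], x$a2[, match(l, x$locus_ids)])
    length(unique(a[!is.na(a)])) > 1L
  }, logical(1))
  if (sum(poly) < 2L) stop("need at least 2 polymorphic loci")

  # dosage table
  cols <- list()
  for (l in seq_len(n_loci(x))) {
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    codes <- sort(unique(c(a1, a2)))
    codes <- codes[!is.na(codes)]
    d <- matrix(0, n_individuals(x), length(codes))
    for (j in seq_along(codes)) {
      d[, j] <- (!is.na(a1) & a1 == codes[j]) + (!is.na(a2) & a2 == codes[j])
    }
    colnames(d) <- paste0(x$locus_ids[l], ".", codes)
    cols[[l]] <- d
  }
  X <- do.call(cbind, cols)
  rownames(X) <- x$individual_ids
  empty <- rowSums(X) == 0
  if (any(empty)) {
    stop("individual(s) with no genotype data: ",
         paste(x$individual_ids[empty], collapse = ", "))
  }
  X <- X[, colSums(X) > 0, drop = FALSE]

  P <- X / sum(X)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  keep <- which(sv$d > max(sv$d[1L], 0) * 1e-8 & sv$d > 1e-12)
  if (!length(keep)) stop("no variability: total inertia is zero")
  if (!is.null(n_axes)) keep <- keep[seq_len(min(n_axes, length(keep)))]
  d <- sv$d[keep]
  eig <- sv$d^2
  eig <- eig[sv$d > max(sv$d[1L], 0) * 1e-8 & sv$d > 1e-12]
  Fc <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*% diag(d, length(d))
  Gc <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cm), "/") %*% diag(d, length(d))
  for (j in seq_along(keep)) {
    i0 <- which.max(abs(Fc[, j]))
    if (Fc[i0, j] < 0) { Fc[, j] <- -Fc[, j]; Gc[, j] <- -Gc[, j] }
  }
  dimnames(Fc) <- list(x$individual_ids, paste0("Axis", seq_along(keep)))
  dimnames(Gc) <- list(colnames(X), paste0("Axis", seq_along(keep)))
  structure(list(coords = Fc,
                 inertia_pct = 100 * eig / sum(eig),
                 eig = eig,
                 col_coords = Gc),
            class = "str_fca")
}

#' @export
print.str_fca <- function(x, ...) {
  cat(sprintf("str_fca: %d individuals, %d axes; axis 1-2 inertia %.2f%% / %.2f%%\n",
              nrow(x$coords), ncol(x$coords),
              x$inertia_pct[1L], ifelse(length(x$inertia_pct) > 1,
                                        x$inertia_pct[2L], NA)))
  invisible(x)
}
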