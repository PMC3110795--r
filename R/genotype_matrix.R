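#' Diploid STR genotype matrix
#'
#' The universal substrate of the package: an individuals-by-loci table of
#' unordered diploid allele calls. Alleles are positive integer codes
#' (typically binned fragment sizes); a missing call has both copies `NA`.
#' Pairs are stored sorted (`a1 <= a2`) since phase is never used.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   copies of each call. `NA` marks missing; a call must be missing in both
#'   copies or neither.
#' @param individual_ids Character vector of unique row labels.
#' @param locus_ids Character vector of unique column labels.
#' @return An object of class `genotype_matrix` with fields
#'   `individual_ids`, `locus_ids`, `a1`, `a2`.
#' @export
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, 1L), 1), matrix(c(2L, 1L), 1),
#'                       "ind1", c("L1", "L2"))
#' n_individuals(gm)
genotype_matrix <- function(a1, a2, individual_ids, locus_ids) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 dimensions differ")
  if (nrow(a1) != length(individual_ids)) stop("individual_ids length mismatch")
  if (ncol(a1) != length(locus_ids)) stop("locus_ids length mismatch")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  if (any(is.na(a1) != is.na(a2))) {
    stop("half-missing call: both alleles of a call must be missing or present")
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE)) {
    stop("allele codes must be positive integers")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, locus_ids)
  structure(list(individual_ids = individual_ids, locus_ids = locus_ids,
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing calls)\n",
              nrow(x$a1), ncol(x$a1), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_individuals <- function(x) length(x$individual_ids)

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) length(x$locus_ids)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param individuals Character ids or index vector of rows to keep
#'   (default all).
#' @param loci Character ids or index vector of columns to keep (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  ri <- if (is.null(individuals)) seq_along(x$individual_ids) else individuals
  ci <- if (is.null(loci)) seq_along(x$locus_ids) else loci
  if (is.character(ri)) {
    miss <- setdiff(ri, x$individual_ids)
    if (length(miss)) stop("unknown individuals: ", paste(miss, collapse = ", "))
    ri <- match(ri, x$individual_ids)
  }
  if (is.character(ci)) {
    miss <- setdiff(ci, x$locus_ids)
    if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
    ci <- match(ci, x$locus_ids)
  }
  genotype_matrix(x$a1[ri, ci, drop = FALSE], x$a2[ri, ci, drop = FALSE],
                  x$individual_ids[ri], x$locus_ids[ci])
}

#' Combine genotype matrices over individuals
#'
#' @param ... `genotype_matrix` objects sharing the same loci.
#' @return A `genotype_matrix` stacking all individuals.
#' @export
rbind_genotypes <- function(...) {
  mats <- list(...)
  loci <- mats[[1L]]$locus_ids
  for (m in mats) {
    if (!identical(m$locus_ids, loci)) stop("locus sets differ")
  }
  genotype_matrix(do.call(rbind, lapply(mats, `[[`, "a1")),
                  do.call(rbind, lapply(mats, `[[`, "a2")),
                  unlist(lapply(mats, `[[`, "individual_ids")),
                  loci)
}

#' Per-locus allele frequencies
#'
#' Relative allele frequencies from non-missing calls, optionally restricted
#' to a subset of individuals. Each returned vector is named by allele code
#' (sorted numerically) and carries attribute `n_calls`, the number of
#' non-missing diploid calls behind it (so `2 * n_calls` gene copies).
#'
#' @param x A `genotype_matrix`.
#' @param individuals Optional ids or indices of the individuals to use.
#' @return Named list (one entry per locus) of named frequency vectors; a
#'   locus with no data in the subset yields a zero-length vector.
#' @export
allele_freqs <- function(x, individuals = NULL) {
  if (!is.null(individuals)) x <- subset_genotypes(x, individuals = individuals)
  out <- vector("list", n_loci(x))
  names(out) <- x$locus_ids
  for (l in seq_len(n_loci(x))) {
    a <- c(x$a1[, l], x$a2[, l])
    a <- a[!is.na(a)]
    if (!length(a)) {
      f <- numeric(0)
      attr(f, "n_calls") <- 0L
    } else {
      tab <- table(a)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      f <- f[order(as.numeric(names(f)))]
      attr(f, "n_calls") <- length(a) %/% 2L
    }
    out[[l]] <- f
  }
  out
}

#' Summarise a single locus
#'
#' Allele count, frequency spectrum, observed heterozygosity Ho and Nei's
#' expected (gene) diversity He = 1 - sum(p_i^2), all from non-missing calls.
#'
#' @param x A `genotype_matrix`.
#' @param locus_id Locus label.
#' @return A list of class `locus_summary` with fields `locus_id`,
#'   `n_alleles`, `freqs`, `Ho`, `He`, `n_calls`.
#' @export
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, 1L, 2L), 3), matrix(c(1L, 2L, 2L), 3),
#'                       c("a", "b", "c"), "L1")
#' summarize_locus(gm, "L1")
summarize_locus <- function(x, locus_id) {
  l <- match(locus_id, x$locus_ids)
  if (is.na(l)) stop("locus not found: ", locus_id)
  a1 <- x$a1[, l]; a2 <- x$a2[, l]
  ok <- !is.na(a1)
  if (!any(ok)) stop("locus ", locus_id, " has no non-missing calls")
  p <- allele_freqs(subset_genotypes(x, loci = locus_id))[[1L]]
  attr(p, "n_calls") <- NULL
  structure(list(locus_id = locus_id,
                 n_alleles = length(p),
                 freqs = p,
                 Ho = mean(a1[ok] != a2[ok]),
                 He = 1 - sum(p^2),
                 n_calls = sum(ok)),
            class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("locus %s: %d alleles, He = %.3f, Ho = %.3f (n = %d calls)\n",
              x$locus_id, x$n_alleles, x$He, x$Ho, x$n_calls))
  invisible(x)
}

#' Summary table across all loci
#'
#' @param x A `genotype_matrix`.
#' @return A data.frame with one row per locus: `locus`, `n_alleles`, `Ho`,
#'   `He`, `n_calls`.
#' @export
locus_summary_table <- function(x) {
  rows <- lapply(x$locus_ids, function(l) {
    s <- summarize_locus(x, l)
    data.frame(locus = l, n_alleles = s$n_alleles, Ho = s$Ho, He = s$He,
               n_calls = s$n_calls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Validate / normalise a sample table. Columns: individual_id, locale,
# habitat (forest/savanna/mixed), region, mt_clade (F/S/unknown). Missing
# optional columns are filled with "unknown".
as_sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"individual_id" %in% names(df)) stop("sample table needs individual_id")
  if (!"locale" %in% names(df)) stop("sample table needs locale")
  if (!"habitat" %in% names(df)) df$habitat <- "unknown"
  if (!"region" %in% names(df)) df$region <- "unknown"
  if (!"mt_clade" %in% names(df)) df$mt_clade <- "unknown"
  df$individual_id <- as.character(df$individual_id)
  df$locale <- as.character(df$locale)
  df$habitat <- as.character(df$habitat)
  df$mt_clade <- as.character(df$mt_clade)
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids in sample table")
  bad <- setdiff(unique(df$habitat), c("forest", "savanna", "mixed", "unknown"))
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$mt_clade), c("F", "S", "unknown"))
  if (length(bad)) stop("unknown mt_clade label(s): ", paste(bad, collapse = ", "))
  df[, c("individual_id", "locale", "habitat", "region", "mt_clade")]
}
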