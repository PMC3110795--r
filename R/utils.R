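# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not disturb
#' the caller's random-number stream. With `seed = NULL` the code runs on the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a substream seed from a master seed
#'
#' Deterministic integer hash of a master seed plus arbitrary labels, kept
#' strictly below 2^31 so it is always a valid R seed. Used to fan one
#' top-level seed out into independent per-stage / per-locale streams.
#'
#' @param seed Master integer seed.
#' @param ... Further integers or character labels mixed into the hash.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "qc")
#' derive_seed(1, "locale", 3)
derive_seed <- function(seed, ...) {
  m <- 2147483629 # large prime < 2^31
  h <- as.double(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      codes <- utf8ToInt(paste(part, collapse = "\r"))
    } else {
      codes <- as.double(part)
    }
    for (v in codes) h <- (h * 31 + (v %% m)) %% m
  }
  as.integer(h)
}

# Base-2 Shannon entropy of a probability vector, with 0*log2(0) := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# All permutations of 1..k as a list (k! entries); used for label alignment.
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", factorial(k))
  i <- 0L
  for (s in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(s, k, after = pos - 1L)
    }
  }
  out
}

# Sample one category per row of a non-negative weight matrix (rows need not
# be normalised). Vectorised over rows; ties impossible almost surely.
sample_rows <- function(w) {
  k <- ncol(w)
  if (k == 1L) return(rep.int(1L, nrow(w)))
  cum <- w %*% upper.tri(diag(k), diag = TRUE)
  u <- stats::runif(nrow(w)) * cum[, k]
  max.col(cum >= u, ties.method = "first")
}

# Stable check that a numeric vector is a probability vector.
check_freq_vector <- function(p, what = "frequency vector", tol = 1e-6) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) || any(p < 0)) {
    stop(what, " must be non-negative numeric with no NA", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}

# write.table wrapper: TSV, LF endings, no quoting.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
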