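# STRUCTURE text dialect: optional header of locus names, then either two
# rows per individual (one allele copy per row) or one row with two columns
# per locus. Missing code is -9. An optional integer/character population
# column may follow the individual label.

#' Write genotypes in STRUCTURE format
#'
#' @param x A [genotype_matrix()].
#' @param path Output file.
#' @param table Optional sample table; if given, the locale column is written
#'   as the population column after each individual label.
#' @param layout `"two_row"` (default; two lines per individual) or
#'   `"two_column"` (two adjacent columns per locus).
#' @param header Write a first line of locus names (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path, table = NULL,
                            layout = c("two_row", "two_column"),
                            header = TRUE) {
  layout <- match.arg(layout)
  pop <- NULL
  if (!is.null(table)) {
    table <- as_sample_table(table)
    pop <- table$locale[match(x$individual_ids, table$individual_id)]
    if (anyNA(pop)) stop("sample table missing some individuals")
  }
  enc <- function(m) { m[is.na(m)] <- -9L; m }
  a1 <- enc(x$a1); a2 <- enc(x$a2)
  lines <- character(0)
  if (header) lines <- paste(x$locus_ids, collapse = " ")
  for (i in seq_len(nrow(a1))) {
    lead <- x$individual_ids[i]
    if (!is.null(pop)) lead <- paste(lead, pop[i])
    if (layout == "two_row") {
      lines <- c(lines,
                 paste(lead, paste(a1[i, ], collapse = " ")),
                 paste(lead, paste(a2[i, ], collapse = " ")))
    } else {
      inter <- as.vector(rbind(a1[i, ], a2[i, ]))
      lines <- c(lines, paste(lead, paste(inter, collapse = " ")))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read genotypes in STRUCTURE format
#'
#' Layout (two-row vs two-column) and the presence of a population column are
#' auto-detected from the token count per line against the locus count in the
#' header; both can be forced. Parse problems are reported with the
#' offending line number.
#'
#' @param path Input file with a first line of locus names.
#' @param layout `"auto"` (default), `"two_row"` or `"two_column"`.
#' @return List with `genotypes` (a [genotype_matrix()]) and `samples` (a
#'   partial sample table with `individual_id` and, when a population column
#'   is present, `locale`; otherwise `NULL`).
#' @export
read_structure <- function(path, layout = c("auto", "two_row", "two_column")) {
  layout <- match.arg(layout)
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) < 2L) stop("STRUCTURE file too short: ", path)
  loci <- strsplit(trimws(raw[keep[1L]]), "[ \t]+")[[1L]]
  L <- length(loci)
  data_lines <- keep[-1L]
  toks <- lapply(raw[data_lines], function(s) strsplit(trimws(s), "[ \t]+")[[1L]])
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L) {
    bad <- data_lines[which(lens != lens[1L])[1L]]
    stop("ragged row at line ", bad, ": expected ", lens[1L], " tokens")
  }
  nt <- lens[1L]
  # admissible shapes: id + [pop] + L (two_row) or 2L (two_column)
  shapes <- list(two_row = c(1L + L, 2L + L),
                 two_column = c(1L + 2L * L, 2L + 2L * L))
  if (layout == "auto") {
    hit <- names(shapes)[vapply(shapes, function(s) nt %in% s, logical(1))]
    if (length(hit) == 0L) {
      stop("cannot match ", nt, " tokens per row to ", L, " loci")
    }
    layout <- hit[1L]
  } else if (!nt %in% shapes[[layout]]) {
    stop("token count ", nt, " inconsistent with layout ", layout)
  }
  has_pop <- nt == shapes[[layout]][2L]
  n_meta <- 1L + has_pop

  parse_int <- function(v, line) {
    suppressWarnings(x <- as.integer(v))
    if (anyNA(x)) {
      stop("non-integer allele token '", v[is.na(x)][1L], "' at line ", line)
    }
    x
  }

  ids_raw <- vapply(toks, `[[`, character(1), 1L)
  pops_raw <- if (has_pop) vapply(toks, `[[`, character(1), 2L) else NULL

  if (layout == "two_row") {
    if (length(toks) %% 2L != 0L) {
      stop("odd number of data rows (", length(toks),
           ") for two-row layout in ", path)
    }
    runs <- rle(ids_raw)
    if (any(runs$lengths != 2L)) {
      bad_id <- runs$values[which(runs$lengths != 2L)[1L]]
      bad_line <- data_lines[which(ids_raw == bad_id)[1L]]
      stop("individual '", bad_id, "' has ", runs$lengths[runs$values == bad_id][1L],
           " rows (line ", bad_line, "); expected 2")
    }
    ids <- runs$values
    n <- length(ids)
    a1 <- matrix(NA_integer_, n, L)
    a2 <- matrix(NA_integer_, n, L)
    for (i in seq_len(n)) {
      r1 <- parse_int(toks[[2L * i - 1L]][-seq_len(n_meta)], data_lines[2L * i - 1L])
      r2 <- parse_int(toks[[2L * i]][-seq_len(n_meta)], data_lines[2L * i])
      a1[i, ] <- r1; a2[i, ] <- r2
    }
    pops <- if (has_pop) pops_raw[seq(1L, by = 2L, length.out = n)] else NULL
  } else {
    if (anyDuplicated(ids_raw)) {
      stop("duplicate individual id in two-column layout: ",
           ids_raw[anyDuplicated(ids_raw)])
    }
    ids <- ids_raw
    n <- length(ids)
    a1 <- matrix(NA_integer_, n, L)
    a2 <- matrix(NA_integer_, n, L)
    for (i in seq_len(n)) {
      v <- parse_int(toks[[i]][-seq_len(n_meta)], data_lines[i])
      a1[i, ] <- v[seq(1L, by = 2L, length.out = L)]
      a2[i, ] <- v[seq(2L, by = 2L, length.out = L)]
    }
    pops <- pops_raw
  }
  a1[a1 == -9L] <- NA_integer_
  a2[a2 == -9L] <- NA_integer_
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    # -9 must appear for both copies of a call
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
    warning("half-missing calls set fully missing")
  }
  samples <- if (!is.null(pops)) {
    data.frame(individual_id = ids, locale = pops, stringsAsFactors = FALSE)
  } else NULL
  list(genotypes = genotype_matrix(a1, a2, ids, loci), samples = samples)
}
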