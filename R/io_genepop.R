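# GenePop 4.x text dialect: a title line, one locus name per line, then one
# "Pop" block per population with lines "<id> ,  <aaabbb> <aaabbb> ...".
# Alleles are fixed-width 2- or 3-digit codes; 00/000 is missing.

#' Write genotypes in GenePop format
#'
#' Individuals are grouped into `Pop` blocks by the locale column of the
#' sample table, in order of first appearance. Allele codes must fit the
#' digit width.
#'
#' @param x A [genotype_matrix()].
#' @param table Sample table mapping every individual to a locale.
#' @param path Output file.
#' @param digits Allele code width, 2 or 3 (default 3).
#' @param title Title line content.
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(x, table, path, digits = 3L,
                          title = "strpop genepop export") {
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  table <- as_sample_table(table)
  pop <- table$locale[match(x$individual_ids, table$individual_id)]
  if (anyNA(pop)) stop("sample table missing some individuals")
  mx <- max(c(x$a1, x$a2), na.rm = TRUE)
  if (mx >= 10^digits) {
    stop("allele code ", mx, " exceeds ", digits, "-digit width")
  }
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", digits, "d"), a)
  }
  lines <- c(title, x$locus_ids)
  for (loc in unique(pop)) {
    lines <- c(lines, "Pop")
    for (i in which(pop == loc)) {
      geno <- paste0(fmt(x$a1[i, ]), fmt(x$a2[i, ]))
      lines <- c(lines, paste0(x$individual_ids[i], " ,  ",
                               paste(geno, collapse = " ")))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read genotypes in GenePop format
#'
#' The allele-code width (2 or 3 digits) is detected from the genotype
#' tokens. Each `Pop` block becomes one locale; the locale label is taken
#' from the shared `<prefix>_` of the block's individual ids when present,
#' else `pop1`, `pop2`, ...
#'
#' @param path Input file.
#' @return List with `genotypes` (a [genotype_matrix()]) and `samples` (a
#'   sample table with `individual_id` and `locale`).
#' @export
read_genepop <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 4L) stop("GenePop file too short: ", path)
  is_pop <- toupper(trimws(raw)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("no locus list / Pop separator found in ", path)
  }
  # locus names: lines 2..(first Pop - 1); allow a single comma-separated line
  loci <- trimws(raw[2:(first_pop - 1L)])
  if (length(loci) == 1L && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1L]])
  }
  L <- length(loci)
  blocks <- cumsum(is_pop)
  ids <- character(0); pops <- integer(0)
  genos <- list()
  for (i in seq_along(raw)[-seq_len(first_pop - 1L)]) {
    if (is_pop[i]) next
    line <- raw[i]
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) < 2L) stop("malformed individual line ", i, " in ", path)
    id <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[ \t]+")[[1L]]
    if (length(toks) != L) {
      stop("line ", i, ": expected ", L, " genotype tokens, got ", length(toks))
    }
    ids <- c(ids, id); pops <- c(pops, blocks[i])
    genos[[length(genos) + 1L]] <- toks
  }
  widths <- unique(nchar(unlist(genos)))
  if (length(widths) != 1L || !widths %in% c(4L, 6L)) {
    stop("inconsistent or unsupported genotype token width(s): ",
         paste(widths, collapse = ", "))
  }
  digits <- widths %/% 2L
  n <- length(ids)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    t1 <- suppressWarnings(as.integer(substr(genos[[i]], 1L, digits)))
    t2 <- suppressWarnings(as.integer(substr(genos[[i]], digits + 1L,
                                             2L * digits)))
    if (anyNA(t1) || anyNA(t2)) stop("non-numeric genotype token for ", ids[i])
    t1[t1 == 0L] <- NA_integer_
    t2[t2 == 0L] <- NA_integer_
    half <- is.na(t1) != is.na(t2)
    if (any(half)) { t1[half] <- NA_integer_; t2[half] <- NA_integer_ }
    a1[i, ] <- t1; a2[i, ] <- t2
  }
  # locale labels per block: common "<prefix>_" of ids if one exists
  locale_of_block <- function(b) {
    bids <- ids[pops == b]
    pref <- unique(sub("_.*$", "", bids))
    if (length(pref) == 1L && any(grepl("_", bids))) pref
    else paste0("pop", match(b, sort(unique(pops))))
  }
  locs <- vapply(sort(unique(pops)), locale_of_block, character(1))
  names(locs) <- sort(unique(pops))
  samples <- data.frame(individual_id = ids,
                        locale = locs[as.character(pops)],
                        stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  list(genotypes = genotype_matrix(a1, a2, ids, loci), samples = samples)
}

#' Read / write a sample table as TSV
#'
#' @param path File path.
#' @return `read_sample_table` returns a validated sample table data.frame.
#' @export
read_sample_table <- function(path) {
  as_sample_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param table Sample table data.frame.
#' @export
write_sample_table <- function(table, path) {
  write_tsv(as_sample_table(table), path)
}
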