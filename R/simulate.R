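#' Configuration for the synthetic STR + mtDNA generator
#'
#' Describes a two-species sampling design: a set of tropical-forest locales,
#' a larger set of savanna locales, and (by default) one mixed-habitat
#' contact-zone locale holding the rare hybrids. Defaults mirror a
#' continent-wide STR survey design: 17 savanna and 5 forest locales, loci
#' with 2-20 alleles, forest-clade mtDNA carried by about 20% of savanna
#' individuals, and hybrids produced by repeated backcrossing of hybrid
#' females into the savanna gene pool.
#'
#' @param n_forest_locales,n_savanna_locales,n_mixed_locales Locale counts.
#' @param individuals_per_locale Diploid individuals sampled per locale.
#' @param n_loci Number of STR loci.
#' @param alleles_per_locus Length-2 integer range; each locus draws its
#'   allele count uniformly from this range.
#' @param divergence_F Balding-Nichols drift parameter in (0,1) controlling
#'   how far each species' allele frequencies drift from the shared
#'   ancestral spectrum (an FST-like quantity).
#' @param hybrid_fraction_mixed Proportion of mixed-locale individuals that
#'   are constructed hybrids (F1 or backcross).
#' @param hybrid_fraction_savanna Proportion of savanna-locale individuals
#'   that are hybrids (default 0; set >0 to emulate rare savanna-side
#'   hybrids).
#' @param backcross_generations Maximum backcross generation g; constructed
#'   hybrids cycle through g = 0 (an F1), 1, ..., this value.
#' @param savanna_Fclade_rate Probability that a pure savanna individual
#'   carries introgressed F-clade mtDNA.
#' @param missing_rate Per-call missing-data probability (missing completely
#'   at random).
#' @param seed Master integer seed; all locale-level substreams derive from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_forest_locales = 5L,
                       n_savanna_locales = 17L,
                       n_mixed_locales = 1L,
                       individuals_per_locale = 20L,
                       n_loci = 12L,
                       alleles_per_locus = c(2L, 20L),
                       divergence_F = 0.3,
                       hybrid_fraction_mixed = 0.2,
                       hybrid_fraction_savanna = 0,
                       backcross_generations = 1L,
                       savanna_Fclade_rate = 0.20,
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_forest_locales = as.integer(n_forest_locales),
              n_savanna_locales = as.integer(n_savanna_locales),
              n_mixed_locales = as.integer(n_mixed_locales),
              individuals_per_locale = as.integer(individuals_per_locale),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              divergence_F = as.numeric(divergence_F),
              hybrid_fraction_mixed = as.numeric(hybrid_fraction_mixed),
              hybrid_fraction_savanna = as.numeric(hybrid_fraction_savanna),
              backcross_generations = as.integer(backcross_generations),
              savanna_Fclade_rate = as.numeric(savanna_Fclade_rate),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  for (f in c("n_forest_locales", "n_savanna_locales", "individuals_per_locale",
              "n_loci")) {
    if (cfg[[f]] < 1L) stop(f, " must be a positive count")
  }
  if (cfg$n_mixed_locales < 0L) stop("n_mixed_locales must be >= 0")
  if (length(cfg$alleles_per_locus) != 2L ||
      any(cfg$alleles_per_locus < 2L) ||
      cfg$alleles_per_locus[1L] > cfg$alleles_per_locus[2L]) {
    stop("alleles_per_locus must be an increasing range with minimum >= 2")
  }
  if (!(cfg$divergence_F > 0 && cfg$divergence_F < 1)) {
    stop("divergence_F must lie strictly in (0, 1)")
  }
  for (f in c("hybrid_fraction_mixed", "hybrid_fraction_savanna",
              "savanna_Fclade_rate", "missing_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$backcross_generations < 0L) stop("backcross_generations must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Drift two species' allele frequencies from an ancestral spectrum
#'
#' Balding-Nichols model: each descendant pool's frequency vector at a locus
#' is an independent Dirichlet draw with concentration
#' `ancestral * (1 - F) / F`, so the expected frequencies equal the ancestral
#' ones while `F` controls the variance (the FST-like divergence of each
#' pool from the ancestor).
#'
#' @param ancestral_freqs List of per-locus frequency vectors, each summing
#'   to 1.
#' @param divergence_F Drift parameter strictly in (0, 1).
#' @param seed Optional integer seed.
#' @return List with per-pool per-locus frequency lists `forest` and
#'   `savanna` (names preserved from `ancestral_freqs`).
#' @export
#' @examples
#' fr <- simulate_species_freqs(list(L1 = c(a1 = 0.5, a2 = 0.5)), 0.3, seed = 1)
#' sum(fr$forest$L1)
simulate_species_freqs <- function(ancestral_freqs, divergence_F, seed = NULL) {
  if (!(is.numeric(divergence_F) && length(divergence_F) == 1L &&
        divergence_F > 0 && divergence_F < 1)) {
    stop("divergence_F must lie strictly in (0, 1)")
  }
  if (is.numeric(ancestral_freqs)) ancestral_freqs <- list(ancestral_freqs)
  lapply(ancestral_freqs, check_freq_vector, what = "ancestral frequency vector")
  scale <- (1 - divergence_F) / divergence_F
  with_seed(seed, {
    draw_pool <- function() {
      lapply(ancestral_freqs, function(p) {
        g <- stats::rgamma(length(p), shape = p * scale)
        # guard against all-zero draws at extreme divergence
        if (sum(g) == 0) g[which.max(p)] <- 1
        f <- g / sum(g)
        names(f) <- names(p)
        f
      })
    }
    list(forest = draw_pool(), savanna = draw_pool())
  })
}

#' Expected minor-species ancestry after repeated backcrossing
#'
#' A hybrid female lineage that backcrosses into the majority species for
#' `g` generations retains `(1/2)^(g+1)` of its nuclear genome from the
#' minor species (`g = 0` is an F1 with 1/2), while her mtDNA clade is
#' transmitted unchanged along the maternal line.
#'
#' @param g Integer backcross generation count, `>= 0`.
#' @return Expected minor-species nuclear ancestry proportion.
#' @export
#' @examples
#' simulate_backcross_fraction(0) # F1: 0.5
#' simulate_backcross_fraction(6) # below 1 percent
simulate_backcross_fraction <- function(g) {
  if (!is.numeric(g) || any(is.na(g)) || any(g < 0) || any(g != floor(g))) {
    stop("g must be a non-negative integer")
  }
  0.5^(g + 1)
}

#' Assign an mtDNA clade label under sex-biased introgression
#'
#' Encodes the maternal-transmission logic of a hybrid zone where hybrid
#' females backcross into the savanna pool: every forest individual and
#' every hybrid-lineage descendant carries the forest (F) clade; a pure
#' savanna individual carries F with probability `savanna_Fclade_rate`
#' (introgressed mtDNA) and S otherwise. No forest individual ever receives
#' S.
#'
#' @param habitat_class Character vector in `{forest, savanna, mixed}`.
#' @param pedigree_class Character vector in
#'   `{pure_forest, pure_savanna, F1, backcross_g}` (any `backcross_*` label
#'   counts as a hybrid lineage), recycled against `habitat_class`.
#' @param savanna_Fclade_rate Introgression probability for pure savanna
#'   individuals.
#' @param seed Optional integer seed.
#' @return Character vector of clade labels "F"/"S".
#' @export
assign_mtdna <- function(habitat_class, pedigree_class,
                         savanna_Fclade_rate = 0.20, seed = NULL) {
  bad <- setdiff(unique(habitat_class), c("forest", "savanna", "mixed"))
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  if (savanna_Fclade_rate < 0 || savanna_Fclade_rate > 1) {
    stop("savanna_Fclade_rate must lie in [0, 1]")
  }
  n <- max(length(habitat_class), length(pedigree_class))
  habitat_class <- rep_len(habitat_class, n)
  pedigree_class <- rep_len(pedigree_class, n)
  hybrid <- pedigree_class == "F1" | startsWith(pedigree_class, "backcross")
  with_seed(seed, {
    clade <- rep("F", n)
    pure_sav <- !hybrid & habitat_class != "forest" &
      pedigree_class == "pure_savanna"
    clade[pure_sav] <- ifelse(stats::runif(sum(pure_sav)) < savanna_Fclade_rate,
                              "F", "S")
    clade
  })
}

# Pedigree classes for one locale: exactly round(frac * n) constructed
# hybrids cycling g = 0..G, remainder pure of the stated species.
locale_pedigrees <- function(n, hybrid_fraction, max_g, pure_class) {
  n_hyb <- round(hybrid_fraction * n)
  ped <- rep(pure_class, n)
  if (n_hyb > 0) {
    gs <- rep(seq.int(0L, max_g), length.out = n_hyb)
    ped[seq_len(n_hyb)] <- ifelse(gs == 0L, "F1", paste0("backcross_", gs))
  }
  ped
}

pedigree_forest_ancestry <- function(pedigree_class) {
  vapply(pedigree_class, function(p) {
    if (p == "pure_forest") 1
    else if (p == "pure_savanna") 0
    else if (p == "F1") 0.5
    else { # backcross_g into the savanna pool: forest is the minor species
      g <- as.integer(sub("backcross_", "", p))
      simulate_backcross_fraction(g)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic STR + mtDNA dataset with known truth
#'
#' Composes the generator: ancestral allele spectra per locus, two drifted
#' species pools, locale layout (forest / savanna / mixed), constructed
#' hybrids in the mixed locale(s), allele-copy-wise genotype sampling from
#' each individual's true ancestry vector, missing calls at random, and
#' maternal-line mtDNA clade assignment. One master seed drives hierarchical
#' per-locale substreams, so output is reproducible byte-for-byte.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `str_sim` with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()]}
#'     \item{samples}{a sample table data.frame (individual_id, locale,
#'       habitat, region, mt_clade)}
#'     \item{truth}{ground truth: `true_Q` (individuals x (forest, savanna)),
#'       `species_freqs`, `pedigree_class`, `mt_clade`}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_savanna_locales = 2,
#'                                    n_forest_locales = 2, seed = 7))
#' head(sim$samples)
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  # locus setup on its own substream
  setup <- with_seed(derive_seed(config$seed, "loci"), {
    n_all <- sample(seq.int(config$alleles_per_locus[1L],
                            config$alleles_per_locus[2L]),
                    config$n_loci, replace = TRUE)
    anc <- lapply(n_all, function(j) {
      g <- stats::rgamma(j, shape = 1)
      f <- g / sum(g)
      names(f) <- as.character(seq_len(j) * 4L + 96L) # tetranucleotide-like codes
      f
    })
    names(anc) <- sprintf("p%02d", seq_len(config$n_loci))
    anc
  })
  pools <- simulate_species_freqs(setup, config$divergence_F,
                                  seed = derive_seed(config$seed, "drift"))

  locales <- data.frame(
    locale = c(sprintf("FO%02d", seq_len(config$n_forest_locales)),
               sprintf("SV%02d", seq_len(config$n_savanna_locales)),
               if (config$n_mixed_locales > 0)
                 sprintf("MX%02d", seq_len(config$n_mixed_locales))),
    habitat = c(rep("forest", config$n_forest_locales),
                rep("savanna", config$n_savanna_locales),
                rep("mixed", config$n_mixed_locales)),
    stringsAsFactors = FALSE)
  locales$region <- c(rep("central_forest", config$n_forest_locales),
                      rep(c("eastern", "southern"),
                          length.out = config$n_savanna_locales),
                      rep("transition", config$n_mixed_locales))

  n_per <- config$individuals_per_locale
  all_gm <- vector("list", nrow(locales))
  samples <- vector("list", nrow(locales))
  trueQ <- vector("list", nrow(locales))
  peds <- vector("list", nrow(locales))

  for (li in seq_len(nrow(locales))) {
    loc <- locales$locale[li]
    hab <- locales$habitat[li]
    ped <- switch(hab,
      forest = rep("pure_forest", n_per),
      savanna = locale_pedigrees(n_per, config$hybrid_fraction_savanna,
                                 config$backcross_generations, "pure_savanna"),
      mixed = locale_pedigrees(n_per, config$hybrid_fraction_mixed,
                               config$backcross_generations, "pure_forest"))
    qf <- pedigree_forest_ancestry(ped)
    ids <- sprintf("%s_%03d", loc, seq_len(n_per))

    res <- with_seed(derive_seed(config$seed, "locale", loc), {
      a1 <- matrix(NA_integer_, n_per, config$n_loci)
      a2 <- matrix(NA_integer_, n_per, config$n_loci)
      for (l in seq_len(config$n_loci)) {
        pf <- pools$forest[[l]]; ps <- pools$savanna[[l]]
        codes <- as.integer(names(pf))
        for (copy in 1:2) {
          from_forest <- stats::runif(n_per) < qf
          al <- integer(n_per)
          if (any(from_forest)) {
            al[from_forest] <- sample.int(length(pf), sum(from_forest),
                                          replace = TRUE, prob = pf)
          }
          if (any(!from_forest)) {
            al[!from_forest] <- sample.int(length(ps), sum(!from_forest),
                                           replace = TRUE, prob = ps)
          }
          if (copy == 1L) a1[, l] <- codes[al] else a2[, l] <- codes[al]
        }
      }
      if (config$missing_rate > 0) {
        drop <- matrix(stats::runif(n_per * config$n_loci) < config$missing_rate,
                       n_per, config$n_loci)
        a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
      }
      clade <- assign_mtdna(rep(hab, n_per), ped, config$savanna_Fclade_rate)
      list(a1 = a1, a2 = a2, clade = clade)
    })

    all_gm[[li]] <- genotype_matrix(res$a1, res$a2, ids, names(setup))
    samples[[li]] <- data.frame(individual_id = ids, locale = loc,
                                habitat = hab, region = locales$region[li],
                                mt_clade = res$clade, stringsAsFactors = FALSE)
    trueQ[[li]] <- cbind(forest = qf, savanna = 1 - qf)
    peds[[li]] <- ped
  }

  gm <- do.call(rbind_genotypes, all_gm)
  tab <- do.call(rbind, samples)
  rownames(tab) <- NULL
  Q <- do.call(rbind, trueQ)
  rownames(Q) <- tab$individual_id
  structure(list(genotypes = gm,
                 samples = as_sample_table(tab),
                 truth = list(true_Q = Q,
                              species_freqs = pools,
                              pedigree_class = stats::setNames(unlist(peds),
                                                               tab$individual_id),
                              mt_clade = stats::setNames(tab$mt_clade,
                                                         tab$individual_id)),
                 config = config),
            class = "str_sim")
}

#' @export
print.str_sim <- function(x, ...) {
  cat(sprintf("str_sim: %d individuals at %d locales, %d loci (seed %d)\n",
              n_individuals(x$genotypes), length(unique(x$samples$locale)),
              n_loci(x$genotypes), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the genotype matrix in STRUCTURE and GenePop dialects, the sample
#' table as TSV, and the ground truth as JSON.
#'
#' @param sim An object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(structure_file = file.path(dir, "genotypes.str"),
             genepop_file = file.path(dir, "genotypes.gen"),
             sample_file = file.path(dir, "samples.tsv"),
             truth_file = file.path(dir, "truth.json"))
  write_structure(sim$genotypes, paths[["structure_file"]], table = sim$samples)
  write_genepop(sim$genotypes, sim$samples, paths[["genepop_file"]])
  write_tsv(sim$samples, paths[["sample_file"]])
  truth <- list(true_Q = apply(sim$truth$true_Q, 1, function(r) as.list(r),
                               simplify = FALSE),
                species_freqs = sim$truth$species_freqs,
                pedigree_class = as.list(sim$truth$pedigree_class),
                mt_clade = as.list(sim$truth$mt_clade))
  jsonlite::write_json(truth, paths[["truth_file"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
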