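# Config-driven orchestration: generate or load data, then QC, admixture
# scan + delta-K, locale means, FCA, chord/NJ tree, SIC ranking and the
# mito-nuclear report, with a machine-readable manifest.

pipeline_stage_names <- c("qc", "admixture", "deltak", "fca", "tree", "sic",
                          "mito")

validate_pipeline_config <- function(config) {
  allowed <- c("simulate", "inputs", "stages", "admixture", "sic", "tree",
               "seed", "out_dir", "exclude_loci")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config must name exactly one of 'simulate' or 'inputs'")
  }
  if (has_inp) {
    need <- c("genotypes", "samples")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop("inputs must name: ", paste(miss, collapse = ", "))
    for (f in need) {
      if (!file.exists(config$inputs[[f]])) {
        stop("input file not found: ", config$inputs[[f]])
      }
    }
  }
  if (!is.null(config$stages)) {
    unknown <- setdiff(names(config$stages), pipeline_stage_names)
    if (length(unknown)) {
      stop("unknown stage toggle(s): ", paste(unknown, collapse = ", "))
    }
  }
  invisible(config)
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file: ", path)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf("[strpop %s] ", format(Sys.time(), "%H:%M:%S")),
                       ...)
}

#' Run the full analysis pipeline from a config
#'
#' Stages: generate (or load) genotypes -> locus QC -> admixture scan over a
#' K range with replicates -> Evanno delta-K -> per-locale cluster means ->
#' FCA -> chord-distance NJ locale tree -> SIC locus ranking -> mito-nuclear
#' concordance and habitat association. Every artifact is written under
#' `out_dir` and listed in `manifest.json` together with the config hash and
#' seed; an identical config yields identical outputs. Per-stage seeds are
#' derived from the single top-level seed by stable hashing, so disabling
#' one stage never changes another's output.
#'
#' The config (YAML or JSON, or an equivalent R list) holds:
#' \describe{
#'   \item{simulate}{[sim_config()] fields for synthetic data, OR}
#'   \item{inputs}{`genotypes` (STRUCTURE `.str` or GenePop `.gen` file) and
#'     `samples` (TSV sample table)}
#'   \item{stages}{named logical toggles among qc, admixture, deltak, fca,
#'     tree, sic, mito (default all on)}
#'   \item{admixture}{`k_range`, `replicates`, `sweeps`, `burnin`, `alpha`,
#'     `lambda`}
#'   \item{exclude_loci}{loci to drop before analysis — the explicit home of
#'     QC-driven exclusions, which are never applied silently}
#'   \item{seed}{top-level integer seed (default 1)}
#' }
#'
#' @param config Path to a YAML/JSON config file, or the config as a list.
#' @param out_dir Output directory (overrides `out_dir` in the config).
#' @param seed Optional override of the config seed.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  seed0 <- as.integer(config$seed)

  stages <- stats::setNames(rep(TRUE, length(pipeline_stage_names)),
                            pipeline_stage_names)
  for (s in names(config$stages)) stages[[s]] <- isTRUE(config$stages[[s]])

  adm <- config$admixture
  k_range <- if (is.null(adm$k_range)) 1:3 else as.integer(unlist(adm$k_range))
  replicates <- if (is.null(adm$replicates)) 3L else as.integer(adm$replicates)
  sweeps <- if (is.null(adm$sweeps)) 300L else as.integer(adm$sweeps)
  burnin <- if (is.null(adm$burnin)) 100L else as.integer(adm$burnin)
  alpha <- if (is.null(adm$alpha)) 1 else adm$alpha
  lambda <- if (is.null(adm$lambda)) 1 else as.numeric(adm$lambda)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  skipped <- character(0)
  add_file <- function(path) files <<- c(files, basename(path))

  # --- data ---
  if (!is.null(config$simulate)) {
    pipeline_log(verbose, "simulating dataset")
    sim_args <- config$simulate
    sim_args$seed <- derive_seed(seed0, "simulate")
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    gm <- sim$genotypes
    samples <- sim$samples
    for (p in write_sim(sim, out_dir)) add_file(p)
  } else {
    pipeline_log(verbose, "loading inputs")
    gpath <- config$inputs$genotypes
    loaded <- if (grepl("\\.gen$", gpath, ignore.case = TRUE)) {
      read_genepop(gpath)
    } else {
      read_structure(gpath)
    }
    gm <- loaded$genotypes
    samples <- read_sample_table(config$inputs$samples)
    sim <- NULL
  }

  # QC exclusions are an explicit config decision, never applied silently
  if (!is.null(config$exclude_loci)) {
    drop <- as.character(unlist(config$exclude_loci))
    miss <- setdiff(drop, gm$locus_ids)
    if (length(miss)) stop("exclude_loci not in data: ",
                           paste(miss, collapse = ", "))
    pipeline_log(verbose, "excluding loci: ", paste(drop, collapse = ", "))
    gm <- subset_genotypes(gm, loci = setdiff(gm$locus_ids, drop))
  }

  # --- qc ---
  if (stages[["qc"]]) {
    pipeline_log(verbose, "locus QC")
    qc <- qc_report(gm, n_permutations = 1000L, seed = derive_seed(seed0, "qc"))
    write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    add_file("qc_report.tsv")
    ld <- linkage_screen(gm, n_permutations = 500L,
                         seed = derive_seed(seed0, "linkage"))
    write_tsv(ld, file.path(out_dir, "linkage.tsv"))
    add_file("linkage.tsv")
  }

  # --- admixture scan ---
  scan <- NULL
  if (stages[["admixture"]]) {
    pipeline_log(verbose, "admixture scan over K = ",
                 paste(k_range, collapse = ","))
    scan <- admixture_scan(gm, k_range = k_range, replicates = replicates,
                           seed = derive_seed(seed0, "admixture"),
                           sweeps = sweeps, burnin = burnin,
                           alpha = alpha, lambda = lambda)
    write_tsv(scan$L, file.path(out_dir, "L_values.tsv"))
    add_file("L_values.tsv")

    # main K for downstream reporting: 2 if scanned, else the smallest K > 1
    main_k <- if (2L %in% k_range) 2L else max(k_range)
    est <- scan$runs[[as.character(main_k)]][[1L]]
    qdf <- data.frame(individual_id = rownames(est$Q),
                      locale = samples$locale[match(rownames(est$Q),
                                                    samples$individual_id)],
                      est$Q, stringsAsFactors = FALSE)
    write_tsv(qdf, file.path(out_dir, sprintf("Q_K%d.tsv", main_k)))
    add_file(sprintf("Q_K%d.tsv", main_k))

    means <- mean_cluster_by_locale(est, samples)
    write_tsv(means, file.path(out_dir, "locale_means.tsv"))
    add_file("locale_means.tsv")
  }

  # --- delta K ---
  if (stages[["deltak"]]) {
    if (is.null(scan)) {
      warning("deltak stage needs the admixture stage; skipped")
      skipped <- c(skipped, "deltak")
    } else if (length(k_range) < 3L) {
      warning("insufficient K values for delta-K (need >= 3); stage skipped")
      skipped <- c(skipped, "deltak")
    } else {
      dk <- scan$delta_k
      if (is.null(dk)) dk <- evanno_delta_k(split(scan$L$L, scan$L$K))
      write_tsv(dk, file.path(out_dir, "delta_k.tsv"))
      add_file("delta_k.tsv")
    }
  }

  # --- fca ---
  if (stages[["fca"]]) {
    pipeline_log(verbose, "correspondence analysis")
    ca <- fca(gm)
    coords <- data.frame(individual_id = rownames(ca$coords),
                         ca$coords[, seq_len(min(4L, ncol(ca$coords))),
                                   drop = FALSE],
                         stringsAsFactors = FALSE)
    write_tsv(coords, file.path(out_dir, "fca_coords.tsv"))
    add_file("fca_coords.tsv")
    write_tsv(data.frame(axis = seq_along(ca$inertia_pct),
                         inertia_pct = ca$inertia_pct),
              file.path(out_dir, "fca_inertia.tsv"))
    add_file("fca_inertia.tsv")
  }

  # --- chord / NJ tree ---
  if (stages[["tree"]]) {
    n_locs <- length(unique(samples$locale))
    if (n_locs < 3L) {
      warning("tree stage needs >= 3 locales; skipped")
      skipped <- c(skipped, "tree")
    } else {
      pipeline_log(verbose, "chord distances and NJ tree")
      angular <- isTRUE(config$tree$angular)
      D <- chord_dist_matrix(gm, samples, angular = angular)
      write_tsv(data.frame(locale = rownames(D), D, check.names = FALSE),
                file.path(out_dir, "chord_dist.tsv"))
      add_file("chord_dist.tsv")
      tree <- neighbor_joining(D)
      ape::write.tree(tree, file.path(out_dir, "locale_tree.nwk"))
      add_file("locale_tree.nwk")
    }
  }

  # --- SIC ranking ---
  if (stages[["sic"]]) {
    f_ids <- samples$individual_id[samples$habitat == "forest"]
    s_ids <- samples$individual_id[samples$habitat == "savanna"]
    if (length(f_ids) < 2L || length(s_ids) < 2L) {
      warning("sic stage needs forest and savanna individuals; skipped")
      skipped <- c(skipped, "sic")
    } else {
      pipeline_log(verbose, "SIC locus ranking")
      ff <- allele_freqs(gm, f_ids)
      sf <- allele_freqs(gm, s_ids)
      ranking <- rank_loci(ff, sf)
      write_tsv(ranking, file.path(out_dir, "sic_ranking.tsv"))
      add_file("sic_ranking.tsv")
      # full profiles: one row per locus, one column per grid point
      grid <- seq(0.01, 0.99, by = 0.01)
      prof <- t(vapply(gm$locus_ids, function(l) {
        if (!length(ff[[l]]) || !length(sf[[l]])) return(rep(NA_real_, length(grid)))
        un <- sort(unique(c(names(ff[[l]]), names(sf[[l]]))))
        a <- stats::setNames(rep(0, length(un)), un); b <- a
        a[names(ff[[l]])] <- ff[[l]]; b[names(sf[[l]])] <- sf[[l]]
        sic_profile(a, b, grid, locus_id = l)$sic_values
      }, numeric(length(grid))))
      prof_df <- data.frame(locus = gm$locus_ids, prof)
      names(prof_df)[-1] <- sprintf("m_%.2f", grid)
      write_tsv(prof_df, file.path(out_dir, "sic_profiles.tsv"))
      add_file("sic_profiles.tsv")
    }
  }

  # --- mito-nuclear ---
  if (stages[["mito"]]) {
    pipeline_log(verbose, "mito-nuclear report")
    clades <- clade_frequencies(samples)
    write_tsv(clades, file.path(out_dir, "clade_frequencies.tsv"))
    add_file("clade_frequencies.tsv")
    if (!is.null(scan) && 2L %in% k_range) {
      est <- scan$runs[["2"]][[1L]]
      means <- mean_cluster_by_locale(est, samples)
      # savanna cluster = larger mean membership among savanna-locale rows
      sav_rows <- means$habitat == "savanna"
      qcols <- grep("^cluster", names(means), value = TRUE)
      sav_cluster <- qcols[which.max(colMeans(means[sav_rows, qcols,
                                                    drop = FALSE]))]
      conc <- concordance_table(clades, means, sav_cluster)
      write_tsv(conc, file.path(out_dir, "concordance.tsv"))
      add_file("concordance.tsv")
    }
    assoc <- tryCatch(habitat_association(clades), error = function(e) e)
    if (inherits(assoc, "error")) {
      warning("habitat association not computable: ", conditionMessage(assoc))
      skipped <- c(skipped, "mito_association")
    } else {
      jsonlite::write_json(list(table = assoc$table, p = assoc$p,
                                margins = list(rows = rowSums(assoc$table),
                                               cols = colSums(assoc$table))),
                           file.path(out_dir, "habitat_test.json"),
                           auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      add_file("habitat_test.json")
    }
  }

  manifest <- list(package = "strpop",
                   version = as.character(utils::packageVersion("strpop")),
                   seed = seed0,
                   config_hash = config_hash(config),
                   stages_run = names(stages)[stages],
                   stages_skipped = unique(skipped),
                   files = sort(unique(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
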