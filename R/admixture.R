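# Bayesian admixture clustering for multi-allelic loci: a Gibbs sampler over
# allele-copy origins z, cluster allele frequencies P, and individual
# ancestry vectors Q, with replicate-run label alignment and the Evanno
# delta-K statistic for choosing the number of clusters.

#' Specification of an admixture-model run
#'
#' @param K Number of clusters (>= 1).
#' @param alpha Symmetric Dirichlet parameter on ancestry vectors. A small
#'   alpha favours unadmixed genomes; alpha > 1 favours admixed ones. Give
#'   `"infer"` for a Metropolis random-walk update (normal proposal with sd
#'   `alpha_propsd`, uniform prior on (0, 10], started at 1).
#' @param alpha_propsd Proposal standard deviation for the alpha update
#'   (default 0.025, the customary small step for this sampler family).
#' @param lambda Symmetric Dirichlet prior on cluster allele frequencies.
#' @param admixture If `TRUE` (default) each allele copy has its own origin
#'   and Q is continuous; if `FALSE` each individual belongs wholly to one
#'   cluster.
#' @param sweeps Total Gibbs sweeps.
#' @param burnin Burn-in sweeps discarded before averaging
#'   (`sweeps > burnin >= 0`).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A list of class `admixture_spec`.
#' @export
admixture_spec <- function(K, alpha = 1, lambda = 1, admixture = TRUE,
                           sweeps = 500L, burnin = 200L, seed = 1L,
                           alpha_propsd = 0.025) {
  infer_alpha <- identical(alpha, "infer")
  if (infer_alpha) alpha <- 1
  spec <- list(K = as.integer(K), alpha = as.numeric(alpha),
               lambda = as.numeric(lambda), admixture = isTRUE(admixture),
               infer_alpha = infer_alpha,
               alpha_propsd = as.numeric(alpha_propsd),
               sweeps = as.integer(sweeps), burnin = as.integer(burnin),
               seed = as.integer(seed))
  if (spec$K < 1L) stop("K must be >= 1")
  if (spec$alpha <= 0) stop("alpha must be > 0")
  if (spec$lambda <= 0) stop("lambda must be > 0")
  if (spec$burnin < 0L || spec$sweeps <= spec$burnin) {
    stop("need sweeps > burnin >= 0")
  }
  structure(spec, class = "admixture_spec")
}

# Encode allele codes at each locus to 1..J; returns list with per-locus
# index matrices and allele-name vectors.
encode_alleles <- function(x) {
  lapply(seq_len(n_loci(x)), function(l) {
    codes <- sort(unique(c(x$a1[, l], x$a2[, l])))
    codes <- codes[!is.na(codes)]
    list(codes = as.character(codes),
         i1 = match(x$a1[, l], codes),
         i2 = match(x$a2[, l], codes))
  })
}

#' Gibbs sampler for the admixture model
#'
#' Cyclic conditional updates: (i) each allele copy's cluster of origin `z`
#' is sampled with probability proportional to `q_ik * p_klj`; (ii) each
#' cluster's allele frequencies are sampled from a Dirichlet with the prior
#' `lambda` plus origin-specific allele counts; (iii) each individual's
#' ancestry vector is sampled from a Dirichlet with `alpha` plus that
#' individual's origin counts (admixture model), or a single cluster label
#' is sampled per individual (no-admixture model). Missing calls are skipped
#' in all counts and in the likelihood. Posterior means of Q and P are
#' averaged over post-burn-in sweeps; the per-sweep data log-likelihood is
#' recorded as a trace. Clusters use independent frequency priors.
#'
#' @param x A [genotype_matrix()] with at least 2 individuals.
#' @param spec An [admixture_spec()].
#' @return An object of class `ancestry_estimate`: `Q` (posterior-mean
#'   individuals x K membership, rows summing to 1), `P` (per-locus K x J
#'   posterior-mean frequency matrices), `loglik_trace` (one entry per
#'   post-burn-in sweep), `L_hat` (see [estimate_log_prob_data()]),
#'   `alpha_trace` (when alpha is inferred) and `spec`.
#' @export
gibbs_admixture <- function(x, spec) {
  stopifnot(inherits(spec, "admixture_spec"))
  N <- n_individuals(x)
  if (N < 2L) stop("need at least 2 individuals")
  K <- spec$K
  L <- n_loci(x)
  enc <- encode_alleles(x)
  kept <- spec$sweeps - spec$burnin

  with_seed(spec$seed, {
    Q <- matrix(1 / K, N, K)
    P <- lapply(enc, function(e) {
      J <- length(e$codes)
      m <- matrix(stats::rgamma(K * J, shape = spec$lambda + 1), K, J)
      m / rowSums(m)
    })
    alpha <- spec$alpha
    Qsum <- matrix(0, N, K)
    Psum <- lapply(enc, function(e) matrix(0, K, length(e$codes)))
    trace <- numeric(kept)
    alpha_trace <- if (spec$infer_alpha) numeric(kept) else NULL

    for (sweep in seq_len(spec$sweeps)) {
      nik <- matrix(0, N, K)          # per-individual origin counts
      cnt <- lapply(enc, function(e) matrix(0, K, length(e$codes)))

      if (spec$admixture || K == 1L) {
        # (a) sample origins z | Q, P for every allele copy
        zs <- vector("list", L)
        for (l in seq_len(L)) {
          Pl <- P[[l]]
          zs[[l]] <- vector("list", 2L)
          for (copy in 1:2) {
            a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
            idx <- which(!is.na(a))
            if (!length(idx)) { zs[[l]][[copy]] <- integer(0); next }
            w <- Q[idx, , drop = FALSE] * t(Pl)[a[idx], , drop = FALSE]
            zs[[l]][[copy]] <- sample_rows(w)
          }
        }

        # (b) per-individual cluster-transposition Metropolis move: propose
        # swapping clusters (k1, k2) jointly in (z_i, q_i); the symmetric
        # Dirichlet prior and the q factors cancel, so acceptance is the
        # allele-frequency likelihood ratio of the swapped assignment. This
        # lets genuinely admixed individuals hop between mirrored modes that
        # plain conditional updates mix between only slowly when alpha is
        # small.
        if (K > 1L) {
          ks <- sample(K, 2L)
          k1 <- ks[1L]; k2 <- ks[2L]
          delta <- numeric(N)
          for (l in seq_len(L)) {
            logPl <- log(pmax(P[[l]], 1e-300))
            for (copy in 1:2) {
              a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
              idx <- which(!is.na(a))
              if (!length(idx)) next
              z <- zs[[l]][[copy]]
              in1 <- z == k1; in2 <- z == k2
              if (any(in1)) {
                delta[idx[in1]] <- delta[idx[in1]] +
                  logPl[k2, a[idx[in1]]] - logPl[k1, a[idx[in1]]]
              }
              if (any(in2)) {
                delta[idx[in2]] <- delta[idx[in2]] +
                  logPl[k1, a[idx[in2]]] - logPl[k2, a[idx[in2]]]
              }
            }
          }
          flip <- log(stats::runif(N)) < delta
          if (any(flip)) {
            for (l in seq_len(L)) {
              for (copy in 1:2) {
                a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
                idx <- which(!is.na(a))
                if (!length(idx)) next
                z <- zs[[l]][[copy]]
                doit <- flip[idx]
                z[doit & z == k1] <- -1L
                z[doit & z == k2] <- k1
                z[z == -1L] <- k2
                zs[[l]][[copy]] <- z
              }
            }
            Q[flip, c(k1, k2)] <- Q[flip, c(k2, k1), drop = FALSE]
          }
        }

        # (c) origin counts from the final assignments
        for (l in seq_len(L)) {
          for (copy in 1:2) {
            a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
            idx <- which(!is.na(a))
            if (!length(idx)) next
            z <- zs[[l]][[copy]]
            for (k in seq_len(K)) {
              sel <- z == k
              if (any(sel)) {
                nik[idx[sel], k] <- nik[idx[sel], k] + 1
                cnt[[l]][k, ] <- cnt[[l]][k, ] +
                  tabulate(a[idx[sel]], nbins = ncol(cnt[[l]]))
              }
            }
          }
        }
      } else {
        # no-admixture: one cluster label per individual
        ll_ik <- matrix(0, N, K)
        for (l in seq_len(L)) {
          logP <- log(P[[l]])
          for (copy in 1:2) {
            a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
            idx <- which(!is.na(a))
            if (!length(idx)) next
            ll_ik[idx, ] <- ll_ik[idx, ] + t(logP)[a[idx], , drop = FALSE]
          }
        }
        w <- exp(ll_ik - apply(ll_ik, 1, max))
        lab <- sample_rows(w)
        for (l in seq_len(L)) {
          for (copy in 1:2) {
            a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
            idx <- which(!is.na(a))
            if (!length(idx)) next
            for (k in seq_len(K)) {
              sel <- lab[idx] == k
              if (any(sel)) {
                cnt[[l]][k, ] <- cnt[[l]][k, ] +
                  tabulate(a[idx[sel]], nbins = ncol(cnt[[l]]))
              }
            }
          }
        }
        nik <- matrix(0, N, K)
        nik[cbind(seq_len(N), lab)] <- 2 * L # only used for Q below
      }

      # P | z
      for (l in seq_len(L)) {
        J <- ncol(cnt[[l]])
        g <- matrix(stats::rgamma(K * J, shape = spec$lambda + cnt[[l]]), K, J)
        rs <- rowSums(g)
        zero <- rs == 0
        if (any(zero)) { g[zero, 1L] <- 1; rs[zero] <- 1 }
        P[[l]] <- g / rs
      }

      # Q | z
      if (spec$admixture || K == 1L) {
        g <- matrix(stats::rgamma(N * K, shape = alpha + nik), N, K)
        rs <- rowSums(g)
        zero <- rs == 0
        if (any(zero)) { g[zero, ] <- 1; rs[zero] <- K }
        Q <- g / rs
      } else {
        Q <- matrix(0, N, K)
        Q[nik > 0] <- 1
      }

      # optional Metropolis step on alpha: symmetric normal proposal with
      # the customary small step (sd 0.025), uniform prior on (0, 10]
      if (spec$infer_alpha && K > 1L && spec$admixture) {
        prop <- alpha + stats::rnorm(1, 0, spec$alpha_propsd)
        if (prop > 0 && prop <= 10) {
          logQ <- log(pmax(Q, 1e-300))
          ld <- function(a) {
            N * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * sum(logQ)
          }
          if (log(stats::runif(1)) < ld(prop) - ld(alpha)) alpha <- prop
        }
      }

      # data log-likelihood under current (Q, P)
      ll <- 0
      for (l in seq_len(L)) {
        mix <- Q %*% P[[l]]
        for (copy in 1:2) {
          a <- if (copy == 1L) enc[[l]]$i1 else enc[[l]]$i2
          idx <- which(!is.na(a))
          if (length(idx)) {
            ll <- ll + sum(log(pmax(mix[cbind(idx, a[idx])], 1e-300)))
          }
        }
      }

      if (sweep > spec$burnin) {
        j <- sweep - spec$burnin
        Qsum <- Qsum + Q
        for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
        trace[j] <- ll
        if (spec$infer_alpha) alpha_trace[j] <- alpha
      }
    }

    Qbar <- Qsum / kept
    Qbar <- Qbar / rowSums(Qbar)
    rownames(Qbar) <- x$individual_ids
    colnames(Qbar) <- paste0("cluster", seq_len(K))
    Pbar <- lapply(seq_len(L), function(l) {
      m <- Psum[[l]] / kept
      m <- m / rowSums(m)
      dimnames(m) <- list(paste0("cluster", seq_len(K)), enc[[l]]$codes)
      m
    })
    names(Pbar) <- x$locus_ids
    structure(list(Q = Qbar, P = Pbar, loglik_trace = trace,
                   L_hat = estimate_log_prob_data_trace(trace),
                   alpha_trace = alpha_trace, spec = spec),
              class = "ancestry_estimate")
  })
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf("ancestry_estimate: %d individuals, K = %d, L_hat = %.1f\n",
              nrow(x$Q), ncol(x$Q), x$L_hat))
  invisible(x)
}

# Internal: model log-probability from a raw trace.
estimate_log_prob_data_trace <- function(trace) {
  if (length(trace) < 2L) stop("trace must have at least 2 entries")
  mean(trace) - stats::var(trace) / 2
}

#' Model log-probability of the data from a likelihood trace
#'
#' The harmonic-style estimator `L_hat = mean(trace) - var(trace)/2`
#' (sample variance), computed from the post-burn-in data log-likelihood
#' trace. This is the per-run L(K) consumed by [evanno_delta_k()].
#'
#' @param estimate An `ancestry_estimate`, or a numeric trace directly.
#' @return `L_hat`.
#' @export
#' @examples
#' estimate_log_prob_data(c(-10, -12)) # mean -11, var 2 -> -12
estimate_log_prob_data <- function(estimate) {
  trace <- if (inherits(estimate, "ancestry_estimate")) {
    estimate$loglik_trace
  } else {
    as.numeric(estimate)
  }
  estimate_log_prob_data_trace(trace)
}

#' Align cluster labels of a replicate run to a reference
#'
#' Cluster labels are arbitrary across replicate runs (label switching).
#' This applies the permutation of `other`'s clusters that maximises the sum
#' over individuals of the dot product between matched Q rows, found by
#' exhaustive search over all K! permutations (exact for the small K used
#' here).
#'
#' @param reference,other `ancestry_estimate` objects with the same K over
#'   the same individuals.
#' @return `other` with Q columns (and P rows) permuted; the permutation is
#'   attached as attribute `permutation`.
#' @export
align_cluster_labels <- function(reference, other) {
  if (ncol(reference$Q) != ncol(other$Q)) stop("mismatched K")
  if (!identical(rownames(reference$Q), rownames(other$Q))) {
    stop("mismatched individuals")
  }
  K <- ncol(reference$Q)
  if (K > 8L) stop("exhaustive alignment supported for K <= 8")
  perms <- all_permutations(K)
  scores <- vapply(perms, function(p) {
    sum(reference$Q * other$Q[, p, drop = FALSE])
  }, numeric(1))
  best <- perms[[which.max(scores)]]
  out <- other
  out$Q <- other$Q[, best, drop = FALSE]
  colnames(out$Q) <- colnames(reference$Q)
  out$P <- lapply(other$P, function(m) {
    m2 <- m[best, , drop = FALSE]
    rownames(m2) <- rownames(m)
    m2
  })
  attr(out, "permutation") <- best
  out
}

#' Evanno delta-K from replicate log-probabilities
#'
#' For replicate runs at consecutive K, the rate of change of L(K) is
#' summarised as `delta_K = mean_r |L(K+1,r) - 2 L(K,r) + L(K-1,r)| /
#' sd_r(L(K,r))`; the uppermost level of structure is the interior K where
#' delta_K peaks. Boundary K values are undefined. Zero replicate standard
#' deviation yields an infinite delta_K with a warning.
#'
#' @param L_runs Named list (names = K values, consecutive integers) of
#'   numeric vectors of replicate `L_hat` values (>= 2 replicates each), or
#'   a data.frame with columns `K` and `L`.
#' @return data.frame: K, mean_L, sd_L, delta_K (NA at the two boundary K).
#' @export
#' @examples
#' evanno_delta_k(list(`1` = c(-1000, -1000, -1000),
#'                     `2` = c(-900, -902, -904),
#'                     `3` = c(-880, -880, -880)))
evanno_delta_k <- function(L_runs) {
  if (is.data.frame(L_runs)) {
    L_runs <- split(L_runs$L, L_runs$K)
  }
  ks <- as.integer(names(L_runs))
  if (anyNA(ks)) stop("L_runs names must be the K values")
  o <- order(ks)
  ks <- ks[o]; L_runs <- L_runs[o]
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1L)) stop("K values must be consecutive")
  reps <- lengths(L_runs)
  if (any(reps < 2L)) stop("need at least 2 replicates per K")
  if (length(unique(reps)) != 1L) stop("replicate counts differ across K")
  R <- reps[1L]
  Lmat <- do.call(cbind, L_runs) # R x nK
  mean_L <- colMeans(Lmat)
  sd_L <- apply(Lmat, 2, stats::sd)
  delta <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)[-c(1L, length(ks))]) {
    second <- Lmat[, j + 1L] - 2 * Lmat[, j] + Lmat[, j - 1L]
    if (sd_L[j] == 0) {
      warning("zero replicate sd at K = ", ks[j], "; delta_K infinite")
      delta[j] <- Inf
    } else {
      delta[j] <- mean(abs(second)) / sd_L[j]
    }
  }
  data.frame(K = ks, mean_L = mean_L, sd_L = sd_L, delta_K = delta,
             row.names = NULL)
}

#' Replicate admixture runs over a range of K
#'
#' Convenience wrapper running [gibbs_admixture()] `replicates` times for
#' each K, with seeds derived from one master seed. Replicates at matched K
#' are label-aligned to the first replicate.
#'
#' @param x A [genotype_matrix()].
#' @param k_range Integer vector of K values.
#' @param replicates Replicate runs per K.
#' @param seed Master seed.
#' @param ... Further arguments passed to [admixture_spec()].
#' @return List with `runs` (nested list runs[[as.character(K)]][[r]]),
#'   `L` (data.frame K, replicate, L) and `delta_k` (data.frame or NULL when
#'   fewer than 3 K values were supplied).
#' @export
admixture_scan <- function(x, k_range = 1:4, replicates = 3L, seed = 1L, ...) {
  runs <- list()
  Ls <- list()
  for (K in k_range) {
    kruns <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      sp <- admixture_spec(K = K, seed = derive_seed(seed, "admix", K, r), ...)
      est <- gibbs_admixture(x, sp)
      if (r > 1L) est <- align_cluster_labels(kruns[[1L]], est)
      kruns[[r]] <- est
      Ls[[length(Ls) + 1L]] <- data.frame(K = K, replicate = r, L = est$L_hat)
    }
    runs[[as.character(K)]] <- kruns
  }
  L <- do.call(rbind, Ls)
  dk <- NULL
  if (length(k_range) >= 3L && all(diff(sort(k_range)) == 1L)) {
    dk <- evanno_delta_k(split(L$L, L$K))
  }
  list(runs = runs, L = L, delta_k = dk)
}

#' Mean cluster membership by locale
#'
#' Arithmetic mean of the Q columns over the individuals sampled at each
#' locale — the per-locale average contribution of each cluster.
#'
#' @param estimate An `ancestry_estimate` (or a bare Q matrix with row
#'   names).
#' @param table Sample table covering every individual in Q.
#' @return data.frame: locale, habitat, n, then one mean column per cluster.
#' @export
mean_cluster_by_locale <- function(estimate, table) {
  Q <- if (inherits(estimate, "ancestry_estimate")) estimate$Q else estimate
  if (is.null(colnames(Q))) colnames(Q) <- paste0("cluster", seq_len(ncol(Q)))
  table <- as_sample_table(table)
  miss <- setdiff(rownames(Q), table$individual_id)
  if (length(miss)) {
    stop("individual(s) missing from sample table: ",
         paste(miss, collapse = ", "))
  }
  idx <- match(rownames(Q), table$individual_id)
  loc <- table$locale[idx]
  hab <- table$habitat[idx]
  locs <- unique(loc)
  rows <- lapply(locs, function(lc) {
    sel <- loc == lc
    means <- colMeans(Q[sel, , drop = FALSE])
    cbind(data.frame(locale = lc, habitat = hab[sel][1L], n = sum(sel),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  do.call(rbind, rows)
}
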