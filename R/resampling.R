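# Resampling machinery for the connectedness statistic: delete-d jackknife,
# rarefaction with 95% CIs, geographic-label permutation null, and the
# latitudinal subsampling experiment. All operations are seed-deterministic
# and record the seed in their output.

# Shared precomputation: incidence matrix for the bin, patristic distances
# restricted to its taxa, and the observed statistic. Resampling replicates
# subset rows of the incidence matrix; pruning the tree and recomputing
# distances would give identical results (pruning preserves patristic
# distances) at far higher cost.
pbc_context <- function(occurrences, tree, time_bin = NULL, mu = 10,
                        regions = NULL) {
  inc <- build_incidence(occurrences, time_bin = time_bin, regions = regions)
  missing_taxa <- setdiff(rownames(inc), tree$tip.label)
  if (length(missing_taxa) > 0) {
    abort(paste0(
      "Occurrence taxa absent from the tree: ",
      paste(missing_taxa, collapse = ", ")
    ))
  }
  D <- patristic_matrix(tree)[rownames(inc), rownames(inc), drop = FALSE]
  list(inc = inc, D = D, mu = mu, observed = pbc_value(inc, D, mu))
}

# Fast scalar pBC used inside replicate loops.
pbc_value <- function(M, D, mu) {
  N <- nrow(M)
  L <- ncol(M)
  O <- 0
  for (k in seq_len(L)) {
    occ <- which(M[, k] > 0)
    dmin <- do.call(pmin, lapply(occ, function(j) D[, j]))
    O <- O + sum(pmax(M[, k], exp(-dmin / mu)))
  }
  (O - N) / (L * N - N)
}

# pBC on a taxon subset; NA when the subset leaves fewer than 2 taxa or
# fewer than 2 occupied regions (caller redraws).
pbc_value_subset <- function(keep, inc, D, mu) {
  M <- inc[keep, , drop = FALSE]
  M <- M[, colSums(M) > 0, drop = FALSE]
  if (nrow(M) < 2 || ncol(M) < 2) return(NA_real_)
  pbc_value(M, D[keep, keep, drop = FALSE], mu)
}

new_resample_distribution <- function(values, seed, observed, label) {
  structure(
    list(
      values = values,
      n_reps = length(values),
      observed = observed,
      seed = seed,
      label = label,
      summary = tibble(
        mean = mean(values),
        sd = sd(values),
        q2.5 = unname(quantile(values, 0.025, type = 7)),
        median = unname(quantile(values, 0.5, type = 7)),
        q97.5 = unname(quantile(values, 0.975, type = 7))
      )
    ),
    class = "pbc_resample"
  )
}

#' @export
print.pbc_resample <- function(x, ...) {
  cat(sprintf(
    "<pbc_resample: %s> %d replicates (seed %s)\n  observed %.5f | mean %.5f sd %.5f | 95%% [%.5f, %.5f]\n",
    x$label, x$n_reps, x$seed %||% "none", x$observed,
    x$summary$mean, x$summary$sd, x$summary$q2.5, x$summary$q97.5
  ))
  invisible(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Delete-d jackknife distribution of pBC
#'
#' Each replicate deletes a uniform random subset of taxa (retaining
#' `ceiling(retain_fraction * N)`), restricts the tree and incidence matrix
#' accordingly, and recomputes pBC. Replicates that leave fewer than two
#' taxa or fewer than two occupied regions are redrawn, up to a cap.
#'
#' @param occurrences Occurrence data frame (see [build_incidence()]).
#' @param tree Time-scaled ultrametric tree covering the occurrence taxa.
#' @param time_bin Optional time-bin name to restrict to.
#' @param mu pBC decay constant in Myr.
#' @param reps Number of replicates. Default 1000.
#' @param retain_fraction Fraction of taxa retained per replicate, in (0, 1].
#'   Default 0.75.
#' @param seed Integer seed for reproducibility.
#' @param max_redraws Cap on total redraws across all replicates.
#' @return A `pbc_resample` object: replicate values, summary, seed.
#' @export
jackknife_pbc <- function(occurrences, tree, time_bin = NULL, mu = 10,
                          reps = 1000, retain_fraction = 0.75, seed = NULL,
                          max_redraws = 100 * reps) {
  if (reps < 1) abort("`reps` must be >= 1.")
  if (retain_fraction <= 0 || retain_fraction > 1) {
    abort("`retain_fraction` must be in (0, 1].")
  }
  ctx <- pbc_context(occurrences, tree, time_bin, mu)
  taxa <- rownames(ctx$inc)
  n_keep <- ceiling(retain_fraction * length(taxa))
  set_seed_if(seed)
  values <- numeric(reps)
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      v <- pbc_value_subset(sample(taxa, n_keep), ctx$inc, ctx$D, mu)
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) abort("dataset too sparse to jackknife")
    }
    values[r] <- v
  }
  new_resample_distribution(values, seed, ctx$observed,
                            sprintf("jackknife (retain %.0f%%)", 100 * retain_fraction))
}

#' Rarefaction curve of pBC with 95% confidence intervals
#'
#' For each subsample size `k` from `min_n` up to the observed taxon count,
#' draws `reps` random `k`-subsets of taxa without replacement, recomputes
#' pBC on each, and records the mean and 2.5/97.5 percentiles. At `k = N`
#' the curve equals the point estimate with a zero-width interval.
#'
#' @inheritParams jackknife_pbc
#' @param min_n Smallest subsample size. Default 5.
#' @return A `pbc_rarefaction` object wrapping a tibble with columns
#'   `level`, `mean`, `ci_low`, `ci_high`, `n_reps`.
#' @export
rarefy_pbc <- function(occurrences, tree, time_bin = NULL, mu = 10,
                       min_n = 5, reps = 1000, seed = NULL,
                       max_redraws = 100 * reps) {
  ctx <- pbc_context(occurrences, tree, time_bin, mu)
  taxa <- rownames(ctx$inc)
  N <- length(taxa)
  if (N < min_n) abort(sprintf("Only %d taxa available; min_n = %d.", N, min_n))
  set_seed_if(seed)
  rows <- purrr::map(seq.int(min_n, N), function(k) {
    if (k == N) {
      vals <- ctx$observed
    } else {
      vals <- numeric(reps)
      redraws <- 0L
      for (r in seq_len(reps)) {
        repeat {
          v <- pbc_value_subset(sample(taxa, k), ctx$inc, ctx$D, mu)
          if (!is.na(v)) break
          redraws <- redraws + 1L
          if (redraws > max_redraws) {
            abort(sprintf("dataset too sparse to rarefy at level %d", k))
          }
        }
        vals[r] <- v
      }
    }
    tibble(
      level = k,
      mean = mean(vals),
      ci_low = unname(quantile(vals, 0.025, type = 7)),
      ci_high = unname(quantile(vals, 0.975, type = 7)),
      n_reps = length(vals)
    )
  })
  structure(
    list(curve = dplyr::bind_rows(rows), observed = ctx$observed,
         mu = mu, seed = seed),
    class = "pbc_rarefaction"
  )
}

#' @export
print.pbc_rarefaction <- function(x, ...) {
  cat(sprintf("<pbc_rarefaction> observed pBC %.5f (mu = %g)\n", x$observed, x$mu))
  print(x$curve, ...)
  invisible(x)
}

#' Permutation null model for pBC
#'
#' Shuffles the taxon-to-region-set assignment across taxa (preserving the
#' multiset of region sets, hence per-region occupancy counts and the number
#' of multi-region taxa) and recomputes pBC for each permutation. The
#' p-value is the plain proportion of permuted values at least as extreme as
#' the observed one; `add_one = TRUE` applies the (b+1)/(m+1) correction.
#'
#' @inheritParams jackknife_pbc
#' @param alternative `"less"` (default; observed statistic lower than the
#'   null, i.e. more endemic than random), `"greater"`, or `"two.sided"`.
#' @param add_one Use the add-one permutation p-value. Default `FALSE`.
#' @return A `pbc_permutation` object: observed value, null values, p-value.
#' @export
permutation_null <- function(occurrences, tree, time_bin = NULL, mu = 10,
                             reps = 1000, seed = NULL,
                             alternative = c("less", "greater", "two.sided"),
                             add_one = FALSE) {
  alternative <- match.arg(alternative)
  if (reps < 1) abort("`reps` must be >= 1.")
  ctx <- pbc_context(occurrences, tree, time_bin, mu)
  N <- nrow(ctx$inc)
  set_seed_if(seed)
  null_values <- numeric(reps)
  for (r in seq_len(reps)) {
    M <- ctx$inc[sample.int(N), , drop = FALSE]
    rownames(M) <- rownames(ctx$inc)
    null_values[r] <- pbc_value(M, ctx$D, mu)
  }
  prop <- function(count) {
    if (add_one) (count + 1) / (reps + 1) else count / reps
  }
  p_less <- prop(sum(null_values <= ctx$observed))
  p_greater <- prop(sum(null_values >= ctx$observed))
  p_value <- switch(alternative,
    less = p_less,
    greater = p_greater,
    two.sided = min(1, 2 * min(p_less, p_greater))
  )
  structure(
    list(
      observed = ctx$observed, null_values = null_values,
      p_value = p_value, alternative = alternative,
      n_reps = reps, seed = seed, mu = mu
    ),
    class = "pbc_permutation"
  )
}

#' @export
print.pbc_permutation <- function(x, ...) {
  cat(sprintf(
    "<pbc_permutation> observed pBC %.5f vs %d permutations: p = %.4g (%s)\n",
    x$observed, x$n_reps, x$p_value, x$alternative
  ))
  invisible(x)
}

#' Latitudinal subsampling experiment
#'
#' Imposes a biased latitudinal sampling window on a dataset: in each
#' replicate, a fixed fraction of the taxa whose latitude falls inside
#' `lat_band` is removed uniformly at random and pBC is recomputed on the
#' remainder. A taxon's latitude is the mean latitude of its occurrences
#' (`latitude_rule = "mean"`), or a taxon counts as in-band if any of its
#' occurrences is (`"any"`). Returns the replicate distribution, a kernel
#' density estimate of it on a 512-point grid over [0, 1] (Silverman
#' bandwidth), and `P(pBC <= t)` for each requested threshold.
#'
#' @inheritParams jackknife_pbc
#' @param lat_band Numeric length-2: the latitude band (degrees) to thin.
#'   Default `c(35, 50)`.
#' @param removal Fraction of in-band taxa removed per replicate
#'   (`ceiling(removal * n_band)` taxa). Default 0.95.
#' @param thresholds pBC thresholds at which to report `P(pBC <= t)`.
#' @param latitude_rule How a taxon's latitude is defined; see Details.
#' @return A `pbc_subsample` object.
#' @export
subsample_experiment <- function(occurrences, tree, time_bin = NULL, mu = 10,
                                 lat_band = c(35, 50), removal = 0.95,
                                 reps = 1000, thresholds = c(0.08, 0.8),
                                 seed = NULL,
                                 latitude_rule = c("mean", "any"),
                                 max_redraws = 100 * reps) {
  latitude_rule <- match.arg(latitude_rule)
  if (length(lat_band) != 2 || lat_band[1] >= lat_band[2]) {
    abort("`lat_band` must be c(min, max) with min < max.")
  }
  if (removal < 0 || removal > 1) abort("`removal` must be in [0, 1].")
  if (!"latitude" %in% names(occurrences)) {
    abort("`occurrences` lacks a `latitude` column.")
  }
  ctx <- pbc_context(occurrences, tree, time_bin, mu)
  taxa <- rownames(ctx$inc)

  occ <- occurrences
  if (!is.null(time_bin) && "time_bin" %in% names(occ)) {
    occ <- tidyr::separate_rows(occ, "time_bin", sep = ";")
    occ <- occ[trimws(occ$time_bin) == time_bin, , drop = FALSE]
  }
  occ <- occ[occ$taxon %in% taxa, , drop = FALSE]
  in_band <- if (latitude_rule == "mean") {
    lat <- tapply(occ$latitude, occ$taxon, mean)
    names(lat)[lat >= lat_band[1] & lat <= lat_band[2]]
  } else {
    unique(occ$taxon[occ$latitude >= lat_band[1] & occ$latitude <= lat_band[2]])
  }
  if (length(in_band) == 0) {
    abort(sprintf("No taxa in the latitudinal band [%g, %g].", lat_band[1], lat_band[2]))
  }
  n_remove <- ceiling(removal * length(in_band))

  set_seed_if(seed)
  values <- numeric(reps)
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      keep <- setdiff(taxa, sample(in_band, n_remove))
      v <- if (length(keep) >= 2) pbc_value_subset(keep, ctx$inc, ctx$D, mu) else NA_real_
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) abort("dataset too sparse for the subsampling experiment")
    }
    values[r] <- v
  }
  dist <- new_resample_distribution(values, seed, ctx$observed,
                                    sprintf("band removal %.0f%%", 100 * removal))
  dens <- if (sd(values) > 0) {
    d <- stats::density(values, bw = "nrd0", n = 512, from = 0, to = 1)
    tibble(pbc = d$x, density = d$y)
  } else {
    tibble(pbc = numeric(0), density = numeric(0))
  }
  structure(
    list(
      distribution = dist,
      removal_fraction = removal,
      lat_band = lat_band,
      n_band_taxa = length(in_band),
      prob_leq = setNames(purrr::map_dbl(thresholds, ~ mean(values <= .x)),
                          as.character(thresholds)),
      density = dens,
      seed = seed
    ),
    class = "pbc_subsample"
  )
}

#' @export
print.pbc_subsample <- function(x, ...) {
  cat(sprintf(
    "<pbc_subsample> removed %.0f%% of %d taxa in [%g, %g] degrees\n",
    100 * x$removal_fraction, x$n_band_taxa, x$lat_band[1], x$lat_band[2]
  ))
  print(x$distribution)
  cat("  P(pBC <= t):", paste(sprintf("%s: %.3f", names(x$prob_leq), x$prob_leq),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Compare two replicate distributions with a rank-sum test
#'
#' Two-sample Wilcoxon (Mann-Whitney) test via [stats::wilcox.test()]:
#' the exact null distribution is used for small untied samples, midranks
#' with a normal approximation otherwise. The reported `W` follows the
#' Mann-Whitney convention (number of pairs in which the first sample
#' exceeds the second, counting ties as half), so `0 <= W <= n1 * n2`.
#'
#' @param a,b `pbc_resample` objects or numeric vectors of replicate values.
#' @return A one-row tibble: `W`, `p_value`, `median_a`, `median_b`, `n_a`,
#'   `n_b`.
#' @export
compare_distributions <- function(a, b) {
  va <- if (inherits(a, "pbc_resample")) a$values else as.numeric(a)
  vb <- if (inherits(b, "pbc_resample")) b$values else as.numeric(b)
  if (length(va) == 0 || length(vb) == 0) abort("Both samples must be non-empty.")
  wt <- suppressWarnings(stats::wilcox.test(va, vb))
  tibble(
    W = unname(wt$statistic),
    p_value = wt$p.value,
    median_a = median(va),
    median_b = median(vb),
    n_a = length(va),
    n_b = length(vb)
  )
}
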