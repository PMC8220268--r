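# Synthetic-data generators with known ground truth: birth-death trees with
# extinct (fossil) tips, region assignments under endemic / random /
# dispersal / cosmopolitan scenarios, latitudinally structured occurrence
# and collection sampling, and covariate series with AR(1) noise for the
# GLS machinery. Every generator is seed-deterministic.

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles and validates the knobs shared by [simulate_tree()],
#' [assign_regions()] and [simulate_sampling()]. Defaults emulate a
#' Campanian-style Laramidian dataset: a few tens of fossil taxa, two
#' regions split at 43 degrees N, and collection effort concentrated in two
#' narrow latitudinal belts near 36-37 and 49-51 degrees N.
#'
#' @param n_taxa Minimum number of tips in the simulated tree. Default 30.
#' @param speciation,extinction Per-lineage rates (per Myr). Defaults 0.3
#'   and 0.1.
#' @param root_age Age of the root in Ma. Default 83.
#' @param range_myr Half-width of each taxon's stratigraphic range around
#'   its tip age (Myr), used for FAD/LAD and time-bin membership. Default 1.
#' @param region_scenario One of `"endemic_clades"`, `"cosmopolitan"`,
#'   `"random"`, `"mk_dispersal"`.
#' @param p Region-membership probability for the `"random"` scenario.
#' @param q Region-switch rate (per Myr) for the `"mk_dispersal"` scenario.
#' @param sampling_profile `"bimodal"` (Campanian-style) or `"uniform"`
#'   (Maastrichtian-style) latitudinal intensity of collections.
#' @param peaks,peak_sd,peak_weights Gaussian peak locations (degrees N),
#'   common standard deviation, and weights of the bimodal profile.
#'   Defaults: 36.5 and 50 degrees N, sd 1 degree, equal weights.
#' @param extent Latitudinal study extent `c(lo, hi)` in degrees. Default
#'   `c(25, 60)`.
#' @param lat_split Boundary between the southern and northern region
#'   (degrees N). Default 43.
#' @param effort Expected number of collections per 1-degree bin (the
#'   bimodal profile redistributes the same total). Default 12.
#' @param detection Probability that a collection samples each taxon whose
#'   range covers its bin. Default 0.8.
#' @param range_width_deg Latitudinal width of a taxon's true range within
#'   its region (degrees). Default 3.
#' @param time_bin Name stamped on generated occurrence records. Default
#'   `"Campanian"`.
#' @param covariate_truth List with `beta` (intercept + slopes on
#'   ln-covariates), `phi`, `sigma` for [simulate_covariates()].
#' @param seed Integer seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 30, speciation = 0.3, extinction = 0.1,
                            root_age = 83, range_myr = 1,
                            region_scenario = c("mk_dispersal", "endemic_clades",
                                                "cosmopolitan", "random"),
                            p = 0.5, q = 0.05,
                            sampling_profile = c("bimodal", "uniform"),
                            peaks = c(36.5, 50), peak_sd = 1,
                            peak_weights = c(0.5, 0.5),
                            extent = c(25, 60), lat_split = 43,
                            effort = 12, detection = 0.8,
                            range_width_deg = 3, time_bin = "Campanian",
                            covariate_truth = list(beta = c(2, 0.5),
                                                   phi = 0.6, sigma = 0.3),
                            seed = NULL) {
  region_scenario <- match.arg(region_scenario)
  sampling_profile <- match.arg(sampling_profile)
  if (speciation < 0 || extinction < 0) abort("Rates must be non-negative.")
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  if (q < 0) abort("`q` must be non-negative.")
  if (detection < 0 || detection > 1) abort("`detection` must be in [0, 1].")
  if (extent[1] >= extent[2]) abort("`extent` must be increasing.")
  if (lat_split <= extent[1] || lat_split >= extent[2]) {
    abort("`lat_split` must lie inside `extent`.")
  }
  structure(
    list(
      n_taxa = n_taxa, speciation = speciation, extinction = extinction,
      root_age = root_age, range_myr = range_myr,
      region_scenario = region_scenario, p = p, q = q,
      sampling_profile = sampling_profile, peaks = peaks, peak_sd = peak_sd,
      peak_weights = peak_weights / sum(peak_weights),
      extent = extent, lat_split = lat_split, effort = effort,
      detection = detection, range_width_deg = range_width_deg,
      time_bin = time_bin, covariate_truth = covariate_truth, seed = seed
    ),
    class = "scenario_config"
  )
}

#' Campanian-style scenario preset
#'
#' Bimodal collection effort (peaks near 36-37 and 49-51 degrees N) with a
#' dispersal-structured fauna.
#' @param ... Overrides passed to [scenario_config()].
#' @export
scenario_campanian <- function(...) {
  scenario_config(sampling_profile = "bimodal", time_bin = "Campanian", ...)
}

#' Maastrichtian-style scenario preset
#'
#' Even collection effort across the latitudinal extent.
#' @param ... Overrides passed to [scenario_config()].
#' @export
scenario_maastrichtian <- function(...) {
  scenario_config(sampling_profile = "uniform", time_bin = "Maastrichtian", ...)
}

# Default Late Cretaceous stage bins (Ma).
default_time_bins <- function() {
  tibble(
    bin = c("Campanian", "Maastrichtian"),
    start_ma = c(83.6, 72.1),
    end_ma = c(72.1, 66.0)
  )
}

bins_for_range <- function(fad, lad, bins = default_time_bins()) {
  hits <- bins$bin[fad > bins$end_ma & lad < bins$start_ma]
  paste(hits, collapse = ";")
}

#' Simulate a fossil tree with dated extinct tips
#'
#' Constant-rate birth-death simulation (via [ape::rlineage()]) retaining
#' extinct lineages as fossil tips, re-simulated until at least `n_taxa`
#' tips are produced. The root is anchored at `root_age` Ma, so each tip's
#' age is its extinction (or final-sampling) time in Ma. Stratigraphic
#' ranges of half-width `range_myr` around the tip age give each taxon a
#' FAD, LAD, and time-bin membership (a range crossing a bin boundary
#' carries both bins). The process starts from a bifurcation at the root,
#' so a pure-birth run to time `T` yields `2 * exp(speciation * T)`
#' expected tips.
#'
#' @param cfg A [scenario_config()].
#' @param max_tries Re-simulation cap. Default 100.
#' @param max_taxa Upper bound on accepted tree size; simulations are
#'   redrawn outside `[n_taxa, max_taxa]` so trees stay in the few-tens
#'   range typical of the target clades. Default `4 * cfg$n_taxa`.
#' @return A list: `tree` (time-scaled [ape::phylo] with `root.time`) and
#'   `ages` (tibble `taxon`, `fad_ma`, `lad_ma`, `tip_age_ma`, `time_bins`).
#' @export
simulate_tree <- function(cfg, max_tries = 100, max_taxa = 4 * cfg$n_taxa) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$speciation <= 0) abort("`speciation` must be positive to grow a tree.")
  if (cfg$n_taxa < 5) abort("`n_taxa` must be at least 5.")
  set_seed_if(cfg$seed)
  growth <- cfg$speciation - cfg$extinction
  t_max <- if (growth > 0.01) {
    min(log(cfg$n_taxa) / growth, cfg$root_age)
  } else {
    min(2 * cfg$n_taxa / cfg$speciation, cfg$root_age)
  }
  tree <- NULL
  for (i in seq_len(max_tries)) {
    cand <- ape::rlineage(cfg$speciation, cfg$extinction, Tmax = t_max)
    if (!is.null(cand) && ape::Ntip(cand) >= cfg$n_taxa &&
        ape::Ntip(cand) <= max_taxa) {
      tree <- cand
      break
    }
  }
  if (is.null(tree)) {
    abort(sprintf(
      "Could not reach %d tips in %d tries (speciation %.3g, extinction %.3g).",
      cfg$n_taxa, max_tries, cfg$speciation, cfg$extinction
    ))
  }
  tree$root.time <- cfg$root_age
  ta <- tip_ages(tree)
  ages <- tibble(
    taxon = names(ta),
    tip_age_ma = unname(ta),
    fad_ma = pmin(unname(ta) + cfg$range_myr, cfg$root_age),
    lad_ma = pmax(unname(ta) - cfg$range_myr, 0)
  )
  ages$time_bins <- purrr::map2_chr(ages$fad_ma, ages$lad_ma, bins_for_range)
  list(tree = tree, ages = ages)
}

#' Assign taxa to biogeographic regions
#'
#' Four scenarios with known ground truth:
#' * `endemic_clades`: the two clades subtending the root are mapped wholly
#'   to north and south (binary-limit pBC = 0 when neither clade is empty);
#' * `cosmopolitan`: every taxon occupies both regions (pBC = 1);
#' * `random`: independent Bernoulli(`p`) membership per region, with one
#'   uniformly chosen region guaranteed when both draws fail;
#' * `mk_dispersal`: a two-state continuous-time Markov character (switch
#'   rate `q` per Myr, via [ape::rTraitDisc()]) evolves along the tree and
#'   the tip state is the region.
#'
#' @param tree An [ape::phylo].
#' @param cfg A [scenario_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A tibble with columns `taxon`, `region` (one row per membership).
#' @export
assign_regions <- function(tree, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  set_seed_if(seed)
  taxa <- tree$tip.label
  regions <- c("north", "south")
  out <- switch(cfg$region_scenario,
    endemic_clades = {
      root <- ape::Ntip(tree) + 1L
      kids <- tree$edge[tree$edge[, 1] == root, 2]
      first_clade <- if (kids[1] <= ape::Ntip(tree)) {
        taxa[kids[1]]
      } else {
        ape::extract.clade(tree, kids[1])$tip.label
      }
      tibble(taxon = taxa,
             region = ifelse(taxa %in% first_clade, "north", "south"))
    },
    cosmopolitan = tidyr::expand_grid(taxon = taxa, region = regions),
    random = {
      member <- matrix(rbinom(2 * length(taxa), 1, cfg$p), ncol = 2)
      none <- rowSums(member) == 0
      member[cbind(which(none), sample(2, sum(none), replace = TRUE))] <- 1L
      tibble(
        taxon = rep(taxa, times = rowSums(member)),
        region = unlist(purrr::map(seq_along(taxa),
                                   ~ regions[member[.x, ] == 1]))
      )
    },
    mk_dispersal = {
      states <- ape::rTraitDisc(
        tree, model = "ER", k = 2, rate = cfg$q,
        states = regions, root.value = sample(2, 1)
      )
      tibble(taxon = taxa, region = as.character(states[taxa]))
    }
  )
  dplyr::arrange(out, .data$taxon, .data$region)
}

# Latitudinal intensity over 1-degree bins, normalized to sum to 1.
profile_weights <- function(cfg, bin_floors) {
  centers <- bin_floors + 0.5
  w <- if (cfg$sampling_profile == "uniform") {
    rep(1, length(centers))
  } else {
    vapply(centers,
           function(x) sum(cfg$peak_weights * stats::dnorm(x, cfg$peaks, cfg$peak_sd)),
           numeric(1))
  }
  w / sum(w)
}

#' Simulate latitudinally structured occurrence and collection tables
#'
#' Each taxon-region membership receives a true latitudinal range inside
#' its region's band (north: above `lat_split`; south: below). Collections
#' are placed in 1-degree bins by independent Poisson draws with mean
#' proportional to the latitudinal profile times total effort; each
#' collection then samples every taxon whose true range covers its bin with
#' probability `detection`.
#'
#' @param assignments Tibble from [assign_regions()] (`taxon`, `region`).
#' @param cfg A [scenario_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A list of tibbles: `occurrences` (taxon, region, latitude,
#'   longitude, time_bin, collection_id), `collections` (collection_id,
#'   latitude, bin_floor), and `ranges` (the true ranges).
#' @export
simulate_sampling <- function(assignments, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  set_seed_if(seed)
  bands <- list(
    north = c(cfg$lat_split, cfg$extent[2]),
    south = c(cfg$extent[1], cfg$lat_split)
  )
  w <- cfg$range_width_deg
  ranges <- assignments
  ranges$lat_min <- NA_real_
  ranges$lat_max <- NA_real_
  for (i in seq_len(nrow(ranges))) {
    band <- bands[[ranges$region[i]]]
    wi <- min(w, band[2] - band[1])
    center <- runif(1, band[1] + wi / 2, band[2] - wi / 2)
    ranges$lat_min[i] <- center - wi / 2
    ranges$lat_max[i] <- center + wi / 2
  }

  bin_floors <- seq(cfg$extent[1], cfg$extent[2] - 1)
  lambda <- cfg$effort * length(bin_floors) * profile_weights(cfg, bin_floors)
  n_coll <- rpois(length(bin_floors), lambda)
  if (sum(n_coll) == 0) {
    warn("Zero collections drawn (effort too low); returning empty tables.")
    return(list(
      occurrences = tibble(taxon = character(0), region = character(0),
                           latitude = numeric(0), longitude = numeric(0),
                           time_bin = character(0), collection_id = character(0)),
      collections = tibble(collection_id = character(0), latitude = numeric(0),
                           bin_floor = numeric(0)),
      ranges = ranges
    ))
  }
  collections <- tibble(
    bin_floor = rep(bin_floors, n_coll),
    latitude = rep(bin_floors, n_coll) + runif(sum(n_coll)),
    collection_id = sprintf("coll_%05d", seq_len(sum(n_coll)))
  )

  occ <- purrr::map_dfr(seq_len(nrow(collections)), function(ci) {
    b <- collections$bin_floor[ci]
    # a taxon is sampleable when its true range overlaps the bin [b, b+1)
    cand <- ranges[ranges$lat_min < b + 1 & ranges$lat_max > b, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    hit <- rbinom(nrow(cand), 1, cfg$detection) == 1
    if (!any(hit)) return(NULL)
    tibble(
      taxon = cand$taxon[hit],
      region = cand$region[hit],
      latitude = collections$latitude[ci],
      collection_id = collections$collection_id[ci]
    )
  })
  if (nrow(occ) == 0) {
    occ <- tibble(taxon = character(0), region = character(0),
                  latitude = numeric(0), collection_id = character(0))
  }
  occ$longitude <- runif(nrow(occ), -112, -100)
  occ$time_bin <- cfg$time_bin
  occ <- occ[, c("taxon", "region", "latitude", "longitude", "time_bin",
                 "collection_id")]
  list(
    occurrences = occ,
    collections = collections[, c("collection_id", "latitude", "bin_floor")],
    ranges = ranges
  )
}

#' Simulate per-bin covariates and a count response with AR(1) noise
#'
#' Covariates are drawn from log-normal generators; the latent ln-scale
#' response is `beta0 + sum(beta_j * ln(cov_j)) + e`, where `e` is a
#' stationary AR(1) process with autocorrelation `phi` and marginal
#' standard deviation `sigma`. The exported `count` column is
#' `round(exp(latent))`; the latent series is kept so estimators can be
#' checked against ground truth without discretization error.
#'
#' @param n_bins Number of 1-degree bins (>= 10). Default 35.
#' @param truth List with `beta` (intercept followed by slopes; slopes
#'   attach to the first `length(beta) - 1` covariates), `phi` in (-1, 1),
#'   and `sigma >= 0`.
#' @param n_covariates Number of covariate columns (extra ones are inert
#'   noise). Default `max(length(truth$beta) - 1, 3)`.
#' @param bin_start First bin floor (degrees). Default 25.
#' @param seed Integer seed.
#' @return A tibble `bin_floor`, `cov1..covm`, `ln_response`, `count`, with
#'   the generating parameters in attribute `truth`.
#' @export
simulate_covariates <- function(n_bins = 35,
                                truth = list(beta = c(2, 0.5), phi = 0.6,
                                             sigma = 0.3),
                                n_covariates = max(length(truth$beta) - 1, 3),
                                bin_start = 25, seed = NULL) {
  if (n_bins < 10) abort("`n_bins` must be at least 10.")
  if (abs(truth$phi) >= 1) abort("`phi` must lie in (-1, 1).")
  if (truth$sigma < 0) abort("`sigma` must be non-negative.")
  slopes <- truth$beta[-1]
  if (n_covariates < length(slopes)) {
    abort("`n_covariates` must cover every slope in `truth$beta`.")
  }
  set_seed_if(seed)
  covs <- matrix(rlnorm(n_bins * n_covariates, meanlog = 3, sdlog = 0.5),
                 nrow = n_bins)
  colnames(covs) <- paste0("cov", seq_len(n_covariates))
  noise <- if (truth$sigma == 0) {
    rep(0, n_bins)
  } else if (truth$phi == 0) {
    rnorm(n_bins, sd = truth$sigma)
  } else {
    as.numeric(arima.sim(
      model = list(ar = truth$phi), n = n_bins,
      sd = truth$sigma * sqrt(1 - truth$phi^2)
    ))
  }
  latent <- truth$beta[1] +
    as.numeric(log(covs[, seq_along(slopes), drop = FALSE]) %*% slopes) + noise
  out <- dplyr::bind_cols(
    tibble(bin_floor = seq(bin_start, length.out = n_bins)),
    as_tibble(covs),
    tibble(ln_response = latent, count = round(exp(latent)))
  )
  attr(out, "truth") <- truth
  out
}

#' Simulate a full scenario dataset
#'
#' Convenience wrapper chaining [simulate_tree()], [assign_regions()] and
#' [simulate_sampling()] under one seed.
#'
#' @param cfg A [scenario_config()].
#' @return A list: `tree`, `ages`, `assignments`, `occurrences`,
#'   `collections`, `ranges`, `config`.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  sim <- simulate_tree(cfg)
  assignments <- assign_regions(sim$tree, cfg,
                                seed = derive_seed(cfg$seed %||% 1L, "regions"))
  sampled <- simulate_sampling(assignments, cfg,
                               seed = derive_seed(cfg$seed %||% 1L, "sampling"))
  c(sim, list(assignments = assignments), sampled, list(config = cfg))
}
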