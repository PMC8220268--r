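# Configuration-driven orchestration: the full chain from inputs (files or
# a synthetic scenario) through time-scaling, connectedness, resampling,
# and the sampling-bias regressions, with per-stage seeds derived from one
# master seed.

#' Derive a stage seed from a master seed
#'
#' Stable arithmetic hash of the stage name folded into the master seed, so
#' every stage draws from its own stream and adding a stage never perturbs
#' the draws of earlier stages. Result is a non-negative integer below
#' 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Default run configuration
#'
#' Returns the default `RunConfig` as a named list; [run_analysis()] merges
#' user configuration (a list or a YAML file) over these defaults.
#' Input can be either a synthetic scenario (`scenario` = arguments to
#' [scenario_config()]) or file paths (`tree_file`, `ages_file`,
#' `occurrence_file`, optionally `covariate_file`).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    scenario = list(),          # args to scenario_config(); NULL if using files
    tree_file = NULL,
    ages_file = NULL,
    occurrence_file = NULL,
    covariate_file = NULL,
    time_bin = NULL,            # NULL = use all records
    mbl = 1,
    age_type = "fad",
    mu = 10,
    mu_range = 1:15,
    reps = 1000,
    retain_fraction = 0.75,
    min_n = 5,
    rarefy = FALSE,
    subsample = list(enabled = FALSE, lat_band = c(35, 50), removal = 0.95,
                     thresholds = c(0.08, 0.8)),
    gls = list(enabled = TRUE, covariates = NULL, log_offset = 1),
    seed = 1L
  )
}

merge_config <- function(user, defaults = default_run_config()) {
  if (is.character(user) && length(user) == 1) {
    user <- yaml::read_yaml(user)
  }
  stopifnot(is.list(user))
  modifyList(defaults, user)
}

#' Validate pipeline inputs without modifying them
#'
#' Cross-checks occurrences, tree, ages and covariates and reports one row
#' per issue with a severity (`"error"` or `"warning"`). An empty tibble
#' means a clean input set. Nothing is modified and nothing stops; callers
#' decide how to act on errors.
#'
#' @param occurrences Occurrence data frame (optional).
#' @param tree [ape::phylo] (optional).
#' @param ages Taxon age table (optional).
#' @param covariates Per-bin covariate table (optional).
#' @return A tibble with columns `severity`, `stage`, `message`.
#' @export
validate_inputs <- function(occurrences = NULL, tree = NULL, ages = NULL,
                            covariates = NULL) {
  issues <- list()
  add <- function(severity, stage, message) {
    issues[[length(issues) + 1]] <<- tibble(
      severity = severity, stage = stage, message = message
    )
  }
  if (!is.null(occurrences)) {
    if ("latitude" %in% names(occurrences)) {
      bad <- which(occurrences$latitude < -90 | occurrences$latitude > 90)
      if (length(bad) > 0) {
        add("error", "occurrences",
            sprintf("latitude outside [-90, 90] in record(s): %s",
                    paste(head(bad, 10), collapse = ", ")))
      }
    }
    if (!all(c("taxon", "region") %in% names(occurrences))) {
      add("error", "occurrences", "missing required column(s): taxon/region")
    }
  }
  if (!is.null(occurrences) && !is.null(tree)) {
    orphans <- setdiff(unique(occurrences$taxon), tree$tip.label)
    if (length(orphans) > 0) {
      add("warning", "cross",
          sprintf("occurrence taxa absent from tree: %s",
                  paste(orphans, collapse = ", ")))
    }
  }
  if (!is.null(ages)) {
    if (any(ages$fad_ma < ages$lad_ma, na.rm = TRUE)) {
      add("error", "ages", "fad_ma < lad_ma for some taxa")
    }
    if (!is.null(tree)) {
      missing_ages <- setdiff(tree$tip.label, ages$taxon)
      if (length(missing_ages) > 0) {
        add("warning", "cross",
            sprintf("tree tips without ages: %s",
                    paste(missing_ages, collapse = ", ")))
      }
    }
  }
  if (!is.null(covariates)) {
    if (!"bin_floor" %in% names(covariates)) {
      add("error", "covariates", "missing `bin_floor` column")
    } else if (is.unsorted(covariates$bin_floor)) {
      add("warning", "covariates", "bins are not sorted south-to-north")
    }
  }
  if (length(issues) == 0) {
    tibble(severity = character(0), stage = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Run the full provincialism analysis
#'
#' Orchestrates: input loading (files or synthetic scenario) -> time-bin
#' filtering and tree pruning -> minimum-branch-length time-scaling ->
#' ultrametricization -> incidence matrix -> pBC with a mu sweep ->
#' jackknife, permutation null and (optionally) rarefaction and the
#' latitudinal subsampling experiment -> latitudinal binning and curve
#' correlation -> (optionally) GLS model selection over covariates.
#' Per-stage seeds are derived from the master seed with [derive_seed()].
#'
#' @param config A named list (merged over [default_run_config()]) or the
#'   path to a YAML file with the same structure.
#' @return A `pbc_run_report`: list of per-stage results plus provenance
#'   (`config`, `seeds`, `versions`, `timestamp`).
#' @export
run_analysis <- function(config = list()) {
  cfg <- merge_config(config)
  seeds <- list(
    scenario = derive_seed(cfg$seed, "scenario"),
    jackknife = derive_seed(cfg$seed, "jackknife"),
    rarefaction = derive_seed(cfg$seed, "rarefaction"),
    permutation = derive_seed(cfg$seed, "permutation"),
    subsample = derive_seed(cfg$seed, "subsample"),
    covariates = derive_seed(cfg$seed, "covariates")
  )

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$occurrence_file)) {
    occurrences <- read_occurrences(cfg$occurrence_file)
    tree <- read_newick(cfg$tree_file)
    ages <- read_taxon_ages(cfg$ages_file)
    covariates <- if (!is.null(cfg$covariate_file)) read_covariates(cfg$covariate_file)
    collections <- NULL
  } else {
    scen <- do.call(scenario_config, modifyList(cfg$scenario,
                                                list(seed = seeds$scenario)))
    sim <- simulate_scenario(scen)
    occurrences <- sim$occurrences
    collections <- sim$collections
    tree <- sim$tree
    ages <- sim$ages
    covariates <- NULL
    if (is.null(cfg$time_bin)) cfg$time_bin <- scen$time_bin
  }
  checks <- validate_inputs(occurrences, tree, ages, covariates)
  if (any(checks$severity == "error")) {
    abort(paste0("Input validation failed:\n",
                 paste(checks$message[checks$severity == "error"], collapse = "\n")))
  }

  # --- tree preparation -----------------------------------------------
  bin_taxa <- intersect(unique(occurrences$taxon), tree$tip.label)
  if (length(bin_taxa) < 2) abort("Fewer than two occurrence taxa on the tree.")
  pruned <- if (length(bin_taxa) < ape::Ntip(tree)) {
    prune_tree(tree, bin_taxa)
  } else {
    tree
  }
  scaled <- timescale_mbl(pruned, ages, mbl = cfg$mbl, age_type = cfg$age_type)
  ultra <- make_ultrametric(scaled)

  # --- connectedness ---------------------------------------------------
  occ_tree <- occurrences[occurrences$taxon %in% bin_taxa, , drop = FALSE]
  inc <- build_incidence(occ_tree, time_bin = cfg$time_bin)
  dist <- patristic_matrix(ultra)
  pbc <- compute_pbc(inc, dist, mu = cfg$mu)
  bc <- compute_bc(inc)
  sweep <- mu_sweep(inc, dist, mus = cfg$mu_range)

  jack <- jackknife_pbc(occ_tree, ultra, time_bin = cfg$time_bin, mu = cfg$mu,
                        reps = cfg$reps, retain_fraction = cfg$retain_fraction,
                        seed = seeds$jackknife)
  perm <- permutation_null(occ_tree, ultra, time_bin = cfg$time_bin,
                           mu = cfg$mu, reps = cfg$reps,
                           seed = seeds$permutation)
  rare <- if (isTRUE(cfg$rarefy) && nrow(inc) >= cfg$min_n) {
    rarefy_pbc(occ_tree, ultra, time_bin = cfg$time_bin, mu = cfg$mu,
               min_n = cfg$min_n, reps = cfg$reps, seed = seeds$rarefaction)
  }
  subs <- if (isTRUE(cfg$subsample$enabled)) {
    subsample_experiment(
      occ_tree, ultra, time_bin = cfg$time_bin, mu = cfg$mu,
      lat_band = cfg$subsample$lat_band, removal = cfg$subsample$removal,
      reps = cfg$reps, thresholds = cfg$subsample$thresholds,
      seed = seeds$subsample
    )
  }

  # --- sampling bias ----------------------------------------------------
  lat_series <- NULL
  correlation <- NULL
  if (!is.null(collections) && nrow(collections) > 0 && nrow(occurrences) > 0) {
    lo <- floor(min(occurrences$latitude, collections$latitude))
    hi <- floor(max(occurrences$latitude, collections$latitude)) + 1
    occ_bins <- bin_by_latitude(occurrences, extent = c(lo, hi))
    coll_bins <- bin_by_latitude(collections, extent = c(lo, hi))
    lat_series <- dplyr::left_join(
      dplyr::rename(occ_bins, occurrences = "count"),
      dplyr::rename(coll_bins, collections = "count"),
      by = "bin_floor"
    )
    correlation <- correlate_series(lat_series$occurrences, lat_series$collections)
  }

  modsel <- NULL
  if (isTRUE(cfg$gls$enabled)) {
    if (is.null(covariates)) {
      covariates <- simulate_covariates(seed = seeds$covariates)
    }
    covs <- cfg$gls$covariates %||%
      grep("^(cov|outcrop|mgvf|slope)", names(covariates), value = TRUE)
    covs <- head(covs, 6)
    if (length(covs) > 0) {
      dat <- covariates
      resp_col <- if ("count" %in% names(dat)) "count" else setdiff(names(dat), c("bin_floor", covs))[1]
      off <- cfg$gls$log_offset
      dat$.response <- log(dat[[resp_col]] + off)
      for (v in covs) dat[[v]] <- log(dat[[v]] + off)
      modsel <- model_selection(dat, ".response", covs)
    }
  }

  structure(
    list(
      pbc = pbc, bc = bc, mu_sweep = sweep,
      jackknife = jack, permutation = perm,
      rarefaction = rare, subsample = subs,
      latitude_series = lat_series, correlation = correlation,
      model_selection = modsel,
      incidence = inc,
      tree = ultra,
      validation = checks,
      seeds = seeds,
      config = cfg,
      versions = list(
        r = R.version.string,
        pbcnet = as.character(utils::packageVersion("pbcnet"))
      ),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    class = "pbc_run_report"
  )
}

#' @export
print.pbc_run_report <- function(x, ...) {
  cat("<pbc_run_report>\n")
  cat(sprintf("  pBC = %.5f (mu = %g), BC = %.5f, N = %d, L = %d\n",
              x$pbc$value, x$pbc$mu, x$bc$value, x$pbc$N, x$pbc$L))
  cat(sprintf("  jackknife mean %.5f (sd %.5f), permutation p = %.4g (%s)\n",
              x$jackknife$summary$mean, x$jackknife$summary$sd,
              x$permutation$p_value, x$permutation$alternative))
  if (!is.null(x$correlation)) {
    cat(sprintf("  occurrence~collection curves: rho = %.3f, tau = %.3f\n",
                x$correlation$rho, x$correlation$tau))
  }
  if (!is.null(x$model_selection)) {
    best <- x$model_selection$table[1, ]
    cat(sprintf("  best GLS model: %s (weight %.3f)\n", best$model, best$weight))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Summary JSON (`report.json`) plus CSVs of the replicate vectors, the mu
#' sweep, the latitudinal series, and the model-selection table.
#'
#' @param report A `pbc_run_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param include_timestamp Include the wall-clock timestamp in the JSON
#'   (disable for byte-identical reruns). Default `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, include_timestamp = TRUE) {
  stopifnot(inherits(report, "pbc_run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    schema = "pbcnet/report/v1",
    pbc = as.list(report$pbc),
    bc = as.list(report$bc),
    jackknife = c(as.list(report$jackknife$summary),
                  list(seed = report$jackknife$seed)),
    permutation = list(observed = report$permutation$observed,
                       p_value = report$permutation$p_value,
                       alternative = report$permutation$alternative,
                       seed = report$permutation$seed),
    correlation = if (!is.null(report$correlation)) as.list(report$correlation),
    best_model = if (!is.null(report$model_selection)) {
      as.list(report$model_selection$table[1, c("model", "AICc", "weight", "pseudo_R2")])
    },
    subsample = if (!is.null(report$subsample)) {
      list(mean = report$subsample$distribution$summary$mean,
           sd = report$subsample$distribution$summary$sd,
           prob_leq = as.list(report$subsample$prob_leq))
    },
    seeds = report$seeds,
    versions = report$versions,
    timestamp = if (include_timestamp) report$timestamp
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(tibble(replicate = seq_along(report$jackknife$values),
                          pbc = report$jackknife$values),
                   file.path(dir, "jackknife.csv"), row.names = FALSE)
  utils::write.csv(tibble(replicate = seq_along(report$permutation$null_values),
                          pbc = report$permutation$null_values),
                   file.path(dir, "permutation_null.csv"), row.names = FALSE)
  utils::write.csv(report$mu_sweep, file.path(dir, "mu_sweep.csv"),
                   row.names = FALSE)
  if (!is.null(report$latitude_series)) {
    utils::write.csv(report$latitude_series, file.path(dir, "latitude_series.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$model_selection)) {
    utils::write.csv(report$model_selection$table,
                     file.path(dir, "model_selection.csv"), row.names = FALSE)
  }
  invisible(dir)
}
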