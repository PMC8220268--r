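# Jackknife, rarefaction, permutation null, latitudinal subsampling, and
# the rank-sum comparison of replicate distributions.

make_two_clade_data <- function(n_per_clade = 5, bridge = 1) {
  # two endemic clades joined at the root, plus `bridge` taxa in both regions
  n <- n_per_clade
  north <- paste0("n", seq_len(n))
  south <- paste0("s", seq_len(n))
  newick <- function(tips, bl) {
    out <- tips[1]
    for (t in tips[-1]) out <- sprintf("(%s:%g,%s:%g)", out, bl, t, bl)
    out
  }
  txt <- sprintf("(%s:5,%s:5);", newick(north, 2), newick(south, 2))
  tree <- parse_newick(txt)
  occ <- dplyr::bind_rows(
    tibble::tibble(taxon = north, region = "north", latitude = 52),
    tibble::tibble(taxon = south, region = "south", latitude = 33)
  )
  if (bridge > 0) {
    occ <- dplyr::bind_rows(occ, tibble::tibble(
      taxon = rep(paste0("n", seq_len(bridge)), each = 2),
      region = rep(c("north", "south"), bridge),
      latitude = 45
    ))
  }
  list(tree = tree, occ = occ)
}

test_that("jackknife with full retention degenerates to the point estimate", {
  d <- make_two_clade_data()
  j <- jackknife_pbc(d$occ, d$tree, mu = 10, reps = 50,
                     retain_fraction = 1, seed = 1)
  expect_equal(j$summary$sd, 0)
  expect_true(all(j$values == j$observed))
})

test_that("fully endemic data jackknifes to zero in the binary limit", {
  d <- make_two_clade_data(bridge = 0)
  j <- jackknife_pbc(d$occ, d$tree, mu = 1e-9, reps = 50,
                     retain_fraction = 0.7, seed = 2)
  expect_true(all(j$values == 0))
})

test_that("jackknife is reproducible from its seed", {
  d <- make_two_clade_data()
  j1 <- jackknife_pbc(d$occ, d$tree, mu = 10, reps = 100,
                      retain_fraction = 0.75, seed = 99)
  j2 <- jackknife_pbc(d$occ, d$tree, mu = 10, reps = 100,
                      retain_fraction = 0.75, seed = 99)
  expect_identical(j1$values, j2$values)
  expect_true(all(j1$values >= 0 & j1$values <= 1))
  expect_error(jackknife_pbc(d$occ, d$tree, retain_fraction = 1.2),
               "retain_fraction")
})

test_that("rarefaction hits the point estimate at full sample size", {
  d <- make_two_clade_data()
  r <- rarefy_pbc(d$occ, d$tree, mu = 10, min_n = 5, reps = 100, seed = 3)
  top <- r$curve[r$curve$level == nrow(build_incidence(d$occ)), ]
  expect_equal(top$mean, r$observed)
  expect_equal(top$ci_low, top$ci_high)
  expect_true(all(diff(r$curve$level) == 1))
  expect_true(all(r$curve$ci_low <= r$curve$mean + 1e-12))
  expect_true(all(r$curve$mean <= r$curve$ci_high + 1e-12))
})

test_that("a cosmopolitan fauna rarefies to a constant curve at 1", {
  tree <- ape::rtree(8)
  occ <- tidyr::expand_grid(taxon = tree$tip.label,
                            region = c("north", "south"))
  occ$latitude <- 40
  r <- rarefy_pbc(occ, tree, mu = 10, min_n = 5, reps = 50, seed = 4)
  expect_equal(r$curve$mean, rep(1, nrow(r$curve)))
})

test_that("rarefaction means agree across seeds within Monte-Carlo error", {
  d <- make_two_clade_data(n_per_clade = 6, bridge = 2)
  r1 <- rarefy_pbc(d$occ, d$tree, mu = 10, min_n = 5, reps = 400, seed = 5)
  r2 <- rarefy_pbc(d$occ, d$tree, mu = 10, min_n = 5, reps = 400, seed = 6)
  # per-level replicate sd backed out of the 95% interval width
  sd_level <- (r1$curve$ci_high - r1$curve$ci_low) / 3.92
  se_diff <- sqrt(2) * sd_level / sqrt(400)
  expect_true(all(abs(r1$curve$mean - r2$curve$mean) <= 4 * se_diff + 1e-9))
})

test_that("permutation p-value is consistent with its null values", {
  d <- make_two_clade_data()
  p <- permutation_null(d$occ, d$tree, mu = 10, reps = 200, seed = 8)
  expect_equal(p$p_value, mean(p$null_values <= p$observed))
  expect_true(all(p$null_values >= 0 & p$null_values <= 1))
  pg <- permutation_null(d$occ, d$tree, mu = 10, reps = 200, seed = 8,
                         alternative = "greater")
  expect_equal(pg$p_value, mean(pg$null_values >= pg$observed))
})

test_that("permutation null is degenerate when all taxa share one region set", {
  tree <- ape::rtree(6)
  occ <- tidyr::expand_grid(taxon = tree$tip.label,
                            region = c("north", "south"))
  p <- permutation_null(occ, tree, mu = 10, reps = 100, seed = 9)
  expect_equal(p$p_value, 1)
  expect_true(all(p$null_values == p$observed))
})

test_that("permutation test detects clade-structured endemism", {
  cfg <- scenario_config(n_taxa = 20, region_scenario = "endemic_clades",
                         seed = 10)
  sim <- simulate_tree(cfg)
  regions <- assign_regions(sim$tree, cfg, seed = 11)
  occ <- regions
  occ$latitude <- ifelse(occ$region == "north", 50, 35)
  u <- make_ultrametric(timescale_mbl(sim$tree, sim$ages, mbl = 1))
  p <- permutation_null(occ, u, mu = 10, reps = 999, seed = 12)
  expect_lt(p$p_value, 0.05)
})

test_that("subsample experiment with zero removal returns the observed value", {
  d <- make_two_clade_data()
  s <- subsample_experiment(d$occ, d$tree, mu = 10, lat_band = c(35, 50),
                            removal = 0, reps = 20, seed = 13)
  expect_true(all(s$distribution$values == s$distribution$observed))
})

test_that("removing the band-restricted bridge taxa lowers pBC", {
  occ <- band_bridge_occurrences()
  tree <- band_bridge_tree()
  s <- subsample_experiment(occ, tree, mu = 10, lat_band = c(35, 50),
                            removal = 0.95, reps = 200, seed = 14,
                            thresholds = c(0.08, 0.8))
  expect_lt(s$distribution$summary$mean, s$distribution$observed)
  expect_true(all(s$prob_leq >= 0 & s$prob_leq <= 1))
  expect_true(s$prob_leq[["0.08"]] <= s$prob_leq[["0.8"]])
  expect_equal(s$n_band_taxa, 2)
  expect_error(
    subsample_experiment(occ, tree, lat_band = c(0, 10), reps = 5),
    "No taxa in the latitudinal band"
  )
})

test_that("rank-sum comparison matches exact and counting oracles", {
  # identical samples: W = n^2 / 2, p near 1
  x <- c(0.1, 0.2, 0.3, 0.4)
  cmp <- compare_distributions(x, x)
  expect_equal(cmp$W, length(x)^2 / 2)
  expect_gt(cmp$p_value, 0.9)

  # fully separated samples: W = 0 and the exact two-sided p = 0.1
  cmp2 <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp2$W, 0)
  expect_equal(cmp2$p_value, 0.1)

  withr::local_seed(15)
  for (i in 1:25) {
    a <- round(runif(sample(5:20, 1)), 1)
    b <- round(runif(sample(5:20, 1)), 1)
    expect_equal(compare_distributions(a, b)$W, w_oracle(a, b))
  }
  expect_error(compare_distributions(numeric(0), 1:3), "non-empty")
})
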