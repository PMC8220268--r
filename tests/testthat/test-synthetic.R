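# Ground-truth generators: trees, region scenarios, sampling, covariates.

test_that("simulate_tree is seed-deterministic and respects n_taxa", {
  cfg <- scenario_config(n_taxa = 15, seed = 7)
  s1 <- simulate_tree(cfg)
  s2 <- simulate_tree(cfg)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$ages, s2$ages)
  expect_gte(ape::Ntip(s1$tree), 15)
  expect_equal(root_time(s1$tree), 83)
  expect_true(all(s1$ages$fad_ma >= s1$ages$lad_ma))
  expect_error(simulate_tree(scenario_config(speciation = 0)), "positive|non-negative")
  expect_error(simulate_tree(scenario_config(n_taxa = 3)), "at least 5")
})

test_that("pure-birth tip counts match the Yule expectation", {
  withr::local_seed(171)
  lambda <- 0.15
  t_end <- 10
  tips <- replicate(300, ape::Ntip(ape::rlineage(lambda, 0, Tmax = t_end)))
  # the simulator starts from a bifurcation at the root (two lineages)
  expected <- 2 * exp(lambda * t_end)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se + 1e-9)
})

test_that("taxon ranges pick up both bins when they cross the boundary", {
  cfg <- scenario_config(n_taxa = 25, seed = 19, range_myr = 1)
  ages <- simulate_tree(cfg)$ages
  crossers <- ages[ages$fad_ma > 72.1 & ages$lad_ma < 72.1, ]
  if (nrow(crossers) > 0) {
    expect_true(all(crossers$time_bins == "Campanian;Maastrichtian"))
  }
  camp_only <- ages[ages$lad_ma >= 72.1, ]
  expect_true(all(camp_only$time_bins == "Campanian"))
})

test_that("region scenarios produce their known connectedness limits", {
  cfg_base <- scenario_config(n_taxa = 15, seed = 23)
  sim <- simulate_tree(cfg_base)
  D <- patristic_matrix(sim$tree)

  to_inc <- function(assign) {
    occ <- assign
    occ$time_bin <- "Campanian"
    build_incidence(occ)
  }

  cosmo <- assign_regions(sim$tree, scenario_config(n_taxa = 15,
                                                    region_scenario = "cosmopolitan"),
                          seed = 1)
  expect_equal(compute_bc(to_inc(cosmo))$value, 1)

  endemic <- assign_regions(sim$tree, scenario_config(n_taxa = 15,
                                                      region_scenario = "endemic_clades"),
                            seed = 1)
  expect_equal(compute_bc(to_inc(endemic))$value, 0)
  expect_equal(dplyr::n_distinct(endemic$region), 2)

  rnd <- assign_regions(sim$tree, scenario_config(n_taxa = 15,
                                                  region_scenario = "random", p = 0.5),
                        seed = 2)
  expect_true(all(table(rnd$taxon) >= 1))
  expect_true(all(rnd$region %in% c("north", "south")))
})

test_that("dispersal rate controls how region-pure the fauna is", {
  withr::local_seed(181)
  purity <- function(q, seed) {
    cfg <- scenario_config(n_taxa = 15, region_scenario = "mk_dispersal",
                           q = q, seed = seed)
    sim <- simulate_tree(cfg)
    a <- assign_regions(sim$tree, cfg, seed = seed + 1000)
    max(table(a$region)) / nrow(a)
  }
  slow <- purrr::map_dbl(1:25, ~ purity(1e-4, .x))
  fast <- purrr::map_dbl(1:25, ~ purity(2, .x))
  expect_gt(mean(slow), 0.95) # q -> 0: tips converge on the root state
  expect_gt(mean(slow), mean(fast))
})

test_that("sampling respects the latitudinal profile and detection rate", {
  cfg <- scenario_campanian(n_taxa = 15, seed = 29, effort = 20)
  sim <- simulate_tree(cfg)
  assign <- assign_regions(sim$tree, cfg, seed = 30)
  samp <- simulate_sampling(assign, cfg, seed = 31)

  # conservation: every occurrence taxon comes from the assignment table
  expect_true(all(samp$occurrences$taxon %in% assign$taxon))
  expect_true(all(samp$occurrences$latitude >= 25 &
                    samp$occurrences$latitude < 60))

  # bimodal mass: most collections near the two peaks
  near_peak <- abs(samp$collections$latitude - 36.5) <= 3 |
    abs(samp$collections$latitude - 50) <= 3
  expect_gt(mean(near_peak), 0.9)

  # detection 0: collections but no occurrences
  cfg0 <- scenario_campanian(n_taxa = 15, seed = 29, detection = 0)
  samp0 <- simulate_sampling(assign, cfg0, seed = 31)
  expect_equal(nrow(samp0$occurrences), 0)
  expect_gt(nrow(samp0$collections), 0)

  # zero effort: warning and empty tables
  cfg_none <- scenario_campanian(n_taxa = 15, seed = 29, effort = 0)
  expect_warning(samp_none <- simulate_sampling(assign, cfg_none, seed = 31),
                 "effort")
  expect_equal(nrow(samp_none$collections), 0)
})

test_that("uniform sampling spreads collections evenly across bins", {
  cfg <- scenario_maastrichtian(n_taxa = 15, seed = 37, effort = 30)
  sim <- simulate_tree(cfg)
  assign <- assign_regions(sim$tree, cfg, seed = 38)
  samp <- simulate_sampling(assign, cfg, seed = 39)
  counts <- bin_by_latitude(samp$collections, extent = c(25, 60))$count
  # Poisson homogeneity: per-bin counts close to the common mean
  expect_true(all(abs(counts - mean(counts)) <= 5 * sqrt(mean(counts))))
})

test_that("covariate generator embeds a recoverable ground truth", {
  # noiseless: coefficients recovered exactly from the latent response
  cv0 <- simulate_covariates(truth = list(beta = c(2, 0.5), phi = 0, sigma = 0),
                             seed = 41)
  d0 <- cv0
  d0$l1 <- log(d0$cov1)
  fit0 <- fit_gls_ar1(d0, ln_response ~ l1, phi = 0)
  expect_equal(unname(fit0$coefficients), c(2, 0.5), tolerance = 1e-8)

  # determinism and error paths
  expect_identical(simulate_covariates(seed = 42), simulate_covariates(seed = 42))
  expect_error(simulate_covariates(truth = list(beta = c(1), phi = 1.2, sigma = 0.1)),
               "phi")
  expect_error(simulate_covariates(n_bins = 5), "at least 10")
  truth <- attr(simulate_covariates(seed = 43), "truth")
  expect_equal(truth$beta, c(2, 0.5))
})
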