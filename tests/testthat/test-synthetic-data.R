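test_that("the default landscape reproduces the study geometry", {
  cfg <- scenario_config(seed = 3)
  meta <- landscape(cfg)
  expect_s3_class(meta, "sample_metadata")
  expect_identical(nrow(meta), 33L)
  expect_identical(length(unique(meta$site_id)), 11L)
  expect_identical(as.integer(table(meta$ecosystem_type)[c("urban",
                                                            "suburban",
                                                            "forest")]),
                   c(12L, 12L, 9L))
  dmax <- max(as.matrix(geographic_distance(meta)))
  expect_gte(dmax, 24.3)
  expect_lte(dmax, 29.7)
  # urbanization axis runs urban (+1) to forest (-1)
  expect_gt(mean(meta$urbanization[meta$ecosystem_type == "urban"]), 0.5)
  expect_lt(mean(meta$urbanization[meta$ecosystem_type == "forest"]), -0.5)
})

test_that("landscape soil chemistry differs by ecosystem type as constructed", {
  ph_diff <- ts_diff <- numeric(5)
  for (s in 1:5) {
    meta <- landscape(scenario_config(seed = s))
    ph_diff[s] <- mean(meta$pH[meta$ecosystem_type == "forest"]) -
      mean(meta$pH[meta$ecosystem_type == "urban"])
    ts_diff[s] <- mean(meta$TS[meta$ecosystem_type == "urban"]) -
      mean(meta$TS[meta$ecosystem_type == "forest"])
  }
  expect_true(all(ph_diff < 0)) # forest soils more acidic
  expect_true(all(ts_diff > 0)) # urban sulfur elevated
})

test_that("sloan sampling yields valid rarefied-depth tables, deterministically", {
  cfg <- scenario_config(n_taxa = 120, depth = 2000, Nm_true = 50, seed = 5)
  tab <- sample_sloan(cfg)
  expect_identical(dim(tab), c(33L, 120L))
  expect_true(all(rowSums(tab$counts) == 2000))
  expect_identical(sample_sloan(cfg)$counts, tab$counts)
  # huge Nm: per-sample shares concentrate on the metacommunity shares
  cfg2 <- scenario_config(n_taxa = 60, depth = 50000, Nm_true = 1e7, seed = 6)
  shares <- commassembly:::metacommunity_shares(cfg2)
  tab2 <- sample_sloan(cfg2, shares = shares)
  obs <- colMeans(tab2$counts / 50000)
  expect_lt(max(abs(obs - shares)), 0.005)
})

test_that("zero-sum drift reduces to metacommunity sampling at m = 1 and fixes at m = 0", {
  cfg <- scenario_config(n_taxa = 40, depth = 5000, J = 4000, m = 1,
                         generations = 3, samples_per_site = 1,
                         regime = "neutral-dynamics", seed = 7)
  shares <- commassembly:::metacommunity_shares(cfg)
  tab <- simulate_neutral_dynamics(cfg, shares = shares)
  obs <- colMeans(tab$counts / 5000)
  # full immigration: mean observed share tracks the metacommunity share
  expect_lt(max(abs(obs - shares)), 4 * sqrt(max(shares) / (11 * 4000)) + 0.01)

  cfg0 <- scenario_config(n_taxa = 15, depth = 1000, J = 40, m = 0,
                          generations = 400, samples_per_site = 1,
                          n_sites = 3, ecosystem_layout = c(urban = 1,
                                                            suburban = 1,
                                                            forest = 1),
                          regime = "neutral-dynamics", seed = 8)
  tab0 <- simulate_neutral_dynamics(cfg0)
  # drift to fixation: every isolated local community is near-monodominant
  expect_true(all(apply(tab0$counts / 1000, 1, max) > 0.95))
})

test_that("niche filtering reduces to neutral sampling when widths are huge", {
  cfg <- scenario_config(n_taxa = 60, depth = 20000, regime = "niche-filtering",
                         niche = list(n_specialists = 0,
                                      background_sigma = c(1e4, 2e4),
                                      noise_sd = 1e-4),
                         seed = 9)
  shares <- commassembly:::metacommunity_shares(cfg)
  tab <- simulate_niche_filtering(cfg, shares = shares)
  obs <- colMeans(tab$counts / 20000)
  expect_lt(max(abs(obs - shares)), 0.004)
})

test_that("planted forest specialists are recovered by ecosystem assignment", {
  hits <- 0L
  n_seeds <- 5
  for (s in 1:n_seeds) {
    cfg <- scenario_config(n_taxa = 150, depth = 5000,
                           regime = "niche-filtering",
                           niche = list(n_specialists = 3), seed = 100 + s)
    meta <- landscape(cfg)
    tab <- simulate_niche_filtering(cfg, meta = meta)
    truth <- attr(tab, "truth")
    forest_taxa <- truth$taxon_id[truth$planted & truth$optimum == -1]
    res <- suppressWarnings(assign_ecosystem(forest_taxa, tab, meta))
    hits <- hits + all(res$taxa$assigned_ecosystem == "forest")
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the mixed scenario emits five coherent groups with a truth record", {
  cfg <- scenario_config(regime = "mixed", n_taxa = 80, depth = 1000,
                         seed = 10)
  ms <- mixed_scenario(cfg)
  expect_identical(names(ms$tables), mixed_group_defaults()$group)
  expect_identical(nrow(ms$truth),
                   sum(vapply(ms$tables, function(t) ncol(t$counts),
                              integer(1))))
  for (tab in ms$tables) {
    expect_true(all(rowSums(tab$counts) == 1000))
    expect_identical(rownames(tab$counts), ms$meta$sample_id)
  }
  # planted flags only in the selection-dominated group
  planted_by_group <- tapply(ms$truth$planted, ms$truth$group, sum)
  expect_identical(unname(planted_by_group["invertebrate_like"]), 30L)
  expect_identical(sum(planted_by_group), 30L)
  # full reproducibility from the same config
  ms2 <- mixed_scenario(cfg)
  expect_identical(ms2$tables$fungus_like$counts, ms$tables$fungus_like$counts)
})

test_that("scenario configs validate their domains", {
  expect_error(scenario_config(n_sites = 1), "at least 2")
  expect_error(scenario_config(ecosystem_layout = c(urban = 2, forest = 2)),
               "sum to n_sites")
  expect_error(scenario_config(extent_km = -3), "positive")
  expect_error(scenario_config(m = 1.5), "\\[0, 1\\]")
  expect_error(scenario_config(niche = list(specialist_sigma = 0)),
               "positive")
  expect_error(scenario_config(niche = list(bogus = 1)), "unknown niche")
})

test_that("habitat-structured landscapes show distance decay and habitat-ordered null deviations", {
  cfg <- scenario_config(n_taxa = 300, depth = 5000,
                         regime = "niche-filtering",
                         niche = list(n_specialists = 20,
                                      frac_filtered = 0.4,
                                      noise_sd = 0.3),
                         seed = 31)
  meta <- landscape(cfg)
  tab <- simulate_niche_filtering(cfg, meta = meta)
  sim <- bray_curtis(tab, as = "similarity")
  geo <- geographic_distance(meta)
  fit <- distance_decay(sim, geo, n_permutations = 199, seed = 1)
  expect_lt(fit$r, 0)
  expect_lt(fit$p_value, 0.05)
  expect_lt(fit$slope, 0)

  # between-habitat pairs deviate upward relative to within-habitat pairs
  rc <- raup_crick_matrix(tab, n_randomizations = 200, seed = 2)
  type <- meta$ecosystem_type[match(rc$ids, meta$sample_id)]
  same <- outer(type, type, "==")
  lt <- lower.tri(rc$values)
  expect_gt(mean(rc$values[lt & !same]), mean(rc$values[lt & same]))
})
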