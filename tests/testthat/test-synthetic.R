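test_that("synthetic CO2 series passes through its anchors, increasing", {
  co2 <- gen_co2_series(1945:2015)
  expect_equal(co2$ca[co2$year == 1965], 320)
  expect_equal(co2$ca[co2$year == 2015], 395)
  expect_true(all(diff(co2$ca) > 0))
  expect_error(gen_co2_series(1960, c("2015" = 395, "1965" = 320)),
               "increasing")
})

test_that("the generator is deterministic under its seed", {
  a <- gen_wue_dataset(generator_config(profile = "small", seed = 42))
  b <- gen_wue_dataset(generator_config(profile = "small", seed = 42))
  expect_identical(a$observations, b$observations)
  expect_identical(a$environment, b$environment)
  expect_identical(a$ndep, b$ndep)
  c <- gen_wue_dataset(generator_config(profile = "small", seed = 43))
  expect_false(identical(a$observations, c$observations))
})

test_that("generated tables satisfy the consuming schemas", {
  sim <- small_sim()
  expect_named(sim$observations, c("site_id", "tree_id", "year",
                                   "delta13c_plant", "species_group"))
  expect_true(all(sim$observations$species_group %in%
                    c("angiosperm", "gymnosperm")))
  expect_true(all(sim$observations$year %in% 1965:2015))
  env <- sim$environment
  expect_true(all(env$precip >= 0) && all(env$pet > 0))
  expect_equal(env$ai, env$precip / env$pet, tolerance = 1e-12)
  expect_true(all(sim$ndep$ndep >= 0))
  expect_identical(assign_zone(sim$sites$lat, sim$sites$lon), sim$sites$zone)
  # environment covers 20 years of deposition history before the window
  expect_equal(min(sim$ndep$year), 1945L)
})

test_that("default study size mirrors the emulated survey", {
  sim <- default_sim()
  expect_equal(nrow(sim$sites), 349L)
  n_trees <- length(sim$truth$tree_effects)
  expect_gt(n_trees, 370)
  expect_lt(n_trees, 460)
  expect_gt(nrow(sim$observations), 8000)
  expect_lt(nrow(sim$observations), 15000)
  expect_gt(max(sim$environment$ai), 2.5) # AI support spreads towards 5
  expect_lt(min(sim$environment$ai), 0.5)
})

test_that("high-N zone cumulative deposition matches its calibration target", {
  sim <- default_sim()
  cov <- build_ndep_covariates(sim$sites, sim$ndep, target_years = 1965:2015)
  cum <- merge(cov$ndep_cum, cov$sites[, c("site_id", "zone")])
  zone_means <- tapply(cum$ndep_cum, cum$zone, mean)
  expect_equal(unname(zone_means["high"]), 17, tolerance = 0.1)
  expect_equal(unname(zone_means["mid"]), 8, tolerance = 0.15)
  expect_true(zone_means["low_north"] < zone_means["mid"])
  expect_true(zone_means["low_south"] <= zone_means["low_north"])
  # conversion consistency with the headline rate
  expect_equal(ndep_rate_kg_ha_yr(zone_means[["high"]]), 8.5, tolerance = 0.1)
})

test_that("site aridity declines through the study period on average", {
  sim <- default_sim()
  slopes <- vapply(split(sim$environment, sim$environment$site_id),
                   function(d) unname(coef(lm(ai ~ year, d))[2]), numeric(1))
  expect_lt(mean(slopes), 0)
})

test_that("noise-free generation round-trips W through the isotope pipeline", {
  cfg <- generator_config(profile = "small", sigma2_tree = 0,
                          sigma2_resid = 0, seed = 5)
  sim <- gen_wue_dataset(cfg)
  tab <- compute_wue_table(sim$observations, sim$co2, sim$atm_delta)
  key <- paste(tab$site_id, tab$tree_id, tab$year)
  sim_key <- paste(sim$observations$site_id, sim$observations$tree_id,
                   sim$observations$year)
  w_true <- sim$truth$w_true[match(key, sim_key)]
  expect_lt(max(abs(tab$w_simple - w_true) / w_true), 1e-9)
})

test_that("mean W above the breakpoint matches the configured level", {
  sim <- default_sim()
  tab <- sim_analysis_table(sim)
  above <- tab[tab$ai > 1, ]
  # standard error accounts for the tree-level clustering that dominates
  tree_means <- tapply(above$w, above$tree_uid, mean)
  se <- sqrt(var(tree_means) / length(tree_means) +
               var(above$w) / nrow(above))
  expect_lt(abs(mean(above$w) - 55), 2 * se + 0.5)
})

test_that("the full pipeline recovers the planted AI breakpoint", {
  sim <- default_sim()
  tab <- sim_analysis_table(sim)
  tab <- suppressMessages(exclude_extreme_ai(tab))
  f <- fit_segmented(tab$ai, tab$w, n_boot = 0)
  expect_true(f$identifiable)
  expect_equal(f$breakpoint, 1, tolerance = 0.1)
  expect_lt(f$slope_below, -15)
  expect_gt(f$slope_above, -3)
})

test_that("generating slope, CO2 effect and variances are recoverable", {
  sim <- default_sim()
  cfg <- sim$truth$config
  tab <- sim_analysis_table(sim)
  tab$ai_hinge <- pmin(tab$ai, cfg$breakpoint)
  tab$gym <- as.numeric(tab$species_group == "gymnosperm")
  # reconstruct the generating N covariate (zone-specific slope, centred)
  tab$n_eff <- cfg$beta_n[tab$zone] *
    (tab$ndep_cum - sim$truth$zone_mean_ndep[tab$zone])
  fit <- fit_lmm(tab, model_spec(c("ai_hinge", "ca", "gym", "n_eff"),
                                 estimation = "REML"))
  b <- fit$coefficients
  est <- function(t) b$estimate[b$term == t]
  se <- function(t) b$se[b$term == t]
  expect_lt(abs(est("ai_hinge") - cfg$slope_below), 3 * se("ai_hinge"))
  expect_lt(abs(est("ca") - cfg$beta_ca), 3 * se("ca"))
  expect_equal(fit$var_tree, cfg$sigma2_tree, tolerance = 0.25)
  expect_equal(fit$var_resid, cfg$sigma2_resid, tolerance = 0.15)
})

test_that("an over-dispersed configuration is rejected", {
  cfg <- generator_config(profile = "small", mean_above = 240,
                          beta_ca = 2, seed = 2)
  expect_error(gen_wue_dataset(cfg), "outside")
})
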