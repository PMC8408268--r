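# Shared fixtures, built in code. The default-size synthetic study is
# expensive enough to build once and reuse across test files.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- gen_wue_dataset(generator_config(seed = 20))
  .fixture_env$sim
}

small_sim <- function(seed = 11) {
  gen_wue_dataset(generator_config(profile = "small", seed = seed))
}

# analysis table (W + AI + N covariates joined) for a simulated bundle
sim_analysis_table <- function(sim, window = 1965:2015) {
  wue <- suppressWarnings(compute_wue_table(sim$observations, sim$co2,
                                            sim$atm_delta))
  cov <- build_ndep_covariates(sim$sites, sim$ndep, target_years = window)
  joined <- join_tables(wue, sim$environment, cov$ndep_cum, quiet = TRUE)
  joined <- joined[joined$year %in% window, , drop = FALSE]
  joined$w <- joined$w_simple
  joined$zone <- cov$sites$zone[match(joined$site_id, cov$sites$site_id)]
  joined
}

# simulate a balanced tree-random-intercept dataset with a CO2 fixed effect
simulate_lmm_data <- function(n_trees = 100, n_years = 30, beta_ca = 0.2,
                              intercept = -20, sd_tree = 10, sd_resid = 5) {
  years <- seq(2015 - n_years + 1, 2015)
  ca <- gen_co2_series(years)$ca
  tree <- rep(seq_len(n_trees), each = n_years)
  eff <- rnorm(n_trees, 0, sd_tree)
  data.frame(
    tree_uid = paste0("T", tree),
    ca = rep(ca, n_trees),
    ai = runif(n_trees * n_years, 0.2, 3), # inert covariate
    w = intercept + beta_ca * rep(ca, n_trees) + eff[tree] +
      rnorm(n_trees * n_years, 0, sd_resid)
  )
}
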