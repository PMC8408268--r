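# Zone-specific shapes of annual N deposition (unitless, scaled internally):
# high - steady rise from 1950 slowing around 2000; mid - strong rise from
# ~1980; low - slow near-linear rise from 1950.
.ndep_shape <- list(
  high = function(y) 1 / (1 + exp(-(y - 1975) / 12)),
  mid = function(y) 0.08 + 1 / (1 + exp(-(y - 1995) / 7)),
  low_north = function(y) 0.25 + 0.75 * pmax(0, y - 1945) / 70,
  low_south = function(y) 0.25 + 0.75 * pmax(0, y - 1945) / 70
)

# Mean cumulative deposition targets per zone over the analysis window,
# g N m-2 per 20 yr (high ~17 is ~8.5 kg N ha-1 yr-1).
.ndep_target <- c(high = 17, mid = 8, low_north = 5, low_south = 3)

# AI distribution per zone: gamma(shape, scale). High-N (central Europe /
# eastern USA) sites are mostly moist; low-N-north sites span the widest
# aridity range.
.ai_gamma <- list(
  high = c(shape = 6.0, scale = 0.25),
  mid = c(shape = 2.0, scale = 0.50),
  low_north = c(shape = 1.8, scale = 0.70),
  low_south = c(shape = 5.0, scale = 0.35)
)

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the structure of the global tree-ring study the package
#' analyses: 349 sites carrying about 411 trees with annual series inside
#' 1965-2015 (environment series start in 1945 so 20-year cumulative
#' deposition is defined from 1965 onward), aridity indices spread over 0-5
#' with zone-specific distributions, rising CO2 anchored at about 320 ppm in
#' 1965 and 395 ppm in 2015, zone-specific N-deposition histories, and a
#' W-AI threshold structure: W declines linearly below the breakpoint at
#' AI = 1 and is flat (mean 55 umol mol-1 at reference CO2) above it.
#' Tree-to-tree variance dominates the residual, as the mixed-model results
#' require.
#'
#' @param profile `"default"` (349 sites) or `"small"` (30 sites; keeps the
#'   full test suite fast).
#' @param n_sites Number of sites.
#' @param years_env Years covered by environment/deposition tables.
#' @param years_obs Analysis window for tree-ring observations.
#' @param breakpoint True AI breakpoint. Default 1.
#' @param slope_below Slope of W vs AI below the breakpoint,
#'   umol mol-1 per AI unit. Default -22.
#' @param mean_above Mean W above the breakpoint at reference CO2 and zone
#'   mean deposition, umol mol-1. Default 55.
#' @param beta_ca Sensitivity of W to CO2, umol mol-1 per ppm. Default 0.15.
#' @param ca_ref Reference CO2 used to centre the CO2 effect, ppm. `NULL`
#'   (default) centres on the realized mean over the generated observations
#'   so `mean_above` is the mean W above the breakpoint by construction.
#' @param beta_n Named vector: effect of cumulative N (g N m-2 20 yr-1,
#'   centred on the zone mean) on W per zone.
#' @param species_offset Half-difference of mean W between gymnosperms
#'   (higher) and angiosperms, umol mol-1. Default 3.
#' @param sigma2_tree Tree-level random-intercept variance. Default 81.
#' @param sigma2_resid Residual (within-tree) variance. Default 36.
#' @param zone_probs Sampling probabilities of the four deposition zones.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(profile = c("default", "small"),
                             n_sites = NULL,
                             years_env = 1945:2015,
                             years_obs = 1965:2015,
                             breakpoint = 1,
                             slope_below = -22,
                             mean_above = 55,
                             beta_ca = 0.15,
                             ca_ref = NULL,
                             beta_n = c(high = 0.05, mid = 0.25,
                                        low_north = 0.25, low_south = 1.2),
                             species_offset = 3,
                             sigma2_tree = 81,
                             sigma2_resid = 36,
                             zone_probs = c(high = 0.40, mid = 0.18,
                                            low_north = 0.32, low_south = 0.10),
                             seed = 1) {
  profile <- match.arg(profile)
  if (is.null(n_sites)) n_sites <- if (profile == "small") 30L else 349L
  stopifnot(n_sites >= 2, sigma2_tree >= 0, sigma2_resid >= 0,
            breakpoint > 0, mean_above > 0,
            all(sort(names(beta_n)) == sort(names(.ndep_target))),
            abs(sum(zone_probs) - 1) < 1e-8)
  structure(list(profile = profile, n_sites = as.integer(n_sites),
                 years_env = years_env, years_obs = years_obs,
                 breakpoint = breakpoint, slope_below = slope_below,
                 mean_above = mean_above, beta_ca = beta_ca, ca_ref = ca_ref,
                 beta_n = beta_n, species_offset = species_offset,
                 sigma2_tree = sigma2_tree, sigma2_resid = sigma2_resid,
                 zone_probs = zone_probs, seed = as.integer(seed)),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic atmospheric CO2 series
#'
#' Smooth, strictly increasing quadratic trajectory through the anchor
#' values ca(1965) = 320 ppm and ca(2015) = 395 ppm:
#' ca(t) = a + b (t - 1945)^2.
#'
#' @param years Integer years (>= 1945).
#' @param anchors Named anchors `c(year1 = ca1, year2 = ca2)` with years as
#'   names; must be increasing in both year and value. Default
#'   `c("1965" = 320, "2015" = 395)`.
#' @return data.frame with `year`, `ca` (umol mol-1).
#' @export
gen_co2_series <- function(years, anchors = c("1965" = 320, "2015" = 395)) {
  stopifnot(length(anchors) == 2)
  ay <- as.numeric(names(anchors))
  if (any(is.na(ay)) || diff(ay) <= 0 || diff(anchors) <= 0)
    stop("anchors must be increasing in year and value")
  t0 <- 1945
  if (any(years < t0)) stop("CO2 series defined for years >= ", t0)
  b <- diff(anchors) / ((ay[2] - t0)^2 - (ay[1] - t0)^2)
  a <- anchors[1] - b * (ay[1] - t0)^2
  data.frame(year = as.integer(years),
             ca = as.numeric(a + b * (years - t0)^2))
}

# scale per zone so the mean cumulative 20-yr deposition over the analysis
# window equals the survey-level target
.ndep_scale <- function(zone, years_obs, window = 20) {
  shape <- .ndep_shape[[zone]]
  unit_cum <- vapply(years_obs, function(y) sum(shape((y - window + 1):y)),
                     numeric(1))
  .ndep_target[[zone]] / mean(unit_cum)
}

#' Synthetic sites, environment and deposition tables
#'
#' Draws site coordinates inside the nominal deposition-zone boxes, then
#' builds per-site annual climate (precipitation, PET, temperature, VPD,
#' aridity index with a mild declining trend) and zone-specific N-deposition
#' trajectories calibrated so zone-mean cumulative 20-year deposition over
#' the analysis window matches the study-level values (high about 17, mid 8,
#' low-north 5, low-south 3 g N m-2 per 20 yr). Deterministic under the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return list with `sites` (`site_id`, `lat`, `lon`, `zone`),
#'   `environment` (`site_id`, `year`, `precip`, `pet`, `tmean`, `vpd`,
#'   `ai`), `ndep` (`site_id`, `year`, `ndep`), and `co2` (`year`, `ca`).
#' @export
gen_environment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, .gen_environment_impl(config))
}

.gen_environment_impl <- function(config) {
  n <- config$n_sites
  zones <- sample(names(config$zone_probs), n, replace = TRUE,
                  prob = config$zone_probs)
  coords <- t(vapply(zones, .sample_coord, numeric(2)))
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                      lat = coords[, 1], lon = coords[, 2], zone = zones,
                      stringsAsFactors = FALSE)
  stopifnot(identical(assign_zone(sites$lat, sites$lon), sites$zone))

  years <- config$years_env
  ny <- length(years)
  scales <- vapply(names(.ndep_target), .ndep_scale, numeric(1),
                   years_obs = config$years_obs)

  env_list <- vector("list", n)
  ndep_list <- vector("list", n)
  for (i in seq_len(n)) {
    z <- zones[i]
    g <- .ai_gamma[[z]]
    ai_base <- min(stats::rgamma(1, shape = g[["shape"]], scale = g[["scale"]]) +
                     0.05, 6)
    pet_base <- stats::rlnorm(1, log(900), 0.25)
    trend <- stats::rnorm(1, -0.0015, 0.001) # AI typically declines over time
    ai <- ai_base * exp(trend * (years - 1980)) *
      stats::rlnorm(ny, 0, 0.08)
    pet <- pet_base * stats::rlnorm(ny, 0, 0.05)
    precip <- ai * pet
    t_base <- 25 - 0.55 * abs(sites$lat[i]) + stats::rnorm(1, 0, 1.5)
    tmean <- t_base + stats::rnorm(ny, 0, 0.6)
    rh <- pmin(100, pmax(5, 100 * pmin(0.95, 0.35 + 0.28 * pmin(ai, 2)) +
                           stats::rnorm(ny, 0, 5)))
    vpd <- vpd_magnus(tmean, rh)
    mult <- stats::rlnorm(1, 0, 0.25) / exp(0.25^2 / 2)
    ndep <- scales[[z]] * .ndep_shape[[z]](years) * mult
    env_list[[i]] <- data.frame(site_id = sites$site_id[i], year = years,
                                precip = precip, pet = pet, tmean = tmean,
                                vpd = vpd, ai = ai, stringsAsFactors = FALSE)
    ndep_list[[i]] <- data.frame(site_id = sites$site_id[i], year = years,
                                 ndep = ndep, stringsAsFactors = FALSE)
  }
  list(sites = sites,
       environment = do.call(rbind, env_list),
       ndep = do.call(rbind, ndep_list),
       co2 = gen_co2_series(years))
}

.zone_boxes <- list(
  high = list(c(45, 59.9, -14.9, 44.9), c(24, 49.9, -99.9, -60.1)),
  mid = list(c(5, 44.9, 70.1, 149.9)),
  low_north = list(c(30, 49, -125, -105), c(61, 69, 10, 169)),
  low_south = list(c(-45, -10, 110, 155), c(-50, -5, -75, -40))
)

.sample_coord <- function(zone) {
  boxes <- .zone_boxes[[zone]]
  b <- boxes[[sample.int(length(boxes), 1L)]]
  c(stats::runif(1, b[1], b[2]), stats::runif(1, b[3], b[4]))
}

#' Generate a complete synthetic tree-ring study
#'
#' Forward model: true W is piecewise-linear in AI with a kink at the
#' configured breakpoint (negative slope below, flat above), plus a linear
#' CO2 effect, a zone-specific cumulative-N effect, a gymnosperm/angiosperm
#' mean offset, a tree-level random intercept and residual noise. The
#' emitted delta-13C chronology is obtained by exact inversion of the simple
#' discrimination model, so running the full pipeline on the generated
#' tables recovers true W up to the injected noise. All generating
#' parameters and latent effects are stored in `truth` for recovery tests.
#' W is generated structurally (not from the optimization module) so that
#' threshold-recovery tests are not circular.
#'
#' @param config A [generator_config()].
#' @return list with `observations` (`site_id`, `tree_id`, `year`,
#'   `delta13c_plant`, `species_group`), `sites`, `environment`, `ndep`,
#'   `co2`, `atm_delta` and `truth` (config, per-observation `w_true`,
#'   tree effects, seed).
#' @export
gen_wue_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    world <- .gen_environment_impl(config)
    .gen_obs_impl(config, world)
  })
}

.gen_obs_impl <- function(config, world) {
  sites <- world$sites
  env <- world$environment
  co2 <- world$co2
  atm <- delta13c_atm_default(config$years_env)

  # trees per site: mostly single-tree sites, occasional 2-3
  n_trees_site <- sample(1:3, nrow(sites), replace = TRUE,
                         prob = c(0.85, 0.12, 0.03))
  tree_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(n_trees_site[i])) {
      k <- k + 1L
      p_gym <- if (sites$zone[i] == "low_south") 0.15 else 0.7
      start <- sample(config$years_obs[config$years_obs <= 1995], 1L)
      end <- sample(config$years_obs[config$years_obs >= 1995], 1L)
      if (end - start < 9L) end <- min(max(config$years_obs), start + 9L)
      tree_rows[[k]] <- data.frame(
        site_id = sites$site_id[i],
        tree_id = paste0("T", j),
        zone = sites$zone[i],
        species_group = if (stats::runif(1) < p_gym) "gymnosperm" else "angiosperm",
        y0 = start, y1 = end,
        tree_effect = stats::rnorm(1, 0, sqrt(config$sigma2_tree)),
        stringsAsFactors = FALSE)
    }
  }
  trees <- do.call(rbind, tree_rows)
  trees$tree_uid <- paste(trees$site_id, trees$tree_id, sep = ":")

  obs <- trees[rep(seq_len(nrow(trees)), trees$y1 - trees$y0 + 1L), ]
  obs$year <- unlist(mapply(seq, trees$y0, trees$y1, SIMPLIFY = FALSE))
  obs$y0 <- obs$y1 <- NULL

  env_key <- paste(env$site_id, env$year)
  ei <- match(paste(obs$site_id, obs$year), env_key)
  stopifnot(!anyNA(ei))
  obs$ai <- env$ai[ei]
  obs$ca <- co2$ca[match(obs$year, co2$year)]

  ncum_all <- build_ndep_covariates(sites, world$ndep,
                                    target_years = config$years_obs)$ndep_cum
  ni <- match(paste(obs$site_id, obs$year), paste(ncum_all$site_id, ncum_all$year))
  stopifnot(!anyNA(ni))
  obs$ndep_cum <- ncum_all$ndep_cum[ni]

  zone_mean_n <- tapply(obs$ndep_cum, obs$zone, mean)
  bn <- config$beta_n[obs$zone]
  ca_ref <- if (is.null(config$ca_ref)) mean(obs$ca) else config$ca_ref
  sp_eff <- ifelse(obs$species_group == "gymnosperm", config$species_offset,
                   -config$species_offset)
  sp_eff <- sp_eff - mean(sp_eff) # centred so mean_above stays the mean
  w_true <- config$mean_above +
    config$slope_below * (pmin(obs$ai, config$breakpoint) - config$breakpoint) +
    config$beta_ca * (obs$ca - ca_ref) +
    bn * (obs$ndep_cum - zone_mean_n[obs$zone]) +
    sp_eff +
    obs$tree_effect
  if (any(w_true < 0 | w_true > obs$ca / 1.6))
    stop("configuration implies W outside [0, ca/1.6]; reduce effect sizes ",
         "or variances")
  w_obs <- w_true + stats::rnorm(nrow(obs), 0, sqrt(config$sigma2_resid))
  w_obs <- pmin(pmax(w_obs, 0.5), obs$ca / 1.6 - 0.5)

  delta <- invert_w_to_delta(w_obs, obs$ca)
  d_atm <- atm$delta13c_atm[match(obs$year, atm$year)]
  obs$delta13c_plant <- delta_plant_from_big_delta(delta, d_atm)

  observations <- obs[, c("site_id", "tree_id", "year", "delta13c_plant",
                          "species_group")]
  rownames(observations) <- NULL
  truth <- list(config = config,
                w_true = w_true, w_obs = w_obs,
                tree_effects = stats::setNames(trees$tree_effect, trees$tree_uid),
                zone_mean_ndep = zone_mean_n)
  list(observations = observations, sites = sites,
       environment = world$environment, ndep = world$ndep, co2 = world$co2,
       atm_delta = atm, truth = truth)
}
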