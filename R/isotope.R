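#' Discrimination constants for the simple ci/ca model
#'
#' Constants of the two-term carbon-isotope discrimination model used to
#' convert discrimination (Delta, permil) to the ratio of intercellular to
#' ambient CO2: ci/ca = (Delta - a)/(b - a).
#'
#' @param frac_a Diffusion (stomatal) discrimination, permil. Default 4.4.
#' @param frac_b Carboxylation (Rubisco) discrimination, permil. Default 27.
#' @return An object of class `"isotope_constants_simple"`.
#' @examples
#' isotope_constants_simple()
#' @export
isotope_constants_simple <- function(frac_a = 4.4, frac_b = 27) {
  stopifnot(is.numeric(frac_a), is.numeric(frac_b),
            length(frac_a) == 1L, length(frac_b) == 1L)
  if (!is.finite(frac_a) || !is.finite(frac_b))
    stop("isotope constants must be finite")
  if (frac_a <= 0 || frac_b <= 0)
    stop("isotope constants must be positive")
  if (frac_b <= frac_a)
    stop("frac_b must exceed frac_a (degenerate constants: b = ", frac_b,
         ", a = ", frac_a, ")")
  structure(list(frac_a = frac_a, frac_b = frac_b),
            class = "isotope_constants_simple")
}

#' Discrimination constants for the mesophyll/photorespiration-corrected model
#'
#' Constants of the extended discrimination model that accounts for mesophyll
#' conductance and photorespiration:
#' ci/ca = \[Delta - a + (b - a_m)(A/ca)(1/g_m) + f * Gamma_star / ca\] / (b - a).
#'
#' @param frac_a Stomatal diffusion discrimination, permil (4.4).
#' @param frac_b Rubisco carboxylation discrimination, permil (30 in this
#'   formulation).
#' @param frac_am Discrimination during dissolution and liquid-phase
#'   diffusion, permil (1.8).
#' @param photoresp_f Discrimination due to photorespiration, permil (12).
#' @param gm Mesophyll conductance to CO2, mol m-2 s-1 (0.2).
#' @param gamma_star Photorespiratory CO2 compensation point,
#'   umol mol-1 (43).
#' @param assim_A Net assimilation rate used in the correction term,
#'   umol m-2 s-1 (default 10). See [cica_corrected()] for an iterative
#'   alternative that solves A jointly with ci.
#' @return An object of class `"isotope_constants_corrected"`.
#' @export
isotope_constants_corrected <- function(frac_a = 4.4, frac_b = 30,
                                        frac_am = 1.8, photoresp_f = 12,
                                        gm = 0.2, gamma_star = 43,
                                        assim_A = 10) {
  vals <- c(frac_a = frac_a, frac_b = frac_b, frac_am = frac_am,
            photoresp_f = photoresp_f, gm = gm, gamma_star = gamma_star,
            assim_A = assim_A)
  if (any(!is.finite(vals)))
    stop("non-finite isotope constant: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (gm <= 0) stop("gm must be > 0")
  if (gamma_star < 0) stop("gamma_star must be >= 0")
  if (!(frac_b > frac_a && frac_a > frac_am && frac_am >= 0))
    stop("constants must satisfy frac_b > frac_a > frac_am >= 0")
  if (photoresp_f < 0) stop("photoresp_f must be >= 0")
  structure(as.list(vals), class = "isotope_constants_corrected")
}

check_finite <- function(x, field) {
  if (!is.numeric(x)) stop("'", field, "' must be numeric")
  bad <- !is.finite(x)
  if (any(bad))
    stop("non-finite value in '", field, "' (", sum(bad), " record(s))")
  invisible(x)
}

#' Carbon-isotope discrimination from plant and atmospheric delta-13C
#'
#' Computes discrimination of plant tissue against 13C relative to the
#' atmospheric source: Delta = (delta_atm - delta_plant) / (1 + delta_plant/1000),
#' with both deltas in permil vs VPDB. This removes the industrial-era decline
#' of atmospheric delta-13C (Suess effect) from wood delta-13C series.
#'
#' @param delta13c_plant Plant (wood) delta-13C, permil.
#' @param delta13c_atm Atmospheric CO2 delta-13C, permil.
#' @return Discrimination Delta, permil. Vectorized; inputs recycle.
#' @examples
#' big_delta(-26, -8) # about 18.48 permil
#' @export
big_delta <- function(delta13c_plant, delta13c_atm) {
  check_finite(delta13c_plant, "delta13c_plant")
  check_finite(delta13c_atm, "delta13c_atm")
  if (any(delta13c_plant <= -40 | delta13c_plant >= 5))
    stop("'delta13c_plant' outside plausible range (-40, 5) permil")
  if (any(delta13c_atm <= -40 | delta13c_atm >= 5))
    stop("'delta13c_atm' outside plausible range (-40, 5) permil")
  (delta13c_atm - delta13c_plant) / (1 + delta13c_plant / 1000)
}

#' Invert discrimination to plant delta-13C
#'
#' Algebraic inverse of [big_delta()]: given Delta and the atmospheric
#' composition, return the plant delta-13C that produced it. Used by the
#' synthetic-data generator to emit delta-13C chronologies.
#'
#' @param big_delta Discrimination, permil.
#' @param delta13c_atm Atmospheric delta-13C, permil.
#' @return Plant delta-13C, permil.
#' @export
delta_plant_from_big_delta <- function(big_delta, delta13c_atm) {
  check_finite(big_delta, "big_delta")
  check_finite(delta13c_atm, "delta13c_atm")
  (delta13c_atm - big_delta) / (1 + big_delta / 1000)
}

#' ci/ca from discrimination (simple model)
#'
#' @param big_delta Discrimination, permil.
#' @param consts Constants from [isotope_constants_simple()].
#' @return ci/ca, dimensionless. Values outside \[0, 1\] are returned as-is;
#'   use [qc_cica()] to flag them.
#' @examples
#' cica_simple(15.7) # 0.5 (midpoint of a = 4.4 and b = 27)
#' @export
cica_simple <- function(big_delta, consts = isotope_constants_simple()) {
  stopifnot(inherits(consts, "isotope_constants_simple"))
  check_finite(big_delta, "big_delta")
  (big_delta - consts$frac_a) / (consts$frac_b - consts$frac_a)
}

#' ci/ca from discrimination (mesophyll/photorespiration-corrected model)
#'
#' Corrected formulation:
#' ci/ca = \[Delta - a + (b - a_m)(A/ca)(1/g_m) + f * Gamma_star / ca\] / (b - a).
#' The assimilation rate A is either the constant `consts$assim_A`
#' (`assim_mode = "constant"`) or solved jointly with ci from the linear CO2
#' response A = k_slope * (ci - Gamma_star) by fixed-point iteration
#' (`assim_mode = "iterative"`, tolerance 1e-8, at most 100 iterations).
#'
#' @param big_delta Discrimination, permil.
#' @param ca Ambient CO2 mole fraction, umol mol-1 (> 0).
#' @param consts Constants from [isotope_constants_corrected()].
#' @param assim_mode `"constant"` (default) or `"iterative"`.
#' @param k_slope Slope of A versus ci (umol m-2 s-1 per umol mol-1), used
#'   only in iterative mode. Default 0.05.
#' @return ci/ca, dimensionless.
#' @export
cica_corrected <- function(big_delta, ca,
                           consts = isotope_constants_corrected(),
                           assim_mode = c("constant", "iterative"),
                           k_slope = 0.05) {
  stopifnot(inherits(consts, "isotope_constants_corrected"))
  assim_mode <- match.arg(assim_mode)
  check_finite(big_delta, "big_delta")
  check_finite(ca, "ca")
  if (any(ca <= 0)) stop("'ca' must be > 0")
  n <- max(length(big_delta), length(ca))
  big_delta <- rep_len(big_delta, n)
  ca <- rep_len(ca, n)
  denom <- consts$frac_b - consts$frac_a
  base <- big_delta - consts$frac_a + consts$photoresp_f * consts$gamma_star / ca
  corr <- function(A) (base + (consts$frac_b - consts$frac_am) * (A / ca) / consts$gm) / denom
  if (assim_mode == "constant") return(corr(consts$assim_A))
  if (k_slope <= 0) stop("'k_slope' must be > 0 in iterative mode")
  A <- rep_len(consts$assim_A, n)
  for (i in seq_len(100L)) {
    cica <- corr(A)
    A_new <- k_slope * (cica * ca - consts$gamma_star)
    if (max(abs(A_new - A)) < 1e-8) return(corr(A_new))
    A <- A_new
  }
  warning("iterative assimilation solve did not converge in 100 iterations")
  corr(A)
}

#' Intrinsic water-use efficiency from ci/ca
#'
#' W = A/gs = (ca - ci)/1.6 = (ca/1.6)(1 - ci/ca), in umol CO2 per mol H2O
#' of stomatal conductance. The factor 1.6 is the ratio of diffusivities of
#' water vapour and CO2 in air.
#'
#' @param ca Ambient CO2, umol mol-1 (> 0).
#' @param cica ci/ca ratio, dimensionless.
#' @return W, umol mol-1. Lies in \[0, ca/1.6\] when `cica` is in \[0, 1\].
#' @examples
#' wue_from_cica(400, 0.6) # 100
#' @export
wue_from_cica <- function(ca, cica) {
  check_finite(ca, "ca")
  check_finite(cica, "cica")
  if (any(ca <= 0)) stop("'ca' must be > 0")
  (ca / 1.6) * (1 - cica)
}

#' Invert W to discrimination under the simple model
#'
#' Exact inverse of the chain [cica_simple()] then [wue_from_cica()]:
#' given W and ca, returns the discrimination Delta that reproduces W.
#'
#' @param w Intrinsic water-use efficiency, umol mol-1, in \[0, ca/1.6\].
#' @param ca Ambient CO2, umol mol-1.
#' @param consts Constants from [isotope_constants_simple()].
#' @return Delta, permil.
#' @export
invert_w_to_delta <- function(w, ca, consts = isotope_constants_simple()) {
  stopifnot(inherits(consts, "isotope_constants_simple"))
  check_finite(w, "w")
  check_finite(ca, "ca")
  if (any(ca <= 0)) stop("'ca' must be > 0")
  if (any(w < 0 | w > ca / 1.6))
    stop("'w' outside [0, ca/1.6]")
  cica <- 1 - 1.6 * w / ca
  consts$frac_a + cica * (consts$frac_b - consts$frac_a)
}

#' Flag ci/ca values outside the physical range
#'
#' @param cica Numeric vector of ci/ca values.
#' @return Character vector: `"ok"` or `"cica_out_of_range"`.
#' @export
qc_cica <- function(cica) {
  ifelse(is.na(cica) | cica < 0 | cica > 1, "cica_out_of_range", "ok")
}

# Anchor points for the bundled approximate atmospheric delta-13C curve
# (permil vs VPDB). Smooth, monotone-declining industrial-era trajectory;
# users with a measured series should supply it instead.
.atm_delta_anchors <- data.frame(
  year  = c(1850, 1900, 1945, 1965, 1980, 1990, 2000, 2010, 2015),
  delta = c(-6.41, -6.64, -6.77, -7.05, -7.53, -7.78, -8.05, -8.30, -8.44)
)

#' Bundled atmospheric delta-13C series (approximate)
#'
#' A smooth monotone (Hyman-filtered spline) curve through historical anchor
#' values of atmospheric CO2 delta-13C, declining from about -6.4 permil in
#' 1850 to about -8.4 permil in 2015 (the Suess effect). It is an
#' approximation for testing and simulation; analyses of real chronologies
#' should use a measured series.
#'
#' @param years Integer vector of calendar years in \[1850, 2015\].
#' @return data.frame with columns `year`, `delta13c_atm`.
#' @export
delta13c_atm_default <- function(years) {
  stopifnot(is.numeric(years))
  if (any(years < 1850 | years > 2015))
    stop("bundled atmospheric delta-13C series covers 1850-2015 only")
  f <- stats::splinefun(.atm_delta_anchors$year, .atm_delta_anchors$delta,
                        method = "hyman")
  data.frame(year = as.integer(years), delta13c_atm = f(years))
}

#' Compute W columns for a tree-ring chronology table
#'
#' Joins a chronology table to annual atmospheric CO2 (and delta-13C, when
#' the table holds raw plant delta-13C rather than discrimination) and adds
#' ci/ca and W under both discrimination models plus a quality flag.
#'
#' @param obs data.frame with columns `site_id`, `tree_id`, `year`,
#'   `species_group`, and exactly one of `delta13c_plant` or `big_delta`.
#' @param co2 data.frame with columns `year`, `ca` (umol mol-1).
#' @param atm_delta Optional data.frame `year`, `delta13c_atm`; defaults to
#'   [delta13c_atm_default()] over the observed years. Ignored when the
#'   table already carries `big_delta`.
#' @param consts_simple,consts_corrected Constant sets for the two models.
#' @param assim_mode Passed to [cica_corrected()].
#' @return The input table with added columns `ca`, `big_delta`,
#'   `cica_simple`, `cica_corrected`, `w_simple`, `w_corrected`, `qc_flag`.
#' @export
compute_wue_table <- function(obs, co2, atm_delta = NULL,
                              consts_simple = isotope_constants_simple(),
                              consts_corrected = isotope_constants_corrected(),
                              assim_mode = "constant") {
  need <- c("site_id", "tree_id", "year")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("chronology table lacks column(s): ",
                         paste(miss, collapse = ", "))
  has_d <- "delta13c_plant" %in% names(obs)
  has_D <- "big_delta" %in% names(obs)
  if (has_d == has_D)
    stop("chronology table must have exactly one of 'delta13c_plant' or 'big_delta'")
  if (!all(c("year", "ca") %in% names(co2)))
    stop("CO2 table needs columns 'year' and 'ca'")
  out <- merge(obs, co2[, c("year", "ca")], by = "year", sort = FALSE)
  if (nrow(out) < nrow(obs))
    warning(nrow(obs) - nrow(out), " observation(s) dropped: no CO2 value for their year")
  if (has_d) {
    if (is.null(atm_delta))
      atm_delta <- delta13c_atm_default(sort(unique(out$year)))
    out <- merge(out, atm_delta[, c("year", "delta13c_atm")],
                 by = "year", sort = FALSE)
    out$big_delta <- big_delta(out$delta13c_plant, out$delta13c_atm)
  }
  out$cica_simple <- cica_simple(out$big_delta, consts_simple)
  out$cica_corrected <- cica_corrected(out$big_delta, out$ca,
                                       consts_corrected, assim_mode)
  out$w_simple <- wue_from_cica(out$ca, out$cica_simple)
  out$w_corrected <- wue_from_cica(out$ca, out$cica_corrected)
  out$qc_flag <- ifelse(qc_cica(out$cica_simple) == "ok" &
                          qc_cica(out$cica_corrected) == "ok",
                        "ok", "cica_out_of_range")
  out[order(out$site_id, out$tree_id, out$year), , drop = FALSE]
}

#' Read a tree-ring chronology table
#'
#' Reads a delimited (CSV/TSV by extension or `sep`) chronology with header
#' columns `site_id, tree_id, year, delta13c` (or `big_delta`),
#' `species_group`; empty cells are missing values. A `delta13c` column is
#' renamed to `delta13c_plant`.
#'
#' @param path File path.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return data.frame.
#' @export
read_chronology <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("delta13c" %in% names(x))
    names(x)[names(x) == "delta13c"] <- "delta13c_plant"
  x
}
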