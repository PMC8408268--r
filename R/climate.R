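# Magnus constants (kPa, dimensionless, degC). The approach is named in the
# climate literature; these particular constants are the common modern fit.
.magnus <- c(es0 = 0.61094, a = 17.625, b = 243.04)

#' Aridity index
#'
#' AI = P/PET, dimensionless. AI < 1 denotes water-limited (arid) climate;
#' AI = 1 is the balance point where precipitation equals atmospheric demand.
#'
#' @param precip Annual precipitation P, mm.
#' @param pet Annual potential evapotranspiration PET, mm (> 0).
#' @param site_id,year Optional labels used in error messages.
#' @return AI, dimensionless.
#' @examples
#' aridity_index(1000, 1000) # 1
#' @export
aridity_index <- function(precip, pet, site_id = NULL, year = NULL) {
  check_finite(precip, "precip")
  check_finite(pet, "pet")
  if (any(precip < 0)) stop("'precip' must be >= 0")
  bad <- pet <= 0
  if (any(bad)) {
    where <- which(bad)[1L]
    lab <- paste0(
      if (!is.null(site_id)) paste0(" site ", rep_len(site_id, length(pet))[where]),
      if (!is.null(year)) paste0(" year ", rep_len(year, length(pet))[where]))
    stop("PET must be > 0 (first offending record:", lab, " index ", where, ")")
  }
  precip / pet
}

#' Saturation vapour pressure (Magnus form)
#'
#' @param tmean Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
saturation_vp <- function(tmean) {
  check_finite(tmean, "tmean")
  .magnus[["es0"]] * exp(.magnus[["a"]] * tmean / (tmean + .magnus[["b"]]))
}

#' Vapour pressure deficit by the August-Roche-Magnus approach
#'
#' VPD = es(T) * (1 - RH/100) with es(T) = 0.61094 * exp(17.625 T / (T + 243.04)) kPa.
#'
#' @param tmean Mean air temperature, degC, in (-60, 60).
#' @param rh Relative humidity, percent, in \[0, 100\].
#' @return VPD, kPa (>= 0).
#' @examples
#' vpd_magnus(20, 50) # about 1.167 kPa
#' @export
vpd_magnus <- function(tmean, rh) {
  check_finite(tmean, "tmean")
  check_finite(rh, "rh")
  if (any(tmean <= -60 | tmean >= 60)) stop("'tmean' outside (-60, 60) degC")
  if (any(rh < 0 | rh > 100)) stop("'rh' outside [0, 100] percent")
  saturation_vp(tmean) * (1 - rh / 100)
}

#' CO2 adjustment of Penman-Monteith PET
#'
#' Multiplicative adjustment of a supplied Penman-Monteith PET for the effect
#' of rising CO2 on canopy surface resistance. The bulk surface resistance in
#' the PM denominator is taken to grow linearly with (ca - ca_ref), so
#'
#'   PET_adj = PET * (s + gamma (1 + rr_ref)) / (s + gamma (1 + rr_ref (1 + k (ca - ca_ref))))
#'
#' where s is the slope of the saturation vapour curve at `tmean`, gamma the
#' psychrometric constant and rr_ref the reference ratio of surface to
#' aerodynamic resistance. At `ca = ca_ref` the factor is exactly 1; it
#' decreases monotonically as ca rises. The linear-resistance reading of the
#' published CO2 correction is a package design choice (see the methods
#' vignette); the adjustment is pluggable via `factor_fn`.
#'
#' @param pet Unadjusted PET, mm.
#' @param tmean Mean air temperature, degC (needed for the vapour-curve slope).
#' @param ca Ambient CO2, umol mol-1 (> 0).
#' @param ca_ref Reference CO2 at which no adjustment applies. Default 300.
#' @param rr_ref Reference rs/ra ratio. Default 0.67 (FAO-style reference
#'   crop with moderate wind).
#' @param co2_sens Fractional increase of surface resistance per umol mol-1
#'   CO2 above the reference. Default 0.0016.
#' @param gamma Psychrometric constant, kPa degC-1. Default 0.066.
#' @param factor_fn Optional replacement strategy: `function(tmean, ca)`
#'   returning the multiplicative factor.
#' @return Adjusted PET, mm (<= `pet` for `ca > ca_ref`).
#' @export
pet_co2_adjust <- function(pet, tmean, ca, ca_ref = 300, rr_ref = 0.67,
                           co2_sens = 0.0016, gamma = 0.066,
                           factor_fn = NULL) {
  check_finite(pet, "pet")
  check_finite(ca, "ca")
  if (any(ca <= 0)) stop("'ca' must be > 0")
  if (!is.null(factor_fn)) return(pet * factor_fn(tmean, ca))
  if (missing(tmean) || is.null(tmean) || any(!is.finite(tmean)))
    stop("PET CO2 adjustment unavailable: 'tmean' missing; proceed with unadjusted PET")
  es <- saturation_vp(tmean)
  s <- es * .magnus[["a"]] * .magnus[["b"]] / (tmean + .magnus[["b"]])^2
  rs_ratio <- rr_ref * (1 + co2_sens * pmax(ca - ca_ref, -1 / co2_sens + 1e-9))
  pet * (s + gamma * (1 + rr_ref)) / (s + gamma * (1 + rs_ratio))
}

#' Aggregate monthly climate to site-year rows
#'
#' Sums precipitation and PET over the calendar year, averages temperature
#' and VPD, and computes the annual aridity index from the annual sums (not
#' the mean of monthly P/PET ratios, which is unstable when monthly PET is
#' near zero). Years with fewer than 12 months are flagged `incomplete` and
#' are excluded from fits by default downstream.
#'
#' @param monthly data.frame with columns `site_id`, `year`, `month`,
#'   `precip`, `pet`, `tmean`, and optionally `vpd` or `rh` (CRU-style input:
#'   VPD derived from `tmean` and `rh`).
#' @param dialect `"terraclimate"` (VPD provided) or `"cru"` (derive VPD from
#'   tmean and rh).
#' @return data.frame with columns `site_id`, `year`, `precip`, `pet`,
#'   `tmean`, `vpd`, `ai`, `complete` (logical).
#' @export
annualize <- function(monthly, dialect = c("terraclimate", "cru")) {
  dialect <- match.arg(dialect)
  need <- c("site_id", "year", "month", "precip", "pet", "tmean")
  miss <- setdiff(need, names(monthly))
  if (length(miss)) stop("monthly table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (dialect == "cru") {
    if (!"rh" %in% names(monthly))
      stop("cru dialect requires an 'rh' column to derive VPD")
    monthly$vpd <- vpd_magnus(monthly$tmean, monthly$rh)
  } else if (!"vpd" %in% names(monthly)) {
    stop("terraclimate dialect requires a 'vpd' column")
  }
  key <- interaction(monthly$site_id, monthly$year, drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  out <- data.frame(
    site_id = as.vector(tapply(as.character(monthly$site_id), key, `[`, 1L)),
    year = as.integer(tapply(monthly$year, key, `[`, 1L)),
    precip = agg(monthly$precip, sum),
    pet = agg(monthly$pet, sum),
    tmean = agg(monthly$tmean, mean),
    vpd = agg(monthly$vpd, mean),
    n_months = as.integer(tapply(monthly$month, key,
                                 function(m) length(unique(m)))),
    stringsAsFactors = FALSE
  )
  out$ai <- aridity_index(out$precip, out$pet, out$site_id, out$year)
  out$complete <- out$n_months == 12L
  out$n_months <- NULL
  rownames(out) <- NULL
  out[order(out$site_id, out$year), , drop = FALSE]
}
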