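#' Carbon-cost function of low leaf water potential
#'
#' The marginal carbon cost of letting leaf water potential fall (embolism
#' risk, refilling, foregone photosynthesis) is represented by a generic
#' non-negative, non-decreasing function f+ of (-psi_leaf). The default form
#' is linear with a configurable coefficient; a power form is also offered.
#'
#' @param form `"linear"` (coef * x) or `"power"` (coef * x^exponent).
#' @param coef Non-negative coefficient. Default 0.1.
#' @param exponent Exponent for the power form (> 0). Default 2.
#' @return Object of class `"fplus_spec"`; callable via [fplus_eval()].
#' @export
fplus_spec <- function(form = c("linear", "power"), coef = 0.1, exponent = 2) {
  form <- match.arg(form)
  stopifnot(is.numeric(coef), coef >= 0, exponent > 0)
  structure(list(form = form, coef = coef, exponent = exponent),
            class = "fplus_spec")
}

#' Evaluate a cost-function specification
#'
#' @param f A [fplus_spec()].
#' @param x Argument (-psi_leaf), MPa (>= 0 in valid use).
#' @return f+(x), non-negative and non-decreasing in x.
#' @export
fplus_eval <- function(f, x) {
  stopifnot(inherits(f, "fplus_spec"))
  switch(f$form,
         linear = f$coef * x,
         power = f$coef * x^f$exponent)
}

#' Parameters of the stomatal-optimization model
#'
#' The model balances the marginal carbon revenue of transpiration against
#' the marginal carbon cost of supplying that water through the hydraulic
#' system.
#'
#' @param D Leaf-to-air vapour mole-fraction gradient, mol mol-1 (> 0).
#' @param ca Ambient CO2, umol mol-1.
#' @param gamma_big CO2 compensation point Gamma, umol mol-1 (ca > Gamma >= 0).
#' @param psi_soil,psi_leaf Soil and leaf water potentials, MPa
#'   (psi_soil >= psi_leaf: water flows down-gradient).
#' @param K Whole-plant hydraulic conductance (flux per MPa, > 0).
#' @param dK_dC Marginal conductance gained per unit carbon invested (> 0).
#' @param fplus Cost function, a [fplus_spec()].
#' @param k_slope Slope of the A-ci response used in deriving the revenue
#'   term (> 0); kept for completeness, it cancels from the optimum.
#' @return Object of class `"optim_params"`.
#' @export
optim_params <- function(D = 0.015, ca = 400, gamma_big = 40,
                         psi_soil = -0.5, psi_leaf = -1.5, K = 4,
                         dK_dC = 0.5, fplus = fplus_spec(), k_slope = 0.05) {
  stopifnot(D > 0, ca > 0, gamma_big >= 0, K > 0, dK_dC > 0, k_slope > 0,
            inherits(fplus, "fplus_spec"))
  if (ca <= gamma_big) stop("'ca' must exceed the compensation point")
  if (psi_soil < psi_leaf)
    stop("psi_soil must be >= psi_leaf (water flows down-gradient)")
  structure(list(D = D, ca = ca, gamma_big = gamma_big, psi_soil = psi_soil,
                 psi_leaf = psi_leaf, K = K, dK_dC = dK_dC, fplus = fplus,
                 k_slope = k_slope), class = "optim_params")
}

#' Marginal carbon revenue of water
#'
#' dA/dE = W^2 / (1.6 D (ca - Gamma)), in umol CO2 per mol H2O: the extra
#' assimilation bought by the last unit of transpiration, at intrinsic
#' water-use efficiency W.
#'
#' @param w Intrinsic water-use efficiency, umol mol-1.
#' @param p An [optim_params()].
#' @return dA/dE; zero iff `w` is zero, quadratic in `w`.
#' @examples
#' marginal_revenue(100, optim_params(D = 0.015, ca = 400, gamma_big = 40))
#' @export
marginal_revenue <- function(w, p) {
  stopifnot(inherits(p, "optim_params"))
  check_finite(w, "w")
  if (p$ca <= p$gamma_big) stop("'ca' must exceed the compensation point")
  w^2 / (1.6 * p$D * (p$ca - p$gamma_big))
}

#' Marginal carbon cost of water
#'
#' dC/dE = 1 / ((psi_soil - psi_leaf) dK/dC) + f+(-psi_leaf) / K: the cost of
#' building conductance to move the extra water, plus the risk cost of the
#' lower leaf water potential it implies. Equal soil and leaf potentials
#' signal infinite cost (no gradient to drive flow).
#'
#' @param p An [optim_params()].
#' @return dC/dE, strictly positive; `Inf` when psi_soil == psi_leaf.
#' @export
marginal_cost <- function(p) {
  stopifnot(inherits(p, "optim_params"))
  grad <- p$psi_soil - p$psi_leaf
  if (grad < 0) stop("psi_soil must be >= psi_leaf")
  if (grad == 0) return(Inf)
  1 / (grad * p$dK_dC) + fplus_eval(p$fplus, -p$psi_leaf) / p$K
}

#' Optimal intrinsic water-use efficiency
#'
#' The profit-maximising W equates marginal revenue and marginal cost:
#' W* = sqrt(1.6 D (ca - Gamma)) * sqrt(dC/dE). The returned optimum is
#' verified internally to satisfy marginal_revenue(W*) = marginal_cost(p).
#'
#' @param p An [optim_params()].
#' @return W*, umol mol-1.
#' @export
optimal_w <- function(p) {
  mc <- marginal_cost(p)
  if (!is.finite(mc)) stop("infinite marginal cost: psi_soil equals psi_leaf")
  w <- sqrt(1.6 * p$D * (p$ca - p$gamma_big)) * sqrt(mc)
  stopifnot(abs(marginal_revenue(w, p) - mc) <= 1e-8 * max(mc, 1))
  w
}

#' W response to soil water potential under two hydric strategies
#'
#' Sweeps psi_soil and returns the optimal W under either endpoint of the
#' iso/anisohydric continuum: `"isohydric"` holds psi_leaf fixed (the
#' soil-to-leaf gradient widens as soil wets, collapsing the
#' conductance-building cost), while `"isohydrodynamic"` holds the gradient
#' (psi_soil - psi_leaf) fixed (the risk cost f+ falls as the soil wets).
#' Both predict W non-increasing as psi_soil rises towards zero: wetter soil,
#' lower water-use efficiency.
#'
#' @param psi_soil_sweep Numeric vector of soil water potentials, MPa,
#'   within (psi_min, 0\].
#' @param strategy `"isohydric"` or `"isohydrodynamic"`.
#' @param p An [optim_params()]; `p$psi_leaf` is the fixed leaf potential
#'   (isohydric; must lie below the whole sweep) and
#'   `p$psi_soil - p$psi_leaf` the fixed gradient (isohydrodynamic).
#' @return data.frame with `psi_soil`, `psi_leaf`, `w`.
#' @export
w_response <- function(psi_soil_sweep, strategy = c("isohydric", "isohydrodynamic"),
                       p = optim_params()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(p, "optim_params"))
  check_finite(psi_soil_sweep, "psi_soil_sweep")
  if (any(psi_soil_sweep > 0)) stop("psi_soil must be <= 0")
  leaf <- switch(strategy,
                 isohydric = rep_len(p$psi_leaf, length(psi_soil_sweep)),
                 isohydrodynamic = psi_soil_sweep - (p$psi_soil - p$psi_leaf))
  if (any(psi_soil_sweep <= leaf))
    stop("sweep requires psi_soil > psi_leaf throughout; adjust psi_leaf ",
         "(isohydric) or the fixed gradient (isohydrodynamic)")
  w <- vapply(seq_along(psi_soil_sweep), function(i) {
    pi <- p; pi$psi_soil <- psi_soil_sweep[i]; pi$psi_leaf <- leaf[i]
    optimal_w(pi)
  }, numeric(1))
  data.frame(psi_soil = psi_soil_sweep, psi_leaf = leaf, w = w)
}

#' Annual hydrological mass-balance parameters
#'
#' Annual soil water balance P = T + r + d (precipitation, transpiration,
#' runoff, drainage, all mm yr-1). At the precipitation P* just sufficient to
#' saturate the soil, T approximates PET.
#'
#' @param pet_PET Potential evapotranspiration, mm yr-1 (> 0).
#' @param runoff_r Runoff, mm yr-1 (>= 0). Default 0.
#' @param drainage_d Drainage, mm yr-1 (>= 0). Default 0.
#' @param precip_P Optional precipitation, mm yr-1.
#' @param transpiration_T Optional transpiration, mm yr-1.
#' @return Object of class `"hydro_params"`.
#' @export
hydro_params <- function(pet_PET, runoff_r = 0, drainage_d = 0,
                         precip_P = NULL, transpiration_T = NULL) {
  stopifnot(is.numeric(pet_PET), runoff_r >= 0, drainage_d >= 0)
  if (pet_PET <= 0) stop("PET must be > 0")
  structure(list(pet_PET = pet_PET, runoff_r = runoff_r,
                 drainage_d = drainage_d, precip_P = precip_P,
                 transpiration_T = transpiration_T),
            class = "hydro_params")
}

#' Aridity-index threshold from the annual water balance
#'
#' AI* = P*/PET = 1 + (r + d)/PET: the aridity index at which precipitation
#' just saturates the soil, above which soil water potential (and hence the
#' optimal W) stops responding to further increases in AI. With runoff and
#' drainage negligible relative to PET, AI* is approximately 1.
#'
#' @param h A [hydro_params()].
#' @return AI*, dimensionless (>= 1).
#' @examples
#' ai_threshold(hydro_params(pet_PET = 1000)) # 1
#' @export
ai_threshold <- function(h) {
  stopifnot(inherits(h, "hydro_params"))
  1 + (h$runoff_r + h$drainage_d) / h$pet_PET
}

#' Predicted W as a function of aridity index
#'
#' Combines the optimization model with a monotone mapping from AI to soil
#' water potential. The default map is psi_soil(AI) = psi_min * max(0, 1 -
#' AI/AI*), i.e. linear recovery from `psi_min` at AI = 0 to saturation
#' (psi_soil = 0) exactly at AI* = [ai_threshold()]. The predicted curve
#' declines strictly below AI*, is constant above it, and is continuous at
#' the threshold: a kink, not a jump.
#'
#' @param ai_grid Numeric vector of AI values (>= 0).
#' @param p An [optim_params()]; `p$psi_leaf` must lie below `psi_min`
#'   (isohydric) so the soil-to-leaf gradient stays positive over the curve.
#' @param h A [hydro_params()] defining AI*.
#' @param psi_min Soil water potential at AI = 0, MPa (< 0). Default -3.
#' @param psisoil_map Optional replacement map `function(ai)`; must be
#'   monotone non-decreasing with psi_soil = 0 for AI >= AI*.
#' @param strategy Passed to [w_response()].
#' @return data.frame with `ai`, `psi_soil`, `w`.
#' @export
predict_w_ai_curve <- function(ai_grid, p = optim_params(psi_leaf = -4),
                               h = hydro_params(pet_PET = 1000),
                               psi_min = -3, psisoil_map = NULL,
                               strategy = "isohydric") {
  check_finite(ai_grid, "ai_grid")
  if (any(ai_grid < 0)) stop("AI must be >= 0")
  ai_star <- ai_threshold(h)
  if (is.null(psisoil_map)) {
    stopifnot(psi_min < 0)
    psisoil_map <- function(ai) psi_min * pmax(0, 1 - ai / ai_star)
  }
  psi <- psisoil_map(ai_grid)
  o <- order(ai_grid)
  if (is.unsorted(psi[o]))
    stop("psi_soil(AI) map must be monotone non-decreasing in AI")
  if (any(psi > 0)) stop("psi_soil(AI) map must return values <= 0")
  if (any(abs(psi[ai_grid >= ai_star]) > 0))
    stop("psi_soil(AI) map must saturate (psi_soil = 0) at AI >= AI*")
  res <- w_response(psi, strategy = strategy, p = p)
  data.frame(ai = ai_grid, psi_soil = psi, w = res$w)
}
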