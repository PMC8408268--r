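test_that("marginal revenue of water is quadratic in W", {
  p <- optim_params(D = 0.015, ca = 400, gamma_big = 40)
  expect_equal(marginal_revenue(0, p), 0)
  # 100^2 / (1.6 * 0.015 * 360) = 1e4 / 8.64
  expect_equal(marginal_revenue(100, p), 1157.41, tolerance = 1e-5)
  expect_equal(marginal_revenue(200, p), 4 * marginal_revenue(100, p))
  expect_error(optim_params(ca = 30, gamma_big = 40), "compensation")
})

test_that("marginal cost adds conductance-building and risk terms", {
  p <- optim_params(psi_soil = -1, psi_leaf = -2, dK_dC = 0.5,
                    fplus = fplus_spec(coef = 0))
  expect_equal(marginal_cost(p), 2) # 1 / (1 * 0.5)
  p2 <- optim_params(psi_soil = -1, psi_leaf = -2, dK_dC = 1, K = 1,
                     fplus = fplus_spec(coef = 0.5))
  expect_equal(marginal_cost(p2), 2) # 1 + f(2)/1 = 1 + 1
  # f(x) = 0.1 x, psi_leaf = -2, K = 4, first term 1.25
  p3 <- optim_params(psi_soil = -0.4, psi_leaf = -2, dK_dC = 0.5, K = 4,
                     fplus = fplus_spec(coef = 0.1))
  expect_equal(marginal_cost(p3), 1.25 + 0.2 / 4)
  # equal potentials signal infinite cost
  p4 <- optim_params(psi_soil = -1, psi_leaf = -1)
  expect_equal(marginal_cost(p4), Inf)
  expect_error(optim_params(psi_soil = -2, psi_leaf = -1), "down-gradient")
})

test_that("optimal W equates marginal revenue and cost", {
  p <- optim_params()
  c0 <- marginal_cost(p)
  expect_equal(optimal_w(p), sqrt(1.6 * p$D * (p$ca - p$gamma_big) * c0))
  # independent numeric oracle: bracketed root of revenue - cost
  set.seed(61)
  for (i in 1:50) {
    pl <- -runif(1, 0.5, 4)
    pr <- optim_params(D = runif(1, 0.005, 0.04), ca = runif(1, 300, 420),
                       gamma_big = runif(1, 20, 60),
                       psi_soil = runif(1, max(pl + 0.05, -1.5), 0),
                       psi_leaf = pl, K = runif(1, 0.5, 10),
                       dK_dC = runif(1, 0.05, 2),
                       fplus = fplus_spec(coef = runif(1, 0, 0.5)))
    target <- marginal_cost(pr)
    root <- uniroot(function(w) marginal_revenue(w, pr) - target,
                    c(1e-9, 1e5), tol = 1e-12)$root
    expect_equal(optimal_w(pr), root, tolerance = 1e-6)
  }
  # D -> 0 limit
  expect_lt(optimal_w(optim_params(D = 1e-10)), 1e-3)
})

test_that("W declines as soil wets under both hydric strategies", {
  sweep <- seq(-3, -0.01, length.out = 80)
  p_iso <- optim_params(psi_leaf = -3.5)
  r_iso <- w_response(sweep, "isohydric", p_iso)
  expect_true(all(diff(r_iso$w) < 0))
  p_dyn <- optim_params(psi_soil = -0.5, psi_leaf = -1.5) # gradient 1 fixed
  r_dyn <- w_response(sweep, "isohydrodynamic", p_dyn)
  expect_true(all(diff(r_dyn$w) < 0))
  expect_equal(r_dyn$psi_soil - r_dyn$psi_leaf, rep(1, 80))
})

test_that("isohydric W ratio matches the closed form when risk cost is zero", {
  # W ~ sqrt(1/(psi_soil + a)) with a = -psi_leaf = 2:
  # ratio at psi -1 vs -0.5 is sqrt(1.5)
  p <- optim_params(psi_leaf = -2, dK_dC = 1, fplus = fplus_spec(coef = 0))
  r <- w_response(c(-1, -0.5), "isohydric", p)
  expect_equal(r$w[1] / r$w[2], sqrt(1.5), tolerance = 1e-10)
  expect_equal(r$w[1] / r$w[2], 1.2247, tolerance = 1e-4)
})

test_that("hydrological threshold AI* = 1 + (r + d)/PET", {
  expect_identical(ai_threshold(hydro_params(pet_PET = 1000)), 1)
  expect_equal(ai_threshold(hydro_params(pet_PET = 1000, runoff_r = 300,
                                         drainage_d = 200)), 1.5)
  expect_equal(ai_threshold(hydro_params(pet_PET = 1000, runoff_r = 100)), 1.1)
  expect_error(hydro_params(pet_PET = 0), "PET")
})

test_that("predicted W-AI curve kinks exactly at the threshold", {
  h <- hydro_params(pet_PET = 1000, runoff_r = 120, drainage_d = 80)
  ai_star <- ai_threshold(h) # 1.2
  grid <- sort(c(seq(0.05, 3, by = 0.05), ai_star))
  cur <- predict_w_ai_curve(grid, h = h)
  below <- cur$w[cur$ai < ai_star]
  above <- cur$w[cur$ai >= ai_star]
  expect_true(all(diff(below) < 0))
  expect_true(all(abs(above - above[1]) < 1e-12))
  # continuity at the kink: no jump, flatness onset at AI* exactly
  w_at <- cur$w[cur$ai == ai_star]
  just_below <- predict_w_ai_curve(ai_star - 1e-8, h = h)$w
  expect_equal(just_below, w_at, tolerance = 1e-6)
  expect_gt(predict_w_ai_curve(ai_star - 0.01, h = h)$w, w_at)
  # saturated grid: identical W everywhere above AI*
  sat <- predict_w_ai_curve(c(2, 3, 4), h = h)
  expect_equal(sat$w, rep(sat$w[1], 3))
})

test_that("non-monotone soil-water maps are rejected", {
  bad <- function(ai) -pmax(0, sin(ai))
  expect_error(predict_w_ai_curve(seq(0.1, 3, 0.1), psisoil_map = bad),
               "monotone")
})

test_that("optimal W rises with D and with ca at fixed cost", {
  base <- optim_params()
  expect_gt(optimal_w(optim_params(D = 0.03)), optimal_w(base))
  expect_gt(optimal_w(optim_params(ca = 420)), optimal_w(base))
})
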