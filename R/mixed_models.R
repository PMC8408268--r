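#' Specify a mixed model for W
#'
#' Fixed effects are polynomial terms of dataset columns, written as
#' `"ca"`, `"ai^2"`, `"ndep_cum^3"` and so on (powers 1-3, no duplicates);
#' the random structure is a tree-level intercept. Covariates enter on their
#' natural scales (no centring or standardisation), so coefficients are
#' directly interpretable in the response units.
#'
#' @param terms Character vector of fixed terms, e.g.
#'   `c("ca", "ai", "ai^2")`.
#' @param response Response column. Default `"w"`.
#' @param random Grouping column for the random intercept. Default
#'   `"tree_uid"`.
#' @param estimation `"ML"` or `"REML"`. ML is required for AICc comparison
#'   across fixed structures. Default `"ML"`.
#' @return Object of class `"wue_model_spec"`.
#' @export
model_spec <- function(terms, response = "w", random = "tree_uid",
                       estimation = c("ML", "REML")) {
  estimation <- match.arg(estimation)
  stopifnot(is.character(terms), length(terms) >= 1)
  parsed <- parse_terms(terms)
  if (anyDuplicated(paste(parsed$var, parsed$power)))
    stop("duplicate fixed terms")
  if (any(parsed$power > 3)) stop("polynomial powers above 3 are not supported")
  structure(list(terms = terms, parsed = parsed, response = response,
                 random = random, estimation = estimation),
            class = "wue_model_spec")
}

parse_terms <- function(terms) {
  m <- regmatches(terms, regexec("^([A-Za-z_][A-Za-z0-9_.]*)(\\^([0-9]+))?$", terms))
  bad <- vapply(m, length, 1L) == 0L | !nzchar(vapply(m, `[`, "", 1L))
  if (any(bad)) stop("malformed term(s): ", paste(terms[bad], collapse = ", "))
  data.frame(var = vapply(m, `[`, "", 2L),
             power = as.integer(ifelse(vapply(m, `[`, "", 4L) == "", "1",
                                       vapply(m, `[`, "", 4L))),
             stringsAsFactors = FALSE)
}

term_to_r <- function(var, power) {
  ifelse(power == 1L, var, paste0("I(", var, "^", power, ")"))
}

spec_formula <- function(spec) {
  fx <- paste(term_to_r(spec$parsed$var, spec$parsed$power), collapse = " + ")
  stats::as.formula(paste0(spec$response, " ~ ", fx,
                           " + (1 | ", spec$random, ")"))
}

#' Fit a linear mixed model for W with a tree random intercept
#'
#' Fits the specified model by (restricted) maximum likelihood via
#' \pkg{lme4}, and extracts the quantities the analysis reports: coefficient
#' table with Wald p-values approximated by the normal distribution,
#' variance components, AICc, and Nakagawa-style marginal and conditional
#' R-squared.
#'
#' @param data Analysis table containing the response, covariates and the
#'   random-grouping column.
#' @param spec A [model_spec()].
#' @return Object of class `"wue_lmm"`: list with `coefficients` (Estimate,
#'   SE, z, p), `var_fixed`, `var_tree`, `var_resid`, `aicc`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_trees`, `converged`, `spec`, `fit` (the
#'   underlying \code{merMod}).
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "wue_model_spec"))
  need <- unique(c(spec$response, spec$parsed$var, spec$random))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  grp <- factor(data[[spec$random]])
  if (nlevels(grp) < 2)
    stop("random intercept over '", spec$random,
         "' is inestimable: fewer than 2 groups")
  if (nrow(data) < nlevels(grp) + length(spec$terms) + 2)
    stop("too few observations for the requested model")

  # collinearity screen on the fixed design (QR rank)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(term_to_r(spec$parsed$var, spec$parsed$power),
                                       collapse = " + "))), data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }

  fml <- spec_formula(spec)
  # convergence/singularity diagnostics are read from optinfo below, so the
  # duplicate console warnings are muted
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = spec$estimation == "REML")))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_tree <- vc$vcov[vc$grp == spec$random][1L]
  var_resid <- vc$vcov[vc$grp == "Residual"][1L]
  var_fixed <- stats::var(as.vector(X %*% beta))
  r2 <- r2_components(var_fixed, var_tree, var_resid)

  ll <- stats::logLik(fit)
  k <- attr(ll, "df") # fixed coefficients incl. intercept + 2 variance components
  n <- nrow(data)
  aicc <- -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)

  structure(list(coefficients = coefs, var_fixed = var_fixed,
                 var_tree = var_tree, var_resid = var_resid,
                 aicc = aicc, k = k, logLik = as.numeric(ll),
                 r2_marginal = r2[["marginal"]],
                 r2_conditional = r2[["conditional"]],
                 n_obs = n, n_trees = nlevels(grp), converged = conv,
                 spec = spec, fit = fit, data = data[need]),
            class = "wue_lmm")
}

#' @export
print.wue_lmm <- function(x, ...) {
  cat("Linear mixed model (", x$spec$estimation, "), ",
      x$n_obs, " obs, ", x$n_trees, " trees\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("variance: tree %.3f, residual %.3f\n", x$var_tree, x$var_resid))
  cat(sprintf("AICc %.2f;  R2 marginal %.3f, conditional %.3f\n",
              x$aicc, x$r2_marginal, x$r2_conditional))
  if (!x$converged) cat("note: convergence warnings reported by lme4\n")
  invisible(x)
}

#' Marginal and conditional R-squared from variance components
#'
#' Marginal R2 = var_fixed / (var_fixed + var_tree + var_resid) measures the
#' variance explained by fixed effects alone; conditional R2 adds the
#' tree-level random-intercept variance to the numerator.
#'
#' @param var_fixed Variance of the fixed-effect predictor.
#' @param var_tree Random-intercept (tree) variance.
#' @param var_resid Residual variance.
#' @return Named vector `c(marginal, conditional)`.
#' @export
r2_components <- function(var_fixed, var_tree, var_resid) {
  stopifnot(var_fixed >= 0, var_tree >= 0, var_resid >= 0)
  tot <- var_fixed + var_tree + var_resid
  if (tot <= 0) stop("zero total variance")
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_tree) / tot)
}

#' Marginal and conditional R-squared of a fitted mixed model
#'
#' @param fit A [fit_lmm()] result.
#' @return Named vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "wue_lmm"))
  if (!fit$converged) warning("R2 computed from a fit with convergence warnings")
  r2_components(fit$var_fixed, fit$var_tree, fit$var_resid)
}

# nested polynomial sets per candidate: absent, {1}, {1,2}, {1,2,3}
.power_sets <- function(max_power) lapply(0:max_power, function(p) seq_len(p))

#' Exhaustive AICc model search over polynomial covariates
#'
#' Enumerates every combination of candidate variables with nested
#' polynomial degree up to `max_power` (a variable enters with powers
#' 1..d), fits each by ML, and ranks by AICc. Ties in AICc (within
#' `tie_tol`) are broken in favour of the model with the fewest covariates.
#' No stepwise shortcuts are taken.
#'
#' @param data Analysis table.
#' @param candidates Character vector of candidate variable columns, in the
#'   canonical entry order used later for importance decomposition
#'   (e.g. `c("ca", "ai", "ndep_cum")`).
#' @param max_power Maximum polynomial degree. Default 3.
#' @param response,random As in [model_spec()].
#' @param tie_tol AICc difference treated as a tie. Default 1e-6.
#' @return Object of class `"aicc_ranking"`: data.frame with one row per
#'   model (`terms`, `n_terms`, `k`, `aicc`, `delta_aicc`, `r2_marginal`,
#'   `r2_conditional`, `converged`), best first; the best fit is in
#'   attribute `"best_fit"`.
#' @export
aicc_search <- function(data, candidates, max_power = 3, response = "w",
                        random = "tree_uid", tie_tol = 1e-6) {
  stopifnot(length(candidates) >= 1)
  miss <- setdiff(c(candidates, response, random), names(data))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  sets <- .power_sets(max_power)
  grid <- expand.grid(rep(list(seq_along(sets)), length(candidates)))
  term_lists <- apply(grid, 1L, function(row) {
    unlist(lapply(seq_along(candidates), function(j) {
      pws <- sets[[row[j]]]
      if (length(pws) == 0L) character(0)
      else ifelse(pws == 1L, candidates[j], paste0(candidates[j], "^", pws))
    }))
  }, simplify = FALSE)
  term_lists <- Filter(length, term_lists)

  fits <- lapply(term_lists, function(tm) {
    sp <- model_spec(tm, response = response, random = random, estimation = "ML")
    tryCatch(fit_lmm(data, sp), error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]; term_lists <- term_lists[keep]
  if (!length(fits)) stop("no candidate model could be fitted")

  tab <- data.frame(
    terms = vapply(term_lists, paste, "", collapse = " + "),
    n_terms = lengths(term_lists),
    k = vapply(fits, function(f) f$k, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    r2_marginal = vapply(fits, function(f) f$r2_marginal, numeric(1)),
    r2_conditional = vapply(fits, function(f) f$r2_conditional, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  # rank by AICc; within tie_tol of the local best, fewest covariates wins
  o <- order(round(tab$aicc / tie_tol) * tie_tol, tab$n_terms)
  tab <- tab[o, , drop = FALSE]
  fits <- fits[o]
  tab$delta_aicc <- tab$aicc - tab$aicc[1L]
  rownames(tab) <- NULL
  structure(tab, best_fit = fits[[1L]], fits_top10 = fits[seq_len(min(10, nrow(tab)))],
            class = c("aicc_ranking", "data.frame"))
}

#' @export
print.aicc_ranking <- function(x, n = 10, ...) {
  cat("AICc all-subsets search (", nrow(x), " models; top ", min(n, nrow(x)),
      " shown)\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative importance of covariates in a mixed model
#'
#' Decomposes the fixed-effect (marginal) explained variance by sequential
#' ANOVA on the fitted model, pooling polynomial terms under their parent
#' variable, and normalises to proportions. Terms enter in the order they
#' appear in the model specification (canonically CO2, then the climate
#' variable(s), then nitrogen); with `diagnostics = TRUE` the decomposition
#' is also computed under the reverse order and attached as an attribute,
#' since sequential shares are order-dependent for correlated covariates.
#'
#' @param fit A [fit_lmm()] result with at least one fixed term.
#' @param diagnostics Also compute the reverse-order decomposition.
#' @return Named numeric vector of proportions (one per parent variable,
#'   non-negative, summing to 1). With `diagnostics = TRUE`, attribute
#'   `"reverse_order"` holds the reverse-entry proportions.
#' @export
relative_importance <- function(fit, diagnostics = FALSE) {
  stopifnot(inherits(fit, "wue_lmm"))
  parsed <- fit$spec$parsed
  if (nrow(parsed) == 0L) stop("model has no fixed effects")
  shares <- .seq_anova_shares(fit$fit, parsed)
  out <- shares
  if (diagnostics) {
    rev_spec <- fit$spec
    ridx <- rev(seq_len(nrow(parsed)))
    rev_spec$parsed <- parsed[ridx, , drop = FALSE]
    rev_spec$terms <- fit$spec$terms[ridx]
    rfit <- fit_lmm(fit$data, rev_spec)
    attr(out, "reverse_order") <- .seq_anova_shares(rfit$fit, rev_spec$parsed)
  }
  out
}

.seq_anova_shares <- function(mer, parsed) {
  a <- stats::anova(mer) # sequential sums of squares over fixed terms
  rterm <- term_to_r(parsed$var, parsed$power)
  ss <- a[rterm, "Sum Sq"]
  if (any(is.na(ss)))
    stop("could not match ANOVA rows to model terms")
  pooled <- tapply(ss, parsed$var, sum)
  pooled <- pooled[unique(parsed$var)] # keep entry order
  prop <- pooled / sum(pooled)
  stats::setNames(as.numeric(prop), names(pooled))
}
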