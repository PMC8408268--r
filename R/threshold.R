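#' Exclude extreme aridity-index observations
#'
#' Removes rows with AI strictly greater than the cutoff (default 5); the
#' retained boundary value AI = cutoff stays in. The number of removals is
#' recorded in the `"n_removed"` attribute and logged.
#'
#' @param data data.frame with an `ai` column.
#' @param cutoff Exclusion threshold. Default 5.
#' @param quiet Suppress the log message.
#' @return Filtered data.frame with attribute `n_removed`.
#' @export
exclude_extreme_ai <- function(data, cutoff = 5, quiet = FALSE) {
  stopifnot("ai" %in% names(data), cutoff > 0)
  drop <- !is.na(data$ai) & data$ai > cutoff
  out <- data[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  if (!quiet) message("excluded ", sum(drop), " observation(s) with AI > ", cutoff)
  out
}

# SSE of the continuous two-segment model y ~ 1 + x + (x - psi)_+ ;
# returns the fit so callers can reuse coefficients.
.hinge_fit <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  f <- stats::.lm.fit(X, y)
  list(sse = sum(f$residuals^2), coef = f$coefficients)
}

#' Segmented (broken-line) regression with one breakpoint
#'
#' Fits the continuous two-segment least-squares model
#' y = b0 + b1 x + b2 (x - psi)_+ by profiling the breakpoint psi on a coarse
#' grid over the central 80 percent of the x range (step `grid_step`),
#' followed by golden-section refinement of the SSE profile. Slopes below and
#' above the breakpoint are b1 and b1 + b2 with t-test p-values from the
#' conditional linear fit; the breakpoint confidence interval is a seeded
#' case-resampling bootstrap percentile interval.
#'
#' If the data carry no detectable slope change (a single line fits
#' essentially as well as any two-segment model), the fit is flagged
#' non-identifiable instead of reporting an arbitrary breakpoint.
#'
#' @param x Predictor (aridity index).
#' @param y Response (W, umol mol-1).
#' @param grid_step Coarse grid step in x units. Default 0.01.
#' @param n_boot Bootstrap replicates for the breakpoint CI (0 to skip).
#'   Default 500.
#' @param conf_level CI level. Default 0.95.
#' @param seed Seed for the bootstrap. Default 1.
#' @return Object of class `"segmented_fit"`: list with `breakpoint`,
#'   `slope_below`, `slope_above`, `intercept`, `breakpoint_ci`, `p_below`,
#'   `p_above`, `sse`, `sse_line`, `n`, `identifiable`, `coef`.
#' @examples
#' x <- seq(0.1, 3, length.out = 200)
#' f <- fit_segmented(x, 80 - 20 * pmin(x, 1), n_boot = 0)
#' f$breakpoint # 1
#' @export
fit_segmented <- function(x, y, grid_step = 0.01, n_boot = 500,
                          conf_level = 0.95, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20) stop("segmented fit needs at least 20 observations")
  rng <- range(x)
  if (diff(rng) <= 0) stop("x is constant")

  search_bp <- function(x, y, step) {
    r <- range(x)
    lo <- r[1] + 0.1 * diff(r)
    hi <- r[2] - 0.1 * diff(r)
    psis <- seq(lo, hi, by = step)
    if (length(psis) < 3L) psis <- seq(lo, hi, length.out = 5L)
    sses <- vapply(psis, function(p) .hinge_fit(x, y, p)$sse, numeric(1))
    i <- which.min(sses)
    a <- psis[max(1L, i - 1L)]; b <- psis[min(length(psis), i + 1L)]
    # golden-section refinement of the (piecewise-smooth) SSE profile
    gr <- (sqrt(5) - 1) / 2
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    fc <- .hinge_fit(x, y, c1)$sse; fd <- .hinge_fit(x, y, d1)$sse
    while (abs(b - a) > 1e-7 * max(1, diff(r))) {
      if (fc < fd) {
        b <- d1; d1 <- c1; fd <- fc
        c1 <- b - gr * (b - a); fc <- .hinge_fit(x, y, c1)$sse
      } else {
        a <- c1; c1 <- d1; fc <- fd
        d1 <- a + gr * (b - a); fd <- .hinge_fit(x, y, d1)$sse
      }
    }
    (a + b) / 2
  }

  psi <- search_bp(x, y, grid_step)
  best <- .hinge_fit(x, y, psi)

  lin <- stats::lm.fit(cbind(1, x), y)
  sse_line <- sum(lin$residuals^2)
  tss <- sum((y - mean(y))^2)
  identifiable <- !(sse_line <= 1e-10 * max(tss, 1) ||
                      (sse_line - best$sse) / max(sse_line, .Machine$double.eps) < 1e-6)

  fit <- stats::lm(y ~ x + hinge, data = data.frame(x = x, y = y,
                                                    hinge = pmax(x - psi, 0)))
  # a noiseless broken line is a perfect fit; its SE warnings are expected
  sm <- suppressWarnings(summary(fit)$coefficients)
  V <- suppressWarnings(stats::vcov(fit))
  slope_below <- unname(stats::coef(fit)["x"])
  slope_above <- unname(stats::coef(fit)["x"] + stats::coef(fit)["hinge"])
  se_below <- sm["x", "Std. Error"]
  se_above <- sqrt(V["x", "x"] + V["hinge", "hinge"] + 2 * V["x", "hinge"])
  df <- fit$df.residual
  p_below <- 2 * stats::pt(abs(slope_below / se_below), df, lower.tail = FALSE)
  p_above <- 2 * stats::pt(abs(slope_above / se_above), df, lower.tail = FALSE)

  bp_ci <- c(NA_real_, NA_real_)
  if (identifiable && n_boot > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      search_bp(x[idx], y[idx], grid_step * 5)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    bp_ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }

  structure(list(
    breakpoint = if (identifiable) psi else NA_real_,
    slope_below = slope_below, slope_above = slope_above,
    intercept = unname(stats::coef(fit)[1L]),
    breakpoint_ci = bp_ci, p_below = p_below, p_above = p_above,
    sse = best$sse, sse_line = sse_line, n = n,
    identifiable = identifiable,
    coef = stats::coef(fit)
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented regression (one breakpoint)\n")
  if (!x$identifiable) {
    cat("  non-identifiable: no detectable slope change (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf("  breakpoint: %.4f  [%.4f, %.4f]\n",
              x$breakpoint, x$breakpoint_ci[1], x$breakpoint_ci[2]))
  cat(sprintf("  slope below: %.4f (p = %.3g)\n", x$slope_below, x$p_below))
  cat(sprintf("  slope above: %.4f (p = %.3g)\n", x$slope_above, x$p_above))
  cat(sprintf("  SSE: %.4g (single line: %.4g), n = %d\n",
              x$sse, x$sse_line, x$n))
  invisible(x)
}

#' Predict from a segmented fit
#'
#' @param object A `"segmented_fit"`.
#' @param newdata Numeric vector of x values.
#' @param ... Unused.
#' @return Fitted values; continuous at the breakpoint by construction.
#' @export
predict.segmented_fit <- function(object, newdata, ...) {
  b <- object$coef
  psi <- if (object$identifiable) object$breakpoint else Inf
  b[1] + b[2] * newdata + b[3] * pmax(newdata - psi, 0)
}

#' Summary statistics of W by aridity class
#'
#' One row per AI bin with count, median, mean, min, max and quartiles of W.
#' Bins are lower-inclusive (`[e_i, e_{i+1})`) with the final upper edge
#' included, so the default edges give bins 0-0.5, 0.5-1, 1-1.5, 1.5-2, 2-5
#' with AI = 5 retained. Quartiles use linear interpolation (type 7).
#'
#' @param data data.frame with `ai` and a W column.
#' @param bin_edges Increasing numeric vector of bin edges.
#'   Default `c(0, 0.5, 1, 1.5, 2, 5)`.
#' @param w_col Name of the W column. Default `"w"`.
#' @return data.frame with columns `ai_bin`, `n`, `median`, `mean`, `min`,
#'   `max`, `q1`, `q3`; empty bins have `n = 0` and NA statistics.
#' @export
bin_summary <- function(data, bin_edges = c(0, 0.5, 1, 1.5, 2, 5),
                        w_col = "w") {
  stopifnot("ai" %in% names(data), w_col %in% names(data),
            length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  ai <- data$ai; w <- data[[w_col]]
  keep <- !is.na(ai) & !is.na(w) & ai >= bin_edges[1] &
    ai <= bin_edges[length(bin_edges)]
  ai <- ai[keep]; w <- w[keep]
  idx <- findInterval(ai, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  rows <- lapply(seq_len(nb), function(i) {
    wi <- w[idx == i]
    if (length(wi) == 0L)
      return(data.frame(ai_bin = paste0(bin_edges[i], "-", bin_edges[i + 1]),
                        n = 0L, median = NA_real_, mean = NA_real_,
                        min = NA_real_, max = NA_real_, q1 = NA_real_,
                        q3 = NA_real_))
    q <- stats::quantile(wi, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(ai_bin = paste0(bin_edges[i], "-", bin_edges[i + 1]),
               n = length(wi), median = q[2], mean = mean(wi),
               min = min(wi), max = max(wi), q1 = q[1], q3 = q[3])
  })
  do.call(rbind, rows)
}

#' Aggregate the analysis table to tree- or site-level means
#'
#' @param data data.frame with `site_id`, `tree_id`, `ai` and a W column.
#' @param level `"observation"` (identity), `"tree"` or `"site"`.
#' @param w_col Name of the W column. Default `"w"`.
#' @return data.frame with grouping keys, mean `ai` and mean W (same column
#'   name), plus `n_obs` per group for the aggregated levels.
#' @export
grouped_views <- function(data, level = c("observation", "tree", "site"),
                          w_col = "w") {
  level <- match.arg(level)
  stopifnot(w_col %in% names(data), "ai" %in% names(data))
  if (level == "observation") return(data)
  keys <- switch(level, tree = c("site_id", "tree_id"), site = "site_id")
  miss <- setdiff(keys, names(data))
  if (length(miss)) stop("missing grouping column(s): ",
                         paste(miss, collapse = ", "))
  g <- interaction(data[keys], drop = TRUE, sep = "\r")
  out <- data[match(levels(g), as.character(g)), keys, drop = FALSE]
  out$ai <- as.numeric(tapply(data$ai, g, mean))
  out[[w_col]] <- as.numeric(tapply(data[[w_col]], g, mean))
  out$n_obs <- as.integer(tapply(data$ai, g, length))
  rownames(out) <- NULL
  out
}
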