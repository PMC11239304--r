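#' Cumulative population rank boundaries of the advantage groups
#'
#' For groups ordered by increasing advantage with population proportions
#' `w_1..w_G`, the boundary `R_g` is the highest percentile rank of the
#' advantage score within group `g`: the cumulative sum of the weights, with
#' `R_0 = 0` and `R_G = 1`.
#'
#' @param weights Positive group proportions summing to 1.
#' @return Numeric vector `(R_0, R_1, ..., R_G)` of length `G + 1`.
#' @export
rank_boundaries <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) >= 1L)
  if (any(weights <= 0)) stop("group weights must be positive")
  if (abs(sum(weights) - 1) > 1e-8) stop("group weights must sum to 1")
  R <- c(0, cumsum(weights))
  R[length(R)] <- 1  # kill accumulated rounding
  R
}

#' Rule out conditions without positive total expected gains
#'
#' A condition is excluded from the equity analysis when its population-level
#' expected health gain, the weighted sum of group gains, is at or below the
#' tolerance. Concentration shares are undefined (denominator ~ 0) for such
#' conditions, and an intervention that delivers no overall gain is not a
#' candidate however its non-gains are distributed. Gains in individual groups
#' may still be negative as long as the total is positive.
#'
#' @param gains Numeric vector of group gains (one condition), or a `T x G`
#'   matrix (rows = conditions).
#' @param weights Group population proportions; default equal.
#' @param tolerance Exclusion threshold: excluded iff total gain `<=`
#'   tolerance. Default 0. For noisy model estimates a small positive value
#'   (e.g. a multiple of the total gain's posterior SD) reproduces exclusion
#'   of conditions whose gains are only approximately zero.
#' @return Logical vector (`TRUE` = excluded), one element per condition, with
#'   the weighted totals as attribute `"total"`.
#' @export
apply_exclusion <- function(gains, weights = NULL, tolerance = 0) {
  if (is.null(dim(gains))) gains <- matrix(gains, nrow = 1L)
  G <- ncol(gains)
  if (is.null(weights)) weights <- rep(1 / G, G)
  rank_boundaries(weights)  # validates weights
  total <- drop(gains %*% weights)
  structure(total <= tolerance, total = total,
            names = rownames(gains))
}

#' Concentration curve of expected health gains
#'
#' The height of the curve at rank boundary `R_g` is the cumulative share of
#' the condition's expected gains accruing to the `g` least-advantaged groups:
#' `h(R_g) = sum(gains[1:g]) / sum(gains)`, with `h(0) = 0` and `h(1) = 1`.
#' Gains distributed independently of advantage put the curve on the 45
#' degree line; curves above the line concentrate gains among the less
#' advantaged. With negative group gains the curve need not be monotone and
#' can leave the unit band.
#'
#' @param gains Numeric vector of group gains, ordered by increasing
#'   advantage.
#' @param weights Group population proportions; default equal.
#' @return An object of class `"concentration_curve"`: a list with `R`
#'   (boundaries, length `G + 1`) and `h` (heights at those boundaries).
#' @export
concentration_curve <- function(gains, weights = NULL) {
  stopifnot(is.numeric(gains), length(gains) >= 1L)
  G <- length(gains)
  if (is.null(weights)) weights <- rep(1 / G, G)
  if (length(weights) != G) stop("'weights' must match the number of groups")
  R <- rank_boundaries(weights)
  tot <- sum(gains)
  if (tot == 0) {
    stop("total gain is zero; the concentration curve is undefined ",
         "(apply_exclusion() should rule this condition out first)")
  }
  h <- c(0, cumsum(gains) / tot)
  h[length(h)] <- 1
  structure(list(R = R, h = h), class = "concentration_curve")
}

#' Health-gain concentration index
#'
#' Twice the signed area between the 45 degree line and the concentration
#' curve, accumulated by the trapezoid rule over the group rank intervals:
#' positive when gains concentrate among the advantaged, negative when they
#' concentrate among the disadvantaged, and zero when gains are independent of
#' advantage. Unlike the classical health concentration index, it is not
#' bounded in \[-1, 1\] when some group gains are negative.
#'
#' @param curve A [concentration_curve()].
#' @return The index `H` (a single number).
#' @export
concentration_index <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  R <- curve$R
  h <- curve$h
  d <- R - h
  sum(diff(R) * (d[-length(d)] + d[-1L]))
}

#' Equitability of an intervention
#'
#' The sign reversal of the concentration index, `Q = -H`, so that higher
#' values indicate equity-enhancing interventions (gains concentrated among
#' the less advantaged).
#'
#' @param H Concentration index (vectorized).
#' @return `Q = -H`.
#' @export
equitability <- function(H) -H

#' Equity summary for every condition
#'
#' Applies the exclusion rule and computes the concentration index `H` and
#' equitability `Q` of every condition from its per-group expected gains.
#'
#' @param gains `T x G` matrix of per-group expected gains (rows named by
#'   condition, columns ordered by increasing advantage), e.g.
#'   `fit_group_outcomes(...)$estimate` or [true_group_gains()].
#' @param weights Group population proportions; default equal.
#' @param tolerance Exclusion threshold, or the string `"2sd"` together with
#'   `sd` to exclude conditions whose total gain is within two posterior
#'   standard deviations of zero.
#' @param sd Optional `T x G` matrix of posterior SDs matching `gains`, used
#'   only by the `"2sd"` tolerance rule (group fits are independent, so the
#'   total-gain SD is the weighted root sum of squares).
#' @return A data frame with one row per condition: `condition`, `total`
#'   (weighted total gain), `excluded`, `H`, `Q` (NA for excluded
#'   conditions). Concentration curves are attached as attribute `"curves"`.
#' @examples
#' gains <- true_group_gains(enumerate_conditions(case_study_design()),
#'                           case_study_effects())
#' equity_table(gains)
#' @export
equity_table <- function(gains, weights = NULL, tolerance = 0, sd = NULL) {
  stopifnot(is.matrix(gains))
  G <- ncol(gains)
  if (is.null(weights)) weights <- rep(1 / G, G)
  if (identical(tolerance, "2sd")) {
    if (is.null(sd)) stop("tolerance = '2sd' needs the 'sd' matrix")
    tol_vec <- 2 * sqrt(drop(sd^2 %*% weights^2))
  } else {
    stopifnot(is.numeric(tolerance), length(tolerance) == 1L)
    tol_vec <- rep(tolerance, nrow(gains))
  }
  total <- drop(gains %*% weights)
  excluded <- total <= tol_vec
  H <- rep(NA_real_, nrow(gains))
  curves <- vector("list", nrow(gains))
  names(curves) <- rownames(gains)
  for (i in which(!excluded)) {
    curves[[i]] <- concentration_curve(gains[i, ], weights)
    H[i] <- concentration_index(curves[[i]])
  }
  out <- data.frame(
    condition = rownames(gains),
    total = total,
    excluded = excluded,
    H = H,
    Q = equitability(H),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Plot concentration curves against the 45 degree line
#'
#' @param curves Named list of [concentration_curve()] objects (e.g. the
#'   `"curves"` attribute of [equity_table()]); NULL entries are skipped.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_concentration_curves <- function(curves, ...) {
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) == 0L) stop("no curves to plot")
  R <- curves[[1L]]$R
  hmat <- vapply(curves, `[[`, numeric(length(R)), "h")
  graphics::matplot(R, hmat, type = "b", pch = 1, lty = 1,
                    xlab = "cumulative population share (by advantage rank)",
                    ylab = "cumulative share of expected gains", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = names(curves), col = seq_along(curves),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(hmat)
}
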