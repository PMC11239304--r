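#' Net health value of an intervention
#'
#' Converts the two decision dimensions of expected outcome gain and delivery
#' cost into a single net health value at willingness-to-pay `lambda`:
#' `NHV = lambda * gain - cost`. `lambda` is the money a payer will spend per
#' unit outcome improvement, so NHV is expressed in money units and is
#' positive when the monetized gain exceeds the delivery cost.
#'
#' @param gain Expected outcome gain(s).
#' @param cost Delivery cost(s).
#' @param lambda Willingness-to-pay (money per unit outcome), `> 0`.
#' @return `lambda * gain - cost`, vectorized over the inputs.
#' @export
net_health_value <- function(gain, cost, lambda) {
  stopifnot(is.numeric(gain), is.numeric(cost), is.numeric(lambda))
  if (any(lambda <= 0)) stop("willingness-to-pay must be positive")
  lambda * gain - cost
}

# components set to On in a label; used only for deterministic tie-breaks
n_on <- function(label, design = NULL) {
  if (!is.null(design)) {
    vapply(label, function(l) length(parse_label(l, design)), integer(1L))
  } else {
    ifelse(label == "Min", 0L, nchar(label))
  }
}


#' Value efficiency frontier over cost and expected outcome
#'
#' Identifies the value-efficient subset of conditions: those on the
#' lower-right convex hull of the (cost, expected gain) scatter, anchored at
#' the least costly condition. Strictly dominated conditions (at least as
#' costly with no larger gain) are dropped first, then extended-dominated ones
#' (whose removal keeps the incremental cost-effectiveness ratios strictly
#' increasing). All other conditions cost more to achieve less-preferred
#' expected outcomes.
#'
#' @param points Data frame with columns `condition`, `cost`, `gain`.
#' @param include_collinear Keep points lying exactly on a hull segment?
#'   Default `FALSE` (strict hull).
#' @param design Optional [factorial_design()], used only to break exact
#'   (cost, gain) ties deterministically (fewer On components, then label).
#' @return An object of class `"value_frontier"`: the member rows ordered by
#'   increasing cost, with an `icer` column giving the incremental
#'   cost-effectiveness ratio (delta cost / delta gain) from the previous
#'   member (NA for the first).
#' @examples
#' design <- case_study_design()
#' conds <- enumerate_conditions(design)
#' pts <- data.frame(condition = conds,
#'                   cost = intervention_cost(conds, design),
#'                   gain = true_mean_gain(conds, case_study_effects()))
#' value_efficiency_frontier(pts)
#' @export
value_efficiency_frontier <- function(points, include_collinear = FALSE,
                                      design = NULL) {
  stopifnot(is.data.frame(points),
            all(c("condition", "cost", "gain") %in% names(points)))
  if (nrow(points) < 1L) stop("need at least one point")
  p <- points[c("condition", "cost", "gain")]

  # deterministic order: cost asc, gain desc, then fewer On components, label
  p <- p[order(p$cost, -p$gain, n_on(p$condition, design), p$condition), ,
         drop = FALSE]
  # at equal cost only the preferred (highest-gain) point can be efficient
  p <- p[!duplicated(p$cost), , drop = FALSE]

  # drop strictly dominated points: gain must increase with cost
  keep <- logical(nrow(p))
  best <- -Inf
  for (i in seq_len(nrow(p))) {
    if (p$gain[i] > best) {
      keep[i] <- TRUE
      best <- p$gain[i]
    }
  }
  keep[1L] <- TRUE  # the least costly condition anchors the frontier
  p <- p[keep, , drop = FALSE]

  # convex-hull scan: slopes (delta gain / delta cost) must strictly decrease
  slope <- function(i, j) (p$gain[j] - p$gain[i]) / (p$cost[j] - p$cost[i])
  stack <- 1L
  for (i in seq_len(nrow(p))[-1L]) {
    while (length(stack) >= 2L) {
      a <- stack[length(stack) - 1L]
      b <- stack[length(stack)]
      turn <- slope(a, b) - slope(b, i)
      drop_b <- if (include_collinear) turn < -1e-12 else turn <= 1e-12
      if (drop_b) stack <- stack[-length(stack)] else break
    }
    stack <- c(stack, i)
  }
  out <- p[stack, , drop = FALSE]
  out$icer <- c(NA_real_, diff(out$cost) / diff(out$gain))
  rownames(out) <- NULL
  structure(out, class = c("value_frontier", "data.frame"),
            points = points)
}

#' Incremental cost-effectiveness ratios along a value efficiency frontier
#'
#' @param frontier A `"value_frontier"` from [value_efficiency_frontier()].
#' @return Numeric vector of ICERs (delta cost / delta gain) between
#'   consecutive frontier members; length `members - 1`, strictly increasing.
#' @export
icers <- function(frontier) {
  stopifnot(inherits(frontier, "value_frontier"))
  if (nrow(frontier) < 2L) {
    stop("ICERs need at least two frontier members")
  }
  frontier$icer[-1L]
}

#' Representative willingness-to-pay thresholds
#'
#' Decision-making differs only across the willingness-to-pay ranges delimited
#' by the frontier ICERs, so a small representative set of thresholds
#' suffices. An explicit user-supplied set passes through verbatim. The
#' default `"bracketing"` strategy picks one value inside every decision
#' range: `lower_mult` times the smallest ICER, the midpoints of consecutive
#' ICERs, and `upper_mult` times the largest ICER.
#'
#' @param icers Strictly increasing positive ICERs (ignored when `values` is
#'   given).
#' @param values Optional explicit thresholds; returned sorted.
#' @param strategy Only `"bracketing"` is defined.
#' @param lower_mult,upper_mult Multipliers for the values below the smallest
#'   and above the largest ICER; defaults 0.5 and 1.5.
#' @return Sorted positive numeric vector of thresholds.
#' @examples
#' representative_wtp(c(133.33, 250, 400, 500))
#' representative_wtp(values = c(170, 330, 580, 830))
#' @export
representative_wtp <- function(icers = NULL, values = NULL,
                               strategy = "bracketing",
                               lower_mult = 0.5, upper_mult = 1.5) {
  if (!is.null(values)) {
    stopifnot(is.numeric(values), length(values) >= 1L)
    if (any(values <= 0)) stop("willingness-to-pay values must be positive")
    return(sort(values))
  }
  strategy <- match.arg(strategy)
  if (is.null(icers) || length(icers) == 0L) {
    stop("need either ICERs or an explicit willingness-to-pay list")
  }
  stopifnot(is.numeric(icers))
  if (any(icers <= 0)) stop("ICERs must be positive")
  e <- sort(icers)
  mids <- if (length(e) >= 2L) (e[-length(e)] + e[-1L]) / 2 else numeric(0L)
  sort(c(lower_mult * e[1L], mids, upper_mult * e[length(e)]))
}

#' Net health equity frontier at a given willingness-to-pay
#'
#' Identifies the decision contenders once equitability joins the criteria:
#' the upper-right convex hull of the (equitability `Q`, net health value
#' `NHV`) scatter, running from the maximum-NHV condition to the maximum-Q
#' condition. Conditions off the hull are dominated: some other condition (or
#' mixture along a hull segment) achieves at least as much net health value
#' without concentrating gains more among the advantaged. Conditions excluded
#' by the equity analysis must be removed before calling.
#'
#' @param points Data frame with columns `condition`, `Q`, `NHV`.
#' @param include_collinear Keep points lying exactly on a hull segment?
#' @param design Optional [factorial_design()] for deterministic tie-breaks.
#' @return An object of class `"equity_frontier"`: member rows ordered from
#'   highest NHV to highest Q, with a `quadrant` column (see [quadrant()]).
#' @export
net_health_equity_frontier <- function(points, include_collinear = FALSE,
                                       design = NULL) {
  stopifnot(is.data.frame(points),
            all(c("condition", "Q", "NHV") %in% names(points)))
  if (nrow(points) < 1L) stop("need at least one point")
  p <- points[c("condition", "Q", "NHV")]

  # scan by increasing Q; prefer higher NHV at equal Q, then fewer
  # components, then label
  p <- p[order(p$Q, -p$NHV, n_on(p$condition, design), p$condition), ,
         drop = FALSE]
  p <- p[!duplicated(p$Q), , drop = FALSE]

  # Pareto filter towards (high Q, high NHV): scan from the right (largest Q)
  # keeping points whose NHV strictly exceeds everything with larger Q
  keep <- logical(nrow(p))
  best <- -Inf
  for (i in rev(seq_len(nrow(p)))) {
    if (p$NHV[i] > best) {
      keep[i] <- TRUE
      best <- p$NHV[i]
    }
  }
  p <- p[keep, , drop = FALSE]

  # upper concave hull over increasing Q: slopes strictly decreasing
  slope <- function(i, j) (p$NHV[j] - p$NHV[i]) / (p$Q[j] - p$Q[i])
  stack <- 1L
  for (i in seq_len(nrow(p))[-1L]) {
    while (length(stack) >= 2L) {
      a <- stack[length(stack) - 1L]
      b <- stack[length(stack)]
      turn <- slope(a, b) - slope(b, i)
      drop_b <- if (include_collinear) turn < -1e-12 else turn <= 1e-12
      if (drop_b) stack <- stack[-length(stack)] else break
    }
    stack <- c(stack, i)
  }
  out <- p[stack, , drop = FALSE]
  out <- out[order(-out$NHV, out$Q), , drop = FALSE]  # highest NHV -> highest Q
  out$quadrant <- quadrant(out$Q, out$NHV)
  rownames(out) <- NULL
  structure(out, class = c("equity_frontier", "data.frame"), points = points)
}

#' Quadrant of the equitability / net-health-value plane
#'
#' Labels a condition by the signs of its equitability (x axis) and net
#' health value (y axis): `"upper-right"` (equity-enhancing and worth its
#' cost), `"upper-left"` (positive NHV, gains favor the advantaged),
#' `"lower-right"` (equity-enhancing but negative NHV), `"lower-left"`, or
#' `"on-axis"` when either coordinate is within `tol` of zero.
#'
#' @param Q Equitability value(s).
#' @param NHV Net health value(s).
#' @param tol Half-width of the on-axis band; default 0 (exact zero).
#' @return Character vector of labels.
#' @export
quadrant <- function(Q, NHV, tol = 0) {
  stopifnot(length(Q) == length(NHV))
  out <- character(length(Q))
  on_axis <- abs(Q) <= tol | abs(NHV) <= tol
  out[on_axis] <- "on-axis"
  vert <- ifelse(NHV > 0, "upper", "lower")
  horiz <- ifelse(Q > 0, "right", "left")
  out[!on_axis] <- paste(vert, horiz, sep = "-")[!on_axis]
  out
}

#' Plot the cost-outcome scatter with its value efficiency frontier
#'
#' @param frontier A `"value_frontier"`; the full scatter it was built from is
#'   drawn from its `"points"` attribute.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_value_frontier <- function(frontier, ...) {
  stopifnot(inherits(frontier, "value_frontier"))
  pts <- attr(frontier, "points")
  graphics::plot(pts$cost, pts$gain, xlab = "cost",
                 ylab = "expected outcome gain", ...)
  graphics::text(pts$cost, pts$gain, pts$condition, pos = 3, cex = 0.7)
  graphics::lines(frontier$cost, frontier$gain, col = "steelblue", lwd = 2)
  graphics::points(frontier$cost, frontier$gain, pch = 19, col = "steelblue")
  invisible(frontier)
}

#' Plot the equitability / net-health-value scatter with its frontier
#'
#' @param frontier An `"equity_frontier"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_equity_frontier <- function(frontier, ...) {
  stopifnot(inherits(frontier, "equity_frontier"))
  pts <- attr(frontier, "points")
  graphics::plot(pts$Q, pts$NHV, xlab = "equitability (Q)",
                 ylab = "net health value", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  graphics::text(pts$Q, pts$NHV, pts$condition, pos = 3, cex = 0.7)
  ord <- order(frontier$Q)
  graphics::lines(frontier$Q[ord], frontier$NHV[ord], col = "firebrick", lwd = 2)
  graphics::points(frontier$Q, frontier$NHV, pch = 19, col = "firebrick")
  invisible(frontier)
}
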