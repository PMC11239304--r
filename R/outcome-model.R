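#' Estimate posterior expected outcome gains per condition
#'
#' Fits a linear regression of the outcome gain on the factorial structure and
#' returns, for every condition of the design, the model-implied expected gain
#' (the posterior expected outcome under a flat prior) with its uncertainty.
#' Following usual practice for factorial optimization trials, factors enter
#' under effect coding (-1/+1); predictions are invariant to the coding choice
#' for a fixed term set.
#'
#' Two inference backends are available. `"closed"` (default) uses the
#' flat-prior conjugate posterior, whose mean equals the least-squares fit;
#' `"sampling"` draws from the normal-inverse-gamma posterior of the same
#' model and summarizes Monte-Carlo cell-mean draws, agreeing with the closed
#' form up to Monte-Carlo error.
#'
#' @param data An ORCT dataset as produced by [simulate_orct()] or
#'   [read_orct_csv()]: one 0/1 column per component plus `outcome` (and
#'   `group` if group scopes are used).
#' @param design The [factorial_design()]; taken from the dataset attribute
#'   when omitted.
#' @param terms Which effects to include: `"two-way"` (all main effects and
#'   two-way interactions; the default), `"main"`, or `"saturated"` (all
#'   interactions, so fitted values equal raw cell means).
#' @param scope `"full"` for the full sample, or an advantage-group number to
#'   fit that group's records only.
#' @param backend `"closed"` or `"sampling"`.
#' @param draws Number of posterior draws for the sampling backend.
#' @param seed Seed for the sampling backend.
#' @return An object of class `"posterior_summary"`: a data frame with columns
#'   `condition`, `estimate` (expected gain), and `sd` (posterior standard
#'   deviation of the cell mean), with the fitted model and metadata attached
#'   as attributes.
#' @examples
#' dat <- simulate_orct(case_study_design(), case_study_effects(), seed = 1)
#' fit_expected_outcomes(dat)
#' @export
fit_expected_outcomes <- function(data, design = NULL,
                                  terms = c("two-way", "main", "saturated"),
                                  scope = "full",
                                  backend = c("closed", "sampling"),
                                  draws = 4000, seed = NULL) {
  terms <- match.arg(terms)
  backend <- match.arg(backend)
  if (is.null(design)) design <- attr(data, "design")
  if (is.null(design)) stop("'design' is required when the dataset carries none")
  stopifnot(inherits(design, "factorial_design"))
  nms <- design$components$name
  missing_cols <- setdiff(c(nms, "outcome"), names(data))
  if (length(missing_cols) > 0L) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  }

  if (!identical(scope, "full")) {
    g <- as.integer(scope)
    if (!"group" %in% names(data)) stop("dataset has no 'group' column")
    data <- data[data$group == g, , drop = FALSE]
    if (nrow(data) == 0L) stop("no records in advantage group ", g)
  }

  order <- switch(terms, main = 1L, `two-way` = 2L, saturated = design$k)
  # effect coding: Off = -1, On = +1
  mdat <- data.frame(lapply(data[nms], function(x) 2 * as.numeric(x) - 1))
  names(mdat) <- nms
  mdat$outcome <- data$outcome
  rhs <- if (order == 1L) paste(nms, collapse = " + ") else
    sprintf("(%s)^%d", paste(nms, collapse = " + "), order)
  fml <- stats::as.formula(paste("outcome ~", rhs))
  fit <- stats::lm(fml, data = mdat)

  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0L) {
    stop("design is rank deficient; inestimable term(s): ",
         paste(aliased, collapse = ", "))
  }

  cm <- condition_matrix(design)
  grid <- as.data.frame(2 * cm - 1)
  names(grid) <- nms

  if (backend == "closed") {
    pr <- stats::predict(fit, newdata = grid, se.fit = TRUE)
    est <- as.numeric(pr$fit)
    sds <- as.numeric(pr$se.fit)
    draws_mat <- NULL
  } else {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
      }
      set.seed(as.integer(seed))
    }
    X <- stats::model.matrix(fit)
    df_res <- fit$df.residual
    if (df_res < 1L) stop("sampling backend needs positive residual degrees of freedom")
    s2 <- sum(stats::residuals(fit)^2) / df_res
    XtX_inv <- chol2inv(qr.R(fit$qr))
    sigma2 <- df_res * s2 / stats::rchisq(draws, df_res)
    beta_hat <- stats::coef(fit)
    Xg <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
    draws_mat <- matrix(NA_real_, nrow = draws, ncol = nrow(grid))
    L <- chol(XtX_inv)
    for (d in seq_len(draws)) {
      beta <- beta_hat + sqrt(sigma2[d]) * drop(crossprod(L, stats::rnorm(length(beta_hat))))
      draws_mat[d, ] <- drop(Xg %*% beta)
    }
    est <- colMeans(draws_mat)
    sds <- apply(draws_mat, 2L, stats::sd)
  }

  out <- data.frame(condition = rownames(cm), estimate = est, sd = sds,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("posterior_summary", "data.frame"),
            fit = fit, design = design, scope = scope, terms = terms,
            backend = backend, draws = draws_mat)
}

#' Predict the expected gain of a single condition from a fitted model
#'
#' @param object A `"posterior_summary"` from [fit_expected_outcomes()].
#' @param code Condition label.
#' @return Named numeric vector with elements `estimate` and `sd`.
#' @export
predict_cell_mean <- function(object, code) {
  stopifnot(inherits(object, "posterior_summary"))
  design <- attr(object, "design")
  lbl <- attr(parse_label(code, design), "label")
  row <- which(object$condition == lbl)
  if (length(row) != 1L) stop("condition '", code, "' not in the design")
  c(estimate = object$estimate[row], sd = object$sd[row])
}

#' Group-by-condition matrix of expected gains
#'
#' Fits a separate model within every advantage group (using only that group's
#' records) and assembles the per-group expected gains `Y_hat[t, g]` required
#' by the equity metrics.
#'
#' @inheritParams fit_expected_outcomes
#' @return A list with `estimate` and `sd`: numeric `T x G` matrices (rows are
#'   conditions, columns groups), plus `weights`, the observed group
#'   proportions.
#' @export
fit_group_outcomes <- function(data, design = NULL,
                               terms = c("two-way", "main", "saturated"),
                               backend = c("closed", "sampling"),
                               draws = 4000, seed = NULL) {
  terms <- match.arg(terms)
  backend <- match.arg(backend)
  if (is.null(design)) design <- attr(data, "design")
  if (!"group" %in% names(data)) stop("dataset has no 'group' column")
  groups <- sort(unique(data$group))
  conds <- enumerate_conditions(design)
  est <- sdm <- matrix(NA_real_, nrow = length(conds), ncol = length(groups),
                       dimnames = list(conds, paste0("g", groups)))
  for (j in seq_along(groups)) {
    s <- fit_expected_outcomes(data, design, terms = terms, scope = groups[j],
                               backend = backend, draws = draws,
                               seed = if (is.null(seed)) NULL else seed + j)
    est[, j] <- s$estimate
    sdm[, j] <- s$sd
  }
  w <- as.numeric(table(factor(data$group, levels = groups)))
  list(estimate = est, sd = sdm, weights = w / sum(w))
}
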