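#' Write / read an ORCT dataset as CSV
#'
#' The on-disk schema is one row per participant with columns `subject_id`,
#' `S`, `group` (1-based advantage group), one 0/1 column per component, and
#' `outcome`. Numeric columns are serialized with 17 significant digits so a
#' write/read round trip reproduces the dataset exactly; the condition label
#' column is reconstructed from the component indicators on read.
#'
#' @param dataset An ORCT data frame (see [simulate_orct()]).
#' @param path File path.
#' @param design A [factorial_design()] describing the component columns;
#'   taken from the dataset attribute when omitted.
#' @return `write_orct_csv()` returns `path` invisibly; `read_orct_csv()`
#'   returns the dataset with condition labels restored and the design
#'   attached.
#' @export
write_orct_csv <- function(dataset, path, design = NULL) {
  if (is.null(design)) design <- attr(dataset, "design")
  stopifnot(inherits(design, "factorial_design"))
  nms <- design$components$name
  cols <- c("subject_id", "S", "group", nms, "outcome")
  missing_cols <- setdiff(cols, names(dataset))
  if (length(missing_cols) > 0L) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- dataset[cols]
  out$S <- formatC(out$S, digits = 17, format = "g")
  out$outcome <- formatC(out$outcome, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_orct_csv
#' @export
read_orct_csv <- function(path, design) {
  stopifnot(inherits(design, "factorial_design"))
  nms <- design$components$name
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "S", "group", nms, "outcome")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0L) {
    stop("dataset file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (nm in nms) {
    v <- dat[[nm]]
    if (!all(v %in% c(0L, 1L))) {
      stop("component column '", nm, "' must contain only 0/1 levels")
    }
  }
  if (!all(dat$group == as.integer(dat$group)) || any(dat$group < 1)) {
    stop("'group' must hold 1-based integer group labels")
  }
  if (any(dat$S < 0 | dat$S > 1)) stop("'S' must lie in [0, 1]")
  if (!is.numeric(dat$outcome)) stop("'outcome' must be numeric")
  dat$condition <- apply(dat[nms], 1L, function(row) {
    condition_label(nms[row == 1L], design)
  })
  dat <- dat[c("subject_id", "S", "group", nms, "condition", "outcome")]
  attr(dat, "design") <- design
  class(dat) <- c("orct_data", class(dat))
  dat
}

# ---- configuration -------------------------------------------------------

effect_fn_from_config <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L) return(constant_effect(x))
  if (is.list(x) && !is.null(x$a)) {
    return(linear_effect(x$a, if (is.null(x$b)) 0 else x$b))
  }
  stop("cannot interpret effect specification for ", what,
       " (expected a number or {a, b})")
}

#' Read a run configuration from YAML or JSON
#'
#' The configuration file declares the design (components with costs), the
#' effect model (`a + b * S` coefficients per component and interaction pair),
#' either simulation settings (`G`, `per_cell_n`, `noise_sd`, `seed`) or a
#' `dataset` path (exactly one of the two), the model spec, equity settings,
#' and the valuation settings (an explicit `wtp` list or a strategy).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"daive_config"` whose elements are ready for
#'   [run_daive()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$design) || is.null(raw$design$components)) {
    stop("config must declare design$components")
  }
  comps <- raw$design$components
  if (is.data.frame(comps)) comps <- split(comps, seq_len(nrow(comps)))
  design <- factorial_design(lapply(comps, function(cc) {
    component_spec(cc$name, cc$cost_on,
                   if (is.null(cc$cost_off)) 0 else cc$cost_off)
  }))
  effects <- NULL
  if (!is.null(raw$effects)) {
    main <- lapply(raw$effects$main, effect_fn_from_config, what = "main effect")
    inter <- lapply(raw$effects$interactions, effect_fn_from_config,
                    what = "interaction")
    baseline <- if (is.null(raw$effects$baseline)) 0 else raw$effects$baseline
    effects <- effect_model(main = main, interactions = inter,
                            baseline = baseline)
  }
  has_sim <- !is.null(raw$simulation)
  has_data <- !is.null(raw$dataset)
  if (has_sim == has_data) {
    stop("config must declare exactly one of 'simulation' or 'dataset'")
  }
  if (has_sim && is.null(effects)) {
    stop("simulation requires an 'effects' block")
  }
  sim <- raw$simulation
  cfg <- list(
    design = design,
    effects = effects,
    dataset = raw$dataset,
    G = if (has_sim && !is.null(sim$G)) sim$G else 5,
    per_cell_n = if (has_sim && !is.null(sim$per_cell_n)) sim$per_cell_n else 10,
    noise_sd = if (has_sim && !is.null(sim$noise_sd)) sim$noise_sd else 1,
    seed = if (has_sim) sim$seed else NULL,
    terms = if (is.null(raw$model$terms)) "two-way" else raw$model$terms,
    backend = if (is.null(raw$model$backend)) "closed" else raw$model$backend,
    draws = if (is.null(raw$model$draws)) 4000 else raw$model$draws,
    exclusion_tolerance =
      if (is.null(raw$equity$tolerance)) "2sd" else raw$equity$tolerance,
    wtp = raw$valuation$wtp,
    output_dir = raw$output_dir
  )
  class(cfg) <- "daive_config"
  cfg
}

# ---- the end-to-end run --------------------------------------------------

#' Run the full decision analysis
#'
#' Orchestrates the whole workflow: simulate (or load) the factorial ORCT
#' dataset, fit the outcome model for the full sample and within every
#' advantage group, compute the equity metrics with the exclusion rule, build
#' the cost-outcome value efficiency frontier with its ICERs, and construct
#' the net health equity frontier at every willingness-to-pay threshold.
#'
#' @param design A [factorial_design()].
#' @param effects An [effect_model()]; required when simulating.
#' @param dataset An ORCT data frame (or path to its CSV); when supplied, no
#'   simulation is performed.
#' @param G,per_cell_n,noise_sd,seed Simulation settings (see
#'   [simulate_orct()]).
#' @param terms,backend,draws Model settings (see [fit_expected_outcomes()]).
#' @param wtp Explicit willingness-to-pay thresholds; when `NULL`, a
#'   representative set is derived from the frontier ICERs by the bracketing
#'   strategy (see [representative_wtp()]).
#' @param exclusion_tolerance Passed to [equity_table()]; the default `"2sd"`
#'   excludes conditions whose total expected gain is not credibly positive
#'   (within two posterior SDs of zero).
#' @param quadrant_tol Tolerance for the on-axis quadrant band.
#' @param out_dir Optional directory; when given, the dataset, equity table,
#'   frontier tables, and the JSON report are written there.
#' @return A list of class `"decision_report"`: `conditions` (per-condition
#'   table with cost, full-sample and per-group expected gains, exclusion
#'   flag, `H`, `Q`), `value_frontier`, `icers`, `wtp`, `equity_frontiers`
#'   (one `"equity_frontier"` per threshold), `dataset`, and `meta`.
#' @examples
#' report <- run_daive(case_study_design(), case_study_effects(), seed = 1,
#'                     wtp = c(170, 330, 580, 830))
#' report$value_frontier
#' report$equity_frontiers[["170"]]
#' @export
run_daive <- function(design, effects = NULL, dataset = NULL,
                      G = 5, per_cell_n = 10, noise_sd = 1, seed = NULL,
                      terms = "two-way", backend = "closed", draws = 4000,
                      wtp = NULL, exclusion_tolerance = "2sd",
                      quadrant_tol = 0, out_dir = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (is.null(dataset)) {
      if (is.null(effects)) stop("simulation requires an effect model")
      simulate_orct(design, effects, G = G, per_cell_n = per_cell_n,
                    noise_sd = noise_sd, seed = seed)
    } else if (is.character(dataset)) {
      read_orct_csv(dataset, design)
    } else {
      dataset
    }
  })

  full <- stage("fit", fit_expected_outcomes(
    dat, design, terms = terms, backend = backend, draws = draws, seed = seed))
  groups <- stage("fit", fit_group_outcomes(
    dat, design, terms = terms, backend = backend, draws = draws, seed = seed))

  eq <- stage("equity", equity_table(
    groups$estimate, weights = groups$weights,
    tolerance = exclusion_tolerance, sd = groups$sd))

  conds <- enumerate_conditions(design)
  cost <- intervention_cost(conds, design)
  pts <- data.frame(condition = conds, cost = cost, gain = full$estimate,
                    stringsAsFactors = FALSE)
  vf <- stage("frontier", value_efficiency_frontier(pts, design = design))
  ic <- if (nrow(vf) >= 2L) icers(vf) else numeric(0L)

  lambda <- stage("valuation", representative_wtp(icers = ic, values = wtp))
  included <- !eq$excluded
  eqf <- lapply(lambda, function(l) {
    nhv <- net_health_value(full$estimate, cost, l)
    p <- data.frame(condition = conds, Q = eq$Q, NHV = nhv,
                    stringsAsFactors = FALSE)[included, , drop = FALSE]
    f <- net_health_equity_frontier(p, design = design)
    f$quadrant <- quadrant(f$Q, f$NHV, tol = quadrant_tol)
    attr(f, "lambda") <- l
    f
  })
  names(eqf) <- format(lambda, trim = TRUE)

  conditions <- cbind(
    data.frame(condition = conds, cost = cost,
               gain = full$estimate, gain_sd = full$sd,
               stringsAsFactors = FALSE),
    as.data.frame(groups$estimate),
    eq[c("total", "excluded", "H", "Q")]
  )
  rownames(conditions) <- NULL

  report <- structure(list(
    conditions = conditions,
    value_frontier = vf,
    icers = ic,
    wtp = lambda,
    equity_frontiers = eqf,
    dataset = dat,
    meta = list(seed = seed, n = nrow(dat), terms = terms, backend = backend,
                exclusion_tolerance = exclusion_tolerance,
                package_version = as.character(utils::packageVersion("daivequity")))
  ), class = "decision_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the decision analysis from a configuration object
#'
#' @param config A `"daive_config"` from [read_run_config()].
#' @param out_dir Output directory; defaults to the config's `output_dir`.
#' @return A `"decision_report"`, see [run_daive()].
#' @export
run_daive_config <- function(config, out_dir = config$output_dir) {
  stopifnot(inherits(config, "daive_config"))
  run_daive(design = config$design, effects = config$effects,
            dataset = config$dataset, G = config$G,
            per_cell_n = config$per_cell_n, noise_sd = config$noise_sd,
            seed = config$seed, terms = config$terms, backend = config$backend,
            draws = config$draws, wtp = config$wtp,
            exclusion_tolerance = config$exclusion_tolerance,
            out_dir = out_dir)
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf("Decision report: %d conditions, N = %d\n",
              nrow(x$conditions), x$meta$n))
  cat("Value efficiency frontier:",
      paste(x$value_frontier$condition, collapse = " -> "), "\n")
  if (length(x$icers) > 0L) {
    cat("ICERs:", paste(format(x$icers, digits = 6), collapse = ", "), "\n")
  }
  for (nm in names(x$equity_frontiers)) {
    f <- x$equity_frontiers[[nm]]
    cat(sprintf("lambda = %s contenders: %s\n", nm,
                paste(sprintf("%s (%s)", f$condition, f$quadrant),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a decision report to disk
#'
#' Writes `dataset.csv`, `conditions.csv`, `value_frontier.csv`, and
#' `report.json` (all numbers with 12 significant digits, so reruns with the
#' same configuration and seed diff identically) into `dir`.
#'
#' @param report A `"decision_report"` from [run_daive()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "decision_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  design <- attr(report$dataset, "design")
  write_orct_csv(report$dataset, file.path(dir, "dataset.csv"), design)
  utils::write.csv(report$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$value_frontier),
                   file.path(dir, "value_frontier.csv"), row.names = FALSE)
  body <- list(
    meta = report$meta,
    conditions = report$conditions,
    value_frontier = as.data.frame(report$value_frontier),
    icers = report$icers,
    wtp = report$wtp,
    equity_frontiers = lapply(report$equity_frontiers, function(f) {
      list(lambda = attr(f, "lambda"), members = as.data.frame(f))
    })
  )
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
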