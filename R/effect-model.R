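#' Linear-in-advantage effect function
#'
#' Declarative building block for effect models: the expected outcome gain
#' contributed by a component is `a + b * S`, where `S` is the systemic
#' advantage score on \[0, 1\]. Use `b = 0` for a constant effect.
#'
#' @param a Intercept (gain at `S = 0`).
#' @param b Slope in the advantage score.
#' @return A function of `S` carrying its coefficients as attributes, so that
#'   configurations remain declarative and serializable.
#' @export
linear_effect <- function(a, b = 0) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  f <- function(S) a + b * S
  attr(f, "coef") <- c(a = a, b = b)
  class(f) <- c("effect_fn", class(f))
  f
}

#' Constant effect function
#'
#' @param a The constant expected gain.
#' @return An effect function, see [linear_effect()].
#' @export
constant_effect <- function(a) linear_effect(a, 0)

#' Specify true component effects as functions of advantage
#'
#' An effect model gives, for each component, the expected outcome gain as a
#' function of the advantage score `S` on \[0, 1\], plus optional pairwise
#' interaction functions that are added when both members of a pair are On.
#' The expected gain of a condition is the baseline plus the sum of the gain
#' functions of its On components plus all applicable interaction terms.
#'
#' @param main Named list of functions of `S`, one per component (names must
#'   match the design's component names when used together). Components omitted
#'   here contribute zero gain.
#' @param interactions Named list of functions of `S`; names are component
#'   pairs joined by `":"` (e.g. `"B:C"`).
#' @param baseline Expected gain of the all-Off condition (default 0; outcomes
#'   are gains relative to baseline).
#' @return An object of class `"effect_model"`.
#' @examples
#' eff <- effect_model(
#'   main = list(A = linear_effect(0.5, 0.5), B = linear_effect(0, 1),
#'               C = constant_effect(0), D = linear_effect(1, -1)),
#'   interactions = list("B:C" = linear_effect(1, -1))
#' )
#' true_gain("BC", 0.3, eff)  # 1 at every S: the interaction offsets B's slope
#' @export
effect_model <- function(main = list(), interactions = list(), baseline = 0) {
  stopifnot(is.list(main), is.list(interactions),
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  if (length(main) > 0L && (is.null(names(main)) || any(!nzchar(names(main))))) {
    stop("'main' must be a named list of functions")
  }
  for (nm in names(main)) {
    if (!is.function(main[[nm]])) stop("main effect '", nm, "' is not a function")
  }
  if (length(interactions) > 0L) {
    if (is.null(names(interactions)) || any(!nzchar(names(interactions)))) {
      stop("'interactions' must be a named list of functions")
    }
    for (nm in names(interactions)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      if (length(pair) != 2L || pair[1L] == pair[2L]) {
        stop("interaction name '", nm, "' must be two distinct components joined by ':'")
      }
      if (!is.function(interactions[[nm]])) {
        stop("interaction '", nm, "' is not a function")
      }
    }
  }
  structure(list(main = main, interactions = interactions, baseline = baseline),
            class = "effect_model")
}

#' True expected outcome gain of a condition at a given advantage score
#'
#' Evaluates the effect model: baseline plus the main-effect functions of all
#' On components plus every interaction function whose both members are On.
#'
#' @param code Condition label, e.g. `"AB"` or `"Min"`.
#' @param S Advantage score(s) in \[0, 1\] (vectorized).
#' @param effects An [effect_model()].
#' @param design Optional [factorial_design()] used to validate and
#'   canonicalize `code`; when omitted, `code` is split into single-character
#'   component labels.
#' @return Numeric vector of expected gains, one per element of `S`.
#' @export
true_gain <- function(code, S, effects, design = NULL) {
  stopifnot(inherits(effects, "effect_model"), is.numeric(S))
  if (any(S < 0 | S > 1, na.rm = TRUE) || anyNA(S)) {
    stop("advantage scores must lie in [0, 1]")
  }
  on <- if (is.null(design)) {
    if (identical(code, "Min")) character(0L)
    else strsplit(code, "")[[1L]]
  } else {
    as.character(parse_label(code, design))
  }
  g <- rep(effects$baseline, length(S))
  for (nm in intersect(names(effects$main), on)) {
    g <- g + effects$main[[nm]](S)
  }
  for (nm in names(effects$interactions)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (all(pair %in% on)) g <- g + effects$interactions[[nm]](S)
  }
  if (any(!is.finite(g))) stop("effect model returned non-finite gains")
  g
}

#' Population-average and stratum-average true gains
#'
#' With `S ~ Uniform(0, 1)`, `true_mean_gain()` integrates the condition's
#' gain function over \[0, 1\]; `true_group_gains()` integrates over each of
#' `G` equal-probability advantage strata `((g-1)/G, g/G)`. These are the
#' noise-free reference values that model estimates converge to, and can be
#' fed directly into the equity and frontier routines for analytic analyses.
#'
#' @param code Condition label(s).
#' @param effects An [effect_model()].
#' @param design Optional [factorial_design()] for label validation.
#' @return `true_mean_gain()`: numeric vector, one value per label.
#' @export
true_mean_gain <- function(code, effects, design = NULL) {
  vapply(code, function(lbl) {
    stats::integrate(function(s) true_gain(lbl, s, effects, design),
                     0, 1, rel.tol = 1e-10)$value
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @rdname true_mean_gain
#' @param G Number of equal-probability advantage groups.
#' @return `true_group_gains()`: numeric `length(code)` by `G` matrix of
#'   stratum-average gains (rows named by condition).
#' @export
true_group_gains <- function(code, effects, G = 5, design = NULL) {
  stopifnot(G >= 1)
  out <- matrix(NA_real_, nrow = length(code), ncol = G,
                dimnames = list(code, paste0("g", seq_len(G))))
  for (i in seq_along(code)) {
    for (g in seq_len(G)) {
      out[i, g] <- G * stats::integrate(
        function(s) true_gain(code[i], s, effects, design),
        (g - 1) / G, g / G, rel.tol = 1e-10)$value
    }
  }
  out
}

#' The HIV medication-adherence case study design and effects
#'
#' A worked `2^4` example: four candidate components for improving medication
#' adherence among people living with HIV — Motivational Interviewing (A),
#' Peer Support (B), a Navigator (C), and Skill-Building Sessions (D) — with
#' delivery costs 100, 125, 200, and 250 money units. Component effects depend
#' on the systemic advantage score `S`: A (`0.5 + 0.5 S`) and B (`S`) work
#' less well for the less advantaged; C has no effect alone (`0`) but offsets
#' B's gradient through a `B:C` interaction (`1 - S`), so the BC combination
#' gains exactly 1 at every `S`; D (`1 - S`) works better for the less
#' advantaged. No other interactions are present.
#'
#' @return `case_study_design()`: a [factorial_design()] with components
#'   A, B, C, D; `case_study_effects()`: the matching [effect_model()].
#' @export
case_study_design <- function() {
  factorial_design(
    component_spec("A", 100),
    component_spec("B", 125),
    component_spec("C", 200),
    component_spec("D", 250)
  )
}

#' @rdname case_study_design
#' @export
case_study_effects <- function() {
  effect_model(
    main = list(
      A = linear_effect(0.5, 0.5),
      B = linear_effect(0, 1),
      C = constant_effect(0),
      D = linear_effect(1, -1)
    ),
    interactions = list("B:C" = linear_effect(1, -1))
  )
}
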