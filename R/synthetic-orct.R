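#' Assign advantage groups by sample quantiles
#'
#' Stratifies observed advantage scores into `G` groups of equal (within one)
#' size, with group labels 1..G nondecreasing in the rank of `S`. Used when
#' loading external datasets; simulated data are stratified by population
#' quantile boundaries at generation time.
#'
#' @param S Numeric vector of advantage scores in \[0, 1\].
#' @param G Number of groups.
#' @return Integer vector of group labels in 1..G.
#' @export
assign_groups <- function(S, G) {
  stopifnot(is.numeric(S), length(S) >= 1L, G >= 1)
  if (any(S < 0 | S > 1, na.rm = TRUE) || anyNA(S)) {
    stop("advantage scores must lie in [0, 1]")
  }
  if (length(unique(S)) < G) {
    stop(sprintf("cannot form %d advantage strata from %d distinct score(s)",
                 G, length(unique(S))))
  }
  r <- rank(S, ties.method = "first")
  as.integer(ceiling(r * G / length(S)))
}

# deterministic per-cell substream: cell counts can change without
# perturbing draws in other cells
cell_seed <- function(seed, g, t_index) {
  as.integer((seed * 48271 + g * 1299721 + t_index * 7919) %% 2147483629L)
}

#' Simulate a factorial ORCT with advantage-dependent effects
#'
#' Generates individual-level data for a `2^k` factorial optimization trial.
#' The advantage score `S` is Uniform(0, 1) overall, drawn stratified: each of
#' the `G` equal-probability strata `((g-1)/G, g/G)` contributes exactly
#' `per_cell_n` individuals to every condition, so cells are balanced by
#' construction. Outcomes are gains relative to baseline,
#' `Y ~ Normal(true_gain(condition, S), noise_sd)`.
#'
#' @param design A [factorial_design()].
#' @param effects An [effect_model()] giving the true gain functions.
#' @param G Number of advantage groups (quantile strata). Default 5
#'   (quintiles).
#' @param per_cell_n Individuals per group per condition. Default 10.
#' @param noise_sd Outcome standard deviation. Default 1.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'   Each (group, condition) cell uses its own substream derived from it.
#' @return A data frame of class `"orct_data"` with columns `subject_id`, `S`,
#'   `group`, one 0/1 column per component, `condition` (label), and
#'   `outcome`; `G * per_cell_n * 2^k` rows. The design is attached as
#'   attribute `"design"`.
#' @examples
#' dat <- simulate_orct(case_study_design(), case_study_effects(), seed = 1)
#' nrow(dat)  # 5 groups x 10 per cell x 16 conditions = 800
#' @export
simulate_orct <- function(design, effects, G = 5, per_cell_n = 10,
                          noise_sd = 1, seed = NULL) {
  stopifnot(inherits(design, "factorial_design"),
            inherits(effects, "effect_model"))
  if (G < 2) stop("'G' must be at least 2")
  if (per_cell_n < 1) stop("'per_cell_n' must be at least 1")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  # restore the caller's RNG state on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  cm <- condition_matrix(design)
  conds <- rownames(cm)
  n_cond <- length(conds)
  rows <- vector("list", G * n_cond)
  idx <- 0L
  for (t in seq_len(n_cond)) {
    for (g in seq_len(G)) {
      idx <- idx + 1L
      rs <- cell_seed(seed, g, t)
      set.seed(rs)
      S <- stats::runif(per_cell_n, min = (g - 1) / G, max = g / G)
      mu <- true_gain(conds[t], S, effects, design)
      # noise on its own substream: enlarging a cell extends, rather than
      # reshuffles, its existing individuals
      set.seed((rs + 1000003L) %% 2147483629L)
      Y <- mu + if (noise_sd > 0) stats::rnorm(per_cell_n, 0, noise_sd) else 0
      rows[[idx]] <- data.frame(
        S = S, group = g, condition = conds[t],
        outcome = Y, stringsAsFactors = FALSE
      )
    }
  }
  dat <- do.call(rbind, rows)
  dat <- cbind(subject_id = seq_len(nrow(dat)), dat)
  ind <- cm[dat$condition, , drop = FALSE]
  rownames(ind) <- NULL
  dat <- cbind(dat[c("subject_id", "S", "group")], as.data.frame(ind),
               dat[c("condition", "outcome")])
  rownames(dat) <- NULL
  attr(dat, "design") <- design
  class(dat) <- c("orct_data", class(dat))
  dat
}
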