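#' False-positive probability of the PCR validation panel
#'
#' A non-Y presence/absence polymorphism masquerades as a Y marker only if
#' it amplifies in every screened male and in no screened female. Under
#' Hardy-Weinberg with presence-allele frequency `q` and a dominant
#' presence model (any copy amplifies), that probability is
#' `[1 - (1-q)^2]^n_males * [(1-q)^2]^n_females`. In the X-linked variant
#' males are hemizygous, so a male is positive with probability `q`.
#'
#' @param q Presence-allele frequency in `[0, 1]`.
#' @param n_males,n_females Total screened individuals of each sex; stage
#'   vectors (e.g. `c(1, 4, 20)` for focal + first + second panel) are
#'   summed.
#' @param x_linked Use the hemizygous-male variant (default autosomal).
#' @return Probability.
#' @examples
#' false_positive_prob(0.5, c(1, 4, 20), c(1, 4, 20))
#' @export
false_positive_prob <- function(q, n_males = c(1, 4, 20),
                                n_females = c(1, 4, 20),
                                x_linked = FALSE) {
  if (any(q < 0 | q > 1)) {
    stop("allele frequency q must lie in [0, 1]", call. = FALSE)
  }
  nm <- sum(n_males)
  nf <- sum(n_females)
  stopifnot(nm >= 0, nf >= 0)
  p_absent <- (1 - q)^2
  p_present <- if (x_linked) q else 1 - p_absent
  p_present^nm * p_absent^nf
}

#' Worst-case panel false-positive probability over allele frequency
#'
#' Maximises [false_positive_prob()] over `q` in `[0, 1]` by a grid scan
#' refined with local optimisation. For an equal panel of `n` males and
#' `n` females the autosomal maximum is exactly `0.25^n`.
#'
#' @inheritParams false_positive_prob
#' @param tol Convergence tolerance of the local refinement.
#' @return List with `q` (maximising frequency) and `p` (the maximum
#'   probability).
#' @examples
#' max_false_positive_prob(25, 25)  # <= 0.25^24
#' @export
max_false_positive_prob <- function(n_males, n_females, x_linked = FALSE,
                                    tol = 1e-12) {
  nm <- sum(n_males)
  nf <- sum(n_females)
  stopifnot(nm >= 1, nf >= 1)
  f <- function(q) false_positive_prob(q, nm, nf, x_linked)
  grid <- seq(0, 1, length.out = 2001L)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= vals[i]) {
    list(q = opt$maximum, p = opt$objective)
  } else {
    list(q = grid[i], p = vals[i])
  }
}

#' Probability that at least one of several screened markers false-positives
#'
#' The per-marker worst-case error compounds over the `m` contigs carried
#' through the panel: `1 - (1 - p)^m`.
#'
#' @param p Per-marker false-positive probability.
#' @param n_markers Number of markers screened.
#' @return Probability that any marker survives the panel spuriously.
#' @export
compound_false_positive <- function(p, n_markers) {
  stopifnot(p >= 0, p <= 1, n_markers >= 1)
  1 - (1 - p)^n_markers
}

#' Smallest equal panel achieving a target false-positive bound
#'
#' Returns the smallest `n` such that the worst-case autosomal
#' false-positive probability of an `n`-male / `n`-female panel,
#' `0.25^n`, does not exceed `target_prob`.
#'
#' @param target_prob Target probability in `(0, 1)`.
#' @return Integer panel size per sex.
#' @examples
#' min_panel_size(1e-6)
#' @export
min_panel_size <- function(target_prob) {
  stopifnot(target_prob > 0, target_prob < 1)
  n <- max(1L, as.integer(ceiling(log(target_prob) / log(0.25) - 1e-9)))
  while (0.25^n > target_prob) n <- n + 1L
  while (n > 1L && 0.25^(n - 1L) <= target_prob) n <- n - 1L
  n
}

#' Full validation-panel report
#'
#' @inheritParams max_false_positive_prob
#' @param n_markers Markers carried into the panel (for the compounded
#'   any-marker error).
#' @return List with the worst-case `q` and `p`, the compounded
#'   `p_any_marker`, and the panel composition.
#' @export
panel_report <- function(n_males = c(1, 4, 20), n_females = c(1, 4, 20),
                         n_markers = 92L, x_linked = FALSE) {
  mx <- max_false_positive_prob(n_males, n_females, x_linked)
  list(n_males = sum(n_males), n_females = sum(n_females),
       x_linked = x_linked, worst_case_q = mx$q, worst_case_p = mx$p,
       n_markers = n_markers,
       p_any_marker = compound_false_positive(mx$p, n_markers))
}
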