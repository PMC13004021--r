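# Robustness-load trade-off (RLTO) model: optimal overabundance as a
# function of transcription level under gamma (bursty) expression noise.

#' Growth-arrest probability under gamma expression noise
#'
#' Protein levels are gamma distributed with shape equal to the message
#' number `mu_m` (mRNA molecules per cell cycle) and free scale (burst
#' size), the canonical bursty-expression limit; the shape parameterization
#' delivers squared coefficient of variation `1/mu_m`.  With the mean
#' expression level set to `o` times the arrest threshold, the per-cycle
#' arrest probability is the probability that the level falls below the
#' threshold:
#' `P_a = P(Gamma(shape = mu_m, mean = mu_m) < mu_m / o)`.
#' The result is scale-free: it depends only on `(mu_m, o)`.
#'
#' @param mu_m Message number (> 0); vectorized.
#' @param o Overabundance (>= 1); vectorized.
#' @return Arrest probability in [0, 1); decreasing in both arguments.
#' @export
arrest_probability <- function(mu_m, o) {
  if (any(mu_m <= 0)) stop("mu_m must be positive", call. = FALSE)
  if (any(o < 1)) stop("o must be >= 1", call. = FALSE)
  stats::pgamma(mu_m / o, shape = mu_m, rate = 1)
}

#' Expected relative fitness of an expression program
#'
#' The fitness of expressing an essential protein at overabundance `o` is
#' the product of the metabolic-load term and the per-cycle survival
#' (non-arrest) term:
#' `F(o) = (1 - epsilon o) (1 - P_a(mu_m, o))`,
#' where `epsilon` is the relative metabolic cost per unit of
#' threshold-level expression.  `F <= 1`; `epsilon o >= 1` yields a
#' non-positive fitness (a valid value, not an error).
#'
#' @param mu_m Message number (> 0).
#' @param o Overabundance (>= 1); vectorized.
#' @param epsilon Relative metabolic cost per unit of threshold-level
#'   expression (default 1e-4, a low-expression essential gene's share of
#'   the proteome).
#' @return Relative fitness (<= 1).
#' @export
expected_fitness <- function(mu_m, o, epsilon = 1e-4) {
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  (1 - epsilon * o) * (1 - arrest_probability(mu_m, o))
}

# Maximize F over o for one mu_m: coarse grid in log10 o followed by
# golden-section refinement.  Unimodality is checked on the grid, not
# assumed: multiple local maxima trigger a warning and the global one is
# returned.
optimize_o <- function(mu_m, epsilon, n_grid = 400) {
  o_hi <- if (epsilon > 0) 1 / epsilon else 1e8
  lg <- seq(0, log10(o_hi), length.out = n_grid)
  fv <- expected_fitness(mu_m, 10^lg, epsilon)
  i <- which.max(fv)
  interior <- which(diff(sign(diff(fv))) < 0) + 1
  if (length(interior) > 1)
    warning("multiple local fitness maxima for mu_m = ", mu_m,
            "; returning the global one", call. = FALSE)
  lo <- lg[max(1, i - 1)]
  hi <- lg[min(n_grid, i + 1)]
  opt <- stats::optimize(function(l) expected_fitness(mu_m, 10^l, epsilon),
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand_o <- c(10^opt$maximum, 10^lg[i], 1)
  cand_f <- expected_fitness(mu_m, cand_o, epsilon)
  j <- which.max(cand_f)
  list(o_star = cand_o[j], f_max = cand_f[j])
}

#' Optimal overabundance across a transcription grid
#'
#' For each message number, maximizes [expected_fitness()] over the
#' overabundance, giving the RLTO-optimal overabundance curve
#' `o_star(mu_m)`.  The curve decreases with transcription: low-expression
#' genes are predicted to be kept in vast excess, high-expression genes
#' close to sufficiency.
#'
#' The admissibility threshold `mu_m_min` is the smallest grid message
#' number at which optimal expression remains robust: the optimum must
#' beat not expressing at all (fitness 0 for an essential gene, since
#' cells below threshold do not proliferate) while cell-to-cell variation
#' stays at or below the mean level (gamma noise CV `1/sqrt(mu_m) <= 1`).
#' In the gamma noise model the variation clause binds at one message per
#' cell cycle, independent of the load parameter — the one-message rule.
#'
#' @param mu_m_grid Message numbers (> 0), increasing.
#' @param epsilon Relative metabolic cost per unit of threshold-level
#'   expression.
#' @return An `rlto_prediction`: list with `curve` (data frame `mu_m`,
#'   `o_star`, `f_max`), `mu_m_min`, and `epsilon`.
#' @export
optimal_overabundance <- function(mu_m_grid, epsilon = 1e-4) {
  if (any(diff(mu_m_grid) < 0))
    stop("mu_m_grid must be increasing", call. = FALSE)
  fits <- lapply(mu_m_grid, optimize_o, epsilon = epsilon)
  curve <- data.frame(mu_m = mu_m_grid,
                      o_star = vapply(fits, `[[`, numeric(1), "o_star"),
                      f_max = vapply(fits, `[[`, numeric(1), "f_max"))
  admissible <- curve$f_max > 0 & curve$mu_m >= 1
  mu_m_min <- if (any(admissible)) min(curve$mu_m[admissible]) else NA_real_
  structure(list(curve = curve, mu_m_min = mu_m_min, epsilon = epsilon),
            class = "rlto_prediction")
}

#' @export
print.rlto_prediction <- function(x, ...) {
  cat("rlto_prediction:", nrow(x$curve), "transcription levels in [",
      min(x$curve$mu_m), ",", max(x$curve$mu_m), "] messages/cycle;",
      "epsilon =", x$epsilon, "; mu_m_min =", x$mu_m_min, "\n")
  cat("  o_star range:", signif(min(x$curve$o_star), 4), "-",
      signif(max(x$curve$o_star), 4), "fold\n")
  invisible(x)
}
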