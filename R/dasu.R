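# Linear-quadratic competition model for secondary cancer induction.
#
# The per-bin risk contribution is
#   (alpha1*D + beta1*D^2/n) * exp(-(alpha2*D + beta2*D^2/n))
# where D is the total bin dose delivered in n fractions. The first factor
# is LQ-shaped mutation induction; the exponential is LQ cell survival, so
# the two processes compete: risk rises with dose, peaks, and decays once
# sterilization dominates. beta1 = alpha1/(alpha/beta), beta2 =
# alpha2/(alpha/beta), both from the same organ alpha/beta ratio.

#' Per-bin secondary cancer risk contribution
#'
#' Evaluates the competition-model risk density for a total bin dose `dose`
#' delivered in `n_fractions` fractions. Vectorized over `dose`.
#'
#' @param dose Total bin dose in Gy(RBE), >= 0. May be a vector.
#' @param n_fractions Number of fractions over which the dose is delivered.
#' @param coeffs A [risk_coefficients()] object.
#' @param kind `"total"` (any induced cancer) or `"fatal"` (induced cancer
#'   leading to death); selects which alpha1 coefficient is used.
#'
#' @return Dimensionless risk contribution(s), >= 0.
#' @examples
#' dasu_bin_term(2, 1, default_coefficients("lung_right"), "total")
#' @export
dasu_bin_term <- function(dose, n_fractions, coeffs, kind = c("total", "fatal")) {
  kind <- match.arg(kind)
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and >= 0", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  a1 <- if (kind == "total") coeffs$alpha1_total else coeffs$alpha1_fatal
  b1 <- beta_of(a1, coeffs$alpha_beta_ratio)
  a2 <- coeffs$alpha2
  b2 <- beta_of(a2, coeffs$alpha_beta_ratio)
  d2n <- dose^2 / n_fractions
  (a1 * dose + b1 * d2n) * exp(-(a2 * dose + b2 * d2n))
}

#' Organ-level secondary cancer induction risk
#'
#' Volume-weighted average of [dasu_bin_term()] over the bins of a
#' differential DVH: with normalized volume fractions this is
#' `sum(v_i * term(D_i))`. Returned as a probability fraction in \[0, 1\];
#' multiply by 100 for the percent convention used in reports.
#'
#' @param x A [dvh()].
#' @param n_fractions Number of fractions of the plan; applied to every bin
#'   (each volume element receives its bin dose spread over all fractions).
#' @param coeffs A [risk_coefficients()] object.
#' @param kind `"total"` or `"fatal"`.
#'
#' @return Numeric scalar risk in \[0, 1\].
#' @examples
#' d <- dvh(c(5, 15, 30), c(0.5, 0.3, 0.2), "lung_left")
#' dasu_organ_risk(d, 18, default_coefficients("lung_left"), "total")
#' @export
dasu_organ_risk <- function(x, n_fractions, coeffs, kind = c("total", "fatal")) {
  kind <- match.arg(kind)
  if (!inherits(x, "dvh")) stop("x must be a dvh object", call. = FALSE)
  if (nrow(x) == 0L) stop("empty DVH", call. = FALSE)
  terms <- dasu_bin_term(x$dose, n_fractions, coeffs, kind)
  sum(x$volume_fraction * terms) / sum(x$volume_fraction)
}
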