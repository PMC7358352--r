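# Organ equivalent dose (OED): two dose distributions are equivalent if
# they cause the same radiation-induced cancer incidence. The OED is the
# volume-weighted average of a risk-equivalent dose RED(D_i) under one of
# three dose-response scenarios:
#   linear              RED = D                (no sterilization)
#   linear-exponential  RED = D * exp(-a'D)    (no repopulation/repair)
#   plateau             RED = (1 - exp(-a'D))/a'  (complete repopulation/repair)
# with a' = alpha + beta*D/n from the LQ model (alpha is the organ's
# sterilization slope alpha2, beta = alpha/(alpha/beta), n fractions).

.red_variants <- c("linear", "linear_exponential", "plateau")

#' Dose-response model variants for the OED
#' @return Character vector of the three supported variants.
#' @export
red_variants <- function() .red_variants

#' Fractionation-corrected sterilization slope
#'
#' Applies the LQ model to the per-fraction dose of a bin:
#' `alpha' = alpha + beta * D / n` with `beta = alpha / (alpha/beta)`.
#' Strictly increasing in `D`. Vectorized over `dose`.
#'
#' @param alpha Linear sterilization slope in 1/Gy (> 0).
#' @param alpha_beta_ratio Ratio in Gy.
#' @param dose Total bin dose in Gy(RBE), >= 0.
#' @param n_fractions Number of fractions.
#' @return alpha' in 1/Gy.
#' @examples
#' alpha_prime(0.129, 3, 36, 18)   # 0.129 + 0.043 * 2
#' @export
alpha_prime <- function(alpha, alpha_beta_ratio, dose, n_fractions) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and >= 0", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  alpha + beta_of(alpha, alpha_beta_ratio) * dose / n_fractions
}

#' Risk-equivalent dose under one dose-response scenario
#'
#' @param dose Bin dose in Gy(RBE), >= 0. Vectorized.
#' @param variant One of [red_variants()].
#' @param a_prime Sterilization slope alpha' in 1/Gy (recycled against
#'   `dose`); must be > 0 for the nonlinear variants.
#' @return RED in Gy(RBE); always within `[0, dose]`.
#' @examples
#' red(10, "linear")
#' red(10, "plateau", a_prime = 0.215)
#' @export
red <- function(dose, variant = c("linear", "linear_exponential", "plateau"),
                a_prime = NULL) {
  variant <- match.arg(variant)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and >= 0", call. = FALSE)
  if (variant == "linear") return(dose)
  if (is.null(a_prime) || any(a_prime <= 0))
    stop("a_prime must be > 0 for the '", variant, "' variant",
         call. = FALSE)
  switch(variant,
    linear_exponential = dose * exp(-a_prime * dose),
    plateau = (1 - exp(-a_prime * dose)) / a_prime
  )
}

#' Organ equivalent dose of a differential DVH
#'
#' Volume-weighted average of the risk-equivalent dose over the DVH bins,
#' `OED = sum(v_i * RED(D_i)) / sum(v_i)`, with the sterilization slope
#' alpha' re-evaluated per bin via [alpha_prime()] from the organ's
#' `alpha2` coefficient.
#'
#' @param x A [dvh()].
#' @param variant One of [red_variants()].
#' @param coeffs A [risk_coefficients()] object; `alpha2` and
#'   `alpha_beta_ratio` are used.
#' @param n_fractions Number of fractions of the plan.
#' @return OED in Gy(RBE); never exceeds the maximum bin dose.
#' @examples
#' d <- dvh(c(5, 15, 30), c(0.5, 0.3, 0.2), "breast_left")
#' oed(d, "plateau", default_coefficients("breast_left"), 18)
#' @export
oed <- function(x, variant = c("linear", "linear_exponential", "plateau"),
                coeffs, n_fractions) {
  variant <- match.arg(variant)
  if (!inherits(x, "dvh")) stop("x must be a dvh object", call. = FALSE)
  if (nrow(x) == 0L) stop("empty DVH", call. = FALSE)
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (variant == "linear") {
    reds <- x$dose
  } else {
    ap <- alpha_prime(coeffs$alpha2, coeffs$alpha_beta_ratio, x$dose,
                      n_fractions)
    reds <- red(x$dose, variant, ap)
  }
  sum(x$volume_fraction * reds) / sum(x$volume_fraction)
}

#' Proton/photon relative risk as an OED ratio
#'
#' `rr = OED_proton / OED_photon` for the same organ and dose-response
#' variant. A value below 1 indicates a lower secondary-malignancy risk
#' with the proton plan. When the photon OED is zero the ratio is
#' undefined and an error of class `secmal_undefined_rr` is raised; cohort
#' summaries exclude such records and log them.
#'
#' @param oed_proton,oed_photon OEDs in Gy(RBE) for the same organ and
#'   variant.
#' @return Dimensionless ratio >= 0.
#' @export
relative_risk <- function(oed_proton, oed_photon) {
  if (any(!is.finite(c(oed_proton, oed_photon))) ||
      oed_proton < 0 || oed_photon < 0)
    stop("OEDs must be finite and >= 0", call. = FALSE)
  if (oed_photon == 0)
    stop(structure(
      class = c("secmal_undefined_rr", "error", "condition"),
      list(message = "relative risk undefined: photon OED is zero",
           call = sys.call(-1))))
  oed_proton / oed_photon
}
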