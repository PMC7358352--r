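#' Organ vocabulary
#'
#' The five thoracic organs at risk supported by the risk models. Risk
#' coefficients exist only for these; any other organ label is an error
#' throughout the package.
#'
#' @return Character vector of valid organ labels.
#' @export
organ_labels <- function() {
  c("lung_right", "lung_left", "breast_right", "breast_left", "esophagus")
}

# ICRP-derived cancer-induction coefficients per paired-organ site.
# alpha1 (Gy^-1) is the low-dose induction slope (fatal vs total cancer);
# alpha2 (Gy^-1) is the cell-sterilization slope entering the exponential
# kill term and the OED dose-response.
.coeff_table <- list(
  lung      = c(alpha1_fatal = 0.0101, alpha1_total = 0.0144, alpha2 = 0.129),
  breast    = c(alpha1_fatal = 0.0028, alpha1_total = 0.0144, alpha2 = 0.008),
  esophagus = c(alpha1_fatal = 0.0014, alpha1_total = 0.0015, alpha2 = 0.274)
)

.organ_site <- function(organ) {
  switch(organ,
    lung_right = , lung_left = "lung",
    breast_right = , breast_left = "breast",
    esophagus = "esophagus",
    stop("unknown organ label: '", organ, "' (expected one of ",
         paste(organ_labels(), collapse = ", "), ")", call. = FALSE)
  )
}

#' Construct a set of risk coefficients for one organ
#'
#' @param organ Organ label (see [organ_labels()]).
#' @param alpha1_fatal,alpha1_total Low-dose induction slopes in 1/Gy for
#'   fatal and total cancer risk. `alpha1_fatal` must not exceed
#'   `alpha1_total`.
#' @param alpha2 Cell-sterilization slope in 1/Gy.
#' @param alpha_beta_ratio Fractionation-sensitivity ratio in Gy; the same
#'   ratio converts both alpha1 and alpha2 to their quadratic counterparts.
#'
#' @return An object of class `risk_coefficients`.
#' @export
risk_coefficients <- function(organ, alpha1_fatal, alpha1_total, alpha2,
                              alpha_beta_ratio = 3) {
  .organ_site(organ)  # validates the label
  vals <- c(alpha1_fatal = alpha1_fatal, alpha1_total = alpha1_total,
            alpha2 = alpha2, alpha_beta_ratio = alpha_beta_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all risk coefficients must be finite and > 0", call. = FALSE)
  if (alpha1_fatal > alpha1_total)
    stop("alpha1_fatal must not exceed alpha1_total", call. = FALSE)
  structure(
    list(organ = organ, alpha1_fatal = alpha1_fatal,
         alpha1_total = alpha1_total, alpha2 = alpha2,
         alpha_beta_ratio = alpha_beta_ratio),
    class = "risk_coefficients"
  )
}

#' Default risk coefficients for an organ
#'
#' Returns the published ICRP-derived induction coefficients and the
#' linear-quadratic sterilization parameter for the requested organ. Both
#' lungs share the lung row and both breasts the breast row. The
#' fractionation ratio alpha/beta defaults to 3 Gy for all five organs.
#'
#' @param organ Organ label (see [organ_labels()]).
#' @param alpha_beta_ratio Fractionation-sensitivity ratio in Gy (default 3).
#'
#' @return A `risk_coefficients` object.
#' @examples
#' default_coefficients("lung_right")
#' default_coefficients("esophagus")
#' @export
default_coefficients <- function(organ, alpha_beta_ratio = 3) {
  site <- .organ_site(organ)
  v <- .coeff_table[[site]]
  risk_coefficients(organ,
                    alpha1_fatal = v[["alpha1_fatal"]],
                    alpha1_total = v[["alpha1_total"]],
                    alpha2 = v[["alpha2"]],
                    alpha_beta_ratio = alpha_beta_ratio)
}

#' Default coefficient set for all supported organs
#'
#' @param alpha_beta_ratio Fractionation-sensitivity ratio in Gy (default 3).
#' @return Named list of `risk_coefficients`, one per organ label.
#' @export
default_coefficient_set <- function(alpha_beta_ratio = 3) {
  out <- lapply(organ_labels(), default_coefficients,
                alpha_beta_ratio = alpha_beta_ratio)
  names(out) <- organ_labels()
  out
}

#' Read a coefficient override file
#'
#' Reads a YAML file mapping organ labels to coefficient overrides and merges
#' it over the defaults, enabling sensitivity analyses without code changes.
#' Keys absent from the file keep their default values.
#'
#' @param path Path to a YAML file of the form
#'   `organ: {alpha1_fatal: ..., alpha1_total: ..., alpha2: ..., alpha_beta_ratio: ...}`.
#' @return Named list of `risk_coefficients` for all five organs.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("coefficient file must be a YAML mapping", call. = FALSE)
  out <- default_coefficient_set()
  for (organ in names(cfg)) {
    .organ_site(organ)
    ov <- cfg[[organ]]
    bad <- setdiff(names(ov), c("alpha1_fatal", "alpha1_total", "alpha2",
                                "alpha_beta_ratio"))
    if (length(bad))
      stop("unknown coefficient field(s) for ", organ, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    cur <- out[[organ]]
    for (f in names(ov)) cur[[f]] <- ov[[f]]
    out[[organ]] <- risk_coefficients(organ, cur$alpha1_fatal,
                                      cur$alpha1_total, cur$alpha2,
                                      cur$alpha_beta_ratio)
  }
  out
}

#' Quadratic coefficient from a linear coefficient and alpha/beta ratio
#'
#' Applies the linear-quadratic relation `beta = alpha / (alpha/beta)`,
#' used for both the induction slope (alpha1 -> beta1) and the sterilization
#' slope (alpha2 -> beta2).
#'
#' @param alpha Linear coefficient in 1/Gy.
#' @param alpha_beta_ratio Ratio in Gy; must be > 0.
#' @return Quadratic coefficient in 1/Gy^2.
#' @examples
#' beta_of(0.129, 3)   # 0.043
#' @export
beta_of <- function(alpha, alpha_beta_ratio) {
  if (!is.numeric(alpha) || !is.numeric(alpha_beta_ratio) ||
      any(alpha <= 0) || any(alpha_beta_ratio <= 0))
    stop("alpha and alpha_beta_ratio must be positive", call. = FALSE)
  alpha / alpha_beta_ratio
}

#' @export
print.risk_coefficients <- function(x, ...) {
  cat(sprintf("Risk coefficients for %s (alpha/beta = %g Gy):\n", x$organ,
              x$alpha_beta_ratio))
  cat(sprintf("  alpha1 fatal: %g /Gy   alpha1 total: %g /Gy   alpha2: %g /Gy\n",
              x$alpha1_fatal, x$alpha1_total, x$alpha2))
  invisible(x)
}
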