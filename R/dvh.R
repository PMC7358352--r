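#' Construct a differential dose-volume histogram
#'
#' A differential DVH stores, for one organ, the fraction of the organ
#' volume whose total physical dose falls in each dose bin. Bin doses are
#' the bin-center doses in Gy(RBE); volume fractions are dimensionless and
#' are normalized to sum to one. Working with fractions (not absolute cc)
#' makes every downstream quantity a volume-weighted average, invariant to
#' absolute organ volume.
#'
#' @param dose Numeric vector of strictly increasing, non-negative bin-center
#'   doses in Gy(RBE).
#' @param volume_fraction Numeric vector of non-negative volume fractions,
#'   same length as `dose`; normalized to sum to 1 when `normalize = TRUE`.
#' @param organ Organ label (see [organ_labels()]).
#' @param normalize If `TRUE` (default), rescale fractions to sum to one;
#'   if `FALSE`, the fractions must already sum to 1 within `1e-6`.
#'
#' @return Object of class `dvh`: a data frame with columns `dose` and
#'   `volume_fraction` and an `organ` attribute.
#' @examples
#' dvh(c(0, 5, 15), c(0.2, 0.5, 0.3), "lung_right")
#' @export
dvh <- function(dose, volume_fraction, organ, normalize = TRUE) {
  .organ_site(organ)
  if (length(dose) < 1L) stop("a DVH needs at least one bin", call. = FALSE)
  if (length(dose) != length(volume_fraction))
    stop("dose and volume_fraction lengths differ", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("bin doses must be finite and >= 0 (organ ", organ, ")", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE))
    stop("bin doses must be strictly increasing (organ ", organ, ")",
         call. = FALSE)
  if (any(!is.finite(volume_fraction)) || any(volume_fraction < 0))
    stop("volume fractions must be finite and >= 0 (organ ", organ, ")",
         call. = FALSE)
  s <- sum(volume_fraction)
  if (s <= 0)
    stop("volume fractions sum to zero (organ ", organ, ")", call. = FALSE)
  if (normalize) {
    volume_fraction <- volume_fraction / s
  } else if (abs(s - 1) > 1e-6) {
    stop("volume fractions must sum to 1 within 1e-6 (organ ", organ,
         ", got ", format(s), ")", call. = FALSE)
  }
  structure(
    data.frame(dose = as.numeric(dose),
               volume_fraction = as.numeric(volume_fraction)),
    organ = organ,
    class = c("dvh", "data.frame")
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("Differential DVH: %s, %d bins, dose 0-%.3g Gy(RBE)\n",
              attr(x, "organ"), nrow(x), max(x$dose)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more bins\n")
  invisible(x)
}

#' Organ label of a DVH
#' @param x A `dvh` object.
#' @return Character scalar.
#' @export
dvh_organ <- function(x) attr(x, "organ")

#' Convert a cumulative DVH to differential form
#'
#' A cumulative DVH gives the organ volume receiving at least each tabulated
#' dose. The differential form is obtained from successive differences,
#' normalized by the total volume (the first cumulative value). Each
#' difference is placed at the midpoint of its dose interval -- the usual
#' treatment-planning-system convention, with bounded bias for fine grids.
#' Any volume remaining at the last tabulated dose is assigned to a terminal
#' bin at that dose. Bins that receive zero volume are dropped.
#'
#' @param doses Strictly increasing dose grid in Gy(RBE).
#' @param cum_volumes Volumes (any consistent unit, e.g. cc) receiving at
#'   least each dose; non-increasing, last value >= 0.
#' @param organ Organ label for the resulting DVH.
#'
#' @return A [dvh()] whose volume fractions sum to exactly 1.
#' @examples
#' cumulative_to_differential(c(0, 10, 20, 30), c(100, 60, 10, 0), "lung_left")
#' @export
cumulative_to_differential <- function(doses, cum_volumes, organ) {
  if (length(doses) != length(cum_volumes) || length(doses) < 1L)
    stop("doses and cum_volumes must be equal-length, non-empty",
         call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0) ||
      is.unsorted(doses, strictly = TRUE))
    stop("doses must be non-negative and strictly increasing (organ ",
         organ, ")", call. = FALSE)
  if (any(!is.finite(cum_volumes)) || any(cum_volumes < 0))
    stop("cumulative volumes must be finite and >= 0 (organ ", organ, ")",
         call. = FALSE)
  if (cum_volumes[1L] <= 0)
    stop("degenerate organ: total volume is zero (organ ", organ, ")",
         call. = FALSE)
  if (is.unsorted(rev(cum_volumes)))
    stop("cumulative volumes must be non-increasing with dose (organ ",
         organ, ")", call. = FALSE)

  total <- cum_volumes[1L]
  k <- length(doses)
  if (k == 1L) {
    # single tabulated point: all volume sits at that dose
    return(dvh(doses, 1, organ, normalize = FALSE))
  }
  mid <- (doses[-k] + doses[-1L]) / 2
  frac <- (cum_volumes[-k] - cum_volumes[-1L]) / total
  bins_d <- c(mid, doses[k])
  bins_f <- c(frac, cum_volumes[k] / total)
  keep <- bins_f > 0
  dvh(bins_d[keep], bins_f[keep], organ, normalize = FALSE)
}

#' Convert a differential DVH back to cumulative form
#'
#' Inverse of [cumulative_to_differential()] up to bin-dose placement:
#' tabulates, at each bin dose, the volume fraction receiving at least that
#' dose. Converting the result back to differential form reproduces the
#' original volume fractions exactly (doses of interior bins move to
#' interval midpoints).
#'
#' @param x A [dvh()].
#' @return Data frame with columns `dose` and `cum_volume` (fractions,
#'   starting at 1).
#' @export
differential_to_cumulative <- function(x) {
  stopifnot(inherits(x, "dvh"))
  cum <- rev(cumsum(rev(x$volume_fraction)))
  data.frame(dose = x$dose, cum_volume = cum)
}
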