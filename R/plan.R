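#' Construct a single-modality treatment plan dose record
#'
#' Bundles one modality's organ DVHs with the fractionation metadata that
#' the linear-quadratic terms need: the number of fractions `n` over which
#' every bin dose is delivered, and the prescription dose.
#'
#' @param modality `"proton"` or `"photon"`.
#' @param n_fractions Positive integer number of fractions.
#' @param prescription_dose Prescription dose in Gy(RBE), > 0.
#' @param dvhs Named list of [dvh()] objects; each name must equal the
#'   stored organ label of its DVH.
#'
#' @return Object of class `plan_dose`.
#' @export
plan_dose <- function(modality, n_fractions, prescription_dose, dvhs) {
  modality <- match.arg(modality, c("proton", "photon"))
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L ||
      n_fractions < 1 || n_fractions != round(n_fractions))
    stop("n_fractions must be a positive integer", call. = FALSE)
  if (!is.numeric(prescription_dose) || length(prescription_dose) != 1L ||
      prescription_dose <= 0)
    stop("prescription_dose must be > 0", call. = FALSE)
  if (!is.list(dvhs) || length(dvhs) < 1L || is.null(names(dvhs)))
    stop("dvhs must be a non-empty named list of dvh objects", call. = FALSE)
  for (organ in names(dvhs)) {
    d <- dvhs[[organ]]
    if (!inherits(d, "dvh"))
      stop("dvhs[['", organ, "']] is not a dvh object", call. = FALSE)
    if (!identical(dvh_organ(d), organ))
      stop("DVH stored under key '", organ, "' is labelled '",
           dvh_organ(d), "'", call. = FALSE)
  }
  structure(list(modality = modality,
                 n_fractions = as.integer(n_fractions),
                 prescription_dose = prescription_dose,
                 dvhs = dvhs),
            class = "plan_dose")
}

#' Construct a matched proton/photon patient record
#'
#' @param patient_id Character scalar identifier.
#' @param sex `"female"` or `"male"`. Breast organs may be present only for
#'   female patients.
#' @param proton,photon [plan_dose()] records of the respective modality,
#'   covering the same organ set.
#'
#' @return Object of class `patient_pair`.
#' @export
patient_pair <- function(patient_id, sex, proton, photon) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      !nzchar(patient_id))
    stop("patient_id must be a non-empty string", call. = FALSE)
  if (!inherits(proton, "plan_dose") || proton$modality != "proton")
    stop("proton must be a plan_dose with modality 'proton' (patient ",
         patient_id, ")", call. = FALSE)
  if (!inherits(photon, "plan_dose") || photon$modality != "photon")
    stop("photon must be a plan_dose with modality 'photon' (patient ",
         patient_id, ")", call. = FALSE)
  if (!setequal(names(proton$dvhs), names(photon$dvhs)))
    stop("proton and photon plans cover different organ sets (patient ",
         patient_id, ")", call. = FALSE)
  if (sex == "male" &&
      any(c("breast_right", "breast_left") %in% names(proton$dvhs)))
    stop("breast DVHs present for male patient ", patient_id, call. = FALSE)
  structure(list(patient_id = patient_id, sex = sex,
                 proton = proton, photon = photon),
            class = "patient_pair")
}

#' @export
print.patient_pair <- function(x, ...) {
  cat(sprintf("Patient %s (%s): %d organs, proton %d fx / %.3g Gy(RBE), photon %d fx / %.3g Gy(RBE)\n",
              x$patient_id, x$sex, length(x$proton$dvhs),
              x$proton$n_fractions, x$proton$prescription_dose,
              x$photon$n_fractions, x$photon$prescription_dose))
  invisible(x)
}
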