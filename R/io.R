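# Plain-text table formats.
#
# DVH table (CSV, UTF-8, header): patient_id, sex, modality, organ,
# n_fractions, prescription_dose_gy, dose_gy, volume. Rows of one
# (patient, modality, organ) block are contiguous and dose-sorted; `volume`
# is cumulative cc or differential volume fraction depending on the dialect.
#
# Results table (CSV): patient_id, organ, modality, model, quantity, value.

.dvh_columns <- c("patient_id", "sex", "modality", "organ",
                  "n_fractions", "prescription_dose_gy", "dose_gy", "volume")

#' Read a cohort of paired DVHs from a CSV table
#'
#' Reads the plain-text DVH dialect (see Details), validates every record,
#' converts cumulative input to differential form and normalizes volume
#' fractions, and assembles one [patient_pair()] per patient. Every patient
#' must carry both a proton and a photon block over the same organ set.
#'
#' @details The file is a UTF-8 CSV with header columns `patient_id`, `sex`,
#' `modality`, `organ`, `n_fractions`, `prescription_dose_gy`, `dose_gy`,
#' `volume`. Rows belonging to one (patient, modality, organ) must be
#' contiguous and sorted by dose. With `dialect = "cumulative"`, `volume` is
#' the absolute volume (e.g. cc) receiving at least `dose_gy`; with
#' `dialect = "differential"`, it is the volume fraction in the bin centred
#' at `dose_gy`.
#'
#' @param path Path to the CSV file.
#' @param dialect `"cumulative"` or `"differential"`.
#' @return List of [patient_pair()] objects, in file order.
#' @seealso [export_cohort()] for the inverse operation.
#' @export
read_dvh_table <- function(path, dialect = c("differential", "cumulative")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("DVH file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(.dvh_columns, names(tab))
  if (length(missing_cols))
    stop("DVH file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("DVH file has no data rows", call. = FALSE)

  bad_organ <- setdiff(unique(tab$organ), organ_labels())
  if (length(bad_organ))
    stop("unknown organ label(s) in DVH file: ",
         paste(bad_organ, collapse = ", "), call. = FALSE)

  pairs <- list()
  for (pid in unique(tab$patient_id)) {
    prows <- tab[tab$patient_id == pid, , drop = FALSE]
    sex <- unique(prows$sex)
    if (length(sex) != 1L)
      stop("inconsistent sex entries for patient ", pid, call. = FALSE)
    plans <- list()
    for (mod in c("proton", "photon")) {
      mrows <- prows[prows$modality == mod, , drop = FALSE]
      if (nrow(mrows) == 0L)
        stop("patient ", pid, " has no ", mod, " rows", call. = FALSE)
      nf <- unique(mrows$n_fractions)
      rx <- unique(mrows$prescription_dose_gy)
      if (length(nf) != 1L || length(rx) != 1L)
        stop("inconsistent fractionation metadata for patient ", pid,
             " (", mod, ")", call. = FALSE)
      dvhs <- list()
      for (organ in unique(mrows$organ)) {
        orows <- mrows[mrows$organ == organ, , drop = FALSE]
        d <- tryCatch({
          if (dialect == "cumulative")
            cumulative_to_differential(orows$dose_gy, orows$volume, organ)
          else
            dvh(orows$dose_gy, orows$volume, organ)
        }, error = function(e) {
          stop("invalid ", dialect, " DVH for patient ", pid, ", ", mod,
               ", ", organ, ": ", conditionMessage(e), call. = FALSE)
        })
        dvhs[[organ]] <- d
      }
      plans[[mod]] <- plan_dose(mod, nf, rx, dvhs)
    }
    pairs[[length(pairs) + 1L]] <-
      patient_pair(pid, sex, plans$proton, plans$photon)
  }
  pairs
}

#' Export a cohort of paired DVHs to the CSV dialect
#'
#' Writes the differential DVH dialect read back by
#' `read_dvh_table(path, "differential")`. Doses and volume fractions are
#' written with full double precision, so a write/read round trip is
#' lossless and all downstream risk computations are bit-identical.
#'
#' @param pairs Non-empty list of [patient_pair()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_cohort <- function(pairs, path) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a non-empty list of patient_pair objects",
         call. = FALSE)
  blocks <- lapply(pairs, function(pp) {
    stopifnot(inherits(pp, "patient_pair"))
    do.call(rbind, lapply(c("proton", "photon"), function(mod) {
      plan <- pp[[mod]]
      do.call(rbind, lapply(names(plan$dvhs), function(organ) {
        d <- plan$dvhs[[organ]]
        data.frame(patient_id = pp$patient_id, sex = pp$sex, modality = mod,
                   organ = organ, n_fractions = plan$n_fractions,
                   prescription_dose_gy = plan$prescription_dose,
                   dose_gy = sprintf("%.17g", d$dose),
                   volume = sprintf("%.17g", d$volume_fraction),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, blocks)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-patient risk results to CSV
#'
#' One row per (patient, organ, modality, model, quantity) in the results
#' dialect. Values are written with full double precision; a round trip
#' through [read_results()] returns equal values to better than 12
#' significant digits.
#'
#' @param results Non-empty data frame with columns `patient_id`, `organ`,
#'   `modality`, `model`, `quantity`, `value` (as produced by
#'   [compute_patient()] or [secmal()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("patient_id", "organ", "modality", "model", "quantity", "value")
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    stop("results is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- results[cols]
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path Path to the results file.
#' @return Data frame with the results columns; `value` numeric, `NA` for
#'   records that were undefined (e.g. relative risks with zero photon OED).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  tab$value <- as.numeric(tab$value)
  tab
}
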