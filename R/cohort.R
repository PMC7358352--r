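# Cohort pipeline: per-patient risk computation over both models, cohort
# medians/ranges, paired proton-vs-photon signed-rank tests, and flagging
# of relative-risk exceedances.

.model_labels <- c(linear = "schneider_linear",
                   linear_exponential = "schneider_linexp",
                   plateau = "schneider_plateau")

.row <- function(pid, organ, modality, model, quantity, value) {
  data.frame(patient_id = pid, organ = organ, modality = modality,
             model = model, quantity = quantity, value = value,
             stringsAsFactors = FALSE)
}

#' Compute all risk quantities for one patient
#'
#' For every organ present in both plans: total and fatal induction risks
#' (competition model, both modalities), OEDs under the three dose-response
#' variants (both modalities), and proton/photon relative risks per
#' variant. Combined bilateral-organ risks (`lung_combined`, and
#' `breast_combined` for female patients) are per-modality sums of the
#' sided risks. Risks are stored as probability fractions in \[0, 1\];
#' relative risks with zero photon OED are recorded as `NA`.
#'
#' @param pair A [patient_pair()].
#' @param coefficients Named list of [risk_coefficients()] per organ
#'   (default [default_coefficient_set()]).
#' @return Long-format data frame with columns `patient_id`, `organ`,
#'   `modality`, `model`, `quantity`, `value`.
#' @export
compute_patient <- function(pair, coefficients = default_coefficient_set()) {
  stopifnot(inherits(pair, "patient_pair"))
  organs <- names(pair$proton$dvhs)
  missing_ph <- setdiff(organs, names(pair$photon$dvhs))
  missing_pr <- setdiff(names(pair$photon$dvhs), organs)
  if (length(missing_ph) || length(missing_pr))
    stop("organ(s) present in only one modality for patient ",
         pair$patient_id, ": ",
         paste(c(missing_ph, missing_pr), collapse = ", "), call. = FALSE)

  rows <- list()
  risks <- list()  # [[organ]][[modality]][[kind]]
  for (organ in organs) {
    cf <- coefficients[[organ]]
    if (is.null(cf))
      stop("no risk coefficients supplied for organ ", organ, call. = FALSE)
    oeds <- list()
    for (mod in c("proton", "photon")) {
      plan <- pair[[mod]]
      d <- plan$dvhs[[organ]]
      for (kind in c("total", "fatal")) {
        rk <- dasu_organ_risk(d, plan$n_fractions, cf, kind)
        risks[[organ]][[mod]][[kind]] <- rk
        rows[[length(rows) + 1L]] <- .row(pair$patient_id, organ, mod,
                                          "dasu", paste0(kind, "_risk"), rk)
      }
      for (variant in red_variants()) {
        ov <- oed(d, variant, cf, plan$n_fractions)
        oeds[[variant]][[mod]] <- ov
        rows[[length(rows) + 1L]] <- .row(pair$patient_id, organ, mod,
                                          .model_labels[[variant]], "oed_gy",
                                          ov)
      }
    }
    for (variant in red_variants()) {
      rr <- tryCatch(
        relative_risk(oeds[[variant]]$proton, oeds[[variant]]$photon),
        secmal_undefined_rr = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- .row(pair$patient_id, organ, "proton",
                                        .model_labels[[variant]],
                                        "relative_risk", rr)
    }
  }

  combine <- list(lung_combined = c("lung_right", "lung_left"))
  if (pair$sex == "female")
    combine$breast_combined <- c("breast_right", "breast_left")
  for (comb in names(combine)) {
    sides <- combine[[comb]]
    if (!all(sides %in% organs)) next
    for (mod in c("proton", "photon")) {
      for (kind in c("total", "fatal")) {
        tot <- sum(vapply(sides, function(o) risks[[o]][[mod]][[kind]],
                          numeric(1)))
        rows[[length(rows) + 1L]] <- .row(pair$patient_id, comb, mod,
                                          "dasu", paste0(kind, "_risk"), tot)
      }
    }
  }
  do.call(rbind, rows)
}

.stack_results <- function(results) {
  if (is.data.frame(results)) return(results)
  if (is.list(results) && length(results) &&
      all(vapply(results, is.data.frame, logical(1))))
    return(do.call(rbind, results))
  stop("results must be a results data frame or a list of them",
       call. = FALSE)
}

#' Summarize a paired cohort
#'
#' Per-organ medians and ranges of every computed quantity, relative-risk
#' medians/ranges per dose-response variant, and two-tailed paired
#' signed-rank p-values for each proton-vs-photon quantity. Patients with
#' an undefined relative risk for an organ (photon OED zero, i.e. the
#' organ is fully spared by both or only the photon plan) are excluded
#' from that organ's relative-risk statistics and listed in the exclusion
#' log. Breast statistics cover female patients only, since only they
#' carry breast DVHs.
#'
#' @param results A results data frame (from [compute_patient()] /
#'   [secmal()]) or a list of per-patient data frames.
#' @return Object of class `secmal_summary` with elements `quantities`
#'   (median/min/max per organ, model, quantity, modality), `relative_risk`
#'   (per organ and variant), `tests` (p-values, `NA` with a note when a
#'   test cannot be formed), and `exclusions`.
#' @export
summarize_cohort <- function(results) {
  res <- .stack_results(results)
  if (nrow(res) == 0L) stop("no results to summarize", call. = FALSE)

  paired_quant <- res[res$quantity != "relative_risk", , drop = FALSE]
  agg_stats <- function(df, by) {
    med <- stats::aggregate(value ~ ., data = df[c(by, "value")], FUN = stats::median)
    names(med)[names(med) == "value"] <- "median"
    mn <- stats::aggregate(value ~ ., data = df[c(by, "value")], FUN = min)
    mx <- stats::aggregate(value ~ ., data = df[c(by, "value")], FUN = max)
    nn <- stats::aggregate(value ~ ., data = df[c(by, "value")], FUN = length)
    med$min <- mn$value
    med$max <- mx$value
    med$n <- nn$value
    med
  }
  quantities <- agg_stats(paired_quant,
                          c("organ", "model", "quantity", "modality"))

  rr <- res[res$quantity == "relative_risk", , drop = FALSE]
  exclusions <- rr[is.na(rr$value), c("patient_id", "organ", "model")]
  if (nrow(exclusions)) exclusions$reason <- "photon OED is zero"
  rr_ok <- rr[!is.na(rr$value), , drop = FALSE]
  relative_risk <- if (nrow(rr_ok))
    agg_stats(rr_ok, c("organ", "model")) else NULL

  # Paired proton-vs-photon tests per organ x model x quantity
  tests <- list()
  keys <- unique(paired_quant[c("organ", "model", "quantity")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- paired_quant[paired_quant$organ == k$organ &
                        paired_quant$model == k$model &
                        paired_quant$quantity == k$quantity, , drop = FALSE]
    pr <- sub[sub$modality == "proton", c("patient_id", "value")]
    ph <- sub[sub$modality == "photon", c("patient_id", "value")]
    common <- intersect(pr$patient_id, ph$patient_id)
    x <- pr$value[match(common, pr$patient_id)]
    y <- ph$value[match(common, ph$patient_id)]
    pv <- NA_real_
    note <- ""
    if (length(common) > 0) {
      pv <- tryCatch(paired_signed_rank(x, y), error = function(e) {
        note <<- conditionMessage(e)
        NA_real_
      })
    } else note <- "no paired patients"
    tests[[i]] <- data.frame(organ = k$organ, model = k$model,
                             quantity = k$quantity, n_pairs = length(common),
                             p_value = pv, note = note,
                             stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)

  structure(list(quantities = quantities, relative_risk = relative_risk,
                 tests = tests, exclusions = exclusions,
                 n_patients = length(unique(res$patient_id))),
            class = "secmal_summary")
}

#' @export
print.secmal_summary <- function(x, ...) {
  cat(sprintf("Cohort summary over %d patient(s)\n\n", x$n_patients))
  risks <- x$quantities[x$quantities$quantity %in%
                          c("total_risk", "fatal_risk"), , drop = FALSE]
  if (nrow(risks)) {
    cat("Cancer induction risks, median % (range):\n")
    for (i in order(risks$organ, risks$quantity, risks$modality)) {
      r <- risks[i, ]
      cat(sprintf("  %-16s %-10s %-7s %5.2f%% (%.2f-%.2f%%)\n", r$organ,
                  r$quantity, r$modality, 100 * r$median, 100 * r$min,
                  100 * r$max))
    }
  }
  if (!is.null(x$relative_risk)) {
    cat("\nProton/photon relative risk, median (range):\n")
    for (i in order(x$relative_risk$organ, x$relative_risk$model)) {
      r <- x$relative_risk[i, ]
      tst <- x$tests[x$tests$organ == r$organ & x$tests$model == r$model &
                       x$tests$quantity == "oed_gy", "p_value"]
      cat(sprintf("  %-16s %-18s %5.2f (%.2f-%.2f)  p = %s\n", r$organ,
                  sub("schneider_", "", r$model), r$median, r$min, r$max,
                  format.pval(tst, digits = 3)))
    }
  }
  if (nrow(x$exclusions))
    cat(sprintf("\n%d relative-risk record(s) excluded (photon OED zero)\n",
                nrow(x$exclusions)))
  invisible(x)
}

#' Flag relative-risk exceedances
#'
#' Returns every (patient, organ, variant) record whose proton/photon
#' relative risk is strictly greater than 1, i.e. organs where the proton
#' plan carries the higher predicted induction risk -- typically
#' lateralized cases where beam weighting pushes dose toward one side.
#'
#' @param results A results data frame, list of them, or a `secmal` object.
#' @return Data frame with columns `patient_id`, `organ`, `variant`, `rr`,
#'   sorted by patient then organ; zero rows when no exceedance exists.
#' @export
flag_rr_exceedances <- function(results) {
  if (inherits(results, "secmal")) results <- results$results
  res <- .stack_results(results)
  rr <- res[res$quantity == "relative_risk" & !is.na(res$value) &
              res$value > 1, , drop = FALSE]
  variant <- names(.model_labels)[match(rr$model, .model_labels)]
  out <- data.frame(patient_id = rr$patient_id, organ = rr$organ,
                    variant = variant, rr = rr$value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$organ, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired secondary-malignancy risk analysis of a cohort
#'
#' The main entry point: runs both risk models over every patient of a
#' paired proton/photon cohort and returns a `secmal` object. Use
#' `summary()` for cohort medians, ranges, relative risks and paired
#' signed-rank tests; `plot()` for relative-risk boxplots;
#' [flag_rr_exceedances()] for organs with proton risk above photon; and
#' [write_results()] on the `results` element to export.
#'
#' @param pairs List of [patient_pair()] objects (e.g. from
#'   [read_dvh_table()] or [generate_cohort()]).
#' @param coefficients Named list of [risk_coefficients()] per organ;
#'   defaults to the published values, override via [read_coefficients()].
#' @return Object of class `secmal` with elements `results` (long data
#'   frame), `patients` (id/sex table), and `coefficients`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, n_female = 3, seed = 7))
#' fit <- secmal(coh$pairs)
#' summary(fit)
#' @export
secmal <- function(pairs, coefficients = default_coefficient_set()) {
  if (inherits(pairs, "patient_pair")) pairs <- list(pairs)
  if (!is.list(pairs) || length(pairs) == 0L ||
      !all(vapply(pairs, inherits, logical(1), "patient_pair")))
    stop("pairs must be a non-empty list of patient_pair objects",
         call. = FALSE)
  results <- do.call(rbind, lapply(pairs, compute_patient,
                                   coefficients = coefficients))
  patients <- data.frame(
    patient_id = vapply(pairs, `[[`, character(1), "patient_id"),
    sex = vapply(pairs, `[[`, character(1), "sex"),
    stringsAsFactors = FALSE)
  structure(list(results = results, patients = patients,
                 coefficients = coefficients, call = match.call()),
            class = "secmal")
}

#' @export
print.secmal <- function(x, ...) {
  cat("Paired proton/photon secondary-malignancy risk analysis\n")
  cat(sprintf("  %d patient(s) (%d female), %d result records\n",
              nrow(x$patients), sum(x$patients$sex == "female"),
              nrow(x$results)))
  exc <- flag_rr_exceedances(x)
  cat(sprintf("  %d relative-risk exceedance(s) (RR > 1)\n", nrow(exc)))
  cat("Use summary() for cohort medians, ranges and paired tests.\n")
  invisible(x)
}

#' @export
summary.secmal <- function(object, ...) summarize_cohort(object$results)

#' Boxplots of proton/photon relative risks per organ
#'
#' One panel per dose-response variant, with the parity line RR = 1.
#'
#' @param x A `secmal` object.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.secmal <- function(x, ...) {
  rr <- x$results[x$results$quantity == "relative_risk" &
                    !is.na(x$results$value), , drop = FALSE]
  if (nrow(rr) == 0L) stop("no relative-risk records to plot", call. = FALSE)
  old <- graphics::par(mfrow = c(1, 3), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  for (variant in red_variants()) {
    sub <- rr[rr$model == .model_labels[[variant]], ]
    graphics::boxplot(value ~ organ, data = sub, las = 2,
                      ylab = "proton/photon relative risk",
                      main = sub("_", "-", variant), xlab = "", ...)
    graphics::abline(h = 1, lty = 2, col = "grey40")
  }
  invisible(x)
}
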