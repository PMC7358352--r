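# Seeded generator of paired proton/photon DVH cohorts with the
# statistical structure of a mediastinal-lymphoma consolidation-RT
# population: photon plans with a broad low/intermediate-dose bath across
# lungs, breasts and esophagus; proton plans with sharply reduced
# out-of-field dose; and occasional lateralized "adversarial" cases where
# the proton dose to the right breast or the esophagus exceeds the photon
# dose.
#
# Each organ DVH is a three-component mixture: a zero-dose mass, an
# exponential low-dose tail truncated at the prescription, and a
# near-prescription plateau mass for tissue adjacent to the target,
# discretized on a fixed 0.5 Gy bin grid. Proton parameters are tied to
# the photon parameters of the same patient-organ (shared per-patient
# jitter, multiplicative sparing), so for non-adversarial organs the
# photon DVH stochastically dominates the proton DVH by construction.

#' Default organ-level generator parameters
#'
#' Per organ: `photon_exposed` (fraction of the organ receiving any dose
#' under photons), `photon_tail_mean` (decay length in Gy of the
#' exponential low-dose bath), `photon_plateau` (volume fraction near the
#' prescription dose), and the proton plan's multiplicative reductions:
#' `proton_sparing` (exposed-fraction multiplier), `proton_tail_frac`
#' (tail decay-length multiplier) and `proton_plateau` (absolute plateau
#' fraction, at most the photon value). All multipliers are <= 1 so the
#' photon DVH dominates the proton DVH for every non-adversarial organ.
#'
#' @return Data frame with one row per organ.
#' @export
default_organ_params <- function() {
  data.frame(
    organ = c("lung_right", "lung_left", "breast_right", "breast_left",
              "esophagus"),
    photon_exposed   = c(0.95, 0.95, 0.85, 0.85, 0.98),
    photon_tail_mean = c(7.0, 7.0, 5.0, 5.0, 8.0),
    photon_plateau   = c(0.10, 0.10, 0.02, 0.02, 0.35),
    proton_sparing   = c(0.60, 0.60, 0.35, 0.35, 0.80),
    proton_tail_frac = c(0.35, 0.35, 0.30, 0.30, 0.45),
    proton_plateau   = c(0.08, 0.08, 0.01, 0.01, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the study population: 23 patients (16 female),
#' prescriptions of 20-39.6 Gy(RBE) delivered in 10-22 fractions of
#' 1.8-2 Gy(RBE) with modes near 36 Gy(RBE) / 18 fractions, and about
#' 2 of 23 patients with a lateralized case whose proton dose to the
#' right breast or esophagus exceeds the photon dose.
#'
#' @param n_patients Number of patients.
#' @param n_female Number of female patients (listed first; only they
#'   carry breast organs).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param fractions_range Integer range of fraction numbers.
#' @param fractions_mode Most common fraction number.
#' @param dose_per_fraction Candidate doses per fraction in Gy(RBE).
#' @param prescription_range Allowed total prescription range in Gy(RBE);
#'   draws of fractions and dose per fraction are reconciled to stay
#'   inside it.
#' @param bin_width DVH discretization bin width in Gy.
#' @param adversarial_fraction Target fraction of lateralized cases;
#'   `round(adversarial_fraction * n_patients)` patients are flagged.
#' @param organ_params Data frame as returned by [default_organ_params()].
#' @param jitter_sd Log-scale standard deviation of the per-patient-organ
#'   variability applied jointly to both modalities.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 23L, n_female = 16L, seed = 42L,
                          fractions_range = c(10L, 22L),
                          fractions_mode = 18L,
                          dose_per_fraction = c(1.8, 2.0),
                          prescription_range = c(20, 39.6),
                          bin_width = 0.5,
                          adversarial_fraction = 2 / 23,
                          organ_params = default_organ_params(),
                          jitter_sd = 0.15) {
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (n_female < 0L || n_female > n_patients)
    stop("n_female must be in [0, n_patients]", call. = FALSE)
  if (any(dose_per_fraction <= 0) || any(prescription_range <= 0) ||
      bin_width <= 0)
    stop("dose ranges and bin width must be positive", call. = FALSE)
  if (adversarial_fraction < 0 || adversarial_fraction > 1)
    stop("adversarial_fraction must be in [0, 1]", call. = FALSE)
  stopifnot(is.data.frame(organ_params),
            all(organ_params$organ %in% organ_labels()))
  structure(list(n_patients = as.integer(n_patients),
                 n_female = as.integer(n_female), seed = as.integer(seed),
                 fractions_range = as.integer(fractions_range),
                 fractions_mode = as.integer(fractions_mode),
                 dose_per_fraction = dose_per_fraction,
                 prescription_range = prescription_range,
                 bin_width = bin_width,
                 adversarial_fraction = adversarial_fraction,
                 organ_params = organ_params, jitter_sd = jitter_sd),
            class = "cohort_config")
}

# Discretize the zero/tail/plateau mixture onto the bin grid.
# Bin centers: 0 (zero-dose mass), then bin_width/2, 3*bin_width/2, ...
# Plateau mass sits in the bin adjacent to the prescription dose.
.mixture_dvh <- function(organ, exposed, tail_mean, plateau, prescription,
                         bin_width) {
  exposed <- min(max(exposed, 0), 1)
  plateau <- min(plateau, exposed)
  tail_mass <- exposed - plateau
  if (exposed <= 0) return(dvh(0, 1, organ, normalize = FALSE))

  edges <- seq(0, prescription, by = bin_width)
  if (edges[length(edges)] < prescription) edges <- c(edges, prescription)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  k <- length(centers)
  tail_bins <- numeric(k)
  if (tail_mass > 0) {
    # truncated-exponential mass per bin on (0, prescription]
    norm <- 1 - exp(-prescription / tail_mean)
    tail_bins <- (exp(-edges[-length(edges)] / tail_mean) -
                    exp(-edges[-1] / tail_mean)) / norm * tail_mass
  }
  plateau_bins <- numeric(k)
  plateau_bins[k] <- plateau

  doses <- c(0, centers)
  fracs <- c(1 - exposed, tail_bins + plateau_bins)
  keep <- fracs > 0
  dvh(doses[keep], fracs[keep], organ, normalize = TRUE)
}

#' Sample one modality's plan for a patient
#'
#' Builds the per-organ mixture DVHs for one modality from already-drawn
#' patient-level parameters. Deterministic given its arguments; all
#' randomness lives in [generate_cohort()]'s parameter draws.
#'
#' @param organs Character vector of organ labels for this patient.
#' @param modality `"proton"` or `"photon"`.
#' @param prescription Prescription dose in Gy(RBE).
#' @param n_fractions Number of fractions.
#' @param organ_params Data frame with the patient's jittered per-organ
#'   mixture parameters (columns as in [default_organ_params()]).
#' @param bin_width DVH bin width in Gy.
#' @return A [plan_dose()].
#' @export
sample_plan <- function(organs, modality, prescription, n_fractions,
                        organ_params, bin_width = 0.5) {
  if (length(organs) == 0L) stop("empty organ set", call. = FALSE)
  dvhs <- list()
  for (organ in organs) {
    p <- organ_params[organ_params$organ == organ, , drop = FALSE]
    if (nrow(p) != 1L)
      stop("no generator parameters for organ ", organ, call. = FALSE)
    if (modality == "photon") {
      dvhs[[organ]] <- .mixture_dvh(organ, p$photon_exposed,
                                    p$photon_tail_mean, p$photon_plateau,
                                    prescription, bin_width)
    } else {
      dvhs[[organ]] <- .mixture_dvh(organ,
                                    p$photon_exposed * p$proton_sparing,
                                    p$photon_tail_mean * p$proton_tail_frac,
                                    p$proton_plateau,
                                    prescription, bin_width)
    }
  }
  plan_dose(modality, n_fractions, prescription, dvhs)
}

# Per-patient substream seed derived by counter so that adding a patient
# does not perturb earlier patients. Kept below 2^31 - 1.
.patient_seed <- function(seed, i) {
  (abs(seed) %% 1000003L) * 2000L + i
}

#' Generate a synthetic paired proton/photon cohort
#'
#' Draws fractionation and per-organ dose-distribution parameters for
#' `n_patients` patients (the first `n_female` female, carrying breast
#' organs), builds both modality plans per patient, and flags
#' `round(adversarial_fraction * n_patients)` lateralized cases by
#' swapping the proton and photon mixture parameters of one organ
#' (right breast for female patients, otherwise esophagus), which makes
#' that organ's proton DVH dominate its photon DVH.
#'
#' @param config A [cohort_config()].
#' @return List with elements `pairs` (list of [patient_pair()]) and
#'   `truth` (data frame recording, per patient, sex, prescription,
#'   fractions, adversarial flag and affected organ).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 4, n_female = 2, seed = 1))
#' length(coh$pairs)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  n <- config$n_patients
  set.seed(config$seed)
  n_adv <- round(config$adversarial_fraction * n)
  adv_patients <- if (n_adv > 0) sort(sample.int(n, n_adv)) else integer(0)

  pairs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.patient_seed(config$seed, i))
    sex <- if (i <= config$n_female) "female" else "male"
    organs <- c("lung_right", "lung_left", "esophagus")
    if (sex == "female")
      organs <- c(organs, "breast_right", "breast_left")

    # fractionation: fraction number peaked at the mode, dose/fraction
    # from the candidate set, reconciled with the prescription range
    fr <- config$fractions_range
    cand <- seq.int(fr[1], fr[2])
    wts <- stats::dnorm(cand, config$fractions_mode, 2.5)
    nf <- sample(cand, 1L, prob = wts)
    dpf_prob <- if (length(config$dose_per_fraction) == 2L)
      c(0.25, 0.75) else NULL
    dpf <- if (length(config$dose_per_fraction) == 1L)
      config$dose_per_fraction
    else sample(config$dose_per_fraction, 1L, prob = dpf_prob)
    rx <- nf * dpf
    pres <- config$prescription_range
    if (rx > pres[2]) { dpf <- min(config$dose_per_fraction); rx <- nf * dpf }
    if (rx < pres[1]) { dpf <- max(config$dose_per_fraction); rx <- nf * dpf }

    # shared per-patient-organ jitter, applied to both modalities
    op <- config$organ_params[config$organ_params$organ %in% organs, ,
                              drop = FALSE]
    jit_tail <- exp(stats::rnorm(nrow(op), 0, config$jitter_sd))
    jit_exp <- exp(stats::rnorm(nrow(op), 0, config$jitter_sd / 2))
    jit_plat <- exp(stats::rnorm(nrow(op), 0, config$jitter_sd))
    op$photon_tail_mean <- op$photon_tail_mean * jit_tail
    op$photon_exposed <- pmin(op$photon_exposed * jit_exp, 1)
    op$photon_plateau <- op$photon_plateau * jit_plat
    op$proton_plateau <- op$proton_plateau * jit_plat

    adversarial <- i %in% adv_patients
    adv_organ <- NA_character_
    proton_op <- op
    if (adversarial) {
      adv_organ <- if (sex == "female") {
        sample(c("breast_right", "esophagus"), 1L)
      } else "esophagus"
    }

    photon <- sample_plan(organs, "photon", rx, nf, op, config$bin_width)
    proton <- sample_plan(organs, "proton", rx, nf, op, config$bin_width)
    if (adversarial) {
      # swap the two modality DVHs for the affected organ: the proton
      # plan inherits the heavier photon dose distribution and vice versa
      tmp <- photon$dvhs[[adv_organ]]
      photon$dvhs[[adv_organ]] <- proton$dvhs[[adv_organ]]
      proton$dvhs[[adv_organ]] <- tmp
    }

    pid <- sprintf("P%02d", i)
    pairs[[i]] <- patient_pair(pid, sex, proton, photon)
    truth[[i]] <- data.frame(patient_id = pid, sex = sex,
                             prescription = rx, n_fractions = nf,
                             adversarial = adversarial,
                             adversarial_organ = adv_organ,
                             stringsAsFactors = FALSE)
  }
  list(pairs = pairs, truth = do.call(rbind, truth))
}
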