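test_that("identical proton and photon plans give unit RR and zero differences", {
  organs <- c("lung_right", "lung_left", "esophagus")
  dvhs <- lapply(organs, function(o)
    dvh(c(0, 3, 9, 27), c(0.25, 0.3, 0.3, 0.15), o))
  names(dvhs) <- organs
  pair <- patient_pair("same", "male",
                       plan_dose("proton", 18L, 36, dvhs),
                       plan_dose("photon", 18L, 36, dvhs))
  res <- compute_patient(pair)
  rr <- res[res$quantity == "relative_risk", "value"]
  expect_true(all(rr == 1))
  for (q in c("total_risk", "fatal_risk", "oed_gy")) {
    sub <- res[res$quantity == q, ]
    pr <- sub[sub$modality == "proton", ]
    ph <- sub[sub$modality == "photon", ]
    expect_identical(pr$value[order(pr$organ, pr$model)],
                     ph$value[order(ph$organ, ph$model)])
  }
})

test_that("fully spared proton plan gives zero risks and zero RR", {
  organs <- c("lung_right", "lung_left", "esophagus")
  zero <- lapply(organs, function(o) dvh(0, 1, o))
  hot <- lapply(organs, function(o) dvh(c(2, 10), c(0.6, 0.4), o))
  names(zero) <- names(hot) <- organs
  pair <- patient_pair("spared", "male",
                       plan_dose("proton", 18L, 36, zero),
                       plan_dose("photon", 18L, 36, hot))
  res <- compute_patient(pair)
  expect_true(all(res[res$quantity == "relative_risk", "value"] == 0))
  pr_risk <- res[res$modality == "proton" &
                   res$quantity %in% c("total_risk", "fatal_risk"), "value"]
  expect_true(all(pr_risk == 0))
})

test_that("per-patient results equal organ-by-organ recomputation", {
  coh <- generate_cohort(cohort_config(n_patients = 2, n_female = 1,
                                       seed = 1))
  pair <- coh$pairs[[1]]
  res <- compute_patient(pair)
  for (organ in names(pair$proton$dvhs)) {
    cf <- default_coefficients(organ)
    for (mod in c("proton", "photon")) {
      plan <- pair[[mod]]
      expect_identical(
        res$value[res$organ == organ & res$modality == mod &
                    res$quantity == "total_risk"],
        dasu_organ_risk(plan$dvhs[[organ]], plan$n_fractions, cf, "total"))
      expect_identical(
        res$value[res$organ == organ & res$modality == mod &
                    res$model == "schneider_plateau" &
                    res$quantity == "oed_gy"],
        oed(plan$dvhs[[organ]], "plateau", cf, plan$n_fractions))
    }
    rr_lin <- res$value[res$organ == organ &
                          res$model == "schneider_linear" &
                          res$quantity == "relative_risk"]
    expect_identical(rr_lin,
                     oed(pair$proton$dvhs[[organ]], "linear", cf,
                         pair$proton$n_fractions) /
                       oed(pair$photon$dvhs[[organ]], "linear", cf,
                           pair$photon$n_fractions))
  }
  # combined bilateral risks are the sums of the sided risks
  for (comb in c("lung_combined", "breast_combined")) {
    sides <- if (comb == "lung_combined") c("lung_right", "lung_left")
             else c("breast_right", "breast_left")
    if (!all(sides %in% names(pair$proton$dvhs))) next
    for (mod in c("proton", "photon")) {
      sided <- sum(res$value[res$organ %in% sides & res$modality == mod &
                               res$quantity == "fatal_risk"])
      expect_equal(res$value[res$organ == comb & res$modality == mod &
                               res$quantity == "fatal_risk"],
                   sided, tolerance = 1e-12)
    }
  }
})

test_that("a male patient cannot carry breast DVHs", {
  organs <- c("lung_right", "lung_left", "breast_left", "esophagus")
  dvhs <- lapply(organs, function(o) dvh(c(0, 5), c(0.5, 0.5), o))
  names(dvhs) <- organs
  expect_error(
    patient_pair("m1", "male",
                 plan_dose("proton", 18L, 36, dvhs),
                 plan_dose("photon", 18L, 36, dvhs)),
    "breast DVHs present for male")
})

test_that("single-patient summary degenerates to that patient's values", {
  res <- compute_patient(toy_pair())
  s <- summarize_cohort(res)
  expect_true(all(s$quantities$median == s$quantities$min))
  expect_true(all(s$quantities$median == s$quantities$max))
  expect_true(all(is.na(s$tests$p_value)))
  expect_true(all(grepl("informative", s$tests$note)))
})

test_that("three-patient medians equal the hand-sorted middle element", {
  pairs <- lapply(1:3, function(i) {
    organs <- c("lung_right", "lung_left", "esophagus")
    mk <- function(scale) {
      d <- lapply(organs, function(o)
        dvh(c(1, 4, 10) * i, c(0.3, 0.4, 0.3) * scale, o))
      names(d) <- organs
      d
    }
    patient_pair(paste0("p", i), "male",
                 plan_dose("proton", 18L, 36, mk(0.5)),
                 plan_dose("photon", 18L, 36, mk(1)))
  })
  fit <- secmal(pairs)
  s <- summarize_cohort(fit$results)
  vals <- fit$results[fit$results$organ == "lung_right" &
                        fit$results$modality == "photon" &
                        fit$results$quantity == "total_risk", "value"]
  expect_equal(
    s$quantities$median[s$quantities$organ == "lung_right" &
                          s$quantities$modality == "photon" &
                          s$quantities$quantity == "total_risk"],
    sort(vals)[2])
})

test_that("combined medians come from per-patient sums, not summed medians", {
  # right/left risks anti-correlated across patients: the median of sums
  # differs from the sum of medians
  mk_pair <- function(pid, d_right, d_left) {
    organs <- c("lung_right", "lung_left", "esophagus")
    doses <- list(lung_right = d_right, lung_left = d_left, esophagus = 2)
    mk <- function(scale) {
      d <- lapply(organs, function(o) dvh(doses[[o]] * scale, 1, o))
      names(d) <- organs
      d
    }
    patient_pair(pid, "male", plan_dose("proton", 18L, 36, mk(0.5)),
                 plan_dose("photon", 18L, 36, mk(1)))
  }
  pairs <- list(mk_pair("a", 2, 14), mk_pair("b", 8, 8), mk_pair("c", 14, 2))
  fit <- secmal(pairs)
  res <- fit$results
  per_patient_sum <- vapply(c("a", "b", "c"), function(pid)
    res$value[res$patient_id == pid & res$organ == "lung_combined" &
                res$modality == "photon" & res$quantity == "total_risk"],
    numeric(1))
  med_org <- function(o) stats::median(
    res$value[res$organ == o & res$modality == "photon" &
                res$quantity == "total_risk"])
  s <- summarize_cohort(res)
  comb_med <- s$quantities$median[s$quantities$organ == "lung_combined" &
                                    s$quantities$modality == "photon" &
                                    s$quantities$quantity == "total_risk"]
  expect_equal(comb_med, stats::median(per_patient_sum))
  expect_false(isTRUE(all.equal(comb_med,
                                med_org("lung_right") + med_org("lung_left"))))
})

test_that("exceedance flagging is strict and sorted", {
  res <- data.frame(
    patient_id = c("p2", "p1", "p1"),
    organ = c("esophagus", "breast_right", "esophagus"),
    modality = "proton",
    model = "schneider_linear",
    quantity = "relative_risk",
    value = c(1.2, 1.0, 0.9),   # exactly 1 is not an exceedance
    stringsAsFactors = FALSE)
  out <- flag_rr_exceedances(res)
  expect_equal(nrow(out), 1)
  expect_equal(out$patient_id, "p2")
  expect_equal(out$variant, "linear")

  res$value <- c(0.5, 0.99, 1.0)
  expect_equal(nrow(flag_rr_exceedances(res)), 0)
})
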