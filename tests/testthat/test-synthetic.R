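test_that("generation is a deterministic function of the configuration", {
  cfg <- cohort_config(n_patients = 5, n_female = 3, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$pairs)) {
    for (mod in c("proton", "photon")) {
      expect_identical(lapply(a$pairs[[i]][[mod]]$dvhs, as.data.frame),
                       lapply(b$pairs[[i]][[mod]]$dvhs, as.data.frame))
    }
  }
  # a different seed changes the cohort
  c2 <- generate_cohort(cohort_config(n_patients = 5, n_female = 3,
                                      seed = 124))
  expect_false(identical(a$truth$prescription, c2$truth$prescription) &&
                 identical(a$pairs[[1]]$photon$dvhs$lung_right$volume_fraction,
                           c2$pairs[[1]]$photon$dvhs$lung_right$volume_fraction))
})

test_that("adding patients does not perturb earlier patients", {
  small <- generate_cohort(cohort_config(n_patients = 4, n_female = 2,
                                         seed = 5, adversarial_fraction = 0))
  big <- generate_cohort(cohort_config(n_patients = 8, n_female = 2,
                                       seed = 5, adversarial_fraction = 0))
  for (i in 1:4)
    expect_identical(
      as.data.frame(small$pairs[[i]]$photon$dvhs$lung_right),
      as.data.frame(big$pairs[[i]]$photon$dvhs$lung_right))
})

test_that("cohort structure matches the configured population", {
  coh <- generate_cohort(cohort_config())
  expect_length(coh$pairs, 23)
  sexes <- vapply(coh$pairs, `[[`, character(1), "sex")
  expect_equal(sum(sexes == "female"), 16)
  for (pp in coh$pairs) {
    has_breast <- all(c("breast_right", "breast_left") %in%
                        names(pp$proton$dvhs))
    expect_identical(has_breast, pp$sex == "female")
    expect_true(pp$proton$prescription_dose >= 20 &&
                  pp$proton$prescription_dose <= 39.6)
    expect_true(pp$proton$n_fractions >= 10 && pp$proton$n_fractions <= 22)
  }
})

test_that("population medians sit near the configured modes", {
  coh <- generate_cohort(cohort_config(n_patients = 200, n_female = 120,
                                       seed = 77))
  expect_lte(abs(stats::median(coh$truth$prescription) - 36), 2)
  expect_lte(abs(stats::median(coh$truth$n_fractions) - 18), 1)
})

test_that("photon DVH stochastically dominates proton for non-adversarial organs", {
  coh <- generate_cohort(cohort_config(seed = 42))
  for (i in seq_along(coh$pairs)) {
    pp <- coh$pairs[[i]]
    adv_organ <- coh$truth$adversarial_organ[i]
    for (organ in names(pp$proton$dvhs)) {
      if (!is.na(adv_organ) && organ == adv_organ) next
      cf <- default_coefficients(organ)
      # dominance at the cumulative-DVH level ...
      grid <- sort(unique(c(pp$proton$dvhs[[organ]]$dose,
                            pp$photon$dvhs[[organ]]$dose)))
      surv <- function(d, g) vapply(g, function(t)
        sum(d$volume_fraction[d$dose >= t - 1e-12]), numeric(1))
      expect_true(all(surv(pp$photon$dvhs[[organ]], grid) >=
                        surv(pp$proton$dvhs[[organ]], grid) - 1e-12))
      # ... implies the linear OED ordering
      expect_gte(oed(pp$photon$dvhs[[organ]], "linear", cf,
                     pp$photon$n_fractions),
                 oed(pp$proton$dvhs[[organ]], "linear", cf,
                     pp$proton$n_fractions))
    }
  }
})

test_that("adversarial flags are honored end to end", {
  # every patient adversarial: the flagged organ has linear RR > 1
  coh <- generate_cohort(cohort_config(n_patients = 1, n_female = 1,
                                       seed = 3, adversarial_fraction = 1))
  expect_true(coh$truth$adversarial[1])
  expect_true(coh$truth$adversarial_organ[1] %in%
                c("breast_right", "esophagus"))
  res <- compute_patient(coh$pairs[[1]])
  rr <- res$value[res$organ == coh$truth$adversarial_organ[1] &
                    res$model == "schneider_linear" &
                    res$quantity == "relative_risk"]
  expect_gt(rr, 1)

  # adversarial_fraction = 0: nobody flagged
  none <- generate_cohort(cohort_config(n_patients = 10, n_female = 5,
                                        seed = 8, adversarial_fraction = 0))
  expect_false(any(none$truth$adversarial))

  # default cohort: about 2/23 flagged, on the allowed organs
  def <- generate_cohort(cohort_config())
  expect_equal(sum(def$truth$adversarial), round(2 / 23 * 23))
  expect_true(all(def$truth$adversarial_organ[def$truth$adversarial] %in%
                    c("breast_right", "esophagus")))
  # male adversarial patients can only be esophagus cases
  male_adv <- def$truth$adversarial & def$truth$sex == "male"
  expect_true(all(def$truth$adversarial_organ[male_adv] == "esophagus"))
})

test_that("degenerate mixture settings produce the expected extremes", {
  params <- default_organ_params()
  # proton sparing factor 0: unit mass at 0 Gy
  params$proton_sparing <- 0
  plan <- sample_plan("lung_right", "proton", 36, 18L, params)
  d <- plan$dvhs$lung_right
  expect_equal(d$dose, 0)
  expect_equal(d$volume_fraction, 1)

  # full in-field fraction with all mass in the plateau: a single bin at
  # the prescription dose
  params <- default_organ_params()
  params$photon_exposed <- 1
  params$photon_plateau <- 1
  plan <- sample_plan("lung_right", "photon", 36, 18L, params)
  d <- plan$dvhs$lung_right
  expect_equal(nrow(d), 1)
  expect_equal(d$volume_fraction, 1)
  expect_lte(abs(d$dose - 36), 0.5)

  expect_error(sample_plan(character(0), "photon", 36, 18L,
                           default_organ_params()),
               "empty organ set")
})
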