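# Independent oracles: plain scalar loops over the model formulas, kept
# deliberately separate from the package's vectorized implementations.

oracle_dasu_risk <- function(doses, fracs, n, a1, a2, abr) {
  b1 <- a1 / abr
  b2 <- a2 / abr
  acc <- 0
  for (i in seq_along(doses)) {
    D <- doses[i]
    acc <- acc + fracs[i] *
      (a1 * D + b1 * D^2 / n) * exp(-(a2 * D + b2 * D^2 / n))
  }
  acc / sum(fracs)
}

oracle_oed <- function(doses, fracs, n, a2, abr, variant) {
  b <- a2 / abr
  acc <- 0
  for (i in seq_along(doses)) {
    D <- doses[i]
    ap <- a2 + b * D / n
    r <- switch(variant,
      linear = D,
      linear_exponential = D * exp(-ap * D),
      plateau = (1 - exp(-ap * D)) / ap)
    acc <- acc + fracs[i] * r
  }
  acc / sum(fracs)
}

# Exhaustive signed-rank null: every one of the 2^m sign assignments of
# the observed midranks is equiprobable. Two-tailed p doubles the smaller
# tail, capped at 1. Works on doubled ranks so comparisons are integer.
oracle_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w2 <- sum(r2[d > 0])
  masks <- 0:(2^m - 1)
  stat <- vapply(masks, function(mask) {
    on <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    sum(r2[on])
  }, numeric(1))
  p_lo <- mean(stat <= w2)
  p_hi <- mean(stat >= w2)
  min(1, 2 * min(p_lo, p_hi))
}

# Random valid differential DVH for property tests.
random_dvh <- function(n_bins, organ = sample(organ_labels(), 1),
                       max_dose = 40) {
  doses <- sort(runif(n_bins, 0, max_dose))
  while (any(diff(doses) <= 0)) doses <- sort(runif(n_bins, 0, max_dose))
  fracs <- rexp(n_bins) + 1e-4
  dvh(doses, fracs, organ)
}

# Minimal hand-built patient pair: photon bath heavier than proton.
toy_pair <- function(pid = "T1", sex = "female") {
  organs <- c("lung_right", "lung_left", "esophagus")
  if (sex == "female") organs <- c(organs, "breast_right", "breast_left")
  mk <- function(scale) {
    dvhs <- lapply(organs, function(o)
      dvh(c(0, 2, 8, 20), c(0.3, 0.3 * scale, 0.25 * scale, 0.15 * scale), o))
    names(dvhs) <- organs
    dvhs
  }
  patient_pair(pid, sex,
               plan_dose("proton", 18L, 36, mk(0.4)),
               plan_dose("photon", 18L, 36, mk(1.0)))
}
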