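# shared fixtures: systems are always built in code

amplifier_system <- function(...) ecg_system(...)

# y = x1 + x2, both zero-mean normal: the textbook Pythagorean case
toy_linear_system <- function(u1 = 3, u2 = 4) {
  mcm_system(
    list(
      uncertain_quantity("x1", 0, pdf_normal(0, u1),
                         group = "measurand", block = "input"),
      uncertain_quantity("x2", 0, pdf_normal(0, u2),
                         group = "environment", block = "input")
    ),
    model = "x1 + x2", name = "toy linear"
  )
}

# amplifier with every source shrunk to a near-point mass: what propagates
# is numerically negligible dispersion around the nominal output
near_degenerate_amplifier <- function(eps = 1e-12) {
  sys <- ecg_system()
  for (nm in names(sys$quantities)) {
    q <- sys$quantities[[nm]]
    sys$quantities[[nm]]$pdf <- if (q$pdf$family == "normal") {
      pdf_normal(q$nominal, eps)
    } else if (q$pdf$family == "u_shaped") {
      pdf_ushaped(q$nominal - eps, q$nominal + eps)
    } else {
      pdf_rectangular(q$nominal - eps, q$nominal + eps)
    }
  }
  sys
}

# nominals of the quantities that enter the static output equation
nominal_values_for_test <- function(sys) {
  qs <- Filter(function(q) q$block != "frequency_only", sys$quantities)
  vapply(qs, function(q) q$nominal, 0)
}

# printed-precision agreement at the study size M = 2e5: one unit in the
# last printed digit plus three Monte Carlo standard errors of the
# statistic. For millivolt cells the sd's standard error is at most
# sd/sqrt(2M) ~ 0.09 mV, so one printed unit (1 mV) already dominates; for
# two-decimal percent cells the standard error of U95/mean reaches
# 1.96 * 57/sqrt(2M) / 2596 * 100 ~ 0.0068 points on the total row, so the
# allowance is 0.005 (half a printed unit) + 3 * 0.0068, i.e. 0.025.
expect_printed_mv <- function(value, printed) {
  expect_lt(abs(value - printed), 1.0)
}
expect_printed_pct <- function(value, printed) {
  expect_lt(abs(value - printed), 0.025)
}
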