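test_that("minimum sample-count rule follows ceil(1e4 / (1 - p))", {
  expect_identical(required_samples(0.95), 200000L)
  expect_identical(required_samples(0.99), 1000000L)
  expect_identical(required_samples(0.90), 100000L)
  expect_error(required_samples(0), "between 0 and 1")
  expect_error(required_samples(1), "between 0 and 1")
  expect_error(required_samples(-0.5), "between 0 and 1")
  # strictly increasing in p
  ps <- seq(0.5, 0.99, by = 0.01)
  expect_true(all(diff(vapply(ps, required_samples, 0L)) >= 0))
  expect_true(required_samples(0.99) > required_samples(0.5))
})

test_that("expanded uncertainty applies the coverage factor to unrounded sd", {
  expect_equal(expanded_uncertainty(0), 0)
  expect_equal(expanded_uncertainty(1), 1.96)
  expect_equal(round(expanded_uncertainty(56.98)), 112)
  expect_equal(expanded_uncertainty(1, p = 0.99), qnorm(0.995))
  expect_error(expanded_uncertainty(-1), "non-negative")
})

test_that("runs are deterministic and reproducible from their seed", {
  sys <- amplifier_system()
  a <- mcm_run(sys, m = 5000, seed = 11)
  b <- mcm_run(sys, m = 5000, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$mean, b$mean)
  c <- mcm_run(sys, m = 5000, seed = 12)
  expect_false(identical(a$samples, c$samples))
  expect_equal(a$m, 5000L)
  expect_equal(length(a$samples), a$m)
  expect_equal(a$seed, 11L)
  # coverage interval contains the mean, U95 derives from unrounded sd
  expect_gt(a$mean, a$coverage_interval[1])
  expect_lt(a$mean, a$coverage_interval[2])
  expect_equal(a$U95, 1.96 * a$sd)
})

test_that("near-point-mass sources propagate essentially no dispersion", {
  res <- mcm_run(near_degenerate_amplifier(), m = 2000, seed = 1)
  expect_equal(res$mean, 2596.374, tolerance = 1e-9)
  expect_lt(res$sd, 1e-6)
})

test_that("per-source runs hold everything else at nominal and reuse draws", {
  sys <- amplifier_system()
  m <- 20000
  full <- mcm_run(sys, m = m, seed = 5)
  vin <- mcm_run_sources(sys, c("vin_plus", "vin_minus"), m = m, seed = 5)
  # mean invariance: every restricted run centres on the full-run mean
  for (subset in sys$groupings) {
    res <- mcm_run_sources(sys, subset, m = m, seed = 5)
    expect_lt(abs(res$mean - full$mean), 3 * full$sd / sqrt(m))
  }
  # the varied columns reuse the full run's draws: a linear single-source
  # run is a deterministic affine map of those draws, so repeating it with
  # the same seed is bit-identical, and vin-only dispersion is well below
  # the all-sources dispersion
  expect_identical(vin$samples,
                   mcm_run_sources(sys, c("vin_plus", "vin_minus"),
                                   m = m, seed = 5)$samples)
  expect_lt(vin$sd, full$sd)
  expect_error(mcm_run_sources(sys, character(0)), "non-empty")
  expect_error(mcm_run_sources(sys, "R99", m = 2000, seed = 1), "R99")
})

test_that("per-source variances add up to the total in quadrature", {
  sys <- amplifier_system()
  budget <- mcm_budget(sys, m = 2e5, seed = 7)
  sum_var <- sum(budget$rows$sd_mV^2)
  expect_lt(abs(sum_var / budget$total$sd_mV^2 - 1), 0.03)
})

test_that("tightening one source never inflates the total dispersion", {
  sys <- amplifier_system()
  m <- 50000
  base <- mcm_run(sys, m = m, seed = 3)
  mc_se <- base$sd / sqrt(2 * m)
  for (nm in c("R5", "R11")) {
    tight <- mcm_run(apply_tolerance(sys, nm, 0.001), m = m, seed = 3)
    expect_lt(tight$sd, base$sd + 3 * mc_se)
  }
  tight_v <- sys
  tight_v$quantities$vin_plus$pdf <- pdf_normal(0.30, 0.004)
  expect_lt(mcm_run(tight_v, m = m, seed = 3)$sd, base$sd + 3 * mc_se)
})

test_that("budgets tabulate rows, groups and the total consistently", {
  sys <- amplifier_system()
  budget <- mcm_budget(sys, m = 5000, seed = 2)
  expect_s3_class(budget, "uncertainty_budget")
  expect_equal(nrow(budget$rows), 5)
  expect_equal(budget$rows$source,
               c("vin", "Baseline", "Preamplifier", "Final stage", "Noise"))
  expect_equal(budget$rows$group,
               c("measurand", "measurand", "measuring_system",
                 "measuring_system", "environment"))
  # percentages are computed against each row's own mean
  expect_equal(budget$rows$U95_pct,
               100 * budget$rows$U95_mV / budget$rows$mean_mV)
  # empty grouping degenerates to the total row alone
  only_total <- mcm_budget(sys, grouping = list(), m = 5000, seed = 2)
  expect_equal(nrow(only_total$rows), 0)
  expect_equal(only_total$total$source, "All sources")
  expect_warning(
    mcm_budget(sys, grouping = list(a = "R1", b = c("R1", "R2")),
               m = 5000, seed = 2),
    "overlapping"
  )
  expect_error(
    mcm_budget(sys, grouping = list(bad = "nope"), m = 5000, seed = 2),
    "nope"
  )
})

test_that("cut-off frequency uncertainty propagates the RC components", {
  sys <- amplifier_system()
  co <- cutoff_uncertainty(sys, m = 20000, seed = 9)
  expect_equal(co$f1$mean, 1 / (2 * pi * 3.3), tolerance = 0.01)
  expect_equal(co$f2$mean, 1e6 / (2 * pi * 1500), tolerance = 0.01)
  expect_gt(co$f1$sd, 0)
  expect_gt(co$f2$sd, 0)
  # ~1 % components give ~1 % relative dispersion on f = 1/(2 pi R C)
  expect_lt(co$f2$sd / co$f2$mean, 0.02)
})

test_that("argument validation happens before any sampling", {
  sys <- amplifier_system()
  expect_error(mcm_run(sys, m = 10, seed = 1), ">= 1000")
  expect_error(mcm_run(sys, m = 5000, seed = 1.5), "integer")
  broken <- sys
  broken$quantities$R1$pdf <- structure(list(family = "normal", mu = 1,
                                             sigma = -1),
                                        class = "pdf_spec")
  expect_error(mcm_run(broken, m = 5000, seed = 1), "sigma")
})
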