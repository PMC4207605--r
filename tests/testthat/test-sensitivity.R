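test_that("MI sensitivity is non-negative and warns on out-of-domain perturbations", {
  sens <- mi_sensitivity(strategy(0.3, 1, theta0 = 1), mi_range = 0.5,
                         duration = 20)
  expect_gte(as.numeric(sens), 0)
  expect_true(length(attr(sens, "deviations")) == 6)
  # a 2 cm amplitude cannot absorb a -3.6 cm perturbation
  expect_warning(
    mi_sensitivity(strategy(0.02, 1, theta0 = 0.5), mi_range = 0.5,
                   duration = 20),
    "domain")
  expect_error(mi_sensitivity(strategy(0.3, 1), mi_range = 0), "mi_range")
})

test_that("sensitivity is the max MI deviation in units of 10% of the MI range", {
  s1 <- mi_sensitivity(strategy(0.3, 1, theta0 = 0.8), mi_range = 0.5,
                       duration = 20)
  dev <- attr(s1, "deviations")
  expect_equal(as.numeric(s1), max(dev) / (0.1 * 0.5))
  # doubling the reference MI range halves the sensitivity
  s2 <- mi_sensitivity(strategy(0.3, 1, theta0 = 0.8), mi_range = 1,
                       duration = 20)
  expect_equal(as.numeric(s2), as.numeric(s1) / 2, tolerance = 1e-10)
  # deterministic for fixed inputs
  expect_equal(attr(s2, "deviations"), dev, tolerance = 1e-12)
})
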