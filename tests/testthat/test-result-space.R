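tiny_map <- function() {
  fixture("tiny_map", function() {
    evaluate_result_space(amplitude_grid = c(0.1, 0.2, 0.3),
                          theta0_grid = c(-0.5, 0.5, 1.0),
                          measures = c("msf", "strobe_var", "jerk"),
                          duration = 15, gle_duration = 15)
  })
}

test_that("a 1x1 grid reproduces the single-strategy measures exactly", {
  mp <- evaluate_result_space(amplitude_grid = 0.1, theta0_grid = 1.0,
                              measures = c("mi", "msf", "strobe_var"),
                              duration = 15)
  ms <- strategy_measures(strategy(0.1, 1, theta0 = 1), duration = 15,
                          gle = FALSE)
  expect_equal(mp$surfaces$mi[1, 1], ms$mi)
  expect_equal(mp$surfaces$msf[1, 1], ms$msf)
  expect_equal(mp$surfaces$strobe_var[1, 1], ms$strobe_var)
  expect_equal(mp$surfaces$predictability_index[1, 1], ms$predictability_index)
})

test_that("failed cells are recorded without aborting the sweep", {
  mp <- evaluate_result_space(amplitude_grid = 0.1,
                              theta0_grid = c(0.5, NaN),
                              measures = "msf", duration = 10)
  expect_equal(nrow(mp$failures), 1L)
  expect_true(is.na(mp$surfaces$msf[1, 2]))
  expect_false(is.na(mp$surfaces$msf[1, 1]))
})

test_that("the cell cache makes re-evaluation cheap and identical", {
  cache <- tempfile(fileext = ".tsv")
  args <- list(amplitude_grid = c(0.1, 0.2), theta0_grid = c(0, 1),
               measures = "msf", duration = 10, cache = cache)
  m1 <- do.call(evaluate_result_space, args)
  t0 <- Sys.time()
  m2 <- do.call(evaluate_result_space, args)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_equal(m2$surfaces$msf, m1$surfaces$msf)
})

test_that("optima location respects the criterion and is transform invariant", {
  mp <- tiny_map()
  o <- locate_optima(mp, "min_msf")
  expect_equal(o$value, min(mp$surfaces$msf))
  expect_equal(o$strategy$amplitude_pp,
               mp$amplitude_grid[o$indices["amplitude"]])
  # a monotone transform of the surface leaves the argopt unchanged
  mp2 <- mp
  mp2$surfaces$msf <- exp(mp2$surfaces$msf)
  o2 <- locate_optima(mp2, "min_msf")
  expect_equal(o2$indices, o$indices)
  # ties break toward larger amplitude, then larger ball angle
  mp3 <- mp
  mp3$surfaces$msf[] <- 1
  o3 <- locate_optima(mp3, "min_msf")
  expect_equal(unname(o3$indices), c(3L, 3L))
  expect_error(locate_optima(mp, "max_mi"), "not present")
})

test_that("bilinear map lookup is exact at nodes and linear in between", {
  mp <- tiny_map()
  expect_equal(map_lookup(mp, "msf", 0.2, 0.5), mp$surfaces$msf[2, 2])
  mid <- map_lookup(mp, "msf", 0.25, 0.5)
  expect_equal(mid, mean(mp$surfaces$msf[2:3, 2]))
  expect_warning(map_lookup(mp, "msf", 0.6, 0), "clipped")
})
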