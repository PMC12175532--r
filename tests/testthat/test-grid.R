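test_that("identical forms give a zero difference everywhere", {
  spec <- gridSpec(c(1, 10, 100), c(0, 100, 300), temps_c = 25)
  g <- compareForms(toyModel(), toyModel(), spec, 25)
  expect_true(all(g@diff == 0))
  expect_identical(g@viable_a, g@viable_b)
})

test_that("doubling kcat_C wins every cell with CO2 > 0 (gross mode)", {
  fast <- buildTemperatureModel(
    kineticParams("fast", 4, 10, 100, 10),
    c(kcat_C = 50, K_C = 30, K_O = 15, kcat_O = 40))
  spec <- gridSpec(c(0.5, 5, 50), c(0, 50, 500), temps_c = 25)
  g <- compareForms(fast, toyModel(), spec, 25, mode = "gross")
  expect_true(all(g@diff > 0))
  # cell-by-cell oracle: direct substitution into the rate law at 25 C
  pf <- paramsAtTemperature(fast, 25)
  ps <- paramsAtTemperature(toyModel(), 25)
  for (i in seq_along(spec@co2_values)) for (j in seq_along(spec@o2_values)) {
    co2 <- spec@co2_values[i]; o2 <- spec@o2_values[j]
    exp_diff <- pf@kcat_C * co2 / (co2 + pf@K_C + pf@K_C * o2 / pf@K_O) -
      ps@kcat_C * co2 / (co2 + ps@K_C + ps@K_C * o2 / ps@K_O)
    expect_equal(g@diff[i, j], exp_diff, tolerance = 1e-12)
  }
})

test_that("net mode with zero loss ratio equals gross mode", {
  spec <- gridSpec(c(1, 10, 100), c(0, 100, 400), temps_c = 25)
  a <- toyModel(); b <- toyModel(c(kcat_C = 60, K_C = 20, K_O = 10,
                                   kcat_O = 30))
  g_gross <- compareForms(a, b, spec, 10, mode = "gross")
  g_net0 <- compareForms(a, b, spec, 10, pgs = pgsModel("none", 0),
                         mode = "net")
  expect_equal(g_net0@diff, g_gross@diff, tolerance = 1e-12)
})

test_that("maxAbsDifference matches an exhaustive scan with tie-breaks", {
  spec <- gridSpec(c(1, 10, 100, 1000), c(0, 100, 300), temps_c = 25)
  g <- compareForms(toyModel(), toyModel(c(kcat_C = 70, K_C = 30, K_O = 15,
                                           kcat_O = 40)), spec, 5)
  mx <- maxAbsDifference(g)
  expect_equal(mx$value, max(abs(g@diff)))
  expect_equal(abs(g@diff[mx$i_co2, mx$i_o2]), mx$value)
  # zero grid: ties broken at lowest CO2 then lowest O2
  gz <- compareForms(toyModel(), toyModel(), spec, 25)
  mz <- maxAbsDifference(gz)
  expect_equal(mz$value, 0)
  expect_equal(c(mz$i_co2, mz$i_o2), c(1, 1))
  # single negative cell: absolute value wins
  g@diff[2, 3] <- -2 * mx$value
  m2 <- maxAbsDifference(g)
  expect_equal(m2$value, 2 * mx$value)
  expect_equal(c(m2$i_co2, m2$i_o2), c(2, 3))
})

test_that("nonviable region is the low-CO2 prefix of each O2 row", {
  spec <- gridSpec(10^seq(-1, 3, length.out = 24),
                   seq(0, 500, length.out = 12), temps_c = 25)
  g <- compareForms(toyModel(), toyModel(c(kcat_C = 60, K_C = 20, K_O = 10,
                                           kcat_O = 30)), spec, 25)
  mask <- nonviableRegion(g)
  for (j in seq_along(spec@o2_values)) {
    col <- mask[, j]
    # monotone in CO2: once viable, stays viable (prefix mask)
    expect_true(all(diff(as.integer(col)) <= 0))
  }
  # O2 = 0 column: no oxygenation, every CO2 > 0 cell is viable
  expect_true(all(!mask[, spec@o2_values == 0]))
  # gross mode refuses
  gg <- compareForms(toyModel(), toyModel(), spec, 25, mode = "gross")
  expect_error(nonviableRegion(gg), "net")
})

test_that("cells at or below break-even for both forms are non-viable", {
  # same S_CO for both forms: break-even at [CO2] = 0.5 * [O2] / S_CO = 10
  # at [O2] = 200; a grid cell just below that line is non-viable for both
  flat <- c(kcat_C = 0, K_C = 0, K_O = 0, kcat_O = 0)
  g <- compareForms(toyModel(flat),
                    buildTemperatureModel(kineticParams("b", 5, 30, 300, 10),
                                          flat),
                    gridSpec(co2_values = 10 * (1 - 1e-9), o2_values = 200,
                             temps_c = 25), 25)
  expect_true(nonviableRegion(g)[1, 1])
  # exactly at break-even (exact in binary arithmetic for the toy enzyme):
  # f = 0 counts as non-viable
  r <- netCarboxylation(toyParams(), gasConditions(10, 200))
  expect_identical(r@f_net, 0)
  expect_false(r@viable)
})

test_that("grid evaluation is purely cell-wise", {
  spec <- gridSpec(c(1, 10, 100), c(0, 50, 400), temps_c = 25)
  a <- toyModel(); b <- toyModel(c(kcat_C = 70, K_C = 10, K_O = 20,
                                   kcat_O = 45))
  g <- compareForms(a, b, spec, 25)
  for (i in seq_along(spec@co2_values)) for (j in seq_along(spec@o2_values)) {
    sub <- compareForms(a, b, gridSpec(spec@co2_values[i],
                                       spec@o2_values[j] + c(0, 1),
                                       temps_c = 25), 25)
    expect_equal(sub@diff[1, 1], g@diff[i, j], tolerance = 1e-12)
  }
})

test_that("a larger kcat_C enthalpy widens the lead as temperature rises", {
  hot <- toyModel(c(kcat_C = 80, K_C = 30, K_O = 15, kcat_O = 40))
  cold <- toyModel(c(kcat_C = 30, K_C = 30, K_O = 15, kcat_O = 40))
  spec <- gridSpec(10^seq(0, 3, length.out = 16),
                   seq(0, 400, length.out = 8), temps_c = c(0, 25))
  # both calibrated to the same value at 25 C, so compare above that point
  mx <- vapply(c(30, 40, 50), function(tc)
    maxAbsDifference(compareForms(hot, cold, spec, tc))$value, numeric(1))
  expect_true(all(diff(mx) > 0))
})

test_that("grid serialization round-trips", {
  spec <- gridSpec(c(1, 10, 100), c(0, 100, 400), temps_c = 25)
  g <- compareForms(toyModel(), toyModel(c(kcat_C = 60, K_C = 20, K_O = 10,
                                           kcat_O = 30)), spec, 25)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeComparisonGrid(g, tmp)
  g2 <- readComparisonGrid(tmp)
  expect_equal(g2@diff, g@diff, tolerance = 1e-9)
  expect_identical(g2@viable_a, g@viable_a)
  expect_identical(g2@form_a, g@form_a)
  # deterministic: writing again is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeComparisonGrid(g, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("degenerate grid specs are rejected", {
  expect_error(gridSpec(numeric(0), c(1, 2)), "non-empty")
  expect_error(gridSpec(c(10, 1), c(1, 2)), "increasing")
  expect_error(gridSpec(c(0, 1), c(1, 2)), "positive")
})
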