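test_that("the identity perturbation leaves parameters and runs untouched", {
  combo <- parseCombo("a3b2c2")
  ps <- defaultParameters(combo)
  ident <- perturbationSpec(1, 1, 1)
  ps2 <- applyOsmDepletion(ps, ident, combo)
  expect_identical(parameterValues(ps2), parameterValues(ps))
  t1 <- simulateTrajectory(baselineState(injured = TRUE), ps, combo)
  t2 <- simulateTrajectory(baselineState(injured = TRUE), ps2, combo)
  expect_identical(t1, t2)
})

test_that("the OSM spec scales exactly the targeted parameters", {
  combo <- parseCombo("a3b2c2")
  ps <- defaultParameters(combo)
  osm <- applyOsmDepletion(ps, perturbationSpec(0.5, 0.5, 0.2), combo)
  v0 <- parameterValues(ps); v1 <- parameterValues(osm)
  expect_identical(v1[["beta"]], 0.5 * v0[["beta"]])
  expect_identical(v1[["Inhib_OC"]], 0.2 * v0[["Inhib_OC"]])
  expect_identical(v1[["Inhib_OC2"]], 0.2 * v0[["Inhib_OC2"]])
  ## under b2 the expansion channel is injury-driven: gamma_OB untouched
  expect_identical(v1[["gamma_OB"]], v0[["gamma_OB"]])
  untouched <- setdiff(parameterNames(),
                       c("beta", "Inhib_OC", "Inhib_OC2"))
  expect_identical(v1[untouched], v0[untouched])
  ## the original set is unchanged (copy semantics)
  expect_identical(parameterValues(ps), v0)
})

test_that("under b1 the expansion factor scales gamma_OB", {
  combo <- parseCombo("a3b1c2")
  ps <- defaultParameters(combo)
  osm <- applyOsmDepletion(ps, perturbationSpec(0.5, 0.5, 0.2), combo)
  expect_identical(parameterValues(osm)[["gamma_OB"]],
                   0.5 * parameterValues(ps)[["gamma_OB"]])
})

test_that("repeated application composes multiplicatively", {
  combo <- parseCombo("a3b1c1")
  ps <- defaultParameters(combo)
  s <- perturbationSpec(0.5, 0.5, 0.2)
  twice <- applyOsmDepletion(applyOsmDepletion(ps, s, combo), s, combo)
  expect_equal(parameterValues(twice)[["beta"]],
               0.25 * parameterValues(ps)[["beta"]])
  expect_equal(parameterValues(twice)[["Inhib_OC"]],
               0.04 * parameterValues(ps)[["Inhib_OC"]])
  expect_equal(parameterValues(twice)[["gamma_OB"]],
               0.25 * parameterValues(ps)[["gamma_OB"]])
})

test_that("negative factors are rejected", {
  expect_error(perturbationSpec(-0.5, 0.5, 0.2), "non-negative")
})

test_that("OSM depletion lowers the peak bone volume (b2) and the
           osteoblast peak where the M2 expansion channel exists (b1)", {
  times <- seq(0, 14, by = 0.25)
  run <- function(nm) {
    combo <- parseCombo(nm)
    ps <- parameterSet()  # published table values
    osm <- applyOsmDepletion(ps, perturbationSpec(), combo)
    base <- simulateTrajectory(baselineState(injured = TRUE), ps, combo,
                               times = times)
    pert <- simulateTrajectory(baselineState(injured = TRUE), osm, combo,
                               times = times)
    compareTrajectories(base, pert)
  }
  peak <- function(cmp, run, v) cmp$peak[cmp$run == run & cmp$variable == v]

  ## best-fitting combination (b2): reduced mineralization and osteoclast
  ## inhibition depress the bone-volume peak
  cmp <- run("a3b2c2")
  expect_equal(nrow(cmp), 18L)  # 9 variables x 2 runs
  expect_lt(peak(cmp, "perturbed", "B"), peak(cmp, "baseline", "B"))

  ## b1 counterpart: the M2-driven expansion channel is scaled, so the
  ## osteoblast peak drops too
  cmp1 <- run("a3b1c2")
  expect_lt(peak(cmp1, "perturbed", "OB"), peak(cmp1, "baseline", "OB"))
  expect_lt(peak(cmp1, "perturbed", "B"), peak(cmp1, "baseline", "B"))
})

test_that("trajectory comparison validates grids and is exact on identity", {
  combo <- parseCombo("a3b2c2")
  ps <- defaultParameters(combo)
  t1 <- simulateTrajectory(baselineState(injured = TRUE), ps, combo)
  cmp <- compareTrajectories(t1, t1)
  wide <- merge(cmp[cmp$run == "baseline", ], cmp[cmp$run == "perturbed", ],
                by = "variable")
  expect_equal(wide$peak.x, wide$peak.y)
  expect_equal(wide$terminal.x, wide$terminal.y)
  t3 <- simulateTrajectory(baselineState(injured = TRUE), ps, combo,
                           times = c(0, 2, 14))
  expect_error(compareTrajectories(t1, t3), "time grid")
})
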