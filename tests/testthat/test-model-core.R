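test_that("state and parameter constructors enforce the domain invariants", {
  st <- baselineState(injured = TRUE)
  expect_identical(names(st), stateVariables())
  expect_equal(unname(st[c("Mo", "M", "OB", "OC", "B", "D")]),
               c(1.4e4, 2.8e4, 3.1e4, 8.8e4, 0.3530, 2.8))
  expect_equal(unname(baselineState()[["D"]]), 0)
  expect_error(modelState(OB = -1), ">= 0")
  expect_error(modelState(XX = 1), "unknown state")
  expect_error(parameterSet(delta_D = -1), ">= 0")
  expect_error(parameterSet(bogus = 1), "unknown parameter")
})

test_that("rate functions implement the selected hypothesis forms", {
  ps <- parameterSet()
  pr <- parameterValues(ps)

  ## a3: inhibition terms vanish at M2 = 0
  b32 <- buildRateFunctions(parseCombo("a3b2c2"), ps)
  st <- modelState(M2 = 0)
  expect_equal(b32$dOC(st), pr[["d_OC"]] * st[["OB"]])
  expect_equal(b32$deltaOC(st), pr[["delta_OC"]])

  ## a3: Inhib_OC * M2 = 1 halves formation
  stHalf <- modelState(M2 = 1 / pr[["Inhib_OC"]])
  expect_equal(b32$dOC(stHalf), pr[["d_OC"]] * stHalf[["OB"]] / 2)

  ## c3 at D = 0: only the pro-inflammatory-macrophage-driven term survives
  b13 <- buildRateFunctions(parseCombo("a1b1c3"), ps)
  st0 <- modelState(D = 0, M1 = 123)
  expect_equal(b13$p1(st0), 0)
  expect_equal(b13$p22(st0), 0)
  expect_equal(b13$p3(st0), pr[["p_32"]] * 123)
  expect_equal(b13$depol3(st0), pr[["depol_3"]])

  ## c2 vs c1 differ only in the anti-inflammatory source
  b31c1 <- buildRateFunctions(parseCombo("a3b1c1"), ps)
  b31c2 <- buildRateFunctions(parseCombo("a3b1c2"), ps)
  stP <- modelState(M1 = 50, Mo1 = 30, D = 1.5)
  expect_equal(b31c1$p21(stP), 0)
  expect_equal(b31c1$p22(stP), pr[["p_2"]] * 1.5)
  expect_equal(b31c2$p21(stP), pr[["p_2"]] * 80)
  expect_equal(b31c2$p22(stP), 0)
  expect_equal(b31c1$p1(stP), b31c2$p1(stP))

  ## a2 replaces M2 by OB in both inhibition terms
  b22 <- buildRateFunctions(parseCombo("a2b2c2"), ps)
  expect_equal(b22$dOC(stP),
               pr[["d_OC"]] / (1 + pr[["Inhib_OC"]] * stP[["OB"]]))
  expect_equal(b22$deltaOC(stP),
               pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * stP[["OB"]]))

  ## b1 vs b2 expansion drivers
  expect_equal(b31c1$gammaOB(stP), pr[["gamma_OB"]] * stP[["M2"]])
  expect_equal(b32$gammaOB(stP), pr[["gamma_OB"]] * stP[["D"]])
})

test_that("evaluateRHS matches an independent transcription of the equations", {
  set.seed(7)
  combos <- enumerateCombos()
  for (rep in 1:20) {
    st <- setNames(runif(9, 0, 100), stateVariables())
    cb <- combos[[sample.int(18, 1)]]
    ps <- parameterSet()
    got <- evaluateRHS(st, ps, cb)
    want <- oracleRHS(st, parameterValues(ps), cb@a, cb@b, cb@c)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("evaluateRHS agrees with assembly from the rate-function bundle", {
  set.seed(11)
  for (cb in enumerateCombos()) {
    st <- setNames(runif(9, 0, 1e4), stateVariables())
    ps <- parameterSet()
    pr <- parameterValues(ps)
    bd <- buildRateFunctions(cb, ps)
    P <- st[["M1"]] + st[["Mo1"]]
    want <- c(
      Mo = pr[["H_Mo"]] - pr[["delta_Mo"]] * st[["Mo"]] + pr[["I_1"]] * P +
        pr[["I_2"]] * st[["D"]] - bd$p3(st) * st[["Mo"]] +
        bd$depol3(st) * st[["Mo1"]],
      M = pr[["H_M"]] - pr[["delta_M"]] * st[["M"]] - bd$dOC(st) * st[["M"]] -
        bd$p1(st) * st[["M"]] - bd$p21(st) * st[["M"]] +
        bd$depol1(st) * st[["M1"]] + bd$depol21(st) * st[["M2"]],
      M1 = bd$p1(st) * st[["M"]] - bd$depol1(st) * st[["M1"]] -
        bd$p22(st) * st[["M1"]] + bd$depol22(st) * st[["M2"]] -
        pr[["delta_M"]] * st[["M1"]],
      M2 = bd$p21(st) * st[["M"]] + bd$p22(st) * st[["M1"]] -
        bd$depol21(st) * st[["M2"]] - bd$depol22(st) * st[["M2"]] -
        pr[["delta_M"]] * st[["M2"]],
      Mo1 = bd$p3(st) * st[["Mo"]] - bd$depol3(st) * st[["Mo1"]] -
        pr[["delta_Mo"]] * st[["Mo1"]],
      OB = pr[["H_OB"]] * st[["OC"]] + bd$gammaOB(st) -
        pr[["delta_OB"]] * st[["OB"]] * st[["B"]],
      OC = bd$dOC(st) * st[["M"]] - bd$deltaOC(st) * st[["OC"]],
      B = pr[["Pi_B"]] * (1 + pr[["beta"]] * st[["M2"]]) * st[["OB"]] -
        pr[["delta_B"]] * (1 + pr[["alpha"]] * P) * st[["OC"]] * st[["B"]],
      D = -pr[["delta_D"]] * P * st[["D"]])
    expect_equal(evaluateRHS(st, ps, cb), want, tolerance = 1e-12,
                 info = comboName(cb))
  }
})

test_that("no anti-inflammatory source without pro-inflammatory cells (c2)", {
  ## under c2 the M2 source is proportional to the pro-inflammatory pool
  combo <- parseCombo("a3b2c2")
  st <- modelState(M1 = 0, Mo1 = 0, D = 2.8)
  d <- evaluateRHS(st, defaultParameters(combo), combo)
  expect_equal(unname(d[["M2"]]), 0)
})

test_that("evaluateRHS rejects negative states", {
  combo <- parseCombo("a3b2c2")
  st <- baselineState()
  st[["OC"]] <- -1
  expect_error(evaluateRHS(st, parameterSet(), combo), ">= 0")
})

test_that("homeostatic derivation reproduces the published worked values", {
  combo <- parseCombo("a3b2c2")
  ps <- deriveHomeostaticParameters(parameterSet(), combo)
  v <- parameterValues(ps)
  ## published d_OC 5.35e-5 and Pi_B 6.018e-7; inputs are printed rounded
  expect_equal(v[["d_OC"]], 5.35e-5, tolerance = 0.01)
  expect_equal(v[["Pi_B"]], 6.018e-7, tolerance = 0.01)
  expect_equal(v[["d_OC"]], 0.53 * 8.8e4 / (3.1e4 * 2.8e4), tolerance = 1e-12)
  expect_equal(v[["Pi_B"]], 5.99e-7 * 8.8e4 * 0.3530 / 3.1e4,
               tolerance = 1e-12)
  expect_equal(v[["H_Mo"]], 0.45 * 1.4e4)
  ## H_M balances death plus the osteoclastogenic drain
  expect_equal(v[["H_M"]], 0.1 * 2.8e4 + v[["d_OC"]] * 3.1e4 * 2.8e4)
})

test_that("derivation makes the baseline an exact fixed point for all 18", {
  base <- baselineState()
  for (cb in enumerateCombos()) {
    ps <- defaultParameters(cb)
    d <- evaluateRHS(base, ps, cb)
    expect_equal(max(abs(d)), 0, info = comboName(cb))
  }
})

test_that("derivation guards against degenerate baselines", {
  combo <- parseCombo("a3b2c2")
  bad <- baselineState()
  bad[["OC"]] <- 0
  expect_error(deriveHomeostaticParameters(parameterSet(), combo, bad),
               "underdetermined")
  injured <- baselineState(injured = TRUE)
  expect_error(deriveHomeostaticParameters(parameterSet(), combo, injured),
               "D = 0")
})
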