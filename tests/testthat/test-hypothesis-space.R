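test_that("the hypothesis space enumerates all 18 combinations", {
  combos <- enumerateCombos()
  expect_length(combos, 18L)
  nms <- vapply(combos, comboName, character(1))
  expect_equal(anyDuplicated(nms), 0L)
  expect_true(all(c("a3b2c2", "a2b2c3") %in% nms))
  ## a-major deterministic order
  expect_equal(names(combos)[1:3], c("a1b1c1", "a1b1c2", "a1b1c3"))
  expect_identical(names(combos), unname(nms))
})

test_that("combination construction validates its indices", {
  expect_error(hypothesisCombo(4, 1, 1), "a")
  expect_error(hypothesisCombo(1, 3, 1), "b")
  expect_error(hypothesisCombo(1, 1, 0), "c")
  expect_error(parseCombo("a4b1c1"))
  expect_error(parseCombo("b1c1"))
  expect_equal(comboName(parseCombo("a2b1c3")), "a2b1c3")
})

test_that("manifest roles are exclusive and cover exactly the used symbols", {
  for (cb in enumerateCombos()) {
    m <- parameterManifest(cb)
    roles <- c(freeParameters(m), fixedParameters(m), derivedParameters(m))
    expect_equal(anyDuplicated(roles), 0L, info = comboName(cb))
    used <- osteomac:::.usedParameters(cb)
    expect_setequal(roles, used)
    expect_equal(parameterCount(m), length(freeParameters(m)))
  }
})

test_that("the a3b2c2 manifest matches the published provenance labels", {
  m <- parameterManifest(parseCombo("a3b2c2"))
  expect_setequal(fixedParameters(m), c("delta_Mo", "delta_M", "delta_OC"))
  expect_setequal(derivedParameters(m),
                  c("H_Mo", "H_M", "H_OB", "d_OC", "Pi_B"))
  expect_setequal(freeParameters(m),
                  c("gamma_OB", "delta_OB", "delta_B", "alpha", "beta",
                    "Inhib_OC", "Inhib_OC2", "delta_D", "I_1", "I_2",
                    "p_31", "p_32", "depol_3", "p_11", "p_12", "p_2",
                    "depol_1", "depol_2"))
  expect_equal(parameterCount(m), 18L)
})

test_that("a1 frees the osteoclast formation magnitude and adds d_OC2", {
  m1 <- parameterManifest(parseCombo("a1b2c2"))
  m3 <- parameterManifest(parseCombo("a3b2c2"))
  expect_true(all(c("d_OC", "d_OC2") %in% freeParameters(m1)))
  expect_false("d_OC2" %in%
                 c(freeParameters(m3), fixedParameters(m3),
                   derivedParameters(m3)))
  expect_true("d_OC" %in% derivedParameters(m3))
})

test_that("unused polarization branch parameters are dropped under c3", {
  m <- parameterManifest(parseCombo("a3b2c3"))
  all3 <- c(freeParameters(m), fixedParameters(m), derivedParameters(m))
  expect_false(any(c("p_12", "depol_1", "p_31") %in% all3))
  expect_true(all(c("p_11", "p_2", "depol_2", "p_32", "depol_3") %in% all3))
})

test_that("manifests are deterministic and the free-H switch works", {
  m1 <- parameterManifest(parseCombo("a2b1c1"))
  m2 <- parameterManifest(parseCombo("a2b1c1"))
  expect_identical(freeParameters(m1), freeParameters(m2))
  mf <- parameterManifest(parseCombo("a2b1c1"), replenishment = "free")
  expect_true(all(c("H_Mo", "H_M") %in% freeParameters(mf)))
  expect_equal(parameterCount(mf), parameterCount(m1) + 2L)
})

test_that("manifestTable lays out roles, defaults and bounds", {
  m <- parameterManifest(parseCombo("a3b2c2"))
  tab <- manifestTable(m)
  expect_setequal(tab$parameter,
                  c(freeParameters(m), fixedParameters(m),
                    derivedParameters(m)))
  expect_true(all(is.na(tab$lower[tab$role != "free"])))
  fr <- tab[tab$role == "free", ]
  expect_true(all(fr$lower < fr$upper))
})
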