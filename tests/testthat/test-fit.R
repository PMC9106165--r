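test_that("zero free parameters returns the computed objective unchanged", {
  combo <- parseCombo("a3b2c2")
  ds <- makeDataset(noise = 0.1, seed = 3)
  ps <- defaultParameters(combo)
  fit <- fitModel(combo, ds, params = ps, free = character(0),
                  settings = fitSettings(restarts = 1, maxit = 10, seed = 3))
  expect_equal(fit@p, 0L)
  ## non-derived parameters pass through untouched; the homeostatic set is
  ## re-derived against the dataset's own baseline means
  m <- parameterManifest(combo)
  keep <- setdiff(parameterNames(), derivedParameters(m))
  expect_identical(parameterValues(fit)[keep], parameterValues(ps)[keep])
  ## the reported J is the objective of the residuals actually returned
  expect_equal(fit@Jinf, objectiveJinf(fitResiduals(fit)))
  expect_equal(fit@J2, objectiveJ2(fitResiduals(fit)))
  expect_equal(fit@AIC_Jinf, 2 * fit@Jinf)
  expect_length(fitTrace(fit), 1L)
})

test_that("fits are deterministic given the seed", {
  combo <- parseCombo("a3b2c2")
  ds <- makeDataset(noise = 0.1, seed = 4)
  s <- fitSettings(restarts = 2, maxit = 60, seed = 11)
  f1 <- fitModel(combo, ds, free = c("gamma_OB", "delta_D"), settings = s)
  f2 <- fitModel(combo, ds, free = c("gamma_OB", "delta_D"), settings = s)
  expect_identical(parameterValues(f1), parameterValues(f2))
  expect_identical(fitTrace(f1), fitTrace(f2))
  expect_identical(fitResiduals(f1), fitResiduals(f2))
})

test_that("the best-so-far trace is monotone non-increasing", {
  combo <- parseCombo("a3b1c1")
  ds <- makeDataset(noise = 0.1, seed = 5)
  fit <- fitModel(combo, ds, free = c("gamma_OB", "delta_B", "alpha"),
                  settings = fitSettings(restarts = 3, maxit = 80, seed = 2))
  expect_true(all(diff(fitTrace(fit)) <= 0))
  expect_gt(length(fitTrace(fit)), 50L)
})

test_that("fit results satisfy the AIC identity and objective ordering", {
  combo <- parseCombo("a3b2c2")
  ds <- makeDataset(noise = 0.1, seed = 6)
  fit <- fitModel(combo, ds, free = c("gamma_OB", "delta_D"),
                  objective = "J2",
                  settings = fitSettings(restarts = 1, maxit = 80, seed = 1))
  expect_gte(fit@J2, fit@Jinf)
  expect_identical(fit@AIC_J2, 2 * fit@p + 2 * fit@J2)
  expect_identical(fit@AIC_Jinf, 2 * fit@p + 2 * fit@Jinf)
  expect_gte(fit@AIC_J2, fit@AIC_Jinf)
  expect_true(fit@nBelowOne >= 0L && fit@nBelowOne <= 40L)
})

test_that("a noiseless two-parameter problem is recovered accurately", {
  combo <- parseCombo("a3b2c2")
  truth <- defaultParameters(combo)
  ds <- makeDataset(noise = 0.05, seed = 1)
  fit <- fitModel(combo, ds, free = c("gamma_OB", "delta_D"),
                  settings = fitSettings(restarts = 3, maxit = 400,
                                         seed = 1))
  est <- parameterValues(fit)[c("gamma_OB", "delta_D")]
  tru <- parameterValues(truth)[c("gamma_OB", "delta_D")]
  expect_true(all(abs(est - tru) / tru < 0.25))
})

test_that("rankModels sorts by AIC with the documented tie-breaks", {
  ds <- makeDataset(noise = 0.1, seed = 7)
  mk <- function(nm, seed) {
    cb <- parseCombo(nm)
    fitModel(cb, ds, params = defaultParameters(cb), free = character(0),
             settings = fitSettings(restarts = 1, maxit = 1, seed = seed))
  }
  fits <- list(mk("a3b2c2", 1), mk("a1b1c1", 1), mk("a2b1c3", 1))
  rk <- rankModels(fits)
  expect_equal(nrow(rk), 3L)
  expect_true(!is.unsorted(rk$AIC_Jinf))
  ## duplicate combos are rejected
  expect_error(rankModels(list(mk("a3b2c2", 1), mk("a3b2c2", 2))),
               "duplicate")
  ## tie-break: equal AICs rank by descending within-error-bar count
  f1 <- fits[[1]]; f2 <- fits[[2]]
  f2@J2 <- f1@J2; f2@Jinf <- f1@Jinf
  f2@p <- f1@p
  f2@AIC_J2 <- f1@AIC_J2; f2@AIC_Jinf <- f1@AIC_Jinf
  f1@nBelowOne <- 25L; f2@nBelowOne <- 15L
  rk2 <- rankModels(list(f2, f1))
  expect_equal(rk2$combo[1], "a3b2c2")
  expect_equal(rk2$n_below_one, c(25L, 15L))
})

test_that("ranking tables round-trip to tab-separated files", {
  ds <- makeDataset(noise = 0.1, seed = 8)
  cb <- parseCombo("a3b2c2")
  fit <- fitModel(cb, ds, free = character(0),
                  settings = fitSettings(restarts = 1, maxit = 1, seed = 1))
  rk <- rankModels(list(fit))
  path <- tempfile(fileext = ".tsv")
  writeRanking(rk, path)
  back <- utils::read.delim(path)
  expect_equal(back$combo, rk$combo)
  expect_equal(back$AIC_Jinf, rk$AIC_Jinf, tolerance = 1e-12)
})
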