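## Independent literal re-transcription of the nine model equations and the
## hypothesis functional forms, written directly from their printed algebraic
## form with no shared code with the package internals. Used as the
## cross-check oracle for evaluateRHS and the integrators.

oracleRHS <- function(state, pars, a, b, cc) {
  Mo <- state[["Mo"]]; M <- state[["M"]]; M1 <- state[["M1"]]
  M2 <- state[["M2"]]; Mo1 <- state[["Mo1"]]; OB <- state[["OB"]]
  OC <- state[["OC"]]; B <- state[["B"]]; D <- state[["D"]]

  ## polarization block
  if (cc == 1) {
    p1 <- pars[["p_11"]] * D + pars[["p_12"]] * D * (M1 + Mo1)
    depol1 <- pars[["depol_1"]] * M2
    p21 <- 0
    p22 <- pars[["p_2"]] * D
    depol21 <- pars[["depol_2"]]
    depol22 <- 0
    p3 <- pars[["p_31"]] * D + pars[["p_32"]] * D * (M1 + Mo1)
    depol3 <- pars[["depol_3"]] * M2
  }
  if (cc == 2) {
    p1 <- pars[["p_11"]] * D + pars[["p_12"]] * D * (M1 + Mo1)
    depol1 <- pars[["depol_1"]] * M2
    p21 <- pars[["p_2"]] * (M1 + Mo1)
    p22 <- 0
    depol21 <- pars[["depol_2"]]
    depol22 <- 0
    p3 <- pars[["p_31"]] * D + pars[["p_32"]] * D * (M1 + Mo1)
    depol3 <- pars[["depol_3"]] * M2
  }
  if (cc == 3) {
    p1 <- pars[["p_11"]] * D
    depol1 <- 0
    p21 <- 0
    p22 <- pars[["p_2"]] * D
    depol21 <- 0
    depol22 <- pars[["depol_2"]]
    p3 <- pars[["p_32"]] * M1
    depol3 <- pars[["depol_3"]]
  }

  ## osteoclast regulation block
  if (a == 1) {
    dOC <- (pars[["d_OC"]] + pars[["d_OC2"]] * (M1 + Mo1)) /
      (1 + pars[["Inhib_OC"]] * M2)
    deltaOC <- pars[["delta_OC"]] * (1 + pars[["Inhib_OC2"]] * M2)
  }
  if (a == 2) {
    dOC <- (pars[["d_OC"]] + pars[["d_OC2"]] * (M1 + Mo1)) /
      (1 + pars[["Inhib_OC"]] * OB)
    deltaOC <- pars[["delta_OC"]] * (1 + pars[["Inhib_OC2"]] * OB)
  }
  if (a == 3) {
    dOC <- pars[["d_OC"]] * OB / (1 + pars[["Inhib_OC"]] * M2)
    deltaOC <- pars[["delta_OC"]] * (1 + pars[["Inhib_OC2"]] * M2)
  }

  ## osteoblast expansion block
  gOB <- if (b == 1) pars[["gamma_OB"]] * M2 else pars[["gamma_OB"]] * D

  c(Mo = pars[["H_Mo"]] - pars[["delta_Mo"]] * Mo +
      pars[["I_1"]] * (M1 + Mo1) + pars[["I_2"]] * D - p3 * Mo +
      depol3 * Mo1,
    M = pars[["H_M"]] - pars[["delta_M"]] * M - dOC * M - p1 * M -
      p21 * M + depol1 * M1 + depol21 * M2,
    M1 = p1 * M - depol1 * M1 - p22 * M1 + depol22 * M2 -
      pars[["delta_M"]] * M1,
    M2 = p21 * M + p22 * M1 - depol21 * M2 - depol22 * M2 -
      pars[["delta_M"]] * M2,
    Mo1 = p3 * Mo - depol3 * Mo1 - pars[["delta_Mo"]] * Mo1,
    OB = pars[["H_OB"]] * OC + gOB - pars[["delta_OB"]] * OB * B,
    OC = dOC * M - deltaOC * OC,
    B = pars[["Pi_B"]] * (1 + pars[["beta"]] * M2) * OB -
      pars[["delta_B"]] * (1 + pars[["alpha"]] * (M1 + Mo1)) * OC * B,
    D = -pars[["delta_D"]] * (M1 + Mo1) * D)
}

## Hand-rolled classical RK4 on the oracle RHS (independent of deSolve).
oracleRK4 <- function(initial, pars, a, b, cc, tEnd, dt) {
  nSteps <- round(tEnd / dt)
  y <- initial
  out <- matrix(NA_real_, nSteps + 1, length(initial),
                dimnames = list(NULL, names(initial)))
  tGrid <- numeric(nSteps + 1)
  out[1, ] <- y
  for (k in seq_len(nSteps)) {
    k1 <- oracleRHS(y, pars, a, b, cc)
    k2 <- oracleRHS(y + dt / 2 * k1, pars, a, b, cc)
    k3 <- oracleRHS(y + dt / 2 * k2, pars, a, b, cc)
    k4 <- oracleRHS(y + dt * k3, pars, a, b, cc)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1, ] <- y
    tGrid[k + 1] <- k * dt
  }
  list(time = tGrid, states = out)
}

## Relative difference between two trajectories, per variable scaled by the
## variable's dynamic range (plain relative error is meaningless for
## populations passing through zero).
trajRelErr <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  scales <- pmax(apply(abs(b), 2, max), 1e-12)
  max(abs(a - b) / rep(scales, each = nrow(a)))
}

## Small synthetic dataset used across fitting tests.
makeDataset <- function(noise = 0.1, seed = 1, combo = parseCombo("a3b2c2")) {
  suppressWarnings(generateReplicates(
    combo, defaultParameters(combo),
    design = studyDesign(noise = noise), seed = seed))
}
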