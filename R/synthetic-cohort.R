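## Paired-cohort simulation: per-ligament random effects on the mechanical
## and uptake truths, a damage effect applied to the damaged member of each
## pair, and per-subsample diffusion series for both contrast agents.

lnorm1 <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s <- sqrt(log(1 + cv^2))
  mean * exp(rnorm(n, -s^2 / 2, s))
}

#' Default between-ligament coefficients of variation
#'
#' Spreads matching the healthy-group dispersion of the study conditions
#' (sd/mean of each parameter).
#'
#' @return named list of CVs.
#' @export
defaultCohortCV <- function() {
  list(E = 26.67 / 70.10, ratioPE = 0.32 / 1.80, A1 = 0.33 / 0.88,
       theta1 = 0.78 / 2.56, A2 = 0.18 / 0.49, theta2 = 14.35 / 137.18,
       gamma = 0.63 / 4.13, yieldStrain = 0.01 / 0.12,
       residualStrain = 0.01 / 0.04, damage = 0.11 / 0.82)
}

#' Default damage effect applied to the damaged member of each pair
#'
#' The stress scale factor `1 - d` defaults to the damaged/healthy modulus
#' ratio 22.13 / 70.10 (a 68% reduction); the residual strain to 0.04. The
#' contrast-agent uptake multiplier is 1 (no group effect on partition).
#'
#' @param d damage fraction in `[0, 1)`.
#' @param residualStrain residual strain after overstrain.
#' @param cectMultiplier multiplier on the damaged member's Pmax.
#' @return named list.
#' @export
defaultDamageEffect <- function(d = 1 - 22.13 / 70.10, residualStrain = 0.04,
                                cectMultiplier = 1) {
  list(d = d, residualStrain = residualStrain,
       cectMultiplier = cectMultiplier)
}

#' Simulate a paired control/damaged cohort with known ground truth
#'
#' Each ligament contributes one control and one damaged subsample. Ligament
#' truths are drawn as lognormal random effects around `controlTruth` with
#' the CVs of `cohortCV`; the damaged member's post-overstrain response is
#' scaled by `1 - d` with the given residual strain. Per subsample and agent
#' a bulk diffusion series is drawn around the agent's uptake truth
#' (ligament-level and subsample-level lognormal effects) with additive
#' partition noise.
#'
#' @param nLigaments number of ligaments (>= 2); the first six are labeled
#'   ACL, the remainder PCL.
#' @param controlTruth a [MechGroundTruth-class] of healthy-group means.
#' @param damageEffect list from [defaultDamageEffect()]; `d = 0` with zero
#'   residual strain gives a null cohort (paired differences have zero mean
#'   by construction).
#' @param cohortCV list from [defaultCohortCV()].
#' @param mechNoiseSd stress noise sd (MPa) on the traces (default 2% of the
#'   healthy peak relaxation stress).
#' @param partitionNoiseSd partition noise sd per timepoint.
#' @param seed RNG seed; the cohort is a pure function of its arguments.
#' @param precondBlocks preconditioning blocks per trace (protocol constant;
#'   lower it to shrink traces in simulation studies).
#' @return a [StudyTable-class]; `@groundTruth` holds `mechParams` (one row
#'   per subsample of true reported-state parameters), `uptake` (true Pmax
#'   and tau per subsample x agent) and `mechTruths` (completed
#'   [MechGroundTruth-class] per sample).
#' @export
genCohort <- function(nLigaments = 11, controlTruth = defaultMechTruth(),
                      damageEffect = defaultDamageEffect(),
                      cohortCV = defaultCohortCV(),
                      mechNoiseSd = 0.02 * (controlTruth@sigmaEq +
                                              controlTruth@A1 + controlTruth@A2),
                      partitionNoiseSd = 0.03, seed = 1,
                      precondBlocks = 5) {
  stopIfNot(nLigaments >= 2, "need at least 2 ligaments")
  withSeed(seed, {
    mech <- list(); diffusion <- list()
    rows <- list(); truthRows <- list(); uptakeRows <- list(); mechTruths <- list()
    agents <- c("iodixanol", "Ta2O5-cNP")
    for (i in seq_len(nLigaments)) {
      lig <- sprintf("L%02d", i)
      type <- if (i <= 6) "ACL" else "PCL"
      cv <- cohortCV
      ratio <- max(1.05, lnorm1(1, 1.80, cv$ratioPE))
      A1 <- lnorm1(1, controlTruth@A1, cv$A1)
      A2 <- lnorm1(1, controlTruth@A2, cv$A2)
      th1 <- lnorm1(1, controlTruth@theta1, cv$theta1)
      th2 <- max(th1 * 4, lnorm1(1, controlTruth@theta2, cv$theta2))
      gam <- pmin(89, pmax(0.5, lnorm1(4, 1, cv$gamma) * controlTruth@gammaDeg))
      names(gam) <- names(controlTruth@gammaDeg)
      d_i <- min(0.95, max(0.05, lnorm1(1, damageEffect$d,
                                        if (damageEffect$d > 0) cv$damage else 0)))
      ligTruth <- defaultMechTruth(
        E = lnorm1(1, controlTruth@E, cv$E),
        sigmaEq = A1 + A2, A1 = A1, theta1 = th1, A2 = A2, theta2 = th2,
        gammaDeg = gam,
        yieldStrain = min(0.15, max(0.09, lnorm1(1, controlTruth@yieldStrain,
                                                 cv$yieldStrain))),
        damageFraction = if (damageEffect$d > 0) d_i else 0,
        residualStrain = if (damageEffect$residualStrain > 0)
          lnorm1(1, damageEffect$residualStrain, cv$residualStrain) else 0)
      ligTruth@sigmaEq <- (A1 + A2) / (ratio - 1)
      ligZ <- rnorm(2)  # ligament-level uptake effect, one per agent

      for (grp in c("control", "damaged")) {
        sid <- paste0(lig, "_", substr(grp, 1, 1))
        g <- genTensileTest(ligTruth, defaultProtocol(grp,
                                                      precondBlocks = precondBlocks),
                            noiseSd = mechNoiseSd, sampleId = sid)
        mech[[sid]] <- g$test
        mechTruths[[sid]] <- g$truth
        sc <- if (grp == "damaged") 1 - ligTruth@damageFraction else 1
        tr <- g$truth
        truthRows[[sid]] <- data.frame(
          sampleId = sid, ligamentId = lig, group = grp,
          E = sc * tr@E, ratioPE = ratio, A1 = sc * tr@A1, theta1 = tr@theta1,
          A2 = sc * tr@A2, theta2 = tr@theta2,
          gamma0.1 = tr@gammaDeg[["0.1"]], gamma0.5 = tr@gammaDeg[["0.5"]],
          gamma1 = tr@gammaDeg[["1"]], gamma2 = tr@gammaDeg[["2"]],
          DSigma = if (grp == "damaged") tr@damageFraction else NA_real_,
          DEpsilon = if (grp == "damaged") tr@damageFraction else NA_real_,
          lambdaEpsilon = if (grp == "damaged") tr@residualStrain else NA_real_,
          yieldStrain = if (grp == "damaged") tr@yieldStrain else NA_real_,
          yieldStress = if (grp == "damaged") tr@yieldStress else NA_real_)
        rows[[sid]] <- data.frame(ligamentId = lig, sampleId = sid,
                                  group = grp, ligamentType = type,
                                  excluded = FALSE)
        for (ai in seq_along(agents)) {
          ag <- agents[ai]
          ut <- agentUptakeTruth(ag)
          sP <- sqrt(log(1 + (ut$PmaxSd / ut$Pmax)^2))
          sT <- sqrt(log(1 + (ut$tauSd / ut$tauH)^2))
          Pm <- ut$Pmax * exp(0.8 * sP * ligZ[ai] + 0.6 * sP * rnorm(1) -
                                sP^2 / 2)
          if (grp == "damaged") Pm <- Pm * damageEffect$cectMultiplier
          ta <- ut$tauH * exp(sT * rnorm(1) - sT^2 / 2)
          key <- paste0(sid, ".", ag)
          diffusion[[key]] <- genDiffusionSeries(Pm, ta, agentTimepoints(ag),
                                                 noiseSd = partitionNoiseSd,
                                                 agent = ag, sampleId = sid)
          uptakeRows[[key]] <- data.frame(sampleId = sid, ligamentId = lig,
                                          group = grp, agent = ag,
                                          PmaxTrue = Pm, tauTrueH = ta)
        }
      }
    }
    st <- new("StudyTable",
              table = do.call(rbind, unname(rows)),
              mech = mech, diffusion = diffusion,
              groundTruth = list(mechParams = do.call(rbind, unname(truthRows)),
                                 uptake = do.call(rbind, unname(uptakeRows)),
                                 mechTruths = mechTruths))
    validObject(st)
    st
  })
}
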