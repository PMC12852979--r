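#' Cross-sectional area of an elliptical sample
#'
#' `area = pi * width * thickness / 4` (mm^2), the standard assumption for
#' dumbbell-cut ligament cross-sections measured by width and thickness.
#'
#' @param widthMm,thicknessMm positive axis lengths in mm.
#' @return area in mm^2.
#' @export
ellipticalArea <- function(widthMm, thicknessMm) {
  stopIfNot(all(widthMm > 0) && all(thicknessMm > 0),
            "width and thickness must be positive")
  unname(pi * widthMm * thicknessMm / 4)
}

#' Convert a tensile trace to a stress-strain series
#'
#' Stress = force / elliptical area (N/mm^2 = MPa); strain =
#' (length - zeroLoadLength) / zeroLoadLength with length = clamp length +
#' displacement. Each sample is labeled with its protocol segment.
#'
#' @param test a [TensileTest-class].
#' @param zeroLoadLength reference length in mm (from [zeroLoadLength()]).
#' @return data.frame with columns `time`, `strain`, `stress`, `segment`.
#' @export
toStressStrain <- function(test, zeroLoadLength) {
  stopIfNot(zeroLoadLength > 0, "zeroLoadLength must be positive")
  g <- geometry(test)
  area <- ellipticalArea(g["width"], g["thickness"])
  tr <- traceData(test)
  L <- g[["clampLength"]] + tr$displacement
  sg <- segmentMap(test)
  lab <- rep(NA_character_, nrow(tr))
  for (i in seq_len(nrow(sg))) {
    sel <- tr$time > sg$tStart[i] - 1e-9 & tr$time <= sg$tEnd[i] + 1e-9
    lab[sel & is.na(lab)] <- sg$label[i]
  }
  data.frame(time = tr$time, strain = (L - zeroLoadLength) / zeroLoadLength,
             stress = tr$force / area, segment = lab)
}

## Extract one labeled segment, with time rebased to the segment boundary.
segmentSlice <- function(sss, test, label) {
  sg <- segmentMap(test)
  i <- match(label, sg$label)
  stopIfNot(!is.na(i), "segment '%s' not present", label)
  out <- sss[sss$segment %in% label & !is.na(sss$segment), , drop = FALSE]
  stopIfNot(nrow(out) > 0, "segment '%s' contains no samples", label)
  out$tSeg <- out$time - sg$tStart[i]
  out
}

#' Zero-load length at a preload stress
#'
#' The zero-load (initial) length is defined, as on the testing device, as
#' the clamp-to-clamp length at which the tensile stress first reaches a
#' 0.05 MPa preload during slow loading. The crossing is located on the
#' loading limb and, when enough samples are available, refined by a local
#' quadratic regression of stress on length around the crossing (restricted
#' to stresses below four times the preload); small inputs fall back to
#' linear interpolation between the bracketing samples.
#'
#' @param series data.frame with numeric columns `length` (mm) and `stress`
#'   (MPa), covering a monotone loading that crosses the preload.
#' @param preloadMPa preload stress, default 0.05 MPa.
#' @return zero-load length in mm.
#' @export
findZeroLoadLength <- function(series, preloadMPa = 0.05) {
  stopIfNot(all(c("length", "stress") %in% names(series)),
            "series must have columns length and stress")
  L <- series$length; s <- series$stress
  stopIfNot(max(s) >= preloadMPa, "preload %.3g MPa never reached", preloadMPa)
  i <- which(s >= preloadMPa)[1]
  if (s[i] == preloadMPa && length(L) < 12) return(L[i])
  if (i == 1L) return(L[1])
  interp <- L[i - 1] + (preloadMPa - s[i - 1]) * (L[i] - L[i - 1]) / (s[i] - s[i - 1])
  if (length(L) < 12) return(interp)
  sel <- which(s <= 4 * preloadMPa)
  if (length(sel) < 12) return(interp)
  x <- L[sel] - L[i]
  fit <- lm(s[sel] ~ x + I(x^2))
  cf <- coef(fit)
  a <- cf[3]; b <- cf[2]; cc <- cf[1] - preloadMPa
  roots <- if (is.na(a) || abs(a) < 1e-12 * max(abs(b), 1)) {
    -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(interp)
    c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  roots <- roots[roots >= min(x) - 1e-9 & roots <= max(x) + 1e-9]
  if (!length(roots)) return(interp)
  unname(L[i] + roots[which.min(abs(roots - (interp - L[i])))])
}

#' Zero-load length from a tensile test's re-zeroing segment
#'
#' @param test a [TensileTest-class].
#' @param label segment to use (`"rezero"` or `"rezero_post"`).
#' @param preloadMPa preload stress, MPa.
#' @return length in mm.
#' @export
zeroLoadLength <- function(test, label = "rezero", preloadMPa = 0.05) {
  g <- geometry(test)
  area <- ellipticalArea(g["width"], g["thickness"])
  sg <- segmentMap(test)
  i <- match(label, sg$label)
  stopIfNot(!is.na(i), "segment '%s' not present", label)
  tr <- traceData(test)
  ## the sample sitting exactly on the left boundary belongs to the previous
  ## segment (and, after damage, to the previous strain reference)
  eps <- if (i == 1L) -1e-9 else 1e-9
  sel <- tr$time > sg$tStart[i] + eps & tr$time <= sg$tEnd[i] + 1e-9
  L <- g[["clampLength"]] + tr$displacement[sel]
  s <- tr$force[sel] / area
  up <- seq_len(which.max(L))  # loading limb only
  findZeroLoadLength(data.frame(length = L[up], stress = s[up]), preloadMPa)
}

#' Young's modulus over the linear region of the 8% ramp
#'
#' Least-squares slope of stress versus strain over the strain window
#' (default 4-8%, which excludes the toe region).
#'
#' @param ramp stress-strain data.frame (columns `strain`, `stress`) covering
#'   the ramp.
#' @param window strain interval used for the fit.
#' @return a [ModulusResult-class]; `lowQuality` is set when R^2 < 0.5.
#' @export
computeYoungModulus <- function(ramp, window = c(0.04, 0.08)) {
  sel <- ramp$strain >= window[1] & ramp$strain <= window[2]
  stopIfNot(sum(sel) >= 10, "modulus window contains %d (<10) samples", sum(sel))
  fit <- lm(stress ~ strain, data = ramp[sel, ])
  r2 <- summary(fit)$r.squared
  new("ModulusResult", E = unname(coef(fit)[2]), fitWindow = window,
      rSquared = r2, lowQuality = r2 < 0.5)
}

#' Two-exponential (Prony) stress-relaxation fit
#'
#' Nonlinear least squares for
#' `sigma(t) = sigmaEq + A1 exp(-t/theta1) + A2 exp(-t/theta2)` with t = 0 at
#' the ramp end. Amplitudes are bounded below by zero; fitting is multi-start
#' (a data-driven start, then a grid theta1 in {1, 3, 10} s x theta2 in
#' {60, 120, 300} s) and the fast/slow ordering theta1 < theta2 is enforced
#' by a post-fit swap. A constant trace returns a degenerate fit (amplitudes
#' zero, time constants at initializer defaults); when the fitted A2 is
#' negligible the slow time constant is flagged unidentifiable.
#'
#' @param hold data.frame with columns `tSeg` (s, 0 at ramp end) and `stress`
#'   (MPa), e.g. from a 600 s relaxation hold.
#' @return a [RelaxationFit-class].
#' @export
fitRelaxation <- function(hold) {
  t <- hold$tSeg; y <- hold$stress
  stopIfNot(length(t) >= 10, "relaxation hold has too few samples")
  if (diff(range(y)) < 1e-10 * max(abs(y), 1)) {
    se <- mean(y)
    return(new("RelaxationFit", sigmaEq = se, A1 = 0, theta1 = 1, A2 = 0,
               theta2 = 100, ratioPE = 1, rmse = 0, degenerate = TRUE,
               theta2Unidentifiable = TRUE))
  }
  seTail <- mean(y[t >= quantile(t, 0.9)])
  Atot <- max(y[which.min(t)] - seTail, 1e-6)
  starts <- c(list(c(th1 = 2, th2 = 100)),
              lapply(seq_len(9), function(k) {
                c(th1 = c(1, 3, 10)[(k - 1) %% 3 + 1],
                  th2 = c(60, 120, 300)[(k - 1) %/% 3 + 1])
              }))
  best <- NULL; tried <- character(0)
  dat <- data.frame(t = t, y = y)
  for (st in starts) {
    tried <- c(tried, sprintf("theta1=%g,theta2=%g", st["th1"], st["th2"]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ se + a1 * exp(-t / th1) + a2 * exp(-t / th2), data = dat,
        start = list(se = seTail, a1 = 0.6 * Atot, a2 = 0.4 * Atot,
                     th1 = unname(st["th1"]), th2 = unname(st["th2"])),
        lower = c(se = -Inf, a1 = 0, a2 = 0, th1 = 1e-3, th2 = 1e-2),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(resid(fit)^2)
      if (is.null(best) || ssr < best$ssr - 1e-15) best <- list(fit = fit, ssr = ssr)
      if (ssr < 1e-16 * length(y)) break
    }
  }
  stopIfNot(!is.null(best), "relaxation fit did not converge (starts tried: %s)",
            paste(tried, collapse = "; "))
  cf <- coef(best$fit)
  a1 <- cf["a1"]; a2 <- cf["a2"]; th1 <- cf["th1"]; th2 <- cf["th2"]
  if (th1 > th2) { tmp <- a1; a1 <- a2; a2 <- tmp; tmp <- th1; th1 <- th2; th2 <- tmp }
  se <- cf["se"]
  scaleRef <- max(abs(se), a1 + a2, 1e-3)
  new("RelaxationFit", sigmaEq = unname(se), A1 = unname(a1),
      theta1 = unname(th1), A2 = unname(a2), theta2 = unname(th2),
      ratioPE = if (se > 0) unname((se + a1 + a2) / se) else 1,
      rmse = rmseOf(y, fitted(best$fit)),
      degenerate = FALSE,
      theta2Unidentifiable = unname(a2 < 1e-4 * scaleRef))
}

#' Phase shift from a sinusoidal loading segment
#'
#' Strain and stress are each fit to `a + b sin(2 pi f t) + c cos(2 pi f t)`
#' by linear least squares (first cycle discarded as transient); the phase
#' shift is `gamma = phase(strain) - phase(stress)`, i.e. the lag of stress
#' behind strain, wrapped to (-90, 90) degrees. Invariant to time origin and
#' additive stress offset.
#'
#' @param segment data.frame with columns `tSeg` (s), `strain`, `stress`.
#' @param frequencyHz loading frequency in Hz.
#' @return a [SinusoidFit-class].
#' @export
fitSinusoidPhase <- function(segment, frequencyHz) {
  t <- segment$tSeg
  nCyc <- diff(range(t)) * frequencyHz
  stopIfNot(nCyc >= 5 - 1e-6,
            "only %.2f cycles at %g Hz (need >= 5)", nCyc, frequencyHz)
  keep <- t - t[1] >= 1 / frequencyHz  # discard transient first cycle
  t <- t[keep]
  w <- 2 * pi * frequencyHz
  X <- cbind(1, sin(w * t), cos(w * t))
  phaseOf <- function(y) {
    cf <- stats::lm.fit(X, y)$coefficients
    list(phi = atan2(cf[3], cf[2]), R = sqrt(cf[2]^2 + cf[3]^2),
         res = y - X %*% cf)
  }
  fe <- phaseOf(segment$strain[keep])
  fs <- phaseOf(segment$stress[keep])
  gam <- wrapHalf((fe$phi - fs$phi) * 180 / pi)
  tss <- sum((segment$stress[keep] - mean(segment$stress[keep]))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - sum(fs$res^2) / tss)) else 1
  new("SinusoidFit", frequencyHz = frequencyHz, stressAmplitude = unname(fs$R),
      gammaDeg = unname(gam), rSquared = r2)
}

## Rolling tangent modulus over a strain window, by local least squares.
tangentModulus <- function(strain, stress, window) {
  n <- length(strain)
  k <- max(5L, round(window / max(diff(range(strain)), 1e-12) * n))
  half <- k %/% 2
  slope <- rep(NA_real_, n)
  cx <- c(0, cumsum(strain)); cy <- c(0, cumsum(stress))
  cxx <- c(0, cumsum(strain^2)); cxy <- c(0, cumsum(strain * stress))
  for (i in (half + 1):(n - half)) {
    a <- i - half; b <- i + half; m <- b - a + 1
    sx <- cx[b + 1] - cx[a]; sy <- cy[b + 1] - cy[a]
    sxx <- cxx[b + 1] - cxx[a]; sxy <- cxy[b + 1] - cxy[a]
    den <- m * sxx - sx^2
    if (den > 0) slope[i] <- (m * sxy - sx * sy) / den
  }
  slope
}

#' Yield point on the 16% overstrain ramp
#'
#' The yield point is the first strain at which the tangent modulus (local
#' least-squares slope over a moving 1% strain window) falls below a fraction
#' (default 70%) of the pre-damage linear modulus. The crossing is then
#' refined by fitting a continuous two-line hinge
#' `stress = a + b strain + c max(0, strain - breakpoint)` in a neighbourhood
#' of the coarse estimate and reporting the optimal breakpoint; for a
#' noiseless bilinear curve this recovers the kink exactly.
#'
#' @param ramp16 stress-strain data.frame of the overstrain ramp (strain
#'   relative to the pre-damage zero-load length).
#' @param ELinear pre-damage linear-region modulus, MPa.
#' @param threshold tangent-drop fraction (default 0.7).
#' @param window tangent window in strain units (default 0.01).
#' @return list with `yieldStrain`, `yieldStress`, `noYield`.
#' @export
detectYield <- function(ramp16, ELinear, threshold = 0.7, window = 0.01) {
  o <- order(ramp16$strain)
  eps <- ramp16$strain[o]; sig <- ramp16$stress[o]
  tan <- tangentModulus(eps, sig, window)
  below <- which(!is.na(tan) & tan < threshold * ELinear)
  if (!length(below))
    return(list(yieldStrain = NA_real_, yieldStress = NA_real_, noYield = TRUE))
  coarse <- eps[below[1]]
  lo <- max(min(eps), coarse - 3 * window)
  hi <- min(max(eps), coarse + 3 * window)
  sel <- eps >= lo & eps <= hi
  x <- eps[sel]; y <- sig[sel]
  rss <- function(brk) {
    X <- cbind(1, x, pmax(0, x - brk))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  opt <- optimize(rss, lower = lo + window / 4, upper = hi - window / 4,
                  tol = 1e-10)
  brk <- opt$minimum
  cf <- stats::lm.fit(cbind(1, x, pmax(0, x - brk)), y)$coefficients
  list(yieldStrain = unname(brk), yieldStress = unname(cf[1] + cf[2] * brk),
       noYield = FALSE)
}

#' Damage parameters from paired pre- and post-overstrain relaxation tests
#'
#' `D_sigma = 1 - sigma_peak,post / sigma_peak,pre` (peak = fitted sigma at
#' t = 0), `D_epsilon = 1 - sigma_eq,post / sigma_eq,pre`, and
#' `lambda_epsilon = (L0_post - L0_pre) / L0_pre`, the residual strain from
#' the shift of the preload-determined zero-load length. These conventions
#' are configuration points, not universal definitions.
#'
#' @param preFit,postFit [RelaxationFit-class] objects from the 8% relaxation
#'   before and after the overstrain.
#' @param zeroLoadPre,zeroLoadPost zero-load lengths in mm.
#' @param yield optional list from [detectYield()].
#' @return a [DamageMetrics-class].
#' @export
damageParameters <- function(preFit, postFit, zeroLoadPre, zeroLoadPost,
                             yield = NULL) {
  peak <- function(f) f@sigmaEq + f@A1 + f@A2
  ds <- 1 - peak(postFit) / peak(preFit)
  de <- 1 - postFit@sigmaEq / preFit@sigmaEq
  lam <- (zeroLoadPost - zeroLoadPre) / zeroLoadPre
  if (is.null(yield))
    yield <- list(yieldStrain = NA_real_, yieldStress = NA_real_, noYield = FALSE)
  new("DamageMetrics", DSigma = ds, DEpsilon = de, lambdaEpsilon = lam,
      yieldStrain = yield$yieldStrain, yieldStress = yield$yieldStress,
      noYield = isTRUE(yield$noYield))
}

#' Full biomechanical analysis of one tensile test
#'
#' Runs the complete extraction: zero-load length, Young's modulus,
#' relaxation fit and per-frequency phase shifts; for damaged-group tests
#' additionally the post-damage repeats, the yield point on the 16% ramp and
#' the damage parameters.
#'
#' @param test a [TensileTest-class].
#' @param preloadMPa preload for zero-load length determination.
#' @param modulusWindow strain window for the modulus fit.
#' @param yieldThreshold,yieldWindow see [detectYield()].
#' @return named list: `zeroLoadLength`, `modulus`, `relaxation`, `sinusoid`
#'   (list by frequency), and for damaged tests `post` (same structure) plus
#'   `damage` (a [DamageMetrics-class]).
#' @export
analyzeTensileTest <- function(test, preloadMPa = 0.05,
                               modulusWindow = c(0.04, 0.08),
                               yieldThreshold = 0.7, yieldWindow = 0.01) {
  sg <- segmentMap(test)
  L0 <- zeroLoadLength(test, "rezero", preloadMPa)
  sss <- toStressStrain(test, L0)
  freqs <- sub("^sinusoid@", "", grep("^sinusoid@", sg$label, value = TRUE))
  out <- list(zeroLoadLength = L0,
              modulus = computeYoungModulus(segmentSlice(sss, test, "ramp8"),
                                            modulusWindow),
              relaxation = fitRelaxation(segmentSlice(sss, test, "hold8")))
  out$sinusoid <- lapply(setNames(freqs, freqs), function(f)
    fitSinusoidPhase(segmentSlice(sss, test, paste0("sinusoid@", f)),
                     as.numeric(f)))
  if (sampleGroup(test) == "damaged") {
    L0p <- zeroLoadLength(test, "rezero_post", preloadMPa)
    sssPost <- toStressStrain(test, L0p)
    post <- list(zeroLoadLength = L0p,
                 modulus = computeYoungModulus(
                   segmentSlice(sssPost, test, "ramp8_post"), modulusWindow),
                 relaxation = fitRelaxation(
                   segmentSlice(sssPost, test, "hold8_post")))
    post$sinusoid <- lapply(setNames(freqs, freqs), function(f)
      fitSinusoidPhase(segmentSlice(sssPost, test, paste0("sinusoid_post@", f)),
                       as.numeric(f)))
    out$post <- post
    yld <- detectYield(segmentSlice(sss, test, "ramp16"), out$modulus@E,
                       yieldThreshold, yieldWindow)
    out$damage <- damageParameters(out$relaxation, post$relaxation, L0, L0p,
                                   yield = yld)
  }
  out
}

#' Flatten a tensile-test analysis into one parameter row
#'
#' For damaged-group tests the reported viscoelastic parameters are the
#' post-damage values (the state the imaging sees), matching how damaged and
#' control groups are compared.
#'
#' @param analysis result of [analyzeTensileTest()].
#' @param sampleId,group identifiers for the row.
#' @return one-row data.frame of biomechanical parameters.
#' @export
biomechRow <- function(analysis, sampleId = NA_character_,
                       group = NA_character_) {
  a <- if (!is.null(analysis$post)) analysis$post else analysis
  rx <- a$relaxation
  row <- data.frame(sampleId = sampleId, group = group,
                    E = a$modulus@E, ratioPE = rx@ratioPE, A1 = rx@A1,
                    theta1 = rx@theta1, A2 = rx@A2, theta2 = rx@theta2)
  for (f in names(a$sinusoid))
    row[[paste0("gamma", f)]] <- a$sinusoid[[f]]@gammaDeg
  dm <- analysis$damage
  row$DSigma <- if (is.null(dm)) NA_real_ else dm@DSigma
  row$DEpsilon <- if (is.null(dm)) NA_real_ else dm@DEpsilon
  row$lambdaEpsilon <- if (is.null(dm)) NA_real_ else dm@lambdaEpsilon
  row$yieldStrain <- if (is.null(dm)) NA_real_ else dm@yieldStrain
  row$yieldStress <- if (is.null(dm)) NA_real_ else dm@yieldStress
  row
}
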