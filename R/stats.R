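## Exact distribution of the positive-rank sum W+ under the symmetric null,
## by dynamic programming over doubled ranks (average ranks for ties make
## 2 * rank integral). Returns probabilities over support 0 .. sum(2r).
signedRankNullPMF <- function(ranks2) {
  S <- sum(ranks2)
  pmf <- numeric(S + 1L)
  pmf[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), pmf[seq_len(S + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetric zero-median paired differences. Zero
#' differences are dropped; ties receive average ranks. For n <= 25 retained
#' pairs the p-value is exact — the null distribution of the positive-rank
#' sum is enumerated over all 2^n sign assignments (computed by dynamic
#' programming, identical to full enumeration) and the two-sided p is
#' `min(1, 2 min(P(W <= w), P(W >= w)))`; beyond n = 25 a normal
#' approximation with tie correction is used.
#'
#' @param x,y paired measurements (e.g. control and damaged values per
#'   ligament); alternatively supply differences via `x` with `y = 0`.
#' @param parameter label carried on the result.
#' @return list of class `PairedComparison` fields: `parameter`, `pairs`,
#'   `W` (positive-rank sum of x - y), `pValue`, `n` (retained pairs),
#'   `exact`, `underpowered` (n < 5).
#' @export
wilcoxonSignedRank <- function(x, y = 0, parameter = NA_character_) {
  stopIfNot(length(y) == 1 || length(y) == length(x),
            "x and y lengths differ")
  d <- x - y
  d <- d[!is.na(d)]
  keep <- d != 0
  stopIfNot(any(keep), "all paired differences are zero")
  d <- d[keep]
  n <- length(d)
  r <- rank(abs(d))  # average ranks for ties
  W <- sum(r[d > 0])
  if (n <= 25) {
    pmf <- signedRankNullPMF(as.integer(round(2 * r)))
    w2 <- as.integer(round(2 * W))
    lo <- sum(pmf[seq_len(w2 + 1L)])           # P(W+ <= w)
    hi <- sum(pmf[(w2 + 1L):length(pmf)])      # P(W+ >= w)
    p <- min(1, 2 * min(lo, hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tieAdj <- sum(tapply(r, r, length)^3 - tapply(r, r, length)) / 48
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tieAdj)
    p <- min(1, 2 * stats::pnorm(-abs(W - mu) / sig))
    exact <- FALSE
  }
  if (n < 5) warning(sprintf("only %d non-zero differences: underpowered", n))
  structure(list(parameter = parameter,
                 pairs = if (length(y) == length(x)) cbind(x, y) else cbind(d),
                 W = W, pValue = p, n = n, exact = exact,
                 underpowered = n < 5),
            class = "PairedComparison")
}

#' @export
print.PairedComparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.4g%s\n",
              x$parameter, x$W, x$n, x$pValue,
              if (x$exact) " (exact)" else " (normal approx.)"))
  invisible(x)
}

## All permutations of seq_len(n), one per row (n <= 8 in practice).
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of average ranks. For n <= 8 the two-sided
#' p-value is exact by full enumeration of the n! rank permutations
#' (`P(|rho_perm| >= |rho_obs|)`); for larger n the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` is used. Invariant to strictly monotone
#' transforms of either input.
#'
#' @param x,y equal-length numeric vectors (n >= 4, non-constant).
#' @param xName,yName,pooling labels carried on the result.
#' @return list of class `CorrelationResult`: `x`, `y`, `rho`, `pValue`,
#'   `n`, `pooling`, `exact`, `significant` (p < 0.05).
#' @export
spearmanCorrelation <- function(x, y, xName = "x", yName = "y",
                                pooling = "pooled") {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopIfNot(n >= 4, "need n >= 4 complete pairs (got %d)", n)
  stopIfNot(sd(x) > 0 && sd(y) > 0, "constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- allPermutations(n)
    rxc <- rx - mean(rx)
    den <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    ## rho of each permutation of y against x (sum(rxc) = 0, so no centering
    ## of the permuted ranks is needed in the numerator)
    rhos <- (matrix(ry[perms], nrow(perms)) %*% rxc) / den
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    exact <- FALSE
  }
  structure(list(x = xName, y = yName, rho = rho, pValue = p, n = n,
                 pooling = pooling, exact = exact, significant = p < 0.05),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s (%s): rho = %.3f, n = %d, p = %.4g%s\n",
              x$y, x$x, x$pooling, x$rho, x$n, x$pValue,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen biomechanics against CECT uptake parameters
#'
#' For every biomechanical parameter crossed with {Pmax, tau} and each
#' contrast agent, computes the Spearman correlation with control and
#' damaged groups pooled — except for the damage-specific parameters
#' (D_sigma, D_epsilon, lambda_epsilon, yield strain/stress), which exist
#' only for damaged samples and are correlated within the damaged group
#' only. Significance is declared at p < 0.05 per test (no multiplicity
#' correction by default; set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param biomech data.frame with `sampleId`, `group` and parameter columns
#'   (see [biomechRow()]).
#' @param cect data.frame with `sampleId`, `agent`, `Pmax`, `tauH`.
#' @param damageParams parameter names restricted to the damaged group.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of correlation rows (parameter, cectParameter, agent,
#'   pooling, rho, pValue, n, significant).
#' @export
correlationScreen <- function(biomech, cect,
                              damageParams = c("DSigma", "DEpsilon",
                                               "lambdaEpsilon", "yieldStrain",
                                               "yieldStress"),
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopIfNot(nrow(cect) > 0 && any(cect$sampleId %in% biomech$sampleId),
            "no common sample ids between biomech and cect tables")
  params <- setdiff(names(biomech), c("sampleId", "group"))
  rows <- list()
  for (ag in unique(cect$agent)) {
    sub <- cect[cect$agent == ag, ]
    merged <- merge(biomech, sub, by = "sampleId")
    for (pm in params) {
      pooling <- if (pm %in% damageParams) "damaged-only" else "pooled"
      dat <- if (pooling == "damaged-only")
        merged[merged$group == "damaged", ] else merged
      for (cp in c("Pmax", "tauH")) {
        res <- tryCatch(
          spearmanCorrelation(dat[[pm]], dat[[cp]], xName = pm, yName = cp,
                              pooling = pooling),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pm, cectParameter = cp, agent = ag, pooling = pooling,
          rho = res$rho, pValue = res$pValue, n = res$n,
          significant = res$significant)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH" && !is.null(out)) {
    out$pAdjusted <- stats::p.adjust(out$pValue, "BH")
    out$significant <- out$pAdjusted < 0.05
  }
  out
}
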