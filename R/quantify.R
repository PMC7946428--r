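## Downstream quantification: knock-in efficiency, KI/WT/KO cell
## classification, colocalization slope, and FRAP one-phase-decay fitting.

#' Knock-in efficiency from cell counts
#'
#' Efficiency = 100 * (GFP-positive cells) / (denominator-positive cells).
#' The denominator is mCherry+ transfected cells in culture experiments, or
#' Cas9(HA)+ transduced cells in dual-virus experiments. With per-coverslip
#' vectors the per-coverslip percentages, their mean and SEM are returned.
#'
#' @param nPositive GFP+ counts (scalar or per-coverslip vector).
#' @param nDenominator denominator counts, same length.
#' @return list(percent, perCoverslip, mean, sem); for a single count pair
#'   mean equals percent and sem is NA.
#' @export
kiEfficiency <- function(nPositive, nDenominator) {
  stopifnot(length(nPositive) == length(nDenominator))
  if (any(nDenominator <= 0)) stop("zero denominator")
  pct <- 100 * nPositive / nDenominator
  list(percent = if (length(pct) == 1L) pct else mean(pct),
       perCoverslip = pct,
       mean = mean(pct),
       sem = if (length(pct) > 1L) stats::sd(pct) / sqrt(length(pct))
             else NA_real_)
}

#' Classify transfected cells as KI / WT / KO
#'
#' GFP+ (and mCherry+) cells are KI. Remaining mCherry+ cells are split by
#' their background-subtracted marker immunofluorescence against the
#' whole-image (maxiROI) mean intensity: above the threshold WT, at or below
#' it KO. Fractions are over all mCherry+ cells, so KI + WT + KO = 100%.
#'
#' @param records data.frame with logical columns \code{mcherryPos},
#'   \code{gfpPos} and numeric \code{markerIntensity}.
#' @param maxiroiIntensity the maxiROI threshold (same units as
#'   markerIntensity, >= 0).
#' @return list(counts, fractions, percent) over the mCherry+ population.
#' @export
classifyKiWtKo <- function(records, maxiroiIntensity) {
  stopifnot(maxiroiIntensity >= 0,
            all(c("mcherryPos", "gfpPos", "markerIntensity") %in%
                names(records)))
  r <- records[records$mcherryPos, , drop = FALSE]
  if (!nrow(r)) stop("zero denominator: no mCherry-positive cells")
  intensity <- pmax(r$markerIntensity, 0)
  cls <- ifelse(r$gfpPos, "KI",
                ifelse(intensity > maxiroiIntensity, "WT", "KO"))
  counts <- c(KI = sum(cls == "KI"), WT = sum(cls == "WT"),
              KO = sum(cls == "KO"))
  list(counts = counts, fractions = counts / nrow(r),
       percent = 100 * counts / nrow(r))
}

#' Colocalization slope by simple linear regression
#'
#' Ordinary least-squares fit of signal B on signal A over paired,
#' background-subtracted ROI intensities (e.g. anti-PSD95 on SEP).
#'
#' @param signalA,signalB numeric vectors of equal length (>= 2 ROIs).
#' @return list(slope, intercept, r2, n).
#' @export
colocSlope <- function(signalA, signalB) {
  stopifnot(length(signalA) == length(signalB))
  keep <- complete.cases(signalA, signalB)
  a <- signalA[keep]; b <- signalB[keep]
  if (length(a) < 2L || length(unique(a)) < 2L)
    stop("degenerate ROI intensities: need >= 2 distinct signal A values")
  fit <- lm(b ~ a)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((b - mean(b))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = if (tss > 0) 1 - rss / tss else NA_real_, n = length(a))
}

#' Background-subtract and normalize a FRAP trace
#'
#' The mean of the two background series is subtracted per time point, then
#' the trace is scaled so the pre-bleach mean is 1 and the first post-bleach
#' value is 0.
#'
#' @param t acquisition times (minutes).
#' @param f raw intensities.
#' @param bg1,bg2 two background ROI series, same length as f.
#' @param bleachIndex index of the first post-bleach point.
#' @return a \code{\link{FrapTrace}}.
#' @export
normalizeFrap <- function(t, f, bg1, bg2, bleachIndex) {
  stopifnot(length(f) == length(t), length(bg1) == length(f),
            length(bg2) == length(f))
  sub <- f - (bg1 + bg2) / 2
  pre <- mean(sub[seq_len(bleachIndex - 1L)])
  post0 <- sub[bleachIndex]
  if (pre <= 0 || pre <= post0)
    stop("trace unusable: pre-bleach signal does not exceed background/bleach")
  FrapTrace(t, (sub - post0) / (pre - post0), bleachIndex)
}

#' Fit the one-phase-decay recovery model to a FRAP trace
#'
#' Least-squares fit of f(t') = plateau * (1 - exp(-t'/tau)) over the
#' post-bleach points (t' = time since bleach). Initialisation is
#' deterministic: plateau from the mean of the last two points, tau from the
#' linearly interpolated time to half plateau; bounds tau > 0,
#' plateau in [0, 1.5]. The immobile fraction is 1 - plateau. Fitting uses
#' Levenberg-Marquardt least squares, which also handles the noiseless
#' zero-residual case.
#'
#' @param trace a \code{\link{FrapTrace}}.
#' @return a \code{\link{FrapFit}}.
#' @export
fitFrap <- function(trace) {
  validObject(trace)
  i <- trace@bleachIndex
  tp <- trace@t[i:length(trace@t)] - trace@t[i]
  y <- trace@f[i:length(trace@f)]
  n <- length(y)

  plateau0 <- max(mean(y[(n - 1L):n]), 1e-6)
  if (max(abs(y)) < 1e-9) {       # fully immobile: no recovery to fit
    return(new("FrapFit", tau = NA_real_, plateau = 0,
               immobileFrac = 1, residualRMS = 0, flagged = FALSE))
  }
  half <- plateau0 / 2
  above <- which(y >= half)
  tau0 <- if (length(above) && above[1] > 1L) {
    k <- above[1]
    frac <- (half - y[k - 1L]) / (y[k] - y[k - 1L])
    max((tp[k - 1L] + frac * (tp[k] - tp[k - 1L])) / log(2), tp[2] / 2)
  } else tp[2]

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau * (1 - exp(-tp / tau)),
                      start = list(plateau = plateau0, tau = tau0),
                      lower = c(plateau = 0, tau = 1e-6),
                      upper = c(plateau = 1.5, tau = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("FRAP fit did not converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  new("FrapFit", tau = unname(est["tau"]), plateau = unname(est["plateau"]),
      immobileFrac = 1 - unname(est["plateau"]), residualRMS = rms,
      flagged = unname(est["plateau"]) > 1)
}

#' Pool FRAP traces and fit the mean trace
#'
#' All traces must share the same time grid and bleach index. The pointwise
#' mean trace (with SEM) is computed and a single one-phase-decay fit is run
#' on it, mirroring the pooled-spine analysis convention.
#'
#' @param traces list of \code{\link{FrapTrace}} objects (>= 2).
#' @return list(fit = \code{\link{FrapFit}}, trace = mean
#'   \code{\link{FrapTrace}}, sem = pointwise SEM).
#' @export
poolFrap <- function(traces) {
  stopifnot(length(traces) >= 2L)
  t0 <- traces[[1]]@t; b0 <- traces[[1]]@bleachIndex
  for (tr in traces)
    if (!isTRUE(all.equal(tr@t, t0)) || tr@bleachIndex != b0)
      stop("grid mismatch: traces are not on a common time grid")
  fm <- vapply(traces, function(tr) tr@f, numeric(length(t0)))
  meanTrace <- FrapTrace(t0, rowMeans(fm), b0)
  sem <- apply(fm, 1L, stats::sd) / sqrt(length(traces))
  list(fit = fitFrap(meanTrace), trace = meanTrace, sem = sem)
}
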