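#' Normalize raw fluorescence to percent of the zero-competitor reading
#'
#' Converts raw intensities to percent of a reference (blank) intensity, as
#' used for competitive displacement curves where fluorescence is expressed
#' relative to the reading in absence of competitor.
#'
#' @param rawIntensities numeric vector of raw readings (AU).
#' @param referenceIntensity the zero-competitor reading (AU), must be > 0.
#' @return numeric vector of percents, \code{100 * raw / reference}, in the
#'   input order.
#' @examples
#' normalizeFluorescence(c(12, 6, 3), 12)
#' @export
normalizeFluorescence <- function(rawIntensities, referenceIntensity) {
  if (length(referenceIntensity) != 1L || !is.finite(referenceIntensity) ||
      referenceIntensity <= 0)
    stop("referenceIntensity must be a single positive number; ",
         "a zero or negative blank is unusable")
  100 * rawIntensities / referenceIntensity
}

#' Fit a one-site saturation binding curve
#'
#' Estimates the probe dissociation constant K_probe and saturating
#' intensity Bmax from a 1-NPN titration, either by nonlinear least squares
#' on the one-site model \eqn{I = B_{max} c / (K + c)} or by Scatchard
#' linearisation (I/c against I; the slope is -1/K).
#'
#' @param series a [SaturationSeries-class].
#' @param method "nonlinear" (default) or "scatchard".
#' @return A [SaturationFit-class] with positive \code{kProbe} and
#'   \code{bMax} and the coefficient of determination of the fitted curve.
#' @details The Scatchard estimate also seeds the nonlinear fit. A titration
#'   that does not increase with concentration (e.g. constant intensity)
#'   cannot identify K and raises an error.
#' @examples
#' s <- simulateSaturation(kProbe = 11.66, noiseSd = 0)
#' fitSaturation(s)
#' fitSaturation(s, method = "scatchard")
#' @importFrom stats lm coef fitted resid nls
#' @export
fitSaturation <- function(series, method = c("nonlinear", "scatchard")) {
  stopifnot(is(series, "SaturationSeries"))
  validObject(series)
  method <- match.arg(method)
  conc <- series@probeConc
  int <- series@intensity

  if (diff(range(int)) <= 1e-10 * max(abs(int), 1))
    stop("saturation fit failed: intensity does not vary with concentration")

  ## Scatchard linearisation: I/c = Bmax/K - I/K
  sc <- lm(I(int / conc) ~ int)
  slope <- unname(coef(sc)[2L])
  intercept <- unname(coef(sc)[1L])
  if (!is.finite(slope) || slope >= 0)
    stop("saturation fit failed: Scatchard slope is non-negative, ",
         "data are inconsistent with one-site saturation")
  kSc <- -1 / slope
  bSc <- intercept * kSc

  if (method == "scatchard") {
    y <- int / conc
    r2 <- 1 - sum(resid(sc)^2) / sum((y - mean(y))^2)
    fit <- new("SaturationFit", proteinId = series@proteinId, kProbe = kSc,
               bMax = bSc, method = "scatchard", goodness = r2)
    validObject(fit)
    return(fit)
  }

  resFn <- function(p) int - p[1L] * conc / (p[2L] + conc)
  nl <- tryCatch(
    minpack.lm::nls.lm(par = c(max(bSc, max(int)), max(kSc, 1e-3)),
                       lower = c(1e-12, 1e-12), fn = resFn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e)
      stop("saturation fit failed to converge: ", conditionMessage(e)))
  est <- nl$par
  if (!all(is.finite(est)) || any(est <= 0))
    stop("saturation fit failed: non-positive parameter estimate")
  r2 <- 1 - sum(nl$fvec^2) / sum((int - mean(int))^2)
  fit <- new("SaturationFit", proteinId = series@proteinId,
             kProbe = est[2L], bMax = est[1L],
             method = "nonlinear", goodness = r2)
  validObject(fit)
  fit
}

## Competitive one-site displacement model used for fitting and simulation:
## percent bound probe as a function of competitor concentration L,
##   percent(L) = 100 (P + K) / (P + K (1 + L/Ki))
## with P the probe concentration and K the probe dissociation constant.
## Its half-displacement point is L50 = Ki (1 + P/K), so inverting with
## Ki = IC50 / (1 + P/K) is exact for this model.
competitionModel <- function(conc, ki, kProbe, probeConc) {
  100 * (probeConc + kProbe) /
    (probeConc + kProbe * (1 + conc / ki))
}

#' Fit a competitive displacement curve and locate its IC50
#'
#' Fits percent fluorescence against competitor concentration with a
#' four-parameter logistic in log-concentration (top fixed, bottom bounded
#' in [0, 50], Hill slope initialised at 1); the IC50 is the fitted midpoint
#' concentration. When the sigmoid fit cannot converge but the observed
#' curve crosses 50 percent, a log-linear interpolation between the two
#' bracketing points is used instead.
#'
#' @param series a [CompetitionSeries-class].
#' @param method "auto" (sigmoid with interpolation fallback, default),
#'   "sigmoid" or "interpolation".
#' @param undeterminedThreshold IC50 above which the result is reported as
#'   undetermined rather than quantified (uM, default 100, the convention
#'   used for weak binders).
#' @param top upper plateau: the number 100 (default; percent fluorescence
#'   is normalized so the zero-competitor level is 100 by construction) or
#'   the string "data" to fix it to the mean of the two lowest-concentration
#'   points.
#' @return A [CompetitionFit-class]. \code{status} is "failed" for curves
#'   showing no displacement (monotonically non-decreasing), "undetermined"
#'   when the IC50 exceeds \code{undeterminedThreshold} or no 50 percent
#'   crossing is observed, otherwise "determined".
#' @details Ties at exactly 50 percent resolve to the lowest concentration
#'   attaining 50. The interpolation method requires an observed crossing.
#' @examples
#' cs <- simulateCompetition(ki = 5.719, kProbe = 11.66, probeConc = 2,
#'                           noiseSd = 0)
#' fitCompetition(cs)
#' @export
fitCompetition <- function(series, method = c("auto", "sigmoid", "interpolation"),
                           undeterminedThreshold = 100, top = 100) {
  stopifnot(is(series, "CompetitionSeries"))
  validObject(series)
  method <- match.arg(method)
  conc <- series@competitorConc
  pct <- series@percentFluorescence
  if (length(conc) < 4L)
    stop("at least 4 competition points are required")

  if (identical(top, "data")) {
    topFix <- mean(pct[seq_len(min(2L, length(pct)))])
  } else {
    topFix <- as.numeric(top)
    if (!is.finite(topFix) || topFix <= 0) stop("invalid 'top'")
  }

  failedFit <- function() new("CompetitionFit", ic50 = NA_real_,
                              hill = NA_real_, top = topFix,
                              bottom = NA_real_, status = "failed",
                              method = "sigmoid", goodness = NA_real_)

  ## no displacement: curve never decreases
  if (all(diff(pct) >= 0)) return(failedFit())

  crossing <- any(pct <= 50) && any(pct >= 50)

  interp <- function() {
    ## lowest concentration at exactly 50 wins; otherwise log-linear
    ## interpolation between the two points bracketing the crossing
    exact <- which(pct == 50)
    if (length(exact)) return(conc[min(exact)])
    i <- which(pct[-length(pct)] > 50 & pct[-1L] < 50)
    if (!length(i)) return(NA_real_)
    i <- i[1L]
    lo <- conc[i]; hi <- conc[i + 1L]
    if (lo <= 0) return(hi * ((50 - pct[i]) / (pct[i + 1L] - pct[i])))
    exp(log(lo) + (50 - pct[i]) * (log(hi) - log(lo)) /
          (pct[i + 1L] - pct[i]))
  }

  statusFor <- function(est) {
    if (!is.finite(est) || est > undeterminedThreshold || !crossing)
      "undetermined" else "determined"
  }

  if (method != "sigmoid" && method == "interpolation") {
    est <- if (crossing) interp() else NA_real_
    fit <- new("CompetitionFit", ic50 = est, hill = NA_real_, top = topFix,
               bottom = NA_real_, status = statusFor(est),
               method = "interpolation", goodness = NA_real_)
    validObject(fit)
    return(fit)
  }

  ## sigmoid: percent = bottom + (top - bottom)/(1 + (L/ic50)^hill),
  ## fitted on the positive-concentration points (the L = 0 point sits on
  ## the fixed upper plateau)
  pos <- conc > 0
  cc <- conc[pos]; pp <- pct[pos]
  start50 <- interp()
  if (!is.finite(start50)) start50 <- exp(mean(log(range(cc))))
  ## residuals of the 4PL with fixed top; p = (bottom, hill, ic50)
  resFn <- function(p) pp - (p[1L] + (topFix - p[1L]) / (1 + (cc / p[3L])^p[2L]))
  nl <- tryCatch({
    out <- minpack.lm::nls.lm(par = c(0, 1, start50),
                              lower = c(0, 0.1, 1e-9),
                              upper = c(50, 10, 1e9), fn = resFn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    if (!out$info %in% 1:4 || !all(is.finite(out$par))) NULL else out
  }, error = function(e) NULL)

  if (is.null(nl)) {
    if (method == "sigmoid" || !crossing) {
      est <- NA_real_
      fit <- new("CompetitionFit", ic50 = est, hill = NA_real_, top = topFix,
                 bottom = NA_real_, status = statusFor(est),
                 method = "sigmoid", goodness = NA_real_)
      return(fit)
    }
    est <- interp()
    fit <- new("CompetitionFit", ic50 = est, hill = NA_real_, top = topFix,
               bottom = NA_real_, status = statusFor(est),
               method = "interpolation", goodness = NA_real_)
    validObject(fit)
    return(fit)
  }

  est <- nl$par
  r2 <- 1 - sum(nl$fvec^2) / sum((pp - mean(pp))^2)
  fit <- new("CompetitionFit", ic50 = est[3L], hill = est[2L], top = topFix,
             bottom = est[1L], status = statusFor(est[3L]),
             method = "sigmoid", goodness = r2)
  validObject(fit)
  fit
}

#' Convert an IC50 to an inhibition constant Ki
#'
#' Applies the competitive-displacement relation
#' \deqn{K_i = \frac{IC_{50}}{1 + [probe]/K_{probe}}}
#' where \eqn{[probe]} is the concentration of the fluorescent reporter
#' (1-NPN) and \eqn{K_{probe}} the dissociation constant of the
#' probe-protein complex.
#'
#' @param ic50 half-displacement concentration, uM (>= 0).
#' @param probeConc reporter concentration, uM (>= 0).
#' @param kProbe probe dissociation constant, uM (> 0).
#' @return Ki in uM. Equals \code{ic50} when \code{probeConc} is 0 and is
#'   strictly smaller otherwise.
#' @examples
#' kiFromIC50(6.70, 2, 11.66)   # linoleic acid vs CSP1
#' kiFromIC50(326.26, 2, 11.66) # thiamethoxam vs CSP1
#' @export
kiFromIC50 <- function(ic50, probeConc, kProbe) {
  if (any(!is.finite(kProbe)) || any(kProbe <= 0))
    stop("kProbe must be positive: the probe dissociation constant ",
         "cannot be zero")
  if (any(ic50 < 0, na.rm = TRUE) || any(probeConc < 0))
    stop("ic50 and probeConc must be non-negative")
  ic50 / (1 + probeConc / kProbe)
}

#' Combine a competition fit with probe constants into an affinity result
#'
#' @param series the fitted [CompetitionSeries-class] (supplies identifiers
#'   and the probe concentration).
#' @param fit the [CompetitionFit-class] from [fitCompetition()].
#' @param kProbe probe dissociation constant for this protein, uM.
#' @return An [AffinityResult-class]; \code{ki} is NA unless the fit status
#'   is "determined".
#' @export
computeAffinity <- function(series, fit, kProbe) {
  stopifnot(is(series, "CompetitionSeries"), is(fit, "CompetitionFit"))
  ki <- if (identical(fit@status, "determined"))
    kiFromIC50(fit@ic50, series@probeConc, kProbe) else NA_real_
  res <- new("AffinityResult", proteinId = series@proteinId,
             ligandId = series@ligandId,
             ic50 = if (identical(fit@status, "determined")) fit@ic50 else NA_real_,
             ki = ki, kProbe = kProbe, probeConc = series@probeConc,
             status = fit@status)
  validObject(res)
  res
}

#' Summarise affinity results per protein-ligand pair
#'
#' Aggregates replicate [AffinityResult-class] objects into one row per
#' (protein, ligand) with the mean and sample sd of determined Ki values.
#'
#' @param results list of [AffinityResult-class] objects.
#' @return data.frame with columns proteinId, ligandId, n, kiMean, kiSd,
#'   status. Replicates of one pair must agree in status.
#' @importFrom stats sd
#' @export
summarizeAffinities <- function(results) {
  if (!length(results))
    return(data.frame(proteinId = character(), ligandId = character(),
                      n = integer(), kiMean = numeric(), kiSd = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  stopifnot(all(vapply(results, is, logical(1), "AffinityResult")))
  key <- paste(vapply(results, proteinId, character(1)),
               vapply(results, ligandId, character(1)), sep = "\r")
  rows <- lapply(split(results, factor(key, levels = unique(key))), function(grp) {
    st <- unique(vapply(grp, fitStatus, character(1)))
    if (length(st) > 1L)
      stop("conflicting statuses (", paste(st, collapse = ", "),
           ") for protein '", proteinId(grp[[1L]]), "', ligand '",
           ligandId(grp[[1L]]), "'")
    ki <- vapply(grp, kiValue, numeric(1))
    data.frame(proteinId = proteinId(grp[[1L]]), ligandId = ligandId(grp[[1L]]),
               n = length(grp),
               kiMean = if (st == "determined") mean(ki) else NA_real_,
               kiSd = if (st == "determined" && length(ki) > 1L) sd(ki) else NA_real_,
               status = st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an affinity table: ligands by proteins
#'
#' Builds the classic ligand-by-protein binding table: one row per ligand,
#' one column per protein, entries "mean" or "mean+/-sd" in uM for
#' determined pairs, "u.d." (undetermined) for pairs whose IC50 exceeded
#' the reporting threshold and "n.d." for failed fits.
#'
#' @param results list of [AffinityResult-class] objects (replicates of one
#'   pair are averaged).
#' @param digits decimal places for the rendered numbers (default 2).
#' @return data.frame of character entries, ligands as rows (column
#'   \code{ligand}), proteins as the remaining columns. Empty input yields
#'   an empty table.
#' @examples
#' cs <- simulateCompetition(ki = 5.78, proteinId = "CSP1",
#'                           ligandId = "linoleic acid", noiseSd = 0)
#' af <- computeAffinity(cs, fitCompetition(cs), kProbe = 11.66)
#' buildAffinityTable(list(af))
#' @export
buildAffinityTable <- function(results, digits = 2) {
  summ <- summarizeAffinities(results)
  if (!nrow(summ))
    return(data.frame(ligand = character(), stringsAsFactors = FALSE))
  ligands <- unique(summ$ligandId)
  proteins <- unique(summ$proteinId)
  out <- data.frame(ligand = ligands, stringsAsFactors = FALSE,
                    check.names = FALSE)
  fmt <- function(m, s) {
    if (is.na(m)) return(NA_character_)
    if (is.na(s)) sprintf(paste0("%.", digits, "f"), m)
    else sprintf(paste0("%.", digits, "f±%.", digits, "f"), m, s)
  }
  for (p in proteins) {
    col <- rep(NA_character_, length(ligands))
    sub <- summ[summ$proteinId == p, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      i <- match(sub$ligandId[j], ligands)
      col[i] <- switch(sub$status[j],
                       determined = fmt(sub$kiMean[j], sub$kiSd[j]),
                       undetermined = "u.d.",
                       failed = "n.d.")
    }
    out[[p]] <- col
  }
  out
}
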