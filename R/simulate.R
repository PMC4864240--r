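## Run expr with a locally seeded RNG, restoring the caller's RNG state.
## Every generator is a bit-exact function of (arguments, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Simulate a 1-NPN saturation titration
#'
#' Generates probe-concentration/intensity pairs from the one-site model
#' \eqn{I = B_{max} c/(K_{probe}+c)} with multiplicative Gaussian noise
#' \eqn{(1+\epsilon)}, \eqn{\epsilon \sim N(0, noiseSd)} — the relative
#' error structure typical of fluorescence intensity readings. The default
#' concentration range 2-30 uM matches the titration protocol the assay
#' stage expects.
#'
#' @param kProbe true probe dissociation constant, uM (default 11.66).
#' @param bMax saturating intensity, AU (default 100).
#' @param nPoints number of titration points (default 15).
#' @param concRange range of probe concentrations, uM (default c(2, 30)).
#' @param conc optional explicit concentration vector overriding
#'   \code{nPoints}/\code{concRange}/\code{spacing}.
#' @param noiseSd relative noise sd (default 0.02).
#' @param spacing "linear" (default) or "log" concentration spacing.
#' @param proteinId identifier (default "CSP1").
#' @param seed integer seed fixing the output bit-for-bit; NULL uses the
#'   current RNG stream.
#' @return A [SaturationSeries-class].
#' @examples
#' simulateSaturation(seed = 1)
#' @importFrom stats rnorm
#' @export
simulateSaturation <- function(kProbe = 11.66, bMax = 100, nPoints = 15,
                               concRange = c(2, 30), conc = NULL,
                               noiseSd = 0.02,
                               spacing = c("linear", "log"),
                               proteinId = "CSP1", seed = NULL) {
  stopifnot(kProbe > 0, bMax > 0, noiseSd >= 0)
  spacing <- match.arg(spacing)
  if (is.null(conc)) {
    conc <- if (spacing == "linear")
      seq(concRange[1L], concRange[2L], length.out = nPoints)
    else exp(seq(log(concRange[1L]), log(concRange[2L]),
                 length.out = nPoints))
  }
  withSeed(seed, {
    eps <- if (noiseSd > 0) rnorm(length(conc), 0, noiseSd) else
      numeric(length(conc))
    intensity <- pmax(0, bMax * conc / (kProbe + conc) * (1 + eps))
    SaturationSeries(proteinId, conc, intensity)
  })
}

#' Simulate a competitive displacement curve
#'
#' Generates percent-fluorescence points from the competitive one-site
#' displacement model
#' \deqn{percent(L) = 100\,\frac{P+K}{P+K(1+L/K_i)}}
#' (P = probe concentration, K = probe dissociation constant), whose
#' analytic half-displacement point \eqn{L_{50} = K_i(1+P/K)} makes the
#' IC50-to-Ki inversion exact. Multiplicative Gaussian noise as in
#' [simulateSaturation()]. Default 8 log-spaced competitor concentrations
#' in 2-50 uM; widen \code{concRange} to bracket a large IC50.
#'
#' @param ki true inhibition constant, uM (default 5.719).
#' @param kProbe probe dissociation constant, uM (default 11.66).
#' @param probeConc 1-NPN concentration, uM (default 2).
#' @param nPoints number of points (default 8).
#' @param concRange competitor concentration range, uM (default c(2, 50)).
#' @param conc optional explicit concentrations (may include 0).
#' @param noiseSd relative noise sd (default 0.02).
#' @param proteinId,ligandId identifiers.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return A [CompetitionSeries-class] (percents clamped to [0, 120]).
#' @examples
#' simulateCompetition(ki = 5.719, noiseSd = 0)
#' @importFrom stats rnorm
#' @export
simulateCompetition <- function(ki = 5.719, kProbe = 11.66, probeConc = 2,
                                nPoints = 8, concRange = c(2, 50),
                                conc = NULL, noiseSd = 0.02,
                                proteinId = "CSP1", ligandId = "ligand",
                                seed = NULL) {
  stopifnot(ki > 0, kProbe > 0, probeConc > 0, noiseSd >= 0)
  if (is.null(conc))
    conc <- exp(seq(log(concRange[1L]), log(concRange[2L]),
                    length.out = nPoints))
  withSeed(seed, {
    pct <- competitionModel(conc, ki, kProbe, probeConc)
    if (noiseSd > 0) pct <- pct * (1 + rnorm(length(conc), 0, noiseSd))
    CompetitionSeries(proteinId, ligandId, conc,
                      pmin(120, pmax(0, pct)), probeConc)
  })
}

## random unit vector in 3 dimensions
.runitvec <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Simulate a docking pose ensemble with a planted consensus cluster
#'
#' Emulates docking one ligand against \code{nModels} receptor models: a
#' fraction \code{occupancy} of models (rounded up) receives a pose
#' jittered at most \code{maxJitter} RMSD around a planted reference
#' geometry, with energy drawn from
#' \eqn{N(energyMean, energySd)}; the remaining models receive decoy poses
#' rigidly displaced at least \code{3 * rmsdCutoff} from the reference with
#' weaker (higher) energies. All poses share atom count and ordering, so
#' the planted cluster is recoverable by RMSD clustering at
#' \code{rmsdCutoff}.
#'
#' @param nModels number of receptor models (default 100).
#' @param occupancy planted cluster occupancy fraction in [0, 1]
#'   (default 0.6).
#' @param energyMean,energySd planted pose energy distribution, kcal/mol
#'   (defaults -6.8635 and 0.25).
#' @param decoyEnergyOffset how much weaker (higher) decoy energies are on
#'   average, kcal/mol (default 2).
#' @param rmsdCutoff the clustering radius the geometry is constructed
#'   around, Angstrom (default 2.0).
#' @param maxJitter maximum RMSD of planted poses from the reference
#'   geometry (default \code{rmsdCutoff/2}, guaranteeing all planted poses
#'   fall within one cluster at \code{rmsdCutoff}).
#' @param nAtoms ligand heavy-atom count (default 20, the size of linoleic
#'   acid).
#' @param proteinId,ligandId identifiers.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return A [PoseEnsemble-class] with one pose per model. The attribute
#'   \code{"plantedModels"} records which model ids received the planted
#'   pose, so recovery of the planted cluster can be checked.
#' @examples
#' pe <- simulatePoseEnsemble(seed = 42)
#' consensusPipeline(pe)
#' @importFrom stats rnorm runif
#' @export
simulatePoseEnsemble <- function(nModels = 100, occupancy = 0.6,
                                 energyMean = -6.8635, energySd = 0.25,
                                 decoyEnergyOffset = 2, rmsdCutoff = 2.0,
                                 maxJitter = rmsdCutoff / 2, nAtoms = 20,
                                 proteinId = "CSP1", ligandId = "ligand",
                                 seed = NULL) {
  stopifnot(nModels >= 1, occupancy >= 0, occupancy <= 1, rmsdCutoff > 0,
            maxJitter >= 0, nAtoms >= 1, energySd >= 0)
  withSeed(seed, {
    ref <- matrix(rnorm(nAtoms * 3, sd = 3), nAtoms, 3)
    nPlanted <- ceiling(occupancy * nModels)
    planted <- if (nPlanted > 0) sort(sample.int(nModels, nPlanted)) else
      integer()
    coords <- array(NA_real_, dim = c(nAtoms, 3, nModels))
    energy <- numeric(nModels)
    for (m in seq_len(nModels)) {
      if (m %in% planted) {
        jit <- matrix(rnorm(nAtoms * 3), nAtoms, 3)
        cur <- sqrt(sum(jit^2) / nAtoms)
        target <- runif(1, 0, maxJitter)
        coords[, , m] <- ref + if (cur > 0) jit * (target / cur) else 0
        energy[m] <- energyMean + if (energySd > 0) rnorm(1, 0, energySd) else 0
      } else {
        shift <- .runitvec() * runif(1, 3 * rmsdCutoff, 6 * rmsdCutoff)
        coords[, , m] <- sweep(ref, 2, shift, `+`)
        energy[m] <- energyMean + decoyEnergyOffset +
          if (energySd > 0) rnorm(1, 0, energySd) else 0
      }
    }
    out <- PoseEnsemble(proteinId, ligandId, nModels,
                        modelId = seq_len(nModels),
                        poseIndex = rep(1L, nModels),
                        energy = energy, coords = coords)
    attr(out, "plantedModels") <- planted
    out
  })
}

#' Simulate a replicate Ct table with known fold changes
#'
#' Builds a qPCR Ct table for one target and one reference (housekeeping)
#' gene across samples with prescribed true fold changes relative to the
#' calibrator. Reference-gene replicates sit at \code{baselineCt}; target
#' replicates are drawn as
#' \code{baselineCt + dctCalibrator - log2(fold) + N(0, noiseSd)} — cycle
#' noise is additive on the Ct scale, and because the ddCt statistic only
#' uses the difference of gene means, replicate scatter of the reference
#' gene is absorbed into the same noise term.
#'
#' @param foldChanges named numeric vector of true fold changes per sample;
#'   the first element is the calibrator unless \code{calibrator} is given.
#'   Values are renormalized so the calibrator's fold is 1. Default
#'   \code{c(control = 1, treated = 10)}, a thiamethoxam-induction-scale
#'   contrast.
#' @param calibrator calibrator sample name (default: first of
#'   \code{foldChanges}).
#' @param targetGene,referenceGene gene identifiers (defaults "CSP1",
#'   "actin").
#' @param nReplicates replicates per sample x gene (default 3).
#' @param baselineCt reference-gene Ct (default 20).
#' @param dctCalibrator calibrator's true delta-Ct, cycles (default 5).
#' @param noiseSd sd of the Ct noise, cycles (default 0.2).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{replicate}, \code{ct}.
#' @examples
#' ct <- simulateCtTable(foldChanges = c(control = 1, treated = 8),
#'                       noiseSd = 0)
#' ddCtFoldChange(ct, "CSP1", "actin", "control")
#' @importFrom stats rnorm
#' @export
simulateCtTable <- function(foldChanges = c(control = 1, treated = 10),
                            calibrator = names(foldChanges)[1L],
                            targetGene = "CSP1", referenceGene = "actin",
                            nReplicates = 3, baselineCt = 20,
                            dctCalibrator = 5, noiseSd = 0.2, seed = NULL) {
  stopifnot(length(foldChanges) >= 1, all(foldChanges > 0),
            nReplicates >= 1, noiseSd >= 0)
  if (is.null(names(foldChanges)))
    names(foldChanges) <- paste0("sample", seq_along(foldChanges))
  if (!calibrator %in% names(foldChanges))
    stop("calibrator '", calibrator, "' not among foldChanges names")
  foldChanges <- foldChanges / foldChanges[[calibrator]]
  withSeed(seed, {
    rows <- lapply(names(foldChanges), function(s) {
      refCt <- rep(baselineCt, nReplicates)
      tgtCt <- baselineCt + dctCalibrator - log2(foldChanges[[s]]) +
        (if (noiseSd > 0) rnorm(nReplicates, 0, noiseSd) else
          rep(0, nReplicates))
      data.frame(
        sample_id = s,
        gene_id = rep(c(referenceGene, targetGene), each = nReplicates),
        replicate = rep(seq_len(nReplicates), 2L),
        ct = c(refCt, tgtCt), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
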