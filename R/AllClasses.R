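#' @import methods
NULL

## ---------------------------------------------------------------------------
## Fluorescence binding assay
## ---------------------------------------------------------------------------

#' SaturationSeries: a 1-NPN titration of one protein
#'
#' Holds probe-concentration/fluorescence-intensity pairs from titrating a
#' fixed protein solution with the fluorescent reporter 1-NPN
#' (N-phenyl-1-naphthylamine). Used to estimate the probe dissociation
#' constant K_probe by [fitSaturation()].
#'
#' @slot proteinId single character identifier.
#' @slot probeConc numeric, probe concentrations in uM; strictly positive and
#'   strictly increasing.
#' @slot intensity numeric, fluorescence readings (arbitrary units),
#'   non-negative, same length as \code{probeConc} (>= 4 points).
#' @slot proteinConc protein concentration in uM (assay constant, default 2).
#'
#' @seealso [SaturationSeries()] constructor, [fitSaturation()],
#'   [simulateSaturation()]
#' @exportClass SaturationSeries
setClass("SaturationSeries",
  representation(
    proteinId = "character",
    probeConc = "numeric",
    intensity = "numeric",
    proteinConc = "numeric"
  ),
  prototype(proteinConc = 2)
)

setValidity("SaturationSeries", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L || is.na(object@proteinId))
    msg <- c(msg, "proteinId must be a single non-NA string")
  n <- length(object@probeConc)
  if (n < 4L)
    msg <- c(msg, "at least 4 titration points are required")
  if (length(object@intensity) != n)
    msg <- c(msg, "probeConc and intensity must have equal length")
  if (any(!is.finite(object@probeConc)) || any(object@probeConc <= 0))
    msg <- c(msg, "probeConc must be finite and strictly positive")
  if (n > 1L && any(diff(object@probeConc) <= 0))
    msg <- c(msg, "probeConc must be strictly increasing")
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    msg <- c(msg, "intensity must be finite and non-negative")
  if (length(object@proteinConc) != 1L || !is.finite(object@proteinConc) ||
      object@proteinConc <= 0)
    msg <- c(msg, "proteinConc must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a SaturationSeries
#'
#' @param proteinId protein identifier.
#' @param probeConc probe (1-NPN) concentrations, uM, strictly increasing.
#' @param intensity fluorescence intensities (AU), same length.
#' @param proteinConc protein concentration, uM (default 2).
#' @return A [SaturationSeries-class] object.
#' @examples
#' s <- SaturationSeries("CSP1", c(2, 5, 10, 20, 30), c(15, 30, 46, 63, 72))
#' @export
SaturationSeries <- function(proteinId, probeConc, intensity, proteinConc = 2) {
  new("SaturationSeries", proteinId = as.character(proteinId),
      probeConc = as.numeric(probeConc), intensity = as.numeric(intensity),
      proteinConc = as.numeric(proteinConc))
}

#' SaturationFit: one-site binding parameters of the probe
#'
#' Result of [fitSaturation()]: the probe dissociation constant and
#' saturating intensity of the one-site model
#' \eqn{I(c) = B_{max} c / (K_{probe} + c)}.
#'
#' @slot proteinId protein identifier carried over from the series.
#' @slot kProbe probe dissociation constant, uM (> 0).
#' @slot bMax saturating intensity, AU (> 0).
#' @slot method "nonlinear" or "scatchard".
#' @slot goodness coefficient of determination of the fit.
#' @exportClass SaturationFit
setClass("SaturationFit",
  representation(
    proteinId = "character",
    kProbe = "numeric",
    bMax = "numeric",
    method = "character",
    goodness = "numeric"
  )
)

setValidity("SaturationFit", function(object) {
  msg <- character()
  if (!is.finite(object@kProbe) || object@kProbe <= 0)
    msg <- c(msg, "kProbe must be positive")
  if (!is.finite(object@bMax) || object@bMax <= 0)
    msg <- c(msg, "bMax must be positive")
  if (!object@method %in% c("nonlinear", "scatchard"))
    msg <- c(msg, "method must be 'nonlinear' or 'scatchard'")
  if (length(msg)) msg else TRUE
})

#' CompetitionSeries: a competitive displacement curve
#'
#' Competitor-concentration/percent-fluorescence pairs for one
#' protein-ligand pair, measured at a fixed reporter (1-NPN) concentration.
#' Percent fluorescence is relative to the zero-competitor reading.
#'
#' @slot proteinId,ligandId identifiers.
#' @slot competitorConc competitor concentrations, uM; non-negative, strictly
#'   increasing.
#' @slot percentFluorescence percents in [0, 120], same length.
#' @slot probeConc 1-NPN concentration, uM (default 2).
#' @seealso [fitCompetition()], [simulateCompetition()]
#' @exportClass CompetitionSeries
setClass("CompetitionSeries",
  representation(
    proteinId = "character",
    ligandId = "character",
    competitorConc = "numeric",
    percentFluorescence = "numeric",
    probeConc = "numeric"
  ),
  prototype(probeConc = 2)
)

setValidity("CompetitionSeries", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L || length(object@ligandId) != 1L)
    msg <- c(msg, "proteinId and ligandId must be single strings")
  n <- length(object@competitorConc)
  if (length(object@percentFluorescence) != n)
    msg <- c(msg, "competitorConc and percentFluorescence must have equal length")
  if (any(!is.finite(object@competitorConc)) || any(object@competitorConc < 0))
    msg <- c(msg, "competitorConc must be finite and non-negative")
  if (n > 1L && any(diff(object@competitorConc) <= 0))
    msg <- c(msg, "competitorConc must be strictly increasing")
  if (any(!is.finite(object@percentFluorescence)) ||
      any(object@percentFluorescence < 0) ||
      any(object@percentFluorescence > 120))
    msg <- c(msg, "percentFluorescence must lie in [0, 120]")
  if (length(object@probeConc) != 1L || !is.finite(object@probeConc) ||
      object@probeConc < 0)
    msg <- c(msg, "probeConc must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a CompetitionSeries
#'
#' @param proteinId,ligandId identifiers.
#' @param competitorConc competitor concentrations, uM, strictly increasing.
#' @param percentFluorescence percent of zero-competitor fluorescence.
#' @param probeConc 1-NPN concentration, uM (default 2).
#' @return A [CompetitionSeries-class] object.
#' @export
CompetitionSeries <- function(proteinId, ligandId, competitorConc,
                              percentFluorescence, probeConc = 2) {
  new("CompetitionSeries", proteinId = as.character(proteinId),
      ligandId = as.character(ligandId),
      competitorConc = as.numeric(competitorConc),
      percentFluorescence = as.numeric(percentFluorescence),
      probeConc = as.numeric(probeConc))
}

#' CompetitionFit: logistic fit of a displacement curve
#'
#' Result of [fitCompetition()]. \code{status} is "determined" when a valid
#' IC50 at or below the undetermined threshold was obtained, "undetermined"
#' when the fitted IC50 exceeds the threshold (default 100 uM) or no 50
#' percent crossing exists, and "failed" when the curve shows no
#' displacement.
#'
#' @slot ic50 half-displacement concentration, uM (NA unless estimable).
#' @slot hill logistic slope (NA for the interpolation fallback).
#' @slot top,bottom plateau percents.
#' @slot status "determined", "undetermined" or "failed".
#' @slot method "sigmoid" or "interpolation".
#' @slot goodness coefficient of determination (NA for interpolation).
#' @exportClass CompetitionFit
setClass("CompetitionFit",
  representation(
    ic50 = "numeric",
    hill = "numeric",
    top = "numeric",
    bottom = "numeric",
    status = "character",
    method = "character",
    goodness = "numeric"
  )
)

setValidity("CompetitionFit", function(object) {
  msg <- character()
  if (!object@status %in% c("determined", "undetermined", "failed"))
    msg <- c(msg, "status must be 'determined', 'undetermined' or 'failed'")
  if (identical(object@status, "determined") &&
      (!is.finite(object@ic50) || object@ic50 <= 0))
    msg <- c(msg, "ic50 must be positive when status is 'determined'")
  if (length(msg)) msg else TRUE
})

#' AffinityResult: Ki for one protein-ligand pair
#'
#' Couples the IC50 of a competition fit with the probe parameters used to
#' convert it to an inhibition constant Ki = IC50 / (1 + [probe]/K_probe).
#'
#' @slot proteinId,ligandId identifiers.
#' @slot ic50,ki,kProbe,probeConc concentrations in uM (ic50/ki NA unless
#'   determined).
#' @slot status the competition-fit status.
#' @seealso [computeAffinity()], [kiFromIC50()], [buildAffinityTable()]
#' @exportClass AffinityResult
setClass("AffinityResult",
  representation(
    proteinId = "character",
    ligandId = "character",
    ic50 = "numeric",
    ki = "numeric",
    kProbe = "numeric",
    probeConc = "numeric",
    status = "character"
  )
)

setValidity("AffinityResult", function(object) {
  msg <- character()
  if (!object@status %in% c("determined", "undetermined", "failed"))
    msg <- c(msg, "invalid status")
  if (identical(object@status, "determined")) {
    if (!is.finite(object@ki) || object@ki <= 0)
      msg <- c(msg, "ki must be positive when determined")
    if (is.finite(object@ic50) && object@probeConc > 0 &&
        object@ki > object@ic50 + 1e-9)
      msg <- c(msg, "ki must not exceed ic50 when probeConc > 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Ensemble docking consensus
## ---------------------------------------------------------------------------

#' PoseEnsemble: docking poses across an ensemble of receptor models
#'
#' All docked poses of one ligand against N homology models of one receptor,
#' in a shared receptor coordinate frame. Coordinates are stored as an
#' nAtoms x 3 x nPoses array; all poses share atom count and ordering, so
#' pose-pose RMSD is meaningful without superposition.
#'
#' @slot proteinId,ligandId identifiers.
#' @slot nModels number of receptor models in the ensemble.
#' @slot modelId integer vector, one entry per pose, in [1, nModels].
#' @slot poseIndex integer vector, pose rank within its model.
#' @slot energy numeric vector, predicted binding free energy (kcal/mol).
#' @slot coords numeric array, dim c(nAtoms, 3, nPoses): ligand heavy-atom
#'   positions in Angstrom.
#' @seealso [clusterPoses()], [consensusPipeline()], [simulatePoseEnsemble()]
#' @exportClass PoseEnsemble
setClass("PoseEnsemble",
  representation(
    proteinId = "character",
    ligandId = "character",
    nModels = "integer",
    modelId = "integer",
    poseIndex = "integer",
    energy = "numeric",
    coords = "array"
  )
)

setValidity("PoseEnsemble", function(object) {
  msg <- character()
  np <- length(object@modelId)
  if (np < 1L)
    msg <- c(msg, "ensemble must contain at least one pose")
  if (length(object@poseIndex) != np || length(object@energy) != np)
    msg <- c(msg, "modelId, poseIndex and energy must have equal length")
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nPoses array")
  else {
    if (d[1] < 1L) msg <- c(msg, "poses must contain at least one atom")
    if (d[3] != np) msg <- c(msg, "third coords dimension must equal the pose count")
  }
  if (length(object@nModels) != 1L || object@nModels < 1L)
    msg <- c(msg, "nModels must be a positive integer")
  else if (np && (any(object@modelId < 1L) || any(object@modelId > object@nModels)))
    msg <- c(msg, "every modelId must lie in [1, nModels]")
  if (any(!is.finite(object@energy)))
    msg <- c(msg, "energies must be finite")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PoseEnsemble
#'
#' @param proteinId,ligandId identifiers.
#' @param nModels number of receptor models.
#' @param modelId,poseIndex integer vectors, one entry per pose.
#' @param energy predicted binding free energies, kcal/mol.
#' @param coords nAtoms x 3 x nPoses array of ligand coordinates (Angstrom).
#' @return A [PoseEnsemble-class] object.
#' @export
PoseEnsemble <- function(proteinId, ligandId, nModels, modelId, poseIndex,
                         energy, coords) {
  new("PoseEnsemble", proteinId = as.character(proteinId),
      ligandId = as.character(ligandId), nModels = as.integer(nModels),
      modelId = as.integer(modelId), poseIndex = as.integer(poseIndex),
      energy = as.numeric(energy), coords = coords)
}

#' PoseCluster: a group of mutually similar poses
#'
#' One cluster from greedy energy-ordered leader clustering: the
#' representative is the lowest-energy member (the cluster seed) and every
#' member lies within the RMSD cutoff of it.
#'
#' @slot memberIdx integer indices of member poses in the source ensemble.
#' @slot memberModelId,memberPoseIndex,memberEnergy per-member metadata.
#' @slot representativeIdx index (into the ensemble) of the seed pose.
#' @slot representativeCoords matrix of the seed pose coordinates.
#' @slot rmsdCutoff the cutoff (Angstrom) used to build the cluster.
#' @seealso [clusterPoses()], [modelsRepresented()], [aggregateEnergy()]
#' @exportClass PoseCluster
setClass("PoseCluster",
  representation(
    memberIdx = "integer",
    memberModelId = "integer",
    memberPoseIndex = "integer",
    memberEnergy = "numeric",
    representativeIdx = "integer",
    representativeCoords = "matrix",
    rmsdCutoff = "numeric"
  )
)

setValidity("PoseCluster", function(object) {
  msg <- character()
  n <- length(object@memberIdx)
  if (n < 1L) msg <- c(msg, "cluster must have at least one member")
  if (length(object@memberModelId) != n || length(object@memberEnergy) != n ||
      length(object@memberPoseIndex) != n)
    msg <- c(msg, "member metadata vectors must have equal length")
  if (!object@representativeIdx %in% object@memberIdx)
    msg <- c(msg, "representative must be a member of the cluster")
  if (length(msg)) msg else TRUE
})

#' ConsensusAffinity: consensus binding mode and predicted Kd
#'
#' Output of [consensusPipeline()]: the representative pose cluster's mean
#' binding free energy, the thermodynamic dissociation constant
#' Kd = exp(dG/RT), and the occupancy-weighted Kd where the weight is the
#' free/bound ratio of receptor models.
#'
#' @slot proteinId,ligandId identifiers.
#' @slot nModels receptor model count.
#' @slot meanEnergy,sdEnergy mean and sample sd of per-model best energies
#'   in the representative cluster, kcal/mol.
#' @slot kd dissociation constant, mol/L.
#' @slot kdMicromolar the same in uM.
#' @slot bound,free model counts with/without the consensus pose.
#' @slot weightedKd occupancy-weighted Kd, uM.
#' @slot degenerate TRUE when free = 0 and the weight was taken as 1.
#' @slot clusterSizes integer vector of member counts of all clusters.
#' @exportClass ConsensusAffinity
setClass("ConsensusAffinity",
  representation(
    proteinId = "character",
    ligandId = "character",
    nModels = "integer",
    meanEnergy = "numeric",
    sdEnergy = "numeric",
    kd = "numeric",
    kdMicromolar = "numeric",
    bound = "integer",
    free = "integer",
    weightedKd = "numeric",
    degenerate = "logical",
    clusterSizes = "integer"
  )
)

setValidity("ConsensusAffinity", function(object) {
  msg <- character()
  if (object@bound < 1L) msg <- c(msg, "bound must be >= 1")
  if (object@free < 0L) msg <- c(msg, "free must be >= 0")
  if (object@bound + object@free != object@nModels)
    msg <- c(msg, "bound + free must equal nModels")
  if (!is.finite(object@kd) || object@kd <= 0)
    msg <- c(msg, "kd must be positive")
  if (length(msg)) msg else TRUE
})
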