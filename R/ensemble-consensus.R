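## Gas constant in kcal/(mol K); temperatures in Kelvin throughout.
.RGAS <- 1.9872e-3

#' Coordinate RMSD between two ligand poses
#'
#' Root-mean-square deviation over ligand heavy atoms, computed without
#' superposition: poses from an ensemble docked into a shared receptor
#' frame are directly comparable, and superposing them would erase
#' binding-site placement differences.
#'
#' @param a,b nAtoms x 3 coordinate matrices with identical atom count and
#'   ordering (Angstrom).
#' @return RMSD in Angstrom; symmetric, zero iff the coordinates are
#'   identical.
#' @examples
#' a <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
#' b <- matrix(c(0, 0, 0, 3, 0, 0), ncol = 3, byrow = TRUE)
#' poseRMSD(a, b)  # sqrt(4/2)
#' @export
poseRMSD <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("atom-count mismatch: poses have ", nrow(a), " and ", nrow(b),
         " atoms")
  if (ncol(a) != 3L) stop("coordinates must be nAtoms x 3 matrices")
  sqrt(sum((a - b)^2) / nrow(a))
}

## RMSD from pose i to every pose in `idx` (vectorized over idx)
.rmsdFrom <- function(coords, i, idx) {
  nAtoms <- dim(coords)[1L]
  ref <- as.numeric(coords[, , i])
  d2 <- colSums((matrix(coords[, , idx], nrow = 3L * nAtoms) - ref)^2)
  sqrt(d2 / nAtoms)
}

#' Greedy energy-ordered leader clustering of docking poses
#'
#' Clusters all poses of an ensemble by coordinate RMSD: poses are visited
#' in order of ascending energy (ties by model id, then pose index); each
#' unassigned pose seeds a new cluster and absorbs every still-unassigned
#' pose within \code{rmsdCutoff} of it. The procedure is deterministic and
#' assigns every pose to exactly one cluster; cluster seeds (the
#' representatives) are pairwise separated by more than the cutoff.
#'
#' @param ensemble a [PoseEnsemble-class].
#' @param rmsdCutoff clustering radius in Angstrom (> 0; default 2.0, a
#'   common docking-pose clustering convention).
#' @return list of [PoseCluster-class], in seed (energy) order.
#' @examples
#' pe <- simulatePoseEnsemble(nModels = 10, occupancy = 0.6, seed = 1)
#' clusters <- clusterPoses(pe)
#' vapply(clusters, modelsRepresented, integer(1))
#' @export
clusterPoses <- function(ensemble, rmsdCutoff = 2.0) {
  stopifnot(is(ensemble, "PoseEnsemble"))
  validObject(ensemble)
  if (!is.finite(rmsdCutoff) || rmsdCutoff <= 0)
    stop("rmsdCutoff must be positive")
  n <- nPoses(ensemble)
  ord <- order(ensemble@energy, ensemble@modelId, ensemble@poseIndex)
  assigned <- logical(n)
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    cand <- which(!assigned)
    d <- .rmsdFrom(ensemble@coords, i, cand)
    members <- cand[d <= rmsdCutoff]
    assigned[members] <- TRUE
    cl <- new("PoseCluster",
              memberIdx = as.integer(sort(members)),
              memberModelId = ensemble@modelId[sort(members)],
              memberPoseIndex = ensemble@poseIndex[sort(members)],
              memberEnergy = ensemble@energy[sort(members)],
              representativeIdx = as.integer(i),
              representativeCoords = ensemble@coords[, , i, drop = TRUE],
              rmsdCutoff = rmsdCutoff)
    clusters[[length(clusters) + 1L]] <- cl
  }
  clusters
}

#' Select the most populated pose cluster
#'
#' Picks the representative binding mode: the cluster represented in the
#' largest number of distinct receptor models (or, with
#' \code{countBy = "poses"}, with the most member poses). Ties break to the
#' lower mean member energy, then to the lower seed energy, then to the
#' seed's (model id, pose index); the selection is invariant under
#' permutation of the input list.
#'
#' @param clusters non-empty list of [PoseCluster-class].
#' @param countBy "models" (default; population counted as distinct
#'   receptor models, matching free/bound bookkeeping over models) or
#'   "poses".
#' @return The selected [PoseCluster-class].
#' @export
selectRepresentative <- function(clusters, countBy = c("models", "poses")) {
  countBy <- match.arg(countBy)
  if (!length(clusters)) stop("no clusters to select from")
  stopifnot(all(vapply(clusters, is, logical(1), "PoseCluster")))
  pop <- if (countBy == "models")
    vapply(clusters, modelsRepresented, integer(1))
  else vapply(clusters, function(x) length(x@memberIdx), integer(1))
  meanE <- vapply(clusters, function(x) mean(x@memberEnergy), numeric(1))
  repE <- vapply(clusters, function(x)
    x@memberEnergy[match(x@representativeIdx, x@memberIdx)], numeric(1))
  repM <- vapply(clusters, function(x)
    x@memberModelId[match(x@representativeIdx, x@memberIdx)], integer(1))
  repP <- vapply(clusters, function(x)
    x@memberPoseIndex[match(x@representativeIdx, x@memberIdx)], integer(1))
  best <- order(-pop, meanE, repE, repM, repP)[1L]
  clusters[[best]]
}

#' Aggregate binding energies of a cluster over receptor models
#'
#' For each receptor model represented in the cluster, takes that model's
#' best (lowest) member energy, then returns the mean and sample standard
#' deviation over those per-model values. Using one value per model avoids
#' over-weighting models that contribute many near-duplicate poses.
#'
#' @param cluster a [PoseCluster-class].
#' @return named list with \code{meanEnergy} and \code{sdEnergy} (kcal/mol;
#'   \code{sdEnergy} is 0 when only one model is represented).
#' @importFrom stats sd
#' @export
aggregateEnergy <- function(cluster) {
  stopifnot(is(cluster, "PoseCluster"))
  perModel <- vapply(split(cluster@memberEnergy, cluster@memberModelId),
                     min, numeric(1))
  list(meanEnergy = mean(perModel),
       sdEnergy = if (length(perModel) > 1L) sd(perModel) else 0)
}

#' Convert a binding free energy to a dissociation constant
#'
#' Thermodynamic conversion \eqn{K_d = \exp(\Delta G / RT)} with
#' R = 1.9872e-3 kcal/(mol K).
#'
#' @param meanEnergy binding free energy dG, kcal/mol.
#' @param temperature Kelvin (> 0; default 300).
#' @return Kd in mol/L; strictly increasing in \code{meanEnergy}.
#' @examples
#' kdFromEnergy(-6.8635) * 1e6  # ~10 uM
#' @export
kdFromEnergy <- function(meanEnergy, temperature = 300) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  exp(meanEnergy / (.RGAS * temperature))
}

#' Inverse of [kdFromEnergy()]: free energy from a dissociation constant
#'
#' @param kd dissociation constant, mol/L (> 0).
#' @param temperature Kelvin (default 300).
#' @return dG in kcal/mol.
#' @export
energyFromKd <- function(kd, temperature = 300) {
  if (any(kd <= 0)) stop("kd must be positive")
  .RGAS * temperature * log(kd)
}

#' Weight a predicted Kd by receptor-model occupancy
#'
#' Weights the thermodynamic Kd by the fraction free/bound, where bound is
#' the number of receptor models exhibiting the consensus pose and free the
#' number that do not. When every model is bound (free = 0) the literal
#' weight would give an unphysical zero, so the weight is taken as 1 and
#' the result flagged degenerate.
#'
#' @param kd dissociation constant (any concentration unit; the weight is
#'   dimensionless).
#' @param bound number of models exhibiting the consensus pose (>= 1).
#' @param free number of models not exhibiting it (>= 0).
#' @return list with \code{weightedKd} and logical \code{degenerate}.
#' @examples
#' occupancyWeightedKd(10, 80, 20)  # 10 * 20/80 = 2.5
#' @export
occupancyWeightedKd <- function(kd, bound, free) {
  if (bound < 1) stop("bound must be >= 1")
  if (free < 0) stop("free must be >= 0")
  if (free == 0)
    list(weightedKd = kd, degenerate = TRUE)
  else
    list(weightedKd = kd * free / bound, degenerate = FALSE)
}

#' Full consensus-affinity pipeline for one pose ensemble
#'
#' Composes [clusterPoses()], [selectRepresentative()],
#' [aggregateEnergy()], [kdFromEnergy()] and [occupancyWeightedKd()]:
#' clusters all poses, selects the most populated cluster as the consensus
#' binding mode, averages its per-model best energies, converts the mean to
#' a Kd at the given temperature and weights it by the free/bound model
#' ratio. \code{bound} is the number of distinct models in the selected
#' cluster; \code{free = nModels - bound}.
#'
#' @param ensemble a [PoseEnsemble-class].
#' @param rmsdCutoff clustering radius, Angstrom (default 2.0).
#' @param temperature Kelvin (default 300).
#' @param countBy population definition passed to [selectRepresentative()].
#' @return A [ConsensusAffinity-class].
#' @examples
#' pe <- simulatePoseEnsemble(nModels = 20, occupancy = 0.6,
#'                            energyMean = -6.8635, energySd = 0, seed = 7)
#' consensusPipeline(pe)
#' @export
consensusPipeline <- function(ensemble, rmsdCutoff = 2.0, temperature = 300,
                              countBy = c("models", "poses")) {
  countBy <- match.arg(countBy)
  clusters <- clusterPoses(ensemble, rmsdCutoff)
  rep <- selectRepresentative(clusters, countBy = countBy)
  agg <- aggregateEnergy(rep)
  kd <- kdFromEnergy(agg$meanEnergy, temperature)
  bound <- modelsRepresented(rep)
  free <- nModels(ensemble) - bound
  w <- occupancyWeightedKd(kd * 1e6, bound, free)
  res <- new("ConsensusAffinity",
             proteinId = ensemble@proteinId, ligandId = ensemble@ligandId,
             nModels = ensemble@nModels,
             meanEnergy = agg$meanEnergy, sdEnergy = agg$sdEnergy,
             kd = kd, kdMicromolar = kd * 1e6,
             bound = as.integer(bound), free = as.integer(free),
             weightedKd = w$weightedKd, degenerate = w$degenerate,
             clusterSizes = vapply(clusters, function(x)
               length(x@memberIdx), integer(1)))
  validObject(res)
  res
}
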