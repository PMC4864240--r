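#' Accessor generics
#'
#' Small accessor family for the assay and docking classes: identifiers,
#' pose counts, per-pose metadata and cluster summaries. Accessors are the
#' supported way to read object contents; slots are internal.
#'
#' @param x an object of one of the package's classes.
#' @param i pose index (for [poseCoords()]).
#' @return \code{proteinId}/\code{ligandId}: character scalars;
#'   \code{nPoses}, \code{nModels}, \code{modelsRepresented}: integers;
#'   \code{poseEnergy}, \code{modelIds}: vectors over poses;
#'   \code{poseCoords}: an nAtoms x 3 coordinate matrix;
#'   \code{memberIndices}: integer indices of cluster members.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("ligandId", function(x) standardGeneric("ligandId"))

#' @rdname accessors
#' @export
setGeneric("nPoses", function(x) standardGeneric("nPoses"))

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("poseEnergy", function(x) standardGeneric("poseEnergy"))

#' @rdname accessors
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname accessors
#' @export
setGeneric("poseCoords", function(x, i) standardGeneric("poseCoords"))

#' @rdname accessors
#' @export
setGeneric("modelsRepresented", function(x) standardGeneric("modelsRepresented"))

#' @rdname accessors
#' @export
setGeneric("memberIndices", function(x) standardGeneric("memberIndices"))

#' @rdname accessors
#' @export
setGeneric("kProbe", function(x) standardGeneric("kProbe"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("kiValue", function(x) standardGeneric("kiValue"))

#' @rdname accessors
#' @export
setGeneric("fitStatus", function(x) standardGeneric("fitStatus"))

## ----------------------------------------------------------------------

#' @describeIn accessors protein identifier of a SaturationSeries
setMethod("proteinId", "SaturationSeries", function(x) x@proteinId)
#' @describeIn accessors protein identifier of a CompetitionSeries
setMethod("proteinId", "CompetitionSeries", function(x) x@proteinId)
#' @describeIn accessors protein identifier of a PoseEnsemble
setMethod("proteinId", "PoseEnsemble", function(x) x@proteinId)
#' @describeIn accessors protein identifier of an AffinityResult
setMethod("proteinId", "AffinityResult", function(x) x@proteinId)
#' @describeIn accessors protein identifier of a ConsensusAffinity
setMethod("proteinId", "ConsensusAffinity", function(x) x@proteinId)

#' @describeIn accessors ligand identifier of a CompetitionSeries
setMethod("ligandId", "CompetitionSeries", function(x) x@ligandId)
#' @describeIn accessors ligand identifier of a PoseEnsemble
setMethod("ligandId", "PoseEnsemble", function(x) x@ligandId)
#' @describeIn accessors ligand identifier of an AffinityResult
setMethod("ligandId", "AffinityResult", function(x) x@ligandId)
#' @describeIn accessors ligand identifier of a ConsensusAffinity
setMethod("ligandId", "ConsensusAffinity", function(x) x@ligandId)

#' @describeIn accessors number of poses in an ensemble
setMethod("nPoses", "PoseEnsemble", function(x) length(x@modelId))
#' @describeIn accessors number of receptor models in an ensemble
setMethod("nModels", "PoseEnsemble", function(x) x@nModels)
#' @describeIn accessors number of receptor models behind a consensus
setMethod("nModels", "ConsensusAffinity", function(x) x@nModels)

#' @describeIn accessors per-pose binding energies (kcal/mol)
setMethod("poseEnergy", "PoseEnsemble", function(x) x@energy)
#' @describeIn accessors per-pose receptor model ids
setMethod("modelIds", "PoseEnsemble", function(x) x@modelId)

#' @describeIn accessors coordinates of pose \code{i} as an nAtoms x 3 matrix
setMethod("poseCoords", "PoseEnsemble", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= length(x@modelId))
  x@coords[, , i, drop = TRUE]
})

#' @describeIn accessors distinct receptor models among cluster members
setMethod("modelsRepresented", "PoseCluster",
          function(x) length(unique(x@memberModelId)))
#' @describeIn accessors ensemble indices of cluster members
setMethod("memberIndices", "PoseCluster", function(x) x@memberIdx)

#' @describeIn accessors probe dissociation constant of a SaturationFit (uM)
setMethod("kProbe", "SaturationFit", function(x) x@kProbe)
#' @describeIn accessors probe dissociation constant of an AffinityResult (uM)
setMethod("kProbe", "AffinityResult", function(x) x@kProbe)

#' @describeIn accessors IC50 of a CompetitionFit (uM)
setMethod("ic50", "CompetitionFit", function(x) x@ic50)
#' @describeIn accessors IC50 of an AffinityResult (uM)
setMethod("ic50", "AffinityResult", function(x) x@ic50)

#' @describeIn accessors inhibition constant Ki of an AffinityResult (uM)
setMethod("kiValue", "AffinityResult", function(x) x@ki)

#' @describeIn accessors status of a CompetitionFit
setMethod("fitStatus", "CompetitionFit", function(x) x@status)
#' @describeIn accessors status of an AffinityResult
setMethod("fitStatus", "AffinityResult", function(x) x@status)

## ----------------------------------------------------------------------
## show methods

setMethod("show", "SaturationSeries", function(object) {
  cat("SaturationSeries for", object@proteinId, "\n",
      " ", length(object@probeConc), "points, probe",
      sprintf("%.3g-%.3g uM,", min(object@probeConc), max(object@probeConc)),
      "protein", object@proteinConc, "uM\n")
})

setMethod("show", "SaturationFit", function(object) {
  cat(sprintf("SaturationFit (%s) for %s: K_probe = %.3f uM, Bmax = %.3g AU, R2 = %.4f\n",
              object@method, object@proteinId, object@kProbe, object@bMax,
              object@goodness))
})

setMethod("show", "CompetitionSeries", function(object) {
  cat("CompetitionSeries:", object@ligandId, "vs", object@proteinId, "\n",
      " ", length(object@competitorConc), "points, competitor",
      sprintf("%.3g-%.3g uM,", min(object@competitorConc),
              max(object@competitorConc)),
      "probe", object@probeConc, "uM 1-NPN\n")
})

setMethod("show", "CompetitionFit", function(object) {
  cat(sprintf("CompetitionFit (%s): status = %s", object@method,
              object@status))
  if (is.finite(object@ic50)) cat(sprintf(", IC50 = %.4g uM", object@ic50))
  cat("\n")
})

setMethod("show", "AffinityResult", function(object) {
  cat("AffinityResult:", object@ligandId, "vs", object@proteinId, "-")
  if (identical(object@status, "determined"))
    cat(sprintf(" IC50 = %.4g uM, Ki = %.4g uM\n", object@ic50, object@ki))
  else cat(" ", object@status, "\n")
})

setMethod("show", "PoseEnsemble", function(object) {
  cat("PoseEnsemble:", object@ligandId, "docked to", object@proteinId, "\n",
      " ", length(object@modelId), "poses over", object@nModels,
      "receptor models,", dim(object@coords)[1], "ligand atoms\n")
})

setMethod("show", "PoseCluster", function(object) {
  cat(sprintf("PoseCluster: %d poses over %d models, seed energy %.3f kcal/mol (cutoff %.2f A)\n",
              length(object@memberIdx), modelsRepresented(object),
              object@memberEnergy[match(object@representativeIdx, object@memberIdx)],
              object@rmsdCutoff))
})

setMethod("show", "ConsensusAffinity", function(object) {
  cat("ConsensusAffinity:", object@ligandId, "vs", object@proteinId, "\n")
  cat(sprintf("  mean dG = %.3f +/- %.3f kcal/mol\n", object@meanEnergy,
              object@sdEnergy))
  cat(sprintf("  Kd = %.4g uM; bound/free = %d/%d; weighted Kd = %.4g uM%s\n",
              object@kdMicromolar, object@bound, object@free,
              object@weightedKd,
              if (object@degenerate) " (degenerate: free = 0)" else ""))
})
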