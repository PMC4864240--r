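# Fixture builders shared across test files. All data are generated in
# code; nothing is read from disk except through the package's own IO.

# Pose ensemble from an explicit list of coordinate matrices.
makeEnsemble <- function(coordList, energy = NULL, modelId = NULL,
                         poseIndex = NULL, nModels = NULL) {
  n <- length(coordList)
  nAtoms <- nrow(coordList[[1L]])
  coords <- array(NA_real_, dim = c(nAtoms, 3L, n))
  for (i in seq_len(n)) coords[, , i] <- coordList[[i]]
  if (is.null(modelId)) modelId <- seq_len(n)
  if (is.null(poseIndex)) poseIndex <- rep(1L, n)
  if (is.null(energy)) energy <- -6 - seq_len(n) * 0.1
  if (is.null(nModels)) nModels <- max(modelId)
  PoseEnsemble("prot", "lig", nModels, modelId, poseIndex, energy, coords)
}

# n atoms at a translated base geometry (rigid translation => RMSD = |shift|)
translatedPose <- function(base, dx = 0, dy = 0, dz = 0) {
  sweep(base, 2L, c(dx, dy, dz), `+`)
}

baseGeometry <- function(nAtoms = 5, seed = 99) {
  set.seed(seed)
  matrix(rnorm(nAtoms * 3, sd = 2), nAtoms, 3)
}

# Independent RMSD oracle: all pairwise pose RMSDs via stats::dist on the
# flattened coordinates (Frobenius norm scaled by sqrt(nAtoms)).
oracleRmsdMatrix <- function(ensemble) {
  n <- nPoses(ensemble)
  nAtoms <- dim(ensemble@coords)[1L]
  flat <- t(vapply(seq_len(n), function(i) as.numeric(poseCoords(ensemble, i)),
                   numeric(nAtoms * 3L)))
  as.matrix(stats::dist(flat)) / sqrt(nAtoms)
}

# Ct record table built by hand from per-sample, per-gene mean Ct values.
makeCtTable <- function(values, nRep = 1L) {
  rows <- do.call(rbind, lapply(names(values), function(s) {
    genes <- values[[s]]
    do.call(rbind, lapply(names(genes), function(g)
      data.frame(sample_id = s, gene_id = g, replicate = seq_len(nRep),
                 ct = rep(genes[[g]], nRep), stringsAsFactors = FALSE)))
  }))
  rownames(rows) <- NULL
  rows
}
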