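## Shared delimited-text reader: header-checked, typed, with row-numbered
## rejection of malformed fields. Row numbers cite file lines (header = 1).
.readDelim <- function(path, required, numericCols, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read '", path, "': ",
                                          conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", path, "': missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("'", path, "': no data rows")
  for (col in intersect(numericCols, names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(as.character(v))))
    if (length(bad))
      stop("'", path, "': non-numeric value \"", v[bad[1L]],
           "\" in column '", col, "' at row ", bad[1L] + 1L)
    df[[col]] <- num
  }
  df
}

#' Read saturation titration data
#'
#' Reads delimited text with columns \code{protein_id},
#' \code{probe_conc_uM}, \code{intensity} (comma-separated by default) and
#' returns one [SaturationSeries-class] per protein.
#'
#' @param path file path.
#' @param proteinConc protein concentration, uM (default 2).
#' @param sep field separator (default ",").
#' @return named list of [SaturationSeries-class], keyed by protein id.
#' @export
readSaturationTable <- function(path, proteinConc = 2, sep = ",") {
  df <- .readDelim(path, c("protein_id", "probe_conc_uM", "intensity"),
                   c("probe_conc_uM", "intensity"), sep)
  lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$probe_conc_uM), ]
    SaturationSeries(d$protein_id[1L], d$probe_conc_uM, d$intensity,
                     proteinConc)
  })
}

#' Read competitive displacement data
#'
#' Reads delimited text with columns \code{protein_id}, \code{ligand_id},
#' \code{competitor_conc_uM} and either \code{percent_fluorescence} or raw
#' \code{intensity}. Raw intensities require a zero-competitor row per
#' series and are normalized internally with [normalizeFluorescence()].
#'
#' @param path file path.
#' @param probeConc 1-NPN concentration, uM (default 2).
#' @param sep field separator (default ",").
#' @return named list of [CompetitionSeries-class], keyed by
#'   "protein/ligand".
#' @export
readCompetitionTable <- function(path, probeConc = 2, sep = ",") {
  df <- .readDelim(path, c("protein_id", "ligand_id", "competitor_conc_uM"),
                   c("competitor_conc_uM", "percent_fluorescence",
                     "intensity"), sep)
  hasPct <- "percent_fluorescence" %in% names(df)
  if (!hasPct && !"intensity" %in% names(df))
    stop("'", path, "': need a 'percent_fluorescence' or 'intensity' column")
  key <- paste(df$protein_id, df$ligand_id, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$competitor_conc_uM), ]
    pct <- if (hasPct) d$percent_fluorescence else {
      i0 <- which(d$competitor_conc_uM == 0)
      if (!length(i0))
        stop("series ", d$protein_id[1L], "/", d$ligand_id[1L],
             ": raw intensities require a zero-competitor row")
      normalizeFluorescence(d$intensity, d$intensity[i0[1L]])
    }
    CompetitionSeries(d$protein_id[1L], d$ligand_id[1L],
                      d$competitor_conc_uM, pct, probeConc)
  })
}

#' Read a docking pose table
#'
#' Reads long-format delimited text, one row per ligand atom per pose, with
#' columns \code{model_id}, \code{pose_index}, \code{energy_kcal_mol},
#' \code{atom_index}, \code{x}, \code{y}, \code{z}. All poses must share
#' the same atom count and ordering.
#'
#' @param path file path.
#' @param proteinId,ligandId identifiers for the ensemble (overridden by
#'   \code{protein_id}/\code{ligand_id} columns when present).
#' @param nModels receptor model count; defaults to \code{max(model_id)}.
#' @param sep field separator (default ",").
#' @return A [PoseEnsemble-class].
#' @export
readPoseTable <- function(path, proteinId = "protein", ligandId = "ligand",
                          nModels = NULL, sep = ",") {
  df <- .readDelim(path, c("model_id", "pose_index", "energy_kcal_mol",
                           "atom_index", "x", "y", "z"),
                   c("model_id", "pose_index", "energy_kcal_mol",
                     "atom_index", "x", "y", "z"), sep)
  if ("protein_id" %in% names(df)) proteinId <- df$protein_id[1L]
  if ("ligand_id" %in% names(df)) ligandId <- df$ligand_id[1L]
  df <- df[order(df$model_id, df$pose_index, df$atom_index), ]
  key <- paste(df$model_id, df$pose_index, sep = "/")
  poses <- split(df, factor(key, levels = unique(key)))
  nAtoms <- unique(vapply(poses, nrow, integer(1)))
  if (length(nAtoms) != 1L)
    stop("'", path, "': poses have inconsistent atom counts (",
         paste(nAtoms, collapse = ", "), ")")
  coords <- array(NA_real_, dim = c(nAtoms, 3L, length(poses)))
  for (i in seq_along(poses))
    coords[, , i] <- as.matrix(poses[[i]][, c("x", "y", "z")])
  PoseEnsemble(proteinId, ligandId,
               nModels = if (is.null(nModels)) max(df$model_id) else nModels,
               modelId = vapply(poses, function(p) p$model_id[1L], numeric(1)),
               poseIndex = vapply(poses, function(p) p$pose_index[1L],
                                  numeric(1)),
               energy = vapply(poses, function(p) p$energy_kcal_mol[1L],
                               numeric(1)),
               coords = coords)
}

#' Read a Ct table
#'
#' Reads delimited text with columns \code{sample_id}, \code{gene_id},
#' \code{replicate}, \code{ct}.
#'
#' @param path file path.
#' @param sep field separator (default ",").
#' @return data.frame suitable for [ddCtFoldChange()].
#' @export
readCtTable <- function(path, sep = ",") {
  .readDelim(path, c("sample_id", "gene_id", "replicate", "ct"),
             c("replicate", "ct"), sep)
}

## ---------------------------------------------------------------------------
## writers
## ---------------------------------------------------------------------------

#' Write simulated or measured series back to the canonical formats
#'
#' Writers producing the same delimited schemas the readers consume, so
#' simulated data can round-trip through the file interface.
#'
#' @param x object to write ([SaturationSeries-class],
#'   [CompetitionSeries-class], [PoseEnsemble-class], or a Ct data.frame).
#'   Saturation/competition writers also accept a list of series.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeSaturationTable <- function(x, path) {
  if (is(x, "SaturationSeries")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(protein_id = s@proteinId, probe_conc_uM = s@probeConc,
               intensity = s@intensity, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeCompetitionTable <- function(x, path) {
  if (is(x, "CompetitionSeries")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(protein_id = s@proteinId, ligand_id = s@ligandId,
               competitor_conc_uM = s@competitorConc,
               percent_fluorescence = s@percentFluorescence,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writePoseTable <- function(x, path) {
  stopifnot(is(x, "PoseEnsemble"))
  nAtoms <- dim(x@coords)[1L]
  n <- nPoses(x)
  df <- data.frame(
    protein_id = x@proteinId, ligand_id = x@ligandId,
    model_id = rep(x@modelId, each = nAtoms),
    pose_index = rep(x@poseIndex, each = nAtoms),
    energy_kcal_mol = rep(x@energy, each = nAtoms),
    atom_index = rep(seq_len(nAtoms), n),
    x = as.numeric(apply(x@coords, 3, function(m) m[, 1L])),
    y = as.numeric(apply(x@coords, 3, function(m) m[, 2L])),
    z = as.numeric(apply(x@coords, 3, function(m) m[, 3L])),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeCtTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write affinity results
#'
#' \code{writeAffinityTable} writes the rendered ligand-by-protein table
#' (delimited text); \code{writeAffinityResults} writes the
#' machine-readable record list (JSON, one record per protein-ligand pair
#' with ic50, ki, status and probe constants).
#'
#' @param results list of [AffinityResult-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAffinityTable <- function(results, path) {
  utils::write.csv(buildAffinityTable(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAffinityTable
#' @export
writeAffinityResults <- function(results, path) {
  recs <- lapply(results, function(r)
    list(protein_id = r@proteinId, ligand_id = r@ligandId,
         ic50_uM = r@ic50, ki_uM = r@ki, k_probe_uM = r@kProbe,
         probe_conc_uM = r@probeConc, status = r@status))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a consensus-affinity report
#'
#' Key-value JSON document with mean/sd energy, Kd (uM), bound/free model
#' counts, the occupancy-weighted Kd and all cluster sizes.
#'
#' @param x a [ConsensusAffinity-class] or a list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConsensusReport <- function(x, path) {
  if (is(x, "ConsensusAffinity")) x <- list(x)
  recs <- lapply(x, function(r)
    list(protein_id = r@proteinId, ligand_id = r@ligandId,
         n_models = r@nModels, mean_energy_kcal_mol = r@meanEnergy,
         sd_energy_kcal_mol = r@sdEnergy, kd_uM = r@kdMicromolar,
         bound = r@bound, free = r@free, weighted_kd_uM = r@weightedKd,
         degenerate = r@degenerate, cluster_sizes = r@clusterSizes))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
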