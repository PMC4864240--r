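#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression of a target gene normalized to a reference
#' (housekeeping) gene and a calibrator sample, following the Livak
#' convention: replicate Ct values are averaged per sample and gene before
#' differencing,
#' \deqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference},\quad
#'       \Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator},\quad
#'       fold = 2^{-\Delta\Delta Ct}.}
#' The sd of \eqn{\Delta Ct} is propagated from the replicate Ct scatter as
#' \eqn{\sqrt{s^2_{target} + s^2_{reference}}} and mapped through the
#' exponential, giving the asymmetric fold range
#' \eqn{[2^{-(\Delta\Delta Ct + s)}, 2^{-(\Delta\Delta Ct - s)}]}.
#'
#' @param ct data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{replicate}, \code{ct} (one row per replicate measurement).
#' @param targetGene,referenceGene gene identifiers; every sample must have
#'   both.
#' @param calibratorSample the sample all others are expressed relative to;
#'   its fold change is exactly 1.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{gene_id}, \code{n_target}, \code{n_reference}, \code{delta_ct},
#'   \code{delta_delta_ct}, \code{fold_change}, \code{sd}, \code{fold_lo},
#'   \code{fold_hi}. \code{sd} is the half-width of the fold range.
#' @examples
#' ct <- simulateCtTable(foldChanges = c(control = 1, treated = 8),
#'                       noiseSd = 0, seed = 1)
#' ddCtFoldChange(ct, "CSP1", "actin", "control")
#' @importFrom stats sd
#' @export
ddCtFoldChange <- function(ct, targetGene, referenceGene, calibratorSample) {
  req <- c("sample_id", "gene_id", "replicate", "ct")
  miss <- setdiff(req, names(ct))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("Ct values must be finite")
  samples <- unique(as.character(ct$sample_id))
  if (!calibratorSample %in% samples)
    stop("calibrator sample '", calibratorSample, "' not present")

  geneStats <- function(s, g) {
    v <- ct$ct[ct$sample_id == s & ct$gene_id == g]
    if (!length(v))
      stop("no Ct measurements for gene '", g, "' in sample '", s, "'")
    list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
         n = length(v))
  }

  perSample <- lapply(samples, function(s) {
    tg <- geneStats(s, targetGene)
    rf <- geneStats(s, referenceGene)
    list(sample = s, dct = tg$mean - rf$mean,
         sdDct = sqrt(tg$sd^2 + rf$sd^2), nT = tg$n, nR = rf$n)
  })
  names(perSample) <- samples
  dctCal <- perSample[[calibratorSample]]$dct

  rows <- lapply(perSample, function(p) {
    ddct <- p$dct - dctCal
    if (identical(p$sample, calibratorSample)) ddct <- 0  # exact by construction
    fold <- 2^(-ddct)
    lo <- 2^(-(ddct + p$sdDct)); hi <- 2^(-(ddct - p$sdDct))
    data.frame(sample_id = p$sample, gene_id = targetGene,
               n_target = p$nT, n_reference = p$nR,
               delta_ct = p$dct, delta_delta_ct = ddct,
               fold_change = fold, sd = (hi - lo) / 2,
               fold_lo = lo, fold_hi = hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise relative-expression results per group
#'
#' Per-group mean, sample sd and count of fold changes, e.g. per
#' developmental stage, insecticide dose or exposure time.
#'
#' @param results data.frame with a \code{fold_change} column (as returned
#'   by [ddCtFoldChange()]).
#' @param grouping either a character vector of column names in
#'   \code{results} to group by, or a vector/factor of group labels with
#'   one entry per row.
#' @return data.frame with the grouping columns plus \code{mean},
#'   \code{sd} (NA for singleton groups) and \code{n}. Groups present as
#'   factor levels but empty are omitted with a warning; empty input gives
#'   an empty table.
#' @importFrom stats sd
#' @export
summarizeReplicates <- function(results, grouping) {
  if (is.character(grouping) && all(grouping %in% names(results))) {
    keys <- results[grouping]
  } else {
    if (length(grouping) != nrow(results) && nrow(results) > 0)
      stop("grouping must name columns of 'results' or have one entry per row")
    keys <- data.frame(group = grouping)
  }
  if (!nrow(results)) {
    out <- keys[0, , drop = FALSE]
    out$mean <- numeric(); out$sd <- numeric(); out$n <- integer()
    return(out)
  }
  if (is.factor(keys[[1L]]) && any(!levels(keys[[1L]]) %in% keys[[1L]]))
    warning("empty group(s) omitted: ",
            paste(setdiff(levels(keys[[1L]]), unique(keys[[1L]])),
                  collapse = ", "))
  keyStr <- do.call(paste, c(lapply(keys, as.character), sep = "\r"))
  idx <- split(seq_len(nrow(results)), factor(keyStr, levels = unique(keyStr)))
  rows <- lapply(idx, function(i) {
    f <- results$fold_change[i]
    cbind(keys[i[1L], , drop = FALSE],
          data.frame(mean = mean(f),
                     sd = if (length(f) > 1L) sd(f) else NA_real_,
                     n = length(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
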