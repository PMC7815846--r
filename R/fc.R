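## Functional connectome construction from regional signal tables, and the
## structural-support masking rule. Confound regression is out of scope:
## this module consumes already-cleaned regional time series.

#' Build a functional connectivity matrix from regional time series
#'
#' Entry (i, j) is the Fisher z-transform atanh(r) of the correlation
#' between the time series of regions i and j; the diagonal is zero and
#' the matrix symmetric by construction. Correlations are clamped to
#' +/- (1 - 1e-12) before the transform so perfectly (anti)correlated
#' rows stay finite. Pearson correlation is the default; Spearman is
#' exposed as an option.
#'
#' @param signals numeric matrix, regions x timepoints (>= 30 timepoints).
#' @param subjectId subject identifier.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return A functional \linkS4class{ConnectivityMatrix}.
#' @export
fcFromTimeseries <- function(signals, subjectId = "unknown",
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  signals <- as.matrix(signals)
  if (ncol(signals) < 30)
    stop("need at least 30 timepoints")
  sds <- apply(signals, 1, stats::sd)
  if (any(sds == 0))
    stop("constant signal in region(s): ",
         paste(which(sds == 0) - 1L, collapse = ", "))
  r <- stats::cor(t(signals), method = method)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  z <- (z + t(z)) / 2   # exact symmetry despite floating-point round-off
  diag(z) <- 0
  ConnectivityMatrix(z, modality = "functional", subjectId = subjectId,
                     weightSemantics = sprintf("Fisher-z %s correlation", method))
}

#' Mask functional connections lacking structural support
#'
#' Discards functional connections between regions with no anatomical
#' connection: output(i, j) = fc(i, j) where sc(i, j) > 0, else 0. The
#' modality stays functional. Idempotent.
#'
#' @param fc functional \linkS4class{ConnectivityMatrix}.
#' @param sc structural \linkS4class{ConnectivityMatrix} on the same
#'   parcellation.
#' @return the masked functional \linkS4class{ConnectivityMatrix}.
#' @export
maskFunctionalBySC <- function(fc, sc) {
  if (modality(fc) != "functional" || modality(sc) != "structural")
    stop("arguments must be a functional and a structural matrix")
  if (nodeCount(fc) != nodeCount(sc))
    stop("matrices have different sizes")
  v <- connValues(fc)
  v[connValues(sc) == 0] <- 0
  ConnectivityMatrix(v, modality = "functional", subjectId = fc@subjectId,
                     weightSemantics = paste(fc@weightSemantics,
                                             "(SC-masked)"))
}
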