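## The central statistic: per-node SC-FC coupling, the Spearman rank
## correlation between the non-zero elements of a region's structural and
## functional connectivity profiles.

#' Coupling of one region's connectivity profiles
#'
#' Restricts both profiles to the indices where the structural entry is
#' nonzero (the structural support defines "non-zero elements"; exact-zero
#' functional values inside the support are retained as data) and returns
#' their Spearman rank correlation with average-rank tie handling. Returns
#' \code{NA} (invalid) if fewer than \code{minNonzero} entries survive or
#' either restricted profile is constant.
#'
#' @param scProfile numeric structural profile (self-entry removed).
#' @param fcProfile numeric functional profile, same length.
#' @param minNonzero minimum surviving entries (default 3).
#' @return Spearman correlation, or \code{NA} if invalid.
#' @export
regionalCoupling <- function(scProfile, fcProfile, minNonzero = 3L) {
  if (length(scProfile) != length(fcProfile))
    stop("profiles must have the same length")
  keep <- scProfile != 0
  if (sum(keep) < minNonzero) return(NA_real_)
  s <- scProfile[keep]
  f <- fcProfile[keep]
  if (stats::sd(s) == 0 || stats::sd(f) == 0) return(NA_real_)
  stats::cor(s, f, method = "spearman")
}

#' Per-node coupling map of one subject
#'
#' Applies \code{\link{regionalCoupling}} to every region, excluding the
#' diagonal self-entry from both profiles.
#'
#' @param sc structural \linkS4class{ConnectivityMatrix}.
#' @param fc functional \linkS4class{ConnectivityMatrix} (already
#'   SC-masked; see \code{\link{maskFunctionalBySC}}).
#' @param minNonzero minimum structural neighbours for a valid node.
#' @return A \linkS4class{CouplingMap}.
#' @export
couplingMap <- function(sc, fc, minNonzero = 3L) {
  if (nodeCount(sc) != nodeCount(fc))
    stop("matrices have different sizes")
  n <- nodeCount(sc)
  S <- connValues(sc)
  Fv <- connValues(fc)
  vals <- vapply(seq_len(n), function(i) {
    regionalCoupling(S[i, -i], Fv[i, -i], minNonzero)
  }, numeric(1))
  CouplingMap(vals, validMask = !is.na(vals),
              subjectId = fc@subjectId, minNonzeroUsed = minNonzero)
}

#' Global (whole-network) coupling
#'
#' Arithmetic mean of the coupling values over valid nodes.
#'
#' @param map a \linkS4class{CouplingMap}.
#' @return numeric scalar.
#' @export
globalCoupling <- function(map) {
  if (!any(map@validMask))
    stop("coupling map has no valid nodes")
  mean(map@values[map@validMask])
}

#' Group-mean coupling map
#'
#' Per-node mean over the subjects where the node is valid; a node is
#' valid in the group map when it is valid in at least 50% of subjects.
#'
#' @param maps list of \linkS4class{CouplingMap} objects.
#' @param subjectIds optional character selection of subjects.
#' @return A \linkS4class{CouplingMap} with subjectId \code{"group_mean"}.
#' @export
groupMeanMap <- function(maps, subjectIds = NULL) {
  if (!is.null(subjectIds))
    maps <- Filter(function(m) m@subjectId %in% subjectIds, maps)
  if (length(maps) == 0)
    stop("empty subject selection")
  vals <- vapply(maps, couplingValues, numeric(nodeCount(maps[[1]])))
  vals <- matrix(vals, ncol = length(maps))
  validFrac <- rowMeans(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  ok <- validFrac >= 0.5
  m[!ok] <- NA_real_
  CouplingMap(m, validMask = ok, subjectId = "group_mean",
              minNonzeroUsed = maps[[1]]@minNonzeroUsed)
}
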