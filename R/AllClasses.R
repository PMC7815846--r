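#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parcellation
## ---------------------------------------------------------------------------

#' Parcellation: node metadata for a parcellated cortex
#'
#' Holds one row of metadata per cortical region: a stable 0-based node id,
#' a label, hemisphere membership, a centroid on the unit sphere (used for
#' spin permutations), an anatomical-space centroid in mm (y is the
#' anterior--posterior axis, posterior negative), a network label and a
#' hierarchy level from 1 (unimodal sensory/sensorimotor) to 4 (transmodal,
#' default-mode-like).
#'
#' Node ids are contiguous \code{0..n-1}; all cross-module references are by
#' node id, never by label. Internally R objects index nodes \code{1..n} in
#' the same order.
#'
#' @slot nodeId integer, 0-based contiguous ids.
#' @slot label character region labels.
#' @slot hemisphere character, \code{"L"} or \code{"R"} per node.
#' @slot sphereXYZ n x 3 numeric matrix of unit-sphere centroids.
#' @slot anatXYZ n x 3 numeric matrix of anatomical centroids (mm).
#' @slot network character network label per node.
#' @slot hierarchyLevel integer in 1..4 per node.
#'
#' @export
setClass("Parcellation",
  representation(
    nodeId = "integer",
    label = "character",
    hemisphere = "character",
    sphereXYZ = "matrix",
    anatXYZ = "matrix",
    network = "character",
    hierarchyLevel = "integer"
  )
)

setValidity("Parcellation", function(object) {
  n <- length(object@nodeId)
  msgs <- character(0)
  if (!identical(object@nodeId, seq_len(n) - 1L))
    msgs <- c(msgs, "nodeId must be 0..n-1 with no gaps or duplicates")
  if (length(object@label) != n || length(object@hemisphere) != n ||
      length(object@network) != n || length(object@hierarchyLevel) != n)
    msgs <- c(msgs, "all per-node fields must have the same length")
  if (!all(object@hemisphere %in% c("L", "R")))
    msgs <- c(msgs, "hemisphere codes must be 'L' or 'R'")
  if (!identical(dim(object@sphereXYZ), c(n, 3L)) ||
      !identical(dim(object@anatXYZ), c(n, 3L)))
    msgs <- c(msgs, "sphereXYZ and anatXYZ must be n x 3 matrices")
  else {
    norms <- sqrt(rowSums(object@sphereXYZ^2))
    if (any(abs(norms - 1) > 1e-6))
      msgs <- c(msgs, "sphere centroids must have unit norm (tolerance 1e-6)")
  }
  if (!all(object@hierarchyLevel %in% 1:4))
    msgs <- c(msgs, "hierarchyLevel must lie in {1,2,3,4}")
  ## each network label maps to exactly one hierarchy level
  if (length(object@network) == n && length(object@hierarchyLevel) == n) {
    lv <- tapply(object@hierarchyLevel, object@network,
                 function(x) length(unique(x)))
    if (any(lv > 1))
      msgs <- c(msgs, "every network must map to exactly one hierarchy level")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Parcellation
#'
#' @param label character region labels.
#' @param hemisphere character vector of \code{"L"}/\code{"R"}.
#' @param sphereXYZ n x 3 matrix of unit-sphere centroids.
#' @param anatXYZ n x 3 matrix of anatomical centroids in mm.
#' @param network character network labels.
#' @param hierarchyLevel integer vector, values in 1..4.
#' @return A validated \linkS4class{Parcellation}.
#' @export
Parcellation <- function(label, hemisphere, sphereXYZ, anatXYZ,
                         network, hierarchyLevel) {
  n <- length(label)
  new("Parcellation",
      nodeId = seq_len(n) - 1L,
      label = as.character(label),
      hemisphere = as.character(hemisphere),
      sphereXYZ = unname(as.matrix(sphereXYZ)),
      anatXYZ = unname(as.matrix(anatXYZ)),
      network = as.character(network),
      hierarchyLevel = as.integer(hierarchyLevel))
}

## ---------------------------------------------------------------------------
## ConnectivityMatrix
## ---------------------------------------------------------------------------

#' ConnectivityMatrix: a symmetric weighted connectome
#'
#' An n x n symmetric weighted adjacency matrix with zero diagonal, tagged
#' with its modality. Structural matrices carry non-negative weights
#' (e.g. normalised streamline weights); functional matrices carry signed
#' Fisher-z correlation values.
#'
#' @slot values n x n numeric matrix, symmetric, zero diagonal.
#' @slot modality \code{"structural"} or \code{"functional"}.
#' @slot subjectId character scalar.
#' @slot weightSemantics free-text description of the edge weights.
#'
#' @export
setClass("ConnectivityMatrix",
  representation(
    values = "matrix",
    modality = "character",
    subjectId = "character",
    weightSemantics = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (anyNA(v)) msgs <- c(msgs, "values must not contain NA")
  else {
    if (max(abs(v - t(v))) > 1e-10)
      msgs <- c(msgs, "values must be symmetric within 1e-10")
    if (any(diag(v) != 0)) msgs <- c(msgs, "diagonal must be exactly 0")
    if (identical(object@modality, "structural") && any(v < 0))
      msgs <- c(msgs, "structural weights must be non-negative")
  }
  if (!object@modality %in% c("structural", "functional"))
    msgs <- c(msgs, "modality must be 'structural' or 'functional'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values square numeric matrix (symmetric, zero diagonal).
#' @param modality \code{"structural"} or \code{"functional"}.
#' @param subjectId subject identifier.
#' @param weightSemantics description of the weights.
#' @return A validated \linkS4class{ConnectivityMatrix}.
#' @export
ConnectivityMatrix <- function(values, modality,
                               subjectId = "unknown",
                               weightSemantics = "") {
  new("ConnectivityMatrix", values = unname(as.matrix(values)),
      modality = modality, subjectId = subjectId,
      weightSemantics = weightSemantics)
}

## ---------------------------------------------------------------------------
## CouplingMap
## ---------------------------------------------------------------------------

#' CouplingMap: per-node structure-function coupling
#'
#' Per-node Spearman correlation between a region's structural and
#' functional connectivity profiles, for one subject or a group aggregate.
#' Nodes where the statistic is undefined (too few structural neighbours, a
#' constant restricted profile) are invalid: the value is \code{NA} and the
#' mask is \code{FALSE}. Invalid nodes propagate as missing, never as zero.
#'
#' @slot values numeric per-node coupling, \code{NA} where invalid.
#' @slot validMask logical per-node validity.
#' @slot subjectId character scalar.
#' @slot minNonzeroUsed integer, the validity threshold applied.
#'
#' @export
setClass("CouplingMap",
  representation(
    values = "numeric",
    validMask = "logical",
    subjectId = "character",
    minNonzeroUsed = "integer"
  )
)

setValidity("CouplingMap", function(object) {
  msgs <- character(0)
  if (length(object@values) != length(object@validMask))
    msgs <- c(msgs, "values and validMask must have the same length")
  else {
    if (anyNA(object@values[object@validMask]))
      msgs <- c(msgs, "values must be defined wherever validMask is TRUE")
    ok <- object@values[object@validMask]
    if (length(ok) && any(ok < -1 | ok > 1))
      msgs <- c(msgs, "valid coupling values must lie in [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CouplingMap
#'
#' @param values per-node coupling values (\code{NA} where invalid).
#' @param validMask logical validity per node.
#' @param subjectId subject identifier.
#' @param minNonzeroUsed threshold recorded on the object.
#' @return A validated \linkS4class{CouplingMap}.
#' @export
CouplingMap <- function(values, validMask = !is.na(values),
                        subjectId = "unknown", minNonzeroUsed = 3L) {
  new("CouplingMap", values = as.numeric(values),
      validMask = as.logical(validMask), subjectId = subjectId,
      minNonzeroUsed = as.integer(minNonzeroUsed))
}

## ---------------------------------------------------------------------------
## GradientSet
## ---------------------------------------------------------------------------

#' GradientSet: diffusion-map gradients of a connectome
#'
#' Component scores from a diffusion map embedding of a normalized-angle
#' affinity matrix. Columns are ordered by descending eigenvalue; the
#' variance explained by each component is its eigenvalue divided by the
#' sum over all non-trivial eigenvalues of the embedding (not only the
#' retained ones), which is carried in \code{eigenvalueSum}.
#'
#' @slot scores n x k numeric matrix of component scores.
#' @slot eigenvalues k positive reals, descending.
#' @slot varianceExplained k reals, eigenvalue_i / eigenvalueSum.
#' @slot eigenvalueSum sum of all non-trivial positive eigenvalues.
#' @slot alignedTo template id, or \code{"none"}.
#' @slot sourceModality \code{"structural"} or \code{"functional"}.
#'
#' @export
setClass("GradientSet",
  representation(
    scores = "matrix",
    eigenvalues = "numeric",
    varianceExplained = "numeric",
    eigenvalueSum = "numeric",
    alignedTo = "character",
    sourceModality = "character"
  )
)

setValidity("GradientSet", function(object) {
  msgs <- character(0)
  k <- ncol(object@scores)
  if (length(object@eigenvalues) != k ||
      length(object@varianceExplained) != k)
    msgs <- c(msgs, "eigenvalues and varianceExplained must match score columns")
  else if (k > 1 && any(diff(object@eigenvalues) > 1e-12))
    msgs <- c(msgs, "eigenvalues must be in descending order")
  if (length(object@eigenvalues) == k && k > 0 &&
      max(abs(object@varianceExplained -
              object@eigenvalues / object@eigenvalueSum)) > 1e-10)
    msgs <- c(msgs, "varianceExplained must equal eigenvalue / eigenvalueSum")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GradientSet
#'
#' @param scores n x k component score matrix.
#' @param eigenvalues k eigenvalues, descending.
#' @param eigenvalueSum sum of all non-trivial positive eigenvalues.
#' @param alignedTo template id or \code{"none"}.
#' @param sourceModality \code{"structural"} or \code{"functional"}.
#' @return A validated \linkS4class{GradientSet}.
#' @export
GradientSet <- function(scores, eigenvalues, eigenvalueSum,
                        alignedTo = "none", sourceModality = "structural") {
  new("GradientSet", scores = as.matrix(scores),
      eigenvalues = as.numeric(eigenvalues),
      varianceExplained = as.numeric(eigenvalues) / eigenvalueSum,
      eigenvalueSum = eigenvalueSum,
      alignedTo = alignedTo, sourceModality = sourceModality)
}

## ---------------------------------------------------------------------------
## SpinNull
## ---------------------------------------------------------------------------

#' SpinNull: spin-permutation null for a map-map correlation
#'
#' A set of rotation-induced node reassignments (rows of
#' \code{permutations}, 1-based indices; duplicates permitted, as in the
#' standard parcel-level spin) together with the empirical Spearman
#' statistic, its null distribution and the permutation p-value.
#'
#' @slot permutations n_perm x n integer matrix of node reassignments.
#' @slot nPerm integer number of permutations.
#' @slot seed integer seed used to draw the rotations.
#' @slot empiricalStat empirical Spearman correlation.
#' @slot nullStats numeric vector of null correlations.
#' @slot pSpin permutation p-value in (0, 1].
#' @slot alternative \code{"greater"}, \code{"less"} or \code{"two_sided"}.
#'
#' @export
setClass("SpinNull",
  representation(
    permutations = "matrix",
    nPerm = "integer",
    seed = "integer",
    empiricalStat = "numeric",
    nullStats = "numeric",
    pSpin = "numeric",
    alternative = "character"
  )
)

setValidity("SpinNull", function(object) {
  msgs <- character(0)
  if (nrow(object@permutations) != object@nPerm)
    msgs <- c(msgs, "permutations must have nPerm rows")
  if (length(object@pSpin) == 1 &&
      (object@pSpin < 0 || object@pSpin > 1))
    msgs <- c(msgs, "pSpin must lie in [0, 1]")
  if (!object@alternative %in% c("greater", "less", "two_sided"))
    msgs <- c(msgs, "alternative must be greater, less or two_sided")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-cohort design objects
## ---------------------------------------------------------------------------

#' CouplingField: planted per-node coupling structure
#'
#' Describes the ground-truth coupling a synthetic cohort plants: a
#' baseline, linear trends along the normalized anterior--posterior
#' coordinate and the network hierarchy, and additive group-specific
#' decoupling at chosen node sets. The realized per-node target kappa is
#' clipped to [-0.99, 0.99].
#'
#' @slot beta0 baseline coupling (Spearman units).
#' @slot betaAP slope per unit normalized A--P coordinate (anterior positive).
#' @slot betaHier slope per hierarchy level (centred at level 2.5).
#' @slot groupDeltas named list: group -> list(nodes = 0-based ids, delta).
#'
#' @export
setClass("CouplingField",
  representation(
    beta0 = "numeric",
    betaAP = "numeric",
    betaHier = "numeric",
    groupDeltas = "list"
  )
)

#' Construct a CouplingField
#'
#' Defaults are calibrated so that, with the default cohort design, the
#' control group's cohort-mean global coupling lands at the value this
#' class of healthy-control connectome analyses reports (about 0.54), with
#' stronger coupling posteriorly and in lower hierarchy levels.
#'
#' @param beta0 baseline coupling.
#' @param betaAP A--P slope (negative: weaker anteriorly).
#' @param betaHier hierarchy slope (negative: weaker in transmodal cortex).
#' @param groupDeltas named list of \code{list(nodes=, delta=)} per group.
#' @return A \linkS4class{CouplingField}.
#' @export
CouplingField <- function(beta0 = 0.415, betaAP = -0.16, betaHier = -0.06,
                          groupDeltas = list()) {
  new("CouplingField", beta0 = beta0, betaAP = betaAP, betaHier = betaHier,
      groupDeltas = groupDeltas)
}

#' CohortDesign: size and noise parameters of a synthetic cohort
#'
#' @slot nNodesPerHemisphere integer nodes per hemisphere.
#' @slot nSubjectsPerGroup named integer vector, subjects per group.
#' @slot scDensity structural edge fraction in (0, 1].
#' @slot distanceDecay decay rate per unit arc length (>= 0).
#' @slot apStretch anisotropy of the connection metric along A--P.
#' @slot noiseSd subject-level noise scale.
#' @slot seed integer master seed.
#'
#' @export
setClass("CohortDesign",
  representation(
    nNodesPerHemisphere = "integer",
    nSubjectsPerGroup = "integer",
    scDensity = "numeric",
    distanceDecay = "numeric",
    apStretch = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortDesign", function(object) {
  msgs <- character(0)
  if (object@scDensity <= 0 || object@scDensity > 1)
    msgs <- c(msgs, "scDensity must lie in (0, 1]")
  if (any(object@nSubjectsPerGroup < 1))
    msgs <- c(msgs, "all group sizes must be >= 1")
  if (object@nNodesPerHemisphere < 10)
    msgs <- c(msgs, "need at least 10 nodes per hemisphere")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortDesign
#'
#' @param nNodesPerHemisphere nodes per hemisphere (default 50, i.e. a
#'   100-node parcellation).
#' @param nSubjectsPerGroup named integer vector of group sizes.
#' @param scDensity structural edge density.
#' @param distanceDecay exponential decay rate of edge probability with
#'   (stretched) arc distance.
#' @param apStretch metric stretch along the A--P axis; values > 1 make the
#'   cortex effectively elongated anterior-posteriorly so the leading
#'   connectivity gradient tracks the A--P axis.
#' @param noiseSd subject-level log-normal noise sd.
#' @param seed master seed.
#' @return A validated \linkS4class{CohortDesign}.
#' @export
CohortDesign <- function(nNodesPerHemisphere = 50L,
                         nSubjectsPerGroup = c(control = 20L),
                         scDensity = 0.6,
                         distanceDecay = 1.0,
                         apStretch = 3.0,
                         noiseSd = 0.1,
                         seed = 1L) {
  new("CohortDesign",
      nNodesPerHemisphere = as.integer(nNodesPerHemisphere),
      nSubjectsPerGroup = structure(as.integer(nSubjectsPerGroup),
                                    names = names(nSubjectsPerGroup)),
      scDensity = scDensity, distanceDecay = distanceDecay,
      apStretch = apStretch, noiseSd = noiseSd, seed = as.integer(seed))
}
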