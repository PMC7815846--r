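#' Number of nodes
#' @param x a package object with a node dimension.
#' @return integer node count.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @describeIn nodeCount nodes in a parcellation
#' @export
setMethod("nodeCount", "Parcellation", function(x) length(x@nodeId))

#' @describeIn nodeCount nodes in a connectivity matrix
#' @export
setMethod("nodeCount", "ConnectivityMatrix", function(x) nrow(x@values))

#' @describeIn nodeCount nodes in a coupling map
#' @export
setMethod("nodeCount", "CouplingMap", function(x) length(x@values))

#' @describeIn nodeCount nodes in a gradient set
#' @export
setMethod("nodeCount", "GradientSet", function(x) nrow(x@scores))

#' Matrix of connection weights
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return the numeric n x n matrix.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @describeIn connValues weight matrix
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' Modality tag
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return \code{"structural"} or \code{"functional"}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @describeIn modality modality of a connectivity matrix
#' @export
setMethod("modality", "ConnectivityMatrix", function(x) x@modality)

#' Per-node coupling values
#' @param x a \linkS4class{CouplingMap}.
#' @return numeric vector with \code{NA} at invalid nodes.
#' @export
setGeneric("couplingValues", function(x) standardGeneric("couplingValues"))

#' @describeIn couplingValues coupling values
#' @export
setMethod("couplingValues", "CouplingMap", function(x) x@values)

#' Validity mask of a coupling map
#' @param x a \linkS4class{CouplingMap}.
#' @return logical vector.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @describeIn validMask validity mask
#' @export
setMethod("validMask", "CouplingMap", function(x) x@validMask)

#' Gradient component scores
#' @param x a \linkS4class{GradientSet}.
#' @return n x k score matrix.
#' @export
setGeneric("gradientScores", function(x) standardGeneric("gradientScores"))

#' @describeIn gradientScores scores
#' @export
setMethod("gradientScores", "GradientSet", function(x) x@scores)

#' Eigenvalues of a gradient set
#' @param x a \linkS4class{GradientSet}.
#' @return numeric vector, descending.
#' @export
setGeneric("gradientEigenvalues",
           function(x) standardGeneric("gradientEigenvalues"))

#' @describeIn gradientEigenvalues eigenvalues
#' @export
setMethod("gradientEigenvalues", "GradientSet", function(x) x@eigenvalues)

#' Variance explained per gradient
#' @param x a \linkS4class{GradientSet}.
#' @return numeric vector; each entry is the component eigenvalue divided by
#'   the sum of all non-trivial eigenvalues.
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @describeIn varianceExplained variance explained
#' @export
setMethod("varianceExplained", "GradientSet", function(x) x@varianceExplained)

#' Permutation p-value of a spin test
#' @param x a \linkS4class{SpinNull}.
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("pSpin", function(x) standardGeneric("pSpin"))

#' @describeIn pSpin spin p-value
#' @export
setMethod("pSpin", "SpinNull", function(x) x@pSpin)

#' Spin-permutation index matrix
#' @param x a \linkS4class{SpinNull}.
#' @return n_perm x n integer matrix (1-based indices).
#' @export
setGeneric("spinPermutations",
           function(x) standardGeneric("spinPermutations"))

#' @describeIn spinPermutations permutations
#' @export
setMethod("spinPermutations", "SpinNull", function(x) x@permutations)

## show methods ---------------------------------------------------------------

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation with", nodeCount(object), "nodes",
      sprintf("(%d L / %d R)\n", sum(object@hemisphere == "L"),
              sum(object@hemisphere == "R")))
  cat("  networks:", paste(unique(object@network), collapse = ", "), "\n")
  cat("  hierarchy levels:",
      paste(sort(unique(object@hierarchyLevel)), collapse = " "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  dens <- mean(v[upper.tri(v)] != 0)
  cat(sprintf("%s ConnectivityMatrix: %d x %d, subject '%s'\n",
              object@modality, nrow(v), ncol(v), object@subjectId))
  cat(sprintf("  edge density %.3f; weights: %s\n", dens,
              object@weightSemantics))
})

setMethod("show", "CouplingMap", function(object) {
  ok <- object@validMask
  cat(sprintf("CouplingMap (%d nodes, %d valid), subject '%s'\n",
              length(ok), sum(ok), object@subjectId))
  if (any(ok))
    cat(sprintf("  mean %.3f, range [%.3f, %.3f]\n",
                mean(object@values[ok]), min(object@values[ok]),
                max(object@values[ok])))
})

setMethod("show", "GradientSet", function(object) {
  cat(sprintf("GradientSet: %d nodes x %d components (%s)\n",
              nrow(object@scores), ncol(object@scores),
              object@sourceModality))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained),
            collapse = " "), "\n")
  cat("  aligned to:", object@alignedTo, "\n")
})

setMethod("show", "SpinNull", function(object) {
  cat(sprintf("SpinNull: %d permutations, alternative = %s\n",
              object@nPerm, object@alternative))
  cat(sprintf("  empirical rho = %.3f, p_spin = %.4g\n",
              object@empiricalStat, object@pSpin))
})
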