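## Macroscale cortical gradients: normalized-angle affinity, diffusion map
## embedding, group templates, Procrustes alignment to the template, sign
## orientation, and correlation of gradients with anatomical axes.

#' Normalized-angle affinity of a connectome
#'
#' Per row, keeps the top \code{rowSparsity} fraction of entries (zeroing
#' the rest, standard practice before gradient embedding), computes the
#' cosine similarity between all pairs of sparsified rows, and maps it to
#' A(i, j) = 1 - arccos(cos_sim) / pi, so identical profiles score 1,
#' orthogonal profiles 0.5 and anti-parallel profiles 0. The result is
#' symmetrized by averaging and the diagonal set to 1.
#'
#' @param conn a \linkS4class{ConnectivityMatrix}.
#' @param rowSparsity fraction of entries kept per row (default 0.1).
#' @return list with \code{values} (n x n affinity in [0, 1]) and
#'   \code{sparsityKept}.
#' @export
normalizedAngleAffinity <- function(conn, rowSparsity = 0.1) {
  W <- connValues(conn)
  n <- nrow(W)
  if (n < 3) stop("need at least 3 nodes")
  keep <- max(1L, ceiling(rowSparsity * n))
  Xs <- t(apply(W, 1, function(row) {
    thr <- sort(row, decreasing = TRUE)[keep]
    row[row < thr] <- 0
    row
  }))
  norms <- sqrt(rowSums(Xs^2))
  if (any(norms == 0))
    stop("row(s) all-zero after sparsification: node ",
         paste(which(norms == 0) - 1L, collapse = ", "))
  cs <- tcrossprod(Xs / norms)
  cs <- pmin(pmax(cs, -1), 1)
  A <- 1 - acos(cs) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  stopifnot(all(A >= 0 & A <= 1))
  list(values = A, sparsityKept = rowSparsity)
}

#' Diffusion map embedding of an affinity matrix
#'
#' Standard diffusion-map construction: the affinity is density-normalized
#' by node degree to the power \code{alpha}, row-normalized to a Markov
#' transition matrix, and eigendecomposed (via the conjugate symmetric
#' operator). The trivial constant eigenvector is dropped; component
#' scores are the remaining eigenvectors scaled by lambda^t, with
#' \code{diffusionTime = 0} meaning the automatic multi-scale weighting
#' lambda / (1 - lambda). Variance explained per component is its
#' eigenvalue over the sum of all non-trivial positive eigenvalues.
#'
#' @param affinity result of \code{\link{normalizedAngleAffinity}} (or any
#'   list with a symmetric non-negative \code{values} matrix).
#' @param nComponents number of gradients to return (default 10).
#' @param alpha density-normalization exponent (default 0.5, anisotropic
#'   diffusion).
#' @param diffusionTime diffusion time t (default 0 = automatic scaling).
#' @param sourceModality modality tag carried on the result.
#' @return A \linkS4class{GradientSet}.
#' @export
diffusionMapEmbed <- function(affinity, nComponents = 10L, alpha = 0.5,
                              diffusionTime = 0,
                              sourceModality = "structural") {
  W <- affinity$values
  if (!all(is.finite(W))) stop("affinity contains non-finite values")
  n <- nrow(W)
  if (nComponents >= n) stop("nComponents must be < n")
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / outer(sqrt(d1), sqrt(d1))
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / eg$vectors[, 1]   # row-wise: divide by trivial eigvec
  lamNT <- lam[-1]
  keepIdx <- seq_len(nComponents) + 1L
  lamK <- lamNT[seq_len(nComponents)]
  lamSafe <- pmin(lamK, 1 - 1e-12)
  scaleK <- if (diffusionTime == 0) lamSafe / (1 - lamSafe)
            else lamSafe^diffusionTime
  scores <- sweep(psi[, keepIdx, drop = FALSE], 2, scaleK, `*`)
  GradientSet(scores = scores, eigenvalues = lamK,
              eigenvalueSum = sum(lamNT[lamNT > 0]),
              alignedTo = "none", sourceModality = sourceModality)
}

#' Build a group-level gradient template
#'
#' Averages the connectivity matrices element-wise, computes the
#' normalized-angle affinity of the mean matrix and embeds it; the result
#' is the fixed alignment reference for individual gradients.
#'
#' @param matrices list of \linkS4class{ConnectivityMatrix} objects of the
#'   same modality and parcellation (>= 2).
#' @param rowSparsity,nComponents,alpha,diffusionTime embedding parameters,
#'   passed through.
#' @return A \linkS4class{GradientSet} with \code{alignedTo = "template"}.
#' @export
buildGroupTemplate <- function(matrices, rowSparsity = 0.1,
                               nComponents = 10L, alpha = 0.5,
                               diffusionTime = 0) {
  if (length(matrices) < 2) stop("need at least 2 matrices")
  mods <- unique(vapply(matrices, modality, character(1)))
  if (length(mods) != 1) stop("cannot mix modalities in one template")
  ns <- unique(vapply(matrices, nodeCount, integer(1)))
  if (length(ns) != 1) stop("matrices have different parcellations")
  meanV <- Reduce(`+`, lapply(matrices, connValues)) / length(matrices)
  meanConn <- ConnectivityMatrix(meanV, modality = mods,
                                 subjectId = "group_mean")
  gs <- diffusionMapEmbed(normalizedAngleAffinity(meanConn, rowSparsity),
                          nComponents = nComponents, alpha = alpha,
                          diffusionTime = diffusionTime,
                          sourceModality = mods)
  gs@alignedTo <- "template"
  gs
}

#' Procrustes-align individual gradients to a template
#'
#' Applies the orthogonal transform (rotation/reflection, no scaling, no
#' translation) minimizing the Frobenius distance between the individual's
#' scores and the template scores: R = U V' from the SVD of
#' X' T. Eigenvalues and variance explained are carried over unchanged.
#'
#' @param individual a \linkS4class{GradientSet}.
#' @param template the reference \linkS4class{GradientSet}.
#' @return the aligned \linkS4class{GradientSet}.
#' @export
procrustesAlign <- function(individual, template) {
  X <- gradientScores(individual)
  Tm <- gradientScores(template)
  if (!all(dim(X) == dim(Tm)))
    stop("individual and template must have the same n and k")
  sv <- svd(crossprod(X, Tm))
  R <- sv$u %*% t(sv$v)
  out <- individual
  out@scores <- X %*% R
  out@alignedTo <- "template"
  out
}

#' Deterministically orient gradient signs
#'
#' Eigenvector sign is arbitrary; this fixes the convention: gradient 1 is
#' flipped so its Spearman correlation with the anatomical y (A--P)
#' coordinate is negative (higher score = more posterior), gradient 2 so
#' its correlation with hierarchy level is positive (higher score = more
#' transmodal). A zero correlation leaves the sign as computed, with a
#' warning. Orientation never alters correlation magnitudes.
#'
#' @param gradset a \linkS4class{GradientSet} with k >= 2.
#' @param parcellation the matching \linkS4class{Parcellation}.
#' @return the oriented \linkS4class{GradientSet}.
#' @export
orientGradients <- function(gradset, parcellation) {
  sc <- gradientScores(gradset)
  if (ncol(sc) < 2) stop("need at least 2 gradients to orient")
  r1 <- spearman(sc[, 1], parcellation@anatXYZ[, 2])
  r2 <- spearman(sc[, 2], as.numeric(parcellation@hierarchyLevel))
  if (r1 == 0 || r2 == 0)
    warning("zero axis correlation; gradient sign left as computed")
  if (r1 > 0) sc[, 1] <- -sc[, 1]
  if (r2 < 0) sc[, 2] <- -sc[, 2]
  out <- gradset
  out@scores <- sc
  out
}

#' Correlate a gradient with an anatomical axis, with spin inference
#'
#' Spearman correlation between per-node gradient scores and a per-node
#' axis (A--P coordinate or hierarchy level), with a spin-permutation
#' p-value: the gradient map is permuted by the rotation-induced
#' reassignments while the axis stays fixed.
#'
#' @param gradientScores per-node numeric scores of one gradient.
#' @param axis per-node numeric axis values.
#' @param permutations n_perm x n integer permutation matrix from
#'   \code{\link{generateSpinPermutations}}.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{rho} and \code{pSpin} plus the underlying
#'   \linkS4class{SpinNull} as \code{spin}.
#' @export
axisCorrelation <- function(gradientScores, axis, permutations,
                            alternative = "two_sided") {
  if (stats::sd(axis) == 0) stop("axis is constant")
  sn <- spinTest(gradientScores, axis, permutations,
                 alternative = alternative)
  list(rho = sn@empiricalStat, pSpin = sn@pSpin, spin = sn)
}
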