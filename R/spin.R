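## Spin-permutation spatial inference: rotation-induced node permutations
## that preserve spatial covariance, and permutation p-values for map-map
## Spearman correlations.

## uniform random rotation (det +1) from an orthonormalized Gaussian triple
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Node reassignment induced by one rotation
#'
#' Rotates the left-hemisphere sphere centroids by \code{Q}, mirrors the
#' rotation across the sagittal plane for the right hemisphere, and
#' reassigns each original node to the nearest rotated centroid within its
#' hemisphere (nearest by arc distance, i.e. largest dot product; ties
#' broken by lowest index; duplicates permitted, as in the standard
#' parcel-level spin).
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param Q 3 x 3 rotation matrix.
#' @return integer permutation vector (1-based global node indices).
#' @export
spinFromRotation <- function(parcellation, Q) {
  xyz <- parcellation@sphereXYZ
  hemi <- parcellation@hemisphere
  M <- diag(c(-1, 1, 1))
  perm <- integer(nrow(xyz))
  for (h in c("L", "R")) {
    idx <- which(hemi == h)
    if (!length(idx)) stop("hemisphere ", h, " has no coordinates")
    Qh <- if (h == "L") Q else M %*% Q %*% M
    rot <- xyz[idx, , drop = FALSE] %*% t(Qh)
    sim <- tcrossprod(xyz[idx, , drop = FALSE], rot)
    perm[idx] <- idx[max.col(sim, ties.method = "first")]
  }
  perm
}

#' Generate a set of spin permutations
#'
#' Draws \code{nPerm} uniform random 3-D rotations and converts each into
#' a hemisphere-respecting node reassignment via
#' \code{\link{spinFromRotation}}. Deterministic given the seed.
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return nPerm x n integer matrix; the seed is attached as an attribute.
#' @export
generateSpinPermutations <- function(parcellation, nPerm = 1000L, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  perms <- withSeed(seed, {
    t(vapply(seq_len(nPerm),
             function(i) spinFromRotation(parcellation, .randomRotation()),
             integer(nodeCount(parcellation))))
  })
  attr(perms, "seed") <- as.integer(seed)
  perms
}

#' Spin permutation test for a map-map correlation
#'
#' The empirical statistic is the Spearman correlation of the two maps;
#' the null distribution is built by applying each rotation-induced
#' reassignment to \code{mapX} (the analysis map) while \code{mapY} (the
#' axis/reference map) stays fixed. Invalid (\code{NA}) nodes are dropped
#' pairwise. The p-value uses the permutation-inclusive (add-one) rule
#' p = (#{null >= empirical} + 1) / (nPerm + 1) for
#' \code{alternative = "greater"}, mirrored for \code{"less"}, and the
#' doubled smaller tail (capped at 1) for \code{"two_sided"}; set
#' \code{addOne = FALSE} for the raw proportion.
#'
#' @param mapX per-node numeric analysis map (will be permuted).
#' @param mapY per-node numeric reference map (held fixed).
#' @param permutations n_perm x n matrix from
#'   \code{\link{generateSpinPermutations}}.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @param addOne use the add-one correction (default TRUE).
#' @return A \linkS4class{SpinNull}.
#' @export
spinTest <- function(mapX, mapY, permutations,
                     alternative = c("two_sided", "greater", "less"),
                     addOne = TRUE) {
  alternative <- match.arg(alternative)
  n <- ncol(permutations)
  if (length(mapX) != n || length(mapY) != n)
    stop("maps must be full parcellation length")
  if (mean(is.na(mapX) | is.na(mapY)) >= 0.1)
    stop("more than 10% of nodes are invalid")
  if (stats::sd(mapX, na.rm = TRUE) == 0 || stats::sd(mapY, na.rm = TRUE) == 0)
    stop("a map is constant")
  emp <- spearman(mapX, mapY)
  nPerm <- nrow(permutations)
  nulls <- vapply(seq_len(nPerm), function(k) {
    spearman(mapX[permutations[k, ]], mapY)
  }, numeric(1))
  nulls <- nulls[is.finite(nulls)]
  m <- length(nulls)
  tail1 <- function(cnt, tot) if (addOne) (cnt + 1) / (tot + 1) else cnt / tot
  pG <- tail1(sum(nulls >= emp), m)
  pL <- tail1(sum(nulls <= emp), m)
  p <- switch(alternative,
              greater = pG,
              less = pL,
              two_sided = min(1, 2 * min(pG, pL)))
  new("SpinNull", permutations = permutations, nPerm = as.integer(nPerm),
      seed = as.integer(attr(permutations, "seed") %||% NA_integer_),
      empiricalStat = emp, nullStats = nulls, pSpin = p,
      alternative = alternative)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
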