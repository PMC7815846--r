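## Internal numerical and seeding helpers.

#' Derive a stage seed from a master seed
#'
#' Stable hash of (master seed, stage name) so that toggling one pipeline
#' stage never reshuffles another stage's randomness. The result is a
#' non-negative integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
deriveSeed <- function(master, stage) {
  ## polynomial rolling hash mod the Mersenne prime 2^31 - 1; the state
  ## stays below 2^31 so every product is exact in double precision
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(paste0(stage, ":", master))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

## evaluate expr under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## short hex digest of an arbitrary R object (FNV-1a over its serialization)
fnvDigest <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 17
  ## sample the byte stream to keep the loop short on large objects
  idx <- as.integer(seq(1L, length(bytes), length.out = min(4096L, length(bytes))))
  for (b in as.integer(bytes[idx])) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

## arc (great-circle) distance matrix between rows of unit-sphere coordinates
arcDistance <- function(xyz1, xyz2 = xyz1) {
  d <- tcrossprod(xyz1, xyz2)
  acos(pmin(pmax(d, -1), 1))
}

#' Spatially autocorrelated random field on parcellation centroids
#'
#' Gaussian-kernel smoothing (bandwidth in radians of arc length) of iid
#' standard normal node noise, standardized to zero mean and unit variance.
#' Fields are isotropic on the sphere, so rotation-based spin nulls apply
#' exactly to them.
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param smoothness kernel bandwidth, radians of arc.
#' @param seed integer seed.
#' @return numeric per-node field.
#' @export
smoothSphereField <- function(parcellation, smoothness = 0.2, seed = 1L) {
  xyz <- parcellation@sphereXYZ
  K <- exp(-arcDistance(xyz)^2 / (2 * smoothness^2))
  K <- K / rowSums(K)
  f <- withSeed(seed, as.numeric(K %*% rnorm(nrow(xyz))))
  as.numeric(scale(f))
}

## Spearman correlation (average ties), NA dropped pairwise
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stats::cor(x[ok], y[ok], method = "spearman")
}

## normal scores (Blom) of a numeric vector, ties broken by average rank
normalScores <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.375) / (n + 0.25))
}
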