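## Synthetic cohort generator. Plants known ground truth — a spatial
## coupling field, group decoupling effects, and gene-expression maps with
## chosen spatial correlations — so every downstream stage can be validated
## end to end. All generators are pure functions of (arguments, seed).

.networkBands <- data.frame(
  network = c("SomMot", "DorsAttn", "SalVentAttn", "Cont",
              "Default", "Limbic", "Vis"),
  level = c(1L, 2L, 2L, 3L, 4L, 3L, 1L),
  stringsAsFactors = FALSE)

## ellipsoid semi-axes (mm) used to embed the sphere anatomically;
## the A-P (y) axis is the longest, as in real cortex
.anatSemiAxes <- c(55, 70, 50)

#' Generate a synthetic two-hemisphere parcellation
#'
#' Places \code{nPerHemisphere} nodes on each unit hemisphere by a
#' deterministic low-discrepancy (Fibonacci) lattice; the right hemisphere
#' is the x-mirror of the left. Anatomical centroids are the sphere
#' centroids scaled onto an ellipsoid whose anterior--posterior (y)
#' semi-axis is 70 mm. Networks are assigned as seven latitude bands, each
#' mapped to a hierarchy level 1--4 following the canonical
#' sensory-to-transmodal ordering.
#'
#' @param nPerHemisphere nodes per hemisphere (>= 10).
#' @param seed integer seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @return A validated \linkS4class{Parcellation}.
#' @export
makeParcellation <- function(nPerHemisphere, seed = 1L) {
  n <- as.integer(nPerHemisphere)
  if (n < 10)
    stop("need at least 10 nodes per hemisphere")
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  golden <- (sqrt(5) - 1) / 2
  az <- pi / 2 + pi * ((i * golden) %% 1)   # azimuth in (pi/2, 3pi/2): x < 0
  r <- sqrt(pmax(0, 1 - z^2))
  left <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  right <- left
  right[, 1] <- -right[, 1]
  sph <- rbind(left, right)
  hemi <- rep(c("L", "R"), each = n)

  ## seven latitude bands per hemisphere -> networks -> hierarchy levels
  band <- cut(rank(z, ties.method = "first"), breaks = 7, labels = FALSE)
  if (length(unique(band)) < 7)
    stop("too few nodes to populate the 4 hierarchy bands")
  network <- rep(.networkBands$network[band], 2)
  level <- rep(.networkBands$level[band], 2)

  anat <- sweep(sph, 2, .anatSemiAxes, `*`)
  label <- paste0(hemi, "_", network, "_", rep(seq_len(n), 2))
  Parcellation(label = label, hemisphere = hemi, sphereXYZ = sph,
               anatXYZ = anat, network = network, hierarchyLevel = level)
}

#' Realize the planted per-node coupling targets
#'
#' kappa_i = beta0 + betaAP * (y_i / 70) + betaHier * (level_i - 2.5),
#' plus any additive group delta at the nodes the field names for
#' \code{group}; clipped to [-0.99, 0.99]. The normalized A--P coordinate
#' runs from -1 (posterior pole) to +1 (anterior pole).
#'
#' @param field a \linkS4class{CouplingField}.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param group group name whose deltas to apply (default none).
#' @return numeric per-node kappa in [-0.99, 0.99].
#' @export
realizeKappa <- function(field, parcellation, group = "control") {
  apNorm <- parcellation@anatXYZ[, 2] / .anatSemiAxes[2]
  kappa <- field@beta0 + field@betaAP * apNorm +
    field@betaHier * (parcellation@hierarchyLevel - 2.5)
  gd <- field@groupDeltas[[group]]
  if (!is.null(gd)) {
    idx <- as.integer(gd$nodes) + 1L
    if (any(idx < 1 | idx > nodeCount(parcellation)))
      stop("groupDeltas names nodes outside the parcellation")
    kappa[idx] <- kappa[idx] + gd$delta
  }
  pmin(0.99, pmax(-0.99, kappa))
}

## distances in the (A-P stretched) connection metric
.connDistance <- function(parcellation, apStretch) {
  xyz <- parcellation@sphereXYZ
  xyz[, 2] <- xyz[, 2] * apStretch
  as.matrix(stats::dist(xyz))
}

#' Generate a group-level structural connectome
#'
#' Edge existence is sampled with probability proportional to
#' exp(-distanceDecay * d), where d is the distance between node centroids
#' in a metric stretched along the anterior--posterior axis (so the leading
#' connectivity gradient of the synthetic cortex tracks A--P, as it does
#' anatomically). The proportionality constant is calibrated so the
#' expected edge density hits \code{scDensity} within 0.02. Weights are
#' log-normal, the matrix symmetric with zero diagonal and non-negative.
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param design a \linkS4class{CohortDesign} (density, decay, stretch).
#' @param seed integer seed.
#' @return A structural \linkS4class{ConnectivityMatrix}.
#' @export
makeGroupSC <- function(parcellation, design, seed = design@seed) {
  n <- nodeCount(parcellation)
  d <- .connDistance(parcellation, design@apStretch)
  up <- upper.tri(d)
  base <- exp(-design@distanceDecay * d[up])
  target <- design@scDensity
  ## calibrate c so that mean(min(1, c*base)) = target
  f <- function(logc) mean(pmin(1, exp(logc) * base)) - target
  lo <- -30; hi <- 30
  if (f(hi) < -0.02)
    stop("requested density unattainable for this decay rate")
  logc <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  p <- pmin(1, exp(logc) * base)
  withSeed(seed, {
    edge <- stats::rbinom(length(p), 1L, p) == 1L
    w <- numeric(length(p))
    w[edge] <- stats::rlnorm(sum(edge), meanlog = 0, sdlog = 0.5)
  })
  v <- matrix(0, n, n)
  v[up] <- w
  v <- v + t(v)
  ConnectivityMatrix(v, modality = "structural",
                     subjectId = "group_template",
                     weightSemantics = "synthetic log-normal streamline weight")
}

## latent Pearson correlation giving expected Spearman kappa under a
## Gaussian copula: population Spearman of a bivariate normal with Pearson
## rho is (6/pi) asin(rho/2), hence the inverse below
.spearmanToPearson <- function(kappa) 2 * sin(pi * kappa / 6)

#' Generate one subject's SC/FC pair with planted coupling
#'
#' Subject SC is the group SC with multiplicative log-normal noise (sdlog =
#' \code{noiseSd}, mean 1) on existing edges. The subject FC profile of
#' node i over its structural neighbours is drawn from a Gaussian copula:
#' the latent profile is rho_i * z + sqrt(1 - rho_i^2) * eps, where z are
#' the normal scores of the SC profile and rho_i = 2 sin(pi kappa_i / 6),
#' the latent Pearson correlation whose population Spearman equals
#' kappa_i. FC is then symmetrized by averaging, masked to the structural
#' support, and placed on a Fisher-z scale.
#'
#' @param groupSC group-level structural \linkS4class{ConnectivityMatrix}.
#' @param kappa per-node target coupling in [-0.99, 0.99].
#' @param noiseSd subject-level noise scale.
#' @param seed integer seed.
#' @param subjectId subject identifier.
#' @return list with elements \code{sc} and \code{fc}.
#' @export
makeSubjectPair <- function(groupSC, kappa, noiseSd = 0.1, seed = 1L,
                            subjectId = "sim") {
  if (any(abs(kappa) > 0.99))
    stop("kappa must lie within [-0.99, 0.99]")
  A <- groupSC@values
  n <- nrow(A)
  if (length(kappa) != n)
    stop("kappa must have one entry per node")
  up <- upper.tri(A)
  withSeed(seed, {
    noise <- numeric(sum(up))
    edge <- A[up] > 0
    noise[edge] <- stats::rlnorm(sum(edge), meanlog = -noiseSd^2 / 2,
                                 sdlog = noiseSd)
    S <- matrix(0, n, n)
    S[up] <- A[up] * noise
    S <- S + t(S)

    rho <- .spearmanToPearson(kappa)
    Fm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      J <- which(S[i, ] > 0)
      m <- length(J)
      if (m == 0) next
      z <- normalScores(S[i, J])
      f <- rho[i] * z + sqrt(1 - rho[i]^2) * stats::rnorm(m)
      Fm[i, J] <- 0.3 + 0.25 * f      # plausible Fisher-z scale
    }
  })
  Fv <- (Fm + t(Fm)) / 2
  Fv[S == 0] <- 0
  diag(Fv) <- 0
  list(sc = ConnectivityMatrix(S, "structural", subjectId,
                               "synthetic log-normal streamline weight"),
       fc = ConnectivityMatrix(Fv, "functional", subjectId,
                               "synthetic Fisher-z correlation"))
}

#' Generate a full synthetic cohort
#'
#' Builds the parcellation and group structural connectome from the
#' design, then per group draws \code{nSubjectsPerGroup} subject SC/FC
#' pairs with the group's planted coupling deltas applied, ages from
#' Normal(66.8, 9.3) and sex as a fair Bernoulli indicator — the
#' demographic profile of the elderly control cohorts this pipeline
#' targets. Deterministic given the design seed.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param field a \linkS4class{CouplingField}.
#' @return list with \code{parcellation}, \code{groupSC}, \code{subjects}
#'   (list of \code{list(sc, fc, subjectId, group)}), \code{covariates}
#'   (data.frame) and \code{kappa} (per-group planted kappa matrix,
#'   nodes x groups).
#' @export
makeCohort <- function(design, field = CouplingField()) {
  parc <- makeParcellation(design@nNodesPerHemisphere,
                           seed = deriveSeed(design@seed, "parcellation"))
  groupSC <- makeGroupSC(parc, design, seed = deriveSeed(design@seed, "sc"))
  groups <- names(design@nSubjectsPerGroup)
  if (is.null(groups)) groups <- paste0("group", seq_along(design@nSubjectsPerGroup))
  kap <- sapply(groups, function(g) realizeKappa(field, parc, g))
  subjects <- list()
  cov <- list()
  for (g in groups) {
    for (s in seq_len(design@nSubjectsPerGroup[[g]])) {
      sid <- sprintf("%s_%02d", g, s)
      pair <- makeSubjectPair(groupSC, kap[, g], noiseSd = design@noiseSd,
                              seed = deriveSeed(design@seed, sid),
                              subjectId = sid)
      subjects[[sid]] <- c(pair, list(subjectId = sid, group = g))
      demo <- withSeed(deriveSeed(design@seed, paste0("demo_", sid)), {
        c(age = stats::rnorm(1, 66.8, 9.3), sex = stats::rbinom(1, 1, 0.5))
      })
      cov[[sid]] <- data.frame(subject_id = sid, group = g,
                               age = demo[["age"]], sex = demo[["sex"]],
                               stringsAsFactors = FALSE)
    }
  }
  list(parcellation = parc, groupSC = groupSC, subjects = subjects,
       covariates = do.call(rbind, c(cov, list(make.row.names = FALSE))),
       kappa = kap)
}

#' Default gene panel for the synthetic expression table
#'
#' Receptor genes of the four neuromodulatory systems (noradrenergic,
#' cholinergic, dopaminergic, serotonergic) typically screened in regional
#' transcriptomic association analyses; user-extensible.
#'
#' @return character vector of gene symbols.
#' @export
defaultGenePanel <- function() {
  c("ADRA2A", "CHRNA2", "CHRNA3", "CHRNA4", "DRD2",
    "HTR1E", "HTR2A", "HTR2C", "HTR4", "HTR5A")
}

## outlier-robust sigmoid normalization to (0, 1): centre at the median,
## scale by the normalized IQR; strictly monotone, so rank statistics are
## unchanged by it
.robustSigmoid <- function(x) {
  s <- stats::IQR(x) / 1.349
  if (s == 0) s <- 1
  1 / (1 + exp(-(x - stats::median(x)) / s))
}

#' Generate a synthetic regions x genes expression table
#'
#' Each planted gene map is a spatially autocorrelated field on the sphere
#' (Gaussian kernel, bandwidth \code{smoothness} radians) mixed with a
#' monotone transform (normal scores) of \code{targetMap} so that its
#' Spearman correlation with the target hits the requested value within
#' 0.1 (checked at generation; the noise field is redrawn up to 20 times).
#' Null genes are pure autocorrelated fields. All values are passed
#' through a scaled, outlier-robust sigmoid into (0, 1) per gene, which
#' preserves ranks and hence all Spearman statistics.
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param targetMap per-node reals the planted genes should track.
#' @param planted named numeric vector: gene symbol -> target Spearman rho
#'   (|rho| <= 0.9).
#' @param nNullGenes number of additional null genes.
#' @param smoothness kernel bandwidth (radians of arc).
#' @param seed integer seed.
#' @return numeric matrix regions x genes in (0, 1).
#' @export
makeExpressionTable <- function(parcellation, targetMap,
                                planted = c(), nNullGenes = 0L,
                                smoothness = 0.2, seed = 1L) {
  if (length(planted) && any(abs(planted) > 0.9))
    stop("planted |rho| must be <= 0.9")
  n <- nodeCount(parcellation)
  if (length(targetMap) != n)
    stop("targetMap must have one value per region")
  t <- normalScores(targetMap)
  genes <- list()
  for (g in seq_along(planted)) {
    rho <- planted[g]
    got <- NULL
    for (attempt in seq_len(20)) {
      e <- smoothSphereField(parcellation, smoothness,
                             seed = deriveSeed(seed, sprintf("gene_%d_%d", g, attempt)))
      mix <- function(a) a * sign(rho) * t + (1 - a) * e
      h <- function(a) spearman(mix(a), targetMap) - rho
      ## h(0) is the noise correlation, h(1) = sign(rho); bracket and solve
      if (sign(h(0)) == sign(h(1))) next
      a <- stats::uniroot(h, c(0, 1), tol = 1e-6)$root
      val <- mix(a)
      if (abs(spearman(val, targetMap) - rho) <= 0.1) { got <- val; break }
    }
    if (is.null(got))
      stop(sprintf("could not attain planted rho = %.2f for gene '%s'",
                   rho, names(planted)[g]))
    genes[[names(planted)[g]]] <- got
  }
  for (g in seq_len(nNullGenes)) {
    genes[[sprintf("null_gene_%02d", g)]] <-
      smoothSphereField(parcellation, smoothness,
                        seed = deriveSeed(seed, sprintf("null_%d", g)))
  }
  m <- vapply(genes, .robustSigmoid, numeric(n))
  rownames(m) <- parcellation@nodeId
  m
}

#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' @param cohort result of \code{\link{makeCohort}}.
#' @param outDir output directory.
#' @return invisibly, the output directory.
#' @export
writeCohort <- function(cohort, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeParcellation(cohort$parcellation, file.path(outDir, "parcellation.tsv"))
  utils::write.table(cohort$covariates, file.path(outDir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in cohort$subjects) {
    writeConnectivityMatrix(s$sc, file.path(outDir, paste0(s$subjectId, "_sc.tsv")))
    writeConnectivityMatrix(s$fc, file.path(outDir, paste0(s$subjectId, "_fc.tsv")))
  }
  invisible(outDir)
}
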