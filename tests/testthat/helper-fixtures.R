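# Shared fixtures, built lazily and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# 100-node parcellation (50 per hemisphere)
smallParcellation <- function() {
  fixture("parc100", function() makeParcellation(50))
}

# default-design control cohort, 20 subjects
controlCohort <- function() {
  fixture("cohort_control", function() {
    makeCohort(CohortDesign(seed = 1L), CouplingField())
  })
}

# coupling maps of the control cohort
controlMaps <- function() {
  fixture("maps_control", function() {
    lapply(controlCohort()$subjects, function(s) {
      couplingMap(s$sc, maskFunctionalBySC(s$fc, s$sc))
    })
  })
}

# independent Spearman oracle: average ties, Pearson on ranks
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent BH step-up oracle: largest k with p_(k) <= k q / m passes
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  pass <- logical(m)
  if (length(k)) pass[o[seq_len(max(k))]] <- TRUE
  pass
}

# random symmetric matrix with zero diagonal
randomSymmetric <- function(n, nonneg = FALSE) {
  v <- matrix(stats::rnorm(n * n), n, n)
  if (nonneg) v <- abs(v)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  v
}
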