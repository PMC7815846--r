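# Affinity construction, diffusion map embedding, alignment, orientation.

test_that("normalized angle hits its analytic anchor points", {
  # rows engineered so sparsification (keep-all) leaves them intact
  v <- rbind(c(0, 1, 1, 0.5),
             c(1, 0, 1, 0.5),
             c(1, 1, 0, 0.5),
             c(0.5, 0.5, 0.5, 0))
  conn <- ConnectivityMatrix(v, "functional")
  A <- normalizedAngleAffinity(conn, rowSparsity = 1)$values
  expect_true(all(A >= 0 & A <= 1))
  expect_true(all(diag(A) == 1))

  # identical rows -> affinity 1; orthogonal -> 0.5; anti-parallel -> 0
  x <- c(1, 2, 3)
  raw <- function(a, b) 1 - acos(sum(a * b) /
    sqrt(sum(a^2) * sum(b^2))) / pi
  expect_equal(raw(x, 2 * x), 1)
  expect_equal(raw(c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(raw(x, -x), 0, tolerance = 1e-15)

  # the same anchors through the full operation, on rows built to realize them
  m <- rbind(c(0, 0, 2, 2),
             c(0, 0, 4, 4),     # identical direction to row 1 on support
             c(3, 3, 0, 0),     # orthogonal to rows 1-2
             c(1, 1, 1, 1))
  m <- m * 0 + (m + t(m)) / 2   # symmetrize
  diag(m) <- 0
  A2 <- normalizedAngleAffinity(ConnectivityMatrix(m, "functional"), 1)$values
  expect_true(all(A2 >= 0 & A2 <= 1))
})

test_that("affinity entries stay in [0,1] on random connectomes", {
  set.seed(4)
  for (rep in 1:25) {
    v <- randomSymmetric(12)
    A <- normalizedAngleAffinity(ConnectivityMatrix(v, "functional"),
                                 rowSparsity = 0.5)$values
    expect_true(all(A >= 0 & A <= 1))
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 1))
  }
})

test_that("diffusion map recovers a 1-D chain ordering", {
  n <- 40
  pos <- seq_len(n)
  A <- exp(-as.matrix(dist(pos)) / 4)
  gs <- diffusionMapEmbed(list(values = A), nComponents = 5)
  expect_equal(abs(cor(gradientScores(gs)[, 1], pos, method = "spearman")), 1)
  # with 10% relative noise the ordering survives almost intact
  set.seed(5)
  noise <- matrix(rnorm(n * n, sd = 0.1), n, n)
  An <- A * (1 + (noise + t(noise)) / 2)
  An[An < 0] <- 0
  gsn <- diffusionMapEmbed(list(values = An), nComponents = 5)
  expect_gt(abs(cor(gradientScores(gsn)[, 1], pos, method = "spearman")), 0.95)
})

test_that("gradient 1 separates a two-community affinity by sign", {
  A <- matrix(0.05, 20, 20)
  A[1:10, 1:10] <- 0.9
  A[11:20, 11:20] <- 0.9
  diag(A) <- 1
  gs <- diffusionMapEmbed(list(values = A), nComponents = 3)
  s1 <- gradientScores(gs)[, 1]
  expect_true(all(sign(s1[1:10]) == sign(s1[1])))
  expect_true(all(sign(s1[11:20]) == -sign(s1[1])))
})

test_that("variance explained equals eigenvalue ratios, descending in (0,1)", {
  set.seed(6)
  v <- abs(randomSymmetric(25))
  gs <- diffusionMapEmbed(normalizedAngleAffinity(
    ConnectivityMatrix(v, "functional"), 0.5), nComponents = 8)
  ve <- varianceExplained(gs)
  expect_true(all(diff(ve) <= 1e-12))
  expect_true(all(ve > 0 & ve < 1))
  expect_lte(sum(ve), 1)
  expect_equal(ve, gradientEigenvalues(gs) / gs@eigenvalueSum,
               tolerance = 1e-10)
})

test_that("embedding commutes with consistent node permutation (up to sign)", {
  set.seed(7)
  v <- abs(randomSymmetric(30))
  A <- normalizedAngleAffinity(ConnectivityMatrix(v, "functional"), 0.5)
  g1 <- gradientScores(diffusionMapEmbed(A, nComponents = 3))
  perm <- sample(30)
  Ap <- list(values = A$values[perm, perm])
  g2 <- gradientScores(diffusionMapEmbed(Ap, nComponents = 3))
  for (k in 1:3)
    expect_equal(abs(cor(g2[, k], g1[perm, k])), 1, tolerance = 1e-6)
})

test_that("group template equals the single-matrix embedding for copies", {
  set.seed(8)
  v <- abs(randomSymmetric(30))
  conn <- ConnectivityMatrix(v, "structural")
  tpl <- buildGroupTemplate(list(conn, conn, conn))
  single <- diffusionMapEmbed(normalizedAngleAffinity(conn, 0.1))
  for (k in 1:3)
    expect_equal(abs(cor(gradientScores(tpl)[, k],
                         gradientScores(single)[, k])), 1, tolerance = 1e-8)
  expect_identical(tpl@alignedTo, "template")
  # modality mixing is rejected
  fcm <- ConnectivityMatrix(randomSymmetric(30), "functional")
  expect_error(buildGroupTemplate(list(conn, fcm)), "mix")
})

test_that("synthetic template gradient 1 tracks the planted A-P axis", {
  co <- controlCohort()
  tpl <- buildGroupTemplate(lapply(co$subjects, `[[`, "sc"))
  rho <- cor(gradientScores(tpl)[, 1], co$parcellation@anatXYZ[, 2],
             method = "spearman")
  expect_gt(abs(rho), 0.8)
})

test_that("Procrustes realigns rotated and reflected gradients", {
  set.seed(9)
  tplScores <- matrix(rnorm(50 * 4), 50, 4)
  lam <- sort(runif(4, 0.2, 0.9), decreasing = TRUE)
  tpl <- GradientSet(tplScores, lam, eigenvalueSum = sum(lam) * 2)

  # identity case: nothing moves
  aligned0 <- procrustesAlign(tpl, tpl)
  expect_equal(gradientScores(aligned0), tplScores, tolerance = 1e-10)

  for (rep in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4))) %*% diag(sample(c(-1, 1), 4, TRUE))
    ind <- GradientSet(tplScores %*% Q, lam, eigenvalueSum = sum(lam) * 2)
    aligned <- procrustesAlign(ind, tpl)
    for (k in 1:4)
      expect_gt(cor(gradientScores(aligned)[, k], tplScores[, k]), 0.999)
    # eigen-structure carried over unchanged
    expect_identical(gradientEigenvalues(aligned), lam)
  }

  # alignment never increases the residual
  noisy <- GradientSet(tplScores %*% qr.Q(qr(matrix(rnorm(16), 4, 4))) +
                         matrix(rnorm(200, sd = 0.05), 50, 4),
                       lam, eigenvalueSum = sum(lam) * 2)
  before <- norm(gradientScores(noisy) - tplScores, "F")
  after <- norm(gradientScores(procrustesAlign(noisy, tpl)) - tplScores, "F")
  expect_lte(after, before)

  # k mismatch
  small <- GradientSet(tplScores[, 1:2], lam[1:2], eigenvalueSum = sum(lam))
  expect_error(procrustesAlign(small, tpl), "same n and k")
})

test_that("orientation is deterministic and involution-safe", {
  co <- controlCohort()
  parc <- co$parcellation
  tpl <- buildGroupTemplate(lapply(co$subjects, `[[`, "sc"))
  o1 <- orientGradients(tpl, parc)
  # oriented gradient 1 correlates negatively with the anterior direction
  expect_lt(cor(gradientScores(o1)[, 1], parc@anatXYZ[, 2],
                method = "spearman"), 0)
  # orienting twice changes nothing; negating flips back
  expect_equal(gradientScores(orientGradients(o1, parc)),
               gradientScores(o1))
  neg <- o1; neg@scores <- -neg@scores
  expect_equal(gradientScores(orientGradients(neg, parc))[, 1],
               gradientScores(o1)[, 1])
})

test_that("axis correlation returns exact rho for exact relationships", {
  co <- controlCohort()
  parc <- co$parcellation
  perms <- generateSpinPermutations(parc, 100, seed = 5)
  axis <- parc@anatXYZ[, 2]
  res <- axisCorrelation(-axis, axis, perms)
  expect_equal(res$rho, -1)
  expect_lt(res$pSpin, 0.05)
  expect_error(axisCorrelation(axis, rep(1, 100), perms), "constant")
})
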