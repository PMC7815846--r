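# Data model validity and delimited-text round trips.

test_that("connectivity matrix loader validates, symmetrizes and round-trips", {
  parc4 <- makeParcellation(10)  # 20 nodes
  tmp <- withr::local_tempdir()

  v <- randomSymmetric(20, nonneg = TRUE)
  f <- file.path(tmp, "sc.tsv")
  writeConnectivityMatrix(ConnectivityMatrix(v, "structural"), f)
  back <- loadConnectivityMatrix(f, parc4, "structural")
  expect_equal(connValues(back), v, tolerance = 0)  # full written precision
  expect_identical(modality(back), "structural")

  # shape mismatch against a bigger parcellation
  parcBig <- makeParcellation(50)
  expect_error(loadConnectivityMatrix(f, parcBig, "structural"), "parcellation")

  # sub-tolerance asymmetry is averaged: 0.5 vs 0.5 + 1e-9 -> 0.5 + 5e-10
  v2 <- matrix(0, 4, 4)
  v2[2, 3] <- 0.5; v2[3, 2] <- 0.5 + 1e-9
  f2 <- file.path(tmp, "asym.tsv")
  write.table(format(v2, digits = 17), f2, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  parcTiny <- list()  # need a 4-node parcellation: build by hand
  sph <- diag(3)[c(1, 2, 3, 1), ]; sph[4, ] <- c(-1, 0, 0)
  p4 <- Parcellation(letters[1:4], c("L", "L", "R", "R"), sph, sph * 70,
                     c("Vis", "Vis", "Default", "Default"), c(1L, 1L, 4L, 4L))
  m <- loadConnectivityMatrix(f2, p4, "structural")
  expect_equal(connValues(m)[2, 3], 0.5 + 5e-10, tolerance = 1e-15)
  expect_equal(connValues(m)[3, 2], 0.5 + 5e-10, tolerance = 1e-15)

  # asymmetry above tolerance is rejected
  v3 <- v2; v3[3, 2] <- 0.5 + 1e-6
  f3 <- file.path(tmp, "bad.tsv")
  write.table(v3, f3, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(loadConnectivityMatrix(f3, p4, "structural"), "asymmetry")

  # NaN entries are a content error
  v4 <- v2; v4[1, 2] <- NaN; v4[2, 1] <- NaN
  f4 <- file.path(tmp, "nan.tsv")
  write.table(v4, f4, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(loadConnectivityMatrix(f4, p4, "structural"), "NaN")
})

test_that("connectivity matrix class enforces its invariants", {
  v <- randomSymmetric(5)
  expect_error(ConnectivityMatrix(v, "structural"), "non-negative")
  expect_silent(ConnectivityMatrix(v, "functional"))
  bad <- abs(v); bad[1, 2] <- bad[1, 2] + 1
  expect_error(ConnectivityMatrix(bad, "structural"), "symmetric")
  d <- abs(v); diag(d) <- 1
  expect_error(ConnectivityMatrix(d, "structural"), "diagonal")
})

test_that("parcellation table round-trips, renormalizes and rejects bad input", {
  parc <- smallParcellation()
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "parc.tsv")
  writeParcellation(parc, f)
  back <- loadParcellation(f)
  expect_equal(back@sphereXYZ, parc@sphereXYZ, tolerance = 1e-12)
  expect_identical(back@hierarchyLevel, parc@hierarchyLevel)
  expect_identical(back@nodeId, parc@nodeId)  # order preserved

  tab <- read.table(f, sep = "\t", header = TRUE)
  # slightly off-unit sphere norm is renormalized
  tab2 <- tab
  tab2[1, c("sphere_x", "sphere_y", "sphere_z")] <-
    0.9995 * tab2[1, c("sphere_x", "sphere_y", "sphere_z")]
  f2 <- file.path(tmp, "renorm.tsv")
  write.table(tab2, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- loadParcellation(f2)
  expect_equal(sum(p2@sphereXYZ[1, ]^2), 1, tolerance = 1e-12)

  # norm off by more than 1e-3 is rejected
  tab3 <- tab
  tab3[1, c("sphere_x", "sphere_y", "sphere_z")] <-
    0.9 * tab3[1, c("sphere_x", "sphere_y", "sphere_z")]
  f3 <- file.path(tmp, "badnorm.tsv")
  write.table(tab3, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadParcellation(f3), "norm")

  # out-of-range hierarchy level is rejected
  tab4 <- tab; tab4$hierarchy_level[1] <- 5L
  f4 <- file.path(tmp, "badlevel.tsv")
  write.table(tab4, f4, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadParcellation(f4))

  # missing column is rejected
  f5 <- file.path(tmp, "missing.tsv")
  write.table(tab[, -3], f5, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadParcellation(f5), "missing")
})

test_that("saveResults writes tables plus a manifest, deterministically", {
  tmp <- withr::local_tempdir()
  bundle <- list(coupling = data.frame(node_id = 0:9, coupling = sqrt(1:10)))
  m <- saveResults(bundle, file.path(tmp, "a"), config = list(x = 1), seed = 7L)
  expect_true(file.exists(file.path(tmp, "a", "coupling.tsv")))
  expect_true(file.exists(file.path(tmp, "a", "manifest.json")))
  tab <- read.table(file.path(tmp, "a", "coupling.tsv"), header = TRUE)
  expect_equal(nrow(tab), 10)
  expect_named(tab, c("node_id", "coupling"))

  # identical rerun produces byte-identical numeric tables
  saveResults(bundle, file.path(tmp, "b"), config = list(x = 1), seed = 7L)
  expect_identical(readLines(file.path(tmp, "a", "coupling.tsv")),
                   readLines(file.path(tmp, "b", "coupling.tsv")))

  # empty bundle: manifest only, with a warning
  expect_warning(saveResults(list(), file.path(tmp, "c")), "empty")
  expect_true(file.exists(file.path(tmp, "c", "manifest.json")))
})

test_that("covariate and expression loaders validate their columns", {
  tmp <- withr::local_tempdir()
  cov <- data.frame(subject_id = c("a", "b"), group = c("g1", "g2"),
                    age = c(60, 70), sex = c(0, 1))
  f <- file.path(tmp, "cov.tsv")
  write.table(cov, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(loadCovariates(f)$age, c(60, 70))
  write.table(cov[, -2], f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadCovariates(f), "missing")

  parc <- smallParcellation()
  ex <- makeExpressionTable(parc, seq_len(nodeCount(parc)),
                            planted = c(G1 = 0.3), nNullGenes = 2, seed = 3)
  fx <- file.path(tmp, "expr.tsv")
  write.table(data.frame(node_id = parc@nodeId, ex, check.names = FALSE),
              fx, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- loadExpressionTable(fx, parc)
  expect_equal(unname(back), unname(ex), tolerance = 1e-12)
  expect_identical(colnames(back), colnames(ex))
})
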