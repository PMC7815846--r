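# Nodewise GLM, BH-FDR, global comparison, coupling-score correlation.

# simulate per-subject coupling maps around a truth map
simulateMaps <- function(truth, groups, sd = 0.05, seed = 1) {
  set.seed(seed)
  maps <- list()
  cov <- list()
  i <- 0
  for (g in names(groups)) {
    for (s in seq_len(groups[[g]])) {
      i <- i + 1
      id <- sprintf("%s_%d", g, s)
      mu <- truth[[g]]
      maps[[id]] <- CouplingMap(pmin(0.99, pmax(-0.99,
        mu + rnorm(length(mu), sd = sd))), subjectId = id)
      cov[[id]] <- data.frame(subject_id = id, group = g,
                              age = rnorm(1, 65, 8), sex = rbinom(1, 1, 0.5))
    }
  }
  list(maps = maps, covariates = do.call(rbind, cov))
}

test_that("fdrBH matches the hand-worked step-up example", {
  r <- fdrBH(c(0.01, 0.02, 0.03, 0.9), q = 0.05)
  # 0.01 <= 1*0.05/4, 0.02 <= 2*0.05/4, 0.03 <= 3*0.05/4; 0.9 fails
  expect_identical(r$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$qValues, stats::p.adjust(c(0.01, 0.02, 0.03, 0.9), "BH"))

  all1 <- fdrBH(rep(1, 5))
  expect_false(any(all1$mask))
  expect_true(all(all1$qValues == 1))

  # m = 1 reduces to the raw threshold
  expect_true(fdrBH(0.04, 0.05)$mask)
  expect_false(fdrBH(0.06, 0.05)$mask)

  expect_error(fdrBH(c(0.5, 0)), "p-values")
  expect_error(fdrBH(c(0.5, 1.2)), "p-values")
})

test_that("fdrBH agrees with an exhaustive step-up oracle", {
  set.seed(11)
  for (rep in 1:300) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdrBH(p, q)$mask, bhOracle(p, q))
  }
})

test_that("the GLM with no covariates reduces to a two-sample t-test", {
  sim <- simulateMaps(list(A = rep(0.5, 10), B = rep(0.45, 10)),
                      c(A = 8L, B = 8L), seed = 2)
  res <- nodewiseGLM(sim$maps, sim$covariates, c("B", "A"),
                     covariateNames = character(0))
  Y <- sapply(sim$maps, couplingValues)
  g <- sim$covariates$group
  for (j in c(1, 5, 10)) {
    tt <- t.test(Y[j, g == "B"], Y[j, g == "A"], var.equal = TRUE)
    expect_equal(res$t_stat[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[j], tt$p.value, tolerance = 1e-10)
    expect_equal(res$beta_group[j],
                 mean(Y[j, g == "B"]) - mean(Y[j, g == "A"]),
                 tolerance = 1e-12)
  }
})

test_that("planted nodewise decoupling is estimated and flagged", {
  truthA <- rep(0.5, 100)
  truthB <- truthA; truthB[1:8] <- truthB[1:8] - 0.2
  sim <- simulateMaps(list(A = truthA, B = truthB), c(A = 15L, B = 15L),
                      sd = 0.05, seed = 3)
  res <- nodewiseGLM(sim$maps, sim$covariates, c("B", "A"))
  expect_equal(mean(res$beta_group[1:8]), -0.2, tolerance = 0.05)
  expect_true(all(res$significant[1:8]))
  expect_lte(sum(res$significant[-(1:8)]), 2)
  # q-values never fall below p-values
  ok <- !is.na(res$p_value)
  expect_true(all(res$q_value[ok] >= res$p_value[ok]))
})

test_that("permuted group labels give a nominal false-positive rate", {
  truth <- rep(0.5, 200)
  sim <- simulateMaps(list(A = truth, B = truth), c(A = 15L, B = 15L),
                      sd = 0.05, seed = 4)
  res <- nodewiseGLM(sim$maps, sim$covariates, c("B", "A"))
  expect_lt(mean(res$p_value < 0.05), 0.12)
  expect_equal(sum(res$significant), 0)
})

test_that("nodes invalid in most subjects are excluded and reported", {
  truth <- rep(0.5, 20)
  sim <- simulateMaps(list(A = truth, B = truth), c(A = 5L, B = 5L), seed = 5)
  # knock out node 1 in 6 of 10 subjects
  for (k in 1:6) {
    v <- couplingValues(sim$maps[[k]]); v[1] <- NA
    sim$maps[[k]] <- CouplingMap(v, subjectId = sim$maps[[k]]@subjectId)
  }
  res <- nodewiseGLM(sim$maps, sim$covariates, c("B", "A"))
  expect_true(is.na(res$p_value[1]))
  expect_false(res$significant[1])
  expect_equal(res$n_used[1], 4)
  expect_error(nodewiseGLM(sim$maps, sim$covariates, c("B", "missing")),
               "at least 3")
})

test_that("global comparison detects a planted global shift and not its absence", {
  truthA <- rep(0.54, 100)
  truthB <- rep(0.48, 100)
  sim <- simulateMaps(list(A = truthA, B = truthB), c(A = 15L, B = 15L),
                      sd = 0.05, seed = 6)
  g <- globalComparison(sim$maps, sim$covariates, c("B", "A"))
  expect_equal(g$difference, -0.06, tolerance = 0.02)
  expect_lt(g$p, 0.05)
  # identical data in both groups: difference exactly zero
  maps2 <- sim$maps
  cv <- sim$covariates
  half <- seq_len(nrow(cv)) <= 15
  for (i in which(!half)) {
    src <- maps2[[which(half)[i - 15]]]
    maps2[[i]] <- CouplingMap(couplingValues(src),
                              subjectId = cv$subject_id[i])
  }
  cv$age <- rep(cv$age[half], 2); cv$sex <- rep(cv$sex[half], 2)
  g0 <- globalComparison(maps2, cv, c("B", "A"))
  expect_equal(g0$difference, 0, tolerance = 1e-12)
})

test_that("coupling-score correlation flags the coupled node", {
  sim <- simulateMaps(list(A = rep(0.5, 30)), c(A = 20L), sd = 0.05, seed = 7)
  scores <- vapply(sim$maps, function(m) couplingValues(m)[4], numeric(1))
  res <- couplingScoreCorrelation(sim$maps, scores)
  expect_equal(res$r[res$node_id == 3], 1, tolerance = 1e-12)
  expect_true(res$significant[res$node_id == 3])
  expect_error(couplingScoreCorrelation(sim$maps, rep(1, 20)), "constant")
  expect_error(couplingScoreCorrelation(sim$maps[1:3], scores[1:3]),
               "at least 5")
})
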