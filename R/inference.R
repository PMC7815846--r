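## Nodewise and global group comparison with covariate adjustment and
## FDR control, plus per-node coupling-behaviour correlation. Mass
## univariate: ordinary least squares per node, no spatial regularization.

## build the subject-level outcome matrix (subjects x nodes) aligned to a
## covariate table
.stackMaps <- function(maps, covariates) {
  ids <- vapply(maps, function(m) m@subjectId, character(1))
  miss <- setdiff(covariates$subject_id, ids)
  if (length(miss))
    stop("no coupling map for subject(s): ", paste(miss, collapse = ", "))
  sel <- maps[match(covariates$subject_id, ids)]
  t(vapply(sel, couplingValues, numeric(nodeCount(maps[[1]]))))
}

## OLS of y on X with a t-test on column `col`; returns c(beta, t, p, df)
.olsContrast <- function(X, y, col = 2L) {
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  if (df < 1 || fit$rank < ncol(X)) return(c(NA, NA, NA, df))
  res <- fit$residuals
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[col, col])
  beta <- unname(fit$coefficients[col])
  tt <- beta / se
  c(beta, tt, 2 * stats::pt(-abs(tt), df), df)
}

#' Nodewise general linear model group comparison
#'
#' Per node, ordinary least squares of the per-subject map values on
#' [intercept, group indicator, covariates], with a two-sided t-test on
#' the group coefficient and Benjamini--Hochberg FDR across valid nodes.
#' The group indicator is 1 for \code{contrast[1]} and 0 for
#' \code{contrast[2]}, so \code{beta_group} is the adjusted
#' \code{contrast[1]} minus \code{contrast[2]} difference (e.g.
#' \code{c("pd", "control")} gives negative betas for decoupling in
#' disease). Nodes invalid in more than 50% of the selected subjects are
#' excluded and reported with \code{NA} statistics.
#'
#' @param maps list of per-subject \linkS4class{CouplingMap} objects (or
#'   gradient-score maps wrapped as CouplingMap).
#' @param covariates data.frame with \code{subject_id}, \code{group} and
#'   the requested covariate columns.
#' @param contrast length-2 character: (test group, reference group).
#' @param covariateNames columns of \code{covariates} to adjust for
#'   (default age and sex; use \code{character(0)} for none).
#' @param qThreshold FDR threshold (default 0.05).
#' @return data.frame with node_id, beta_group, t_stat, p_value, q_value,
#'   significant, n_used.
#' @export
nodewiseGLM <- function(maps, covariates, contrast,
                        covariateNames = c("age", "sex"),
                        qThreshold = 0.05) {
  stopifnot(length(contrast) == 2)
  keep <- covariates$group %in% contrast
  cv <- covariates[keep, , drop = FALSE]
  if (!all(table(factor(cv$group, levels = contrast)) >= 3))
    stop("both groups need at least 3 subjects")
  Y <- .stackMaps(maps, cv)
  g <- as.numeric(cv$group == contrast[1])
  X <- cbind(intercept = 1, group = g)
  for (nm in covariateNames) X <- cbind(X, as.numeric(cv[[nm]]))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  nNodes <- ncol(Y)
  out <- matrix(NA_real_, nNodes, 4)
  nUsed <- integer(nNodes)
  for (j in seq_len(nNodes)) {
    ok <- !is.na(Y[, j])
    nUsed[j] <- sum(ok)
    if (mean(ok) <= 0.5) next
    if (length(unique(g[ok])) < 2) next
    Xo <- X[ok, , drop = FALSE]
    if (qr(Xo)$rank < ncol(Xo)) next
    out[j, ] <- .olsContrast(Xo, Y[ok, j])
  }
  p <- out[, 3]
  fdr <- fdrBH(p, qThreshold)
  data.frame(node_id = seq_len(nNodes) - 1L,
             beta_group = out[, 1], t_stat = out[, 2], p_value = p,
             q_value = fdr$qValues, significant = fdr$mask,
             n_used = nUsed)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement (cumulative
#' minimum from the largest rank), as implemented in
#' \code{stats::p.adjust(method = "BH")}, plus the threshold mask.
#' \code{NA} p-values (excluded nodes) stay \code{NA} and are never
#' significant.
#'
#' @param pValues numeric vector of p-values in (0, 1] (NA allowed).
#' @param q FDR threshold (default 0.05).
#' @return list with \code{qValues} and logical \code{mask}
#'   (significant at \code{q}).
#' @export
fdrBH <- function(pValues, q = 0.05) {
  ok <- !is.na(pValues)
  if (any(pValues[ok] <= 0 | pValues[ok] > 1))
    stop("p-values must lie in (0, 1]")
  qv <- stats::p.adjust(pValues, method = "BH")
  mask <- !is.na(qv) & qv < q
  list(qValues = qv, mask = mask)
}

#' Covariate-adjusted comparison of global coupling
#'
#' Computes the whole-network mean coupling per subject and fits the same
#' covariate-adjusted GLM on the scalar outcome.
#'
#' @inheritParams nodewiseGLM
#' @return list with \code{difference} (adjusted contrast[1] - contrast[2]),
#'   \code{t}, \code{p}, \code{df} and the per-group unadjusted means.
#' @export
globalComparison <- function(maps, covariates, contrast,
                             covariateNames = c("age", "sex")) {
  stopifnot(length(contrast) == 2)
  keep <- covariates$group %in% contrast
  cv <- covariates[keep, , drop = FALSE]
  if (!all(table(factor(cv$group, levels = contrast)) >= 3))
    stop("both groups need at least 3 subjects")
  ids <- vapply(maps, function(m) m@subjectId, character(1))
  sel <- maps[match(cv$subject_id, ids)]
  y <- vapply(sel, globalCoupling, numeric(1))
  g <- as.numeric(cv$group == contrast[1])
  X <- cbind(intercept = 1, group = g)
  for (nm in covariateNames) X <- cbind(X, as.numeric(cv[[nm]]))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  r <- .olsContrast(X, y)
  list(difference = r[1], t = r[2], p = r[3], df = r[4],
       groupMeans = tapply(y, factor(cv$group, levels = contrast), mean))
}

#' Correlate per-node coupling with a subject-level score
#'
#' Per selected node, correlates coupling across subjects with a
#' behavioural/cognition score (Spearman by default), with BH-FDR across
#' the selected nodes.
#'
#' @param maps list of per-subject \linkS4class{CouplingMap} objects.
#' @param scores named numeric vector (names = subject ids) or a vector
#'   aligned with \code{maps}.
#' @param nodes 0-based node ids to test (default all).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param q FDR threshold (default 0.05).
#' @return data.frame with node_id, r, p_value, q_value, significant, n.
#' @export
couplingScoreCorrelation <- function(maps, scores, nodes = NULL,
                                     method = c("spearman", "pearson"),
                                     q = 0.05) {
  method <- match.arg(method)
  ids <- vapply(maps, function(m) m@subjectId, character(1))
  if (!is.null(names(scores))) scores <- scores[ids]
  ok <- !is.na(scores)
  if (sum(ok) < 5) stop("need at least 5 subjects with scores")
  if (stats::sd(scores[ok]) == 0) stop("score is constant")
  Y <- t(vapply(maps[ok], couplingValues, numeric(nodeCount(maps[[1]]))))
  s <- scores[ok]
  if (is.null(nodes)) nodes <- seq_len(ncol(Y)) - 1L
  res <- t(vapply(nodes + 1L, function(j) {
    yy <- Y[, j]
    use <- !is.na(yy)
    if (sum(use) < 5) return(c(NA, NA, sum(use)))
    ct <- suppressWarnings(
      stats::cor.test(yy[use], s[use], method = method, exact = FALSE))
    ## a perfect correlation underflows to p = 0; keep it in (0, 1]
    c(unname(ct$estimate), max(ct$p.value, .Machine$double.xmin), sum(use))
  }, numeric(3)))
  fdr <- fdrBH(res[, 2], q)
  data.frame(node_id = nodes, r = res[, 1], p_value = res[, 2],
             q_value = fdr$qValues, significant = fdr$mask, n = res[, 3])
}
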