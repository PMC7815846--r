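## Spatial transcriptomic association: correlate a group coupling-difference
## map with regional gene-expression maps, FDR-corrected across genes and
## guarded against spatial autocorrelation by spin permutation of the
## difference map.

#' Covariate-adjusted coupling-difference map
#'
#' The per-node adjusted group coefficient (contrast[1] minus contrast[2])
#' from the nodewise GLM; invalid nodes are \code{NA}.
#'
#' @inheritParams nodewiseGLM
#' @return numeric per-node difference map.
#' @export
deltaCouplingMap <- function(maps, covariates, contrast,
                             covariateNames = c("age", "sex")) {
  nodewiseGLM(maps, covariates, contrast,
              covariateNames = covariateNames)$beta_group
}

#' Correlate a coupling-difference map with gene expression
#'
#' Per gene, the Spearman correlation between the difference map and the
#' gene's regional expression column; BH-FDR across genes; and a spin test
#' per gene in which the difference map is permuted by rotation-induced
#' reassignments while expression stays fixed. A gene is reported
#' significant only when both q < \code{qThreshold} and
#' p_spin < \code{pSpinThreshold} (set \code{requireSpin = FALSE} to use
#' FDR alone). A constant expression column yields \code{NA} results for
#' that gene, with a warning; other genes are unaffected. Missing delta
#' nodes are dropped pairwise per gene.
#'
#' @param delta per-node numeric difference map (NA allowed, < 10%).
#' @param expression regions x genes numeric matrix with gene symbols as
#'   column names (see \code{\link{loadExpressionTable}}).
#' @param parcellation the matching \linkS4class{Parcellation}.
#' @param nPerm number of spin permutations (default 1000).
#' @param qThreshold FDR threshold across genes (default 0.05).
#' @param pSpinThreshold spin threshold (default 0.05).
#' @param seed seed for the rotations.
#' @param permutations optional precomputed permutation matrix.
#' @param requireSpin require the spin conjunction (default TRUE).
#' @param alternative tail for the spin test (default two_sided).
#' @return data.frame with gene, rho, p_value, q_value, p_spin,
#'   significant.
#' @export
geneMapCorrelation <- function(delta, expression, parcellation,
                               nPerm = 1000L, qThreshold = 0.05,
                               pSpinThreshold = 0.05, seed = 1L,
                               permutations = NULL, requireSpin = TRUE,
                               alternative = "two_sided") {
  if (length(delta) != nodeCount(parcellation) ||
      nrow(expression) != nodeCount(parcellation))
    stop("delta and expression must match the parcellation")
  if (is.null(colnames(expression)) || anyDuplicated(colnames(expression)))
    stop("expression must have unique gene symbols as column names")
  if (is.null(permutations))
    permutations <- generateSpinPermutations(parcellation, nPerm, seed)
  genes <- colnames(expression)
  res <- data.frame(gene = genes, rho = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, p_spin = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    e <- expression[, g]
    if (stats::sd(e, na.rm = TRUE) == 0) {
      warning("constant expression for gene '", genes[g], "'; skipped")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(delta, e, method = "spearman", exact = FALSE))
    res$rho[g] <- unname(ct$estimate)
    res$p_value[g] <- max(ct$p.value, .Machine$double.xmin)
    sn <- spinTest(delta, e, permutations, alternative = alternative)
    res$p_spin[g] <- pSpin(sn)
  }
  fdr <- fdrBH(res$p_value, qThreshold)
  res$q_value <- fdr$qValues
  res$significant <- fdr$mask &
    (if (requireSpin) !is.na(res$p_spin) & res$p_spin < pSpinThreshold
     else TRUE)
  res
}
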