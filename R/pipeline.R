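## Pipeline orchestration: one configuration drives simulate -> coupling ->
## gradients (+ axis inference) -> group comparison -> gene association,
## with per-stage seeds derived from the master seed and a reproducible
## text report.

#' Default pipeline configuration
#'
#' A complete demo configuration: a synthetic three-group cohort
#' (control / pd_high / pd_low) at desk scale with planted global
#' decoupling in the disease groups and focal extra decoupling in the
#' low-performer group, plus a synthetic gene panel with one planted
#' spatial association.
#'
#' @param masterSeed integer master seed; every stochastic stage derives
#'   its own seed from it by stable hashing.
#' @return a nested list understood by \code{\link{runPipeline}}.
#' @export
defaultRunConfig <- function(masterSeed = 1L) {
  list(
    master_seed = as.integer(masterSeed),
    stages = list(simulate = TRUE, coupling = TRUE, gradients = TRUE,
                  compare = TRUE, genes = TRUE),
    simulate = list(
      nodes_per_hemisphere = 50L,
      subjects_per_group = list(control = 10L, pd_high = 10L, pd_low = 10L),
      density = 0.6, decay = 1.0, ap_stretch = 3.0, noise_sd = 0.1,
      beta0 = 0.415, beta_ap = -0.16, beta_hier = -0.06,
      delta_global = list(pd_high = -0.06, pd_low = -0.075),
      delta_nodes = list(pd_low = list(nodes = 0:7, delta = -0.15)),
      expression = list(planted = list(DRD2 = -0.4), n_null_genes = 9L,
                        smoothness = 0.2)
    ),
    coupling = list(min_nonzero = 3L),
    gradients = list(sparsity = 0.1, alpha = 0.5, components = 10L,
                     diffusion_time = 0),
    spin = list(n_perm = 1000L, alternative = "two_sided"),
    compare = list(contrasts = list(c("pd_high", "control"),
                                    c("pd_low", "pd_high")),
                   covariates = c("age", "sex"), q = 0.05),
    genes = list(contrast = c("pd_high", "control"), q = 0.05,
                 p_spin = 0.05)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it (shallow per stage) over
#' \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
loadRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(user$master_seed %||% 1L)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.validateConfig <- function(config) {
  need <- c("master_seed", "stages", "simulate", "coupling", "gradients",
            "spin", "compare", "genes")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration is missing sections: ", paste(miss, collapse = ", "))
  st <- config$stages
  if (isTRUE(st$coupling) && !isTRUE(st$simulate))
    stop("coupling stage requires the simulate stage")
  if ((isTRUE(st$compare) || isTRUE(st$genes)) && !isTRUE(st$coupling))
    stop("compare/genes stages require the coupling stage")
  if (isTRUE(st$gradients) && !isTRUE(st$simulate))
    stop("gradients stage requires the simulate stage")
  invisible(TRUE)
}

## assemble the CouplingField a simulate-config describes
.fieldFromConfig <- function(sim) {
  gd <- list()
  for (g in names(sim$delta_global)) {
    gd[[g]] <- list(nodes = integer(0), delta = 0)
  }
  field <- CouplingField(beta0 = sim$beta0, betaAP = sim$beta_ap,
                         betaHier = sim$beta_hier)
  ## global shifts are encoded as a delta over every node
  n <- 2L * as.integer(sim$nodes_per_hemisphere)
  deltas <- list()
  allGroups <- union(names(sim$delta_global), names(sim$delta_nodes))
  for (g in allGroups) {
    d <- rep(0, n)
    if (!is.null(sim$delta_global[[g]]))
      d <- d + sim$delta_global[[g]]
    if (!is.null(sim$delta_nodes[[g]]))
      d[as.integer(sim$delta_nodes[[g]]$nodes) + 1L] <-
        d[as.integer(sim$delta_nodes[[g]]$nodes) + 1L] +
        sim$delta_nodes[[g]]$delta
    deltas[[g]] <- list(nodes = which(d != 0) - 1L,
                        delta = d[d != 0])
  }
  field@groupDeltas <- deltas
  field
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' described by the configuration, writes per-node result tables and a
#' JSON manifest to \code{outDir} (if given), and returns the results
#' bundle together with a human-readable report: global coupling per
#' group, significant decoupled nodes, gradient--axis correlations with
#' spin p-values, and the gene association table.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param outDir optional output directory.
#' @return invisibly, a list of stage results plus \code{report}
#'   (character vector of report lines).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  .validateConfig(config)
  seed0 <- as.integer(config$master_seed)
  st <- config$stages
  res <- list(config = config)
  report <- c("scfcoupling pipeline report",
              sprintf("master seed: %d", seed0), "")

  if (isTRUE(st$simulate)) {
    sim <- config$simulate
    design <- CohortDesign(
      nNodesPerHemisphere = sim$nodes_per_hemisphere,
      nSubjectsPerGroup = unlist(sim$subjects_per_group),
      scDensity = sim$density, distanceDecay = sim$decay,
      apStretch = sim$ap_stretch, noiseSd = sim$noise_sd,
      seed = deriveSeed(seed0, "simulate"))
    field <- .fieldFromConfig(sim)
    cohort <- makeCohort(design, field)
    res$cohort <- cohort
    report <- c(report, sprintf(
      "simulate: %d nodes, groups [%s]",
      nodeCount(cohort$parcellation),
      paste(sprintf("%s n=%d", names(design@nSubjectsPerGroup),
                    design@nSubjectsPerGroup), collapse = ", ")))
  }

  if (isTRUE(st$coupling)) {
    mn <- config$coupling$min_nonzero
    maps <- lapply(res$cohort$subjects, function(s) {
      couplingMap(s$sc, maskFunctionalBySC(s$fc, s$sc), minNonzero = mn)
    })
    res$maps <- maps
    cov <- res$cohort$covariates
    gm <- vapply(maps, globalCoupling, numeric(1))
    byGroup <- tapply(gm, cov$group[match(names(maps), cov$subject_id)], mean)
    res$globalByGroup <- byGroup
    report <- c(report, "", "global SC-FC coupling (cohort means):",
                sprintf("  %s: %.3f", names(byGroup), byGroup))
  }

  spinPerms <- NULL
  if (isTRUE(st$gradients)) {
    g <- config$gradients
    parc <- res$cohort$parcellation
    scMats <- lapply(res$cohort$subjects, `[[`, "sc")
    template <- buildGroupTemplate(scMats, rowSparsity = g$sparsity,
                                   nComponents = g$components,
                                   alpha = g$alpha,
                                   diffusionTime = g$diffusion_time)
    template <- orientGradients(template, parc)
    spinPerms <- generateSpinPermutations(parc, config$spin$n_perm,
                                          seed = deriveSeed(seed0, "spin"))
    ap <- axisCorrelation(gradientScores(template)[, 1],
                          parc@anatXYZ[, 2], spinPerms,
                          alternative = config$spin$alternative)
    hier <- axisCorrelation(gradientScores(template)[, 2],
                            as.numeric(parc@hierarchyLevel), spinPerms,
                            alternative = config$spin$alternative)
    res$template <- template
    res$axis <- list(ap = ap, hierarchy = hier)
    report <- c(report, "", "structural template gradients:",
                sprintf("  variance explained: g1 %.1f%%, g2 %.1f%%",
                        100 * varianceExplained(template)[1],
                        100 * varianceExplained(template)[2]),
                sprintf("  gradient 1 vs A-P axis: rho = %.3f, p_spin = %.4g",
                        ap$rho, ap$pSpin),
                sprintf("  gradient 2 vs hierarchy: rho = %.3f, p_spin = %.4g",
                        hier$rho, hier$pSpin))
  }

  if (isTRUE(st$compare)) {
    cc <- config$compare
    cov <- res$cohort$covariates
    res$compare <- list()
    report <- c(report, "", "group comparisons:")
    for (ct in cc$contrasts) {
      nw <- nodewiseGLM(res$maps, cov, ct, covariateNames = cc$covariates,
                        qThreshold = cc$q)
      gl <- globalComparison(res$maps, cov, ct,
                             covariateNames = cc$covariates)
      key <- paste(ct, collapse = "_vs_")
      res$compare[[key]] <- list(nodewise = nw, global = gl)
      report <- c(report, sprintf(
        "  %s vs %s: global diff %.3f (p = %.3g); %d/%d nodes significant at q < %.2f",
        ct[1], ct[2], gl$difference, gl$p, sum(nw$significant),
        sum(!is.na(nw$p_value)), cc$q))
    }
  }

  if (isTRUE(st$genes)) {
    gn <- config$genes
    cov <- res$cohort$covariates
    parc <- res$cohort$parcellation
    delta <- deltaCouplingMap(res$maps, cov, gn$contrast,
                              covariateNames = config$compare$covariates)
    ex <- config$simulate$expression
    expression <- makeExpressionTable(
      parc, targetMap = ifelse(is.na(delta), 0, delta),
      planted = unlist(ex$planted), nNullGenes = ex$n_null_genes,
      smoothness = ex$smoothness,
      seed = deriveSeed(seed0, "expression"))
    if (is.null(spinPerms))
      spinPerms <- generateSpinPermutations(parc, config$spin$n_perm,
                                            seed = deriveSeed(seed0, "spin"))
    ga <- geneMapCorrelation(delta, expression, parc,
                             qThreshold = gn$q, pSpinThreshold = gn$p_spin,
                             permutations = spinPerms)
    res$delta <- delta
    res$genes <- ga
    hits <- ga$gene[ga$significant]
    report <- c(report, "", sprintf(
      "gene association (%s vs %s): %d/%d genes significant%s",
      gn$contrast[1], gn$contrast[2], length(hits), nrow(ga),
      if (length(hits)) paste0(" (", paste(hits, collapse = ", "), ")")
      else ""))
  }

  res$report <- report
  if (!is.null(outDir)) {
    bundle <- list()
    if (!is.null(res$maps)) {
      vals <- vapply(res$maps, couplingValues,
                     numeric(nodeCount(res$maps[[1]])))
      bundle$coupling <- data.frame(node_id = seq_len(nrow(vals)) - 1L, vals,
                                    check.names = FALSE)
    }
    if (!is.null(res$template))
      bundle$template_gradients <- data.frame(
        node_id = seq_len(nodeCount(res$template)) - 1L,
        gradientScores(res$template)[, 1:2])
    for (key in names(res$compare))
      bundle[[paste0("nodewise_", key)]] <- res$compare[[key]]$nodewise
    if (!is.null(res$genes)) bundle$gene_association <- res$genes
    saveResults(bundle, outDir, config = config, seed = seed0)
    writeLines(report, file.path(outDir, "report.txt"))
  }
  invisible(res)
}
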