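## Delimited-text I/O. TSV is the exchange format throughout: matrices are
## written without headers (n rows x n numeric columns); parcellation,
## covariate and expression tables carry a header row; the run manifest is
## JSON. Loaders never reorder nodes — row order equals parcellation order.

#' Load a connectivity matrix from a TSV file
#'
#' Reads an n x n numeric table (no header), validates it against the
#' parcellation size, symmetrizes by averaging if the worst asymmetry is at
#' most 1e-8 (absorbing text round-trip noise) and errors on anything
#' larger, forces a zero diagonal, and tags the result with the modality.
#'
#' @param path path to a TSV matrix file.
#' @param parcellation the \linkS4class{Parcellation} the matrix indexes.
#' @param modality \code{"structural"} or \code{"functional"}.
#' @param subjectId subject identifier stored on the object.
#' @return A validated \linkS4class{ConnectivityMatrix}.
#' @export
loadConnectivityMatrix <- function(path, parcellation, modality,
                                   subjectId = basename(path)) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  storage.mode(v) <- "double"
  n <- nodeCount(parcellation)
  if (nrow(v) != n || ncol(v) != n)
    stop(sprintf("matrix is %d x %d but parcellation has %d nodes",
                 nrow(v), ncol(v), n))
  if (anyNA(v))
    stop("matrix contains NaN/NA entries")
  asym <- max(abs(v - t(v)))
  if (asym > 1e-8)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance 1e-8", asym))
  v <- (v + t(v)) / 2
  diag(v) <- 0
  ConnectivityMatrix(v, modality = modality, subjectId = subjectId,
                     weightSemantics = if (modality == "structural")
                       "normalised streamline weight" else "Fisher-z correlation")
}

#' Write a connectivity matrix as headerless TSV
#'
#' @param conn a \linkS4class{ConnectivityMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConnectivityMatrix <- function(conn, path) {
  utils::write.table(format(conn@values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parcColumns <- c("node_id", "label", "hemisphere",
                  "sphere_x", "sphere_y", "sphere_z",
                  "anat_x", "anat_y", "anat_z",
                  "network", "hierarchy_level")

#' Load a parcellation table
#'
#' Expects a TSV with header columns \code{node_id}, \code{label},
#' \code{hemisphere}, \code{sphere_x/y/z}, \code{anat_x/y/z},
#' \code{network}, \code{hierarchy_level}. Sphere centroids within 1e-3 of
#' unit norm are renormalized; larger deviations are an error.
#'
#' @param path path to the TSV file.
#' @return A validated \linkS4class{Parcellation}.
#' @export
loadParcellation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(.parcColumns, names(tab))
  if (length(missing))
    stop("parcellation table is missing columns: ",
         paste(missing, collapse = ", "))
  if (!identical(as.integer(tab$node_id), seq_len(nrow(tab)) - 1L))
    stop("node_id must be contiguous 0..n-1 in file order")
  sph <- as.matrix(tab[, c("sphere_x", "sphere_y", "sphere_z")])
  norms <- sqrt(rowSums(sph^2))
  if (any(abs(norms - 1) > 1e-3))
    stop("sphere centroid norms deviate from 1 by more than 1e-3")
  sph <- sph / norms
  Parcellation(label = tab$label, hemisphere = tab$hemisphere,
               sphereXYZ = sph,
               anatXYZ = as.matrix(tab[, c("anat_x", "anat_y", "anat_z")]),
               network = tab$network,
               hierarchyLevel = tab$hierarchy_level)
}

#' Write a parcellation table
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeParcellation <- function(parcellation, path) {
  p <- parcellation
  tab <- data.frame(node_id = p@nodeId, label = p@label,
                    hemisphere = p@hemisphere,
                    sphere_x = p@sphereXYZ[, 1], sphere_y = p@sphereXYZ[, 2],
                    sphere_z = p@sphereXYZ[, 3],
                    anat_x = p@anatXYZ[, 1], anat_y = p@anatXYZ[, 2],
                    anat_z = p@anatXYZ[, 3],
                    network = p@network, hierarchy_level = p@hierarchyLevel)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a covariate table
#'
#' TSV with header; requires columns \code{subject_id}, \code{group},
#' \code{age}, \code{sex}; an optional \code{score} column is kept.
#'
#' @param path path to the TSV file.
#' @return data.frame, one row per subject.
#' @export
loadCovariates <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("covariate table is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in covariate table")
  tab
}

#' Load a regions x genes expression table
#'
#' TSV with header; first column \code{node_id} (0-based, parcellation
#' order), remaining columns one per gene.
#'
#' @param path path to the TSV file.
#' @param parcellation optional \linkS4class{Parcellation} to validate
#'   region count and order against.
#' @return numeric matrix, regions x genes, gene symbols as column names.
#' @export
loadExpressionTable <- function(path, parcellation = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "node_id")
    stop("expression table must start with a node_id column")
  if (!is.null(parcellation) &&
      !identical(as.integer(tab$node_id), parcellation@nodeId))
    stop("expression table regions do not match the parcellation")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene symbols in expression table")
  m
}

#' Save a results bundle to a directory
#'
#' Writes each element of \code{bundle} as delimited text with headers
#' (data.frames and matrices as TSV, scalars/lists into the manifest) plus
#' a JSON run manifest carrying a configuration hash, the seed and package
#' version. Re-running with the same seed and configuration produces
#' byte-identical numeric tables.
#'
#' @param bundle named list of data.frames / matrices / scalar summaries.
#' @param outDir output directory (created if needed).
#' @param config configuration object included (hashed) in the manifest.
#' @param seed the seed the run used.
#' @return invisibly, the manifest as a list.
#' @export
saveResults <- function(bundle, outDir, config = list(), seed = NA_integer_) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (length(bundle) == 0)
    warning("empty results bundle: writing manifest only")
  files <- character(0)
  scalars <- list()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x) || is.matrix(x)) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(x), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, basename(f))
    } else {
      scalars[[nm]] <- x
    }
  }
  manifest <- list(
    package = "scfcoupling",
    version = as.character(utils::packageVersion("scfcoupling")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = fnvDigest(config),
    files = files,
    summaries = scalars
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
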