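# TSV/GMT/JSON input-output.
#
# Dialects: expression matrices are tab-separated with a header row of
# sample ids and a first column of gene identifiers; missing values are
# "NA"; clinical and truth tables are plain TSV with fixed column names.

.writeTsvMatrix <- function(x, path, idCol = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.readTsvMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a simulated cohort to a fixture directory
#'
#' Serializes a [SimulatedCohort-class] as one expression TSV per dataset,
#' a clinical TSV, two truth TSVs, and a JSON manifest recording the files,
#' seed, and per-file MD5 hashes. Round-trips losslessly through
#' [readFixture()].
#'
#' @param bundle A [SimulatedCohort-class].
#' @param directory Output directory (created if needed).
#' @param force Overwrite an existing manifest? Default `FALSE`.
#' @return Invisibly, the manifest list.
#' @export
writeFixture <- function(bundle, directory, force = FALSE) {
  stopifnot(is(bundle, "SimulatedCohort"))
  if (nrow(bundle@studies[[1]]) == 0L) stop("no genes")
  manifestPath <- file.path(directory, "manifest.json")
  if (file.exists(manifestPath) && !force) {
    stop("manifest already exists in '", directory,
         "'; use force = TRUE to overwrite")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (st in bundle@studies) {
    f <- paste0("expression_", datasetId(st), ".tsv")
    .writeTsvMatrix(exprs(st), file.path(directory, f))
    files <- c(files, f)
  }
  utils::write.table(bundle@clinical, file.path(directory, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(bundle@truth$samples,
                     file.path(directory, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(bundle@truth$genes,
                     file.path(directory, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  files <- c(files, "clinical.tsv", "truth_samples.tsv", "truth_genes.tsv")
  manifest <- list(
    files = files,
    datasets = vapply(bundle@studies, datasetId, character(1)),
    platforms = vapply(bundle@studies, platform, character(1)),
    seed = bundle@config$seed,
    md5 = as.list(tools::md5sum(file.path(directory, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture directory back into a SimulatedCohort
#'
#' @param directory Directory written by [writeFixture()].
#' @return A [SimulatedCohort-class] (config holds only the recorded seed).
#' @export
readFixture <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  clinical <- utils::read.delim(file.path(directory, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  studiesList <- vector("list", length(manifest$datasets))
  for (i in seq_along(manifest$datasets)) {
    ds <- manifest$datasets[i]
    m <- .readTsvMatrix(file.path(directory,
                                  paste0("expression_", ds, ".tsv")))
    studiesList[[i]] <- ExpressionStudy(
      m, platform = manifest$platforms[i], datasetId = ds)
  }
  truth <- list(
    samples = utils::read.delim(file.path(directory, "truth_samples.tsv"),
                                stringsAsFactors = FALSE),
    genes = utils::read.delim(file.path(directory, "truth_genes.tsv"),
                              stringsAsFactors = FALSE))
  new("SimulatedCohort", studies = studiesList, clinical = clinical,
      truth = truth, config = list(seed = manifest$seed))
}

#' Read one expression study from a TSV matrix
#'
#' @param path TSV file: header row of sample ids, first column of probe or
#'   gene identifiers.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param datasetId Study identifier.
#' @param probeMap Optional named probe-to-gene map (see
#'   [ExpressionStudy()]).
#' @return An [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(path, platform, datasetId,
                                probeMap = NULL) {
  m <- .readTsvMatrix(path)
  # inputs are expected on the log2 scale already; a gross range violation
  # usually means untransformed counts
  if (any(m < -10 | m > 30, na.rm = TRUE)) {
    warning("values outside [-10, 30] in ", path,
            "; input may not be log2 scale")
  }
  ExpressionStudy(m, platform = platform, datasetId = datasetId,
                  probeMap = probeMap)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name <tab> description <tab> gene1 <tab> gene2 ...`.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

#' Serialize a SignatureModel to JSON
#'
#' @param model A [SignatureModel-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeSignature <- function(model, path) {
  stopifnot(is(model, "SignatureModel"))
  jsonlite::write_json(
    list(genes = signatureGenes(model),
         beta = unname(signatureBeta(model)),
         cutoff = signatureCutoff(model),
         learning_aic = model@learningAic,
         meta = model@provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a SignatureModel from JSON
#'
#' @param path File written by [writeSignature()].
#' @return A [SignatureModel-class].
#' @export
readSignature <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  SignatureModel(genes = j$genes, beta = j$beta,
                 cutoff = if (is.null(j$cutoff)) NA_real_ else j$cutoff,
                 learningAic = if (is.null(j$learning_aic)) NA_real_ else
                   j$learning_aic,
                 provenance = as.list(j$meta))
}
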