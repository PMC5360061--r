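## Tab-delimited matrix IO: first column holds row ids, remaining columns
## are sample ids. UTF-8, '.' decimal.

.write_matrix_tsv <- function(mat, path, id_col = "id") {
  dt <- data.table::data.table(id = rownames(mat))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

.write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}

#' Write a simulated dataset to disk as a plain-text fixture bundle
#'
#' Writes one expression/probe-map/phenotype TSV triple per clinical study,
#' the prediagnostic triple, the ground-truth table and a JSON manifest
#' listing every file with study metadata. The bundle round-trips losslessly
#' through [read_fixture_bundle()] up to numeric printing precision.
#'
#' @param path directory to create/populate.
#' @param studies `studies` element of [simulate_clinical_studies()].
#' @param cohort result of [simulate_prediag_cohort()].
#' @param truth ground-truth data.frame.
#' @return the manifest (invisibly).
#' @export
write_fixture_bundle <- function(path, studies, cohort, truth) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  files <- character(0)
  wf <- function(fun, obj, name, ...) {
    fun(obj, file.path(path, name), ...)
    files <<- c(files, name)
    name
  }
  manifest <- list(studies = list(), prediag = list(), truth = "truth.tsv")
  for (st in studies) {
    id <- st$study_id
    manifest$studies[[id]] <- list(
      study_id = id, tissue = st$tissue,
      expr = wf(.write_matrix_tsv, st$expr, paste0(id, "_expr.tsv"),
                id_col = "probe_id"),
      probe_map = wf(.write_table_tsv, st$probe_map,
                     paste0(id, "_probemap.tsv")),
      pheno = wf(.write_table_tsv, st$pheno, paste0(id, "_pheno.tsv"))
    )
  }
  manifest$prediag <- list(
    expr = wf(.write_matrix_tsv, cohort$expr, "prediag_expr.tsv",
              id_col = "probe_id"),
    probe_map = wf(.write_table_tsv, cohort$probe_map,
                   "prediag_probemap.tsv"),
    pheno = wf(.write_table_tsv, cohort$pheno, "prediag_pheno.tsv")
  )
  wf(.write_table_tsv, truth, "truth.tsv")
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param path bundle directory containing `manifest.json`.
#' @return list with `studies`, `cohort` and `truth` shaped like the
#'   simulator outputs.
#' @export
read_fixture_bundle <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  studies <- lapply(mf$studies, function(s) {
    list(expr = .read_matrix_tsv(file.path(path, s$expr)),
         probe_map = .read_table_tsv(file.path(path, s$probe_map)),
         pheno = .read_table_tsv(file.path(path, s$pheno)),
         tissue = s$tissue, study_id = s$study_id)
  })
  names(studies) <- NULL
  cohort <- list(expr = .read_matrix_tsv(file.path(path, mf$prediag$expr)),
                 probe_map = .read_table_tsv(file.path(path,
                                                       mf$prediag$probe_map)),
                 pheno = .read_table_tsv(file.path(path, mf$prediag$pheno)))
  truth <- .read_table_tsv(file.path(path, mf$truth))
  list(studies = studies, cohort = cohort, truth = truth)
}
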