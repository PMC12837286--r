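## plain-text I/O: Matrix Market + TSV for references, CSV for matrices and
## fractions, JSON/TSV for reports

#' Write a reference to a directory
#'
#' Layout: `matrix.mtx` (sparse gene x cell counts), `genes.tsv`
#' (`gene_id`, `marker_of`) and `cells.tsv` (`cell_id`, `fine`, `normal`,
#' `coarse`, `donor_id`, `mito_fraction`).
#'
#' @param reference a [SingleCellReference-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeReference <- function(reference, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cnt <- SummarizedExperiment::assay(reference, "counts")
  Matrix::writeMM(cnt, file.path(dir, "matrix.mtx"))
  mk <- markerGenes(reference)
  markerOf <- rep(NA_character_, nrow(cnt))
  names(markerOf) <- rownames(cnt)
  for (t in names(mk)) markerOf[mk[[t]]] <- t
  utils::write.table(
    data.frame(gene_id = rownames(cnt), marker_of = unname(markerOf)),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(reference)
  utils::write.table(
    data.frame(cell_id = colnames(cnt), fine = cd$fine, normal = cd$normal,
               coarse = cd$coarse, donor_id = cd$donor_id,
               mito_fraction = format(cd$mito_fraction, digits = 15)),
    file.path(dir, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference from a directory
#'
#' Loads the `matrix.mtx` + `genes.tsv` + `cells.tsv` layout written by
#' [writeReference()], validates dimensions and label-hierarchy totality,
#' and strips all-zero gene rows (logging the count).
#'
#' @param dir directory containing the three files.
#' @return a [SingleCellReference-class].
#' @export
readReference <- function(dir) {
  for (f in c("matrix.mtx", "genes.tsv", "cells.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("missing file: %s", file.path(dir, f)), call. = FALSE)
    }
  }
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(genes)) {
    stop("genes.tsv must carry a gene_id column", call. = FALSE)
  }
  needed <- c("cell_id", "fine", "normal", "coarse", "donor_id",
              "mito_fraction")
  missing <- setdiff(needed, colnames(cells))
  if (length(missing)) {
    stop(sprintf("cells.tsv missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but genes.tsv has %d rows and cells.tsv %d rows",
      nrow(counts), ncol(counts), nrow(genes), nrow(cells)), call. = FALSE)
  }
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  keep <- Matrix::rowSums(counts) > 0
  if (any(!keep)) {
    message(sprintf("removed %d non-expressed gene(s)", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
    genes <- genes[keep, , drop = FALSE]
  }
  markers <- list()
  if ("marker_of" %in% colnames(genes)) {
    ok <- !is.na(genes$marker_of) & genes$marker_of != ""
    if (any(ok)) markers <- split(genes$gene_id[ok], genes$marker_of[ok])
  }
  SingleCellReference(counts, cells, markers = markers)
}

#' Read a labelled numeric matrix from CSV
#'
#' First column holds row labels, header holds column labels. Rows must be
#' rectangular and the body numeric; violations are parse errors naming
#' the first offending line.
#'
#' @param path CSV file.
#' @param orientation documented orientation of the file, stored as an
#'   attribute (`"genes_x_samples"` or `"samples_x_types"`).
#' @return numeric matrix with dimnames.
#' @export
readMatrixCSV <- function(path, orientation = c("genes_x_samples",
                                                "samples_x_types")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected row labels plus numeric columns",
                          call. = FALSE)
  lab <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    badLine <- which(is.na(v) & !is.na(body[[j]]))
    if (length(badLine)) {
      stop(sprintf("non-numeric cell at line %d, column '%s'",
                   badLine[1] + 1L, colnames(body)[j]), call. = FALSE)
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- lab
  attr(m, "orientation") <- orientation
  m
}

#' Write a labelled numeric matrix to CSV
#'
#' Values are written with 15 significant digits so round trips are exact
#' to at least 1e-10; labels are preserved byte-exact.
#'
#' @param m matrix with dimnames.
#' @param path output CSV.
#' @param labelName header of the row-label column.
#' @return `path`, invisibly.
#' @export
writeMatrixCSV <- function(m, path, labelName = "id") {
  df <- data.frame(rownames(m),
                   apply(m, 2, function(x) format(x, digits = 15,
                                                  trim = TRUE,
                                                  scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(labelName, colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write estimated fractions to CSV
#' @param fm a [FractionMatrix-class] (or sample x type matrix).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeFractions <- function(fm, path) {
  v <- if (methods::is(fm, "FractionMatrix")) fractions(fm) else as.matrix(fm)
  writeMatrixCSV(v, path, labelName = "sample")
}

#' Read a fractions CSV (samples x types)
#'
#' @param path CSV with a `sample` label column.
#' @param sumConstrained whether rows are expected to sum to one.
#' @return a [FractionMatrix-class].
#' @export
readFractions <- function(path, sumConstrained = FALSE) {
  m <- readMatrixCSV(path, "samples_x_types")
  if (any(m < 0)) {
    stop("negative entries are not valid fractions", call. = FALSE)
  }
  FractionMatrix(m, sumConstrained = sumConstrained)
}

.tidyReport <- function(report, experiment = NA_character_,
                        group = NA_character_) {
  pt <- perTypeMetrics(report)
  rows <- list()
  for (metric in c("pearson", "rmse", "mae", "mape")) {
    flag <- rep("", nrow(pt))
    if (metric == "pearson") flag[pt$pearson_undefined] <- "undefined"
    if (metric == "mape") flag[pt$mape_undefined] <- "undefined"
    rows[[metric]] <- data.frame(
      experiment = experiment, group = group, cell_type = pt$cell_type,
      metric = metric, value = pt[[metric]], flag = flag,
      stringsAsFactors = FALSE)
  }
  g <- data.frame(
    experiment = experiment, group = group, cell_type = "all",
    metric = "global_pearson", value = report@globalPearson,
    flag = if (report@globalUndefined) "undefined" else "",
    stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), g)
}

#' Write an evaluation or spillover report
#'
#' `.json` paths get a JSON document (via jsonlite, full precision);
#' `.tsv` paths get the tidy long format (columns: experiment, group,
#' cell_type, metric, value, flag).
#'
#' @param report an [EvaluationReport-class], [SpilloverReport-class] or
#'   plain list.
#' @param path output file ending in `.json` or `.tsv`.
#' @param experiment optional experiment name for the tidy format.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, experiment = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    if (!methods::is(report, "EvaluationReport")) {
      stop("tidy TSV output is defined for EvaluationReport objects",
           call. = FALSE)
    }
    utils::write.table(.tidyReport(report, experiment), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (methods::is(report, "EvaluationReport")) {
    list(global_pearson = report@globalPearson,
         global_pearson_undefined = report@globalUndefined,
         per_type = perTypeMetrics(report),
         per_sample_rmse = as.list(sampleRMSE(report)),
         n_samples = report@nSamples, n_types = report@nTypes)
  } else if (methods::is(report, "SpilloverReport")) {
    list(spill_matrix_pct = as.data.frame(report@spillMatrix),
         correct_pct = as.list(report@correctPct),
         total_spillover_pct = report@totalSpilloverPct)
  } else {
    report
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
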