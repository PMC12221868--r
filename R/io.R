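#' Readers and writers for the exchange formats
#'
#' Matrices travel as TSV with the first header cell fixed to `"id"`, the
#' first column holding gene or cell-type identifiers, and the remaining
#' header cells the sample / cell-type ids. Values are serialized with 17
#' significant digits so doubles round-trip losslessly and integer counts
#' are bit-exact. Single-cell datasets use a Matrix Market triplet
#' (`matrix.mtx`, genes x cells) with `genes.tsv`, `barcodes.tsv`, and a
#' two-column `cell_types.tsv` (cell_id, label) sidecar. TSV is canonical
#' (no decimal-comma hazards); comma-separated files are accepted on read
#' via delimiter sniffing.
#'
#' @name io
NULL

.write_tsv_matrix <- function(values, path) {
  header <- paste(c("id", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i],
            sprintf("%.17g", values[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
}

.read_delim_matrix <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  split <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(split)
  if (length(unique(widths)) != 1)
    stop(sprintf("%s: ragged rows (line %d has %d fields, expected %d)",
                 path, which(widths != widths[1])[1],
                 widths[widths != widths[1]][1], widths[1]))
  header <- split[[1]]
  ids <- vapply(split[-1], `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("%s: duplicate id '%s' at line %d", path, dup[1],
                 1 + which(ids == dup[1])[2]))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(header) - 1,
                 dimnames = list(ids, header[-1]))
  for (i in seq_along(ids)) {
    v <- suppressWarnings(as.numeric(split[[i + 1]][-1]))
    if (anyNA(v))
      stop(sprintf("%s: non-numeric value at line %d", path, i + 1))
    vals[i, ] <- v
  }
  vals
}

#' @rdname io
#' @param x object to write.
#' @param path file path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  .write_tsv_matrix(x$values, path)
  invisible(path)
}

#' @rdname io
#' @param space value-space tag to attach on read.
#' @export
read_expression_matrix <- function(path, space = "counts") {
  expression_matrix(.read_delim_matrix(path, "expression"), space = space)
}

#' @rdname io
#' @export
write_reference_profile <- function(x, path) {
  stopifnot(inherits(x, "reference_profile"))
  .write_tsv_matrix(x$values, path)
  invisible(path)
}

#' @rdname io
#' @export
read_reference_profile <- function(path) {
  reference_profile(.read_delim_matrix(path, "reference"))
}

#' @rdname io
#' @param strict simplex validation mode (see [proportion_matrix()]).
#' @export
write_proportion_matrix <- function(x, path) {
  stopifnot(inherits(x, "proportion_matrix"))
  .write_tsv_matrix(x$values, path)
  invisible(path)
}

#' @rdname io
#' @export
read_proportion_matrix <- function(path, strict = TRUE) {
  proportion_matrix(.read_delim_matrix(path, "proportions"), strict = strict)
}

#' @rdname io
#' @param dir directory holding / receiving the MTX triplet.
#' @export
write_single_cell_dataset <- function(x, dir) {
  stopifnot(inherits(x, "single_cell_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(paste(colnames(x$counts), x$cell_types, sep = "\t"),
             file.path(dir, "cell_types.tsv"))
  invisible(dir)
}

#' @rdname io
#' @export
read_single_cell_dataset <- function(dir) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cell_types.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing single-cell sidecar file(s): ",
         paste(missing, collapse = ", "))
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  ct_raw <- strsplit(readLines(file.path(dir, "cell_types.tsv")), "\t",
                     fixed = TRUE)
  ct_map <- stats::setNames(vapply(ct_raw, `[`, character(1), 2),
                            vapply(ct_raw, `[`, character(1), 1))
  if (!all(cells %in% names(ct_map)))
    stop("cell_types.tsv does not label every barcode")
  single_cell_dataset(counts, gene_ids = genes, cell_ids = cells,
                      cell_types = unname(ct_map[cells]))
}

#' @rdname io
#' @export
write_results_table <- function(x, path) {
  stopifnot(inherits(x, "results_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  do.call(results_table, df)
}

#' Write a provenance sidecar
#'
#' Records the configuration, seeds, package version, and SHA-256
#' fingerprints of the input files next to every pipeline output, so runs
#' can be audited and reproduced.
#'
#' @param path output JSON path.
#' @param config named list of run parameters.
#' @param inputs character vector of input file paths to fingerprint.
#' @return the path, invisibly.
#' @export
write_provenance <- function(path, config = list(), inputs = character()) {
  checksums <- vapply(inputs, function(f) {
    if (!file.exists(f)) return(NA_character_)
    as.character(tools::md5sum(f))  # see note below
  }, character(1))
  # R ships md5 only; prefer the system sha256sum when available
  sha <- vapply(inputs, function(f) {
    if (!file.exists(f)) return(NA_character_)
    out <- tryCatch(system2("sha256sum", f, stdout = TRUE),
                    error = function(e) NA_character_)
    if (length(out)) strsplit(out[1], " ")[[1]][1] else NA_character_
  }, character(1))
  prov <- list(package = "deconbench",
               version = as.character(utils::packageVersion("deconbench")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config,
               inputs = lapply(seq_along(inputs), function(i)
                 list(path = inputs[i], sha256 = sha[i], md5 = checksums[i])))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
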