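# Readers/writers for the interchange formats: delimited cell/spot/point
# tables, Matrix Market counts with index files, AIRR Rearrangement TSV,
# and JSON/GMT gene sets. Delimited text is UTF-8 with mandatory headers;
# comma-separated by default with a tab option.

readDelim <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = sep, header = TRUE))
}

writeDelim <- function(df, path, sep = ",") {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read / write a cell metadata table
#'
#' Requires columns `cell_id`, `sample_id`, `tls_status`, `subcluster`;
#' `lineage` and embedding columns are carried through when present. TLS
#' status labels are validated against `allowedStatuses`.
#'
#' @param path delimited text file.
#' @param sep field separator ("," default, "\t" optional).
#' @param allowedStatuses permitted status labels; default nTLS, imTLS,
#'   mTLS.
#' @return data.frame cell table.
#' @export
readCellTable <- function(path, sep = ",", allowedStatuses = tlsStatuses()) {
  df <- readDelim(path, sep)
  assertColumns(df, c("cell_id", "sample_id", "tls_status", "subcluster"),
                basename(path))
  bad <- setdiff(unique(df$tls_status), allowedStatuses)
  if (length(bad))
    stop("unknown TLS status label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowedStatuses, collapse = ", "))
  df
}

#' @rdname readCellTable
#' @param cells cell table to write.
#' @export
writeCellTable <- function(cells, path, sep = ",") {
  writeDelim(as.data.frame(cells), path, sep)
}

#' Read / write a sparse count matrix as Matrix Market plus index files
#'
#' The directory holds `matrix.mtx` (cells x genes), `barcodes.tsv` (cell
#' ids, one per line) and `genes.tsv` (gene symbols).
#'
#' @param dir directory containing/receiving the three files.
#' @return for the reader, a [Matrix::dgCMatrix-class] with dimnames.
#' @export
readCounts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("file not found: ", mtx)
  header <- readLines(mtx, n = 1L)
  if (!startsWith(header, "%%MatrixMarket"))
    stop("malformed MTX header at line 1 of ", mtx)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  gn <- readLines(file.path(dir, "genes.tsv"))
  if (length(bc) != nrow(m) || length(gn) != ncol(m))
    stop("index files do not match matrix dimensions")
  dimnames(m) <- list(bc, gn)
  m
}

#' @rdname readCounts
#' @param counts cells x genes matrix.
#' @export
writeCounts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read / write receptor chains in AIRR Rearrangement TSV
#'
#' Standard AIRR column names are used on disk (`cell_id`, `locus`,
#' `junction`, `junction_aa`, `v_call`, `j_call`, `junction_length`) and
#' mapped to the package's internal names (`cdr3_nt`, `cdr3_aa`,
#' `v_gene`, `j_gene`).
#'
#' @param path AIRR TSV file.
#' @return data.frame receptor table.
#' @export
readAirr <- function(path) {
  df <- readDelim(path, sep = "\t")
  assertColumns(df, c("cell_id", "locus", "junction", "v_call", "j_call"),
                basename(path))
  out <- data.frame(cell_id = df$cell_id, locus = df$locus,
                    cdr3_nt = df$junction,
                    cdr3_aa = if ("junction_aa" %in% names(df))
                      df$junction_aa else NA_character_,
                    v_gene = df$v_call, j_gene = df$j_call,
                    stringsAsFactors = FALSE)
  out$junction_length <- if ("junction_length" %in% names(df))
    as.integer(df$junction_length) else nchar(out$cdr3_nt)
  bad <- !is.na(out$cdr3_nt) & out$junction_length != nchar(out$cdr3_nt)
  if (any(bad))
    stop("junction_length disagrees with junction for ", sum(bad),
         " record(s)")
  out
}

#' @rdname readAirr
#' @param chains receptor table to write.
#' @export
writeAirr <- function(chains, path) {
  assertColumns(chains, c("cell_id", "locus", "cdr3_nt", "v_gene",
                          "j_gene"), "chains")
  df <- data.frame(cell_id = chains$cell_id, locus = chains$locus,
                   junction = chains$cdr3_nt,
                   junction_aa = chains$cdr3_aa %||% NA_character_,
                   v_call = chains$v_gene, j_call = chains$j_gene,
                   junction_length = nchar(chains$cdr3_nt),
                   stringsAsFactors = FALSE)
  writeDelim(df, path, sep = "\t")
}

#' Map a 10x-style filtered_contig table to the receptor-table layout
#'
#' @param path CSV with at least `barcode`, `chain`, `cdr3_nt`, `v_gene`,
#'   `j_gene` columns.
#' @return data.frame receptor table.
#' @export
readTenxContigs <- function(path) {
  df <- readDelim(path, sep = ",")
  assertColumns(df, c("barcode", "chain", "cdr3_nt", "v_gene", "j_gene"),
                basename(path))
  data.frame(cell_id = df$barcode, locus = df$chain, cdr3_nt = df$cdr3_nt,
             cdr3_aa = if ("cdr3" %in% names(df)) df$cdr3 else
               NA_character_,
             v_gene = df$v_gene, j_gene = df$j_gene,
             junction_length = nchar(df$cdr3_nt), stringsAsFactors = FALSE)
}

#' Read / write a spot x cell-type abundance table
#'
#' First column `spot_id`; remaining columns one per cell type (optional
#' `x`, `y` spot coordinates are carried as an attribute).
#'
#' @param path delimited file.
#' @param sep field separator.
#' @return numeric matrix, rows = spots, columns = cell types.
#' @export
readSpots <- function(path, sep = ",") {
  df <- readDelim(path, sep)
  assertColumns(df, "spot_id", basename(path))
  coords <- intersect(c("x", "y"), names(df))
  types <- setdiff(names(df), c("spot_id", coords))
  if (!length(types)) stop("no cell-type columns in ", basename(path))
  m <- as.matrix(df[, types, drop = FALSE])
  rownames(m) <- df$spot_id
  if (length(coords) == 2L)
    attr(m, "coords") <- as.matrix(df[, coords])
  if (any(m < 0)) stop("negative abundances in ", basename(path))
  m
}

#' @rdname readSpots
#' @param abund abundance matrix to write.
#' @export
writeSpots <- function(abund, path, sep = ",") {
  df <- data.frame(spot_id = rownames(abund) %||%
                     sprintf("spot%04d", seq_len(nrow(abund))),
                   as.data.frame(as.matrix(abund)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeDelim(df, path, sep)
}

#' Read / write phenotype-labelled imaging point tables
#'
#' Columns: `core_id`, `tls_status`, `cell_id`, `x`, `y`, `phenotype`
#' (inForm-style per-cell exports map onto this after column renaming).
#'
#' @param path delimited file.
#' @param sep field separator.
#' @param allowedStatuses permitted TLS status labels.
#' @return data.frame point table.
#' @export
readPoints <- function(path, sep = ",", allowedStatuses = tlsStatuses()) {
  df <- readDelim(path, sep)
  assertColumns(df, c("core_id", "tls_status", "x", "y", "phenotype"),
                basename(path))
  bad <- setdiff(unique(df$tls_status), allowedStatuses)
  if (length(bad))
    stop("unknown TLS status label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowedStatuses, collapse = ", "))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("non-finite coordinates in ", basename(path))
  df
}

#' @rdname readPoints
#' @param points point table to write.
#' @export
writePoints <- function(points, path, sep = ",") {
  writeDelim(points, path, sep)
}

#' Read / write gene-set collections (JSON and GMT)
#'
#' @param path file path; JSON maps set names to gene arrays, GMT is the
#'   usual tab-separated name/description/genes layout.
#' @return named list of [geneSet()] objects.
#' @export
readGeneSetsJson <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(lapply(names(lst), function(n) geneSet(n, lst[[n]])),
                  names(lst))
}

#' @rdname readGeneSetsJson
#' @param sets named list of gene sets to write.
#' @export
writeGeneSetsJson <- function(sets, path) {
  jsonlite::write_json(lapply(sets, `[[`, "genes"), path)
  invisible(path)
}

#' @rdname readGeneSetsJson
#' @export
readGmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(f) geneSet(f[1], f[-(1:2)]))
  stats::setNames(sets, vapply(lines, `[[`, character(1), 1L))
}

#' Write a JSON sidecar of ground-truth simulation parameters
#'
#' @param truth list of planted parameters (specs, labels).
#' @param path output JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
  clean <- rapply(truth, unclass, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
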