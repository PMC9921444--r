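#' Read a GCT (#1.2) expression matrix
#'
#' Parses the tab-delimited GCT dialect used for bulk TPM distributions:
#' line 1 is the version tag `#1.2`, line 2 declares `<n_genes>\t<n_samples>`,
#' line 3 is the header (`Name`, `Description`, then sample ids), followed by
#' one row per gene. Only version `#1.2` is accepted.
#'
#' @param path path to a GCT file (plain text).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `"tpm"`
#'   (genes x samples, non-negative), rownames = gene ids, colnames = sample
#'   ids, and the `Description` column in `rowData`.
#' @export
readGCT <- function(path) {
  stopIfNot(file.exists(path), sprintf("GCT file not found: %s", path))
  lines <- readLines(path)
  stopIfNot(length(lines) >= 3L, "GCT file truncated")
  if (!identical(trimws(lines[1L]), "#1.2"))
    stop("GCT format error: expected version tag '#1.2', got '",
         lines[1L], "'", call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || any(is.na(dims[1:2])))
    stop("GCT format error: malformed dimension line", call. = FALSE)
  nGenes <- dims[1L]; nSamples <- dims[2L]
  header <- strsplit(lines[3L], "\t")[[1L]]
  stopIfNot(length(header) == nSamples + 2L,
            "GCT integrity error: header width disagrees with declared samples")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != nGenes)
    stop(sprintf(
      "GCT integrity error: declared %d genes but body has %d rows",
      nGenes, length(body)), call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(parts)
  stopIfNot(all(widths == nSamples + 2L),
            "GCT integrity error: ragged data rows")
  flat <- unlist(parts, use.names = FALSE)
  m <- matrix(flat, nrow = nGenes, byrow = TRUE)
  geneIds <- m[, 1L]
  descr <- m[, 2L]
  vals <- suppressWarnings(matrix(as.numeric(m[, -(1:2), drop = FALSE]),
                                  nrow = nGenes))
  if (anyNA(vals))
    stop("GCT parse error: non-numeric expression value", call. = FALSE)
  if (any(vals < 0))
    stop("GCT integrity error: negative expression values", call. = FALSE)
  if (anyDuplicated(geneIds))
    stop("GCT integrity error: duplicate gene ids", call. = FALSE)
  sampleIds <- header[-(1:2)]
  if (anyDuplicated(sampleIds))
    stop("GCT integrity error: duplicate sample ids", call. = FALSE)
  dimnames(vals) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = vals),
    rowData = S4Vectors::DataFrame(Description = descr, row.names = geneIds))
  stageLog("read_gct", genes = nGenes, samples = nSamples)
  se
}

#' Write a GCT (#1.2) expression matrix
#'
#' @param se a `SummarizedExperiment` (first assay written) or a plain
#'   genes x samples matrix with dimnames.
#' @param path output path.
#' @param digits significant digits for values (default 7; round trips to at
#'   least 6 significant digits).
#' @return invisibly, `path`.
#' @export
writeGCT <- function(se, path, digits = 7L) {
  if (methods::is(se, "SummarizedExperiment")) {
    vals <- SummarizedExperiment::assay(se, 1L)
    descr <- if ("Description" %in%
                 names(SummarizedExperiment::rowData(se)))
      as.character(SummarizedExperiment::rowData(se)$Description)
    else rownames(vals)
  } else {
    vals <- as.matrix(se)
    descr <- rownames(vals)
  }
  stopIfNot(!is.null(rownames(vals)) && !is.null(colnames(vals)),
            "matrix must carry gene and sample ids as dimnames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(vals), ncol(vals), sep = "\t"), con)
  writeLines(paste(c("Name", "Description", colnames(vals)),
                   collapse = "\t"), con)
  fmt <- apply(vals, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(vals), descr, fmt, sep = "\t"), con)
  invisible(path)
}

#' Read a rectangular numeric CSV matrix
#'
#' Reads a CSV with a header row and an id column into a numeric matrix.
#' `orientation` states what the file's rows are; the returned matrix is
#' normalized to genes x samples (`"genes"`) or samples x features
#' (`"samples"`), i.e. rows as given in the file.
#'
#' @param path CSV path.
#' @param orientation `"genes"` (rows are genes, columns samples) or
#'   `"samples"` (rows are samples, columns features).
#' @return numeric matrix with dimnames; attribute `orientation` records the
#'   convention.
#' @export
readCSVMatrix <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  stopIfNot(file.exists(path), sprintf("CSV file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  stopIfNot(ncol(df) >= 2L, "CSV must have an id column and data columns")
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "CSV parse error: non-numeric value '%s' at row '%s', column '%s'",
      raw[bad[1L], bad[2L]], ids[bad[1L]], colnames(raw)[bad[2L]]),
      call. = FALSE)
  }
  structure(vals, orientation = orientation)
}

#' Write a numeric matrix as CSV
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param idName header of the id column.
#' @return invisibly, `path`.
#' @export
writeCSVMatrix <- function(mat, path, idName = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1L] <- idName
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
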