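## Plain-text interchange formats: cell-track CSV (cell_id, parent_id,
## time_h, area_um2, fluor_au with -1 as the missing-fluorescence sentinel;
## parent_id -1 marks progenitors), TSV count matrices (gene_id then
## t_<hours> columns) and per-gene TSV tables.

#' Read / write cell-track tables
#'
#' The CSV schema is \code{cell_id, parent_id, time_h, area_um2, fluor_au};
#' \code{parent_id = -1} marks progenitor cells and \code{fluor_au = -1}
#' marks absent fluorescence. Any segmentation/tracking tool's output can
#' be adapted to this schema.
#'
#' @param path file path.
#' @return [readCellTracks()]: a \linkS4class{LineageTree}.
#' @export
readCellTracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "parent_id", "time_h", "area_um2")
  if (!all(need %in% names(tr))) {
    stop("cell-track CSV needs columns: ", paste(need, collapse = ", "))
  }
  tr$parent_id[tr$parent_id < 0] <- NA_integer_
  if ("fluor_au" %in% names(tr) && all(tr$fluor_au < 0)) {
    tr$fluor_au <- NULL
  }
  tr <- tr[order(tr$cell_id, tr$time_h), ]
  rownames(tr) <- NULL
  prog <- unique(tr$cell_id[is.na(tr$parent_id)])
  new("LineageTree",
    tracks = tr, progenitorIds = as.integer(prog),
    metadata = list(source = path)
  )
}

#' @rdname readCellTracks
#' @param tree a \linkS4class{LineageTree}.
#' @export
writeCellTracks <- function(tree, path) {
  tr <- cellTracks(tree)
  out <- data.frame(
    cell_id = tr$cell_id,
    parent_id = ifelse(is.na(tr$parent_id), -1L, tr$parent_id),
    time_h = tr$time_h, area_um2 = tr$area_um2,
    fluor_au = if ("fluor_au" %in% names(tr)) tr$fluor_au else -1
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write TFNseq count matrices
#'
#' TSV with a \code{gene_id} first column and one \code{t_<hours>} column
#' per fraction.
#'
#' @param path file path.
#' @return [readCountMatrix()]: a \linkS4class{TfnseqExperiment}.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  tcols <- grep("^t_", names(df), value = TRUE)
  if (!length(tcols)) stop("no t_<hours> columns found")
  times <- as.numeric(sub("^t_", "", tcols))
  m <- as.matrix(df[, tcols, drop = FALSE])
  rownames(m) <- df$gene_id
  TfnseqExperiment(m, times, metadata = list(source = path))
}

#' @rdname readCountMatrix
#' @param x a \linkS4class{TfnseqExperiment}.
#' @export
writeCountMatrix <- function(x, path) {
  m <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  names(df) <- c("gene_id", paste0("t_", fractionTimes(x)))
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a per-gene TSV table
#'
#' @param x \code{data.frame}.
#' @param path file path.
#' @export
writeGeneTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
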