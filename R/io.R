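#' @title Readers and writers for the pipeline's file formats
#' @description Plain-text formats only: BED intervals (0-based
#'   half-open), tab-separated matrices and design sheets, the
#'   alignment-block TSV, a simple motif matrix format, FASTA (via
#'   Biostrings), and JSON truth-table sidecars. Every writer's output
#'   round-trips through the corresponding reader without loss.
#' @name io
NULL

#' Read / write BED interval files
#'
#' BED with at least 3 columns; columns 4-6 map to \code{name},
#' \code{score}, \code{strand} and any further columns are kept as
#' \code{extra1}, \code{extra2}, ...
#'
#' @param path file path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optional extra columns.
#' @export
readBed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n <- ncol(x)
  names(x) <- c(std[seq_len(min(n, 6))],
                if (n > 6) paste0("extra", seq_len(n - 6)))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  .validate_intervals(x, paste("BED file", basename(path)))
  x
}

#' @rdname readBed
#' @param x interval data.frame (chrom/start/end first; any further
#'   columns are written in order).
#' @export
writeBed <- function(x, path) {
  .validate_intervals(x, "BED output")
  first <- c("chrom", "start", "end")
  x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the alignment-block map TSV
#'
#' Tab-separated with a header naming the eight block columns.
#'
#' @param path file path.
#' @return an \code{\linkS4class{AlignmentBlockMap}}.
#' @export
readBlockMap <- function(path) {
  AlignmentBlockMap(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' @rdname readBlockMap
#' @param map an \code{AlignmentBlockMap}.
#' @export
writeBlockMap <- function(map, path) {
  utils::write.table(alignmentBlocks(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write motif matrix files
#'
#' One or more motifs per file. Each motif starts with a header line
#' \code{"> consensus <TAB> name <TAB> threshold"} followed by one row of
#' four tab-separated probabilities (A C G T) per motif position.
#'
#' @param path file path.
#' @return list of \code{\linkS4class{PWMotif}} objects.
#' @export
readMotifFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\t")[[1]]
    if (length(hdr) < 3L)
      stop("motif header needs consensus, name, threshold: ",
           lines[starts[i]])
    rows <- lines[(starts[i] + 1L):ends[i]]
    probs <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
    out[[i]] <- PWMotif(hdr[2], probs, as.numeric(hdr[3]))
  }
  stats::setNames(out, vapply(out, motifName, ""))
}

#' @rdname readMotifFile
#' @param pwms list of \code{PWMotif} objects (or a single one).
#' @export
writeMotifFile <- function(pwms, path) {
  if (methods::is(pwms, "PWMotif")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf("> %s\t%s\t%.10g", consensusSeq(p), motifName(p),
                       detectionThreshold(p)), con)
    utils::write.table(motifProbs(p), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a numeric TSV matrix
#'
#' Tab-separated with a header row of sample names and row names in the
#' first column.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readTsvMatrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(x)
}

#' @rdname readTsvMatrix
#' @param mat matrix with dimnames.
#' @export
writeTsvMatrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a generic TSV table (header, no row names)
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readTsv
#' @param x data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' @param path file path.
#' @return a \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname readFasta
#' @param seqs a \code{DNAStringSet} (or named character vector).
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
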