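#' @title Genomic interval helpers (BED convention)
#' @description All interval tables in this package use 0-based half-open
#'   coordinates, i.e. the BED convention: a peak \code{[start, end)}
#'   covers \code{end - start} bases. These helpers convert to and from
#'   the 1-based closed \code{GRanges}/\code{IRanges} representation used
#'   for overlap arithmetic.
#' @name intervals
NULL

#' @importFrom GenomicRanges GRanges seqnames findOverlaps pintersect reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom BiocGenerics width
NULL

.validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " table needs columns chrom, start, end")
  if (nrow(x) && (any(x$start < 0) || any(x$start >= x$end)))
    stop(what, " table has invalid coordinates (need 0 <= start < end)")
  invisible(x)
}

#' Convert a BED-convention interval table to GRanges
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and optionally \code{strand}.
#' @return A \code{GRanges} (1-based closed).
#' @export
bedToGRanges <- function(x) {
  .validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
}

#' Base-pair overlap of each query interval with the union of a subject set
#'
#' For every query interval, the number of its bases covered by the
#' reduced (unioned) subject intervals. Used for the coverage-based
#' conservation stringencies and TE containment. Interval arithmetic runs
#' on \code{IRanges} per chromosome (cheaper than full \code{GRanges}
#' objects in the tight per-peak loops of the simulation studies).
#'
#' @param query,subject interval data.frames (BED convention).
#' @return Integer vector of covered base counts, one per query row.
#' @export
overlapCoverage <- function(query, subject) {
  if (nrow(query) == 0L) return(integer(0))
  cov <- integer(nrow(query))
  if (nrow(subject) == 0L) return(cov)
  .validate_intervals(query, "query")
  .validate_intervals(subject, "subject")
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    q <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    s <- IRanges::reduce(IRanges::IRanges(subject$start[si] + 1L,
                                          subject$end[si]))
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- pmin(BiocGenerics::end(q)[qh], BiocGenerics::end(s)[sh]) -
      pmax(BiocGenerics::start(q)[qh], BiocGenerics::start(s)[sh]) + 1L
    agg <- rowsum(w, qh)
    cov[qi[as.integer(rownames(agg))]] <- as.integer(agg)
  }
  cov
}

#' Does each query interval overlap any subject interval?
#'
#' @inheritParams overlapCoverage
#' @return Logical vector, one per query row.
#' @export
overlapsAny <- function(query, subject) {
  overlapCoverage(query, subject) > 0L
}

#' Project intervals across species through an alignment block map
#'
#' Converts coordinates between the focal genome and another species using
#' the colinear gapless blocks of an \code{\linkS4class{AlignmentBlockMap}}.
#' Each query interval is intersected with every block of the species; the
#' overlapping piece is carried across by offset arithmetic (reversed for
#' minus-strand blocks). Projected fragments that are adjacent on the
#' target (gap 0, same chromosome and strand) are merged, so a \code{split}
#' projection means the interval genuinely lands in two or more disjoint
#' locations. Intervals outside all blocks project to nothing (zero rows,
#' not an error).
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}
#'   (BED convention) in the source coordinate system.
#' @param map an \code{\linkS4class{AlignmentBlockMap}}.
#' @param species the non-focal species to project to or from.
#' @param direction \code{"focal_to_target"} (default) or
#'   \code{"target_to_focal"}.
#' @return data.frame with columns \code{query} (row index into
#'   \code{intervals}), \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (the block strand the fragment passed through).
#' @export
projectIntervals <- function(intervals, map, species,
                             direction = c("focal_to_target",
                                           "target_to_focal")) {
  direction <- match.arg(direction)
  .validate_intervals(intervals)
  b <- alignmentBlocks(map)
  b <- b[b$species == species, , drop = FALSE]
  empty <- data.frame(query = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  if (nrow(intervals) == 0L || nrow(b) == 0L) return(empty)

  if (direction == "focal_to_target") {
    src <- data.frame(chrom = b$focal_chrom, start = b$focal_start,
                      end = b$focal_end)
    dst <- data.frame(chrom = b$target_chrom, start = b$target_start,
                      end = b$target_end)
  } else {
    src <- data.frame(chrom = b$target_chrom, start = b$target_start,
                      end = b$target_end)
    dst <- data.frame(chrom = b$focal_chrom, start = b$focal_start,
                      end = b$focal_end)
  }
  qi <- si <- integer(0)
  for (ch in intersect(unique(intervals$chrom), unique(src$chrom))) {
    qw <- which(intervals$chrom == ch)
    sw <- which(src$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(intervals$start[qw] + 1L, intervals$end[qw]),
      IRanges::IRanges(src$start[sw] + 1L, src$end[sw]))
    qi <- c(qi, qw[S4Vectors::queryHits(ov)])
    si <- c(si, sw[S4Vectors::subjectHits(ov)])
  }
  if (!length(qi)) return(empty)
  os <- pmax(intervals$start[qi], src$start[si])
  oe <- pmin(intervals$end[qi], src$end[si])
  plus <- b$strand[si] == "+"
  # offset arithmetic; minus-strand blocks reverse within-block position
  new_start <- ifelse(plus, dst$start[si] + (os - src$start[si]),
                            dst$start[si] + (src$end[si] - oe))
  new_end <- ifelse(plus, dst$start[si] + (oe - src$start[si]),
                          dst$start[si] + (src$end[si] - os))
  out <- data.frame(query = qi, chrom = dst$chrom[si],
                    start = as.integer(new_start),
                    end = as.integer(new_end),
                    strand = b$strand[si])
  out <- out[order(out$query, out$chrom, out$start), , drop = FALSE]
  .merge_adjacent(out)
}

# merge fragments of the same query that are adjacent (gap 0) on the
# target, same chromosome and strand
.merge_adjacent <- function(out) {
  if (nrow(out) < 2L) { rownames(out) <- NULL; return(out) }
  keep <- logical(nrow(out))
  keep[1] <- TRUE
  j <- 1L
  for (i in 2:nrow(out)) {
    if (out$query[i] == out$query[j] && out$chrom[i] == out$chrom[j] &&
        out$strand[i] == out$strand[j] && out$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], out$end[i])
    } else {
      keep[i] <- TRUE
      j <- i
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a single interval
#'
#' Convenience wrapper around \code{\link{projectIntervals}} for one
#' interval; also reports whether the projection is split across two or
#' more disjoint target locations.
#'
#' @param chrom,start,end the interval (BED convention).
#' @inheritParams projectIntervals
#' @return A list with \code{fragments} (data.frame) and \code{split}
#'   (logical).
#' @export
projectInterval <- function(chrom, start, end, map, species,
                            direction = "focal_to_target") {
  fr <- projectIntervals(
    data.frame(chrom = chrom, start = start, end = end),
    map, species, direction)
  fr$query <- NULL
  list(fragments = fr, split = nrow(fr) >= 2L)
}
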