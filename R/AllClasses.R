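#' @import methods
#' @importFrom stats median quantile rbinom rnorm runif setNames var
NULL

DNA_BASES <- c("A", "C", "G", "T")

# probability floor applied per matrix cell before taking logs, so that a
# zero probability yields a large negative (not infinite) log-odds score
PWM_PROB_FLOOR <- 0.001

#' PWMotif: a position weight matrix with a detection threshold
#'
#' S4 container for a transcription-factor binding motif: a per-position
#' base-probability matrix (rows are positions, columns A/C/G/T, each row
#' summing to 1) together with the log-odds detection threshold above which
#' a scanned site is considered bound. The background model is uniform
#' (0.25 per base), matching the scoring convention of standard motif
#' scanners.
#'
#' @slot name motif name.
#' @slot probs numeric matrix, length-by-4, rows summing to 1.
#' @slot threshold log-odds detection threshold (natural log).
#' @export
setClass("PWMotif",
         representation(name = "character", probs = "matrix",
                        threshold = "numeric"))

setValidity("PWMotif", function(object) {
  p <- object@probs
  if (ncol(p) != 4L) return("probability matrix must have 4 columns (ACGT)")
  if (!identical(colnames(p), DNA_BASES))
    return("probability matrix columns must be named A, C, G, T")
  if (any(p < 0)) return("negative probabilities")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    return("each probability row must sum to 1 (tolerance 1e-6)")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("threshold must be a single finite number")
  if (object@threshold > maxScore(object) + 1e-9)
    return("threshold exceeds the maximum achievable score")
  TRUE
})

#' Construct a PWMotif
#'
#' @param name motif name.
#' @param probs length-by-4 probability matrix; columns in A, C, G, T order
#'   (named or unnamed).
#' @param threshold log-odds detection threshold (natural log, uniform
#'   background).
#' @return A \code{\linkS4class{PWMotif}}.
#' @export
PWMotif <- function(name, probs, threshold) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES
  new("PWMotif", name = name, probs = probs, threshold = threshold)
}

#' @describeIn PWMotif-class motif length (number of positions)
#' @param x a PWMotif.
#' @export
setMethod("length", "PWMotif", function(x) nrow(x@probs))

#' Accessors for PWMotif
#'
#' \code{motifName}, \code{detectionThreshold}, \code{motifProbs},
#' \code{consensusSeq} and \code{maxScore} read the motif name, its
#' log-odds threshold, the probability matrix, the argmax consensus string
#' and the score of the consensus under the floored log-odds model.
#'
#' @param object a \code{\linkS4class{PWMotif}}.
#' @name PWMotif-accessors
NULL

#' @rdname PWMotif-accessors
#' @export
setGeneric("motifName", function(object) standardGeneric("motifName"))
#' @rdname PWMotif-accessors
#' @export
setMethod("motifName", "PWMotif", function(object) object@name)

#' @rdname PWMotif-accessors
#' @export
setGeneric("detectionThreshold",
           function(object) standardGeneric("detectionThreshold"))
#' @rdname PWMotif-accessors
#' @export
setMethod("detectionThreshold", "PWMotif", function(object) object@threshold)

#' @rdname PWMotif-accessors
#' @export
setGeneric("motifProbs", function(object) standardGeneric("motifProbs"))
#' @rdname PWMotif-accessors
#' @export
setMethod("motifProbs", "PWMotif", function(object) object@probs)

#' @rdname PWMotif-accessors
#' @export
setGeneric("consensusSeq", function(object) standardGeneric("consensusSeq"))
#' @rdname PWMotif-accessors
#' @export
setMethod("consensusSeq", "PWMotif", function(object) {
  paste(DNA_BASES[max.col(object@probs, ties.method = "first")],
        collapse = "")
})

#' @rdname PWMotif-accessors
#' @export
setGeneric("maxScore", function(object) standardGeneric("maxScore"))
#' @rdname PWMotif-accessors
#' @export
setMethod("maxScore", "PWMotif", function(object) {
  sum(log(pmax(apply(object@probs, 1, max), PWM_PROB_FLOOR) / 0.25))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s': %d positions, consensus %s, threshold %.3f (max %.3f)\n",
              object@name, length(object), consensusSeq(object),
              object@threshold, maxScore(object)))
})

#' AlignmentBlockMap: colinear gapless alignment blocks
#'
#' S4 container for a focal-referenced multiple whole-genome alignment
#' flattened to gapless, equal-length colinear blocks. Each block maps a
#' focal-genome interval to an interval of equal length in one other
#' species, on the + or - strand. All coordinates are 0-based half-open
#' (BED convention). Blocks belonging to one species may not overlap on the
#' focal genome.
#'
#' @slot blocks data.frame with columns \code{focal_chrom},
#'   \code{focal_start}, \code{focal_end}, \code{species},
#'   \code{target_chrom}, \code{target_start}, \code{target_end},
#'   \code{strand}.
#' @export
setClass("AlignmentBlockMap", representation(blocks = "data.frame"))

.BLOCK_COLS <- c("focal_chrom", "focal_start", "focal_end", "species",
                 "target_chrom", "target_start", "target_end", "strand")

setValidity("AlignmentBlockMap", function(object) {
  b <- object@blocks
  if (!all(.BLOCK_COLS %in% names(b)))
    return(paste("blocks must have columns:",
                 paste(.BLOCK_COLS, collapse = ", ")))
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$focal_start < 0) || any(b$focal_start >= b$focal_end) ||
      any(b$target_start < 0) || any(b$target_start >= b$target_end))
    return("invalid block coordinates (need 0 <= start < end)")
  if (any((b$focal_end - b$focal_start) != (b$target_end - b$target_start)))
    return("focal and target block lengths must be equal")
  if (!all(b$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  for (sp in unique(b$species)) {
    bs <- b[b$species == sp, ]
    o <- order(bs$focal_chrom, bs$focal_start)
    bs <- bs[o, ]
    same <- bs$focal_chrom[-1] == bs$focal_chrom[-nrow(bs)]
    if (nrow(bs) > 1 && any(same & bs$focal_start[-1] < bs$focal_end[-nrow(bs)]))
      return(sprintf("blocks for species '%s' overlap on the focal genome", sp))
  }
  TRUE
})

#' Construct an AlignmentBlockMap
#'
#' @param blocks data.frame of blocks (see
#'   \code{\linkS4class{AlignmentBlockMap}} for the required columns).
#' @return An \code{AlignmentBlockMap}.
#' @export
AlignmentBlockMap <- function(blocks) {
  blocks <- as.data.frame(blocks)[, .BLOCK_COLS]
  blocks$focal_start <- as.integer(blocks$focal_start)
  blocks$focal_end <- as.integer(blocks$focal_end)
  blocks$target_start <- as.integer(blocks$target_start)
  blocks$target_end <- as.integer(blocks$target_end)
  new("AlignmentBlockMap", blocks = blocks)
}

#' @describeIn AlignmentBlockMap-class the block table
#' @param object an AlignmentBlockMap.
#' @export
setGeneric("alignmentBlocks",
           function(object) standardGeneric("alignmentBlocks"))
#' @rdname AlignmentBlockMap-class
#' @export
setMethod("alignmentBlocks", "AlignmentBlockMap",
          function(object) object@blocks)

#' @describeIn AlignmentBlockMap-class species present in the map
#' @export
setGeneric("mapSpecies", function(object) standardGeneric("mapSpecies"))
#' @rdname AlignmentBlockMap-class
#' @export
setMethod("mapSpecies", "AlignmentBlockMap",
          function(object) sort(unique(object@blocks$species)))

setMethod("show", "AlignmentBlockMap", function(object) {
  b <- object@blocks
  cat(sprintf("AlignmentBlockMap: %d blocks, %d species (%s)\n",
              nrow(b), length(unique(b$species)),
              paste(sort(unique(b$species)), collapse = ", ")))
})
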