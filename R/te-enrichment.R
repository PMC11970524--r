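#' @title Transposable-element family enrichment
#' @description Tests whether TE families are over- or under-represented
#'   in a target peak set (e.g. diapause-specific accessible chromatin)
#'   relative to one of three backgrounds: the genome-wide base-pair
#'   abundance of the family, all accessible chromatin, or size-matched
#'   control loci shifted 10 kb downstream of the targets. Enrichment is
#'   assessed with exact binomial tests on the per-region containment
#'   rate, BH-adjusted across families.
#' @name te-enrichment
NULL

#' Size-matched control loci
#'
#' Shifts every peak \code{offset} bp downstream (increasing coordinates;
#' peaks are unstranded) on its own chromosome. Loci that would run past
#' the chromosome end are dropped with a warning; the output is
#' size-matched to the retained inputs by construction.
#'
#' @param peaks interval data.frame.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param offset shift in bp (default 10000; negative shifts upstream).
#' @return interval data.frame of control loci.
#' @export
makeControlLoci <- function(peaks, chrom_sizes, offset = 10000L) {
  .validate_intervals(peaks, "peak")
  out <- data.frame(chrom = peaks$chrom,
                    start = peaks$start + offset,
                    end = peaks$end + offset)
  lim <- chrom_sizes[out$chrom]
  keep <- !is.na(lim) & out$end <= lim & out$start >= 0L
  if (any(!keep))
    warning(sum(!keep), " control locus/loci beyond chromosome bounds dropped")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family containment rate
#'
#' Fraction of intervals overlapping (>= 1 bp) at least one TE of the
#' family. This region-level rate is what the binomial enrichment test
#' uses for interval backgrounds.
#'
#' @param intervals non-empty interval data.frame.
#' @param te TE annotation (interval data.frame with \code{family}).
#' @param family family label.
#' @return fraction in \[0, 1\].
#' @export
familyRate <- function(intervals, te, family) {
  if (!nrow(intervals)) stop("familyRate: empty interval set")
  fam <- te[te$family == family, , drop = FALSE]
  mean(overlapsAny(intervals, fam))
}

#' Genome-wide base-pair rate of a family
#'
#' Fraction of the genome covered by (reduced) intervals of the family;
#' the background rate used for the GENOME background.
#'
#' @param te TE annotation.
#' @param family family label.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return fraction in \[0, 1\].
#' @export
genomeFamilyRate <- function(te, family, chrom_sizes) {
  fam <- te[te$family == family, , drop = FALSE]
  if (!nrow(fam)) return(0)
  covered <- sum(BiocGenerics::width(
    GenomicRanges::reduce(bedToGRanges(fam), ignore.strand = TRUE)))
  covered / sum(as.numeric(chrom_sizes))
}

#' TE family enrichment against a background
#'
#' For each family, counts target regions containing the family and
#' compares against the background rate with two one-sided exact binomial
#' tests; the reported p-value is the smaller one-sided p doubled (capped
#' at 1) and the direction follows the fold. Background rates of exactly
#' 0 or 1 are floored into \code{[1/(10 n_bg), 1 - 1/(10 n_bg)]} so the
#' binomial stays defined; floored rows are flagged and should be left
#' out of headline summaries. BH adjustment is applied across families
#' within the background.
#'
#' @param targets target interval data.frame (non-empty).
#' @param background a list: \code{kind} in \code{"GENOME"},
#'   \code{"ALL_CHROMATIN"}, \code{"CONTROL_LOCI"}; \code{intervals}
#'   (interval data.frame, required for the two interval kinds);
#'   \code{chrom_sizes} (required for GENOME).
#' @param te TE annotation with \code{family} column.
#' @param families families to test (default: all in \code{te}).
#' @param alpha significance level for the \code{significant} flag on
#'   q-values (default 0.05).
#' @return data.frame: family, n_target_regions, k_with_family,
#'   expected_rate, fold, direction, p_value, q_value, floored,
#'   significant.
#' @export
teFamilyEnrichment <- function(targets, background, te,
                               families = sort(unique(te$family)),
                               alpha = 0.05) {
  if (!nrow(targets)) stop("teFamilyEnrichment: empty target set")
  kind <- match.arg(background$kind,
                    c("GENOME", "ALL_CHROMATIN", "CONTROL_LOCI"))
  n <- nrow(targets)
  if (kind == "GENOME") {
    if (is.null(background$chrom_sizes))
      stop("GENOME background needs chrom_sizes")
    n_bg <- n  # no background region count; floor on the target count
    p0_of <- function(fam) genomeFamilyRate(te, fam, background$chrom_sizes)
  } else {
    bg <- background$intervals
    if (is.null(bg) || !nrow(bg))
      stop(kind, " background needs non-empty intervals")
    n_bg <- nrow(bg)
    p0_of <- function(fam) familyRate(bg, te, fam)
  }
  floor_ <- 1 / (10 * n_bg)
  known <- families %in% te$family
  if (any(!known)) {
    warning("unknown TE families skipped: ",
            paste(families[!known], collapse = ", "))
    families <- families[known]
  }
  rows <- lapply(families, function(fam) {
    k <- sum(overlapsAny(targets, te[te$family == fam, , drop = FALSE]))
    p0 <- p0_of(fam)
    floored <- p0 <= 0 || p0 >= 1
    p0 <- min(max(p0, floor_), 1 - floor_)
    pg <- binomialTest(k, n, p0, "greater")$p_value
    pl <- binomialTest(k, n, p0, "less")$p_value
    fold <- (k / n) / p0
    data.frame(family = fam, n_target_regions = n, k_with_family = k,
               expected_rate = p0, fold = fold,
               direction = if (fold > 1) "ENRICHED" else "DEPLETED",
               p_value = min(1, 2 * min(pg, pl)), floored = floored,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)$adjusted
  out$significant <- out$q_value < alpha
  rownames(out) <- NULL
  out
}
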