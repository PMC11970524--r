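#' @title Cross-species chromatin-accessibility conservation
#' @description Projects ATAC-seq peaks between species through an
#'   alignment-block map, tags each focal peak as conserved per species at
#'   a chosen stringency, and assigns the evolutionary conservation
#'   category (ancient/very ancient, recent, very recent) for both
#'   chromatin accessibility and the underlying sequence. Also implements
#'   the diapause-specific differential-peak selection rule, nearest-gene
#'   assignment, and genomic-feature annotation.
#' @name peak-conservation
NULL

CONSERVATION_CATEGORIES <- c("ANCIENT_VERY_ANCIENT", "RECENT", "VERY_RECENT")
STRINGENCIES <- c("RELAXED", "STRICT", "VERY_STRICT")

#' Tag focal peaks as conserved per species
#'
#' A focal peak is conserved in a species when the union of that species'
#' peaks, projected onto the focal genome, covers the focal peak at the
#' requested stringency: RELAXED needs any overlap (>= 1 bp), STRICT needs
#' >= 25\% of the focal peak covered, VERY_STRICT >= 50\% (boundaries
#' inclusive).
#'
#' @param focal_peaks interval data.frame on the focal genome.
#' @param projected_peaks named list (species -> interval data.frame of
#'   that species' peaks already projected onto focal coordinates).
#' @param stringency \code{"RELAXED"} (default), \code{"STRICT"} or
#'   \code{"VERY_STRICT"}.
#' @return logical matrix, peaks x species.
#' @export
tagConserved <- function(focal_peaks, projected_peaks,
                         stringency = c("RELAXED", "STRICT", "VERY_STRICT")) {
  stringency <- match.arg(stringency)
  .validate_intervals(focal_peaks, "focal peak")
  need <- switch(stringency, RELAXED = 0, STRICT = 0.25, VERY_STRICT = 0.5)
  width <- focal_peaks$end - focal_peaks$start
  out <- vapply(projected_peaks, function(pp) {
    cov <- overlapCoverage(focal_peaks, pp)
    if (stringency == "RELAXED") cov >= 1L else cov >= need * width
  }, logical(nrow(focal_peaks)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(focal_peaks),
                  dimnames = list(NULL, names(projected_peaks)))
  out
}

#' Assign evolutionary conservation categories
#'
#' Category logic over per-species conserved flags for peaks of the focal
#' species: a peak present only in the focal species is VERY_RECENT;
#' present in the focal plus at least one other African killifish but no
#' outgroup is RECENT; present in the focal, at least one other African
#' killifish and at least one outgroup is ANCIENT_VERY_ANCIENT. Peaks
#' absent from all other African killifish yet present in an outgroup are
#' also placed in ANCIENT_VERY_ANCIENT (the accessibility was retained
#' across the deeper split even though the intermediate lineages lost it).
#'
#' @param flags logical matrix (peaks x species) of conserved flags,
#'   columns named by species; must include the focal species with all
#'   flags TRUE.
#' @param roles named character vector species -> role in
#'   \code{c("FOCAL", "AFRICAN_KILLIFISH", "OUTGROUP")}; exactly one
#'   FOCAL.
#' @return factor of categories, one per peak.
#' @export
classifyConservation <- function(flags, roles) {
  flags <- as.matrix(flags)
  focal <- names(roles)[roles == "FOCAL"]
  if (length(focal) != 1L)
    stop("classifyConservation: exactly one FOCAL species required")
  if (focal %in% colnames(flags) && !all(flags[, focal]))
    stop("classifyConservation: only focal peaks (focal flag TRUE) are classified")
  afr <- intersect(names(roles)[roles == "AFRICAN_KILLIFISH"],
                   colnames(flags))
  outg <- intersect(names(roles)[roles == "OUTGROUP"], colnames(flags))
  if (!length(afr) || !length(outg))
    stop("classifyConservation: need >= 1 African killifish and >= 1 outgroup")
  afr_any <- rowSums(flags[, afr, drop = FALSE]) > 0
  out_any <- rowSums(flags[, outg, drop = FALSE]) > 0
  cat <- ifelse(out_any, "ANCIENT_VERY_ANCIENT",
         ifelse(afr_any, "RECENT", "VERY_RECENT"))
  factor(cat, levels = CONSERVATION_CATEGORIES)
}

#' Sequence-level conservation categories
#'
#' Same category logic as \code{\link{classifyConservation}}, but
#' "conserved" means the focal peak has an aligned orthologous region in
#' the species: at least 1 bp of the peak lies inside an alignment block
#' for that species (RELAXED), or the blocks cover >= 25\%/50\% of the
#' peak at the stricter settings.
#'
#' @param focal_peaks interval data.frame on the focal genome.
#' @param map an \code{\linkS4class{AlignmentBlockMap}}.
#' @param roles named role vector (see \code{\link{classifyConservation}}).
#' @param stringency coverage stringency, as in \code{\link{tagConserved}}.
#' @return A list with \code{category} (factor per peak) and \code{flags}
#'   (logical matrix peaks x non-focal species).
#' @export
classifySequenceConservation <- function(focal_peaks, map, roles,
                                         stringency = "RELAXED") {
  b <- alignmentBlocks(map)
  species <- setdiff(names(roles), names(roles)[roles == "FOCAL"])
  aligned <- lapply(stats::setNames(species, species), function(sp) {
    bs <- b[b$species == sp, , drop = FALSE]
    data.frame(chrom = bs$focal_chrom, start = bs$focal_start,
               end = bs$focal_end)
  })
  flags <- tagConserved(focal_peaks, aligned, stringency)
  focal <- names(roles)[roles == "FOCAL"]
  full <- cbind(flags,
                matrix(TRUE, nrow(focal_peaks), 1,
                       dimnames = list(NULL, focal)))
  list(category = classifyConservation(full, roles), flags = flags)
}

#' End-to-end accessibility-conservation pipeline
#'
#' Projects every non-focal species' peaks onto the focal genome, tags
#' conservation at the chosen stringency and classifies categories. Also
#' reports which non-focal peaks project to two or more disjoint focal
#' locations (split peaks); split projections are retained in the
#' conservation call.
#'
#' @param focal_peaks interval data.frame of focal peaks (with optional
#'   \code{peak_id} column).
#' @param species_peaks named list (non-focal species -> interval
#'   data.frame in that species' own coordinates).
#' @param map an \code{\linkS4class{AlignmentBlockMap}}.
#' @param roles named role vector; exactly one FOCAL.
#' @param stringency conservation stringency.
#' @return A list with \code{calls} (data.frame: peak_id, category, one
#'   conserved flag column per species), \code{flags} (logical matrix) and
#'   \code{split} (named list of logical vectors per species: which input
#'   peaks were split by projection).
#' @export
peakConservationPipeline <- function(focal_peaks, species_peaks, map, roles,
                                     stringency = "RELAXED") {
  focal <- names(roles)[roles == "FOCAL"]
  if (length(focal) != 1L) stop("exactly one FOCAL species required")
  projected <- list()
  split <- list()
  for (sp in names(species_peaks)) {
    pr <- projectIntervals(species_peaks[[sp]], map, sp,
                           direction = "target_to_focal")
    n_frag <- tabulate(pr$query, nbins = nrow(species_peaks[[sp]]))
    split[[sp]] <- n_frag >= 2L
    projected[[sp]] <- pr[, c("chrom", "start", "end")]
  }
  flags <- tagConserved(focal_peaks, projected, stringency)
  full <- cbind(flags, matrix(TRUE, nrow(focal_peaks), 1,
                              dimnames = list(NULL, focal)))
  category <- classifyConservation(full, roles)
  ids <- if ("peak_id" %in% names(focal_peaks)) focal_peaks$peak_id
         else seq_len(nrow(focal_peaks))
  calls <- data.frame(peak_id = ids, category = category)
  calls <- cbind(calls, as.data.frame(flags))
  list(calls = calls, flags = flags, split = split)
}

#' Select diapause-specific differential peaks
#'
#' A peak is diapause-specific when it is significantly up (chromatin more
#' open) in at least one diapause contrast by at least one of the two
#' differential methods, while the development-vs-development contrast is
#' non-significant under both methods (significance by either method in
#' development rejects the peak; set \code{dev_both = FALSE} to require
#' both methods to call the development change before rejecting).
#'
#' @param calls data.frame with columns \code{peak_id}, \code{contrast},
#'   \code{contrast_type} (\code{"DIAPAUSE"} or \code{"DEVELOPMENT"}),
#'   \code{method}, \code{significant} (logical), \code{log2fc}. Both
#'   methods must be present for every contrast of every peak.
#' @param dev_both if TRUE (default), the development contrast must be
#'   non-significant under BOTH methods.
#' @return character vector of selected peak ids.
#' @export
selectDiapauseSpecificPeaks <- function(calls, dev_both = TRUE) {
  need <- c("peak_id", "contrast", "contrast_type", "method",
            "significant", "log2fc")
  if (!all(need %in% names(calls)))
    stop("selectDiapauseSpecificPeaks: missing columns: ",
         paste(setdiff(need, names(calls)), collapse = ", "))
  methods_ <- unique(calls$method)
  if (length(methods_) != 2L)
    stop("selectDiapauseSpecificPeaks: exactly two methods expected")
  cnt <- table(calls$peak_id, calls$contrast)
  if (any(cnt != 2L))
    stop("selectDiapauseSpecificPeaks: every peak needs both methods for every contrast")
  dia <- calls$contrast_type == "DIAPAUSE"
  dev <- calls$contrast_type == "DEVELOPMENT"
  up_dia <- tapply(dia & calls$significant & calls$log2fc > 0,
                   calls$peak_id, any)
  dev_sig_n <- tapply(dev & calls$significant, calls$peak_id, sum)
  reject_dev <- if (dev_both) dev_sig_n >= 1L else dev_sig_n >= 2L
  ids <- names(up_dia)[up_dia & !reject_dev[names(up_dia)]]
  ids
}

#' Assign peaks to their nearest gene
#'
#' Each peak is assigned to the gene whose transcription start site (TSS)
#' is nearest by interval distance (0 when the TSS falls inside the peak).
#' Equidistant ties are broken deterministically: smaller gene start
#' coordinate first, then lexicographic gene id.
#'
#' @param peaks interval data.frame.
#' @param genes data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; TSS is \code{start} on the
#'   + strand and \code{end - 1} on the - strand.
#' @return data.frame with \code{gene_id} and \code{distance} per peak
#'   (NA when the peak's chromosome has no annotated gene).
#' @export
assignPeakToGene <- function(peaks, genes) {
  if (nrow(genes) == 0L) stop("assignPeakToGene: empty annotation")
  .validate_intervals(peaks, "peak")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    ord <- gi[order(genes$start[gi], genes$gene_id[gi])]
    # distance of peak [s, e) to TSS t: 0 inside, else gap to nearest edge
    d <- pmax(outer(peaks$start[pi], tss[ord], "-"),
              outer(-(peaks$end[pi] - 1L), tss[ord], "+"))
    d[d < 0L] <- 0L
    j <- max.col(-d, ties.method = "first")
    out_gene[pi] <- genes$gene_id[ord][j]
    out_dist[pi] <- d[cbind(seq_along(pi), j)]
  }
  data.frame(gene_id = out_gene, distance = out_dist)
}

#' Annotate peaks by genomic feature
#'
#' Labels each peak PROMOTER, EXON, INTRON or DISTAL_INTERGENIC with
#' precedence PROMOTER > EXON > INTRON > DISTAL_INTERGENIC. The promoter
#' window is strand-aware around the TSS: with the default
#' \code{c(-2000, 500)}, a + strand gene's promoter spans 2000 bp upstream
#' to 500 bp downstream of its TSS (mirrored for - strand genes). INTRON
#' means inside a gene body but outside every exon and promoter window.
#'
#' @param peaks interval data.frame.
#' @param genes gene table (see \code{\link{assignPeakToGene}}).
#' @param exons interval data.frame of exons (columns chrom, start, end).
#' @param promoter_window \code{c(upstream, downstream)} relative to the
#'   TSS in transcription direction; upstream negative.
#' @return factor per peak.
#' @export
annotatePeakRegion <- function(peaks, genes, exons,
                               promoter_window = c(-2000L, 500L)) {
  .validate_intervals(peaks, "peak")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  w1 <- promoter_window[1]; w2 <- promoter_window[2]
  prom <- data.frame(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", tss + w1, tss - w2 + 1L),
    end = ifelse(genes$strand == "+", tss + w2, tss - w1 + 1L))
  prom$start <- pmax(prom$start, 0L)
  prom <- prom[prom$end > prom$start, , drop = FALSE]
  bodies <- genes[, c("chrom", "start", "end")]
  in_prom <- overlapsAny(peaks, prom)
  in_exon <- overlapsAny(peaks, exons)
  in_gene <- overlapsAny(peaks, bodies)
  lab <- ifelse(in_prom, "PROMOTER",
         ifelse(in_exon, "EXON",
         ifelse(in_gene, "INTRON", "DISTAL_INTERGENIC")))
  factor(lab, levels = c("PROMOTER", "EXON", "INTRON", "DISTAL_INTERGENIC"))
}
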