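#' @title PWM scoring, scanning and cross-species motif conservation
#' @description Log-odds scoring of transcription-factor binding motifs
#'   against a uniform background, sliding-window scanning on both
#'   strands, per-position information content, and the cross-species
#'   conservation assessment of focal binding sites: a site is conserved
#'   in a species when the aligned sequence still scores at or above the
#'   motif's detection threshold; sites whose aligned position lost the
#'   motif but which have an identical motif nearby in the other species
#'   are excluded from the conserved/non-conserved tally. Motif origin is
#'   classified as transposon-derived (overlapping an annotated TE) or
#'   mutation-derived.
#' @name motif-conservation
NULL

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
NULL

.seq_to_int <- function(seq) {
  # A=1 C=2 G=3 T=4, anything else (N, ...) = NA
  m <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  m
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.log_odds_matrix <- function(pwm) {
  log(pmax(motifProbs(pwm), PWM_PROB_FLOOR) / 0.25)
}

#' Score a sequence against a PWM
#'
#' Summed log-odds score \code{sum_i log(p[i, base_i] / 0.25)} with a
#' probability floor of 0.001 per matrix cell (natural log). A sequence
#' containing any non-ACGT letter is non-scorable and returns \code{NA}.
#'
#' @param pwm a \code{\linkS4class{PWMotif}}.
#' @param seq DNA string whose length equals the motif length.
#' @return numeric score, or \code{NA} for non-scorable input.
#' @export
scoreSequence <- function(pwm, seq) {
  n <- length(pwm)
  if (nchar(seq) != n)
    stop("scoreSequence: sequence length ", nchar(seq),
         " != motif length ", n)
  idx <- .seq_to_int(seq)
  if (anyNA(idx)) return(NA_real_)
  lo <- .log_odds_matrix(pwm)
  sum(lo[cbind(seq_len(n), idx)])
}

# vectorised scores at every offset of a sequence (integer-encoded);
# positions overlapping a non-ACGT letter score NA
.scan_scores <- function(lo, idx) {
  n <- nrow(lo); L <- length(idx)
  if (L < n) return(numeric(0))
  n_off <- L - n + 1L
  s <- numeric(n_off)
  na <- logical(n_off)
  for (j in seq_len(n)) {
    v <- lo[j, ][idx[j:(j + n_off - 1L)]]
    na <- na | is.na(v)
    v[is.na(v)] <- 0
    s <- s + v
  }
  s[na] <- NA_real_
  s
}

#' Scan a sequence for motif hits
#'
#' Slides the PWM across every offset of the sequence (and of its reverse
#' complement when \code{both_strands}) and reports all positions scoring
#' at or above the detection threshold. Overlapping hits are all reported.
#' Offsets are 0-based relative to the forward sequence; a minus-strand
#' hit at offset k means the reverse complement of
#' \code{seq[k, k + motif length)} matches.
#'
#' @param pwm a \code{\linkS4class{PWMotif}}.
#' @param seq DNA string, length >= motif length.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame with \code{offset}, \code{strand}, \code{score},
#'   \code{matched_sequence} (forward-genome sequence at the hit).
#' @export
scanSequence <- function(pwm, seq, both_strands = TRUE) {
  n <- length(pwm)
  L <- nchar(seq)
  if (L < n) stop("scanSequence: sequence shorter than the motif")
  lo <- .log_odds_matrix(pwm)
  thr <- detectionThreshold(pwm)
  idx <- .seq_to_int(seq)
  hits <- list()
  sp <- .scan_scores(lo, idx)
  kp <- which(!is.na(sp) & sp >= thr)
  if (length(kp))
    hits[["+"]] <- data.frame(offset = kp - 1L, strand = "+",
                              score = sp[kp])
  if (both_strands) {
    rc <- .revcomp(seq)
    sm <- .scan_scores(lo, .seq_to_int(rc))
    km <- which(!is.na(sm) & sm >= thr)
    if (length(km))
      hits[["-"]] <- data.frame(offset = L - n - (km - 1L), strand = "-",
                                score = sm[km])
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0),
                      matched_sequence = character(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  out$matched_sequence <- substring(seq, out$offset + 1L, out$offset + n)
  rownames(out) <- NULL
  out
}

#' Per-position information content of a PWM
#'
#' \code{IC_i = 2 + sum_b p log2 p} (with 0 log 0 = 0): 0 bits when all
#' four bases are equally likely, 2 bits when a single base is fixed.
#'
#' @param pwm a \code{\linkS4class{PWMotif}}.
#' @return A list with \code{per_position} (bits per position) and
#'   \code{total}.
#' @export
informationContent <- function(pwm) {
  p <- motifProbs(pwm)
  pl <- p * log2(p)
  pl[p == 0] <- 0
  ic <- 2 + rowSums(pl)
  list(per_position = ic, total = sum(ic))
}

#' Assess cross-species conservation of focal motif hits
#'
#' For every focal binding-site hit and every non-focal species: project
#' the hit interval through the alignment map (a missing or split
#' projection gives ALIGNMENT_ABSENT), fetch the aligned sequence
#' (reverse-complemented across minus-strand blocks and for minus-strand
#' hits so it is scored in motif orientation), and score it. A score at or
#' above the detection threshold is CONSERVED. Otherwise the aligned
#' region extended by \code{nearby_window} bp on both sides is scanned on
#' both strands; an above-threshold hit there marks the site
#' EXCLUDED_NEARBY (an identical motif exists nearby and the site is
#' removed from the conserved/non-conserved denominator), else
#' NOT_CONSERVED.
#'
#' @param hits data.frame of focal hits: \code{chrom}, \code{start},
#'   \code{end} (BED convention, width = motif length), \code{strand}.
#' @param map an \code{\linkS4class{AlignmentBlockMap}}.
#' @param sequences named list, species -> \code{DNAStringSet} of that
#'   species' genome (names are chromosome names). Must cover every
#'   non-focal species of \code{map} that is assessed.
#' @param pwm the \code{\linkS4class{PWMotif}} that produced the hits.
#' @param species character vector of species to assess (default: all
#'   species in the map).
#' @param nearby_window bp of flank scanned for the nearby-motif
#'   exclusion (default 100).
#' @return data.frame with one row per hit x species: \code{hit},
#'   \code{species}, \code{aligned_sequence}, \code{score},
#'   \code{passes_threshold}, \code{nearby_identical_motif},
#'   \code{verdict} in CONSERVED / NOT_CONSERVED / EXCLUDED_NEARBY /
#'   ALIGNMENT_ABSENT.
#' @export
assessSiteConservation <- function(hits, map, sequences, pwm,
                                   species = mapSpecies(map),
                                   nearby_window = 100L) {
  .validate_intervals(hits, "hit")
  thr <- detectionThreshold(pwm)
  n <- length(pwm)
  res <- list()
  for (sp in species) {
    if (!sp %in% names(sequences))
      stop("assessSiteConservation: no sequences for species ", sp)
    fa <- sequences[[sp]]
    pr <- projectIntervals(hits, map, sp, "focal_to_target")
    n_frag <- tabulate(pr$query, nbins = nrow(hits))
    aligned <- rep(NA_character_, nrow(hits))
    score <- rep(NA_real_, nrow(hits))
    nearby <- rep(FALSE, nrow(hits))
    verdict <- rep("ALIGNMENT_ABSENT", nrow(hits))
    ok <- which(n_frag == 1L)
    frag <- pr[match(ok, pr$query), , drop = FALSE]
    # a gapped (shortened) projection cannot hold the full motif
    full <- (frag$end - frag$start) == (hits$end - hits$start)[ok]
    for (i in seq_along(ok)) {
      h <- ok[i]
      if (!full[i]) next
      f <- frag[i, ]
      if (!f$chrom %in% names(fa)) next
      s <- as.character(Biostrings::subseq(fa[[f$chrom]],
                                           f$start + 1L, f$end))
      if (f$strand == "-") s <- .revcomp(s)
      if (hits$strand[h] == "-") s <- .revcomp(s)
      aligned[h] <- s
      sc <- scoreSequence(pwm, s)
      score[h] <- sc
      if (!is.na(sc) && sc >= thr) {
        verdict[h] <- "CONSERVED"
        next
      }
      # nearby-identical-motif exclusion: scan the flank-extended region
      lo_ <- max(0L, f$start - nearby_window)
      hi_ <- min(length(fa[[f$chrom]]), f$end + nearby_window)
      if (hi_ - lo_ >= n) {
        region <- as.character(Biostrings::subseq(fa[[f$chrom]],
                                                  lo_ + 1L, hi_))
        nh <- scanSequence(pwm, region, both_strands = TRUE)
        if (nrow(nh) > 0L) {
          nearby[h] <- TRUE
          verdict[h] <- "EXCLUDED_NEARBY"
          next
        }
      }
      verdict[h] <- "NOT_CONSERVED"
    }
    res[[sp]] <- data.frame(
      hit = seq_len(nrow(hits)), species = sp,
      aligned_sequence = aligned, score = score,
      passes_threshold = !is.na(score) & score >= thr,
      nearby_identical_motif = nearby, verdict = verdict,
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize conserved-site fractions
#'
#' Per-species conserved fraction = CONSERVED / (CONSERVED +
#' NOT_CONSERVED); EXCLUDED_NEARBY and ALIGNMENT_ABSENT sites are removed
#' from the denominator (set \code{count_excluded = TRUE} to count
#' excluded sites as non-conserved instead). The cross-species average is
#' the unweighted mean over species; a pooled fraction over all sites is
#' reported alongside.
#'
#' @param sites output of \code{\link{assessSiteConservation}}.
#' @param count_excluded count EXCLUDED_NEARBY in the denominator
#'   (default FALSE).
#' @return A list with \code{per_species} (data.frame: species,
#'   n_conserved, n_scored, fraction), \code{average} and \code{pooled}
#'   (fractions in percent are left to the caller; these are proportions).
#' @export
summarizeConservation <- function(sites, count_excluded = FALSE) {
  if (!nrow(sites)) stop("summarizeConservation: no sites")
  denom_levels <- c("CONSERVED", "NOT_CONSERVED",
                    if (count_excluded) "EXCLUDED_NEARBY")
  keep <- sites$verdict %in% denom_levels
  s <- sites[keep, , drop = FALSE]
  sp <- sort(unique(sites$species))
  n_cons <- vapply(sp, function(x)
    sum(s$species == x & s$verdict == "CONSERVED"), integer(1))
  n_scored <- vapply(sp, function(x) sum(s$species == x), integer(1))
  frac <- ifelse(n_scored > 0, n_cons / n_scored, NA_real_)
  list(per_species = data.frame(species = sp, n_conserved = n_cons,
                                n_scored = n_scored, fraction = frac,
                                row.names = NULL),
       average = mean(frac, na.rm = TRUE),
       pooled = if (sum(n_scored)) sum(n_cons) / sum(n_scored) else NA_real_)
}

#' Classify the evolutionary origin of focal motif hits
#'
#' A hit is TE_DERIVED when it overlaps an annotated transposable element
#' by at least 1 bp on the focal genome, otherwise MUTATION_DERIVED.
#' Sharing is SHARED when the site is CONSERVED in at least one non-focal
#' species, else FOCAL_ONLY. When per-species TE annotations are given,
#' each hit x species is additionally placed in the four-way TE/motif
#' co-conservation grid: TE_AND_MOTIF (TE present at the aligned location
#' and the motif conserved), TE_NO_MOTIF, MOTIF_NO_TE, NEITHER, or NA
#' when the alignment is absent.
#'
#' @param hits focal hit data.frame (as in
#'   \code{\link{assessSiteConservation}}).
#' @param te focal TE annotation: interval data.frame with a
#'   \code{family} column.
#' @param sites conservation assessment from
#'   \code{\link{assessSiteConservation}}.
#' @param map alignment map (needed for the co-conservation grid).
#' @param te_by_species optional named list of TE interval data.frames in
#'   each non-focal species' own coordinates.
#' @return A list with \code{calls} (data.frame: hit, origin, sharing)
#'   and \code{coconservation} (data.frame hit x species x category, or
#'   NULL when \code{te_by_species} is absent).
#' @export
classifyMotifOrigin <- function(hits, te, sites, map = NULL,
                                te_by_species = NULL) {
  te_hit <- overlapsAny(hits, te)
  cons <- sites$verdict == "CONSERVED"
  shared <- tapply(cons, sites$hit, any)
  sharing <- ifelse(shared[as.character(seq_len(nrow(hits)))],
                    "SHARED", "FOCAL_ONLY")
  calls <- data.frame(
    hit = seq_len(nrow(hits)),
    origin = ifelse(te_hit, "TE_DERIVED", "MUTATION_DERIVED"),
    sharing = unname(sharing), row.names = NULL)
  coco <- NULL
  if (!is.null(te_by_species)) {
    if (is.null(map)) stop("co-conservation grid needs the alignment map")
    rows <- list()
    for (sp in names(te_by_species)) {
      pr <- projectIntervals(hits, map, sp, "focal_to_target")
      te_sp <- rep(FALSE, nrow(hits))
      if (nrow(pr)) {
        ovl <- overlapsAny(pr[, c("chrom", "start", "end")],
                           te_by_species[[sp]])
        te_sp[unique(pr$query[ovl])] <- TRUE
      }
      vsp <- sites[sites$species == sp, , drop = FALSE]
      verdict <- vsp$verdict[match(seq_len(nrow(hits)), vsp$hit)]
      motif_sp <- verdict == "CONSERVED"
      cat <- ifelse(verdict == "ALIGNMENT_ABSENT" | is.na(verdict), NA,
             ifelse(te_sp & motif_sp, "TE_AND_MOTIF",
             ifelse(te_sp, "TE_NO_MOTIF",
             ifelse(motif_sp, "MOTIF_NO_TE", "NEITHER"))))
      rows[[sp]] <- data.frame(hit = seq_len(nrow(hits)), species = sp,
                               category = cat, row.names = NULL)
    }
    coco <- do.call(rbind, rows)
    rownames(coco) <- NULL
  }
  list(calls = calls, coconservation = coco)
}
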