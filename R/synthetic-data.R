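#' @title Seeded synthetic-data generators with planted ground truth
#' @description Every pipeline input can be simulated with known truth:
#'   paralog tables with planted age-bin enrichment and expression
#'   specialization, cross-species peak sets with planted conservation
#'   categories, motif universes with planted conserved / mutated /
#'   TE-derived / nearby-displaced binding sites, knockout experiments
#'   with a planted program-reversal coefficient, and lipid tables with
#'   planted diapause-specific fold changes. All generators use a single
#'   explicitly seeded RNG and deterministic quota placement (fractions
#'   are hit exactly, not in expectation), so small-n recovery tests are
#'   exact; the same seed reproduces identical output.
#' @name synthetic-data
NULL

# deterministic per-bin quota via largest remainder, so counts sum to n
.quota <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# derive a stage-specific seed below 2^31 from a base seed and a label
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

DEV_CONDITIONS <- c("DEV_HB", "DEV_1DPH")
DIA_CONDITIONS <- c("DIA_3D", "DIA_6D", "DIA_1M")

#' Paralog pair labels with planted age bins and specialization
#'
#' Lightweight generator of the label layer only (no expression):
#' deterministic quotas place pairs into age bins and mark the planted
#' specialized pairs per bin. Ages are drawn uniformly inside each bin's
#' range.
#'
#' @param n_pairs number of paralog pairs.
#' @param bin_proportions named proportions over
#'   \code{VERY_ANCIENT}, \code{ANCIENT}, \code{RECENT_VERY_RECENT}
#'   (sum 1).
#' @param per_bin_specialization_rate named per-bin planted
#'   specialization rates in \[0, 1\].
#' @param seed integer seed.
#' @param stochastic draw bin membership and specialization as Bernoulli
#'   variables instead of exact quotas (default FALSE: deterministic
#'   placement, so planted fractions are hit exactly).
#' @return data.frame: pair_id, gene_a, gene_b, orthogroup_id,
#'   duplication_age_mya, chrom_a, chrom_b, family_size_a,
#'   family_size_b, age_bin, specialized_truth.
#' @export
genParalogLabels <- function(n_pairs = 2000L,
                             bin_proportions = c(VERY_ANCIENT = 0.2,
                                                 ANCIENT = 0.3,
                                                 RECENT_VERY_RECENT = 0.5),
                             per_bin_specialization_rate =
                               c(VERY_ANCIENT = 0.4, ANCIENT = 0.15,
                                 RECENT_VERY_RECENT = 0.15),
                             seed = 1L, stochastic = FALSE) {
  set.seed(seed)
  bin_proportions <- bin_proportions[AGE_BINS]
  rate <- per_bin_specialization_rate[AGE_BINS]
  if (anyNA(bin_proportions) || anyNA(rate))
    stop("bin_proportions and rates must be named by the three age bins")
  if (any(rate < 0 | rate > 1)) stop("rates must lie in [0, 1]")
  if (stochastic) {
    if (abs(sum(bin_proportions) - 1) > 1e-8)
      stop("proportions must sum to 1")
    bin <- sample(AGE_BINS, n_pairs, replace = TRUE,
                  prob = bin_proportions)
  } else {
    counts <- .quota(n_pairs, bin_proportions)
    bin <- rep(AGE_BINS, counts)
  }
  age_rng <- list(VERY_ANCIENT = c(474, 900), ANCIENT = c(112, 473),
                  RECENT_VERY_RECENT = c(0.5, 110.5))
  age <- numeric(n_pairs)
  spec <- logical(n_pairs)
  for (b in AGE_BINS) {
    i <- which(bin == b)
    age[i] <- runif(length(i), age_rng[[b]][1], age_rng[[b]][2])
    if (stochastic) {
      spec[i] <- runif(length(i)) < rate[[b]]
    } else {
      n_spec <- round(rate[[b]] * length(i))
      # deterministic quota: first n_spec pairs of the bin specialized
      spec[i[seq_len(n_spec)]] <- TRUE
    }
  }
  # shuffle so bin and specialization structure is not positional
  o <- sample.int(n_pairs)
  bin <- bin[o]; age <- age[o]; spec <- spec[o]
  ids <- sprintf("P%05d", seq_len(n_pairs))
  data.frame(
    pair_id = ids,
    gene_a = paste0("g", ids, "a"), gene_b = paste0("g", ids, "b"),
    orthogroup_id = paste0("OG", ids),
    duplication_age_mya = age,
    chrom_a = paste0("chr", sample.int(19, n_pairs, replace = TRUE)),
    chrom_b = paste0("chr", sample.int(19, n_pairs, replace = TRUE)),
    family_size_a = sample.int(5, n_pairs, replace = TRUE),
    family_size_b = sample.int(5, n_pairs, replace = TRUE),
    age_bin = bin, specialized_truth = spec, row.names = NULL)
}

#' Full paralog universe: labels, expression, differential table
#'
#' Extends \code{\link{genParalogLabels}} with a log-normal expression
#' matrix over the five killifish conditions (two development stages,
#' three diapause time points) and the stand-in differential table.
#' Specialized pairs receive opposing planted fold changes: the
#' diapause-role gene is up by \code{effect_size_log2} in every diapause
#' condition and the development-role gene down by the same amount.
#' With \code{expression_noise_sd = 0} replicates are exact and the
#' specialization classifier recovers the planted labels perfectly.
#'
#' @inheritParams genParalogLabels
#' @param expression_noise_sd log2-scale replicate noise SD (0 allowed).
#' @param effect_size_log2 planted specialization effect (log2 fold
#'   change, default 4 = 16x).
#' @param n_replicates_per_condition replicates per condition (>= 2).
#' @param base_log2_mean baseline log2 expression level.
#' @param fdr FDR used for the bundled differential table.
#' @return A list: \code{pairs} (truth columns included),
#'   \code{expression}, \code{design}, \code{differential},
#'   \code{truth} (pair_id, age_bin, specialized, diapause_gene),
#'   \code{params}.
#' @export
genParalogUniverse <- function(n_pairs = 2000L,
                               bin_proportions = c(VERY_ANCIENT = 0.2,
                                                   ANCIENT = 0.3,
                                                   RECENT_VERY_RECENT = 0.5),
                               per_bin_specialization_rate =
                                 c(VERY_ANCIENT = 0.4, ANCIENT = 0.15,
                                   RECENT_VERY_RECENT = 0.15),
                               expression_noise_sd = 0,
                               effect_size_log2 = 4,
                               n_replicates_per_condition = 3L,
                               base_log2_mean = 8,
                               fdr = 0.05, seed = 1L) {
  pairs <- genParalogLabels(n_pairs, bin_proportions,
                            per_bin_specialization_rate, seed)
  set.seed(deriveSeed(seed, "paralog_expression"))
  conditions <- c(DEV_CONDITIONS, DIA_CONDITIONS)
  phase <- c(rep("DEVELOPMENT", 2), rep("DIAPAUSE", 3))
  design <- data.frame(
    sample = paste0(rep(conditions, each = n_replicates_per_condition),
                    "_r", seq_len(n_replicates_per_condition)),
    condition = rep(conditions, each = n_replicates_per_condition),
    phase = rep(phase, each = n_replicates_per_condition))
  genes <- c(pairs$gene_a, pairs$gene_b)
  is_dia <- design$phase == "DIAPAUSE"
  # per-gene planted log2 shift in diapause: +effect for the diapause
  # role gene, -effect for its partner, 0 otherwise
  shift <- c(ifelse(pairs$specialized_truth, effect_size_log2, 0),
             ifelse(pairs$specialized_truth, -effect_size_log2, 0))
  mu <- matrix(base_log2_mean, nrow = length(genes), ncol = nrow(design))
  mu[, is_dia] <- mu[, is_dia] + shift
  noise <- if (expression_noise_sd > 0)
    matrix(rnorm(length(mu), 0, expression_noise_sd), nrow = nrow(mu))
  else 0
  expr <- 2^(mu + noise)
  dimnames(expr) <- list(genes, design$sample)
  differential <- differentialExpressionStandin(expr, design)
  truth <- data.frame(pair_id = pairs$pair_id, age_bin = pairs$age_bin,
                      specialized = pairs$specialized_truth,
                      diapause_gene = ifelse(pairs$specialized_truth,
                                             pairs$gene_a, NA_character_))
  list(pairs = pairs, expression = expr, design = design,
       differential = differential, truth = truth,
       params = list(n_pairs = n_pairs,
                     bin_proportions = bin_proportions,
                     per_bin_specialization_rate =
                       per_bin_specialization_rate,
                     expression_noise_sd = expression_noise_sd,
                     effect_size_log2 = effect_size_log2,
                     n_replicates_per_condition =
                       n_replicates_per_condition, seed = seed))
}

#' Cross-species peak universe with planted conservation categories
#'
#' Builds focal peaks on a synthetic focal genome, plants each peak's
#' conservation category by creating (or omitting) overlapping peaks in
#' the other species inside alignment blocks, and emits the block map.
#' Categories are placed by deterministic quota. ANCIENT_VERY_ANCIENT
#' peaks get peaks in every African killifish and outgroup; RECENT peaks
#' only in African killifish; VERY_RECENT peaks in no other species
#' (blocks are created only where a species' peak exists, so sequence
#' and accessibility categories coincide by construction). A
#' \code{split_fraction} of extra non-focal peaks straddle two blocks
#' mapping to two disjoint focal loci.
#'
#' @param species_roles named role vector with exactly one FOCAL, >= 1
#'   AFRICAN_KILLIFISH and >= 1 OUTGROUP.
#' @param n_peaks number of focal peaks.
#' @param category_proportions named proportions over the three
#'   conservation categories (sum 1).
#' @param peak_width focal peak width in bp.
#' @param spacing distance between consecutive focal peak starts.
#' @param split_fraction fraction (of \code{n_peaks}) of extra split
#'   peaks planted per non-focal species.
#' @param minus_strand_fraction fraction of blocks placed on the minus
#'   strand.
#' @param jitter maximal random shift of non-focal peaks inside their
#'   block (keeps >= 50\% overlap with the projected focal peak).
#' @param seed integer seed.
#' @return A list: \code{focal_peaks}, \code{species_peaks} (named list,
#'   species coordinates; extra split peaks have \code{split_truth}
#'   TRUE), \code{map}, \code{roles}, \code{truth} (peak_id, category),
#'   \code{params}.
#' @export
genPeakUniverse <- function(species_roles = c(nfur = "FOCAL",
                                              aaus = "AFRICAN_KILLIFISH",
                                              astr = "AFRICAN_KILLIFISH",
                                              olat = "OUTGROUP",
                                              drer = "OUTGROUP"),
                            n_peaks = 500L,
                            category_proportions =
                              c(ANCIENT_VERY_ANCIENT = 0.2, RECENT = 0.3,
                                VERY_RECENT = 0.5),
                            peak_width = 200L, spacing = 3000L,
                            split_fraction = 0, minus_strand_fraction = 0.25,
                            jitter = 40L, seed = 1L) {
  set.seed(seed)
  focal <- names(species_roles)[species_roles == "FOCAL"]
  if (length(focal) != 1L) stop("exactly one FOCAL species required")
  others <- setdiff(names(species_roles), focal)
  afr <- names(species_roles)[species_roles == "AFRICAN_KILLIFISH"]
  outg <- names(species_roles)[species_roles == "OUTGROUP"]
  if (!length(afr) || !length(outg))
    stop("need >= 1 AFRICAN_KILLIFISH and >= 1 OUTGROUP species")
  category_proportions <- category_proportions[CONSERVATION_CATEGORIES]
  counts <- .quota(n_peaks, category_proportions)
  category <- sample(rep(CONSERVATION_CATEGORIES, counts))

  start <- spacing * (seq_len(n_peaks) - 1L) + 1000L
  focal_peaks <- data.frame(peak_id = sprintf("peak%05d", seq_len(n_peaks)),
                            chrom = "chr1", start = start,
                            end = start + peak_width)
  conserved_in <- function(cat) switch(cat,
    ANCIENT_VERY_ANCIENT = others, RECENT = afr, VERY_RECENT = character(0))

  blocks <- list(); speaks <- list()
  # per-species target-coordinate stride, sized so regular and split
  # blocks of one species can never collide in target space
  stride <- 2 * spacing * n_peaks + 4e6
  offset_of <- function(sp) stride * match(sp, others)
  for (sp in others) {
    off <- offset_of(sp)
    rows <- list(); prs <- list()
    for (i in seq_len(n_peaks)) {
      if (!sp %in% conserved_in(category[i])) next
      fs <- focal_peaks$start[i] - 150L
      fe <- focal_peaks$end[i] + 150L
      strand <- if (runif(1) < minus_strand_fraction) "-" else "+"
      ts <- as.integer(off + fs)
      rows[[length(rows) + 1L]] <- data.frame(
        focal_chrom = "chr1", focal_start = fs, focal_end = fe,
        species = sp, target_chrom = "chr1", target_start = ts,
        target_end = ts + (fe - fs), strand = strand)
      # species peak: the projected focal peak, jittered inside the block
      if (strand == "+") {
        ps <- ts + (focal_peaks$start[i] - fs)
      } else {
        ps <- ts + (fe - focal_peaks$end[i])
      }
      j <- sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      ps <- max(ts, min(ps + j, ts + (fe - fs) - peak_width))
      prs[[length(prs) + 1L]] <- data.frame(
        peak_id = sprintf("%s_%05d", sp, i), chrom = "chr1",
        start = ps, end = ps + peak_width, split_truth = FALSE)
    }
    blocks[[sp]] <- do.call(rbind, rows)
    speaks[[sp]] <- if (length(prs)) do.call(rbind, prs) else
      data.frame(peak_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 split_truth = logical(0))
  }

  # split peaks: one species peak spanning two adjacent blocks in species
  # coordinates that map to two disjoint focal loci (away from real peaks)
  n_split <- round(split_fraction * n_peaks)
  if (n_split > 0) {
    gap_base <- spacing * n_peaks + 100000L
    for (sp in others) {
      off <- offset_of(sp)
      for (k in seq_len(n_split)) {
        # two focal loci 5 kb apart, adjacent in species coordinates
        f1 <- gap_base + (k - 1L) * 20000L
        f2 <- f1 + 5000L
        len <- 300L
        # target coordinates beyond every regular block of this species
        t1 <- as.integer(off + spacing * n_peaks + 1e6 + (k - 1L) * 5000L)
        blocks[[sp]] <- rbind(blocks[[sp]], data.frame(
          focal_chrom = "chr1",
          focal_start = c(f1, f2), focal_end = c(f1 + len, f2 + len),
          species = sp, target_chrom = "chr1",
          target_start = c(t1, t1 + len),
          target_end = c(t1 + len, t1 + 2L * len), strand = "+"))
        speaks[[sp]] <- rbind(speaks[[sp]], data.frame(
          peak_id = sprintf("%s_split%03d", sp, k), chrom = "chr1",
          start = t1 + len - 100L, end = t1 + len + 100L,
          split_truth = TRUE))
      }
    }
  }
  empty_blocks <- data.frame(
    focal_chrom = character(0), focal_start = integer(0),
    focal_end = integer(0), species = character(0),
    target_chrom = character(0), target_start = integer(0),
    target_end = integer(0), strand = character(0))
  all_blocks <- do.call(rbind, c(list(empty_blocks), unname(blocks)))
  map <- AlignmentBlockMap(all_blocks)
  list(focal_peaks = focal_peaks, species_peaks = speaks, map = map,
       roles = species_roles,
       truth = data.frame(peak_id = focal_peaks$peak_id,
                          category = category),
       params = list(n_peaks = n_peaks,
                     category_proportions = category_proportions,
                     split_fraction = split_fraction, seed = seed))
}

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# mutate motif positions (most informative first) until the planted
# sequence scores below the threshold; errors if impossible
.mutate_below_threshold <- function(pwm, motif_seq) {
  p <- motifProbs(pwm)
  ord <- order(apply(p, 1, max), decreasing = TRUE)
  s <- strsplit(motif_seq, "")[[1]]
  for (pos in ord) {
    worst <- DNA_BASES[which.min(p[pos, ])]
    s[pos] <- worst
    cand <- paste(s, collapse = "")
    if (scoreSequence(pwm, cand) < detectionThreshold(pwm)) return(cand)
  }
  stop("cannot mutate the motif below its detection threshold")
}

#' Motif universe with planted conservation, TE and nearby quotas
#'
#' Each binding site lives on its own small contig (one per species,
#' aligned end-to-end by a single + strand block). The focal contig
#' carries the PWM consensus at a fixed offset. Deterministic quotas
#' (applied identically in every non-focal species) make the first
#' \code{conserved_fraction} of sites carry the intact motif in the
#' aligned species; all other aligned sites carry point mutations forcing
#' a sub-threshold score. Among the non-conserved sites, the next
#' \code{nearby_fraction} (of all sites) carry an identical motif
#' displaced a short distance from the aligned position, triggering the
#' nearby-motif exclusion. The last \code{te_fraction} of sites overlap a
#' planted focal TE interval. Background sequence is redrawn until it
#' contains no spurious above-threshold hit, so quota recovery is exact.
#'
#' @param pwm a \code{\linkS4class{PWMotif}} whose consensus scores at or
#'   above its threshold (otherwise unplantable: error).
#' @param n_sites number of binding sites.
#' @param conserved_fraction fraction of sites conserved in every
#'   non-focal species.
#' @param te_fraction fraction of sites overlapping a planted focal TE.
#' @param nearby_fraction fraction of sites with a displaced identical
#'   motif in non-focal species.
#' @param species names: first element is the focal species.
#' @param window_width contig width per site.
#' @param motif_offset offset of the planted motif within the contig.
#' @param nearby_shift displacement of the nearby motif (must stay
#'   within the assessment window).
#' @param seed integer seed.
#' @return A list: \code{sequences} (species -> DNAStringSet),
#'   \code{map}, \code{te} (focal TE intervals), \code{hits} (planted
#'   focal hits), \code{pwm}, \code{truth} (per site: conserved,
#'   nearby_excluded, te_derived, origin, sharing), \code{params}.
#' @export
genMotifUniverse <- function(pwm, n_sites = 200L,
                             conserved_fraction = 0.05,
                             te_fraction = 0.05, nearby_fraction = 0.10,
                             species = c("nfur", "aaus", "drer"),
                             window_width = 260L, motif_offset = 80L,
                             nearby_shift = 40L, seed = 1L) {
  set.seed(seed)
  n <- length(pwm)
  cons_seq <- consensusSeq(pwm)
  if (scoreSequence(pwm, cons_seq) < detectionThreshold(pwm))
    stop("consensus scores below the detection threshold: unplantable")
  if (conserved_fraction + nearby_fraction > 1)
    stop("conserved_fraction + nearby_fraction must be <= 1")
  focal <- species[1]; others <- species[-1]
  # nearby-excluded sites leave the conservation denominator, so the
  # conserved quota is taken over the assessable (non-excluded) sites:
  # summarize_conservation then recovers conserved_fraction exactly
  n_near <- round(nearby_fraction * n_sites)
  n_cons <- round(conserved_fraction * (n_sites - n_near))
  n_te <- round(te_fraction * n_sites)
  conserved <- seq_len(n_sites) <= n_cons
  nearby <- !conserved & seq_len(n_sites) <= (n_cons + n_near)
  te_derived <- seq_len(n_sites) > (n_sites - n_te)

  plant <- function(background, at, motif) {
    paste0(substr(background, 1, at), motif,
           substr(background, at + n + 1L, nchar(background)))
  }
  # exactly the intended hits and nothing else, so quota recovery is exact
  hits_ok <- function(s, offsets) {
    h <- scanSequence(pwm, s, TRUE)
    nrow(h) == length(offsets) && setequal(h$offset, offsets) &&
      all(h$strand == "+")
  }
  mutated <- .mutate_below_threshold(pwm, cons_seq)
  seqs <- lapply(stats::setNames(species, species),
                 function(x) character(n_sites))
  for (i in seq_len(n_sites)) {
    ok <- FALSE
    for (try in 1:200) {
      bg <- .random_dna(window_width)
      focal_seq <- plant(bg, motif_offset, cons_seq)
      other_seq <- if (conserved[i]) plant(bg, motif_offset, cons_seq)
                   else plant(bg, motif_offset, mutated)
      if (nearby[i])
        other_seq <- plant(other_seq, motif_offset + nearby_shift, cons_seq)
      want <- if (conserved[i]) motif_offset
              else if (nearby[i]) motif_offset + nearby_shift
              else integer(0)
      if (hits_ok(focal_seq, motif_offset) && hits_ok(other_seq, want)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not draw a clean background; detection threshold too low")
    seqs[[focal]][i] <- focal_seq
    for (sp in others) seqs[[sp]][i] <- other_seq
  }
  contigs <- sprintf("site%05d", seq_len(n_sites))
  sequences <- lapply(seqs, function(x)
    Biostrings::DNAStringSet(stats::setNames(x, contigs)))
  blocks <- do.call(rbind, lapply(others, function(sp)
    data.frame(focal_chrom = contigs, focal_start = 0L,
               focal_end = window_width, species = sp,
               target_chrom = contigs, target_start = 0L,
               target_end = window_width, strand = "+")))
  map <- AlignmentBlockMap(blocks)
  hits <- data.frame(chrom = contigs, start = motif_offset,
                     end = motif_offset + n, strand = "+",
                     score = scoreSequence(pwm, cons_seq))
  te <- if (any(te_derived))
    data.frame(chrom = contigs[te_derived], start = motif_offset - 5L,
               end = motif_offset + n + 5L, family = "TE_FAM1",
               te_class = "DNA")
  else
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), family = character(0),
               te_class = character(0))
  truth <- data.frame(
    site = seq_len(n_sites), conserved = conserved,
    nearby_excluded = nearby, te_derived = te_derived,
    origin = ifelse(te_derived, "TE_DERIVED", "MUTATION_DERIVED"),
    sharing = ifelse(conserved, "SHARED", "FOCAL_ONLY"))
  list(sequences = sequences, map = map, te = te, hits = hits, pwm = pwm,
       truth = truth,
       params = list(n_sites = n_sites,
                     conserved_fraction = conserved_fraction,
                     te_fraction = te_fraction,
                     nearby_fraction = nearby_fraction, seed = seed))
}

#' Knockout experiment with a planted program-reversal coefficient
#'
#' Simulates single-embryo expression for wildtype, scramble and knockout
#' embryos in diapause and development. Every gene carries a control
#' diapause-vs-development log2 fold change drawn from
#' \code{N(0, control_lfc_sd)}; in knockout diapause embryos the gene is
#' additionally shifted by \code{reversal_coefficient} times its control
#' fold change plus \code{N(0, noise_sd)} gene-level noise. A reversal
#' coefficient of -1 with vanishing noise collapses the diapause program
#' exactly onto development.
#'
#' @param n_genes number of genes (the simulated DEG set).
#' @param reversal_coefficient planted coefficient (negative = program
#'   reversal).
#' @param noise_sd SD of the gene-level knockout noise (log2).
#' @param n_embryos_per_group embryos per genotype x state (>= 3).
#' @param control_lfc_sd SD of the control program fold changes (log2).
#' @param embryo_noise_sd per-embryo measurement noise SD (log2).
#' @param tf name of the knocked-out factor (genotype label).
#' @param seed integer seed.
#' @return A list: \code{expression} (genes x embryos), \code{samples}
#'   (sample sheet), \code{truth} (per-gene control lfc and planted
#'   knockout shift, plus the coefficient), \code{params}.
#' @export
genKOExperiment <- function(n_genes = 500L, reversal_coefficient = -0.8,
                            noise_sd = 0.5, n_embryos_per_group = 6L,
                            control_lfc_sd = 2, embryo_noise_sd = 0.2,
                            tf = "REST", seed = 1L) {
  if (n_embryos_per_group < 3L)
    stop("genKOExperiment: need >= 3 embryos per group")
  set.seed(seed)
  genotypes <- c("WILDTYPE", "SCRAMBLE", paste0("KO:", tf))
  states <- c("DIAPAUSE", "DEVELOPMENT")
  grid <- expand.grid(rep = seq_len(n_embryos_per_group),
                      genotype = genotypes, state = states,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("emb%03d", seq_len(nrow(grid))),
    genotype = grid$genotype, state = grid$state)
  base <- rnorm(n_genes, 8, 1)
  control_lfc <- rnorm(n_genes, 0, control_lfc_sd)
  ko_shift <- reversal_coefficient * control_lfc + rnorm(n_genes, 0, noise_sd)
  mu <- matrix(base, n_genes, nrow(samples))
  dia <- samples$state == "DIAPAUSE"
  ko <- samples$genotype == paste0("KO:", tf)
  mu[, dia] <- mu[, dia] + control_lfc
  mu[, dia & ko] <- mu[, dia & ko] + ko_shift
  expr <- 2^(mu + matrix(rnorm(length(mu), 0, embryo_noise_sd),
                         nrow = n_genes))
  dimnames(expr) <- list(sprintf("gene%05d", seq_len(n_genes)),
                         samples$sample_id)
  list(expression = expr, samples = samples,
       truth = data.frame(gene = rownames(expr),
                          control_lfc = control_lfc, ko_shift = ko_shift),
       params = list(n_genes = n_genes,
                     reversal_coefficient = reversal_coefficient,
                     noise_sd = noise_sd,
                     n_embryos_per_group = n_embryos_per_group,
                     tf = tf, seed = seed))
}

.LIPID_CLASS_MIX <- c(TG = 0.35, PC = 0.15, PE = 0.10, DG = 0.08,
                      PI = 0.07, SM = 0.06, PS = 0.05, LPC = 0.05,
                      Cer = 0.05, ChE = 0.04)

#' Lipid concentration table with planted diapause-specific lipids
#'
#' Log-normal molar concentrations over the four conditions
#' (pre-diapause, development, diapause 6 days, diapause 1 month).
#' The first \code{n_diapause_specific} lipids shift by
#' \code{fold_change} in both diapause conditions only (alternating up
#' and down). Class membership follows deterministic quotas over
#' \code{class_mix}; names are syntactically valid
#' \code{CLASS(c:d/...)} strings, and the planted TG lipids include a
#' 22:6 chain so the very-long-chain flag is exercised.
#'
#' @param n_lipids number of lipid species.
#' @param class_mix named proportions over lipid classes (sum 1).
#' @param n_diapause_specific number of planted diapause-specific
#'   lipids.
#' @param fold_change planted fold change (1 = null).
#' @param cv coefficient of variation of replicate concentrations.
#' @param n_samples_per_condition samples per condition (>= 2).
#' @param seed integer seed.
#' @return A list: \code{matrix} (lipid x sample), \code{conditions}
#'   (named vector sample -> condition), \code{species} (parsed lipids),
#'   \code{truth} (lipid, planted, direction), \code{params}.
#' @export
genLipidTable <- function(n_lipids = 200L, class_mix = .LIPID_CLASS_MIX,
                          n_diapause_specific = 40L, fold_change = 2,
                          cv = 0.2, n_samples_per_condition = 4L, seed = 1L) {
  if (n_diapause_specific > n_lipids)
    stop("n_diapause_specific must be <= n_lipids")
  if (cv <= 0) stop("cv must be positive")
  set.seed(seed)
  counts <- .quota(n_lipids, class_mix)
  classes <- rep(names(class_mix), counts)
  carbons_pool <- c(14L, 16L, 18L, 20L, 22L, 24L)
  db_pool <- 0:6
  make_name <- function(cls, force_vlc = FALSE) {
    k <- .CLASS_CHAINS[cls]
    if (is.na(k)) k <- 2L
    carb <- sample(carbons_pool, k, replace = TRUE,
                   prob = c(0.25, 0.3, 0.25, 0.1, 0.07, 0.03))
    db <- pmin(sample(db_pool, k, replace = TRUE,
                      prob = c(0.3, 0.25, 0.15, 0.1, 0.1, 0.05, 0.05)),
               pmax(carb - 12L, 0L))
    if (force_vlc) { carb[k] <- 22L; db[k] <- 6L }
    paste0(cls, "(", paste0(carb, ":", db, collapse = "/"), ")")
  }
  # planted lipids first; planted TGs carry a 22:6 chain
  planted <- seq_len(n_lipids) <= n_diapause_specific
  names_ <- character(n_lipids)
  seen <- character(0)
  for (i in seq_len(n_lipids)) {
    repeat {
      nm <- make_name(classes[i], force_vlc = planted[i] &&
                        classes[i] == "TG")
      if (!nm %in% seen) break
    }
    seen <- c(seen, nm)
    names_[i] <- nm
  }
  conds <- rep(LIPID_CONDITIONS, each = n_samples_per_condition)
  snames <- paste0(conds, "_s", seq_len(n_samples_per_condition))
  sdlog <- sqrt(log(1 + cv^2))
  base <- exp(rnorm(n_lipids, log(10), 1.5))
  mat <- matrix(base, n_lipids, length(conds)) *
    exp(matrix(rnorm(n_lipids * length(conds), 0, sdlog), n_lipids))
  in_dia <- conds %in% c("DIA_6D", "DIA_1M")
  direction <- rep(NA_character_, n_lipids)
  if (any(planted) && fold_change != 1) {
    up <- planted & (seq_len(n_lipids) %% 2L == 1L)
    dn <- planted & !up
    mat[up, in_dia] <- mat[up, in_dia] * fold_change
    mat[dn, in_dia] <- mat[dn, in_dia] / fold_change
    direction[up] <- "UP"; direction[dn] <- "DOWN"
  }
  dimnames(mat) <- list(names_, snames)
  species <- lapply(names_, parseLipidName)
  list(matrix = mat,
       conditions = stats::setNames(conds, snames),
       species = species,
       truth = data.frame(lipid = names_,
                          planted = planted & fold_change != 1,
                          direction = direction),
       params = list(n_lipids = n_lipids,
                     n_diapause_specific = n_diapause_specific,
                     fold_change = fold_change, cv = cv,
                     n_samples_per_condition = n_samples_per_condition,
                     seed = seed))
}
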