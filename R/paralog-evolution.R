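#' @title Paralog age, specialization and enrichment analysis
#' @description Classifies paralog pairs of the African turquoise killifish
#'   (and comparator species) by duplication age, calls diapause expression
#'   specialization from differential-expression evidence, and tests
#'   whether specialization is enriched in particular age bins by bootstrap
#'   subsampling and chi-square contingency tests.
#' @name paralog-evolution
NULL

AGE_BINS <- c("VERY_ANCIENT", "ANCIENT", "RECENT_VERY_RECENT")

#' Remove pairs from oversized paralog families
#'
#' Drops every pair in which either gene has more than \code{max_partners}
#' paralog partners; large inter-connected families inflate pairwise
#' analyses. A gene with exactly \code{max_partners} partners is retained
#' (the cut is strict).
#'
#' @param pairs data.frame with at least \code{family_size_a} and
#'   \code{family_size_b} columns (partner counts for each gene).
#' @param max_partners maximum allowed partner count (default 20).
#' @return The filtered data.frame, with attributes \code{n_removed} and
#'   \code{n_kept}.
#' @export
filterParalogFamilies <- function(pairs, max_partners = 20L) {
  if (!all(c("family_size_a", "family_size_b") %in% names(pairs)))
    stop("filterParalogFamilies: family_size_a/family_size_b missing")
  if (anyNA(pairs$family_size_a) || anyNA(pairs$family_size_b))
    stop("filterParalogFamilies: family sizes contain NA")
  keep <- pairs$family_size_a <= max_partners &
          pairs$family_size_b <= max_partners
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Assign duplication-age bins
#'
#' Bins a duplication age (million years ago) into the three categories
#' used throughout the analysis: very ancient (shared with vertebrates,
#' strictly older than the upper boundary), ancient (shared with fish),
#' and recent/very recent (killifish-specific). Ages exactly at the upper
#' boundary fall in ANCIENT; ages exactly at the lower boundary fall in
#' RECENT_VERY_RECENT.
#'
#' @param age_mya numeric vector of duplication ages (>= 0).
#' @param boundaries \code{c(lower, upper)} in mya; defaults
#'   \code{c(111, 473.3)}.
#' @return factor with levels \code{VERY_ANCIENT}, \code{ANCIENT},
#'   \code{RECENT_VERY_RECENT}.
#' @export
assignAgeBin <- function(age_mya, boundaries = c(111, 473.3)) {
  if (anyNA(age_mya) || any(age_mya < 0))
    stop("assignAgeBin: ages must be non-negative and non-missing")
  bin <- ifelse(age_mya > boundaries[2], "VERY_ANCIENT",
         ifelse(age_mya > boundaries[1], "ANCIENT", "RECENT_VERY_RECENT"))
  factor(bin, levels = AGE_BINS)
}

#' Differential-expression stand-in
#'
#' Pluggable replacement for an external count-model differential engine:
#' for every (diapause condition x development condition) contrast it runs
#' a row-wise Welch test on log2-transformed normalized expression and
#' adjusts p-values with Benjamini-Hochberg across genes within each
#' contrast. Externally computed differential tables with the same schema
#' (\code{gene}, \code{contrast}, \code{log2fc}, \code{padj}) may be
#' substituted anywhere this output is consumed.
#'
#' @param expr numeric matrix, genes x samples (normalized, non-log).
#' @param design data.frame with columns \code{sample}, \code{condition},
#'   \code{phase} (\code{"DIAPAUSE"} or \code{"DEVELOPMENT"}); every
#'   condition needs >= 2 replicates.
#' @param log_offset pseudocount added before log2 (default 1).
#' @return data.frame with columns \code{gene}, \code{contrast}
#'   (\code{"<diapause>_vs_<development>"}), \code{log2fc} (diapause minus
#'   development), \code{padj}, \code{p_raw}.
#' @export
differentialExpressionStandin <- function(expr, design, log_offset = 1) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  design <- as.data.frame(design)
  if (!all(c("sample", "condition", "phase") %in% names(design)))
    stop("design needs columns sample, condition, phase")
  if (!all(design$sample %in% colnames(expr)))
    stop("design lists samples absent from the expression matrix")
  counts <- table(design$condition)
  if (any(counts < 2L))
    stop("every condition needs >= 2 replicates")
  dia <- unique(design$condition[design$phase == "DIAPAUSE"])
  dev <- unique(design$condition[design$phase == "DEVELOPMENT"])
  if (!length(dia) || !length(dev))
    stop("design needs at least one condition per phase")
  lexpr <- log2(expr + log_offset)
  res <- vector("list", length(dia) * length(dev))
  k <- 0L
  for (d in dia) for (v in dev) {
    k <- k + 1L
    sd_ <- design$sample[design$condition == d]
    sv <- design$sample[design$condition == v]
    w <- rowWelchTest(lexpr[, sd_, drop = FALSE], lexpr[, sv, drop = FALSE])
    res[[k]] <- data.frame(
      gene = rownames(expr),
      contrast = paste0(d, "_vs_", v),
      log2fc = w$mean_diff,
      p_raw = w$p_value,
      padj = bhAdjust(w$p_value)$adjusted,
      row.names = NULL)
  }
  do.call(rbind, res)
}

#' Call diapause expression specialization of a paralog pair set
#'
#' A pair is specialized when one gene is significantly up in diapause
#' (positive fold change at \code{padj < fdr} in at least one
#' diapause-vs-development contrast) while its partner is either
#' significantly down in diapause in some contrast, or has a higher median
#' expression across all development samples than across all diapause
#' samples. Three rule variants are provided: \code{"nfur"} (the full rule
#' with the median clause), \code{"alim_strict"} (partner must be
#' significantly down, no median clause), and \code{"mouse"} (the up gene
#' must be significant against every development condition and the partner
#' down against every development condition). If both genes qualify as
#' diapause-up the pair is not specialized: specialization requires
#' opposing roles.
#'
#' Verdicts are symmetric in gene order: swapping \code{gene_a} and
#' \code{gene_b} can only swap the role assignment, never the verdict.
#'
#' @param pairs data.frame with \code{pair_id}, \code{gene_a},
#'   \code{gene_b}.
#' @param differential differential table (\code{gene}, \code{contrast},
#'   \code{log2fc}, \code{padj}) covering both genes of every pair, from
#'   \code{\link{differentialExpressionStandin}} or an external engine.
#' @param expr expression matrix (genes x samples), needed for the median
#'   clause; may be \code{NULL} in \code{"alim_strict"} mode.
#' @param design design data.frame (see
#'   \code{\link{differentialExpressionStandin}}).
#' @param mode rule variant.
#' @param fdr significance threshold on adjusted p-values (default 0.05).
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{specialized}, \code{diapause_gene}, \code{development_gene},
#'   \code{rule_path} (\code{"partner_down"}, \code{"partner_median"} or
#'   \code{NA}) and \code{mode}.
#' @export
classifySpecialization <- function(pairs, differential, expr = NULL,
                                   design = NULL,
                                   mode = c("nfur", "alim_strict", "mouse"),
                                   fdr = 0.05) {
  mode <- match.arg(mode)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing_genes <- setdiff(genes, unique(differential$gene))
  if (length(missing_genes))
    stop("genes missing from the differential table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))

  sig <- differential$padj < fdr
  n_contrasts <- length(unique(differential$contrast))
  up_any <- tapply(sig & differential$log2fc > 0, differential$gene, any)
  dn_any <- tapply(sig & differential$log2fc < 0, differential$gene, any)
  up_all <- tapply(sig & differential$log2fc > 0, differential$gene, sum) ==
    n_contrasts
  dn_all <- tapply(sig & differential$log2fc < 0, differential$gene, sum) ==
    n_contrasts

  med_higher_dev <- NULL
  if (mode == "nfur") {
    if (is.null(expr) || is.null(design))
      stop("nfur mode needs the expression matrix and design (median clause)")
    if (!all(genes %in% rownames(expr)))
      stop("genes missing from the expression matrix: ",
           paste(utils::head(setdiff(genes, rownames(expr)), 5),
                 collapse = ", "))
    dia_s <- design$sample[design$phase == "DIAPAUSE"]
    dev_s <- design$sample[design$phase == "DEVELOPMENT"]
    med_dia <- apply(expr[genes, dia_s, drop = FALSE], 1, stats::median)
    med_dev <- apply(expr[genes, dev_s, drop = FALSE], 1, stats::median)
    med_higher_dev <- med_dev > med_dia
  }

  up_of <- function(g) if (mode == "mouse") isTRUE(up_all[g]) else
    isTRUE(up_any[g])
  partner_of <- function(g) {
    # clause on the non-up partner; returns the rule path or NA
    if (mode == "mouse") {
      if (isTRUE(dn_all[g])) "partner_down" else NA_character_
    } else if (mode == "alim_strict") {
      if (isTRUE(dn_any[g])) "partner_down" else NA_character_
    } else {
      if (isTRUE(dn_any[g])) "partner_down"
      else if (isTRUE(med_higher_dev[g])) "partner_median"
      else NA_character_
    }
  }

  n <- nrow(pairs)
  specialized <- logical(n)
  dia_gene <- dev_gene <- rule <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    a_up <- up_of(a); b_up <- up_of(b)
    if (a_up && b_up) next  # opposing roles required
    if (a_up) {
      rp <- partner_of(b)
      if (!is.na(rp)) {
        specialized[i] <- TRUE
        dia_gene[i] <- a; dev_gene[i] <- b; rule[i] <- rp
      }
    } else if (b_up) {
      rp <- partner_of(a)
      if (!is.na(rp)) {
        specialized[i] <- TRUE
        dia_gene[i] <- b; dev_gene[i] <- a; rule[i] <- rp
      }
    }
  }
  data.frame(pair_id = pairs$pair_id, specialized = specialized,
             diapause_gene = dia_gene, development_gene = dev_gene,
             rule_path = rule, mode = mode, row.names = NULL)
}

#' Age-bin enrichment of specialized paralog pairs
#'
#' For each age bin, compares the fraction of specialized pairs falling in
#' the bin against the fraction of all pairs in the bin (the genome-wide
#' expectation). Uncertainty is assessed by recomputing the
#' observed/expected ratio over \code{n_boot} random subsamples of
#' \code{subsample_fraction} of all pairs drawn without replacement, and a
#' p-value comes from a Pearson chi-square test on the 2x2 table
#' (specialized yes/no x in-bin yes/no).
#'
#' @param bins factor/character of age bins, one per pair.
#' @param specialized logical vector, one per pair.
#' @param n_boot number of bootstrap subsamples (default 10000; 0 skips
#'   the bootstrap).
#' @param subsample_fraction fraction of pairs per subsample (default 0.5).
#' @param seed integer seed for the subsampling RNG.
#' @param with_replacement draw subsamples with replacement instead
#'   (default \code{FALSE}, i.e. plain subsampling).
#' @return A list with \code{summary} (data.frame: bin, counts, observed
#'   and expected fractions, enrichment ratio, chi-square p) and
#'   \code{bootstrap_ratios} (matrix, \code{n_boot} x bins).
#' @export
binEnrichment <- function(bins, specialized, n_boot = 10000L,
                          subsample_fraction = 0.5, seed = 1L,
                          with_replacement = FALSE) {
  if (length(bins) != length(specialized))
    stop("binEnrichment: bins and specialized lengths differ")
  bins <- factor(bins, levels = union(AGE_BINS, unique(as.character(bins))))
  bins <- droplevels(bins)
  N <- length(bins)
  n_spec <- sum(specialized)
  lv <- levels(bins)

  ratio_of <- function(idx) {
    b <- bins[idx]; s <- specialized[idx]
    ns <- sum(s)
    obs <- as.numeric(table(b[s])[lv]) / ns
    exp_ <- as.numeric(table(b)[lv]) / length(idx)
    obs[is.na(obs)] <- 0
    obs / exp_
  }

  in_bin_n <- as.integer(table(bins)[lv])
  spec_in_bin <- as.integer(table(bins[specialized])[lv])
  spec_in_bin[is.na(spec_in_bin)] <- 0L
  observed <- spec_in_bin / n_spec
  expected <- in_bin_n / N
  ratio <- observed / expected
  ratio[in_bin_n == 0L] <- NA_real_  # empty bin: undefined, flagged

  chi_p <- vapply(seq_along(lv), function(i) {
    tab <- matrix(c(spec_in_bin[i], n_spec - spec_in_bin[i],
                    in_bin_n[i] - spec_in_bin[i],
                    (N - n_spec) - (in_bin_n[i] - spec_in_bin[i])),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    chiSquare2x2(tab)$p_value
  }, numeric(1))

  boot <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    m <- as.integer(ceiling(subsample_fraction * N))
    boot <- matrix(NA_real_, nrow = n_boot, ncol = length(lv),
                   dimnames = list(NULL, lv))
    for (r in seq_len(n_boot)) {
      idx <- sample.int(N, m, replace = with_replacement)
      boot[r, ] <- ratio_of(idx)
    }
  }

  list(summary = data.frame(
         bin = lv, n_pairs_in_bin = in_bin_n,
         n_specialized_in_bin = spec_in_bin,
         observed_fraction = observed, expected_fraction = expected,
         enrichment_ratio = ratio, chi2_p = chi_p, row.names = NULL),
       bootstrap_ratios = boot)
}

#' Same- vs different-chromosome classification of a paralog pair
#'
#' @param chrom_a,chrom_b chromosome labels of the two genes; unplaced
#'   scaffolds (label starting with \code{"scaffold"} or \code{NA}) give
#'   \code{UNKNOWN}, which downstream comparisons exclude.
#' @return character vector in \code{SAME_CHROMOSOME},
#'   \code{DIFFERENT_CHROMOSOME}, \code{UNKNOWN}.
#' @export
classifyPairLocation <- function(chrom_a, chrom_b) {
  unknown <- is.na(chrom_a) | is.na(chrom_b) |
    grepl("^scaffold", chrom_a, ignore.case = TRUE) |
    grepl("^scaffold", chrom_b, ignore.case = TRUE)
  if (any(unknown))
    warning(sum(unknown), " pair(s) with unplaced/missing chromosome -> UNKNOWN")
  out <- ifelse(chrom_a == chrom_b, "SAME_CHROMOSOME", "DIFFERENT_CHROMOSOME")
  out[unknown] <- "UNKNOWN"
  out
}

#' Test association between specialization and genomic co-location
#'
#' 2x2 contingency test of specialized (yes/no) against same-chromosome
#' (yes/no), excluding pairs with UNKNOWN location. Pearson chi-square is
#' used unless a cell is empty, in which case Fisher's exact test is the
#' fallback.
#'
#' @param specialized logical vector per pair.
#' @param location output of \code{\link{classifyPairLocation}}.
#' @return A \code{\link{TestResult}}; its \code{estimate} is the odds
#'   ratio of being same-chromosome among specialized vs non-specialized.
#' @export
compareLocationDistribution <- function(specialized, location) {
  keep <- location != "UNKNOWN"
  s <- specialized[keep]
  same <- location[keep] == "SAME_CHROMOSOME"
  tab <- matrix(c(sum(s & same), sum(s & !same),
                  sum(!s & same), sum(!s & !same)), nrow = 2, byrow = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (any(tab == 0)) {
    ht <- stats::fisher.test(tab)
    return(TestResult(NA_real_, ht$p.value, NA_real_, "two_sided",
                      "fisher_exact", estimate = unname(ht$estimate)))
  }
  r <- chiSquare2x2(tab)
  r$estimate <- or
  r
}

#' Cross-species correlation of diapause expression programs
#'
#' Spearman correlation of per-gene diapause-vs-development log fold
#' changes between two species over their one-to-one orthologs.
#'
#' @param ortholog_map data.frame with columns \code{gene_a}, \code{gene_b}
#'   linking genes of species A to orthologs in species B.
#' @param lfc_a,lfc_b named numeric vectors of log fold changes, names are
#'   gene ids in the respective species.
#' @return A \code{\link{TestResult}} with \code{estimate} = rho and an
#'   extra element \code{n} (orthologs used).
#' @export
crossSpeciesProgramCorrelation <- function(ortholog_map, lfc_a, lfc_b) {
  a <- lfc_a[ortholog_map$gene_a]
  b <- lfc_b[ortholog_map$gene_b]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("crossSpeciesProgramCorrelation: fewer than 3 shared orthologs")
  r <- spearmanCor(unname(a[ok]), unname(b[ok]))
  r$n <- sum(ok)
  r
}

#' Genes uniquely regulated in the focal species
#'
#' Focal significant genes whose orthologs are not significant (or have no
#' ortholog) in every other species provided.
#'
#' @param de_sets named list of significant gene-id sets; must contain
#'   \code{focal}.
#' @param ortholog_maps named list (one per non-focal species in
#'   \code{de_sets}) of data.frames with columns \code{focal_gene},
#'   \code{other_gene}.
#' @param focal name of the focal species in \code{de_sets} (default
#'   \code{"focal"}).
#' @return character vector of uniquely regulated focal genes.
#' @export
uniquelyRegulatedGenes <- function(de_sets, ortholog_maps,
                                   focal = "focal") {
  if (!focal %in% names(de_sets))
    stop("uniquelyRegulatedGenes: focal species missing from de_sets")
  others <- setdiff(names(de_sets), focal)
  out <- de_sets[[focal]]
  for (sp in others) {
    m <- ortholog_maps[[sp]]
    if (is.null(m))
      stop("uniquelyRegulatedGenes: no ortholog map for species ", sp)
    hit_focal <- m$focal_gene[m$other_gene %in% de_sets[[sp]]]
    out <- setdiff(out, hit_focal)
  }
  out
}
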