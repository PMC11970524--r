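#' @title Transcription-factor knockout program analysis
#' @description Quantifies how a CRISPR knockout of a transcription factor
#'   moves the embryonic transcriptome relative to the diapause program:
#'   differentially expressed genes are called against both controls
#'   (scramble-injected and non-injected wildtype) and the knockout
#'   fold-change vector is correlated with the control
#'   diapause-vs-development program. A negative rank correlation means
#'   the knockout shifts diapause embryos toward a development-like
#'   state; a positive one means the program is enhanced.
#' @name ko-program
NULL

.group_samples <- function(samples, genotype, state) {
  samples$sample_id[samples$genotype == genotype & samples$state == state]
}

#' Dual-control differentially expressed genes
#'
#' A gene is a knockout DEG only when it is significant at
#' \code{padj < fdr} against BOTH controls (scramble and wildtype), with
#' concordant fold-change sign; this removes injection artifacts that
#' show up against only one control. The differential engine is the
#' row-wise Welch test on log2 expression with BH adjustment; externally
#' computed tables with the same schema can replace it.
#'
#' @param expr normalized expression matrix, genes x samples.
#' @param samples data.frame with \code{sample_id}, \code{genotype}
#'   (\code{"WILDTYPE"}, \code{"SCRAMBLE"} or \code{"KO:<gene>"}),
#'   \code{state} (\code{"DIAPAUSE"}/\code{"DEVELOPMENT"}).
#' @param tf knocked-out transcription factor name (genotype
#'   \code{"KO:<tf>"}).
#' @param state embryo state analyzed (default \code{"DIAPAUSE"}).
#' @param fdr DEG threshold on adjusted p-values (default 0.1).
#' @param log_offset pseudocount before log2.
#' @return data.frame per gene: lfc and padj against each control,
#'   \code{is_deg}.
#' @export
callDualControlDegs <- function(expr, samples, tf, state = "DIAPAUSE",
                                fdr = 0.1, log_offset = 1) {
  expr <- as.matrix(expr)
  ko <- .group_samples(samples, paste0("KO:", tf), state)
  sc <- .group_samples(samples, "SCRAMBLE", state)
  wt <- .group_samples(samples, "WILDTYPE", state)
  if (length(ko) < 3L || length(sc) < 3L || length(wt) < 3L)
    stop("callDualControlDegs: every group needs >= 3 samples (ko=",
         length(ko), ", scramble=", length(sc), ", wildtype=",
         length(wt), ")")
  le <- log2(expr + log_offset)
  vs_sc <- rowWelchTest(le[, ko, drop = FALSE], le[, sc, drop = FALSE])
  vs_wt <- rowWelchTest(le[, ko, drop = FALSE], le[, wt, drop = FALSE])
  padj_sc <- bhAdjust(vs_sc$p_value)$adjusted
  padj_wt <- bhAdjust(vs_wt$p_value)$adjusted
  data.frame(
    gene = rownames(expr),
    lfc_vs_scramble = vs_sc$mean_diff, padj_vs_scramble = padj_sc,
    lfc_vs_wildtype = vs_wt$mean_diff, padj_vs_wildtype = padj_wt,
    is_deg = padj_sc < fdr & padj_wt < fdr &
      sign(vs_sc$mean_diff) == sign(vs_wt$mean_diff),
    row.names = NULL)
}

#' Contrast fold changes for the program-shift correlation
#'
#' Computes the two log fold-change vectors the program-shift test
#' correlates: the control (wildtype + scramble) diapause-vs-development
#' program, and the knockout-vs-scramble change within diapause.
#'
#' @inheritParams callDualControlDegs
#' @return A list with named numeric vectors \code{control_lfc} and
#'   \code{ko_lfc} (log2).
#' @export
koContrasts <- function(expr, samples, tf, log_offset = 1) {
  expr <- as.matrix(expr)
  le <- log2(expr + log_offset)
  ctrl_dia <- c(.group_samples(samples, "WILDTYPE", "DIAPAUSE"),
                .group_samples(samples, "SCRAMBLE", "DIAPAUSE"))
  ctrl_dev <- c(.group_samples(samples, "WILDTYPE", "DEVELOPMENT"),
                .group_samples(samples, "SCRAMBLE", "DEVELOPMENT"))
  ko_dia <- .group_samples(samples, paste0("KO:", tf), "DIAPAUSE")
  sc_dia <- .group_samples(samples, "SCRAMBLE", "DIAPAUSE")
  if (!length(ctrl_dia) || !length(ctrl_dev) || !length(ko_dia))
    stop("koContrasts: missing sample group(s)")
  control_lfc <- rowMeans(le[, ctrl_dia, drop = FALSE]) -
    rowMeans(le[, ctrl_dev, drop = FALSE])
  ko_lfc <- rowMeans(le[, ko_dia, drop = FALSE]) -
    rowMeans(le[, sc_dia, drop = FALSE])
  list(control_lfc = control_lfc, ko_lfc = ko_lfc)
}

#' Program-shift classification
#'
#' Spearman correlation between the knockout-vs-control fold changes of
#' DEGs in diapause and the control diapause-vs-development fold changes
#' of the same genes. \code{p >= alpha} gives NO_EFFECT; otherwise a
#' positive rho is ENHANCED and a negative rho REVERSED (the diapause
#' program collapses toward development).
#'
#' @param ko_lfc,control_lfc named numeric vectors over the same genes
#'   (the DEG set); >= 3 shared genes required.
#' @param alpha significance level (default 0.05).
#' @return A list: \code{n_genes}, \code{rho}, \code{p},
#'   \code{classification}.
#' @export
programShift <- function(ko_lfc, control_lfc, alpha = 0.05) {
  genes <- intersect(names(ko_lfc), names(control_lfc))
  if (is.null(names(ko_lfc)) || is.null(names(control_lfc))) {
    if (length(ko_lfc) != length(control_lfc))
      stop("programShift: unnamed vectors of unequal length")
    genes <- seq_along(ko_lfc)
    x <- ko_lfc; y <- control_lfc
  } else {
    x <- ko_lfc[genes]; y <- control_lfc[genes]
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("programShift: fewer than 3 usable genes")
  r <- spearmanCor(unname(x[ok]), unname(y[ok]))
  cls <- if (is.na(r$p_value) || r$p_value >= alpha) "NO_EFFECT"
         else if (r$estimate > 0) "ENHANCED" else "REVERSED"
  list(n_genes = sum(ok), rho = r$estimate, p = r$p_value,
       classification = cls)
}

#' Specialization shift of paralog pairs under knockout
#'
#' For every diapause-specialized paralog pair, takes the median
#' expression (log2) of the diapause-role gene and of the
#' development-role gene across the control (wildtype + scramble) and
#' knockout diapause samples, then fits a two-way ANOVA with factors
#' gene-role x genotype over pairs. The interaction term tests whether
#' the degree of specialization (diapause-gene minus development-gene
#' median) differs between knockout and control.
#'
#' @param pairs data.frame with \code{pair_id}, \code{diapause_gene},
#'   \code{development_gene} (>= 2 pairs).
#' @param expr normalized expression matrix, genes x samples.
#' @param samples sample sheet (see \code{\link{callDualControlDegs}}).
#' @param tf knocked-out transcription factor.
#' @param state embryo state (default \code{"DIAPAUSE"}).
#' @param log_offset pseudocount before log2.
#' @return A list: \code{table} (long data.frame pair x role x genotype
#'   with the median values), \code{gap_control}, \code{gap_ko} (mean
#'   specialization gaps), \code{anova} (the three
#'   \code{\link{TestResult}}s), \code{interaction_p}.
#' @export
specializationShift <- function(pairs, expr, samples, tf,
                                state = "DIAPAUSE", log_offset = 1) {
  if (nrow(pairs) < 2L) stop("specializationShift: need >= 2 pairs")
  if (anyNA(pairs$diapause_gene) || anyNA(pairs$development_gene))
    stop("specializationShift: missing role assignment")
  expr <- as.matrix(expr)
  le <- log2(expr + log_offset)
  ctrl <- c(.group_samples(samples, "WILDTYPE", state),
            .group_samples(samples, "SCRAMBLE", state))
  ko <- .group_samples(samples, paste0("KO:", tf), state)
  if (!length(ctrl) || !length(ko))
    stop("specializationShift: both genotype groups must be present")
  med <- function(genes, cols)
    apply(le[genes, cols, drop = FALSE], 1, stats::median)
  long <- rbind(
    data.frame(pair = pairs$pair_id, role = "DIAPAUSE_GENE",
               genotype = "CONTROL",
               value = med(pairs$diapause_gene, ctrl)),
    data.frame(pair = pairs$pair_id, role = "DEVELOPMENT_GENE",
               genotype = "CONTROL",
               value = med(pairs$development_gene, ctrl)),
    data.frame(pair = pairs$pair_id, role = "DIAPAUSE_GENE",
               genotype = "KO", value = med(pairs$diapause_gene, ko)),
    data.frame(pair = pairs$pair_id, role = "DEVELOPMENT_GENE",
               genotype = "KO", value = med(pairs$development_gene, ko)))
  rownames(long) <- NULL
  gap <- function(g) {
    d <- long[long$genotype == g, ]
    mean(d$value[d$role == "DIAPAUSE_GENE"]) -
      mean(d$value[d$role == "DEVELOPMENT_GENE"])
  }
  an <- twoWayAnova(long$value, long$role, long$genotype)
  list(table = long, gap_control = gap("CONTROL"), gap_ko = gap("KO"),
       anova = an, interaction_p = an$interaction$p_value)
}
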