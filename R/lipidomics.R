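#' @title Untargeted lipidomics: normalization and diapause-specific lipids
#' @description Parses lipid shorthand names into class and acyl chains,
#'   median-normalizes molar concentrations (excluding storage lipids TG
#'   and DG from the factor computation), classifies diapause-specific
#'   lipids with Welch tests and BH correction, flags very-long-chain
#'   species (any acyl chain of 22 or more carbons), and summarizes class
#'   concentrations and fatty-acid composition with SFA/MUFA/PUFA
#'   grouping.
#' @name lipidomics
NULL

LIPID_CONDITIONS <- c("PRE_DIA", "DEV", "DIA_6D", "DIA_1M")

# expected acyl-chain counts per class; single-chain notation for a
# multi-chain class is "summed" shorthand (total carbons:double bonds)
.CLASS_CHAINS <- c(TG = 3L, DG = 2L, MG = 1L, PC = 2L, PE = 2L, PI = 2L,
                   PS = 2L, PG = 2L, PA = 2L, LPC = 1L, LPE = 1L,
                   SM = 2L, Cer = 2L, ChE = 1L)

#' Parse a lipid shorthand name
#'
#' Accepts \code{CLASS(c1:d1/c2:d2/...)} per-chain notation and
#' \code{CLASS(c:d)} summed notation, with optional ether/plasmalogen
#' prefixes (\code{O-}, \code{P-}) preserved per chain. A single chain
#' given for a class that carries several (e.g. \code{PC(38:6)}) is kept
#' as one pseudo-chain flagged \code{summed}.
#'
#' @param name lipid name string.
#' @return A list: \code{name}, \code{lipid_class}, \code{chains}
#'   (data.frame \code{carbons}, \code{double_bonds}, \code{prefix}),
#'   \code{summed}.
#' @export
parseLipidName <- function(name) {
  m <- regmatches(name,
                  regexec("^([A-Za-z]+)\\(([^()]+)\\)$", name))[[1]]
  if (length(m) != 3L)
    stop("unparseable lipid name: '", name, "'")
  cls <- m[2]
  toks <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  cm <- regmatches(toks, regexec("^([OP]-)?([0-9]+):([0-9]+)$", toks))
  bad <- vapply(cm, length, integer(1)) != 4L
  if (any(bad))
    stop("unparseable chain token '", toks[bad][1], "' in '", name, "'")
  chains <- data.frame(
    carbons = as.integer(vapply(cm, `[`, "", 3)),
    double_bonds = as.integer(vapply(cm, `[`, "", 4)),
    prefix = vapply(cm, `[`, "", 2))
  if (any(chains$carbons <= 0))
    stop("chain with zero carbons in '", name, "'")
  expected <- .CLASS_CHAINS[cls]
  summed <- !is.na(expected) && expected > 1L && nrow(chains) == 1L
  list(name = name, lipid_class = cls, chains = chains,
       summed = summed)
}

#' Format a parsed lipid back to its canonical name
#'
#' Inverse of \code{\link{parseLipidName}} (round-trip identity).
#'
#' @param species a parsed lipid list.
#' @return character name.
#' @export
formatLipidName <- function(species) {
  ch <- species$chains
  paste0(species$lipid_class, "(",
         paste0(ch$prefix, ch$carbons, ":", ch$double_bonds,
                collapse = "/"), ")")
}

#' Very-long-chain flag
#'
#' TRUE when any parsed acyl chain has 22 or more carbons (e.g. 22:6,
#' docosahexaenoic acid). Summed-notation lipids are undetermined
#' (\code{NA}): the total carbon count cannot be attributed to a single
#' chain.
#'
#' @param species a parsed lipid (see \code{\link{parseLipidName}}).
#' @return logical, or \code{NA} for summed notation.
#' @export
isVeryLongChain <- function(species) {
  if (isTRUE(species$summed)) return(NA)
  any(species$chains$carbons >= 22L)
}

#' Median normalization of a lipid concentration matrix
#'
#' Corrects for differences in starting material: each sample is rescaled
#' so that its median concentration over non-excluded lipids (storage
#' classes TG and DG are excluded from the factor computation because
#' they change biologically) equals the grand median of those per-sample
#' medians. The factor applies to ALL lipids of the sample, excluded
#' classes included. Idempotent.
#'
#' @param mat lipid x sample concentration matrix (rownames are lipid
#'   names).
#' @param classes character vector of lipid classes, one per row.
#' @param exclude_classes classes excluded from the factor computation
#'   (default TG and DG).
#' @return normalized matrix; attribute \code{factors} holds the
#'   per-sample scale factors.
#' @export
medianNormalize <- function(mat, classes, exclude_classes = c("TG", "DG")) {
  mat <- as.matrix(mat)
  keep <- !(classes %in% exclude_classes)
  if (!any(keep))
    stop("medianNormalize: no non-excluded lipids")
  med <- apply(mat[keep, , drop = FALSE], 2, stats::median)
  if (any(med == 0)) stop("medianNormalize: a sample median is zero")
  target <- stats::median(med)
  f <- target / med
  out <- sweep(mat, 2, f, "*")
  attr(out, "factors") <- f
  out
}

#' Classify diapause-specific lipids
#'
#' Welch tests (on log2 concentrations) for every diapause x development
#' condition pair plus the development-vs-development pair, each
#' BH-adjusted across lipids. A lipid is diapause-specific when it is
#' significant with a consistent fold-change sign in at least one
#' diapause-vs-development comparison (\code{mode = "any_consistent"},
#' default; \code{"all"} requires all four) AND the two development
#' conditions do not differ significantly.
#'
#' @param mat lipid x sample concentration matrix.
#' @param conditions named character vector sample -> condition, levels
#'   \code{PRE_DIA}, \code{DEV}, \code{DIA_6D}, \code{DIA_1M}; >= 2
#'   samples per condition.
#' @param alpha significance threshold on adjusted p-values
#'   (default 0.05).
#' @param mode \code{"any_consistent"} or \code{"all"}.
#' @return data.frame: lipid, diapause_specific, direction (UP/DOWN in
#'   diapause), plus the q-value of every comparison.
#' @export
classifyDiapauseLipids <- function(mat, conditions, alpha = 0.05,
                                   mode = c("any_consistent", "all")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  conditions <- conditions[colnames(mat)]
  if (anyNA(conditions)) stop("every sample needs a condition label")
  counts <- table(factor(conditions, levels = LIPID_CONDITIONS))
  if (any(counts < 2L))
    stop("every condition needs >= 2 samples")
  lm_ <- log2(mat)
  cols <- function(cond) which(conditions == cond)
  dia <- c("DIA_6D", "DIA_1M"); dev <- c("PRE_DIA", "DEV")
  comp <- expand.grid(dia = dia, dev = dev, stringsAsFactors = FALSE)
  q <- sgn <- matrix(NA_real_, nrow(mat), nrow(comp))
  for (i in seq_len(nrow(comp))) {
    w <- rowWelchTest(lm_[, cols(comp$dia[i]), drop = FALSE],
                      lm_[, cols(comp$dev[i]), drop = FALSE])
    q[, i] <- bhAdjust(w$p_value)$adjusted
    sgn[, i] <- sign(w$mean_diff)
  }
  wdev <- rowWelchTest(lm_[, cols("PRE_DIA"), drop = FALSE],
                       lm_[, cols("DEV"), drop = FALSE])
  q_dev <- bhAdjust(wdev$p_value)$adjusted

  sig <- q < alpha
  n_sig <- rowSums(sig)
  consistent <- vapply(seq_len(nrow(mat)), function(i) {
    s <- sgn[i, sig[i, ]]
    length(s) > 0L && length(unique(s)) == 1L
  }, logical(1))
  hit <- if (mode == "all") n_sig == nrow(comp) & consistent
         else n_sig >= 1L & consistent
  specific <- hit & q_dev >= alpha
  direction <- rep(NA_character_, nrow(mat))
  direction[specific] <- ifelse(
    vapply(which(specific), function(i) sgn[i, sig[i, ]][1], numeric(1)) > 0,
    "UP", "DOWN")
  out <- data.frame(lipid = rownames(mat), diapause_specific = specific,
                    direction = direction, row.names = NULL)
  colnames(q) <- paste0("q_", comp$dia, "_vs_", comp$dev)
  cbind(out, as.data.frame(q), q_dev_vs_dev = q_dev)
}

#' Per-class concentration sums
#'
#' @param mat lipid x sample matrix.
#' @param classes lipid class per row.
#' @return class x sample matrix of summed molar concentrations.
#' @export
classConcentrations <- function(mat, classes) {
  rowsum(as.matrix(mat), group = classes)
}

#' Fatty-acid composition of a lipid class
#'
#' Each acyl-chain occurrence of a (non-summed) lipid in the class
#' contributes its parent lipid's molar concentration; the fraction of a
#' fatty acid is its summed contribution over the total across fatty
#' acids of the class (per sample, fractions sum to 1). Chains are also
#' grouped by saturation: SFA (0 double bonds), MUFA (1), PUFA (>= 2).
#'
#' @param mat lipid x sample matrix.
#' @param species list of parsed lipids (one per row of \code{mat}).
#' @param lipid_class class to summarize.
#' @return A list: \code{fa_fraction} (fatty acid x sample),
#'   \code{saturation_fraction} (SFA/MUFA/PUFA x sample).
#' @export
fattyAcidComposition <- function(mat, species, lipid_class) {
  mat <- as.matrix(mat)
  idx <- which(vapply(species, function(s)
    s$lipid_class == lipid_class && !isTRUE(s$summed), logical(1)))
  if (!length(idx))
    stop("fattyAcidComposition: class '", lipid_class,
         "' has no non-summed lipids")
  rows <- lapply(idx, function(i) {
    ch <- species[[i]]$chains
    data.frame(fa = paste0(ch$carbons, ":", ch$double_bonds),
               db = ch$double_bonds, lipid = i)
  })
  occ <- do.call(rbind, rows)
  contrib <- mat[occ$lipid, , drop = FALSE]
  fa_sum <- rowsum(contrib, group = occ$fa)
  total <- colSums(fa_sum)
  sat <- ifelse(occ$db == 0, "SFA", ifelse(occ$db == 1, "MUFA", "PUFA"))
  sat_sum <- rowsum(contrib, group = factor(sat,
                                            levels = c("SFA", "MUFA", "PUFA")))
  list(fa_fraction = sweep(fa_sum, 2, total, "/"),
       saturation_fraction = sweep(sat_sum, 2, total, "/"))
}
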