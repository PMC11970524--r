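# Independent brute-force oracles and shared fixtures for the test suite.
# Every oracle is written as plainly as possible (scalar loops, no package
# internals) so it stays independent of the implementation it checks.

# a strongly informative 10-position motif used across motif tests
makeTestPWM <- function(threshold_fraction = 0.7) {
  cons <- c("T", "G", "A", "C", "C", "A", "C", "G", "T", "G")
  p <- matrix(0.04, 10, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(cons)) p[i, cons[i]] <- 0.88
  full <- PWMotif("TESTTF", p, 0)
  PWMotif("TESTTF", p, threshold_fraction * maxScore(full))
}

randomPWM <- function(len) {
  p <- matrix(stats::rexp(len * 4), len, 4)
  p <- p / rowSums(p)
  colnames(p) <- c("A", "C", "G", "T")
  PWMotif("RND", p, 0)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-position log-odds score with the 0.001 probability floor
oracleScore <- function(probs, seq) {
  bases <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in seq_along(bases)) {
    j <- match(bases[i], c("A", "C", "G", "T"))
    if (is.na(j)) return(NA_real_)
    s <- s + log(max(probs[i, j], 0.001) / 0.25)
  }
  s
}

oracleRevcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# all-offset scan on both strands, scalar loops
oracleScan <- function(probs, threshold, seq) {
  n <- nrow(probs)
  L <- nchar(seq)
  hits <- list()
  for (o in 0:(L - n)) {
    sub <- substr(seq, o + 1, o + n)
    s <- oracleScore(probs, sub)
    if (!is.na(s) && s >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = s)
    sm <- oracleScore(probs, oracleRevcomp(sub))
    if (!is.na(sm) && sm >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "-",
                                             score = sm)
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# brute-force projection of one interval through a block table
# (0-based half-open), returning merged fragments sorted like the
# implementation output
oracleProject <- function(chrom, start, end, blocks, species) {
  b <- blocks[blocks$species == species, , drop = FALSE]
  frs <- list()
  for (i in seq_len(nrow(b))) {
    if (b$focal_chrom[i] != chrom) next
    os <- max(start, b$focal_start[i]); oe <- min(end, b$focal_end[i])
    if (os >= oe) next
    if (b$strand[i] == "+") {
      ts <- b$target_start[i] + (os - b$focal_start[i])
      te <- b$target_start[i] + (oe - b$focal_start[i])
    } else {
      ts <- b$target_start[i] + (b$focal_end[i] - oe)
      te <- b$target_start[i] + (b$focal_end[i] - os)
    }
    frs[[length(frs) + 1]] <- data.frame(chrom = b$target_chrom[i],
                                         start = ts, end = te,
                                         strand = b$strand[i])
  }
  if (!length(frs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  fr <- do.call(rbind, frs)
  fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
  # merge adjacent (gap 0) fragments on the same chrom/strand
  out <- fr[1, , drop = FALSE]
  if (nrow(fr) > 1) for (i in 2:nrow(fr)) {
    j <- nrow(out)
    if (fr$chrom[i] == out$chrom[j] && fr$strand[i] == out$strand[j] &&
        fr$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], fr$end[i])
    } else out <- rbind(out, fr[i, ])
  }
  rownames(out) <- NULL
  out
}

# brute-force nearest-TSS assignment with the deterministic tie-break
oracleNearestGene <- function(peak, genes) {
  g <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA, distance = NA))
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  d <- pmax(0L, peak$start - tss, tss - (peak$end - 1L))
  o <- order(d, g$start, g$gene_id)
  list(gene_id = g$gene_id[o[1]], distance = d[o[1]])
}

# hand conservation-category oracle over presence flags
oracleCategory <- function(flag_by_species, roles) {
  afr <- names(roles)[roles == "AFRICAN_KILLIFISH"]
  outg <- names(roles)[roles == "OUTGROUP"]
  if (any(flag_by_species[outg])) "ANCIENT_VERY_ANCIENT"
  else if (any(flag_by_species[afr])) "RECENT"
  else "VERY_RECENT"
}

randomIntervals <- function(n, chroms = "chr1", max_pos = 100000L,
                            width_range = c(50L, 400L)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w)
}
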