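roles4 <- c(nfur = "FOCAL", aaus = "AFRICAN_KILLIFISH",
            astr = "AFRICAN_KILLIFISH", olat = "OUTGROUP",
            drer = "OUTGROUP")

test_that("projection: single block identity, splits, and misses", {
  blocks <- data.frame(
    focal_chrom = "chr1", focal_start = c(1000L, 5000L),
    focal_end = c(2000L, 6000L), species = "aaus",
    target_chrom = c("chrA", "chrB"), target_start = c(100L, 700L),
    target_end = c(1100L, 1700L), strand = "+")
  map <- AlignmentBlockMap(blocks)

  one <- projectInterval("chr1", 1200, 1300, map, "aaus")
  expect_false(one$split)
  expect_equal(one$fragments$start, 300L)
  expect_equal(one$fragments$end, 400L)

  # spanning two blocks mapping to different chromosomes
  two <- projectInterval("chr1", 1900, 5100, map, "aaus")
  expect_true(two$split)
  expect_equal(nrow(two$fragments), 2L)
  expect_setequal(two$fragments$chrom, c("chrA", "chrB"))

  none <- projectInterval("chr1", 3000, 3100, map, "aaus")
  expect_equal(nrow(none$fragments), 0L)
  expect_false(none$split)
})

test_that("minus-strand projection reverses coordinates and round-trips", {
  map <- AlignmentBlockMap(data.frame(
    focal_chrom = "chr1", focal_start = 100L, focal_end = 200L,
    species = "aaus", target_chrom = "chrZ", target_start = 1000L,
    target_end = 1100L, strand = "-"))
  p <- projectInterval("chr1", 110, 130, map, "aaus")
  # focal [110,130) sits 10 from block start; on '-' it lands 10 from the
  # block end: [1000 + (200-130), 1000 + (200-110)) = [1070, 1090)
  expect_equal(p$fragments$start, 1070L)
  expect_equal(p$fragments$end, 1090L)
  back <- projectInterval("chrZ", 1070, 1090, map, "aaus",
                          direction = "target_to_focal")
  expect_equal(back$fragments$start, 110L)
  expect_equal(back$fragments$end, 130L)
})

test_that("adjacent projected fragments merge; disjoint ones flag split", {
  # two blocks adjacent on the target: projection must merge, not split
  map <- AlignmentBlockMap(data.frame(
    focal_chrom = "chr1", focal_start = c(0L, 500L),
    focal_end = c(100L, 600L), species = "aaus", target_chrom = "chrA",
    target_start = c(0L, 100L), target_end = c(100L, 200L),
    strand = "+"))
  # interval covering the tails of both blocks
  p <- projectIntervals(data.frame(chrom = "chr1", start = 50, end = 550),
                        map, "aaus")
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(50L, 150L))
})

test_that("projection agrees with a brute-force oracle on random maps", {
  set.seed(77)
  # random non-overlapping focal blocks with random strands/targets
  starts <- sort(sample.int(500000, 120)) * 10L
  blocks <- data.frame(
    focal_chrom = "chr1", focal_start = starts,
    focal_end = starts + sample(50:900, 120, replace = TRUE),
    species = "aaus",
    target_chrom = sample(c("cA", "cB", "cC"), 120, replace = TRUE),
    target_start = sample.int(1000000, 120),
    strand = sample(c("+", "-"), 120, replace = TRUE))
  blocks$focal_end <- pmin(blocks$focal_end, c(starts[-1], Inf))
  blocks <- blocks[blocks$focal_end > blocks$focal_start, ]
  blocks$target_end <- blocks$target_start +
    (blocks$focal_end - blocks$focal_start)
  map <- AlignmentBlockMap(blocks)
  iv <- randomIntervals(300, max_pos = 5100000L, width_range = c(20L, 2000L))
  pr <- projectIntervals(iv, map, "aaus")
  for (q in seq_len(nrow(iv))) {
    got <- pr[pr$query == q, c("chrom", "start", "end", "strand")]
    rownames(got) <- NULL
    want <- oracleProject(iv$chrom[q], iv$start[q], iv$end[q],
                          blocks, "aaus")
    want$start <- as.integer(want$start); want$end <- as.integer(want$end)
    expect_equal(got, want)
  }
})

test_that("round trip focal -> species -> focal is the identity in-block", {
  set.seed(13)
  starts <- sort(sample.int(100000, 60)) * 20L
  blocks <- data.frame(
    focal_chrom = "chr1", focal_start = starts,
    focal_end = starts + sample(100:800, 60, replace = TRUE),
    species = "aaus", target_chrom = "cT",
    target_start = seq(0L, by = 1000000L, length.out = 60),
    strand = sample(c("+", "-"), 60, replace = TRUE))
  blocks$focal_end <- pmin(blocks$focal_end, c(starts[-1], Inf))
  blocks$target_end <- blocks$target_start +
    (blocks$focal_end - blocks$focal_start)
  map <- AlignmentBlockMap(blocks)
  for (r in 1:200) {
    b <- blocks[sample.int(nrow(blocks), 1), ]
    w <- b$focal_end - b$focal_start
    s <- b$focal_start + sample.int(w, 1) - 1L
    e <- s + sample.int(b$focal_end - s, 1)
    fwd <- projectInterval("chr1", s, e, map, "aaus")
    expect_equal(nrow(fwd$fragments), 1L)
    back <- projectInterval(fwd$fragments$chrom, fwd$fragments$start,
                            fwd$fragments$end, map, "aaus",
                            "target_to_focal")
    expect_equal(back$fragments$start, s)
    expect_equal(back$fragments$end, e)
  }
})

test_that("conservation stringencies use inclusive coverage thresholds", {
  focal <- data.frame(chrom = "chr1", start = 1000L, end = 1200L)  # 200 bp
  cover <- function(bp) list(aaus = data.frame(
    chrom = "chr1", start = 1000L, end = 1000L + bp))
  expect_true(tagConserved(focal, cover(1), "RELAXED")[1, 1])
  expect_false(tagConserved(focal, cover(40), "STRICT")[1, 1])   # 20%
  expect_true(tagConserved(focal, cover(50), "STRICT")[1, 1])    # 25%
  expect_false(tagConserved(focal, cover(99), "VERY_STRICT")[1, 1])
  expect_true(tagConserved(focal, cover(100), "VERY_STRICT")[1, 1])  # 50%
  # coverage is over the union: two 30 bp pieces pass STRICT together
  split_peaks <- list(aaus = data.frame(
    chrom = "chr1", start = c(1000L, 1100L), end = c(1030L, 1130L)))
  expect_true(tagConserved(focal, split_peaks, "STRICT")[1, 1])
})

test_that("category logic matches the 16-combination hand oracle", {
  others <- setdiff(names(roles4), "nfur")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  names(combos) <- others
  flags <- cbind(as.matrix(combos), nfur = TRUE)
  got <- classifyConservation(flags, roles4)
  for (i in seq_len(nrow(combos))) {
    expect_equal(as.character(got[i]),
                 oracleCategory(unlist(combos[i, ]), roles4))
  }
  # spot checks straight from the rule definitions
  expect_equal(as.character(classifyConservation(
    cbind(nfur = TRUE, aaus = FALSE, astr = FALSE, olat = FALSE,
          drer = FALSE), roles4)), "VERY_RECENT")
  expect_equal(as.character(classifyConservation(
    cbind(nfur = TRUE, aaus = TRUE, astr = FALSE, olat = FALSE,
          drer = FALSE), roles4)), "RECENT")
  # outgroup-exception: absent in African killifish, present in zebrafish
  expect_equal(as.character(classifyConservation(
    cbind(nfur = TRUE, aaus = FALSE, astr = FALSE, olat = FALSE,
          drer = TRUE), roles4)), "ANCIENT_VERY_ANCIENT")
  expect_error(classifyConservation(
    cbind(nfur = FALSE, aaus = TRUE, astr = TRUE, olat = TRUE,
          drer = TRUE), roles4), "focal")
})

test_that("stringency monotonicity holds on random peak sets", {
  set.seed(55)
  for (r in 1:60) {
    focal <- randomIntervals(20, max_pos = 20000L)
    projected <- list(aaus = randomIntervals(30, max_pos = 20000L),
                      drer = randomIntervals(10, max_pos = 20000L))
    vs <- tagConserved(focal, projected, "VERY_STRICT")
    st <- tagConserved(focal, projected, "STRICT")
    rx <- tagConserved(focal, projected, "RELAXED")
    expect_true(all(st[vs]))  # very strict implies strict
    expect_true(all(rx[st]))  # strict implies relaxed
  }
})

test_that("generator truth is recovered for categories, splits, sequence", {
  pk <- genPeakUniverse(n_peaks = 400, split_fraction = 0.1, seed = 8)
  pc <- peakConservationPipeline(pk$focal_peaks, pk$species_peaks,
                                 pk$map, pk$roles, "RELAXED")
  expect_equal(as.character(pc$calls$category),
               as.character(pk$truth$category))
  for (sp in names(pk$species_peaks))
    expect_equal(pc$split[[sp]], pk$species_peaks[[sp]]$split_truth)
  sq <- classifySequenceConservation(pk$focal_peaks, pk$map, pk$roles)
  expect_equal(as.character(sq$category), as.character(pk$truth$category))
  # all-very-recent corner: no other species ever conserved
  vr <- genPeakUniverse(n_peaks = 50,
                        category_proportions = c(
                          ANCIENT_VERY_ANCIENT = 0, RECENT = 0,
                          VERY_RECENT = 1), seed = 2)
  pcv <- peakConservationPipeline(vr$focal_peaks, vr$species_peaks,
                                  vr$map, vr$roles, "RELAXED")
  expect_true(all(pcv$calls$category == "VERY_RECENT"))
})

test_that("diapause-specific peak selection implements the two-method rule", {
  mk <- function(peak, contrast, type, method, sig, fc)
    data.frame(peak_id = peak, contrast = contrast, contrast_type = type,
               method = method, significant = sig, log2fc = fc)
  grid <- function(peak, dia1_a, dia1_b, dev_a, dev_b,
                   fc_dia = 1, fc_dev = 0.2) rbind(
    mk(peak, "dia6_vs_dev", "DIAPAUSE", "A", dia1_a, fc_dia),
    mk(peak, "dia6_vs_dev", "DIAPAUSE", "B", dia1_b, fc_dia),
    mk(peak, "dev_vs_dev", "DEVELOPMENT", "A", dev_a, fc_dev),
    mk(peak, "dev_vs_dev", "DEVELOPMENT", "B", dev_b, fc_dev))
  calls <- rbind(
    grid("p_up_oneMethod", TRUE, FALSE, FALSE, FALSE),
    grid("p_devBoth", TRUE, TRUE, TRUE, TRUE),
    grid("p_devOne", TRUE, TRUE, TRUE, FALSE),
    grid("p_down", TRUE, TRUE, FALSE, FALSE, fc_dia = -2),
    grid("p_clean", TRUE, TRUE, FALSE, FALSE))
  sel <- selectDiapauseSpecificPeaks(calls)
  expect_setequal(sel, c("p_up_oneMethod", "p_clean"))
  # flipped development rule: only rejection by both methods counts
  sel2 <- selectDiapauseSpecificPeaks(calls, dev_both = FALSE)
  expect_setequal(sel2, c("p_up_oneMethod", "p_clean", "p_devOne"))
  expect_error(selectDiapauseSpecificPeaks(calls[-1, ]), "both methods")
})

test_that("nearest-gene assignment matches brute force with tie-breaks", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"),
                      chrom = "chr1", start = c(5000L, 1000L, 9000L),
                      end = c(6000L, 2000L, 9500L),
                      strand = c("+", "+", "-"))
  # peak overlapping gA's TSS
  r <- assignPeakToGene(data.frame(chrom = "chr1", start = 900L,
                                   end = 1100L), genes)
  expect_equal(r$gene_id, "gA")
  expect_equal(r$distance, 0L)
  # equidistant between gA (TSS 1000) and gB (TSS 5000): gA wins (start)
  r2 <- assignPeakToGene(data.frame(chrom = "chr1", start = 2999L,
                                    end = 3001L), genes)
  expect_equal(r2$gene_id, "gA")
  set.seed(99)
  genes_r <- data.frame(gene_id = sprintf("g%03d", 1:80), chrom = "chr1",
                        start = sample.int(50000, 80))
  genes_r$end <- genes_r$start + sample(500:3000, 80, replace = TRUE)
  genes_r$strand <- sample(c("+", "-"), 80, replace = TRUE)
  peaks <- randomIntervals(300, max_pos = 60000L)
  got <- assignPeakToGene(peaks, genes_r)
  for (i in seq_len(nrow(peaks))) {
    want <- oracleNearestGene(peaks[i, ], genes_r)
    expect_equal(got$gene_id[i], want$gene_id)
    expect_equal(got$distance[i], want$distance)
  }
  expect_error(assignPeakToGene(peaks, genes_r[0, ]), "empty annotation")
})

test_that("genomic-feature annotation follows the precedence order", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000L,
                      end = 20000L, strand = "+")
  exons <- data.frame(chrom = "chr1", start = c(10000L, 15000L),
                      end = c(10500L, 15800L))
  ann <- function(s, e) as.character(annotatePeakRegion(
    data.frame(chrom = "chr1", start = s, end = e), genes, exons))
  expect_equal(ann(9900L, 9950L), "PROMOTER")     # TSS-100
  expect_equal(ann(15100L, 15200L), "EXON")
  expect_equal(ann(12000L, 12100L), "INTRON")
  expect_equal(ann(40000L, 40100L), "DISTAL_INTERGENIC")
  # promoter wins over exon at the TSS
  expect_equal(ann(10000L, 10400L), "PROMOTER")
  # minus-strand gene: promoter upstream means higher coordinates
  genes2 <- data.frame(gene_id = "g2", chrom = "chr1", start = 10000L,
                       end = 20000L, strand = "-")
  expect_equal(as.character(annotatePeakRegion(
    data.frame(chrom = "chr1", start = 20500L, end = 20600L),
    genes2, exons)), "PROMOTER")
})
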