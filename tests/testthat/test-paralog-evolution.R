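test_that("family filter removes pairs with >20 partners, keeps exactly 20", {
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      family_size_a = c(21L, 20L, 3L),
                      family_size_b = c(2L, 2L, 25L))
  out <- filterParalogFamilies(pairs)
  expect_equal(out$pair_id, "p2")
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(nrow(filterParalogFamilies(pairs[0, ])), 0L)
  expect_error(filterParalogFamilies(data.frame(pair_id = "x")), "missing")
})

test_that("age bins partition with the documented boundary handling", {
  expect_equal(as.character(assignAgeBin(c(500, 200, 0, 473.3, 111))),
               c("VERY_ANCIENT", "ANCIENT", "RECENT_VERY_RECENT",
                 "ANCIENT", "RECENT_VERY_RECENT"))
  expect_error(assignAgeBin(-1), "non-negative")
  set.seed(3)
  ages <- runif(500, 0, 900)
  b <- assignAgeBin(ages)
  expect_equal(sum(table(b)), 500L)
})

test_that("differential stand-in finds planted folds and accepts substitutes", {
  set.seed(21)
  u <- genParalogUniverse(n_pairs = 150, expression_noise_sd = 0.2,
                          effect_size_log2 = 2, seed = 21)
  de <- u$differential
  spec_genes <- u$pairs$gene_a[u$pairs$specialized_truth]
  hit <- tapply(de$padj < 0.05 & de$log2fc > 0, de$gene, any)[spec_genes]
  expect_gte(mean(hit), 0.9)

  # identical condition means: nothing significant
  flat <- matrix(100, 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  design <- data.frame(sample = paste0("s", 1:10),
                       condition = rep(c("DEV_A", "DIA_A"), each = 5),
                       phase = rep(c("DEVELOPMENT", "DIAPAUSE"), each = 5))
  de_flat <- differentialExpressionStandin(flat, design)
  expect_true(all(de_flat$padj == 1))

  # an externally supplied table drives identical downstream calls
  calls1 <- classifySpecialization(u$pairs, de, u$expression, u$design)
  de_external <- de[sample(nrow(de)), ]  # same content, shuffled rows
  calls2 <- classifySpecialization(u$pairs, de_external, u$expression,
                                   u$design)
  expect_identical(calls1, calls2)
})

test_that("specialization rule fires on the documented clauses", {
  pairs <- data.frame(pair_id = "p1", gene_a = "A", gene_b = "B")
  de <- function(a_fc, a_p, b_fc, b_p)
    data.frame(gene = c("A", "B"), contrast = "DIA_6D_vs_DEV_HB",
               log2fc = c(a_fc, b_fc), padj = c(a_p, b_p))
  expr <- matrix(c(10, 10, 100, 100,   # A: up in diapause
                   50, 50, 50, 50),    # B: flat medians
                 2, 4, byrow = TRUE,
                 dimnames = list(c("A", "B"),
                                 c("d1", "d2", "i1", "i2")))
  design <- data.frame(sample = c("d1", "d2", "i1", "i2"),
                       condition = c("DEV_HB", "DEV_HB", "DIA_6D", "DIA_6D"),
                       phase = c("DEVELOPMENT", "DEVELOPMENT",
                                 "DIAPAUSE", "DIAPAUSE"))

  # partner significantly down
  r <- classifySpecialization(pairs, de(2, 0.01, -1, 0.03), expr, design)
  expect_true(r$specialized)
  expect_equal(r$diapause_gene, "A")
  expect_equal(r$rule_path, "partner_down")

  # partner non-significant but median(dev) > median(dia)
  expr2 <- expr; expr2["B", ] <- c(80, 80, 10, 10)
  r2 <- classifySpecialization(pairs, de(2, 0.01, -1, 0.5), expr2, design)
  expect_true(r2$specialized)
  expect_equal(r2$rule_path, "partner_median")

  # both genes up: opposing roles required
  r3 <- classifySpecialization(pairs, de(2, 0.01, 3, 0.01), expr, design)
  expect_false(r3$specialized)

  # nothing significant, medians flat
  r4 <- classifySpecialization(pairs, de(0.2, 0.8, -0.1, 0.9), expr, design)
  expect_false(r4$specialized)

  # strict mode refuses the median clause
  r5 <- classifySpecialization(pairs, de(2, 0.01, -1, 0.5), expr2, design,
                               mode = "alim_strict")
  expect_false(r5$specialized)

  # verdict symmetric in gene order
  sw <- data.frame(pair_id = "p1", gene_a = "B", gene_b = "A")
  r6 <- classifySpecialization(sw, de(2, 0.01, -1, 0.03), expr, design)
  expect_true(r6$specialized)
  expect_equal(r6$diapause_gene, "A")

  expect_error(classifySpecialization(
    data.frame(pair_id = "p", gene_a = "A", gene_b = "ZZZ"),
    de(1, 1, 1, 1), expr, design), "ZZZ")
})

test_that("bin enrichment: ratios average to 1 and bootstrap is consistent", {
  lab <- genParalogLabels(n_pairs = 800, seed = 5)
  e <- binEnrichment(lab$age_bin, lab$specialized_truth, n_boot = 500,
                     seed = 2)
  s <- e$summary
  # bin-size weighted mean of ratios is 1 by construction
  expect_equal(sum(s$enrichment_ratio * s$n_pairs_in_bin) /
                 sum(s$n_pairs_in_bin), 1, tolerance = 1e-12)
  expect_equal(sum(s$n_pairs_in_bin), 800L)
  expect_true(all(abs(colMeans(e$bootstrap_ratios) /
                        s$enrichment_ratio - 1) < 0.05))
  # shuffled pair labels destroy the planted enrichment
  set.seed(9)
  e0 <- binEnrichment(sample(lab$age_bin), lab$specialized_truth,
                      n_boot = 0)
  expect_true(all(abs(e0$summary$enrichment_ratio - 1) < 0.25))
})

test_that("pair location classification and its contingency test", {
  expect_equal(classifyPairLocation("chr3", "chr3"), "SAME_CHROMOSOME")
  expect_equal(classifyPairLocation("chr3", "chr5"), "DIFFERENT_CHROMOSOME")
  expect_warning(u <- classifyPairLocation("scaffold_12", "chr1"),
                 "UNKNOWN")
  expect_equal(u, "UNKNOWN")

  # shared oracle with the chi-square example table
  spec <- rep(c(TRUE, FALSE), c(40, 160))
  loc <- rep(c("SAME_CHROMOSOME", "DIFFERENT_CHROMOSOME",
               "SAME_CHROMOSOME", "DIFFERENT_CHROMOSOME"),
             c(10, 30, 10, 150))
  r <- compareLocationDistribution(spec, loc)
  expect_equal(r$statistic, 12.5, tolerance = 1e-12)

  # planted depletion of same-chromosome pairs among specialized
  set.seed(31)
  n <- 2000
  spec2 <- runif(n) < 0.3
  p_same <- ifelse(spec2, 0.10, 0.20)  # odds ratio ~ 0.5
  loc2 <- ifelse(runif(n) < p_same, "SAME_CHROMOSOME",
                 "DIFFERENT_CHROMOSOME")
  expect_lt(compareLocationDistribution(spec2, loc2)$p_value, 0.05)
})

test_that("cross-species program correlation recovers planted dependence", {
  map <- data.frame(gene_a = paste0("a", 1:500),
                    gene_b = paste0("b", 1:500))
  set.seed(14)
  lfc_a <- setNames(rnorm(500), map$gene_a)
  expect_equal(crossSpeciesProgramCorrelation(
    map, lfc_a, setNames(unname(lfc_a), map$gene_b))$estimate, 1)
  expect_equal(crossSpeciesProgramCorrelation(
    map, lfc_a, setNames(-unname(lfc_a), map$gene_b))$estimate, -1)
  # bivariate normal with correlation 0.5; Spearman rho close to planted
  z <- 0.5 * unname(lfc_a) + sqrt(1 - 0.25) * rnorm(500)
  r <- crossSpeciesProgramCorrelation(map, lfc_a, setNames(z, map$gene_b))
  expect_lt(abs(r$estimate - 0.5), 0.1)
  expect_equal(r$n, 500L)
  expect_error(crossSpeciesProgramCorrelation(
    map[1:2, ], lfc_a, setNames(z, map$gene_b)), "fewer than 3")
})

test_that("uniquely regulated genes follow pure set logic", {
  de <- list(focal = paste0("g", 1:10), sp2 = c("x2", "x3"),
             sp3 = c("y9"))
  maps <- list(
    sp2 = data.frame(focal_gene = c("g2", "g3"), other_gene = c("x2", "x3")),
    sp3 = data.frame(focal_gene = c("g9", "g9"), other_gene = c("y9", "y9b")))
  expect_setequal(uniquelyRegulatedGenes(de, maps),
                  paste0("g", c(1, 4:8, 10)))
  # other species silent: focal set unchanged
  de2 <- list(focal = de$focal, sp2 = character(0))
  expect_equal(uniquelyRegulatedGenes(de2, maps["sp2"]), de$focal)
  # focal set fully mapped into significant orthologs: empty result
  de3 <- list(focal = c("g2", "g3"), sp2 = c("x2", "x3"))
  expect_length(uniquelyRegulatedGenes(de3, maps["sp2"]), 0)
  expect_error(uniquelyRegulatedGenes(list(focal = "g", sp9 = "h"),
                                      list()), "sp9")
})
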