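test_that("PWM scoring: analytic cases and the floor", {
  unif <- PWMotif("U", matrix(0.25, 6, 4,
                              dimnames = list(NULL, c("A", "C", "G", "T"))),
                  0)
  expect_equal(scoreSequence(unif, "ACGTAC"), 0)
  # fully degenerate motif scores n*ln(4) on its consensus
  deg <- matrix(0, 5, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  deg[, "G"] <- 1
  pd <- PWMotif("D", deg, 1)
  expect_equal(scoreSequence(pd, "GGGGG"), 5 * log(4), tolerance = 1e-12)
  # hand per-position sum: ln(0.7/0.25) + ln(0.97/0.25)
  p2 <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.01, 0.97, 0.01, 0.01), 2, 4,
               byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(scoreSequence(PWMotif("H", p2, 0), "AC"),
               log(2.8) + log(3.88), tolerance = 1e-12)
  # off-consensus base hits the floor, not -Inf
  expect_equal(scoreSequence(pd, "GGGGA"),
               4 * log(4) + log(0.001 / 0.25), tolerance = 1e-12)
  expect_true(is.na(scoreSequence(unif, "ACGTAN")))
  expect_error(scoreSequence(unif, "ACGT"), "length")
})

test_that("PWM validity: rows must sum to 1, threshold must be reachable", {
  bad <- matrix(c(0.5, 0.2, 0.2, 0.2), 1, 4)
  expect_error(PWMotif("B", bad, 0), "sum to 1")
  good <- matrix(0.25, 4, 4)
  expect_error(PWMotif("B", good, 99), "exceeds the maximum")
})

test_that("scoring and scanning agree with a naive oracle on random input", {
  set.seed(123)
  for (r in 1:150) {
    pwm <- randomPWM(sample(4:12, 1))
    seq <- randomDNA(length(pwm))
    expect_equal(scoreSequence(pwm, seq),
                 oracleScore(motifProbs(pwm), seq), tolerance = 1e-9)
  }
  for (r in 1:40) {
    len <- sample(5:9, 1)
    base <- randomPWM(len)
    thr <- quantile(replicate(30, oracleScore(motifProbs(base),
                                              randomDNA(len))), 0.8)
    pwm <- PWMotif("RND", motifProbs(base), unname(thr))
    seq <- randomDNA(sample(30:80, 1))
    got <- scanSequence(pwm, seq)
    want <- oracleScan(motifProbs(pwm), detectionThreshold(pwm), seq)
    want <- want[order(want$offset, want$strand), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("scan finds planted consensus on both strands; strand symmetry", {
  pwm <- makeTestPWM()
  cons <- consensusSeq(pwm)
  seq <- paste0(randomDNA(20), cons, randomDNA(20))
  # regenerate until the flanks are clean, then plant deterministically
  set.seed(4)
  while (nrow(scanSequence(pwm, seq)) != 1L)
    seq <- paste0(randomDNA(20), cons, randomDNA(20))
  h <- scanSequence(pwm, seq)
  expect_equal(h$offset, 20L)
  expect_equal(h$strand, "+")
  # reverse complement swaps the strand label, preserves the multiset
  h2 <- scanSequence(pwm, oracleRevcomp(seq))
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, h$score)
  expect_equal(h2$offset, nchar(seq) - 10L - 20L)
  # threshold above the maximum: nothing can match
  hi <- PWMotif("HI", motifProbs(pwm), maxScore(pwm))
  expect_equal(nrow(scanSequence(hi, randomDNA(200))), 0L)
})

test_that("information content: uniform 0, fixed 2, half-half 1", {
  m <- matrix(c(0.25, 0.25, 0.25, 0.25,
                1, 0, 0, 0,
                0.5, 0.5, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ic <- informationContent(PWMotif("IC", m, 0))
  expect_equal(ic$per_position, c(0, 2, 1), tolerance = 1e-12)
  expect_equal(ic$total, 3)
})

test_that("site conservation verdicts: conserved, mutated, nearby-excluded", {
  pwm <- makeTestPWM()
  mu <- genMotifUniverse(pwm, n_sites = 120, conserved_fraction = 0.10,
                        te_fraction = 0.05, nearby_fraction = 0.10,
                        seed = 42)
  sites <- assessSiteConservation(mu$hits, mu$map, mu$sequences, pwm)
  per_hit <- split(sites, sites$hit)
  for (i in seq_len(nrow(mu$truth))) {
    v <- per_hit[[as.character(i)]]$verdict
    if (mu$truth$conserved[i]) expect_true(all(v == "CONSERVED"))
    else if (mu$truth$nearby_excluded[i])
      expect_true(all(v == "EXCLUDED_NEARBY"))
    else expect_true(all(v == "NOT_CONSERVED"))
  }
  # identical aligned sequence always passes its own threshold
  expect_true(all(sites$passes_threshold[sites$verdict == "CONSERVED"]))
  # EXCLUDED_NEARBY implies failed threshold plus the nearby flag
  ex <- sites[sites$verdict == "EXCLUDED_NEARBY", ]
  expect_true(all(!ex$passes_threshold & ex$nearby_identical_motif))
})

test_that("conservation summary removes excluded sites from the denominator", {
  sites <- data.frame(
    hit = 1:8, species = "aaus",
    verdict = c("CONSERVED", "NOT_CONSERVED", "NOT_CONSERVED",
                "NOT_CONSERVED", "EXCLUDED_NEARBY", "EXCLUDED_NEARBY",
                "ALIGNMENT_ABSENT", "ALIGNMENT_ABSENT"))
  s <- summarizeConservation(sites)
  expect_equal(s$per_species$fraction, 0.25)
  # adding excluded sites leaves the default fraction unchanged
  more <- rbind(sites, data.frame(hit = 9:10, species = "aaus",
                                  verdict = "EXCLUDED_NEARBY"))
  expect_equal(summarizeConservation(more)$per_species$fraction, 0.25)
  # the alternative convention counts them as non-conserved
  expect_equal(summarizeConservation(sites, count_excluded = TRUE)
               $per_species$fraction, 1 / 6)
})

test_that("motif origin: TE overlap, sharing, and co-conservation grid", {
  pwm <- makeTestPWM()
  mu <- genMotifUniverse(pwm, n_sites = 100, conserved_fraction = 0.10,
                        te_fraction = 0.10, nearby_fraction = 0.10,
                        seed = 17)
  sites <- assessSiteConservation(mu$hits, mu$map, mu$sequences, pwm)
  origin <- classifyMotifOrigin(mu$hits, mu$te, sites)
  expect_equal(origin$calls$origin, mu$truth$origin)
  expect_equal(origin$calls$sharing, mu$truth$sharing)
  # co-conservation grid with the focal TE layout mirrored in a species
  te_sp <- list(aaus = mu$te[, c("chrom", "start", "end", "family")])
  oc <- classifyMotifOrigin(mu$hits, mu$te, sites, mu$map, te_sp)
  grid <- oc$coconservation[oc$coconservation$species == "aaus", ]
  te_sites <- mu$truth$te_derived
  cons_sites <- mu$truth$conserved
  expect_true(all(grid$category[te_sites & cons_sites] == "TE_AND_MOTIF"))
  expect_true(all(grid$category[te_sites & !cons_sites] == "TE_NO_MOTIF"))
  expect_true(all(grid$category[!te_sites & cons_sites] == "MOTIF_NO_TE"))
  expect_true(all(grid$category[!te_sites & !cons_sites] == "NEITHER"))
})
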