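#' @title End-to-end pipeline orchestration
#' @description Binds the analysis stages into a reproducible run: a
#'   seeded simulate step writes every input file (paralog tables,
#'   expression matrices, peak BEDs, block map, species FASTA, motif
#'   file, TE BED, knockout expression, lipid table) with a JSON truth
#'   sidecar; the run step reads them back through the package's own
#'   readers, executes the enabled stages in dependency order, writes
#'   per-stage result tables and a manifest with input/output hashes,
#'   parameters and warnings. Identical config + seed gives
#'   byte-identical outputs.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param outdir output directory for the run.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a config list (thresholds, stage toggles, simulation
#'   parameters) that \code{\link{runPipeline}} accepts; can be stored
#'   as YAML.
#' @export
defaultPipelineConfig <- function(outdir = tempfile("regremodel_run_"),
                                  seed = 1L) {
  list(
    outdir = outdir, seed = as.integer(seed),
    stages = c("paralogs", "peaks", "motifs", "te", "ko", "lipids"),
    fdr = 0.05, ko_fdr = 0.1, alpha = 0.05,
    stringency = "RELAXED", nearby_window = 100L, n_boot = 1000L,
    simulate = list(
      n_pairs = 400L, n_peaks = 200L, n_sites = 60L,
      n_genes_ko = 200L, n_lipids = 120L))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of
#'   \code{\link{defaultPipelineConfig}} (missing fields fall back to
#'   the defaults).
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  cfg[names(user)] <- user
  cfg
}

.sim_pwm <- function() {
  # a strongly informative 10-mer used by the simulate stage
  cons <- c("T", "G", "A", "C", "C", "A", "C", "G", "T", "G")
  p <- matrix(0.04, 10, 4, dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(cons)) p[i, cons[i]] <- 0.88
  pwm <- PWMotif("SIMTF1", p, 0)
  PWMotif("SIMTF1", p, 0.7 * maxScore(pwm))
}

#' Simulate every pipeline input into a directory
#'
#' @param config pipeline config (see
#'   \code{\link{defaultPipelineConfig}}).
#' @return the input directory path (invisibly); files written under
#'   \code{<outdir>/inputs} plus \code{truth.json}.
#' @export
simulateInputs <- function(config) {
  ind <- file.path(config$outdir, "inputs")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- config$simulate
  truth <- list()

  pu <- genParalogUniverse(n_pairs = sim$n_pairs,
                           seed = deriveSeed(seed, "paralogs"))
  writeTsv(pu$pairs[, !(names(pu$pairs) %in%
                          c("age_bin", "specialized_truth"))],
           file.path(ind, "paralog_pairs.tsv"))
  writeTsvMatrix(pu$expression, file.path(ind, "expression.tsv"))
  writeTsv(pu$design, file.path(ind, "design.tsv"))
  truth$paralogs <- pu$truth

  pk <- genPeakUniverse(n_peaks = sim$n_peaks, split_fraction = 0.05,
                        seed = deriveSeed(seed, "peaks"))
  writeBed(pk$focal_peaks[, c("chrom", "start", "end", "peak_id")],
           file.path(ind, "focal_peaks.bed"))
  for (sp in names(pk$species_peaks))
    writeBed(pk$species_peaks[[sp]][, c("chrom", "start", "end", "peak_id")],
             file.path(ind, paste0("peaks_", sp, ".bed")))
  writeBlockMap(pk$map, file.path(ind, "blocks.tsv"))
  writeTsv(data.frame(species = names(pk$roles), role = unname(pk$roles)),
           file.path(ind, "roles.tsv"))
  truth$peaks <- pk$truth

  mu <- genMotifUniverse(.sim_pwm(), n_sites = sim$n_sites,
                         seed = deriveSeed(seed, "motifs"))
  writeMotifFile(mu$pwm, file.path(ind, "motifs.txt"))
  for (sp in names(mu$sequences))
    writeFasta(mu$sequences[[sp]], file.path(ind, paste0(sp, ".fa")))
  writeBed(mu$hits[, c("chrom", "start", "end", "strand")],
           file.path(ind, "motif_hits.bed"))
  writeBed(mu$te, file.path(ind, "te.bed"))
  writeBlockMap(mu$map, file.path(ind, "motif_blocks.tsv"))
  truth$motifs <- mu$truth

  ko <- genKOExperiment(n_genes = sim$n_genes_ko,
                        seed = deriveSeed(seed, "ko"))
  writeTsvMatrix(ko$expression, file.path(ind, "ko_expression.tsv"))
  writeTsv(ko$samples, file.path(ind, "ko_samples.tsv"))
  truth$ko <- ko$truth

  li <- genLipidTable(n_lipids = sim$n_lipids,
                      seed = deriveSeed(seed, "lipids"))
  writeTsvMatrix(li$matrix, file.path(ind, "lipids.tsv"))
  writeTsv(data.frame(sample = names(li$conditions),
                      condition = unname(li$conditions)),
           file.path(ind, "lipid_samples.tsv"))
  truth$lipids <- li$truth

  jsonlite::write_json(truth, file.path(ind, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(ind)
}

#' Validate pipeline input files
#'
#' Schema checks on an input directory produced by
#' \code{\link{simulateInputs}} (or assembled by hand in the same
#' layout): BED coordinate sanity, design completeness, motif
#' probability row sums, alignment-block length equality. Report-only:
#' returns a data.frame of issues (zero rows = valid).
#'
#' @param indir input directory.
#' @return data.frame with columns \code{file} and \code{issue}.
#' @export
validateInputs <- function(indir) {
  issues <- list()
  note <- function(file, issue)
    issues[[length(issues) + 1L]] <<- data.frame(file = file,
                                                 issue = issue)
  for (f in list.files(indir, pattern = "\\.bed$", full.names = TRUE)) {
    x <- try(readBed(f), silent = TRUE)
    if (inherits(x, "try-error"))
      note(basename(f), "invalid BED coordinates")
  }
  bf <- file.path(indir, "blocks.tsv")
  if (file.exists(bf)) {
    b <- utils::read.table(bf, sep = "\t", header = TRUE)
    if (any((b$focal_end - b$focal_start) !=
            (b$target_end - b$target_start)))
      note("blocks.tsv", "unequal focal/target block lengths")
  }
  mf <- file.path(indir, "motifs.txt")
  if (file.exists(mf)) {
    p <- try(readMotifFile(mf), silent = TRUE)
    if (inherits(p, "try-error"))
      note("motifs.txt", "motif rows do not sum to 1 or malformed file")
  }
  df <- file.path(indir, "design.tsv")
  ef <- file.path(indir, "expression.tsv")
  if (file.exists(df) && file.exists(ef)) {
    d <- readTsv(df); e <- readTsvMatrix(ef)
    if (!all(d$sample %in% colnames(e)))
      note("design.tsv", "design lists samples absent from expression.tsv")
  }
  if (!length(issues))
    return(data.frame(file = character(0), issue = character(0)))
  do.call(rbind, issues)
}

#' Run the full pipeline
#'
#' Simulates inputs when \code{<outdir>/inputs} does not yet exist, then
#' executes the enabled stages in dependency order, writing one result
#' table per stage under \code{<outdir>/results} and a JSON manifest
#' with parameters, input/output MD5 hashes and collected warnings.
#'
#' @param config pipeline config list (see
#'   \code{\link{defaultPipelineConfig}}) or a YAML path.
#' @return the manifest (invisibly), also written to
#'   \code{<outdir>/manifest.json}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outdir <- config$outdir
  resd <- file.path(outdir, "results")
  dir.create(resd, recursive = TRUE, showWarnings = FALSE)
  ind <- file.path(outdir, "inputs")
  if (!dir.exists(ind)) simulateInputs(config)
  val <- validateInputs(ind)
  if (nrow(val))
    stop("input validation failed: ",
         paste(val$file, val$issue, sep = ": ", collapse = "; "))
  warnings_log <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage_out <- list()

  if ("paralogs" %in% config$stages) {
    pairs <- readTsv(file.path(ind, "paralog_pairs.tsv"))
    expr <- readTsvMatrix(file.path(ind, "expression.tsv"))
    design <- readTsv(file.path(ind, "design.tsv"))
    pairs <- filterParalogFamilies(pairs)
    de <- differentialExpressionStandin(expr, design)
    calls <- classifySpecialization(pairs, de, expr, design,
                                    fdr = config$fdr)
    bins <- assignAgeBin(pairs$duplication_age_mya)
    enr <- binEnrichment(bins, calls$specialized, n_boot = config$n_boot,
                         seed = deriveSeed(config$seed, "bin_boot"))
    out <- cbind(pairs[, c("pair_id", "duplication_age_mya")],
                 age_bin = bins, calls[, -1])
    writeTsv(out, file.path(resd, "paralog_specialization.tsv"))
    writeTsv(enr$summary, file.path(resd, "bin_enrichment.tsv"))
    stage_out$paralogs <- list(
      n_pairs = nrow(pairs), n_specialized = sum(calls$specialized),
      enrichment = enr$summary$enrichment_ratio)
  }

  if ("peaks" %in% config$stages) {
    roles_df <- readTsv(file.path(ind, "roles.tsv"))
    roles <- stats::setNames(roles_df$role, roles_df$species)
    focal_peaks <- readBed(file.path(ind, "focal_peaks.bed"))
    names(focal_peaks)[4] <- "peak_id"
    others <- setdiff(names(roles), names(roles)[roles == "FOCAL"])
    species_peaks <- lapply(stats::setNames(others, others), function(sp)
      readBed(file.path(ind, paste0("peaks_", sp, ".bed"))))
    map <- readBlockMap(file.path(ind, "blocks.tsv"))
    pc <- wcollect(peakConservationPipeline(
      focal_peaks, species_peaks, map, roles,
      stringency = config$stringency))
    writeTsv(pc$calls, file.path(resd, "peak_conservation.tsv"))
    stage_out$peaks <- list(
      n_peaks = nrow(focal_peaks),
      category_counts = as.list(table(pc$calls$category)))
  }

  if ("motifs" %in% config$stages) {
    pwm <- readMotifFile(file.path(ind, "motifs.txt"))[[1]]
    mmap <- readBlockMap(file.path(ind, "motif_blocks.tsv"))
    hits <- readBed(file.path(ind, "motif_hits.bed"))
    names(hits)[4] <- "strand"
    te <- readBed(file.path(ind, "te.bed"))
    names(te)[4:5] <- c("family", "te_class")
    sps <- unique(c(mapSpecies(mmap)))
    fas <- list()
    for (fa in list.files(ind, pattern = "\\.fa$", full.names = TRUE))
      fas[[sub("\\.fa$", "", basename(fa))]] <- readFasta(fa)
    sites <- assessSiteConservation(hits, mmap, fas, pwm,
                                    species = sps,
                                    nearby_window = config$nearby_window)
    summ <- summarizeConservation(sites)
    origin <- classifyMotifOrigin(hits, te, sites)
    writeTsv(sites, file.path(resd, "motif_conservation.tsv"))
    writeTsv(origin$calls, file.path(resd, "motif_origin.tsv"))
    stage_out$motifs <- list(
      conserved_fraction_avg = summ$average,
      origin_counts = as.list(table(paste(origin$calls$origin,
                                          origin$calls$sharing))))
  }

  if ("te" %in% config$stages) {
    te <- readBed(file.path(ind, "te.bed"))
    names(te)[4:5] <- c("family", "te_class")
    hits <- readBed(file.path(ind, "motif_hits.bed"))
    chrom_sizes <- stats::setNames(rep(10000L, length(unique(te$chrom))),
                                   unique(te$chrom))
    enr <- teFamilyEnrichment(
      hits[, c("chrom", "start", "end")],
      list(kind = "GENOME", chrom_sizes = chrom_sizes), te,
      alpha = config$alpha)
    writeTsv(enr, file.path(resd, "te_enrichment.tsv"))
    stage_out$te <- list(n_families = nrow(enr),
                         n_significant = sum(enr$significant))
  }

  if ("ko" %in% config$stages) {
    expr <- readTsvMatrix(file.path(ind, "ko_expression.tsv"))
    samples <- readTsv(file.path(ind, "ko_samples.tsv"))
    tf <- sub("^KO:", "", grep("^KO:", unique(samples$genotype),
                               value = TRUE)[1])
    degs <- callDualControlDegs(expr, samples, tf, fdr = config$ko_fdr)
    lfc <- koContrasts(expr, samples, tf)
    genes <- degs$gene[degs$is_deg]
    shift <- if (length(genes) >= 3L)
      programShift(lfc$ko_lfc[genes], lfc$control_lfc[genes],
                   alpha = config$alpha)
    else list(n_genes = length(genes), rho = NA_real_, p = NA_real_,
              classification = "NO_EFFECT")
    writeTsv(degs, file.path(resd, "ko_degs.tsv"))
    writeTsv(data.frame(tf = tf, n_degs = sum(degs$is_deg),
                        rho = shift$rho, p = shift$p,
                        classification = shift$classification),
             file.path(resd, "ko_program_shift.tsv"))
    stage_out$ko <- list(tf = tf, n_degs = sum(degs$is_deg),
                         classification = shift$classification)
  }

  if ("lipids" %in% config$stages) {
    mat <- readTsvMatrix(file.path(ind, "lipids.tsv"))
    ss <- readTsv(file.path(ind, "lipid_samples.tsv"))
    conditions <- stats::setNames(ss$condition, ss$sample)
    species <- lapply(rownames(mat), parseLipidName)
    classes <- vapply(species, `[[`, "", "lipid_class")
    norm <- medianNormalize(mat, classes)
    calls <- classifyDiapauseLipids(norm, conditions,
                                    alpha = config$alpha)
    calls$very_long_chain <- vapply(species, function(s)
      ifelse(is.na(isVeryLongChain(s)), NA, isVeryLongChain(s)),
      logical(1))
    writeTsv(calls, file.path(resd, "lipid_calls.tsv"))
    writeTsvMatrix(classConcentrations(norm, classes),
                   file.path(resd, "lipid_class_sums.tsv"))
    stage_out$lipids <- list(
      n_lipids = nrow(mat),
      n_diapause_specific = sum(calls$diapause_specific))
  }

  manifest <- list(
    seed = config$seed,
    parameters = config[c("fdr", "ko_fdr", "alpha", "stringency",
                          "nearby_window", "n_boot")],
    stages = stage_out,
    input_md5 = as.list(tools::md5sum(sort(list.files(ind,
                                                      full.names = TRUE)))),
    output_md5 = as.list(tools::md5sum(sort(list.files(resd,
                                                       full.names = TRUE)))),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
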