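# Stage orchestration: one structured-text (YAML) config, files as the
# only interface between stages, a provenance sidecar per stage, and
# fixed-seed reproducibility.  Stages: simulate, pheno-stats, diversity,
# gwas, classify, trace, design-markers, validate-dh, all.

#' Default pipeline configuration
#'
#' Thresholds mirror the analysis defaults: MAF minimum 0.1, kNN
#' imputation with k = 3 and minimum row data frequency 0.8, q-value
#' significance threshold 0.5, QTL merge gap 15 cM, adjacent-pair LD r^2
#' minimum 0.7 with at least 3 markers per block, carrier similarity
#' threshold 0.9, annealing range 55-62 C.
#'
#' @param outDir output directory.
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @return a named list of class "PipelineConfig".
#' @export
pipelineConfig <- function(outDir = "pedqtl-out", seed = 1L) {
  structure(list(
    out_dir = outDir, seed = as.integer(seed),
    maf_min = 0.1, knn_k = 3, knn_min_freq = 0.8,
    q_threshold = 0.5, gap_cm = 15,
    r2_min = 0.7, block_min_markers = 3, carrier_threshold = 0.9,
    trait = "FlYd",
    primer = list(primer_len = c(18, 25), tm_range = c(55, 62),
                  amplicon = c(150, 600), snp_frac_tol = 0.1),
    simulate = list(n_panel = 65, n_dh_lines = 151, n_dh_populations = 3,
                    n_markers_per_lg = 400,
                    contig_length = 1000, contig_divergence = 0.03)),
    class = "PipelineConfig")
}

#' Read / write a pipeline configuration
#' @param path YAML file.
#' @return \code{readPipelineConfig}: a "PipelineConfig" list merged over
#'   the defaults.
#' @export
readPipelineConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  mergeIn <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeIn(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  cfg <- mergeIn(cfg, usr)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config a "PipelineConfig".
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validatePipelineConfig <- function(cfg) {
  stopIfNot(cfg$maf_min >= 0 && cfg$maf_min <= 0.5, "maf_min outside [0,0.5]")
  stopIfNot(cfg$q_threshold > 0 && cfg$q_threshold <= 1,
            "q_threshold outside (0,1]")
  stopIfNot(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min outside [0,1]")
  stopIfNot(cfg$carrier_threshold >= 0 && cfg$carrier_threshold <= 1,
            "carrier_threshold outside [0,1]")
  stopIfNot(cfg$gap_cm >= 0, "gap_cm must be non-negative")
  stopIfNot(is.finite(cfg$seed), "every stochastic stage needs a seed")
  invisible(TRUE)
}

stagePath <- function(cfg, ...) file.path(cfg$out_dir, ...)

# provenance sidecar: config hash, seed, package version
writeProvenance <- function(cfg, stage, inputs = character(0)) {
  side <- stagePath(cfg, paste0(stage, ".provenance.yaml"))
  h <- sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = "")) *
             seq_along(utf8ToInt(paste(deparse(unclass(cfg)),
                                       collapse = "")))) %% 2147483647
  yaml::write_yaml(list(stage = stage, seed = cfg$seed, config_hash = h,
                        package = as.character(utils::packageVersion("pedQTL")),
                        inputs = inputs), side)
  invisible(side)
}

requireStageFile <- function(cfg, file, neededBy, producedBy) {
  p <- stagePath(cfg, file)
  if (!file.exists(p))
    stop(sprintf("stage '%s' needs %s; run stage '%s' first",
                 neededBy, file, producedBy), call. = FALSE)
  p
}

#' Run one pipeline stage (or all of them)
#'
#' Every stage reads its inputs from, and writes its outputs to,
#' `config$out_dir`; there is no hidden state between stages.  With a
#' fixed seed the whole pipeline is byte-reproducible.
#'
#' @param stage one of "simulate", "pheno-stats", "diversity", "gwas",
#'   "classify", "trace", "design-markers", "validate-dh", "all".
#' @param config a "PipelineConfig" (see \code{\link{pipelineConfig}}).
#' @return invisibly, a character vector of the files written.
#' @export
runPipeline <- function(stage = "all", config = pipelineConfig()) {
  validatePipelineConfig(config)
  stages <- c("simulate", "pheno-stats", "diversity", "gwas", "classify",
              "trace", "design-markers", "validate-dh")
  stopIfNot(stage %in% c(stages, "all"), paste("unknown stage:", stage))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- unlist(lapply(stages, runPipeline, config = config))
    return(invisible(out))
  }
  written <- switch(stage,
    "simulate" = stageSimulate(config),
    "pheno-stats" = stagePhenoStats(config),
    "diversity" = stageDiversity(config),
    "gwas" = stageGwas(config),
    "classify" = stageClassify(config),
    "trace" = stageTrace(config),
    "design-markers" = stageDesignMarkers(config),
    "validate-dh" = stageValidateDh(config))
  writeProvenance(config, stage)
  invisible(written)
}

stageSimulate <- function(cfg) {
  sc <- SimulationConfig(seed = cfg$seed,
                         n_markers_per_lg = cfg$simulate$n_markers_per_lg)
  st <- simulateBreedingStudy(sc, seed = cfg$seed,
                              nPanel = cfg$simulate$n_panel,
                              nDHLines = cfg$simulate$n_dh_lines,
                              nDHPopulations = cfg$simulate$n_dh_populations)
  files <- c(genotypes = "genotypes.tsv", map = "map.tsv",
             phenotypes = "phenotypes.tsv", pedigree = "pedigree.tsv",
             kernel = "kernel_type.tsv", qtl = "planted_qtls.tsv",
             focal = "focal.txt")
  writeGenotypes(st$genotypes, stagePath(cfg, files["genotypes"]))
  writeGeneticMap(st$map, stagePath(cfg, files["map"]))
  writePhenotypes(st$phenotypes, stagePath(cfg, files["phenotypes"]))
  writePedigree(st$pedigree, stagePath(cfg, files["pedigree"]))
  write.table(data.frame(accession = names(st$kernelType),
                         kernel_type = st$kernelType),
              stagePath(cfg, files["kernel"]), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(st$qtlMarkers, stagePath(cfg, files["qtl"]), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(st$focal, stagePath(cfg, files["focal"]))
  for (i in seq_along(st$dhPopulations)) {
    p <- st$dhPopulations[[i]]
    tb <- data.frame(line = rownames(calls(p)), phenotype = dhPhenotype(p),
                     calls(p), check.names = FALSE)
    write.table(tb, stagePath(cfg, sprintf("dh_population_%d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(p@name, p@parents),
               stagePath(cfg, sprintf("dh_population_%d.meta", i)))
  }
  unname(files)
}

loadPanel <- function(cfg, stage) {
  g <- readGenotypes(requireStageFile(cfg, "genotypes.tsv", stage,
                                      "simulate"))
  map <- readGeneticMap(requireStageFile(cfg, "map.tsv", stage, "simulate"))
  list(genotypes = g, map = map)
}

stagePhenoStats <- function(cfg) {
  ph <- readPhenotypes(requireStageFile(cfg, "phenotypes.tsv", "pheno-stats",
                                        "simulate"))
  an <- twoWayAnova(ph, cfg$trait)
  vc <- varianceComponents(an)
  h2 <- broadSenseHeritability(vc)
  ec <- envCorrelations(ph, cfg$trait)
  writePhenoReport(an, vc, h2, ec, stagePath(cfg, "pheno_report.tsv"))
  gv <- data.frame(accession = names(ec$genotypic_values),
                   genotypic_value = ec$genotypic_values)
  write.table(gv, stagePath(cfg, "genotypic_values.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("pheno_report.tsv", "genotypic_values.tsv")
}

stageDiversity <- function(cfg) {
  pl <- loadPanel(cfg, "diversity")
  filt <- filterMarkers(pl$genotypes, cfg$maf_min, map = pl$map)
  imp <- knnImpute(filt, k = cfg$knn_k, minFreq = cfg$knn_min_freq)
  pca <- genotypePCA(imp)
  coords <- data.frame(accession = rownames(pca$coordinates),
                       pca$coordinates)
  write.table(coords, stagePath(cfg, "pca_coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(component = seq_along(pca$proportion),
                         proportion_pct = 100 * pca$proportion),
              stagePath(cfg, "pca_proportions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tree <- upgmaTree(genotypeDistance(imp))
  writeNewickTree(tree, stagePath(cfg, "upgma.nwk"))
  writeGenotypes(imp, stagePath(cfg, "genotypes_imputed.tsv"))
  c("pca_coordinates.tsv", "pca_proportions.tsv", "upgma.nwk",
    "genotypes_imputed.tsv")
}

stageGwas <- function(cfg) {
  g <- readGenotypes(requireStageFile(cfg, "genotypes_imputed.tsv", "gwas",
                                      "diversity"))
  map <- readGeneticMap(requireStageFile(cfg, "map.tsv", "gwas", "simulate"))
  gv <- read.table(requireStageFile(cfg, "genotypic_values.tsv", "gwas",
                                    "pheno-stats"), header = TRUE, sep = "\t")
  kt <- read.table(requireStageFile(cfg, "kernel_type.tsv", "gwas",
                                    "simulate"), header = TRUE, sep = "\t")
  focal <- readLines(requireStageFile(cfg, "focal.txt", "gwas", "simulate"))[1]
  y <- setNames(gv$genotypic_value, gv$accession)
  kernel <- setNames(kt$kernel_type, kt$accession)
  K <- kinshipMatrix(g)
  mta <- mlmScan(g, y, K, covariates = kernel, focal = focal, map = map)
  writeMtaTable(mta, stagePath(cfg, "mta.tsv"))
  params <- data.frame(lambda = attr(mta, "lambda"), pi0 = attr(mta, "pi0"))
  write.table(params, stagePath(cfg, "gwas_parameters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  "mta.tsv"
}

readMta <- function(cfg, stage) {
  p <- requireStageFile(cfg, "mta.tsv", stage, "gwas")
  tb <- read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(marker_id = tb$marker, maf = tb$MAF, p_value = tb$p,
             q_value = tb$q, r_squared = tb$R2_pct / 100,
             effect = tb$effect, map_source = tb$map_source,
             linkage_group = as.character(tb$linkage_group),
             position = tb$cM, stringsAsFactors = FALSE)
}

stageClassify <- function(cfg) {
  mta <- readMta(cfg, "classify")
  g <- readGenotypes(requireStageFile(cfg, "genotypes_imputed.tsv",
                                      "classify", "diversity"))
  map <- readGeneticMap(requireStageFile(cfg, "map.tsv", "classify",
                                         "simulate"))
  qtls <- classifyMTAs(mta, gapCm = cfg$gap_cm, qThreshold = cfg$q_threshold)
  blocks <- if (nrow(qtls)) lapply(seq_len(nrow(qtls)), function(i)
    detectLDBlock(g, map, qtls[i, ], r2Min = cfg$r2_min,
                  minMarkers = cfg$block_min_markers)) else list()
  writeQtlTable(qtls, stagePath(cfg, "qtls.tsv"), blocks)
  "qtls.tsv"
}

stageTrace <- function(cfg) {
  g <- readGenotypes(requireStageFile(cfg, "genotypes_imputed.tsv", "trace",
                                      "diversity"))
  map <- readGeneticMap(requireStageFile(cfg, "map.tsv", "trace", "simulate"))
  ped <- readPedigree(requireStageFile(cfg, "pedigree.tsv", "trace",
                                       "simulate"))
  focal <- readLines(requireStageFile(cfg, "focal.txt", "trace",
                                      "simulate"))[1]
  qt <- read.table(requireStageFile(cfg, "qtls.tsv", "trace", "classify"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  rows <- list(); simsAll <- list()
  for (i in seq_len(nrow(qt))) {
    mk <- strsplit(qt$markers[i], ",")[[1]]
    if (!is.na(qt$ld_block[i]) && qt$ld_block[i] == "+" &&
        nzchar(qt$block_markers[i])) {
      blkTb <- mapTable(map)
      inBlk <- blkTb$marker_id[blkTb$linkage_group == qt$linkage_group[i] &
                                 blkTb$position >= qt$block_start[i] &
                                 blkTb$position <= qt$block_end[i]]
      mk <- union(mk, intersect(inBlk, markerIds(g)))
    }
    sims <- blockSimilarity(g, mk, focal)
    tr <- traceOrigin(ped, sims, focal, cfg$carrier_threshold)
    simsAll[[qt$qtl_id[i]]] <- sims
    rows[[i]] <- data.frame(
      qtl_id = qt$qtl_id[i], origin = tr$origin_class,
      source_ancestors = paste(tr$source_ancestors, collapse = ","),
      discrepancy = tr$discrepancy, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qtl_id = character(0))
  write.table(out, stagePath(cfg, "qtl_origins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(simsAll)) {
    simMat <- do.call(cbind, simsAll)
    write.table(data.frame(accession = rownames(simMat), simMat,
                           check.names = FALSE),
                stagePath(cfg, "block_similarities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  c("qtl_origins.tsv", "block_similarities.tsv")
}

stageDesignMarkers <- function(cfg) {
  # one synthetic homoeologous triplet per validated assay slot,
  # seeded from the master seed
  sim <- cfg$simulate
  sets <- list(); reports <- list()
  for (i in 1:3) {
    trip <- simulateContigTriplet(sim$contig_length, sim$contig_divergence,
                                  snpOffset = round(sim$contig_length / 2),
                                  alleles = c("T", "G"),
                                  seed = childSeed(cfg$seed, 700 + i))
    ps <- tryCatch(designPrimerSet(trip, cfg$primer,
                                   markerId = sprintf("assay%02d", i)),
                   error = function(e) NULL)
    if (is.null(ps)) next
    val <- validatePrimerSet(ps, trip)
    sets[[length(sets) + 1]] <- ps
    reports[[length(reports) + 1]] <-
      data.frame(marker = ps@markerId, pass = val$pass,
                 failures = paste(val$failures, collapse = "; "))
  }
  stopIfNot(length(sets) > 0, "no assay could be designed")
  writePrimerTable(sets, stagePath(cfg, "primers.tsv"))
  write.table(do.call(rbind, reports), stagePath(cfg, "primer_validation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  c("primers.tsv", "primer_validation.tsv")
}

stageValidateDh <- function(cfg) {
  qtlTb <- read.table(requireStageFile(cfg, "planted_qtls.tsv", "validate-dh",
                                       "simulate"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  pops <- list()
  for (i in seq_len(cfg$simulate$n_dh_populations)) {
    f <- requireStageFile(cfg, sprintf("dh_population_%d.tsv", i),
                          "validate-dh", "simulate")
    meta <- readLines(stagePath(cfg, sprintf("dh_population_%d.meta", i)))
    tb <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    g <- as.matrix(tb[, -(1:2)])
    rownames(g) <- tb$line
    pops[[i]] <- DHPopulation(meta[1], meta[2:3], g,
                              setNames(tb$phenotype, tb$line))
  }
  markers <- unique(intersect(qtlTb$marker_id, colnames(calls(pops[[1]]))))
  # keep one representative of any set of markers aliased across the
  # combined populations (tightly linked loci segregate identically in a
  # biparental cross)
  gAll <- do.call(rbind, lapply(pops, function(p)
    calls(p)[, markers, drop = FALSE]))
  keep <- markers
  if (length(markers) > 1) {
    cc <- suppressWarnings(abs(cor(gAll, use = "pairwise.complete.obs")))
    cc[!is.finite(cc)] <- 0
    drop <- character(0)
    for (i in seq_along(markers)) for (j in seq_len(i - 1))
      if (cc[i, j] > 1 - 1e-12 && !(markers[j] %in% drop))
        drop <- c(drop, markers[i])
    keep <- setdiff(markers, drop)
  }
  rep <- dhValidationReport(pops, keep,
                            stagePath(cfg, "dh_validation.tsv"))
  cmp <- comparePredictionSchemes(pops, keep)
  write.table(cmp$predictions, stagePath(cfg, "dh_predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(scheme = c("DH_total", "DH_each"),
                         r = c(cmp$r_total, cmp$r_each)),
              stagePath(cfg, "dh_prediction_accuracy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("dh_validation.tsv", "dh_predictions.tsv", "dh_prediction_accuracy.tsv")
}
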