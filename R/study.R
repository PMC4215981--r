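#' Simulate a complete synthetic breeding study
#'
#' Builds, from one \code{\link{SimulationConfig}}, everything the pipeline
#' consumes: a pedigree whose focal line descends from a two-parent cross
#' of bred intermediates (so the panel shows the strong familial
#' relatedness of a breeding programme), inbred genotypes for every line,
#' a binary kernel-type classification driven by one marker locus,
#' multi-environment phenotypes with planted QTLs, and doubled-haploid
#' validation populations from crosses of the focal line with other panel
#' members.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed integer seed (defaults to `config$seed`).
#' @param nPanel total panel size including pedigree members.
#' @param nDHLines lines per doubled-haploid population.
#' @param nDHPopulations number of DH validation crosses.
#' @param missingRate fraction of panel calls set missing (array no-calls;
#'   exercises imputation and keeps near-duplicate markers distinct, as in
#'   real data).
#' @param nAncestral ancestral haplotypes behind the founders (see
#'   \code{\link{simulateFounders}}); NULL draws founder alleles
#'   independently per marker (no local LD).
#' @param founderBlockCm ancestral-segment length for the mosaic mode.
#' @return a list of class "BreedingStudy" with elements `config`, `map`,
#'   `pedigree`, `genotypes`, `panel`, `focal`, `kernelType`,
#'   `kernelMarker`, `qtlMarkers`, `phenotypes`, `dhPopulations`.
#' @export
simulateBreedingStudy <- function(config = SimulationConfig(), seed = NULL,
                                  nPanel = 65, nDHLines = 151,
                                  nDHPopulations = 3, missingRate = 0.02,
                                  nAncestral = 3, founderBlockCm = 30) {
  if (is.null(seed)) seed <- config$seed
  map <- simulationMap(config)
  nf <- max(config$n_founders, 4)
  fnd <- sprintf("F%03d", seq_len(nf))
  ped <- data.frame(line = fnd, mother = NA_character_,
                    father = NA_character_, stringsAsFactors = FALSE)
  # pair founders into intermediates, then two parental lines, then focal
  layer <- fnd
  gen <- 0
  while (length(layer) > 2) {
    gen <- gen + 1
    nxt <- character(0)
    for (k in seq_len(floor(length(layer) / 2))) {
      id <- sprintf("G%d_%02d", gen, k)
      ped <- rbind(ped, data.frame(line = id, mother = layer[2 * k - 1],
                                   father = layer[2 * k]))
      nxt <- c(nxt, id)
    }
    if (length(layer) %% 2 == 1) nxt <- c(nxt, layer[length(layer)])
    layer <- nxt
  }
  focal <- "FOCAL"
  ped <- rbind(ped, data.frame(line = focal, mother = layer[1],
                               father = layer[2]))
  core <- ped$line
  # fill the panel with crosses among existing lines (breeding-programme
  # relatives of the focal lineage)
  nExtra <- nPanel - nrow(ped)
  stopIfNot(nExtra >= 0, "nPanel smaller than the core pedigree")
  pairs <- withSeed(childSeed(seed, 101), {
    lapply(seq_len(nExtra), function(i) sample(core, 2))
  })
  for (i in seq_len(nExtra))
    ped <- rbind(ped, data.frame(line = sprintf("PNL%02d", i),
                                 mother = pairs[[i]][1],
                                 father = pairs[[i]][2]))
  pedigree <- Pedigree(ped)
  # founders carry ancestral haplotype blocks so the panel shows the local
  # LD of a real breeding pool (blocks around selected loci)
  founderG <- simulateFounders(nf, map, childSeed(seed, 102),
                               nAncestral = nAncestral,
                               blockCm = founderBlockCm)
  rownames(founderG@calls) <- fnd
  genotypes <- simulatePedigreeLines(pedigree, founderG, map,
                                     childSeed(seed, 103))
  g <- calls(genotypes)
  # kernel locus: a 5D marker whose minor-allele class (not carried by the
  # focal line) is nearest the hard:soft ratio of a soft-dominated panel
  kLg <- if ("5D" %in% mapTable(map)$linkage_group) "5D" else
    mapTable(map)$linkage_group[1]
  cand <- mapTable(map)$marker_id[mapTable(map)$linkage_group == kLg]
  hardFrac <- vapply(cand, function(m) mean(g[, m] != g[focal, m]),
                     numeric(1))
  kernelMarker <- cand[which.min(abs(hardFrac - 17 / 65))]
  kernelType <- as.integer(g[, kernelMarker] != g[focal, kernelMarker])
  names(kernelType) <- rownames(g)
  qtlIds <- resolveQtlMarkers(config$qtl_spec, map, colnames(g))
  qtlMarkers <- data.frame(marker_id = qtlIds,
                           linkage_group = config$qtl_spec$linkage_group,
                           effect = config$qtl_spec$effect,
                           stringsAsFactors = FALSE)
  phen <- simulatePhenotypes(genotypes, config, childSeed(seed, 104),
                             map = map, kernelType = kernelType)
  # DH validation crosses: focal x panel lines outside the focal lineage,
  # preferring crosses that segregate for the planted QTLs (as validation
  # crosses would be chosen), then overall polymorphism
  others <- setdiff(rownames(g), core)
  if (length(others) < nDHPopulations)
    others <- setdiff(rownames(g), c(focal, fnd))
  qtlPoly <- vapply(others, function(l)
    sum(g[l, qtlIds] != g[focal, qtlIds]), numeric(1))
  poly <- vapply(others, function(l) mean(g[l, ] != g[focal, ]), numeric(1))
  parents <- others[order(-qtlPoly, -poly)][seq_len(nDHPopulations)]
  dhPops <- lapply(seq_along(parents), function(i) {
    pop <- simulateDHPopulation(g[parents[i], ], g[focal, ], nDHLines, map,
                                childSeed(seed, 200 + i),
                                name = paste0(parents[i], "/", focal))
    pop@parents <- c(parents[i], focal)
    go <- calls(pop)
    # genetic value in original coding: oriented 1 means the focal allele
    gval <- numeric(nrow(go))
    if (length(qtlIds)) {
      orig <- vapply(qtlIds, function(m)
        ifelse(go[, m] == 1L, g[focal, m], 1L - g[focal, m]),
        integer(nrow(go)))
      gval <- as.numeric(orig %*% qtlMarkers$effect)
    }
    noise <- withSeed(childSeed(seed, 300 + i),
                      rnorm(nrow(go), 0,
                            sqrt(config$var_genotype + config$var_residual)))
    pop@phenotype <- setNames(config$mu + gval + noise, rownames(go))
    pop
  })
  names(dhPops) <- vapply(dhPops, function(p) p@name, character(1))
  # observed panel matrix: array no-calls at missingRate; truth kept too
  gObs <- g
  if (missingRate > 0) {
    nmiss <- round(missingRate * length(g))
    hole <- withSeed(childSeed(seed, 105),
                     sample.int(length(g), nmiss))
    gObs[hole] <- NA_integer_
  }
  structure(list(config = config, map = map, pedigree = pedigree,
                 genotypes = GenotypeMatrix(gObs),
                 genotypesTrue = genotypes, panel = rownames(g),
                 focal = focal,
                 kernelType = kernelType, kernelMarker = kernelMarker,
                 qtlMarkers = qtlMarkers, phenotypes = phen,
                 dhPopulations = dhPops),
            class = "BreedingStudy")
}
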