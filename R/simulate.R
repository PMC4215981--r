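# Synthetic breeding-population generator.  Emulates the statistical
# structure the downstream analysis assumes: a small inbred panel descended
# from a known pedigree (strong kinship), a binary soft/hard kernel locus
# with a large fixed effect, multi-environment phenotypes with variance
# components giving broad-sense heritability about 0.38, planted additive
# QTLs with per-allele effects of 1.5-2.7 trait units, and doubled-haploid
# populations of about 150 lines from biparental crosses.  All lines are
# inbred: heterozygotes are never generated.  Crossovers follow the Haldane
# (no-interference) model with one meiosis per derived line.  Every
# stochastic operation takes an explicit seed; no global random state leaks.

#' Simulation configuration
#'
#' Defaults encode the study conditions the package targets: 9 environments
#' with 2 replicates, variance components (genotype, environment, residual)
#' = (6.5, 7.3, 3.1) trait-units^2 so that broad-sense heritability is
#' about 0.385, twelve planted additive QTLs with per-allele effects drawn
#' once in 1.5-2.7 trait units, and a kernel locus with a 4 trait-unit
#' fixed effect.  `var_residual` is the residual variance of environment
#' means (the error stratum of the two-way ANOVA); plot-level noise is
#' scaled by the replicate count so that replicate averaging recovers it.
#'
#' @param n_founders number of pedigree founders.
#' @param n_markers_per_lg markers per linkage group (evenly spaced).
#' @param lg_lengths named numeric vector of linkage-group lengths (cM).
#' @param qtl_spec data.frame(linkage_group, position, effect) of planted
#'   QTLs; NULL places `n_qtl` QTLs at evenly spread positions with effects
#'   drawn uniformly in `qtl_effect_range` (from `seed`).
#' @param n_qtl,qtl_effect_range used when `qtl_spec` is NULL.
#' @param kernel_locus_effect fixed effect (trait units) of the hard-kernel
#'   allele.
#' @param var_genotype,var_environment,var_residual variance components
#'   (trait-units^2), all >= 0.
#' @param n_environments,n_reps environments and replicates per environment.
#' @param mu trait grand mean.
#' @param seed integer seed; mandatory for any stochastic call.
#' @return a list of class "SimulationConfig".
#' @export
SimulationConfig <- function(n_founders = 8,
                             n_markers_per_lg = 400,
                             lg_lengths = c(`1A` = 150, `2B` = 150, `3B` = 150,
                                            `5D` = 150, `7A` = 150),
                             qtl_spec = NULL,
                             n_qtl = 12,
                             qtl_effect_range = c(1.5, 2.7),
                             kernel_locus_effect = 4,
                             var_genotype = 6.5,
                             var_environment = 7.3,
                             var_residual = 3.1,
                             n_environments = 9,
                             n_reps = 2,
                             mu = 64,
                             seed = 1L) {
  stopIfNot(all(c(var_genotype, var_environment, var_residual) >= 0),
            "variance components must be non-negative")
  stopIfNot(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "an explicit integer seed is mandatory")
  if (is.null(names(lg_lengths)))
    names(lg_lengths) <- paste0("LG", seq_along(lg_lengths))
  if (is.null(qtl_spec)) {
    lgs <- rep(names(lg_lengths), length.out = n_qtl)
    pos <- withSeed(childSeed(seed, 9011), {
      vapply(lgs, function(lg) runif(1, 0.1, 0.9) * lg_lengths[[lg]],
             numeric(1))
    })
    eff <- withSeed(childSeed(seed, 9012),
                    runif(n_qtl, qtl_effect_range[1], qtl_effect_range[2]))
    qtl_spec <- data.frame(linkage_group = lgs, position = unname(pos),
                           effect = eff, stringsAsFactors = FALSE)
  }
  bad <- qtl_spec$position < 0 |
    qtl_spec$position > lg_lengths[qtl_spec$linkage_group]
  stopIfNot(!any(is.na(bad)) && !any(bad),
            "QTL positions must lie inside their linkage group")
  structure(list(
    n_founders = n_founders, n_markers_per_lg = n_markers_per_lg,
    lg_lengths = lg_lengths, qtl_spec = qtl_spec,
    kernel_locus_effect = kernel_locus_effect,
    var_genotype = var_genotype, var_environment = var_environment,
    var_residual = var_residual, n_environments = n_environments,
    n_reps = n_reps, mu = mu, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Evenly spaced simulation map
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param map_source label stored in the map.
#' @return a \linkS4class{GeneticMap} with `n_markers_per_lg` markers per
#'   linkage group at evenly spaced cM positions.
#' @export
simulationMap <- function(config, map_source = "SNP-consensus") {
  rows <- lapply(names(config$lg_lengths), function(lg) {
    n <- config$n_markers_per_lg
    data.frame(marker_id = sprintf("%s_m%04d", lg, seq_len(n)),
               linkage_group = lg,
               position = seq(0, config$lg_lengths[[lg]], length.out = n),
               map_source = map_source, stringsAsFactors = FALSE)
  })
  GeneticMap(do.call(rbind, rows))
}

#' Simulate fully homozygous founder genotypes
#'
#' Per-marker founder allele frequencies are drawn uniformly on
#' [0.1, 0.9] (so post-filter MAF >= 0.1 is commonly satisfied) unless
#' supplied; each founder's call is an independent Bernoulli draw.
#'
#' @param nFounders number of founders (>= 2).
#' @param map a \linkS4class{GeneticMap}; must be non-empty.
#' @param seed integer seed.
#' @param freq optional per-marker allele-1 frequencies (recycled).
#' @param nAncestral when set, founders are built as Markov mosaics of
#'   this many ancestral haplotypes (themselves independent
#'   Bernoulli(freq) draws per marker), which gives the panel the local
#'   linkage disequilibrium of a real breeding pool; per-marker allele
#'   frequencies then hold in expectation only, not conditionally on the
#'   realised ancestors.
#' @param blockCm mean ancestral-segment length (cM) for the mosaic mode.
#' @return a \linkS4class{GenotypeMatrix} of homozygous 0/1 calls.
#' @export
simulateFounders <- function(nFounders, map, seed, freq = NULL,
                             nAncestral = NULL, blockCm = 30) {
  tb <- mapTable(map)
  stopIfNot(nrow(tb) > 0, "empty genetic map")
  stopIfNot(nFounders >= 2, "need at least two founders")
  m <- nrow(tb)
  withSeed(seed, {
    if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
    freq <- rep_len(freq, m)
    if (is.null(nAncestral)) {
      g <- matrix(rbinom(nFounders * m, 1L, rep(freq, each = nFounders)),
                  nrow = nFounders,
                  dimnames = list(sprintf("F%03d", seq_len(nFounders)),
                                  tb$marker_id))
      return(GenotypeMatrix(g))
    }
    # ancestral-mosaic mode: independent ancestral haplotypes, founders
    # switch ancestral source along each linkage group
    anc <- matrix(rbinom(nAncestral * m, 1L, rep(freq, each = nAncestral)),
                  nrow = nAncestral)
    g <- matrix(NA_integer_, nFounders, m,
                dimnames = list(sprintf("F%03d", seq_len(nFounders)),
                                tb$marker_id))
    for (lg in unique(tb$linkage_group)) {
      idx <- which(tb$linkage_group == lg)
      pswitch <- 1 - exp(-diff(tb$position[idx]) / blockCm)
      for (f in seq_len(nFounders)) {
        src <- integer(length(idx))
        src[1] <- sample.int(nAncestral, 1)
        if (length(idx) > 1) {
          sw <- runif(length(idx) - 1) < pswitch
          for (k in 2:length(idx))
            src[k] <- if (sw[k - 1]) sample.int(nAncestral, 1) else src[k - 1]
        }
        g[f, idx] <- anc[cbind(src, idx)]
      }
    }
    GenotypeMatrix(g)
  })
}

haldaneR <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# n gametes from a phased haplotype pair, Haldane crossovers within linkage
# groups, independent assortment across them.  Returns n x markers matrix.
gameteMatrix <- function(hap1, hap2, map, n, seed) {
  tb <- mapTable(map)
  hap1 <- hap1[tb$marker_id]; hap2 <- hap2[tb$marker_id]
  stopIfNot(!anyNA(hap1) && !anyNA(hap2),
            "parent haplotypes must cover all map markers without missing")
  out <- matrix(NA_integer_, n, nrow(tb),
                dimnames = list(NULL, tb$marker_id))
  withSeed(seed, {
    for (lg in unique(tb$linkage_group)) {
      idx <- which(tb$linkage_group == lg)
      m <- length(idx)
      start <- matrix(rbinom(n, 1L, 0.5), n, 1)
      if (m > 1) {
        r <- haldaneR(diff(tb$position[idx]))
        sw <- matrix(rbinom(n * (m - 1), 1L, rep(r, each = n)), n, m - 1)
        cs <- sw                      # row-wise cumulative crossover count
        if (ncol(sw) > 1)
          for (cc in 2:ncol(sw)) cs[, cc] <- cs[, cc - 1] + sw[, cc]
        phase <- cbind(start, (start[, 1] + cs) %% 2)
      } else phase <- start
      h1 <- matrix(hap1[idx], n, m, byrow = TRUE)
      h2 <- matrix(hap2[idx], n, m, byrow = TRUE)
      out[, idx] <- ifelse(phase == 0, h1, h2)
    }
  })
  out
}

#' Simulate one gamete from a phased parent
#'
#' Crossovers are placed per linkage group under the Haldane model
#' (recombination fraction r = (1 - exp(-2d/100))/2 for d cM); linkage
#' groups assort independently.  Inbred parents are trivially phased (pass
#' the genotype as both haplotypes).
#'
#' @param hap1,hap2 named 0/1 vectors over the map's markers (the phased
#'   haplotype pair).
#' @param map a \linkS4class{GeneticMap}.
#' @param seed integer seed.
#' @param n number of gametes.
#' @return named vector (n = 1) or n x markers matrix of 0/1 alleles.
#' @export
simulateGamete <- function(hap1, hap2, map, seed, n = 1L) {
  g <- gameteMatrix(hap1, hap2, map, n, seed)
  if (n == 1L) g[1L, ] else g
}

#' Simulate inbred lines down a pedigree
#'
#' Each non-founder is the doubled single gamete of the F1 of its parents
#' (one meiosis, DH-style fixing), so all lines are fully inbred and every
#' allele traces to a founder allele.  Lines are generated in topological
#' order.
#'
#' @param pedigree a \linkS4class{Pedigree}; founders must be rows of
#'   `founderGenotypes`.
#' @param founderGenotypes \linkS4class{GenotypeMatrix} of the founders.
#' @param map a \linkS4class{GeneticMap}.
#' @param seed integer seed.
#' @return \linkS4class{GenotypeMatrix} over all pedigree lines.
#' @export
simulatePedigreeLines <- function(pedigree, founderGenotypes, map, seed) {
  e <- pedigreeEntries(pedigree)
  ord <- topoOrderPedigree(e)
  stopIfNot(!is.null(ord), "cyclic pedigree")
  fnd <- founders(pedigree)
  stopIfNot(all(fnd %in% accessionIds(founderGenotypes)),
            "founder genotypes missing for some pedigree founders")
  tb <- mapTable(map)
  g <- matrix(NA_integer_, length(ord), nrow(tb),
              dimnames = list(ord, tb$marker_id))
  g[fnd, ] <- calls(founderGenotypes)[fnd, tb$marker_id]
  for (i in seq_along(ord)) {
    id <- ord[i]
    p <- parentsOf(pedigree, id)
    if (is.null(p)) next
    g[id, ] <- simulateGamete(g[p[["mother"]], ], g[p[["father"]], ],
                              map, childSeed(seed, i))
  }
  GenotypeMatrix(g)
}

#' Simulate multi-environment phenotypes
#'
#' y(line, env, rep) = mu + sum_q effect_q x_q + kernel_effect k + g_line +
#' E_env + eps, with g_line ~ N(0, var_genotype) a polygenic value drawn
#' once per line (reproducible from the seed), E_env ~ N(0,
#' var_environment) per environment, and plot residuals scaled so that the
#' variance of replicate means is `var_residual`.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} of the panel.
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed integer seed.
#' @param map optional \linkS4class{GeneticMap} used to resolve
#'   `qtl_spec` rows to their nearest marker; not needed when `qtl_spec`
#'   has a `marker_id` column or is empty.
#' @param kernelType optional named 0/1 vector (1 = hard kernel) adding the
#'   `kernel_locus_effect` fixed effect.
#' @param trait trait name in the output.
#' @return a \linkS4class{PhenotypeTable}.
#' @export
simulatePhenotypes <- function(genotypes, config, seed, map = NULL,
                               kernelType = NULL, trait = "FlYd") {
  stopIfNot(all(c(config$var_genotype, config$var_environment,
                  config$var_residual) >= 0), "negative variance")
  g <- calls(genotypes)
  acc <- rownames(g)
  qs <- config$qtl_spec
  qeff <- numeric(length(acc))
  if (!is.null(qs) && nrow(qs)) {
    ids <- resolveQtlMarkers(qs, map, colnames(g))
    for (j in seq_along(ids))
      qeff <- qeff + qs$effect[j] * g[, ids[j]]
  }
  keff <- if (is.null(kernelType)) 0 else
    config$kernel_locus_effect * kernelType[acc]
  envs <- sprintf("E%02d", seq_len(config$n_environments))
  withSeed(seed, {
    # polygenic line value: many small marker effects, centred and scaled
    # to the configured genotypic variance, so relatives resemble each
    # other (the value is a deterministic function of the genotypes given
    # the seed)
    gval <- numeric(length(acc))
    if (config$var_genotype > 0) {
      a <- rnorm(ncol(g))
      raw <- as.numeric(scale(g, scale = FALSE) %*% a)
      gval <- if (sd(raw) > 0) raw * sqrt(config$var_genotype) / sd(raw)
        else rnorm(length(acc), 0, sqrt(config$var_genotype))
    }
    eenv <- rnorm(length(envs), 0, sqrt(config$var_environment))
    recs <- expand.grid(accession = acc, environment = envs,
                        replicate = seq_len(config$n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eps <- rnorm(nrow(recs), 0,
                 sqrt(config$var_residual * config$n_reps))
    ia <- match(recs$accession, acc)
    ie <- match(recs$environment, envs)
    recs$trait <- trait
    recs$value <- config$mu + qeff[ia] +
      (if (length(keff) > 1) keff[ia] else keff) +
      gval[ia] + eenv[ie] + eps
    PhenotypeTable(recs)
  })
}

# resolve qtl_spec rows to marker ids: use marker_id column if present,
# otherwise nearest map marker on the stated linkage group
resolveQtlMarkers <- function(qs, map, markerNames) {
  if ("marker_id" %in% names(qs)) {
    stopIfNot(all(qs$marker_id %in% markerNames),
              "qtl_spec markers absent from the genotype matrix")
    return(qs$marker_id)
  }
  stopIfNot(!is.null(map), "a map is needed to resolve QTL positions")
  tb <- mapTable(map)
  vapply(seq_len(nrow(qs)), function(j) {
    cand <- tb[tb$linkage_group == qs$linkage_group[j], ]
    stopIfNot(nrow(cand) > 0, "qtl_spec linkage group absent from map")
    cand$marker_id[which.min(abs(cand$position - qs$position[j]))]
  }, character(1))
}

#' Simulate a doubled-haploid population
#'
#' Each line is a single F1 gamete doubled; at every parent-polymorphic
#' marker the expected allele frequency is 0.5.  Calls are oriented so that
#' 1 is the focal (second) parent's allele.
#'
#' @param parent1,parent2 named 0/1 genotype vectors of the inbred parents
#'   (parent2 is the focal parent).
#' @param nLines number of DH lines (>= 1).
#' @param map a \linkS4class{GeneticMap}.
#' @param seed integer seed.
#' @param name population label.
#' @param phenotype optional named numeric vector (defaults to NA).
#' @return a \linkS4class{DHPopulation}.
#' @export
simulateDHPopulation <- function(parent1, parent2, nLines, map, seed,
                                 name = "DH", phenotype = NULL) {
  stopIfNot(nLines >= 1, "nLines must be >= 1")
  tb <- mapTable(map)
  p1 <- parent1[tb$marker_id]; p2 <- parent2[tb$marker_id]
  if (all(p1 == p2, na.rm = TRUE))
    warning("cross is monomorphic at all markers")
  g <- gameteMatrix(p1, p2, map, nLines, seed)
  # orient: 1 = focal (parent2) allele
  go <- ifelse(g == matrix(p2, nLines, length(p2), byrow = TRUE), 1L, 0L)
  rownames(go) <- sprintf("%s_L%03d", gsub("[^A-Za-z0-9]", "", name),
                          seq_len(nLines))
  if (is.null(phenotype))
    phenotype <- setNames(rep(NA_real_, nLines), rownames(go))
  DHPopulation(name, c(parent1 = "P1", parent2 = "P2"), go, phenotype)
}

#' Simulate a homoeologous contig triplet
#'
#' Three sequences descend from a common random ancestor with independent
#' substitutions per genome at half the stated rate, so that the expected
#' pairwise divergence between any two genomes is `divergence`; the target
#' SNP exists only in the designated genome.  Unless divergence is zero, the
#' construction is resampled (bounded retries) until at least one
#' genome-discriminating site lies within `window` bases on each side of
#' the SNP.
#'
#' @param length contig length (bases).
#' @param divergence expected pairwise per-site divergence between any two
#'   genomes, in [0, 0.2).
#' @param snpOffset 0-based offset of the target SNP (interior).
#' @param alleles character(2): (ref, alt) bases of the SNP.
#' @param seed integer seed.
#' @param genome subgenome carrying the SNP ("A", "B" or "D").
#' @param window flanking window (bases) that must contain a
#'   genome-discriminating site on each side.
#' @param maxRetries resampling bound.
#' @return a \linkS4class{ContigTriplet}.
#' @export
simulateContigTriplet <- function(length, divergence, snpOffset,
                                  alleles = c("T", "G"), seed, genome = "A",
                                  window = 200, maxRetries = 20) {
  stopIfNot(divergence >= 0 && divergence < 0.2,
            "divergence must be in [0, 0.2)")
  stopIfNot(snpOffset > 0 && snpOffset < length - 1,
            "snpOffset must be interior to the sequence")
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(maxRetries)) {
    trip <- withSeed(childSeed(seed, try), {
      anc <- sample(bases, length, replace = TRUE)
      seqs <- lapply(c(A = "A", B = "B", D = "D"), function(gn) {
        s <- anc
        hit <- which(runif(length) < divergence / 2)
        if (length(hit))
          s[hit] <- vapply(s[hit], function(b)
            sample(setdiff(bases, b), 1), character(1))
        s
      })
      seqs[[genome]][snpOffset + 1] <- alleles[1]
      # the SNP site must not double as a genome-discriminating site
      for (gn in setdiff(names(seqs), genome))
        seqs[[gn]][snpOffset + 1] <- anc[snpOffset + 1]
      if (identical(alleles[1], anc[snpOffset + 1]) && divergence == 0) {
        # keep "identical except the SNP" contract trivially satisfied
      }
      seqs
    })
    others <- setdiff(c("A", "B", "D"), genome)
    disc <- trip[[genome]] != trip[[others[1]]] &
      trip[[genome]] != trip[[others[2]]]
    disc[snpOffset + 1] <- FALSE
    lo <- max(1, snpOffset + 1 - window); hi <- min(length, snpOffset + 1 + window)
    ok <- divergence == 0 ||
      (any(disc[lo:snpOffset]) && any(disc[(snpOffset + 2):hi]))
    if (ok) {
      return(ContigTriplet(DNAStringSet(vapply(trip, paste, character(1),
                                               collapse = "")),
                           genome, snpOffset, alleles[1], alleles[2]))
    }
  }
  ach <- mean(trip[[genome]] != trip[[setdiff(c("A","B","D"), genome)[1]]])
  stop(sprintf(paste0("could not place a genome-discriminating site within ",
                      "%d bases of the SNP after %d tries ",
                      "(achieved pairwise divergence %.4f)"),
               window, maxRetries, ach), call. = FALSE)
}
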