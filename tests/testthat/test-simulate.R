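test_that("founder simulation honours frequency, determinism and coding", {
  gm <- lineMap(1)
  f <- simulateFounders(2, gm, seed = 1)
  expect_true(all(calls(f) %in% c(0L, 1L)))
  expect_identical(calls(simulateFounders(5, lineMap(20), seed = 9)),
                   calls(simulateFounders(5, lineMap(20), seed = 9)))
  # binomial oracle: frequency 0.3 at n = 10,000 founders
  f2 <- simulateFounders(10000, gm, seed = 4, freq = 0.3)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(calls(f2)) - 0.3), 3 * se)
  expect_error(simulateFounders(2, GeneticMap(data.frame(
    marker_id = character(0), linkage_group = character(0),
    position = numeric(0), map_source = character(0))), seed = 1),
    "empty")
})

test_that("gametes follow the Haldane model within and across linkage groups", {
  # r = 0: complete co-transmission
  gm0 <- GeneticMap(c("a", "b"), "1A", c(5, 5))
  h1 <- setNames(c(0L, 0L), c("a", "b")); h2 <- setNames(c(1L, 1L), c("a", "b"))
  g <- simulateGamete(h1, h2, gm0, seed = 2, n = 2000)
  expect_true(all(g[, 1] == g[, 2]))
  # 10 cM: recombinant fraction (1 - exp(-0.2))/2 = 0.0906
  gm10 <- GeneticMap(c("a", "b"), "1A", c(0, 10))
  g10 <- simulateGamete(h1, h2, gm10, seed = 3, n = 100000)
  rf <- mean(g10[, 1] != g10[, 2])
  p <- (1 - exp(-0.2)) / 2
  expect_lt(abs(rf - p), 3 * sqrt(p * (1 - p) / 100000))
  # different linkage groups: independent assortment, r = 0.5
  gmX <- GeneticMap(c("a", "b"), c("1A", "2B"), c(0, 0))
  gX <- simulateGamete(h1, h2, gmX, seed = 5, n = 100000)
  expect_lt(abs(mean(gX[, 1] != gX[, 2]) - 0.5), 3 * sqrt(0.25 / 100000))
  expect_error(simulateGamete(setNames(c(0L, NA), c("a", "b")), h2, gm10,
                              seed = 1), "missing")
})

test_that("pedigree lines stay inbred and transmit only parental alleles", {
  gm <- lineMap(60)
  ped <- Pedigree(data.frame(
    line = c("P1", "P2", "C1"), mother = c(NA, NA, "P1"),
    father = c(NA, NA, "P2")))
  f <- simulateFounders(2, gm, seed = 11)
  rownames(f@calls) <- c("P1", "P2")
  g <- simulatePedigreeLines(ped, f, gm, seed = 12)
  m <- calls(g)
  # transmission closure: child allele always one of the parental alleles
  expect_true(all(m["C1", ] == m["P1", ] | m["C1", ] == m["P2", ]))
  # child of two identical founders equals the founders
  f2 <- f; f2@calls["P2", ] <- f2@calls["P1", ]
  g2 <- simulatePedigreeLines(ped, f2, gm, seed = 13)
  expect_identical(calls(g2)["C1", ], calls(g2)["P1", ])
  expect_error(simulatePedigreeLines(
    Pedigree(data.frame(line = c("A", "B"), mother = c("B", "A"),
                        father = c("B", "A"))), f, gm, seed = 1))
})

test_that("full sibs are more kin than unrelated founders", {
  gm <- lineMap(80)
  nrep <- 60
  sib <- unrel <- numeric(nrep)
  for (i in seq_len(nrep)) {
    ped <- Pedigree(data.frame(
      line = c("P1", "P2", "P3", "P4", "S1", "S2"),
      mother = c(NA, NA, NA, NA, "P1", "P1"),
      father = c(NA, NA, NA, NA, "P2", "P2")))
    f <- simulateFounders(4, gm, seed = 500 + i)
    rownames(f@calls) <- c("P1", "P2", "P3", "P4")
    g <- calls(simulatePedigreeLines(ped, f, gm, seed = 600 + i))
    sib[i] <- mean(g["S1", ] == g["S2", ])
    unrel[i] <- mean(g["P3", ] == g["P4", ])
  }
  expect_gt(mean(sib), mean(unrel))
})

test_that("phenotype simulation reduces correctly in degenerate settings", {
  gm <- lineMap(10)
  f <- simulateFounders(6, gm, seed = 3)
  cfg0 <- SimulationConfig(var_genotype = 0, var_environment = 0,
                           var_residual = 0, qtl_spec = data.frame(
                             linkage_group = character(0),
                             position = numeric(0), effect = numeric(0)),
                           n_environments = 3, n_reps = 2, mu = 64)
  ph <- simulatePhenotypes(f, cfg0, seed = 5)
  expect_true(all(phenoRecords(ph)$value == 64))
  # one QTL of effect 2 with zero residual: class difference exactly 2
  qs <- data.frame(marker_id = mapTable(gm)$marker_id[5], linkage_group = "1A",
                   position = mapTable(gm)$position[5], effect = 2)
  cfg1 <- SimulationConfig(var_genotype = 0, var_environment = 1,
                           var_residual = 0, qtl_spec = qs,
                           n_environments = 2, n_reps = 1)
  ph1 <- simulatePhenotypes(f, cfg1, seed = 6)
  r <- phenoRecords(ph1)
  env1 <- r[r$environment == "E01", ]
  x <- calls(f)[env1$accession, qs$marker_id]
  expect_equal(diff(tapply(env1$value, x, mean)[c("0", "1")]),
               c(`1` = 2))
  expect_error(SimulationConfig(var_residual = -1), "non-negative")
})

test_that("DH populations segregate 1:1 and flag monomorphic crosses", {
  gm <- lineMap(1)
  p1 <- setNames(0L, mapTable(gm)$marker_id)
  p2 <- setNames(1L, mapTable(gm)$marker_id)
  pop <- simulateDHPopulation(p1, p2, 10000, gm, seed = 7)
  frac <- mean(calls(pop)[, 1])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # parents sharing an allele: monomorphic in all lines (oriented to 1)
  gm2 <- lineMap(2)
  q1 <- setNames(c(0L, 1L), mapTable(gm2)$marker_id)
  q2 <- setNames(c(1L, 1L), mapTable(gm2)$marker_id)
  pop2 <- simulateDHPopulation(q1, q2, 50, gm2, seed = 8)
  expect_true(all(calls(pop2)[, 2] == 1L))
  expect_warning(simulateDHPopulation(q2, q2, 5, gm2, seed = 9),
                 "monomorphic")
})

test_that("contig triplets carry the stated divergence and target SNP", {
  # divergence 0: identical sequences except the SNP
  t0 <- simulateContigTriplet(400, 0, 200, c("T", "G"), seed = 2)
  s <- lapply(contigSequences(t0), function(x) strsplit(as.character(x), "")[[1]])
  expect_equal(sum(s$A != s$B), 1L)
  expect_equal(which(s$A != s$B), 201L)
  # binomial oracle: 1 kb at 3% pairwise divergence -> about 30 differences
  t3 <- simulateContigTriplet(1000, 0.03, 500, c("T", "G"), seed = 5)
  s3 <- lapply(contigSequences(t3), function(x) strsplit(as.character(x), "")[[1]])
  se <- sqrt(1000 * 0.03 * 0.97)
  expect_lt(abs(sum(s3$A != s3$B) - 30), 3 * se)
  expect_lt(abs(sum(s3$B != s3$D) - 30), 3 * se)
  # the target SNP reads back at the stated offset with stated alleles
  snp <- targetSnp(t3)
  expect_equal(s3$A[snp$offset + 1], snp$ref)
  expect_equal(snp$ref, "T"); expect_equal(snp$alt, "G")
  expect_error(simulateContigTriplet(400, 0.3, 200, c("T", "G"), seed = 1),
               "divergence")
})

test_that("the breeding study is reproducible and internally consistent", {
  st <- suppressWarnings(simulateBreedingStudy(
    SimulationConfig(n_markers_per_lg = 30), seed = 77, nPanel = 25,
    nDHLines = 30))
  st2 <- suppressWarnings(simulateBreedingStudy(
    SimulationConfig(n_markers_per_lg = 30), seed = 77, nPanel = 25,
    nDHLines = 30))
  expect_identical(calls(st$genotypes), calls(st2$genotypes))
  expect_identical(phenoRecords(st$phenotypes), phenoRecords(st2$phenotypes))
  expect_equal(length(st$panel), 25)
  expect_true(all(st$qtlMarkers$marker_id %in% markerIds(st$genotypes)))
  expect_true(st$focal %in% pedigreeEntries(st$pedigree)$line)
  expect_setequal(unique(st$kernelType), c(0L, 1L))
})
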