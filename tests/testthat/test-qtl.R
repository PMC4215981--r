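# minimal MTA table for grouping tests
mtaRow <- function(id, lg, pos, src = "SNP-consensus", q = 0.3) {
  data.frame(marker_id = id, maf = 0.3, p_value = q / 10, q_value = q,
             r_squared = 0.1, effect = 2, map_source = src,
             linkage_group = lg, position = pos, stringsAsFactors = FALSE)
}

test_that("markers within the gap merge into one QTL, distant ones split", {
  # the 3B pattern: a 61.0-71.7 cM cluster and a marker at 91.1 form two
  # QTLs at a 15 cM gap
  mta <- rbind(mtaRow(paste0("s", 1:4), "3B", c(61.0, 64.2, 68.4, 71.7)),
               mtaRow("s5", "3B", 91.1))
  q <- classifyMTAs(mta, gapCm = 15)
  expect_equal(nrow(q), 2)
  expect_equal(q$qtl_id, c("3B.1", "3B.2"))
  expect_equal(q$cm_start, c(61.0, 91.1))
  expect_equal(q$cm_end, c(71.7, 91.1))
  expect_equal(q$n_markers, c(4, 1))
  # a single marker forms a single one-member QTL labelled by its group
  q1 <- classifyMTAs(mtaRow("x", "5A", 27.8), gapCm = 15)
  expect_equal(q1$qtl_id, "5A")
  expect_equal(q1$n_markers, 1)
})

test_that("grouping equals the transitive closure of the gap relation", {
  set.seed(41)
  for (rep in 1:20) {
    pos <- sort(round(runif(12, 0, 200), 1))
    mta <- mtaRow(sprintf("m%02d", 1:12), "2B", pos)
    gap <- sample(c(5, 15, 30), 1)
    q <- classifyMTAs(mta, gapCm = gap)
    # oracle: closure over the adjacency pos[i+1] - pos[i] <= gap
    brk <- cumsum(c(0, diff(pos) > gap))
    expect_equal(nrow(q), length(unique(brk)))
    expect_equal(q$n_markers, as.vector(table(brk)))
  }
})

test_that("QTL grouping is idempotent and order-invariant", {
  mta <- rbind(mtaRow(paste0("a", 1:3), "1B", c(10, 12, 40)),
               mtaRow(paste0("b", 1:2), "7D", c(1.6, 2.1), src = "DArT-consensus"))
  q1 <- classifyMTAs(mta, gapCm = 15)
  q2 <- classifyMTAs(mta[sample(nrow(mta)), ], gapCm = 15)
  expect_equal(q1, q2, ignore_attr = TRUE)
  # maps are grouped separately: DArT markers never merge with SNP markers
  expect_setequal(q1$map_source[q1$linkage_group == "7D"], "DArT-consensus")
})

test_that("unlocated significant markers are reported, not grouped", {
  mta <- rbind(mtaRow("ok", "1B", 10), mtaRow("lost", NA, NA))
  q <- classifyMTAs(mta, gapCm = 15)
  expect_equal(nrow(q), 1)
  expect_equal(attr(q, "unlocated"), "lost")
})

test_that("LD r-squared behaves at its boundary cases", {
  set.seed(42)
  m <- matrix(rbinom(40, 1, 0.5), 10, 4,
              dimnames = list(paste0("a", 1:10), paste0("m", 1:4)))
  m[, 2] <- m[, 1]          # perfect correlation
  m[, 3] <- 1L - m[, 1]     # perfect anti-correlation
  g <- GenotypeMatrix(m)
  expect_equal(ldR2(g, "m1", "m1"), 1)
  expect_equal(ldR2(g, "m1", "m2"), 1)
  expect_equal(ldR2(g, "m1", "m3"), 1)
  expect_true(is.na(ldR2(g, "m1", "m4") ) ||
                ldR2(g, "m1", "m4") <= 1)   # defined when polymorphic
  mono <- gmat(cbind(rep(1L, 10), rbinom(10, 1, 0.5)))
  expect_true(is.na(ldR2(mono, "m01", "m02")))
  # independent markers at n = 10,000: r^2 near zero
  big <- gmat(matrix(rbinom(20000, 1, 0.5), 10000, 2))
  expect_lt(ldR2(big, "m01", "m02"), 0.003)
})

test_that("a planted high-LD segment is recovered exactly as a block", {
  set.seed(43)
  n <- 40
  hap <- rbinom(n, 1, 0.5)
  m <- matrix(rbinom(n * 9, 1, 0.5), n, 9)
  for (j in 3:7) m[, j] <- hap                      # 5-marker segment
  # a couple of recombinants so adjacent r^2 is high but below 1
  m[1:2, 4] <- 1 - m[1:2, 4]
  colnames(m) <- sprintf("m%02d", 1:9); rownames(m) <- sprintf("a%02d", 1:n)
  g <- GenotypeMatrix(m)
  map <- GeneticMap(colnames(m), "6A", seq(0, 16, 2), "SNP-consensus")
  qtl <- data.frame(qtl_id = "6A", map_source = "SNP-consensus",
                    linkage_group = "6A", markers = "m05",
                    stringsAsFactors = FALSE)
  blk <- detectLDBlock(g, map, qtl, r2Min = 0.7, minMarkers = 3)
  expect_true(blk$present)
  expect_setequal(blk$marker_ids, sprintf("m%02d", 3:7))
  expect_equal(blk$size_cm, 8)
  # allele-code flips do not change the block
  m2 <- m; m2[, 5] <- 1L - m2[, 5]
  blk2 <- detectLDBlock(GenotypeMatrix(m2), map, qtl, 0.7, 3)
  expect_setequal(blk2$marker_ids, blk$marker_ids)
  # an isolated single-marker QTL yields an absent block
  qtl2 <- qtl; qtl2$markers <- "m01"
  blk3 <- detectLDBlock(g, map, qtl2, 0.7, 3)
  expect_false(blk3$present)
})

test_that("block similarity counts matching calls against the focal line", {
  m <- matrix(c(1L, 1L, 1L, 1L,
                1L, 1L, 1L, 0L,
                0L, 0L, 0L, 0L,
                1L, NA, 1L, 0L), 4, 4, byrow = TRUE,
              dimnames = list(c("focal", "near", "far", "gappy"),
                              paste0("m", 1:4)))
  s <- blockSimilarity(GenotypeMatrix(m), paste0("m", 1:4), "focal")
  expect_equal(s[["focal"]], 1)
  expect_equal(s[["near"]], 0.75)
  expect_equal(s[["far"]], 0)
  expect_equal(s[["gappy"]], 2 / 3)     # over mutually non-missing markers
})

test_that("origin classes follow the focal line's parents", {
  ped <- Pedigree(data.frame(
    line = c("GM", "GF", "M", "F", "X"),
    mother = c(NA, NA, "GM", NA, "M"),
    father = c(NA, NA, "GF", NA, "F")))
  simBase <- c(GM = 0.2, GF = 0.2, M = 0.2, F = 0.2)
  # maternal path carries the block: mother and her mother
  s <- simBase; s[c("M", "GM")] <- 1
  tr <- traceOrigin(ped, s, "X", carrierThreshold = 0.9)
  expect_equal(tr$origin_class, "maternal")
  expect_equal(tr$source_ancestors, "GM")
  expect_false(tr$discrepancy)
  # both parents carry: undetermined side
  s2 <- simBase; s2[c("M", "F", "GM")] <- 1
  expect_equal(traceOrigin(ped, s2, "X", 0.9)$origin_class,
               "both_undetermined")
  # a non-founder carrier with no carrying parent flags a discrepancy
  s3 <- simBase; s3["M"] <- 1
  tr3 <- traceOrigin(ped, s3, "X", 0.9)
  expect_true(tr3$discrepancy)
  expect_equal(tr3$source_ancestors, "M")
  expect_error(traceOrigin(ped, s, "nope", 0.9), "absent")
})

test_that("tagged transmission recovers the introducing founder", {
  # block introduced in one founder, transmitted to the focal line; the
  # trace must name that founder as the source
  gm <- GeneticMap(sprintf("b%d", 1:6), "2B", rep(10, 6), "SNP-consensus")
  ok <- 0
  for (i in 1:25) {
    ped <- Pedigree(data.frame(
      line = c("F1", "F2", "F3", "F4", "M", "P", "X"),
      mother = c(NA, NA, NA, NA, "F1", "F3", "M"),
      father = c(NA, NA, NA, NA, "F2", "F4", "P")))
    f <- simulateFounders(4, gm, seed = 8000 + i, freq = 0.5)
    fc <- calls(f); rownames(fc) <- c("F1", "F2", "F3", "F4")
    fc["F1", ] <- 1L                        # tag: F1 carries the block
    fc["F2", ] <- 0L; fc["F3", ] <- 0L; fc["F4", ] <- 0L
    g <- simulatePedigreeLines(ped, GenotypeMatrix(fc), gm, seed = 8100 + i)
    if (!all(calls(g)["X", ] == 1L)) next   # focal must have inherited it
    sims <- blockSimilarity(g, sprintf("b%d", 1:6), "X")
    tr <- traceOrigin(ped, sims, "X", carrierThreshold = 0.9)
    if ("F1" %in% tr$source_ancestors && !tr$discrepancy) ok <- ok + 1
  }
  expect_gt(ok, 0)
  # every conditioned replicate must trace back to F1
  expect_equal(ok, sum(vapply(1:25, function(i) {
    ped <- Pedigree(data.frame(
      line = c("F1", "F2", "F3", "F4", "M", "P", "X"),
      mother = c(NA, NA, NA, NA, "F1", "F3", "M"),
      father = c(NA, NA, NA, NA, "F2", "F4", "P")))
    f <- simulateFounders(4, gm, seed = 8000 + i, freq = 0.5)
    fc <- calls(f); rownames(fc) <- c("F1", "F2", "F3", "F4")
    fc["F1", ] <- 1L; fc["F2", ] <- 0L; fc["F3", ] <- 0L; fc["F4", ] <- 0L
    g <- simulatePedigreeLines(ped, GenotypeMatrix(fc), gm, seed = 8100 + i)
    all(calls(g)["X", ] == 1L)
  }, logical(1))))
})
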