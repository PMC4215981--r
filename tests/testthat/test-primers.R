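test_that("melting temperature responds to composition and length", {
  expect_gt(meltingTemperature("GCGCGCGCGCGCGCGCGCGC"),
            meltingTemperature("ATATATATATATATATATAT"))
  expect_gt(meltingTemperature("ACGTACGTACGTACGTACGTACGT"),
            meltingTemperature("ACGTACGTACGTACGT"))
  expect_error(meltingTemperature("ACGT"), "short")
})

test_that("GSP design fails cleanly without genome-discriminating sites", {
  t0 <- simulateContigTriplet(600, 0, 300, c("T", "G"), seed = 4)
  expect_error(designGSP(t0), "no genome-specific site")
})

test_that("designed GSPs anchor on discriminating sites with the SNP at one third", {
  for (seed in c(3, 8, 15)) {
    trip <- simulateContigTriplet(1000, 0.03, 500, c("T", "G"), seed = seed)
    gsp <- designGSP(trip)
    tgt <- as.character(contigSequences(trip)[[targetSnp(trip)$genome]])
    # post-hoc verification: primers sit on the target sequence
    expect_equal(substr(tgt, gsp$amplicon[1] + 1,
                        gsp$amplicon[1] + nchar(gsp$forward)), gsp$forward)
    # SNP fraction within [1/3 - 0.1, 1/3 + 0.1] from the nearer primer
    f <- min(gsp$snp_frac, 1 - gsp$snp_frac)
    expect_gte(f, 0.233); expect_lte(f, 0.434)
    expect_true(gsp$length >= 150 && gsp$length <= 600)
    # each primer footprint covers at least one discriminating site
    disc <- which(pedQTL:::discriminatingSites(trip))
    fw <- (gsp$amplicon[1] + 1):(gsp$amplicon[1] + nchar(gsp$forward))
    rv <- (gsp$amplicon[2] - nchar(gsp$reverse) + 1):gsp$amplicon[2]
    expect_gt(length(intersect(disc, fw)), 0)
    expect_gt(length(intersect(disc, rv)), 0)
    # Tm inside the annealing window
    expect_true(all(gsp$tm >= 55 & gsp$tm <= 62))
  }
})

test_that("ASPs end on the SNP with the engineered third-base transversion", {
  nOk <- 0
  for (seed in 1:40) {
    trip <- simulateContigTriplet(1000, 0.03, 500, c("T", "G"), seed = seed)
    ps <- tryCatch(designPrimerSet(trip), error = function(e) NULL)
    if (is.null(ps)) next
    nOk <- nOk + 1
    a1 <- ps@aspAllele1; a2 <- ps@aspAllele2
    # the two ASPs differ from each other only at the 3' base
    expect_equal(which(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]]),
                 nchar(a1))
    expect_equal(substring(a1, nchar(a1)), ps@aspAlleles[1])
    expect_equal(substring(a2, nchar(a2)), ps@aspAlleles[2])
    # exactly one engineered mismatch against its own allele's template,
    # two against the other allele's template
    tgt <- as.character(contigSequences(trip)[[targetSnp(trip)$genome]])
    snpPos <- targetSnp(trip)$offset + 1
    len <- nchar(a1)
    tmplWith <- function(allele) {
      s <- tgt; substr(s, snpPos, snpPos) <- allele; s
    }
    footprint <- function(tmpl) {
      if (ps@aspOrientation == "forward")
        substr(tmpl, snpPos - len + 1, snpPos)
      else pedQTL:::revcompStr(substr(tmpl, snpPos, snpPos + len - 1))
    }
    mm <- function(p, t) sum(strsplit(p, "")[[1]] != strsplit(t, "")[[1]])
    own1 <- footprint(tmplWith(targetSnp(trip)$ref))
    own2 <- footprint(tmplWith(targetSnp(trip)$alt))
    expect_equal(mm(a1, own1), 1)   # only the engineered transversion
    expect_equal(mm(a2, own2), 1)
    expect_equal(mm(a1, own2), 2)   # transversion + allele mismatch
    expect_equal(mm(a2, own1), 2)
    # the engineered substitution is the documented transversion partner
    expect_equal(ps@aspMismatch$substituted,
                 unname(c(A = "C", C = "A", G = "T", T = "G")[
                   ps@aspMismatch$original]))
  }
  expect_gt(nOk, 30)
})

test_that("in-silico PCR honours the band-pattern contract", {
  trip <- simulateContigTriplet(1000, 0.03, 500, c("T", "G"), seed = 3)
  ps <- designPrimerSet(trip)
  seqs <- contigSequences(trip)
  tgt <- as.character(seqs[[targetSnp(trip)$genome]])
  snpPos <- targetSnp(trip)$offset + 1
  t1 <- tgt; substr(t1, snpPos, snpPos) <- targetSnp(trip)$ref
  t2 <- tgt; substr(t2, snpPos, snpPos) <- targetSnp(trip)$alt
  b1 <- insilicoPCR(ps, t1)
  expect_equal(b1$reaction1$n_bands, 2)     # matching allele: GSP + ASP band
  expect_equal(b1$reaction2$n_bands, 1)     # non-matching: GSP band only
  expect_equal(max(b1$reaction1$band_sizes),
               unname(ps@expectedSizes[["gsp"]]))
  expect_equal(min(b1$reaction1$band_sizes),
               unname(ps@expectedSizes[["asp"]]))
  b2 <- insilicoPCR(ps, t2)
  expect_equal(b2$reaction2$n_bands, 2)
  expect_equal(b2$reaction1$n_bands, 1)
  # off-target genomes: no bands at all
  for (gn in setdiff(names(seqs), targetSnp(trip)$genome)) {
    off <- insilicoPCR(ps, as.character(seqs[[gn]]))
    expect_equal(off$reaction1$n_bands, 0)
    expect_equal(off$reaction2$n_bands, 0)
  }
})

test_that("primer binding sites equal a brute-force scan of every offset", {
  # independent oracle: slide the primer over every offset on both strands
  bruteSites <- function(primer, template) {
    p <- strsplit(primer, "")[[1]]; L <- length(p)
    tc <- strsplit(template, "")[[1]]
    rc <- strsplit(pedQTL:::revcompStr(primer), "")[[1]]
    hits <- list()
    for (s in seq_len(length(tc) - L + 1)) {
      w <- tc[s:(s + L - 1)]
      mmF <- which(w != p)
      if (length(mmF) <= 3 && !(L %in% mmF) &&
          sum(L - mmF + 1 <= 5) <= 1)
        hits[[length(hits) + 1]] <- c(s, s + L - 1, 1)
      mmR <- which(w != rc)
      if (length(mmR) <= 3 && !(1 %in% mmR) && sum(mmR <= 5) <= 1)
        hits[[length(hits) + 1]] <- c(s, s + L - 1, -1)
    }
    do.call(rbind, hits)
  }
  set.seed(51)
  for (rep in 1:5) {
    tmpl <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    primer <- substr(tmpl, 100, 119)
    # plant a near-match elsewhere
    sub <- strsplit(substr(tmpl, 100, 119), "")[[1]]
    sub[7] <- setdiff(c("A", "C", "G", "T"), sub[7])[1]
    tmpl2 <- paste0(substr(tmpl, 1, 299), paste(sub, collapse = ""),
                    substr(tmpl, 320, 400))
    got <- pedQTL:::primerBindingSites(primer, tmpl2)
    want <- bruteSites(primer, tmpl2)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want))
      expect_setequal(paste(got$start, got$strand),
                      paste(want[, 1], ifelse(want[, 3] == 1, "+", "-")))
  }
})

test_that("validation passes a well-formed set and fails a wrong-genome set", {
  trip <- simulateContigTriplet(1000, 0.03, 500, c("T", "G"), seed = 3)
  ps <- designPrimerSet(trip)
  expect_true(validatePrimerSet(ps, trip)$pass)
  # constructed counterexample: GSPs lifted from the B genome
  bseq <- as.character(contigSequences(trip)[["B"]])
  bad <- ps
  bad@gspForward <- substr(bseq, 350, 371)
  bad@gspReverse <- pedQTL:::revcompStr(substr(bseq, 560, 581))
  v <- validatePrimerSet(bad, trip)
  expect_false(v$pass)
  expect_true(any(grepl("off-target amplification", v$failures)))
})
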