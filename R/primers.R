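# Conversion of an array SNP into a genome-specific + allele-specific PCR
# assay for a polyploid, and in-silico PCR verification.
#
# Genome specificity is obtained by anchoring each genome-specific primer
# (GSP) 3' end on a site where the target subgenome differs from both
# homoeologous partners, so that off-genome binding fails the 3'-exact
# binding rule.  Allele specificity follows the classic two-reaction
# design: each allele-specific primer (ASP) ends on the SNP and carries an
# engineered destabilising mismatch at the third base from the 3' end.
# The primer-binding rule used throughout (3' base exact, at most 1
# mismatch within the 3'-terminal 5 bases, at most 3 overall, ungapped) is
# an engineering contract, not thermodynamics.

# --- nearest-neighbour melting temperature (SantaLucia 1998 unified
#     parameters; 0.25 uM primer; salt as the monovalent equivalent of a
#     standard PCR mix, 50 mM KCl + 1.5 mM MgCl2 ~ 150 mM) ----------------
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbour primer melting temperature
#'
#' Unified nearest-neighbour model with terminal initiation terms, 0.25 uM
#' primer, and a salt correction at the monovalent equivalent of a
#' standard PCR buffer (50 mM KCl plus 1.5 mM MgCl2, about 150 mM).
#'
#' @param seq primer sequence (5'->3').
#' @return Tm in degrees Celsius.
#' @export
meltingTemperature <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  stopIfNot(length(s) >= 8, "primer too short for a meaningful Tm")
  pairs <- paste0(s[-length(s)], s[-1])
  dh <- sum(NN_DH[pairs]); ds <- sum(NN_DS[pairs])
  for (term in c(s[1], s[length(s)])) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ct <- 0.25e-6
  tm <- dh * 1000 / (ds + 1.987 * log(ct / 4)) - 273.15
  tm + 16.6 * log10(0.15)
}

complementBase <- c(A = "T", C = "G", G = "C", T = "A")
revcompStr <- function(x) paste(rev(complementBase[strsplit(x, "")[[1]]]),
                                collapse = "")

# deterministic transversion partner used for the engineered ASP mismatch
TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

#' Retrieve the homoeologous contig triplet for a probe
#'
#' Local-alignment search (match +1, mismatch -2, affine gaps: open 4,
#' extend 1) of the probe against a genome-labelled contig database; the
#' best-scoring contig per subgenome is retained and the contig with a
#' perfect full-length probe match is designated the target genome.
#'
#' @param probe probe sequence containing the SNP (character or
#'   DNAString); the template carries the `alleles[1]` base.
#' @param contigDb \link[Biostrings]{DNAStringSet} whose names identify
#'   the genome of origin (an A/B/D token or `genome=X` tag).
#' @param snpOffsetInProbe 0-based offset of the SNP within the probe.
#' @param alleles character(2): (ref, alt).
#' @param minScore minimum alignment score per genome; default half the
#'   probe length (calibrated so 97%-identical homoeologs pass and
#'   unrelated sequences fail).
#' @return a \linkS4class{ContigTriplet}.
#' @export
findHomoeologs <- function(probe, contigDb, snpOffsetInProbe, alleles,
                           minScore = NULL) {
  probe <- toupper(as.character(probe))
  if (is.null(minScore)) minScore <- nchar(probe) / 2
  nm <- names(contigDb)
  lab <- ifelse(grepl("genome=([ABD])", nm),
                sub(".*genome=([ABD]).*", "\\1", nm),
                sub(".*\\b([ABD])\\b.*", "\\1", nm))
  stopIfNot(all(lab %in% c("A", "B", "D")),
            "contig names must identify genomes A, B or D")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2)
  best <- list()
  for (gn in c("A", "B", "D")) {
    idx <- which(lab == gn)
    if (!length(idx)) next
    scores <- vapply(idx, function(i)
      Biostrings::pairwiseAlignment(probe, contigDb[[i]], type = "local",
                                    substitutionMatrix = submat,
                                    gapOpening = 4, gapExtension = 1,
                                    scoreOnly = TRUE), numeric(1))
    if (max(scores) >= minScore)
      best[[gn]] <- list(i = idx[which.max(scores)], score = max(scores))
  }
  if (length(best) < 3)
    stop("homoeolog set incomplete: genomes above minimum score: ",
         paste(names(best), collapse = ", "), call. = FALSE)
  target <- names(best)[vapply(best, function(b) b$score, numeric(1)) ==
                          nchar(probe)]
  if (length(target) == 0) {
    target <- names(best)[which.max(vapply(best, function(b) b$score,
                                           numeric(1)))]
    warning("no contig matches the probe perfectly; using best-scoring ",
            "genome ", target)
  }
  target <- target[1]
  seqs <- DNAStringSet(vapply(best, function(b)
    as.character(contigDb[[b$i]]), character(1)))
  names(seqs) <- names(best)
  hit <- matchPattern(probe, seqs[[target]], max.mismatch = 2)
  stopIfNot(length(hit) >= 1, "probe not locatable on the target contig")
  snpOffset <- BiocGenerics::start(hit)[1] - 1L + as.integer(snpOffsetInProbe)
  ref <- as.character(subseq(seqs[[target]], snpOffset + 1, snpOffset + 1))
  if (identical(ref, alleles[2])) alleles <- rev(alleles)
  stopIfNot(identical(ref, alleles[1]),
            "neither stated allele matches the target contig at the SNP")
  ContigTriplet(seqs, target, snpOffset, alleles[1], alleles[2])
}

# per-position flags on the target contig: TRUE where the target base
# differs from both homoeologous partners (gap = difference)
discriminatingSites <- function(triplet) {
  seqs <- contigSequences(triplet)
  tgt <- as.character(seqs[[triplet@snpGenome]])
  others <- setdiff(names(seqs), triplet@snpGenome)
  tchr <- strsplit(tgt, "")[[1]]
  diffTo <- function(other) {
    ochr0 <- strsplit(as.character(seqs[[other]]), "")[[1]]
    if (length(ochr0) == length(tchr)) return(tchr != ochr0)
    aln <- Biostrings::pairwiseAlignment(
      seqs[[other]], seqs[[triplet@snpGenome]], type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 4, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    out <- rep(TRUE, length(tchr))     # unaligned target positions differ
    ti <- 0
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        ti <- ti + 1
        out[ti] <- pa[k] == "-" || pa[k] != sa[k]
      }
    }
    out
  }
  d <- diffTo(others[1]) & diffTo(others[2])
  d[triplet@snpOffset + 1] <- FALSE     # the SNP itself is allelic, not genomic
  d
}

#' Design a genome-specific primer pair
#'
#' Each primer's 3'-terminal base is anchored on a genome-discriminating
#' site (target differs from both homoeologs), the amplicon length lies in
#' `constraints$amplicon`, the SNP sits at about one third of the interval
#' between the primers (within `constraints$snp_frac_tol` of 1/3, measured
#' from the nearer primer), and both primer Tm values fall in the
#' annealing range.
#'
#' @param triplet a \linkS4class{ContigTriplet}.
#' @param constraints list; defaults: primer length 18-25, annealing range
#'   55-62 C, amplicon 150-600 bp, SNP fraction tolerance 0.1.
#' @return list with `forward`, `reverse` (sequences 5'->3'), 0-based
#'   half-open `amplicon` interval, `length`, `snp_frac`, `tm` and the
#'   1-based SNP position `snp_pos`.
#' @export
designGSP <- function(triplet,
                      constraints = list(primer_len = c(18, 25),
                                         tm_range = c(55, 62),
                                         amplicon = c(150, 600),
                                         snp_frac_tol = 0.1)) {
  cs <- constraints
  if (is.null(cs$primer_len)) cs$primer_len <- c(18, 25)
  if (is.null(cs$tm_range)) cs$tm_range <- c(55, 62)
  if (is.null(cs$amplicon)) cs$amplicon <- c(150, 600)
  if (is.null(cs$snp_frac_tol)) cs$snp_frac_tol <- 0.1
  tgt <- as.character(contigSequences(triplet)[[triplet@snpGenome]])
  L <- nchar(tgt)
  snpPos <- triplet@snpOffset + 1L         # 1-based
  disc <- which(discriminatingSites(triplet))
  if (length(disc) == 0)
    stop("no genome-specific site", call. = FALSE)
  lensF <- seq(cs$primer_len[1], cs$primer_len[2])
  tmOK <- function(seq) {
    tm <- meltingTemperature(seq)
    tm >= cs$tm_range[1] && tm <= cs$tm_range[2]
  }
  fr3 <- disc[disc < snpPos - 1]           # candidate forward 3' anchors
  rr3 <- disc[disc > snpPos + 1]           # candidate reverse 3' anchors
  sawSite <- FALSE; sawTm <- FALSE
  for (f3 in rev(fr3)) {                   # nearest to the SNP first
    for (lf in lensF) {
      astart <- f3 - lf + 1
      if (astart < 1) next
      dF <- snpPos - astart + 1
      for (r3 in rr3) {
        for (lr in lensF) {
          aend <- r3 + lr - 1
          if (aend > L) next
          A <- aend - astart + 1
          if (A < cs$amplicon[1] || A > cs$amplicon[2]) next
          frac <- dF / A
          if (abs(min(frac, 1 - frac) - 1 / 3) > cs$snp_frac_tol) next
          sawSite <- TRUE
          fwd <- substr(tgt, astart, f3)
          rev_ <- revcompStr(substr(tgt, r3, aend))
          if (!tmOK(fwd) || !tmOK(rev_)) { sawTm <- TRUE; next }
          return(list(forward = fwd, reverse = rev_,
                      amplicon = c(astart - 1L, aend), length = A,
                      snp_frac = frac, snp_pos = snpPos,
                      tm = c(forward = meltingTemperature(fwd),
                             reverse = meltingTemperature(rev_))))
        }
      }
    }
  }
  if (!length(fr3) || !length(rr3) || !sawSite) {
    if (!sawSite && length(fr3) && length(rr3))
      stop("constraint-infeasible: no amplicon in ",
           cs$amplicon[1], "-", cs$amplicon[2],
           " bp places the SNP at 1/3 between discriminating anchors",
           call. = FALSE)
    stop("no genome-specific site", call. = FALSE)
  }
  stop("constraint-infeasible: primer Tm outside the annealing range ",
       cs$tm_range[1], "-", cs$tm_range[2], " C at every feasible anchor",
       call. = FALSE)
}

#' Design the two allele-specific primers
#'
#' Each ASP ends exactly on the SNP with its allele as the 3' base and
#' carries the deterministic transversion substitution (A<->C, G<->T) at
#' the third base from the 3' end.  Orientation is chosen so that the ASP
#' amplicon (ASP paired with the distal GSP) is the shorter side of the
#' 1/3 split.
#'
#' @param triplet a \linkS4class{ContigTriplet}.
#' @param gsp result of \code{\link{designGSP}}.
#' @param constraints as in \code{\link{designGSP}}.
#' @param markerId assay label.
#' @return a \linkS4class{PrimerSet}.
#' @export
designASP <- function(triplet, gsp,
                      constraints = list(primer_len = c(18, 25),
                                         tm_range = c(55, 62)),
                      markerId = "assay") {
  cs <- constraints
  if (is.null(cs$primer_len)) cs$primer_len <- c(18, 25)
  if (is.null(cs$tm_range)) cs$tm_range <- c(55, 62)
  tgt <- as.character(contigSequences(triplet)[[triplet@snpGenome]])
  snpPos <- gsp$snp_pos
  astart <- gsp$amplicon[1] + 1L; aend <- gsp$amplicon[2]
  stopIfNot(snpPos > astart && snpPos < aend, "SNP outside the GSP amplicon")
  alleles <- c(triplet@refAllele, triplet@altAllele)
  stopIfNot(alleles[1] != alleles[2], "identical alleles")
  orientation <- if (gsp$snp_frac <= 0.5) "reverse" else "forward"
  buildAsp <- function(len, allele) {
    if (orientation == "forward") {
      s <- snpPos - len + 1
      stopIfNot(s >= astart, "ASP footprint extends past the amplicon")
      p <- strsplit(substr(tgt, s, snpPos), "")[[1]]
      p[len] <- allele
    } else {
      e <- snpPos + len - 1
      stopIfNot(e <= aend, "ASP footprint extends past the amplicon")
      p <- strsplit(revcompStr(substr(tgt, snpPos, e)), "")[[1]]
      p[len] <- complementBase[[allele]]
    }
    orig <- p[len - 2]
    p[len - 2] <- TRANSVERSION[[orig]]
    list(seq = paste(p, collapse = ""), orig = orig, sub = p[len - 2])
  }
  lens <- seq(cs$primer_len[1], cs$primer_len[2])
  tms <- vapply(lens, function(l)
    meltingTemperature(buildAsp(l, alleles[1])$seq), numeric(1))
  inR <- tms >= cs$tm_range[1] & tms <= cs$tm_range[2]
  len <- if (any(inR)) lens[which(inR)[1]] else
    lens[which.min(pmin(abs(tms - cs$tm_range[1]),
                        abs(tms - cs$tm_range[2])))]
  a1 <- buildAsp(len, alleles[1]); a2 <- buildAsp(len, alleles[2])
  aspAlleles <- if (orientation == "forward") alleles else
    unname(complementBase[alleles])
  aspProduct <- if (orientation == "reverse")
    (snpPos + len - 1) - astart + 1 else aend - (snpPos - len + 1) + 1
  new("PrimerSet", markerId = markerId, gspForward = gsp$forward,
      gspReverse = gsp$reverse, aspAllele1 = a1$seq, aspAllele2 = a2$seq,
      aspAlleles = aspAlleles, aspOrientation = orientation,
      aspMismatch = list(position_from_3prime = 3L, original = a1$orig,
                         substituted = a1$sub),
      expectedSizes = c(gsp = gsp$length, asp = aspProduct),
      annealingRange = cs$tm_range)
}

#' Design a full genome- plus allele-specific assay
#'
#' Convenience wrapper: \code{\link{designGSP}} then
#' \code{\link{designASP}}.
#'
#' @inheritParams designGSP
#' @param markerId assay label.
#' @return a \linkS4class{PrimerSet}.
#' @export
designPrimerSet <- function(triplet, constraints = list(),
                            markerId = "assay") {
  gsp <- designGSP(triplet, constraints)
  designASP(triplet, gsp, constraints, markerId = markerId)
}

# binding sites of a primer on a template under the engineering rule:
# ungapped full-length hit, 3'-terminal base exact, <= 1 mismatch within
# the 3'-terminal 5 bases, <= 3 mismatches overall.  Returns a data.frame
# of footprints with the strand and the template position of the 3' end.
primerBindingSites <- function(primer, template, maxMismatch = 3) {
  template <- if (is(template, "DNAString")) template else DNAString(template)
  pl <- nchar(primer)
  res <- list()
  scan <- function(pat, strand) {
    hits <- matchPattern(DNAString(pat), template, max.mismatch = maxMismatch)
    if (length(hits) == 0) return(NULL)
    starts <- BiocGenerics::start(hits); ends <- BiocGenerics::end(hits)
    keep <- logical(length(starts))
    p <- strsplit(pat, "")[[1]]
    tchr <- strsplit(as.character(template), "")[[1]]
    for (i in seq_along(starts)) {
      if (starts[i] < 1 || ends[i] > length(tchr)) next
      w <- tchr[starts[i]:ends[i]]
      mm <- which(w != p)
      threePrime <- if (strand == "+") pl else 1L
      distTo3 <- if (strand == "+") pl - mm + 1L else mm
      keep[i] <- length(mm) <= maxMismatch &&
        !(threePrime %in% mm) && sum(distTo3 <= 5) <= 1
    }
    if (!any(keep)) return(NULL)
    data.frame(start = starts[keep], end = ends[keep], strand = strand,
               three_prime = if (strand == "+") ends[keep] else starts[keep])
  }
  plus <- scan(primer, "+")
  minus <- scan(revcompStr(primer), "-")
  out <- rbind(plus, minus)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0),
                               three_prime = integer(0)) else out
}

#' In-silico PCR of a primer set
#'
#' Each reaction contains both GSPs and one ASP.  A primer binds a site
#' iff its 3'-terminal base matches, it has at most 1 mismatch within its
#' 3'-terminal 5 bases and at most 3 overall (ungapped).  Amplicons are
#' enumerated for every convergent plus/minus pair of bound primers within
#' `maxProduct` bases; zero bands is a valid outcome.
#'
#' @param primers a \linkS4class{PrimerSet}.
#' @param template template sequence (character or DNAString).
#' @param maxProduct largest amplicon considered (bp).
#' @return list with one "BandPattern" per reaction (`reaction1` carries
#'   ASP allele 1): `n_bands` and sorted `band_sizes`.
#' @export
insilicoPCR <- function(primers, template, maxProduct = 2000) {
  reactions <- list(reaction1 = primers@aspAllele1,
                    reaction2 = primers@aspAllele2)
  lapply(reactions, function(asp) {
    prim <- c(primers@gspForward, primers@gspReverse, asp)
    sites <- do.call(rbind, lapply(prim, function(p) {
      s <- primerBindingSites(p, template)
      if (nrow(s)) s$primer <- p
      s
    }))
    bands <- integer(0)
    if (!is.null(sites) && nrow(sites)) {
      fw <- sites[sites$strand == "+", , drop = FALSE]
      rv <- sites[sites$strand == "-", , drop = FALSE]
      if (nrow(fw) && nrow(rv)) {
        for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
          if (fw$three_prime[i] > rv$three_prime[j]) next    # divergent
          size <- rv$end[j] - fw$start[i] + 1L
          if (size >= max(nchar(fw$primer[i]), nchar(rv$primer[j])) &&
              size <= maxProduct)
            bands <- c(bands, size)
        }
      }
    }
    bands <- sort(unique(bands))
    structure(list(n_bands = length(bands), band_sizes = bands),
              class = "BandPattern")
  })
}

#' Validate a primer set's genome and allele specificity
#'
#' Builds the four relevant templates from the triplet (target contig with
#' each SNP allele, plus the two off-genome contigs) and checks the
#' expected band contract: the reaction whose ASP matches the template
#' allele gives 2 bands (GSP product + shorter ASP product), the other
#' reaction gives 1 band (GSP product only), and off-genome templates give
#' 0 bands.
#'
#' @param primers a \linkS4class{PrimerSet}.
#' @param triplet the \linkS4class{ContigTriplet} the assay was designed
#'   on.
#' @return list: `pass` (logical), `failures` (character), `patterns`
#'   (band patterns per template x reaction).
#' @export
validatePrimerSet <- function(primers, triplet) {
  seqs <- contigSequences(triplet)
  tgt <- as.character(seqs[[triplet@snpGenome]])
  sub1 <- tgt
  substr(sub1, triplet@snpOffset + 1, triplet@snpOffset + 1) <-
    triplet@refAllele
  sub2 <- tgt
  substr(sub2, triplet@snpOffset + 1, triplet@snpOffset + 1) <-
    triplet@altAllele
  templates <- c(list(allele1 = sub1, allele2 = sub2),
                 lapply(as.list(as.character(
                   seqs[setdiff(names(seqs), triplet@snpGenome)])), identity))
  patterns <- lapply(templates, function(tp) insilicoPCR(primers, tp))
  failures <- character(0)
  expect <- function(tmpl, rxn, n, what) {
    got <- patterns[[tmpl]][[rxn]]$n_bands
    if (got != n)
      failures <<- c(failures, sprintf("%s/%s: expected %d band(s), got %d%s",
                                       tmpl, rxn, n, got, what))
  }
  expect("allele1", "reaction1", 2, " (matching allele)")
  expect("allele1", "reaction2", 1, " (non-matching allele)")
  expect("allele2", "reaction2", 2, " (matching allele)")
  expect("allele2", "reaction1", 1, " (non-matching allele)")
  for (gn in setdiff(names(seqs), triplet@snpGenome)) {
    got1 <- patterns[[gn]]$reaction1$n_bands
    got2 <- patterns[[gn]]$reaction2$n_bands
    if (got1 != 0 || got2 != 0)
      failures <- c(failures,
                    sprintf("off-target amplification on genome %s", gn))
  }
  list(pass = length(failures) == 0, failures = failures,
       patterns = patterns)
}
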