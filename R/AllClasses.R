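#' @import methods
#' @importFrom stats aov anova cor lm optimize pf pt predict qf rbinom rnorm
#'   runif sd setNames smooth.spline t.test var complete.cases coef prcomp
#' @importFrom utils head read.table write.table
NULL

#' Genetic map of markers
#'
#' Positions of markers on linkage groups of one or more consensus maps.
#' Positions are in centimorgans (cM) and must be non-negative; the table is
#' kept sorted by (map source, linkage group, position) so that downstream
#' interval operations (QTL grouping, LD blocks) can assume map order.
#'
#' @slot table data.frame with columns `marker_id`, `linkage_group`,
#'   `position` (cM) and `map_source`.
#' @export
setClass("GeneticMap", representation(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("marker_id", "linkage_group", "position", "map_source")
  if (!all(need %in% names(tb)))
    return(paste("map table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb) == 0) return(TRUE)
  if (!is.numeric(tb$position)) return("position must be numeric (cM)")
  if (any(!is.finite(tb$position)) || any(tb$position < 0))
    return("positions must be finite and non-negative")
  if (anyDuplicated(tb[, c("marker_id", "map_source")]))
    return("(marker_id, map_source) pairs must be unique")
  # sortedness within (map_source, linkage_group)
  key <- paste(tb$map_source, tb$linkage_group, sep = "\r")
  if (any(tapply(tb$position, key, function(p) any(diff(p) < 0))))
    return("positions must be non-decreasing within each linkage group")
  TRUE
})

#' Biallelic genotype matrix for inbred accessions
#'
#' Calls are coded 0/1 (homozygous classes of an inbred line) with `NA` for
#' missing.  By convention code 1 may be oriented per marker to the focal
#' line's allele; orientation is a property of how the matrix was built,
#' not enforced here.
#'
#' @slot calls integer matrix, accessions in rows (rownames = accession ids),
#'   markers in columns (colnames = marker ids); values in \{0, 1, NA\}.
#' @export
setClass("GenotypeMatrix", representation(calls = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@calls
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("calls must have accession rownames and marker colnames")
  if (anyDuplicated(rownames(m))) return("duplicate accession ids")
  if (anyDuplicated(colnames(m))) return("duplicate marker ids")
  v <- m[!is.na(m)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("genotype codes must be 0, 1 or NA")
  TRUE
})

#' Long-format multi-environment phenotype table
#'
#' @slot records data.frame with columns `accession`, `environment`,
#'   `replicate`, `trait`, `value`.  (accession, environment, replicate,
#'   trait) combinations are unique; values may be NA (missing plots).
#' @export
setClass("PhenotypeTable", representation(records = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  r <- object@records
  need <- c("accession", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(r)))
    return(paste("phenotype records need columns:", paste(need, collapse = ", ")))
  if (nrow(r) && anyDuplicated(r[, c("accession", "environment", "replicate", "trait")]))
    return("(accession, environment, replicate, trait) must be unique")
  if (nrow(r) && !is.numeric(r$value)) return("value must be numeric")
  TRUE
})

#' Pedigree of inbred lines
#'
#' Acyclic parent graph: every line has zero (founder) or two recorded
#' parents (mother, father).  Parents must themselves be entries.
#'
#' @slot entries data.frame with columns `line`, `mother`, `father`
#'   (NA for founders).
#' @export
setClass("Pedigree", representation(entries = "data.frame"))

setValidity("Pedigree", function(object) {
  e <- object@entries
  need <- c("line", "mother", "father")
  if (!all(need %in% names(e)))
    return("pedigree needs columns line, mother, father")
  if (anyDuplicated(e$line)) return("duplicate line ids in pedigree")
  par <- c(e$mother, e$father)
  par <- par[!is.na(par)]
  if (!all(par %in% e$line))
    return("every named parent must itself be a pedigree entry")
  if (any(xor(is.na(e$mother), is.na(e$father))))
    return("lines must have zero or two recorded parents")
  if (is.null(topoOrderPedigree(e))) return("pedigree graph is cyclic")
  TRUE
})

#' Homoeologous contig triplet with a target SNP
#'
#' Three highly similar contigs from the A, B and D subgenomes of a
#' hexaploid, plus the position and alleles of the target SNP, which is
#' present only on the designated target subgenome.
#'
#' @slot sequences \link[Biostrings]{DNAStringSet} of length 3, names in
#'   \{"A","B","D"\}.
#' @slot snpGenome genome label carrying the SNP.
#' @slot snpOffset 0-based offset of the SNP in the target contig.
#' @slot refAllele,altAllele single bases; the target contig carries
#'   `refAllele` at `snpOffset`.
#' @export
setClass("ContigTriplet", representation(
  sequences = "DNAStringSet", snpGenome = "character",
  snpOffset = "integer", refAllele = "character", altAllele = "character"))

setValidity("ContigTriplet", function(object) {
  if (length(object@sequences) != 3L) return("exactly three contigs required")
  nm <- names(object@sequences)
  if (is.null(nm) || !setequal(nm, c("A", "B", "D")))
    return("contigs must be named A, B and D")
  if (!object@snpGenome %in% nm) return("snpGenome must be one of A/B/D")
  tgt <- object@sequences[[object@snpGenome]]
  if (object@snpOffset < 0L || object@snpOffset >= length(tgt))
    return("snpOffset outside the target contig")
  base <- as.character(Biostrings::subseq(tgt, object@snpOffset + 1L,
                                          object@snpOffset + 1L))
  if (!identical(base, object@refAllele))
    return("refAllele does not match the target contig at snpOffset")
  if (identical(object@refAllele, object@altAllele))
    return("ref and alt alleles must differ")
  TRUE
})

#' Marker-based kinship matrix
#'
#' Allele-sharing similarity rescaled so the minimum off-diagonal is 0 and
#' the diagonal 1; used as the covariance structure of the polygenic random
#' effect in the mixed-model scan.
#'
#' @slot values symmetric numeric matrix with accession dimnames.
#' @export
setClass("KinshipMatrix", representation(values = "matrix"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("kinship matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("kinship matrix needs matching accession dimnames")
  if (!isSymmetric(unname(v), tol = 1e-8)) return("kinship matrix must be symmetric")
  off <- v[row(v) != col(v)]
  if (length(off) && (min(off) < -1e-8 || max(off) > max(diag(v)) + 1e-8))
    return("off-diagonal values must lie in [0, max(diagonal)]")
  TRUE
})

#' Doubled-haploid validation population
#'
#' Genotypes at validation markers (0/1 oriented so 1 = focal-parent allele)
#' and a single-trait phenotype per line.
#'
#' @slot name population label (e.g. "Kinuhime/Kitahonami").
#' @slot parents character(2): non-focal parent, focal parent.
#' @slot genotypes integer matrix lines x markers (0/1/NA).
#' @slot phenotype named numeric vector of trait values per line.
#' @export
setClass("DHPopulation", representation(
  name = "character", parents = "character",
  genotypes = "matrix", phenotype = "numeric"))

setValidity("DHPopulation", function(object) {
  g <- object@genotypes
  if (is.null(rownames(g)) || is.null(colnames(g)))
    return("genotypes need line rownames and marker colnames")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L))) return("genotype codes must be 0/1/NA")
  if (!identical(sort(names(object@phenotype)), sort(rownames(g))))
    return("phenotype must be named by the genotyped lines")
  if (length(object@parents) != 2L) return("exactly two parents")
  TRUE
})

#' Genome-specific + allele-specific PCR assay for one SNP
#'
#' A genome-specific primer pair (GSP-F/GSP-R) anchoring the assay to one
#' homoeologous subgenome, plus two allele-specific primers (ASPs) whose 3'
#' base sits on the SNP and which carry an engineered destabilising mismatch
#' at the third base from the 3' end.
#'
#' @slot markerId assay label.
#' @slot gspForward,gspReverse primer sequences (5'->3').
#' @slot aspAllele1,aspAllele2 allele-specific primer sequences (5'->3').
#' @slot aspAlleles the two SNP alleles, in the order of the ASP slots.
#' @slot aspOrientation "forward" or "reverse".
#' @slot aspMismatch list(position_from_3prime = 3, original, substituted).
#' @slot expectedSizes named numeric: gsp and asp amplicon lengths (bp).
#' @slot annealingRange numeric(2), deg C.
#' @export
setClass("PrimerSet", representation(
  markerId = "character", gspForward = "character", gspReverse = "character",
  aspAllele1 = "character", aspAllele2 = "character", aspAlleles = "character",
  aspOrientation = "character", aspMismatch = "list",
  expectedSizes = "numeric", annealingRange = "numeric"))

setValidity("PrimerSet", function(object) {
  if (!object@aspOrientation %in% c("forward", "reverse"))
    return("aspOrientation must be forward or reverse")
  a1 <- object@aspAllele1; a2 <- object@aspAllele2
  if (nchar(a1) != nchar(a2)) return("ASPs must have equal length")
  if (substring(a1, nchar(a1)) != object@aspAlleles[1] ||
      substring(a2, nchar(a2)) != object@aspAlleles[2])
    return("ASP 3'-terminal base must equal its allele")
  d <- which(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]])
  if (!identical(d, nchar(a1)))
    return("the two ASPs must differ only at the 3' base")
  if (object@expectedSizes[["gsp"]] <= object@expectedSizes[["asp"]])
    return("GSP product must be longer than the ASP product")
  TRUE
})
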