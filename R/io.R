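# On-disk formats: delimited text (tab or comma, auto-detected), FASTA via
# Biostrings, newick via ape.  All readers validate and reject malformed
# input rather than coercing; every writer/reader pair is a round-trip
# identity on valid data.  Sequence offsets are 0-based half-open
# internally and 1-based inclusive in human-readable reports.

detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

splitFields <- function(lines, sep, path) {
  fields <- strsplit(lines, sep, fixed = TRUE)
  n <- lengths(fields)
  if (length(unique(n)) != 1L) {
    bad <- which(n != n[1])[1]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, n[bad], n[1]), call. = FALSE)
  }
  fields
}

#' Read / write a genotype matrix
#'
#' Layout: header row of marker ids; first column accession ids; calls coded
#' `0`, `1` and missing as `NA` or `-`.  Delimiter (tab/comma) is
#' auto-detected on read; `write_genotypes` emits tab-separated text with
#' `NA` for missing so that write-then-read is an identity.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @return \code{readGenotypes}: a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detectSep(path)
  lines <- readLines(path)
  stopIfNot(length(lines) >= 2, paste("genotype file has no data rows:", path))
  fields <- splitFields(lines, sep, path)
  header <- fields[[1]]
  markers <- header[-1]
  acc <- vapply(fields[-1], `[`, character(1), 1L)
  body <- t(vapply(fields[-1], function(f) f[-1], character(length(markers))))
  if (length(markers) == 1L) body <- matrix(body, ncol = 1L)
  body[body %in% c("-", "")] <- NA_character_
  ok <- is.na(body) | body %in% c("0", "1", "NA")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code '%s' at accession %s, marker %s in %s",
                 body[idx[1], idx[2]], acc[idx[1]], markers[idx[2]], path),
         call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.integer(body), nrow = length(acc),
                               dimnames = list(acc, markers)))
  GenotypeMatrix(m)
}

#' @rdname readGenotypes
#' @param x a \linkS4class{GenotypeMatrix}.
#' @export
writeGenotypes <- function(x, path) {
  m <- calls(x)
  out <- cbind(accession = rownames(m),
               matrix(ifelse(is.na(m), "NA", as.character(m)), nrow = nrow(m),
                      dimnames = dimnames(m)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genetic map
#'
#' Columns: marker_id, linkage_group, position (cM), map_source (optional,
#' defaults to "consensus").  Rows are sorted by (map source, linkage group,
#' cM) on load.
#'
#' @param path file path.
#' @return \code{readGeneticMap}: a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path) {
  sep <- detectSep(path)
  tb <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  stopIfNot(all(c("marker_id", "linkage_group", "position") %in% names(tb)),
            "map file needs columns marker_id, linkage_group, position")
  pos <- suppressWarnings(as.numeric(tb$position))
  if (anyNA(pos) && !anyNA(tb$position))
    stop("non-numeric cM position in ", path, call. = FALSE)
  tb$position <- pos
  GeneticMap(tb)
}

#' @rdname readGeneticMap
#' @param x a \linkS4class{GeneticMap}.
#' @export
writeGeneticMap <- function(x, path) {
  write.table(mapTable(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Long format with columns accession, environment, replicate, trait, value.
#' Environment labels follow the first-letter-of-location + harvest-year
#' convention (e.g. "K09") when importing study data, but any labels are
#' accepted.  Missing values permitted.
#'
#' @param path file path.
#' @return \code{readPhenotypes}: a \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path) {
  sep <- detectSep(path)
  tb <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  PhenotypeTable(tb)
}

#' @rdname readPhenotypes
#' @param x a \linkS4class{PhenotypeTable}.
#' @export
writePhenotypes <- function(x, path) {
  write.table(phenoRecords(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a pedigree
#'
#' Columns: line, mother, father ("NA" or empty for founders).  Acyclicity
#' and parent existence are enforced on load.
#'
#' @param path file path.
#' @return \code{readPedigree}: a \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  sep <- detectSep(path)
  tb <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  Pedigree(tb)
}

#' @rdname readPedigree
#' @param x a \linkS4class{Pedigree}.
#' @export
writePedigree <- function(x, path) {
  write.table(pedigreeEntries(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a homoeologous contig triplet from FASTA
#'
#' Headers must contain the genome labels A, B and D (either the whole
#' header, or as a `genome=X` tag).  The target SNP is supplied by the
#' caller because FASTA carries no variant annotation.
#'
#' @param path FASTA file with three records.
#' @param snpGenome,snpOffset,refAllele,altAllele target SNP description
#'   (offset 0-based).
#' @return A \linkS4class{ContigTriplet}.
#' @export
readContigTriplet <- function(path, snpGenome, snpOffset, refAllele, altAllele) {
  seqs <- readDNAStringSet(path)
  stopIfNot(length(seqs) == 3L, "FASTA must contain exactly three records")
  nm <- names(seqs)
  lab <- ifelse(grepl("genome=([ABD])", nm),
                sub(".*genome=([ABD]).*", "\\1", nm),
                sub(".*\\b([ABD])\\b.*", "\\1", nm))
  stopIfNot(setequal(lab, c("A", "B", "D")),
            "FASTA headers must identify genomes A, B and D")
  names(seqs) <- lab
  ContigTriplet(seqs, snpGenome, snpOffset, refAllele, altAllele)
}

#' Read doubled-haploid validation populations
#'
#' Best-effort layout shim for combined DH genotype + phenotype tables:
#' columns `population`, `line`, `phenotype`, then one 0/1 column per
#' validation marker (1 = focal-parent allele).  Population labels of the
#' form "other/focal" are split into the parent pair.
#'
#' @param path delimited file.
#' @return named list of \linkS4class{DHPopulation}.
#' @export
readDhPopulations <- function(path) {
  sep <- detectSep(path)
  tb <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("population", "line", "phenotype")
  stopIfNot(all(need %in% names(tb)),
            "DH table needs columns population, line, phenotype")
  markers <- setdiff(names(tb), need)
  out <- lapply(split(tb, tb$population), function(d) {
    g <- as.matrix(d[, markers, drop = FALSE])
    storage.mode(g) <- "integer"
    rownames(g) <- d$line
    parents <- strsplit(d$population[1], "/")[[1]]
    if (length(parents) != 2) parents <- c("P1", "P2")
    DHPopulation(d$population[1], parents, g,
                 setNames(d$phenotype, d$line))
  })
  out
}

#' Write sequences to FASTA
#' @param x named character vector or DNAStringSet.
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- DNAStringSet(x)
  writeXStringSet(x, path)
  invisible(path)
}

#' Write a phylogenetic tree as newick
#' @param tree an \link[ape]{ape} "phylo" object.
#' @param path output path.
#' @export
writeNewickTree <- function(tree, path) {
  stopIfNot(inherits(tree, "phylo") && length(tree$tip.label) > 0,
            "empty or invalid tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a primer table
#'
#' One row per designed assay: marker, GSP-F, GSP-R, the two ASPs, product
#' sizes (bp) and the annealing range (deg C).
#'
#' @param primerSets list of \linkS4class{PrimerSet}.
#' @param path output path.
#' @return the table, invisibly.
#' @export
writePrimerTable <- function(primerSets, path) {
  rows <- lapply(primerSets, function(p) data.frame(
    marker = p@markerId, gsp_forward = p@gspForward, gsp_reverse = p@gspReverse,
    asp_allele1 = p@aspAllele1, asp_allele2 = p@aspAllele2,
    allele1 = p@aspAlleles[1], allele2 = p@aspAlleles[2],
    asp_orientation = p@aspOrientation,
    gsp_product_bp = p@expectedSizes[["gsp"]],
    asp_product_bp = p@expectedSizes[["asp"]],
    annealing_min_c = p@annealingRange[1], annealing_max_c = p@annealingRange[2],
    stringsAsFactors = FALSE))
  tb <- do.call(rbind, rows)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tb)
}
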