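#' Construct a GeneticMap
#'
#' @param marker_id,linkage_group,position,map_source vectors of equal
#'   length, or a single data.frame in `marker_id` with those columns.
#' @return A \linkS4class{GeneticMap}, sorted by (map source, linkage group,
#'   cM, marker id).
#' @examples
#' gm <- GeneticMap(c("m1", "m2"), "1A", c(0, 10))
#' @export
GeneticMap <- function(marker_id, linkage_group = NULL, position = NULL,
                       map_source = "consensus") {
  if (is.data.frame(marker_id)) {
    tb <- marker_id
    if (!"map_source" %in% names(tb)) tb$map_source <- map_source
  } else {
    tb <- data.frame(marker_id = as.character(marker_id),
                     linkage_group = as.character(linkage_group),
                     position = as.numeric(position),
                     map_source = as.character(map_source),
                     stringsAsFactors = FALSE)
  }
  tb$marker_id <- as.character(tb$marker_id)
  tb$linkage_group <- as.character(tb$linkage_group)
  tb$map_source <- as.character(tb$map_source)
  if (!is.numeric(tb$position)) stop("non-numeric cM positions")
  tb <- tb[order(tb$map_source, tb$linkage_group, tb$position, tb$marker_id), ,
           drop = FALSE]
  rownames(tb) <- NULL
  new("GeneticMap", table = tb[, c("marker_id", "linkage_group", "position",
                                   "map_source")])
}

#' @describeIn GeneticMap the underlying map table.
#' @param x a GeneticMap.
#' @export
mapTable <- function(x) x@table

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix (accessions x markers) of 0/1/NA
#'   calls with dimnames.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(calls) {
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls)
}

#' @rdname genotype-accessors
#' @param x a GenotypeMatrix (or kindred object).
#' @return `calls()`: the integer call matrix (lines x markers; for a
#'   \linkS4class{DHPopulation}, calls oriented to the focal parent).
#' @export
calls <- function(x) {
  if (is(x, "DHPopulation")) x@genotypes else x@calls
}

#' Accessors for genotype-like objects
#'
#' @name genotype-accessors
#' @param x object with accessions/markers.
#' @return character vectors of ids.
#' @export
accessionIds <- function(x) {
  if (is(x, "KinshipMatrix")) rownames(x@values) else rownames(x@calls)
}

#' @rdname genotype-accessors
#' @export
markerIds <- function(x) colnames(x@calls)

#' Construct a PhenotypeTable
#'
#' @param records data.frame with columns accession, environment, replicate,
#'   trait, value.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(records) {
  records$accession <- as.character(records$accession)
  records$environment <- as.character(records$environment)
  records$replicate <- as.integer(records$replicate)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)
  rownames(records) <- NULL
  new("PhenotypeTable", records = records[, c("accession", "environment",
                                              "replicate", "trait", "value")])
}

#' @describeIn PhenotypeTable the long-format records.
#' @param x a PhenotypeTable.
#' @export
phenoRecords <- function(x) x@records

#' Construct a Pedigree
#'
#' @param line,mother,father equal-length vectors (NA parents for founders),
#'   or a single data.frame in `line` with those columns.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(line, mother = NULL, father = NULL) {
  if (is.data.frame(line)) e <- line
  else e <- data.frame(line = as.character(line),
                       mother = as.character(mother),
                       father = as.character(father),
                       stringsAsFactors = FALSE)
  for (cc in c("line", "mother", "father")) e[[cc]] <- as.character(e[[cc]])
  rownames(e) <- NULL
  new("Pedigree", entries = e[, c("line", "mother", "father")])
}

#' @describeIn Pedigree the parent table.
#' @param x a Pedigree.
#' @export
pedigreeEntries <- function(x) x@entries

#' @describeIn Pedigree ids of lines without recorded parents.
#' @export
founders <- function(x) x@entries$line[is.na(x@entries$mother)]

#' @describeIn Pedigree the (mother, father) of a line, or NULL for founders.
#' @param id line id.
#' @export
parentsOf <- function(x, id) {
  e <- x@entries
  i <- match(id, e$line)
  if (is.na(i)) stop("line not in pedigree: ", id)
  if (is.na(e$mother[i])) return(NULL)
  c(mother = e$mother[i], father = e$father[i])
}

#' Construct a KinshipMatrix
#' @param values symmetric similarity matrix with accession dimnames.
#' @return A \linkS4class{KinshipMatrix}.
#' @export
KinshipMatrix <- function(values) new("KinshipMatrix", values = values)

#' @describeIn DHPopulation per-line phenotype vector.
#' @param x a DHPopulation.
#' @export
dhPhenotype <- function(x) x@phenotype

#' @describeIn KinshipMatrix the similarity matrix.
#' @param x a KinshipMatrix.
#' @export
kinshipValues <- function(x) x@values

#' Construct a DHPopulation
#' @param name population label.
#' @param parents character(2): (other parent, focal parent).
#' @param genotypes lines x markers 0/1/NA matrix, 1 = focal-parent allele.
#' @param phenotype named numeric vector of trait values.
#' @return A \linkS4class{DHPopulation}.
#' @export
DHPopulation <- function(name, parents, genotypes, phenotype) {
  storage.mode(genotypes) <- "integer"
  new("DHPopulation", name = name, parents = parents,
      genotypes = genotypes, phenotype = phenotype[rownames(genotypes)])
}

#' Construct a ContigTriplet
#' @param sequences named character vector or DNAStringSet (names A/B/D).
#' @param snpGenome genome label carrying the target SNP.
#' @param snpOffset 0-based offset of the SNP in the target contig.
#' @param refAllele,altAllele SNP alleles; target contig carries `refAllele`.
#' @return A \linkS4class{ContigTriplet}.
#' @export
ContigTriplet <- function(sequences, snpGenome, snpOffset, refAllele, altAllele) {
  if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
  new("ContigTriplet", sequences = sequences, snpGenome = snpGenome,
      snpOffset = as.integer(snpOffset), refAllele = refAllele,
      altAllele = altAllele)
}

#' @describeIn ContigTriplet the three contig sequences.
#' @param x a ContigTriplet.
#' @export
contigSequences <- function(x) x@sequences

#' @describeIn ContigTriplet the target SNP as a list
#'   (genome, offset 0-based, ref, alt).
#' @export
targetSnp <- function(x) list(genome = x@snpGenome, offset = x@snpOffset,
                              ref = x@refAllele, alt = x@altAllele)

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneticMap: %d markers, %d linkage group(s), source(s): %s\n",
              nrow(tb), length(unique(paste(tb$map_source, tb$linkage_group))),
              paste(unique(tb$map_source), collapse = ", ")))
})

setMethod("show", "GenotypeMatrix", function(object) {
  m <- object@calls
  cat(sprintf("GenotypeMatrix: %d accessions x %d markers (%.1f%% missing)\n",
              nrow(m), ncol(m), 100 * mean(is.na(m))))
})

setMethod("show", "PhenotypeTable", function(object) {
  r <- object@records
  cat(sprintf(
    "PhenotypeTable: %d records, %d accessions, %d environments, traits: %s\n",
    nrow(r), length(unique(r$accession)), length(unique(r$environment)),
    paste(unique(r$trait), collapse = ", ")))
})

setMethod("show", "Pedigree", function(object) {
  e <- object@entries
  cat(sprintf("Pedigree: %d lines (%d founders)\n",
              nrow(e), sum(is.na(e$mother))))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d accessions, off-diagonal range [%.3f, %.3f]\n",
              nrow(object@values),
              min(object@values[row(object@values) != col(object@values)]),
              max(object@values[row(object@values) != col(object@values)])))
})

setMethod("show", "DHPopulation", function(object) {
  cat(sprintf("DHPopulation '%s' (%s x %s): %d lines, %d markers\n",
              object@name, object@parents[1], object@parents[2],
              nrow(object@genotypes), ncol(object@genotypes)))
})

setMethod("show", "ContigTriplet", function(object) {
  cat(sprintf("ContigTriplet: lengths %s; SNP %s>%s at offset %d on genome %s\n",
              paste(Biostrings::width(object@sequences), collapse = "/"),
              object@refAllele, object@altAllele, object@snpOffset,
              object@snpGenome))
})

setMethod("show", "PrimerSet", function(object) {
  cat(sprintf(
    "PrimerSet '%s': GSP %dbp product, ASP (%s) %dbp product, alleles %s/%s\n",
    object@markerId, round(object@expectedSizes[["gsp"]]),
    object@aspOrientation, round(object@expectedSizes[["asp"]]),
    object@aspAlleles[1], object@aspAlleles[2]))
})
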