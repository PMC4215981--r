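# Map-based grouping of significant markers into QTLs, LD block detection
# around them, within-block genotype similarity, and pedigree tracing of
# each QTL's origin.

#' Group significant markers into QTLs on the map
#'
#' Within each (map source, linkage group), significant markers are sorted
#' by cM and consecutive markers closer than `gapCm` are merged into one
#' QTL (the transitive closure of the gap relation).  QTLs are labelled
#' `<linkage group>` when the group carries a single QTL and
#' `<linkage group>.<index>` (by position order, map sources ordered so
#' that SNP maps precede DArT maps) otherwise.  Markers not significant at
#' `qThreshold`, and markers without a map position, are excluded; the
#' unlocated significant markers are reported in attribute "unlocated".
#'
#' @param mta \code{\link{mlmScan}} result with map columns.
#' @param gapCm merge threshold in cM.
#' @param qThreshold q-value significance threshold.
#' @return data.frame, one row per QTL: qtl_id, map_source, linkage_group,
#'   cm_start, cm_end, n_markers, member means of MAF / q / R^2 / effect,
#'   and `markers` (comma-joined ids).
#' @export
classifyMTAs <- function(mta, gapCm = 15, qThreshold = 0.5) {
  sig <- mta[mta$q_value < qThreshold, , drop = FALSE]
  unlocated <- sig$marker_id[is.na(sig$linkage_group) | is.na(sig$position)]
  sig <- sig[!sig$marker_id %in% unlocated, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- data.frame(qtl_id = character(0))
    attr(out, "unlocated") <- unlocated
    return(out)
  }
  # SNP-derived maps before DArT-derived ones, then alphabetical
  srcRank <- function(s) ifelse(grepl("SNP", s, ignore.case = TRUE), 0L,
                                ifelse(grepl("DArT", s, ignore.case = TRUE),
                                       1L, 2L))
  sig <- sig[order(srcRank(sig$map_source), sig$map_source,
                   sig$linkage_group, sig$position), , drop = FALSE]
  groups <- list()
  for (key in unique(paste(sig$map_source, sig$linkage_group, sep = "\r"))) {
    blk <- sig[paste(sig$map_source, sig$linkage_group, sep = "\r") == key, ,
               drop = FALSE]
    brk <- c(0, cumsum(diff(blk$position) > gapCm))
    for (b in unique(brk)) groups <- c(groups, list(blk[brk == b, ,
                                                        drop = FALSE]))
  }
  rows <- lapply(groups, function(gr) data.frame(
    map_source = gr$map_source[1], linkage_group = gr$linkage_group[1],
    cm_start = min(gr$position), cm_end = max(gr$position),
    n_markers = nrow(gr), maf = mean(gr$maf), q_value = mean(gr$q_value),
    r_squared = mean(gr$r_squared), effect = mean(gr$effect),
    markers = paste(gr$marker_id, collapse = ","), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # label: index within linkage group over all map sources, in scan order
  out <- out[order(srcRank(out$map_source), out$map_source,
                   out$linkage_group, out$cm_start), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(out)), out$linkage_group,
                    FUN = seq_along)
  nPerLg <- as.vector(table(out$linkage_group)[out$linkage_group])
  out$qtl_id <- ifelse(nPerLg == 1, out$linkage_group,
                       paste0(out$linkage_group, ".", idx))
  out <- out[, c("qtl_id", "map_source", "linkage_group", "cm_start",
                 "cm_end", "n_markers", "maf", "q_value", "r_squared",
                 "effect", "markers")]
  rownames(out) <- NULL
  attr(out, "unlocated") <- unlocated
  out
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of the 0/1 allele codes across accessions
#' (equivalent to haplotype r^2 for inbred biallelic data).
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param markerA,markerB marker ids.
#' @return r^2 in [0, 1]; NA when either marker is monomorphic or fewer
#'   than 3 mutually non-missing pairs exist.
#' @export
ldR2 <- function(g, markerA, markerB) {
  m <- calls(g)
  x <- m[, markerA]; y <- m[, markerB]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Detect the LD block containing a QTL
#'
#' On the QTL's map and linkage group, finds the maximal run of
#' consecutive genotyped map markers that contains at least one QTL member
#' and within which every adjacent-pair r^2 is at least `r2Min`.  The
#' block is declared present if the run has at least `minMarkers` markers.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param map a \linkS4class{GeneticMap}.
#' @param qtl one row of the \code{\link{classifyMTAs}} result.
#' @param r2Min adjacent-pair r^2 threshold.
#' @param minMarkers minimum run length for a block to be called present.
#' @return list of class "LDBlock": linkage_group, map_source, present,
#'   start_cm, end_cm, size_cm, marker_ids.
#' @export
detectLDBlock <- function(g, map, qtl, r2Min = 0.7, minMarkers = 3) {
  tb <- mapTable(map)
  tb <- tb[tb$map_source == qtl$map_source &
             tb$linkage_group == qtl$linkage_group &
             tb$marker_id %in% markerIds(g), , drop = FALSE]
  tb <- tb[order(tb$position), , drop = FALSE]
  members <- strsplit(qtl$markers, ",")[[1]]
  ids <- tb$marker_id
  adj <- if (nrow(tb) > 1)
    vapply(seq_len(nrow(tb) - 1), function(i)
      ldR2(g, ids[i], ids[i + 1]), numeric(1)) else numeric(0)
  linked <- !is.na(adj) & adj >= r2Min
  # runs of markers joined by linked adjacencies
  runId <- c(0, cumsum(!linked))
  best <- NULL
  for (rid in unique(runId)) {
    run <- which(runId == rid)
    if (!any(ids[run] %in% members)) next
    if (is.null(best) || length(run) > length(best)) best <- run
  }
  if (is.null(best)) best <- which(ids %in% members)[1]
  present <- length(best) >= minMarkers
  res <- list(linkage_group = qtl$linkage_group, map_source = qtl$map_source,
              qtl_id = qtl$qtl_id, present = present,
              start_cm = if (present) min(tb$position[best]) else NA_real_,
              end_cm = if (present) max(tb$position[best]) else NA_real_,
              size_cm = if (present) diff(range(tb$position[best])) else
                NA_real_,
              marker_ids = if (present) ids[best] else character(0),
              n_markers = if (present) length(best) else length(best))
  class(res) <- "LDBlock"
  res
}

#' Within-block genotype similarity to the focal line
#'
#' For every accession, the fraction of block markers whose call is
#' identical to the focal line's, over mutually non-missing markers.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param markers block marker ids (or an "LDBlock").
#' @param focal focal accession id.
#' @return named vector of similarities in [0, 1]; NA (with a warning) for
#'   accessions with no mutually non-missing block marker.
#' @export
blockSimilarity <- function(g, markers, focal) {
  if (inherits(markers, "LDBlock")) markers <- markers$marker_ids
  m <- calls(g)
  stopIfNot(focal %in% rownames(m), "focal line not genotyped")
  mk <- intersect(markers, colnames(m))
  stopIfNot(length(mk) > 0, "no block markers genotyped in the focal line")
  fm <- m[focal, mk]
  stopIfNot(any(!is.na(fm)), "focal line unscored at all block markers")
  sims <- apply(m[, mk, drop = FALSE], 1, function(v) {
    ok <- !is.na(v) & !is.na(fm)
    if (!any(ok)) return(NA_real_)
    mean(v[ok] == fm[ok])
  })
  if (anyNA(sims))
    warning("accessions with no block-marker overlap: ",
            paste(names(sims)[is.na(sims)], collapse = ", "))
  sims
}

#' Trace a QTL's origin through the pedigree
#'
#' An accession carries the block when its within-block similarity to the
#' focal line reaches `carrierThreshold`.  The origin class follows the
#' focal line's parents (maternal / paternal / both-undetermined); source
#' ancestors are carriers reached from the focal line through carrier-only
#' parent paths that have no carrying parent themselves.  A discrepancy is
#' flagged when a non-founder carrier on those paths has no carrying
#' parent (the block appears without a recorded source).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param similarities named vector from \code{\link{blockSimilarity}}
#'   (members missing from it are tolerated and flagged).
#' @param focal focal line id (must be in the pedigree).
#' @param carrierThreshold similarity threshold for carrier status.
#' @return list of class "OriginAssignment": origin_class in
#'   \{"maternal", "paternal", "both_undetermined", "undetermined"\},
#'   source_ancestors, carriers, discrepancy flag, missing_members.
#' @export
traceOrigin <- function(pedigree, similarities, focal,
                        carrierThreshold = 0.9) {
  e <- pedigreeEntries(pedigree)
  stopIfNot(focal %in% e$line, "focal line absent from pedigree")
  missing <- setdiff(e$line, names(similarities))
  carrier <- names(similarities)[!is.na(similarities) &
                                   similarities >= carrierThreshold]
  carrier <- union(carrier, focal)      # the focal line carries by definition
  p <- parentsOf(pedigree, focal)
  origin <- if (is.null(p)) "undetermined" else {
    mo <- p[["mother"]] %in% carrier; fa <- p[["father"]] %in% carrier
    if (mo && fa) "both_undetermined"
    else if (mo) "maternal" else if (fa) "paternal" else "undetermined"
  }
  # walk carrier-only paths upward from the focal line
  sources <- character(0); discrepancy <- FALSE
  visited <- character(0)
  frontier <- focal
  while (length(frontier)) {
    id <- frontier[1]; frontier <- frontier[-1]
    if (id %in% visited) next
    visited <- c(visited, id)
    pr <- parentsOf(pedigree, id)
    if (is.null(pr)) {                   # founder carrier: a source
      if (id != focal || is.null(parentsOf(pedigree, focal)))
        sources <- c(sources, id)
      next
    }
    carryingParents <- pr[pr %in% carrier]
    if (length(carryingParents) == 0) {
      # non-founder carrier with no carrying parent: the block appears
      # without a recorded source
      sources <- c(sources, id)
      discrepancy <- TRUE
      next
    }
    frontier <- c(frontier, unname(carryingParents))
  }
  sources <- setdiff(unique(sources), character(0))
  res <- list(origin_class = origin, source_ancestors = sources,
              carriers = setdiff(carrier, focal), discrepancy = discrepancy,
              missing_members = missing, carrier_threshold = carrierThreshold)
  class(res) <- "OriginAssignment"
  res
}

#' Write the QTL and LD-block tables
#' @param qtls \code{\link{classifyMTAs}} result.
#' @param blocks list of "LDBlock" results (optional).
#' @param path output file.
#' @export
writeQtlTable <- function(qtls, path, blocks = NULL) {
  out <- qtls
  out$maf <- round(out$maf, 3); out$q_value <- round(out$q_value, 3)
  out$r_squared_pct <- round(100 * out$r_squared, 1); out$r_squared <- NULL
  out$effect <- round(out$effect, 3)
  if (!is.null(blocks)) {
    bm <- do.call(rbind, lapply(blocks, function(b) data.frame(
      qtl_id = b$qtl_id, ld_block = ifelse(b$present, "+", "-"),
      block_start = b$start_cm, block_end = b$end_cm,
      block_size = b$size_cm, block_markers = b$n_markers)))
    out <- merge(out, bm, by = "qtl_id", all.x = TRUE, sort = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
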