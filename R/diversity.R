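# Genotype curation and diversity structure: MAF/redundancy filtering,
# kNN imputation (Manhattan distance, unweighted neighbour average),
# correlation-based PCA, identity-by-state distances and a UPGMA
# dendrogram with a deterministic tie-break.

#' Minor allele frequency per marker
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return named vector of MAF over non-missing calls (NaN if all missing).
#' @export
minorAlleleFreq <- function(g) {
  m <- calls(g)
  p <- colMeans(m, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' Filter markers by MAF and redundancy
#'
#' Removes markers with minor allele frequency (over non-missing calls)
#' below `mafMin`, then optionally collapses redundant markers: markers
#' whose call vectors are exactly identical, including the missingness
#' pattern.  Of each redundancy group the marker that comes first in map
#' order (or column order when no map is given) is retained.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param mafMin MAF threshold (markers strictly below are dropped).
#' @param dropRedundant collapse identical call vectors?
#' @param map optional \linkS4class{GeneticMap} defining the retention
#'   order.
#' @return filtered \linkS4class{GenotypeMatrix} (possibly with zero
#'   markers, with a warning).
#' @export
filterMarkers <- function(g, mafMin = 0.1, dropRedundant = TRUE, map = NULL) {
  m <- calls(g)
  maf <- minorAlleleFreq(g)
  keep <- !is.na(maf) & maf >= mafMin
  m <- m[, keep, drop = FALSE]
  if (dropRedundant && ncol(m) > 1) {
    ord <- colnames(m)
    if (!is.null(map)) {
      tb <- mapTable(map)
      ord <- c(intersect(tb$marker_id, ord), setdiff(ord, tb$marker_id))
    }
    m <- m[, ord, drop = FALSE]
    key <- apply(m, 2, function(v) paste(ifelse(is.na(v), "N", v),
                                         collapse = ""))
    m <- m[, !duplicated(key), drop = FALSE]
  }
  if (ncol(m) == 0) warning("no markers survive filtering")
  GenotypeMatrix(m)
}

#' k-nearest-neighbour genotype imputation
#'
#' Accessions with less than `minFreq` fraction of non-missing calls are
#' dropped with a warning.  Each remaining missing call is replaced by the
#' unweighted average call of the `k` nearest accessions by Manhattan
#' distance over shared non-missing markers (mean absolute difference, so
#' accessions with different missingness are comparable), rounded to the
#' nearer code; ties round to 1.  Neighbours missing at the target marker
#' are passed over in favour of the next nearest.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param k number of neighbours.
#' @param minFreq minimum fraction of non-missing calls per accession.
#' @return complete \linkS4class{GenotypeMatrix}.
#' @export
knnImpute <- function(g, k = 3, minFreq = 0.8) {
  m <- calls(g)
  cover <- rowMeans(!is.na(m))
  if (any(cover < minFreq)) {
    warning("dropping accessions below minimum data frequency: ",
            paste(rownames(m)[cover < minFreq], collapse = ", "))
    m <- m[cover >= minFreq, , drop = FALSE]
  }
  stopIfNot(k < nrow(m), "k must be smaller than the number of accessions")
  if (!anyNA(m)) return(GenotypeMatrix(m))
  # pairwise mean absolute difference over shared non-missing markers
  obs <- !is.na(m)
  x <- m; x[!obs] <- 0L
  shared <- obs %*% t(obs)
  sumAbs <- x %*% t(x)                      # sum xi*yi over shared
  rs <- obs %*% t(x)                        # per pair: sum of y over shared
  # |xi - yi| for 0/1 data = xi + yi - 2 xi yi
  manh <- (x %*% t(obs) + rs - 2 * sumAbs) / shared
  diag(manh) <- Inf
  out <- m
  for (i in which(rowSums(!obs) > 0)) {
    ord <- order(manh[i, ])   # distance, ties by row order
    for (j in which(!obs[i, ])) {
      nb <- ord[!is.na(m[ord, j])]
      if (length(nb) == 0) {             # fall back to the marker mean
        out[i, j] <- as.integer(round(mean(m[, j], na.rm = TRUE)))
        next
      }
      nb <- nb[seq_len(min(k, length(nb)))]
      avg <- mean(m[nb, j])
      out[i, j] <- if (avg >= 0.5) 1L else 0L
    }
  }
  GenotypeMatrix(out)
}

#' Correlation-based principal component analysis of genotypes
#'
#' Markers are standardised to unit variance (correlation PCA);
#' zero-variance markers are excluded with a warning.  Component signs are
#' fixed by making the largest-magnitude loading of each component
#' positive.
#'
#' @param g complete \linkS4class{GenotypeMatrix} (impute first).
#' @param nComponents number of components to return.
#' @return list with `coordinates` (accessions x components),
#'   `proportion` (fraction of total variance per component) and
#'   `loadings`.
#' @export
genotypePCA <- function(g, nComponents = 3) {
  m <- calls(g)
  stopIfNot(!anyNA(m), "PCA requires a complete matrix; impute first")
  stopIfNot(nrow(m) >= 2, "need at least two accessions")
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance markers excluded from PCA")
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  nComponents <- min(nComponents, ncol(pc$x))
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(nComponents), drop = FALSE]
  load <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { coords[, j] <- -coords[, j]; load[, j] <- -load[, j] }
  }
  list(coordinates = coords, proportion = prop[seq_len(nComponents)],
       loadings = load)
}

#' Identity-by-state distance matrix
#'
#' distance = 1 - proportion of shared calls over the markers non-missing
#' in both accessions.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return symmetric distance matrix with accession dimnames.
#' @export
genotypeDistance <- function(g) {
  s <- allele_sharing(calls(g))
  d <- 1 - s
  stopIfNot(all(is.finite(d)), "non-finite distance (no shared markers)")
  d
}

# proportion of matching calls over mutually non-missing markers
allele_sharing <- function(m) {
  obs <- !is.na(m)
  x <- m; x[!obs] <- 0L
  shared <- obs %*% t(obs)
  both1 <- x %*% t(x)
  one <- x %*% t(obs); two <- obs %*% t(x)
  mism <- one + two - 2 * both1            # count of differing calls
  res <- (shared - mism) / shared
  res[shared == 0] <- NaN
  dimnames(res) <- list(rownames(m), rownames(m))
  res
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration on a distance matrix; when several pairs
#' tie at the minimum distance the pair whose lexicographically smallest
#' member id is smallest (then the smaller partner id) is merged, making
#' the tree deterministic.  Returned as an \link[ape]{ape} "phylo" tree
#' with ultrametric branch lengths (leaf depth = merge height / 2).
#'
#' @param d symmetric distance matrix with dimnames.
#' @return a "phylo" tree.
#' @export
upgmaTree <- function(d) {
  stopIfNot(all(is.finite(d)), "non-finite distance")
  n <- nrow(d)
  stopIfNot(n >= 2, "need at least two taxa")
  labels <- rownames(d)
  # active clusters: newick fragment, size, height, sorted member ids
  cl <- lapply(seq_len(n), function(i)
    list(newick = labels[i], size = 1, height = 0, min_id = labels[i]))
  dd <- d
  while (length(cl) > 1) {
    k <- length(cl)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      key <- sort(c(cl[[i]]$min_id, cl[[j]]$min_id))
      cand <- list(i = i, j = j, dist = dd[i, j], key = key)
      if (is.null(best) || cand$dist < best$dist - 1e-12 ||
          (abs(cand$dist - best$dist) <= 1e-12 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
        best <- cand
    }
    i <- best$i; j <- best$j
    # canonical child order: smaller member id first
    if (cl[[i]]$min_id > cl[[j]]$min_id) { k2 <- i; i <- j; j <- k2 }
    h <- best$dist / 2
    bi <- h - cl[[i]]$height; bj <- h - cl[[j]]$height
    merged <- list(
      newick = sprintf("(%s:%.10g,%s:%.10g)", cl[[i]]$newick, bi,
                       cl[[j]]$newick, bj),
      size = cl[[i]]$size + cl[[j]]$size, height = h,
      min_id = min(cl[[i]]$min_id, cl[[j]]$min_id))
    # average-linkage update weighted by cluster sizes
    rest <- setdiff(seq_len(k), c(i, j))
    newrow <- (cl[[i]]$size * dd[i, rest] + cl[[j]]$size * dd[j, rest]) /
      (cl[[i]]$size + cl[[j]]$size)
    dd <- dd[rest, rest, drop = FALSE]
    dd <- rbind(cbind(dd, newrow), c(newrow, 0))
    cl <- c(cl[rest], list(merged))
  }
  ape::read.tree(text = paste0(cl[[1]]$newick, ";"))
}
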