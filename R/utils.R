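#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet reverseComplement subseq matchPattern pairwiseAlignment
#' @importFrom BiocGenerics start end width
NULL

# Run expr with a locally seeded RNG; the caller's random state is restored
# afterwards so no function leaks global randomness.
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required for stochastic operations")
  withr::with_seed(as.integer(seed), expr)
}

# Topological order of pedigree entries (founders first), or NULL if cyclic.
topoOrderPedigree <- function(entries) {
  lines <- entries$line
  parents <- lapply(seq_len(nrow(entries)), function(i) {
    p <- c(entries$mother[i], entries$father[i])
    p[!is.na(p)]
  })
  names(parents) <- lines
  placed <- character(0)
  remaining <- lines
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(l)
      all(parents[[l]] %in% placed), logical(1))]
    if (!length(ready)) return(NULL)
    ready <- sort(ready)  # deterministic within a layer
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# derive a reproducible child seed from a parent seed and an index,
# kept below 2^31 - 1
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
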