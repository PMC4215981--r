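# Shared fixtures, built in code.  The medium breeding study is expensive
# enough to cache for the session.

fixtureEnv <- new.env(parent = emptyenv())

# 65-line study at reduced marker density (120/LG) for association-level
# tests; built once
mediumStudy <- function() {
  if (is.null(fixtureEnv$medium)) {
    fixtureEnv$medium <- suppressWarnings(simulateBreedingStudy(
      SimulationConfig(n_markers_per_lg = 120), seed = 101,
      nPanel = 65, nDHLines = 120))
  }
  fixtureEnv$medium
}

# small deterministic map helpers
lineMap <- function(n, lg = "1A", length_cm = 100, source = "SNP-consensus") {
  GeneticMap(sprintf("%s_m%03d", lg, seq_len(n)), lg,
             seq(0, length_cm, length.out = n), source)
}

# genotype matrix from a plain matrix with default dimnames
gmat <- function(m, acc = NULL, mk = NULL) {
  if (is.null(acc)) acc <- sprintf("a%02d", seq_len(nrow(m)))
  if (is.null(mk)) mk <- sprintf("m%02d", seq_len(ncol(m)))
  dimnames(m) <- list(acc, mk)
  GenotypeMatrix(m)
}

# long phenotype table from an accession x environment matrix of means
phenoFromMatrix <- function(tab, trait = "FlYd", reps = 1) {
  recs <- expand.grid(accession = rownames(tab), environment = colnames(tab),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  recs$trait <- trait
  recs$value <- tab[cbind(recs$accession, recs$environment)]
  PhenotypeTable(recs)
}

# identity kinship over given accession ids (naive model: no relatedness)
identityKinship <- function(ids) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  KinshipMatrix(m)
}

# independent restricted-likelihood evaluation (direct solves, no
# eigen-rotation) used as the grid-search oracle for the REML variance
# ratio
remlLogLikDirect <- function(lam, y, X, K) {
  n <- length(y); p <- ncol(X)
  V <- lam * K + diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  rss <- drop(t(r) %*% Vi %*% r)
  -0.5 * ((n - p) * log(rss) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XVX, logarithm = TRUE)$modulus[1])
}

# brute-force Storey q-values: minimise pi0*m*t/#(p<=t) over thresholds
# t in the p-set itself
bruteQValues <- function(p, pi0 = 1) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- sort(p[p >= pi])
    min(pmin(1, pi0 * m * ts / vapply(ts, function(t) sum(p <= t),
                                      numeric(1))))
  }, numeric(1))
}
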