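# Kinship mixed-linear-model association scan with Storey q-values.
#
# The scan fits, per marker, y = mu + beta_k*kernel + beta_m*x + u + e with
# u ~ N(0, sigma2_g * K) and e ~ N(0, sigma2_e * I).  The variance ratio
# lambda = sigma2_g/sigma2_e is estimated by REML through a one-time
# spectral decomposition of K; by default it is estimated once under the
# null model (no marker) and reused for every marker (the
# "population parameters previously determined" shortcut), with an exact
# per-marker refit behind `exact = TRUE`.

#' Marker-based kinship matrix
#'
#' Allele-sharing similarity (proportion of matching calls over mutually
#' non-missing markers), linearly rescaled so that the minimum
#' off-diagonal is 0 and the diagonal 1.  Feed a MAF-filtered matrix.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{KinshipMatrix}.
#' @export
kinshipMatrix <- function(g) {
  s <- allele_sharing(calls(g))
  stopIfNot(all(is.finite(s)),
            "some accession pair shares no non-missing markers")
  off <- s[row(s) != col(s)]
  m0 <- min(off)
  k <- (s - m0) / (1 - m0)
  diag(k) <- 1
  KinshipMatrix(k)
}

# restricted log-likelihood of the variance ratio lambda, on rotated data
remlLogLik <- function(loglam, yt, Xt, d) {
  lam <- exp(loglam)
  w <- 1 / (lam * d + 1)
  n <- length(yt); p <- ncol(Xt)
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  beta <- tryCatch(solve(XX, crossprod(XtW, yt)), error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  -0.5 * ((n - p) * log(rss) + sum(log(lam * d + 1)) +
            determinant(XX, logarithm = TRUE)$modulus[1])
}

# REML estimate of lambda by coarse grid + local optimisation
estimateLambda <- function(yt, Xt, d, lower = log(1e-5), upper = log(1e5)) {
  grid <- seq(lower, upper, length.out = 61)
  ll <- vapply(grid, remlLogLik, numeric(1), yt = yt, Xt = Xt, d = d)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(remlLogLik, c(lo, hi), yt = yt, Xt = Xt, d = d,
                  maximum = TRUE, tol = 1e-8)
  # compare against both boundaries in case the optimum sits at an edge
  cand <- c(opt$maximum, lower, upper)
  obj <- c(opt$objective,
           remlLogLik(lower, yt, Xt, d), remlLogLik(upper, yt, Xt, d))
  exp(cand[which.max(obj)])
}

# weighted least squares on rotated data; returns rss and coefficients
wlsFit <- function(yt, Xt, w) {
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  qrXX <- qr(XX)
  if (qrXX$rank < ncol(Xt)) return(NULL)
  beta <- solve(qrXX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  list(beta = drop(beta), rss = sum(w * r^2))
}

#' Mixed-linear-model association scan
#'
#' @param g complete \linkS4class{GenotypeMatrix} for the tested markers
#'   (impute first).
#' @param phenotype named vector of genotypic values (one per accession).
#' @param K a \linkS4class{KinshipMatrix} over the same accessions.
#' @param covariates optional named vector or matrix of fixed covariates
#'   (e.g. the 0/1 kernel-type indicator).
#' @param focal optional focal accession id; marker codes are oriented so
#'   that positive effects mean the focal line's allele increases the
#'   trait.
#' @param exact re-estimate the variance ratio per marker (default reuses
#'   the null-model estimate).
#' @param map optional \linkS4class{GeneticMap}; when given, linkage
#'   group / position / map source columns are joined onto the result.
#' @return data.frame (one row per tested marker): marker_id, maf,
#'   p_value, q_value, r_squared, effect, plus map columns when available;
#'   markers confounded with the covariates are skipped and reported in
#'   attribute "skipped"; attributes "lambda" and "pi0" carry the variance
#'   ratio and the Storey pi0 estimate.
#' @export
mlmScan <- function(g, phenotype, K, covariates = NULL, focal = NULL,
                    exact = FALSE, map = NULL) {
  m <- calls(g)
  stopIfNot(!anyNA(m), "genotypes must be complete; impute first")
  acc <- intersect(names(phenotype)[!is.na(phenotype)], rownames(m))
  acc <- intersect(acc, accessionIds(K))
  stopIfNot(length(acc) >= 5, "too few accessions with phenotype and kinship")
  m <- m[acc, , drop = FALSE]
  y <- phenotype[acc]
  Kv <- kinshipValues(K)[acc, acc]
  X0 <- matrix(1, length(acc), 1, dimnames = list(acc, "intercept"))
  if (!is.null(covariates)) {
    cv <- if (is.matrix(covariates)) covariates[acc, , drop = FALSE] else
      matrix(covariates[acc], ncol = 1, dimnames = list(acc, "covariate"))
    X0 <- cbind(X0, cv)
  }
  eig <- eigen(Kv, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  X0t <- crossprod(U, X0)
  lambda <- estimateLambda(yt, X0t, d)
  w0 <- 1 / (lambda * d + 1)
  null0 <- wlsFit(yt, X0t, w0)
  # weighted total SS about the GLS intercept-only fit, for marker r^2
  int0 <- wlsFit(yt, X0t[, 1, drop = FALSE], w0)
  markers <- colnames(m)
  if (is.null(focal)) {
    orient <- rep(1L, length(markers))
  } else {
    stopIfNot(focal %in% rownames(m), "focal accession not genotyped")
    orient <- ifelse(m[focal, ] == 1L, 1L, -1L)
  }
  maf <- minorAlleleFreq(GenotypeMatrix(m))
  rows <- vector("list", length(markers))
  skipped <- character(0)
  for (j in seq_along(markers)) {
    x <- m[, j]
    xt <- drop(crossprod(U, x))
    if (exact) {
      lamj <- estimateLambda(yt, cbind(X0t, xt), d)
      wj <- 1 / (lamj * d + 1)
      nullj <- wlsFit(yt, X0t, wj)
    } else { wj <- w0; nullj <- null0 }
    fit <- if (var(x) == 0) NULL else wlsFit(yt, cbind(X0t, xt), wj)
    if (is.null(fit)) {
      # singular fixed-effect design: marker confounded with covariates
      skipped <- c(skipped, markers[j]); next
    }
    dfe <- length(yt) - ncol(X0t) - 1
    Fstat <- (nullj$rss - fit$rss) / (fit$rss / dfe)
    p <- pf(Fstat, 1, dfe, lower.tail = FALSE)
    beta <- fit$beta[length(fit$beta)] * orient[j]
    r2 <- (nullj$rss - fit$rss) / int0$rss
    rows[[j]] <- data.frame(marker_id = markers[j], maf = maf[j],
                            p_value = p, r_squared = r2, effect = beta,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  stopIfNot(!is.null(res) && nrow(res) > 0, "no testable markers")
  qv <- storeyQValues(res$p_value)
  res$q_value <- qv$q_values
  res <- res[, c("marker_id", "maf", "p_value", "q_value", "r_squared",
                 "effect")]
  if (!is.null(map)) {
    tb <- mapTable(map)
    i <- match(res$marker_id, tb$marker_id)
    res$map_source <- tb$map_source[i]
    res$linkage_group <- tb$linkage_group[i]
    res$position <- tb$position[i]
  }
  rownames(res) <- NULL
  attr(res, "lambda") <- lambda
  attr(res, "pi0") <- qv$pi0
  attr(res, "skipped") <- skipped
  res
}

#' Storey q-values
#'
#' pi0 is estimated by the smoother method: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over lambda = 0, 0.05, ..., 0.90,
#' cubic-spline smoothed (df = 3) and evaluated at lambda = 0.90; the
#' estimate falls back to 1 when it leaves (0, 1] or when too few p-values
#' are available to smooth.  q_i = min over t >= p_i of pi0 m t / #\{p <= t\},
#' clipped to [0, 1] and monotone non-decreasing in p.
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0 optional fixed pi0 (skips estimation).
#' @return list with `q_values` (same order as `p`) and `pi0`.
#' @export
storeyQValues <- function(p, pi0 = NULL) {
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lam <- seq(0, 0.90, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m >= 8) {
      fit <- try(smooth.spline(lam, pi0l, df = 3), silent = TRUE)
      if (inherits(fit, "try-error")) 1 else
        predict(fit, x = 0.90)$y
    } else 1
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  }
  o <- order(p)
  ranked <- p[o]
  q <- pi0 * m * ranked / seq_len(m)
  q <- rev(cummin(rev(q)))       # enforce monotonicity in p
  q <- pmin(q, 1)
  out <- numeric(m); out[o] <- q
  list(q_values = out, pi0 = pi0)
}

#' Write the marker-trait association table
#'
#' Delimited text, one row per tested marker: marker, map source, linkage
#' group, cM, MAF, p, q, R^2 (%), effect.
#'
#' @param mta result of \code{\link{mlmScan}} (with map columns).
#' @param path output file.
#' @export
writeMtaTable <- function(mta, path) {
  out <- data.frame(marker = mta$marker_id,
                    map_source = if ("map_source" %in% names(mta))
                      mta$map_source else NA,
                    linkage_group = if ("linkage_group" %in% names(mta))
                      mta$linkage_group else NA,
                    cM = if ("position" %in% names(mta)) mta$position else NA,
                    MAF = round(mta$maf, 3),
                    p = signif(mta$p_value, 4), q = signif(mta$q_value, 4),
                    R2_pct = round(100 * mta$r_squared, 1),
                    effect = round(mta$effect, 3))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
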