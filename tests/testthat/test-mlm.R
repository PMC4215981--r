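test_that("with identity kinship the scan reduces to OLS ANCOVA", {
  set.seed(31)
  n <- 10
  m <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
              dimnames = list(sprintf("a%02d", 1:n), paste0("m", 1:4)))
  kern <- setNames(rep(c(0, 1), each = n / 2), rownames(m))
  y <- setNames(rnorm(n) + 1.5 * m[, 2] + 2 * kern, rownames(m))
  res <- suppressWarnings(
    mlmScan(GenotypeMatrix(m), y, identityKinship(rownames(m)),
            covariates = kern))
  # oracle: per-marker ANCOVA F-test from lm
  for (j in seq_len(4)) {
    if (!paste0("m", j) %in% res$marker_id) next
    fit <- lm(y ~ kern + m[, j])
    p <- anova(fit)["m[, j]", "Pr(>F)"]
    expect_equal(res$p_value[res$marker_id == paste0("m", j)], p,
                 tolerance = 1e-6)
  }
})

test_that("REML variance ratio matches an independent grid search", {
  st <- mediumStudy()
  set.seed(32)
  acc <- sample(st$panel, 12)
  g <- knnImpute(filterMarkers(st$genotypes, 0.1), k = 3)
  gsub <- GenotypeMatrix(calls(g)[acc, , drop = FALSE])
  K <- kinshipMatrix(gsub)
  y <- envCorrelations(st$phenotypes)$genotypic_values[acc]
  res <- suppressWarnings(mlmScan(gsub, y, K))
  lamHat <- attr(res, "lambda")
  # oracle: direct-solve restricted likelihood, coarse-to-fine grid at
  # 1e-4 resolution
  X <- matrix(1, length(acc), 1)
  Kv <- kinshipValues(K)
  ll <- function(l) remlLogLikDirect(l, unname(y), X, Kv)
  coarse <- seq(0.001, 50, length.out = 500)
  l0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(1e-4, l0 * 0.8), l0 * 1.2, by = 1e-4)
  lamGrid <- fine[which.max(vapply(fine, ll, numeric(1)))]
  # the estimator must attain at least the grid optimum's likelihood, and
  # agree with it when the optimum is interior
  expect_gte(ll(lamHat), ll(lamGrid) - 1e-6)
  if (l0 < 45)
    expect_equal(lamHat, lamGrid, tolerance = max(2e-3, 0.01 * lamGrid))
})

test_that("markers confounded with the covariate are skipped with reason", {
  set.seed(33)
  n <- 12
  m <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
              dimnames = list(sprintf("a%02d", 1:n), paste0("m", 1:3)))
  m[, 3] <- rep(1L, n)                      # monomorphic
  kern <- setNames(m[, 1], rownames(m))     # marker 1 equals the covariate
  y <- setNames(rnorm(n), rownames(m))
  res <- suppressWarnings(mlmScan(GenotypeMatrix(m), y,
                                  identityKinship(rownames(m)),
                                  covariates = kern))
  expect_setequal(attr(res, "skipped"), c("m1", "m3"))
  expect_equal(res$marker_id, "m2")
})

test_that("effects are oriented to the focal line's allele", {
  set.seed(34)
  n <- 20
  m <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
              dimnames = list(sprintf("a%02d", 1:n), c("m1", "m2")))
  m[1, ] <- c(1L, 0L)
  y <- setNames(2 * m[, 1] - 2 * m[, 2] + rnorm(n, 0, 0.1), rownames(m))
  res <- suppressWarnings(mlmScan(GenotypeMatrix(m), y,
                                  identityKinship(rownames(m)),
                                  focal = "a01"))
  # focal carries allele 1 at m1 (positive effect) and allele 0 at m2
  # (so the focal allele again increases the trait)
  expect_gt(res$effect[res$marker_id == "m1"], 0)
  expect_gt(res$effect[res$marker_id == "m2"], 0)
})

test_that("Storey q-values match the brute-force threshold minimisation", {
  expect_equal(storeyQValues(0.05, pi0 = 1)$q_values, 0.05)
  q4 <- storeyQValues(c(0.01, 0.02, 0.8, 0.9), pi0 = 1)$q_values
  expect_equal(q4, c(0.04, 0.04, 0.9, 0.9))
  # randomised sets up to 10 p-values against the oracle
  set.seed(35)
  for (i in 1:25) {
    p <- round(runif(sample(2:10, 1)), 3)
    expect_equal(storeyQValues(p, pi0 = 1)$q_values, bruteQValues(p),
                 tolerance = 1e-12)
    pi0 <- runif(1, 0.2, 1)
    expect_equal(storeyQValues(p, pi0 = pi0)$q_values,
                 bruteQValues(p, pi0), tolerance = 1e-12)
  }
  expect_error(storeyQValues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p and pi0 estimation stays in (0, 1]", {
  set.seed(36)
  p <- c(runif(300, 0, 1), runif(100, 0, 0.01))
  res <- storeyQValues(p)
  expect_true(res$pi0 > 0 && res$pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(res$q_values[o]) >= -1e-12))
  # number called significant is non-decreasing in the threshold
  alphas <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(alphas, function(a) sum(res$q_values <= a), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("kinship correction calibrates the null scan where the naive model inflates", {
  cfg <- SimulationConfig(n_markers_per_lg = 150, qtl_spec = data.frame(
    linkage_group = character(0), position = numeric(0),
    effect = numeric(0)))
  ksK <- ksI <- numeric(5)
  for (i in 1:5) {
    st <- suppressWarnings(simulateBreedingStudy(cfg, seed = 4100 + i,
                                                 nPanel = 65, nDHLines = 2,
                                                 nDHPopulations = 1,
                                                 nAncestral = NULL))
    filt <- filterMarkers(st$genotypes, 0.1)
    gi <- knnImpute(filt, k = 3)
    y <- envCorrelations(st$phenotypes)$genotypic_values
    resK <- suppressWarnings(mlmScan(gi, y, kinshipMatrix(gi)))
    resI <- suppressWarnings(mlmScan(gi, y,
                                     identityKinship(accessionIds(gi))))
    ksK[i] <- suppressWarnings(stats::ks.test(resK$p_value, "punif")$statistic)
    ksI[i] <- suppressWarnings(stats::ks.test(resI$p_value, "punif")$statistic)
  }
  expect_lt(median(ksK), median(ksI))
  expect_true(all(ksK < 0.08))
})

test_that("markers linked only to the kernel locus fade under the covariate", {
  cfg <- SimulationConfig(n_markers_per_lg = 150, qtl_spec = data.frame(
    linkage_group = character(0), position = numeric(0),
    effect = numeric(0)), kernel_locus_effect = 6)
  st <- suppressWarnings(simulateBreedingStudy(cfg, seed = 4301,
                                               nPanel = 65, nDHLines = 2,
                                               nDHPopulations = 1))
  gi <- knnImpute(filterMarkers(st$genotypes, 0.1), k = 3)
  y <- envCorrelations(st$phenotypes)$genotypic_values
  K <- kinshipMatrix(gi)
  with_cov <- suppressWarnings(mlmScan(gi, y, K, covariates = st$kernelType))
  without <- suppressWarnings(mlmScan(gi, y, K))
  tb <- mapTable(st$map)
  kpos <- tb$position[tb$marker_id == st$kernelMarker]
  klg <- tb$linkage_group[tb$marker_id == st$kernelMarker]
  linked <- tb$marker_id[tb$linkage_group == klg &
                           abs(tb$position - kpos) < 10 &
                           tb$marker_id != st$kernelMarker]
  linked <- intersect(linked, with_cov$marker_id)
  pw <- with_cov$p_value[match(linked, with_cov$marker_id)]
  po <- without$p_value[match(linked, without$marker_id)]
  expect_gt(median(pw), median(po))
})
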