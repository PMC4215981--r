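# Phenotype analysis: two-way random-effects ANOVA on the genotype x
# environment mean table, method-of-moments variance components,
# broad-sense heritability, environment correlation structure, genotypic
# values, and kernel-type-stratified trait correlations.

# genotype x environment table of replicate means for one trait
envMeanTable <- function(pheno, trait) {
  r <- phenoRecords(pheno)
  r <- r[r$trait == trait & !is.na(r$value), , drop = FALSE]
  stopIfNot(nrow(r) > 0, paste("trait not present:", trait))
  tapply(r$value, list(r$accession, r$environment), mean)
}

#' Two-way crossed ANOVA of a multi-environment trait
#'
#' Replicate values are averaged per (genotype, environment) first; the
#' crossed two-way ANOVA (genotype + environment, no interaction term
#' beyond the residual stratum) is then run on the mean table.  Missing
#' cells are handled by the unweighted least-squares fit and flagged.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param trait trait name.
#' @return list of class "AnovaResult": mean squares (`ms_genotype`,
#'   `ms_environment`, `ms_error`), degrees of freedom, F ratios,
#'   `n_genotypes`, `n_environments`, and `balanced`.
#' @export
twoWayAnova <- function(pheno, trait = "FlYd") {
  tab <- envMeanTable(pheno, trait)
  stopIfNot(nrow(tab) >= 2 && ncol(tab) >= 2,
            "need at least 2 genotypes and 2 environments")
  balanced <- !anyNA(tab)
  if (!balanced)
    warning("unbalanced genotype x environment table; ",
            "least-squares (unweighted-means) approximation used")
  d <- data.frame(value = as.vector(tab),
                  genotype = factor(rep(rownames(tab), ncol(tab))),
                  environment = factor(rep(colnames(tab), each = nrow(tab))))
  d <- d[!is.na(d$value), , drop = FALSE]
  fit <- aov(value ~ genotype + environment, data = d)
  an <- anova(fit)
  msg <- an["genotype", "Mean Sq"]; mse <- an["environment", "Mean Sq"]
  mser <- an["Residuals", "Mean Sq"]
  # a numerically zero error stratum leaves F undefined
  if (!is.finite(mser) || mser < 1e-12 * (1 + mean(d$value)^2)) mser <- 0
  res <- list(ms_genotype = msg, ms_environment = mse, ms_error = mser,
              df_genotype = an["genotype", "Df"],
              df_environment = an["environment", "Df"],
              df_error = an["Residuals", "Df"],
              f_genotype = if (mser > 0) msg / mser else NA_real_,
              f_environment = if (mser > 0) mse / mser else NA_real_,
              n_genotypes = nrow(tab), n_environments = ncol(tab),
              balanced = balanced)
  class(res) <- "AnovaResult"
  res
}

#' Variance components by expected mean squares
#'
#' Method-of-moments solution of the random-effects two-way model:
#' var_resid = MS_error; var_g = (MS_genotype - MS_error)/n_environments;
#' var_e = (MS_environment - MS_error)/n_genotypes.  Negative estimates
#' are truncated to zero and flagged.
#'
#' @param anova an "AnovaResult" (or a list with `ms_genotype`,
#'   `ms_environment`, `ms_error`, `n_genotypes`, `n_environments`).
#' @return list of class "VarianceComponents" with `var_g`, `var_e`,
#'   `var_resid`, sample sizes and a `truncated` flag.
#' @export
varianceComponents <- function(anova) {
  stopIfNot(anova$n_environments >= 2 && anova$n_genotypes >= 2,
            "need at least 2 genotypes and 2 environments")
  vg <- (anova$ms_genotype - anova$ms_error) / anova$n_environments
  ve <- (anova$ms_environment - anova$ms_error) / anova$n_genotypes
  vr <- anova$ms_error
  trunc <- vg < 0 || ve < 0
  res <- list(var_g = max(vg, 0), var_e = max(ve, 0), var_resid = vr,
              n_genotypes = anova$n_genotypes,
              n_environments = anova$n_environments, truncated = trunc)
  class(res) <- "VarianceComponents"
  res
}

#' Broad-sense heritability
#'
#' H^2 = var_g / (var_g + var_e + var_resid): the genotypic share of the
#' total phenotypic variance across environments (all three variance
#' components in the denominator).
#'
#' @param vc a "VarianceComponents" list.
#' @return heritability as a fraction in [0, 1], or NA when all components
#'   are zero.
#' @export
broadSenseHeritability <- function(vc) {
  tot <- vc$var_g + vc$var_e + vc$var_resid
  if (tot <= 0) return(NA_real_)
  vc$var_g / tot
}

#' Environment correlations and genotypic values
#'
#' Pearson correlations between environments over pairwise-complete
#' accessions, and the genotypic value of each accession as its mean over
#' environments.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param trait trait name.
#' @return list with `correlations` (environment x environment matrix) and
#'   `genotypic_values` (named vector of accession means over
#'   environments).
#' @export
envCorrelations <- function(pheno, trait = "FlYd") {
  tab <- envMeanTable(pheno, trait)
  stopIfNot(ncol(tab) >= 2, "need at least 2 environments")
  ce <- matrix(NA_real_, ncol(tab), ncol(tab),
               dimnames = list(colnames(tab), colnames(tab)))
  diag(ce) <- 1
  for (i in seq_len(ncol(tab) - 1)) for (j in (i + 1):ncol(tab)) {
    ok <- complete.cases(tab[, c(i, j)])
    if (sum(ok) < 3) {
      warning(sprintf("fewer than 3 shared accessions for %s vs %s",
                      colnames(tab)[i], colnames(tab)[j]))
      next
    }
    ce[i, j] <- ce[j, i] <- cor(tab[ok, i], tab[ok, j])
  }
  list(correlations = ce,
       genotypic_values = rowMeans(tab, na.rm = TRUE))
}

#' Trait correlations overall and within kernel-type strata
#'
#' Pearson correlation of two traits' genotypic values, overall and within
#' the soft (0) and hard (1) kernel strata; separates structure-driven
#' correlation (two shifted clusters) from within-class correlation.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param traitX,traitY trait names.
#' @param kernelType named 0/1 vector for every accession used.
#' @return data.frame with rows overall / soft / hard: n and r.
#' @export
stratifiedTraitCorrelations <- function(pheno, traitX, traitY, kernelType) {
  gx <- rowMeans(envMeanTable(pheno, traitX), na.rm = TRUE)
  gy <- rowMeans(envMeanTable(pheno, traitY), na.rm = TRUE)
  acc <- intersect(names(gx), names(gy))
  stopIfNot(all(acc %in% names(kernelType)),
            "kernel type must be known for all accessions used")
  strata <- list(overall = acc,
                 soft = acc[kernelType[acc] == 0],
                 hard = acc[kernelType[acc] == 1])
  rows <- lapply(names(strata), function(s) {
    a <- strata[[s]]
    if (length(a) < 3) {
      warning("stratum of size < 3: ", s)
      return(data.frame(stratum = s, n = length(a), r = NA_real_))
    }
    data.frame(stratum = s, n = length(a), r = cor(gx[a], gy[a]))
  })
  do.call(rbind, rows)
}

#' Write the phenotype-analysis report
#'
#' ANOVA table, variance components, heritability and the environment
#' correlation matrix as one delimited text report.
#'
#' @param anova "AnovaResult"; @param vc "VarianceComponents";
#' @param h2 heritability fraction; @param envcor output of
#'   \code{\link{envCorrelations}}; @param path output file.
#' @export
writePhenoReport <- function(anova, vc, h2, envcor, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# two-way ANOVA (genotype x environment means)", con)
  an <- data.frame(stratum = c("genotype", "environment", "error"),
                   df = c(anova$df_genotype, anova$df_environment,
                          anova$df_error),
                   mean_square = c(anova$ms_genotype, anova$ms_environment,
                                   anova$ms_error),
                   F = c(anova$f_genotype, anova$f_environment, NA))
  write.table(format(an, digits = 6), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("\n# variance components\nvar_g\t%.4f\nvar_e\t%.4f\nvar_resid\t%.4f\nheritability_pct\t%.1f",
                     vc$var_g, vc$var_e, vc$var_resid, 100 * h2), con)
  writeLines("\n# environment correlations", con)
  write.table(round(envcor$correlations, 3), con, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}
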