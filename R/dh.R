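# Doubled-haploid validation: allele-mean t-tests per marker, multi-marker
# least-squares prediction models, and predicted-vs-actual correlation.

#' Allele-mean t-test for one validation marker
#'
#' Two-sided pooled-variance t-test of the trait values by allele class,
#' with the focal parent's allele class (code 1) reported first.  A
#' monomorphic marker yields a single-class result with a missing p-value
#' rather than an error.
#'
#' @param pop a \linkS4class{DHPopulation}.
#' @param marker marker id.
#' @return list: `n` (per class), `mean` (per class), `p` (NA if
#'   monomorphic or a class has < 2 lines), `t`.
#' @export
alleleMeanTest <- function(pop, marker) {
  g <- calls(pop)[, marker]
  y <- dhPhenotype(pop)
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  y1 <- y[g == 1L]; y0 <- y[g == 0L]
  n <- c(focal = length(y1), other = length(y0))
  means <- c(focal = mean(y1), other = mean(y0))
  if (any(n < 2)) {
    return(list(n = n, mean = means, p = NA_real_, t = NA_real_,
                monomorphic = any(n == 0)))
  }
  tt <- t.test(y1, y0, var.equal = TRUE)
  list(n = n, mean = means, p = tt$p.value, t = unname(tt$statistic),
       monomorphic = FALSE)
}

#' Fit a multi-marker regression model
#'
#' Ordinary least squares of the phenotype on the 0/1 marker codes.  When
#' several populations are combined, population-specific intercepts absorb
#' the mean differences between crosses; markers monomorphic within a
#' population still contribute through the lines of the populations where
#' they segregate, and markers monomorphic across all used lines are
#' excluded with a warning.
#'
#' @param pops a \linkS4class{DHPopulation} or list of them.
#' @param markers marker ids to use (default: all shared markers).
#' @param dropAliased drop perfectly collinear markers (keeping the first
#'   of each aliased set) instead of raising an error.
#' @return list of class "MarkerRegressionModel": `coefficients`,
#'   `markers`, `populations`, `fit` (the lm object), `r_squared`.
#' @export
fitMarkerRegression <- function(pops, markers = NULL, dropAliased = FALSE) {
  if (is(pops, "DHPopulation")) pops <- list(pops)
  if (is.null(markers))
    markers <- Reduce(intersect, lapply(pops, function(p)
      colnames(calls(p))))
  d <- do.call(rbind, lapply(pops, function(p) {
    g <- calls(p)[, markers, drop = FALSE]
    data.frame(population = p@name, y = dhPhenotype(p)[rownames(g)], g,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  d <- d[complete.cases(d), , drop = FALSE]
  stopIfNot(nrow(d) >= length(markers) + 1,
            "fewer complete lines than model parameters")
  keep <- markers[vapply(markers, function(m) var(d[[m]]) > 0, logical(1))]
  if (length(keep) < length(markers))
    warning("monomorphic markers excluded from the fit: ",
            paste(setdiff(markers, keep), collapse = ", "))
  stopIfNot(length(keep) > 0, "no polymorphic markers to fit")
  rhs <- paste(c(if (length(pops) > 1) "population",
                 sprintf("`%s`", keep)), collapse = " + ")
  fit <- lm(stats::as.formula(paste("y ~", rhs)), data = d)
  if (any(is.na(coef(fit)))) {
    bad <- gsub("`", "", names(coef(fit))[is.na(coef(fit))])
    if (!dropAliased)
      stop("rank-deficient design; collinear terms: ",
           paste(bad, collapse = ", "), call. = FALSE)
    warning("dropping aliased markers: ", paste(bad, collapse = ", "))
    keep <- setdiff(keep, bad)
    stopIfNot(length(keep) > 0, "no markers left after aliasing")
    rhs <- paste(c(if (length(pops) > 1) "population",
                   sprintf("`%s`", keep)), collapse = " + ")
    fit <- lm(stats::as.formula(paste("y ~", rhs)), data = d)
  }
  co <- coef(fit)
  names(co) <- gsub("`", "", names(co))
  res <- list(coefficients = co, markers = keep,
              populations = vapply(pops, function(p) p@name, character(1)),
              fit = fit, r_squared = summary(fit)$r.squared)
  class(res) <- "MarkerRegressionModel"
  res
}

#' Predict trait values and correlate with observations
#'
#' Linear prediction per line from a fitted marker-regression model, and
#' the Pearson correlation with the observed phenotype over lines with
#' complete data.
#'
#' @param model a "MarkerRegressionModel".
#' @param pop a \linkS4class{DHPopulation} genotyped at the model markers.
#' @return list: `predicted` (named vector), `actual`, `r` (NA when the
#'   predictions have zero variance).
#' @export
predictAndCorrelate <- function(model, pop) {
  g <- calls(pop)[, model$markers, drop = FALSE]
  stopIfNot(all(model$markers %in% colnames(calls(pop))),
            "population not genotyped at all model markers")
  nd <- data.frame(population = pop@name, g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  pred <- tryCatch(predict(model$fit, newdata = nd),
                   error = function(e)
                     stop("population not predictable with this model ",
                          "(unseen population level?): ", conditionMessage(e),
                          call. = FALSE))
  names(pred) <- rownames(g)
  y <- dhPhenotype(pop)[names(pred)]
  ok <- !is.na(pred) & !is.na(y)
  r <- if (sum(ok) >= 3 && sd(pred[ok]) > 0 && sd(y[ok]) > 0)
    cor(pred[ok], y[ok]) else NA_real_
  if (sum(ok) >= 3 && (sd(pred[ok]) == 0))
    warning("zero-variance prediction; correlation undefined")
  list(predicted = pred, actual = y, r = r)
}

#' Table-4-style validation report over populations and markers
#'
#' @param pops list of \linkS4class{DHPopulation}.
#' @param markers marker ids.
#' @param path optional output file (tab-separated).
#' @return data.frame: population, marker, n/mean per allele class, p.
#' @export
dhValidationReport <- function(pops, markers, path = NULL) {
  rows <- list()
  for (p in pops) for (m in intersect(markers, colnames(calls(p)))) {
    tst <- alleleMeanTest(p, m)
    rows[[length(rows) + 1]] <- data.frame(
      population = p@name, marker = m,
      n_focal = tst$n[["focal"]], mean_focal = round(tst$mean[["focal"]], 2),
      n_other = tst$n[["other"]], mean_other = round(tst$mean[["other"]], 2),
      p = signif(tst$p, 3), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Coefficients of the model-free comparison of the two prediction schemes
#'
#' Fits the combined-population model ("DH_total", population intercepts)
#' and the per-population models ("DH_each"), predicts every line with the
#' relevant model, and reports the pooled predicted-vs-actual correlation
#' for each scheme.
#'
#' @param pops list of \linkS4class{DHPopulation}.
#' @param markers marker ids.
#' @return list: `r_total`, `r_each`, `model_total`, `models_each`,
#'   `predictions` (data.frame).
#' @export
comparePredictionSchemes <- function(pops, markers) {
  total <- fitMarkerRegression(pops, markers, dropAliased = TRUE)
  predT <- lapply(pops, function(p) predictAndCorrelate(total, p))
  each <- lapply(pops, function(p) {
    mk <- markers[vapply(markers, function(m)
      var(calls(p)[, m], na.rm = TRUE) > 0, logical(1))]
    fitMarkerRegression(p, mk, dropAliased = TRUE)
  })
  predE <- lapply(seq_along(pops), function(i)
    predictAndCorrelate(each[[i]], pops[[i]]))
  pool <- function(preds) {
    pr <- unlist(lapply(preds, `[[`, "predicted"))
    ac <- unlist(lapply(preds, `[[`, "actual"))
    ok <- !is.na(pr) & !is.na(ac)
    cor(pr[ok], ac[ok])
  }
  df <- do.call(rbind, lapply(seq_along(pops), function(i) data.frame(
    population = pops[[i]]@name, line = names(predT[[i]]$predicted),
    actual = predT[[i]]$actual,
    predicted_total = predT[[i]]$predicted,
    predicted_each = predE[[i]]$predicted, stringsAsFactors = FALSE)))
  list(r_total = pool(predT), r_each = pool(predE), model_total = total,
       models_each = each, predictions = df)
}
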