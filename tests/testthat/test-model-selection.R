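makeFit <- function(spec, lnL, binning = rsaBinning(spec@nBins),
                    estimates = NULL) {
  if (is.null(estimates)) {
    estimates <- lapply(spec@forms, function(f)
      switch(f, constant = 0.5, linear = c(0.5, 0),
             `per-bin` = rep(0.5, spec@nBins)))
    names(estimates) <- names(spec@forms)
  }
  df <- modelDf(spec)
  new("CodonFit", spec = spec, estimates = estimates, logLik = lnL,
      df = df, aic = 2 * df - 2 * lnL, converged = TRUE, nSitesUsed = 100L,
      pi = uniformPi(), binning = binning)
}

test_that("degrees of freedom sum 1/2/n over the three parameter forms", {
  expect_identical(modelDf(modelSpec("GY94", "linear", "linear", "per-bin")),
                   24L)
  expect_identical(modelDf(modelSpec("GY94", "per-bin", "per-bin", "per-bin")),
                   60L)
  expect_identical(modelDf(modelSpec("GY94")), 3L)
  expect_identical(modelDf(modelSpec("GY94", "per-bin", "linear", "per-bin")),
                   42L)
  ## bin count propagates into per-bin forms
  expect_identical(
    modelDf(modelSpec("GY94", "constant", "constant", "per-bin", nBins = 7)),
    9L)
  ## grouped specs: shared forms plus one value per tie class
  gs <- groupedCodonSpec(c("a", "b"), t = "linear", kappa = "per-bin",
                         nBins = 20)
  expect_identical(modelDf(gs), 2L + 20L + 2L + 2L)
  gsTied <- groupedCodonSpec(c("a", "b"), t = "linear", kappa = "per-bin",
                             interceptTies = c(a = "all", b = "all"),
                             nBins = 20)
  expect_identical(modelDf(gsTied), 2L + 20L + 1L + 2L)
})

test_that("AIC is 2 df - 2 lnL", {
  expect_equal(aicScore(-839713.86, 24), 1679475.72)
  expect_equal(aicScore(-839736.74, 6), 1679485.48)
  expect_equal(aicScore(0, 1), 2)
  expect_error(aicScore(0, 0), "df")
})

test_that("the model space enumerates the 27 form combinations", {
  specs <- enumerateModelSpecs("GY94", nBins = 20)
  expect_length(specs, 27)
  labels <- vapply(specs, function(s) paste(s@forms, collapse = "/"), "")
  expect_identical(anyDuplicated(labels), 0L)
  noConst <- vapply(specs, function(s) !any(s@forms == "constant"), NA)
  expect_identical(sum(noConst), 8L)
  mg <- enumerateModelSpecs("MG94", nBins = 10)
  expect_length(mg, 27)
  expect_true(all(vapply(mg, function(s) s@family == "MG94", NA)))
})

test_that("ranking sorts by AIC with df and label tie-breaks", {
  b <- rsaBinning(20)
  f1 <- makeFit(modelSpec("GY94"), -10)                      # AIC 26
  f2 <- makeFit(modelSpec("GY94", "linear"), -10)            # AIC 28
  tab <- rankModels(list(f2, f1))
  expect_identical(tab$df, c(3L, 4L))
  expect_equal(tab$deltaAIC, c(0, 2))
  ## equal AIC: smaller df wins
  f3 <- makeFit(modelSpec("GY94", "linear"), -9)             # AIC 26, df 4
  tab2 <- rankModels(list(f3, f1))
  expect_identical(tab2$df, c(3L, 4L))
  ## trend-sign column: positive slope reported as "+"
  fUp <- makeFit(modelSpec("GY94", omega = "linear"), -10,
                 estimates = list(omega = c(0.1, 0.2), t = 0.5, kappa = 2))
  expect_identical(rankModels(list(fUp))$omegaSlope, "+")
})

test_that("likelihood-ratio tests use the chi-square on the df difference", {
  con <- makeFit(modelSpec("GY94"), -100)
  lin <- makeFit(modelSpec("GY94", omega = "linear"), -100)
  eq <- lrTest(con, lin)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)
  ## statistic 3.841 on 1 df sits at the 5% point
  lin2 <- makeFit(modelSpec("GY94", omega = "linear"), -100 + 3.841 / 2)
  expect_equal(lrTest(con, lin2)$p.value, 0.05, tolerance = 1e-3)
  ## non-nested pairs are rejected
  tLin <- makeFit(modelSpec("GY94", t = "linear"), -99)
  expect_error(lrTest(lin, tLin), "not nested")
  ## the nested fit cannot beat the full fit
  worse <- makeFit(modelSpec("GY94", omega = "linear"), -101)
  expect_error(lrTest(con, worse), "higher log-likelihood")
})

test_that("grouped fits tie and free parameters across groups correctly", {
  base <- modelSpec("GY94", omega = "linear", nBins = 4)
  params <- list(omega = c(0.1, 0.3), t = 0.5, kappa = 2)
  sdA <- simData(4000, base, params, seed = 41)
  sdB <- simData(4000, base, params, seed = 42)
  groups <- list(a = sdA$data, b = sdB$data)
  pi <- uniformPi()
  ctl <- list(nStarts = 2, seed = 1)

  spec <- groupedCodonSpec(c("a", "b"), t = "constant", kappa = "constant",
                           nBins = 4)
  fit <- fitGroupedModel(groups, spec, pi, rsaBinning(4), ctl)
  ## identically distributed groups get near-identical omega lines
  expect_equal(unname(fit@omegaIntercepts["a"]),
               unname(fit@omegaIntercepts["b"]), tolerance = 0.12)
  expect_equal(unname(fit@omegaSlopes["a"]), unname(fit@omegaSlopes["b"]),
               tolerance = 0.25)
  expect_identical(fit@df, 1L + 1L + 2L + 2L)

  ## tying everything reproduces the pooled single fit
  tied <- groupedCodonSpec(c("a", "b"), t = "constant", kappa = "constant",
                           interceptTies = c(a = "all", b = "all"),
                           slopeTies = c(a = "all", b = "all"), nBins = 4)
  fitTied <- fitGroupedModel(groups, tied, pi, rsaBinning(4), ctl)
  pooledAln <- Biostrings::DNAStringSet(c(
    paste0(as.character(sdA$alignment)[1], as.character(sdB$alignment)[1]),
    paste0(as.character(sdA$alignment)[2], as.character(sdB$alignment)[2])))
  pooledRsa <- rbind(sdA$siteRsa,
                     data.frame(site = sdB$siteRsa$site + 4000,
                                rsa = sdB$siteRsa$rsa))
  pooledData <- binPairCounts(pooledAln, pooledRsa, rsaBinning(4))
  fitPooled <- fitCodonModel(base, pooledData, pi, rsaBinning(4), ctl)
  expect_equal(fitTied@logLik, fitPooled@logLik, tolerance = 1e-4)
  expect_identical(fitTied@df, fitPooled@df)

  ## a clearly different slope is detected by the slope-equality LRT
  sdC <- simData(4000, base, list(omega = c(0.1, 0.8), t = 0.5, kappa = 2),
                 seed = 43)
  groups2 <- list(a = sdA$data, b = sdC$data)
  free <- fitGroupedModel(groups2, spec, pi, rsaBinning(4), ctl)
  slopeTied <- groupedCodonSpec(c("a", "b"), t = "constant",
                                kappa = "constant",
                                slopeTies = c(a = "s", b = "s"), nBins = 4)
  restr <- fitGroupedModel(groups2, slopeTied, pi, rsaBinning(4), ctl)
  lr <- lrTest(restr, free)
  expect_lt(lr$p.value, 0.01)
  expect_gt(unname(free@omegaSlopes["b"]), unname(free@omegaSlopes["a"]))

  ## referencing a missing group errors
  expect_error(fitGroupedModel(list(a = sdA$data), spec, pi), "absent")
})
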