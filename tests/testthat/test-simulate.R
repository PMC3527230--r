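test_that("simulation is deterministic given a seed and collapses at t = 0", {
  spec <- modelSpec("GY94", nBins = 4)
  b <- rsaBinning(4)
  params <- list(omega = 0.3, t = 0.4, kappa = 2)
  s1 <- simulateCodonPair(200, spec, params, binning = b, seed = 5)
  s2 <- simulateCodonPair(200, spec, params, binning = b, seed = 5)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
  expect_identical(s1$siteRsa, s2$siteRsa)
  s3 <- simulateCodonPair(200, spec, params, binning = b, seed = 6)
  expect_false(identical(as.character(s1$alignment),
                         as.character(s3$alignment)))
  ## vanishing branch length: descendant equals ancestor everywhere
  s0 <- simulateCodonPair(300, spec, list(omega = 0.3, t = 1e-12, kappa = 2),
                          binning = b, seed = 7)
  expect_identical(as.character(s0$alignment)[[1]],
                   as.character(s0$alignment)[[2]])
  expect_error(simulateCodonPair(100, spec, params, binning = b),
               "seed")
  expect_error(simulateCodonPair(100, spec, params, binning = b, seed = 1,
                                 rsaDist = list(kind = "nope")), "unknown")
})

test_that("RSA distributions cover [0, 1] as configured", {
  spec <- modelSpec("GY94", nBins = 4)
  b <- rsaBinning(4)
  params <- list(omega = 0.3, t = 0.4, kappa = 2)
  for (dist in list(list(kind = "uniform"),
                    list(kind = "beta", shape1 = 0.5, shape2 = 3),
                    list(kind = "mixture"))) {
    s <- simulateCodonPair(2000, spec, params, binning = b, seed = 11,
                           rsaDist = dist)
    expect_true(all(s$siteRsa$rsa >= 0 & s$siteRsa$rsa <= 1))
  }
  ## the empirical-like mixture is buried-skewed
  s <- simulateCodonPair(5000, spec, params, binning = b, seed = 12,
                         rsaDist = list(kind = "mixture"))
  expect_lt(median(s$siteRsa$rsa), 0.5)
})

test_that("simulated pair frequencies match pi_i P_ij", {
  ## single effective matrix (constant parameters), many sites; compare the
  ## empirical distribution over the six substitution classes with the
  ## theoretical pi_i P_ij mass via a chi-square goodness-of-fit test
  spec <- modelSpec("GY94", nBins = 2)
  b <- rsaBinning(2)
  set.seed(23)
  piRaw <- rgamma(61, 4); pi <- piRaw / sum(piRaw)
  params <- list(omega = 0.2, t = 0.6, kappa = 3)
  s <- simulateCodonPair(1e5, spec, params, pi = pi, binning = b, seed = 27)
  sense <- unname(senseCodons())
  i <- match(substring(as.character(s$alignment)[[1]],
                       seq(1, 3e5, 3), seq(3, 3e5, 3)), sense)
  j <- match(substring(as.character(s$alignment)[[2]],
                       seq(1, 3e5, 3), seq(3, 3e5, 3)), sense)
  cls <- codonSubstitutionClasses()
  obs <- table(factor(cls[cbind(i, j)],
                      levels = sort(unique(as.vector(cls)))))
  p <- transitionMatrix(gy94RateMatrix(0.2, 3, pi), 0.6)
  mass <- pi * p
  expProb <- vapply(names(obs), function(k) sum(mass[cls == k]), 0)
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expProb,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 1e-3)
})

test_that("fitting the generating model dominates the truth and is
           label-symmetric", {
  spec <- modelSpec("GY94", nBins = 4)
  b <- rsaBinning(4)
  params <- list(omega = 0.3, t = 0.4, kappa = 2)
  pi <- uniformPi()
  for (seed in c(31, 32, 33)) {
    s <- simulateCodonPair(1500, spec, params, binning = b, seed = seed)
    d <- binPairCounts(s$alignment, s$siteRsa, b)
    fit <- fitCodonModel(spec, d, pi, b, list(nStarts = 2, seed = 1))
    llTrue <- codonLogLik(spec, params, d, pi, b)
    expect_gte(fit@logLik, llTrue - 1e-6)  # MLE dominance
    swapped <- Biostrings::DNAStringSet(rev(as.character(s$alignment)))
    dSwap <- binPairCounts(swapped, s$siteRsa, b)
    fitSwap <- fitCodonModel(spec, dSwap, pi, b, list(nStarts = 2, seed = 1))
    expect_equal(fitSwap@logLik, fit@logLik, tolerance = 1e-4)
  }
})

test_that("recovery experiments aggregate bias and RMSE per parameter", {
  spec <- modelSpec("GY94", nBins = 4)
  out <- recoveryExperiment(800, spec, list(omega = 0.3, t = 0.4, kappa = 2),
                            replicates = 3, seed = 51,
                            control = list(nStarts = 1))
  expect_setequal(unique(out$perReplicate$parameter),
                  c("omega", "t", "kappa"))
  expect_identical(nrow(out$summary), 3L)
  expect_true(all(is.finite(out$summary$rmse)))
  ## estimates are in a sane range even at this small size
  expect_true(all(out$summary$mean > 0))
})
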