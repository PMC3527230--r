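test_that("substitution numbers sum pi-weighted rate flow over pair types", {
  set.seed(13)
  piRaw <- rgamma(61, 3); pi <- piRaw / sum(piRaw)
  q <- gy94RateMatrix(0.2, 2, pi)
  en <- substitutionNumbers(q, 0.5)
  ## vanishing omega kills the nonsynonymous flow
  enNull <- substitutionNumbers(gy94RateMatrix(1e-12, 2, pi), 0.5)
  expect_lt(enNull[["nonsyn"]], 1e-10)
  expect_gt(enNull[["syn"]], 0)
  ## linearity in t
  en2 <- substitutionNumbers(q, 1.0)
  expect_equal(2 * en, en2)
  ## totals conservation against the diagonal
  expect_equal(en[["syn"]] + en[["nonsyn"]],
               -0.5 * sum(pi * diag(rateMatrix(q))))
})

test_that("physical site counts enumerate single-nucleotide neighbors", {
  pi <- uniformPi()
  ps <- physicalSiteCounts(pi)
  percodon <- ps$perCodon
  ## independent oracle: enumerate all 9 mutations of each codon with the
  ## genetic code straight from Biostrings
  gc <- Biostrings::GENETIC_CODE
  oracle <- function(codon) {
    s <- 0; n <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == b) next
      mut <- codon; substr(mut, p, p) <- b
      if (gc[[mut]] == "*") next  # stop mutations carry no site weight
      if (gc[[mut]] == gc[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
    }
    c(S = s, N = n)
  }
  for (codon in c("TTA", "GGG", "ATG", "TGG", "AAA")) {
    expected <- oracle(codon)
    row <- percodon[percodon$codon == codon, ]
    expect_equal(row$S, expected[["S"]], info = codon)
    expect_equal(row$N, expected[["N"]], info = codon)
  }
  ## four-fold degenerate third position contributes one full synonymous site
  expect_gte(percodon$S[percodon$codon == "GGG"], 1)
  ## codons without stop neighbors have S + N = 3; TGG (both its stop
  ## mutations removed) has less
  expect_equal(percodon$S[percodon$codon == "GGG"] +
                 percodon$N[percodon$codon == "GGG"], 3)
  expect_lt(percodon$S[percodon$codon == "TGG"] +
              percodon$N[percodon$codon == "TGG"], 3)
  ## aggregates are pi-weighted means
  expect_equal(ps$S + ps$N, mean(percodon$S + percodon$N))
})

test_that("mutational-opportunity counts reduce to physical counts at
           kappa = 1, uniform pi", {
  pi <- uniformPi()
  mo <- mutationalOpportunityCounts(1, pi)
  ps <- physicalSiteCounts(pi)
  expect_equal(mo$S, ps$S, tolerance = 1e-12)
  expect_equal(mo$N, ps$N, tolerance = 1e-12)
  ## transition bias inflates synonymous opportunity (synonymous changes are
  ## transition-enriched at third positions)
  mo10 <- mutationalOpportunityCounts(10, pi)
  expect_gt(mo10$S / ps$S, 1)
  expect_gt(mo10$S / mo10$N, mo$S / mo$N)
})

test_that("rate profiles divide substitution numbers by site counts", {
  b <- rsaBinning(4)
  ## constant model: flat profile under both definitions
  spec <- modelSpec("GY94", nBins = 4)
  sd <- simData(3000, spec, list(omega = 0.25, t = 0.5, kappa = 2), seed = 19)
  fit <- fitCodonModel(spec, sd$data, sd$pi, b, list(nStarts = 2, seed = 1))
  prof <- rateProfile(fit)
  expect_identical(nrow(prof), 4L)
  for (col in c("dN_mut", "dS_mut", "dN_phys", "dS_phys"))
    expect_equal(diff(range(prof[[col]])), 0)
  ## mutational-opportunity dN/dS identity with omega(r_k)
  expect_lt(max(abs(prof$dN_mut / prof$dS_mut - prof$omega)), 1e-6)
  ## totals conservation across the two definitions
  pi <- uniformPi()
  ps <- physicalSiteCounts(pi)
  for (k in seq_len(nrow(prof))) {
    mo <- mutationalOpportunityCounts(estimates(fit)$kappa, pi)
    totMut <- prof$dN_mut[k] * mo$N + prof$dS_mut[k] * mo$S
    totPhys <- prof$dN_phys[k] * ps$N + prof$dS_phys[k] * ps$S
    expect_equal(totMut, totPhys, tolerance = 1e-10)
  }
})

test_that("per-bin kappa decouples the two dS definitions", {
  ## a synthetic fitted model with linear omega, linear t and strongly
  ## varying per-bin kappa: dS under the two definitions must diverge
  b <- rsaBinning(4)
  spec <- modelSpec("GY94", omega = "linear", t = "linear",
                    kappa = "per-bin", nBins = 4)
  fit <- new("CodonFit", spec = spec,
             estimates = list(omega = c(0.05, 0.2), t = c(0.3, 2),
                              kappa = c(8, 4, 2, 1)),
             logLik = 0, df = modelDf(spec), aic = 2 * modelDf(spec),
             converged = TRUE, nSitesUsed = 0L, pi = uniformPi(),
             binning = b)
  prof <- rateProfile(fit)
  ratio <- prof$dS_mut / prof$dS_phys
  expect_gt(diff(range(ratio)), 0.01)
  ## the omega identity still holds bin by bin
  expect_lt(max(abs(prof$dN_mut / prof$dS_mut - prof$omega)), 1e-6)
  ## MG94 profiles report omega = beta/alpha
  specM <- modelSpec("MG94", alpha = "linear", beta = "linear",
                     kappa = "constant", nBins = 4)
  fitM <- new("CodonFit", spec = specM,
              estimates = list(alpha = c(0.4, 0.3), beta = c(0.04, 0.2),
                               kappa = 2),
              logLik = 0, df = modelDf(specM), aic = 2 * modelDf(specM),
              converged = TRUE, nSitesUsed = 0L, pi = uniformPi(),
              binning = b)
  profM <- rateProfile(fitM)
  mids <- binMidpoints(b)
  expect_equal(profM$omega,
               (0.04 + 0.2 * mids) / (0.4 + 0.3 * mids), tolerance = 1e-10)
})
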