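test_that("F3x4 frequencies multiply position-specific nucleotide counts", {
  ## degenerate alignment: all mass on ATG
  aln <- Biostrings::DNAStringSet(c(a = "ATGATGATG", b = "ATGATGATG"))
  pi <- codonFrequenciesF3x4(aln)
  expect_equal(unname(pi["ATG"]), 1)
  ## uniform nucleotide usage at all positions -> 1/61 after
  ## stop-renormalization
  s <- paste(rep(c("AAA", "CCC", "GGG", "TTT"), 2), collapse = "")
  alnU <- Biostrings::DNAStringSet(c(a = s, b = s))
  piU <- codonFrequenciesF3x4(alnU)
  expect_equal(unname(piU), rep(1 / 61, 61), tolerance = 1e-12)
  ## independent hand calculation for a two-codon toy alignment
  aln2 <- Biostrings::DNAStringSet(c(a = "ATGAAA", b = "ATGGGA"))
  pi2 <- codonFrequenciesF3x4(aln2)
  cc <- c("ATG", "AAA", "ATG", "GGA")
  f <- sapply(1:3, function(p)
    table(factor(substr(cc, p, p), levels = c("A", "C", "G", "T"))) / 4)
  sense <- unname(senseCodons())
  raw <- f[substr(sense, 1, 1), 1] * f[substr(sense, 2, 2), 2] *
    f[substr(sense, 3, 3), 3]
  expect_equal(unname(pi2), unname(raw / sum(raw)))
  ## gapped-only alignment errors
  expect_error(codonFrequenciesF3x4(
    Biostrings::DNAStringSet(c(a = "---", b = "---"))), "no ungapped")
})

test_that("GY94 generator entries follow the substitution classes", {
  pi <- uniformPi()
  names(pi) <- unname(senseCodons())
  omega <- 0.1; kappa <- 3
  q <- rateMatrix(gy94RateMatrix(omega, kappa, pi))
  expect_equal(q["TTA", "CTA"], kappa * pi[["CTA"]])        # syn transition
  expect_equal(q["AAA", "ACC"], 0)                          # multi
  expect_equal(q["GAA", "GAT"], omega * pi[["GAT"]])        # nonsyn tv
  expect_equal(q["TTT", "TTC"], kappa * pi[["TTC"]])        # syn ts
  expect_equal(q["ATG", "ATA"], kappa * omega * pi[["ATA"]])  # nonsyn ts
  expect_equal(unname(rowSums(q)), rep(0, 61), tolerance = 1e-12)
  expect_error(gy94RateMatrix(-1, 2, pi), "omega")
  expect_error(gy94RateMatrix(0.2, 0, pi), "kappa")
})

test_that("generators are stationary and reversible for skewed frequencies", {
  set.seed(11)
  piRaw <- rexp(61); pi <- piRaw / sum(piRaw)
  q <- gy94RateMatrix(0.3, 4, pi)
  Q <- rateMatrix(q)
  expect_lt(max(abs(pi %*% Q)), 1e-10)                     # pi Q = 0
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)           # detailed balance
  ## increasing omega raises nonsynonymous entries, leaves synonymous alone
  Q2 <- rateMatrix(gy94RateMatrix(0.6, 4, pi))
  cls <- codonSubstitutionClasses()
  ns <- cls %in% c("nonsyn_ts", "nonsyn_tv")
  syn <- cls %in% c("syn_ts", "syn_tv")
  expect_true(all(Q2[ns] > Q[ns]))
  expect_equal(Q2[syn], Q[syn])
})

test_that("transition matrices match an independent dense exponential", {
  set.seed(5)
  piRaw <- rgamma(61, 2); pi <- piRaw / sum(piRaw)
  q <- gy94RateMatrix(0.25, 2.5, pi)
  expect_equal(transitionMatrix(q, 0), diag(61), ignore_attr = TRUE)
  expect_error(transitionMatrix(q, -1), "non-negative")
  for (t in c(0.05, 0.7, 3)) {
    p <- transitionMatrix(q, t)
    expect_equal(unname(rowSums(p)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(p >= 0))
    ## oracle: ape's dense matrix exponential
    expect_equal(unname(p), ape::matexpo(t * rateMatrix(q)),
                 tolerance = 1e-9)
    ## detailed balance propagates to P
    expect_lt(max(abs(pi * p - t(pi * p))), 1e-12)
  }
  ## stationary limit: for large t every row approaches pi (the unscaled
  ## generator relaxes slowly, so t must be very large)
  pInf <- transitionMatrix(q, 1e4)
  expect_equal(unname(pInf), matrix(pi, 61, 61, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("MG94 is defined by the alpha = t, beta = t*omega correspondence", {
  set.seed(9)
  piRaw <- rexp(61); pi <- piRaw / sum(piRaw)
  ## alpha = beta reduces to GY94 with omega = 1 and t = alpha
  qm <- mg94RateMatrix(0.4, 0.4, 3, pi)
  qg <- gy94RateMatrix(1, 3, pi)
  expect_equal(rateMatrix(qm), 0.4 * rateMatrix(qg), tolerance = 1e-12)
  ## unit-time MG94 equals GY94 at (t, omega): alpha=0.7, beta=0.07 <-> t=0.7,
  ## omega=0.1
  pm <- transitionMatrix(mg94RateMatrix(0.7, 0.07, 3, pi), 1)
  pg <- transitionMatrix(gy94RateMatrix(0.1, 3, pi), 0.7)
  expect_lt(max(abs(pm - pg)), 1e-10)
  expect_equal(unname(rowSums(rateMatrix(qm))), rep(0, 61), tolerance = 1e-12)
})
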