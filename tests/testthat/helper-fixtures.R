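## shared fixtures, all generated in code

uniformPi <- function() rep(1 / 61, 61)

## a quick simulated data set: returns alignment, siteRsa, data, binning
simData <- function(nSites, spec, params, pi = uniformPi(),
                    nBinsUsed = spec@nBins, seed = 1,
                    rsaDist = list(kind = "uniform")) {
  binning <- rsaBinning(nBinsUsed)
  sim <- simulateCodonPair(nSites, spec, params, pi = pi, binning = binning,
                           rsaDist = rsaDist, seed = seed)
  list(alignment = sim$alignment, siteRsa = sim$siteRsa,
       data = binPairCounts(sim$alignment, sim$siteRsa, binning),
       binning = binning, pi = pi)
}

## independent per-site log-likelihood oracle: no binned sufficient
## statistics, P from ape's dense matrix exponential
naiveLogLik <- function(spec, params, alignment, siteRsa, binning, pi) {
  stopifnot(spec@family == "GY94")
  mids <- binMidpoints(binning)
  bins <- assignBins(siteRsa$rsa, binning)
  codons <- Biostrings::DNAStringSet(alignment)
  s1 <- as.character(codons[[1]])
  s2 <- as.character(codons[[2]])
  sense <- unname(senseCodons())
  evalF <- function(form, v) switch(form,
    constant = rep(v[1], length(mids)),
    linear = v[1] + v[2] * mids,
    `per-bin` = v)
  om <- evalF(spec@forms[["omega"]], params$omega)
  tv <- evalF(spec@forms[["t"]], params$t)
  kv <- evalF(spec@forms[["kappa"]], params$kappa)
  pcache <- list()
  ll <- 0
  for (s in seq_len(nrow(siteRsa))) {
    site <- siteRsa$site[s]
    c1 <- substr(s1, 3 * site - 2, 3 * site)
    c2 <- substr(s2, 3 * site - 2, 3 * site)
    i <- match(c1, sense); j <- match(c2, sense)
    if (is.na(i) || is.na(j)) next
    k <- bins[s]
    key <- as.character(k)
    if (is.null(pcache[[key]])) {
      q <- rateMatrix(gy94RateMatrix(om[k], kv[k], pi))
      pcache[[key]] <- ape::matexpo(tv[k] * q)
    }
    ll <- ll + log(pi[i] * pcache[[key]][i, j])
  }
  ll
}

## a small synthetic DSSP-format file (text built in code, never a real PDB)
writeDsspFixture <- function(path, withBreak = FALSE) {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  2  1  0  0  0 TOTAL NUMBER OF RESIDUES",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  fmt <- function(num, chain, aa, acc) {
    left <- sprintf("%5d%5d %s %s  H", num, num, chain, aa)  # AA at col 14
    paste0(formatC(left, width = -34), sprintf("%4d", acc),  # ACC at 35-38
           "      0, 0.0     0, 0.0   0.0   0.0")
  }
  brk <- paste0(formatC(sprintf("%5d%5s %s %s", 3L, "", " ", "!"),
                        width = -34), sprintf("%4d", 0L))
  lines <- c(hdr, fmt(1, "A", "A", 56), fmt(2, "A", "W", 130))
  if (withBreak) lines <- c(lines, brk, fmt(4, "A", "G", 40))
  writeLines(lines, path)
  path
}
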