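## dN and dS are derived quantities, not fitted parameters: the expected
## numbers of synonymous and nonsynonymous substitutions per unit sequence
## come from summing pi_i * Q_ij over the appropriate ordered pairs, and are
## divided by synonymous/nonsynonymous site counts. Two site-count
## definitions are supported: physical sites (enumerate the single-nucleotide
## mutations of each codon, 1/3 site each) and mutational opportunity (weight
## sites by the probability of a synonymous/nonsynonymous mutation under the
## fitted mutation process with omega = 1). Mutations creating stop codons
## are excluded from both numerators and site counts: the substitution
## process lives on sense codons.

.classIsSyn <- function() {
  cls <- codonSubstitutionClasses()
  cls == "syn_ts" | cls == "syn_tv"
}

.classIsNonsyn <- function() {
  cls <- codonSubstitutionClasses()
  cls == "nonsyn_ts" | cls == "nonsyn_tv"
}

#' Expected numbers of synonymous and nonsynonymous substitutions
#'
#' Sums \eqn{t \, \pi_i Q_{ij}} over synonymous and over nonsynonymous
#' ordered codon pairs: the expected number of substitutions of each kind per
#' codon site over time `t` under the stationary process.
#'
#' @param q a [CodonRateMatrix-class].
#' @param t evolutionary time (>= 0).
#' @return named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
substitutionNumbers <- function(q, t) {
  if (t < 0) stop("t must be non-negative")
  flow <- q@pi * q@q  # pi_i * Q_ij
  c(syn = t * sum(flow[.classIsSyn()]),
    nonsyn = t * sum(flow[.classIsNonsyn()]))
}

#' Physical synonymous and nonsynonymous site counts
#'
#' For each sense codon, each of its 9 single-nucleotide mutations contributes
#' 1/3 of a site, classified as synonymous or nonsynonymous by comparing the
#' encoded amino acids; mutations to stop codons contribute nothing. Aggregate
#' counts are averages over codons weighted by the stationary frequencies.
#'
#' @param pi codon frequencies (length 61).
#' @return list with `perCodon` (data.frame `codon`, `S`, `N`) and the
#'   pi-weighted aggregates `S` and `N`.
#' @examples
#' ps <- physicalSiteCounts(rep(1 / 61, 61))
#' subset(ps$perCodon, codon == "GGG")  # 4-fold site: S = 1
#' @export
physicalSiteCounts <- function(pi) {
  pi <- .checkPi(pi)
  cls <- codonSubstitutionClasses()
  synN <- rowSums(cls == "syn_ts" | cls == "syn_tv") / 3
  nonsynN <- rowSums(cls == "nonsyn_ts" | cls == "nonsyn_tv") / 3
  list(perCodon = data.frame(codon = .codonStrings(), S = synN, N = nonsynN,
                             row.names = NULL),
       S = sum(pi * synN), N = sum(pi * nonsynN))
}

#' Mutational-opportunity site counts
#'
#' Weights each site by the probability that a mutation at it is synonymous
#' versus nonsynonymous under the fitted mutation process with selection
#' removed (omega = 1, fitted kappa): site counts proportional to
#' \eqn{\sum \pi_i Q^{neutral}_{ij}} over synonymous and nonsynonymous pairs.
#' Counts are invariant to the overall scaling of the neutral generator; the
#' total S + N is normalized to the physical-sites total (3 sites per codon
#' minus the stop-mutation fraction), so that with kappa = 1 and uniform
#' frequencies the two definitions coincide.
#'
#' @param kappa transition/transversion ratio of the fitted model at the RSA
#'   value of interest.
#' @param pi codon frequencies (length 61).
#' @return list with aggregates `S` and `N`.
#' @export
mutationalOpportunityCounts <- function(kappa, pi) {
  pi <- .checkPi(pi)
  qn <- gy94RateMatrix(omega = 1, kappa = kappa, pi = pi)
  flow <- qn@pi * qn@q
  sRaw <- sum(flow[.classIsSyn()])
  nRaw <- sum(flow[.classIsNonsyn()])
  ps <- physicalSiteCounts(pi)
  scale <- (ps$S + ps$N) / (sRaw + nRaw)
  list(S = scale * sRaw, N = scale * nRaw)
}

#' Per-bin dN and dS profile of a fitted model
#'
#' For each occupied RSA bin, computes the expected synonymous and
#' nonsynonymous substitution numbers under the fitted model and divides them
#' by synonymous/nonsynonymous site counts under both definitions. Under the
#' mutational-opportunity definition dN/dS reproduces the fitted
#' \eqn{\omega(r_k)} exactly; under the physical-sites definition dN and dS
#' can show different RSA trends when kappa varies with RSA.
#'
#' For MG94 fits the effective branch length is \eqn{\alpha(r_k)} and
#' \eqn{\omega(r_k) = \beta(r_k)/\alpha(r_k)}.
#'
#' @param fit a [CodonFit-class].
#' @param binning the binning to evaluate at; defaults to the fit's.
#' @return data.frame with one row per occupied bin: `bin`, `r`, `omega`,
#'   `dN_mut`, `dS_mut`, `dN_phys`, `dS_phys`.
#' @export
rateProfile <- function(fit, binning = fit@binning) {
  mids <- binMidpoints(binning)
  ev <- .evalParams(fit@spec, fit@estimates, mids)
  bins <- which(vapply(seq_along(mids), function(k)
    all(vapply(ev, function(v) is.finite(v[k]), NA)), NA))
  pi <- .checkPi(fit@pi)
  ps <- physicalSiteCounts(pi)
  rows <- lapply(bins, function(k) {
    if (fit@spec@family == "GY94") {
      omega <- ev$omega[k]; kappa <- ev$kappa[k]; tt <- ev$t[k]
    } else {
      kappa <- ev$kappa[k]; tt <- ev$alpha[k]; omega <- ev$beta[k] / ev$alpha[k]
    }
    q <- gy94RateMatrix(omega, kappa, pi, r = mids[k])
    en <- substitutionNumbers(q, tt)
    mo <- mutationalOpportunityCounts(kappa, pi)
    data.frame(bin = k, r = mids[k], omega = omega,
               dN_mut = en[["nonsyn"]] / mo$N, dS_mut = en[["syn"]] / mo$S,
               dN_phys = en[["nonsyn"]] / ps$N, dS_phys = en[["syn"]] / ps$S)
  })
  do.call(rbind, rows)
}
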