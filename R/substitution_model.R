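## RSA-dependent codon rate matrices. For a site with RSA r the generator has
## off-diagonal entries (i != j):
##
##   Q_ij = 0                     more than one nucleotide change
##        = Pi_j                  synonymous transversion
##        = kappa(r) Pi_j         synonymous transition
##        = omega(r) Pi_j         nonsynonymous transversion
##        = kappa(r) omega(r) Pi_j  nonsynonymous transition
##
## and the finite-time transition matrix is P = exp[t(r) Q]. There is NO
## per-bin rescaling of Q to one expected substitution per unit time: t is in
## the arbitrary units implied by the unit synonymous-transversion baseline,
## and is itself a fitted function of r.

#' F3x4 codon frequencies from a pairwise alignment
#'
#' Estimates codon frequencies as the product of empirical nucleotide
#' frequencies at the three codon positions, counted over all ungapped,
#' unambiguous codons of both sequences, then restricted to the 61 sense
#' codons and renormalized to sum to one. Frequencies are estimated once from
#' the whole alignment, treated as fixed during optimization, and not counted
#' as free parameters.
#'
#' @param alignment a pairwise codon alignment: a `DNAStringSet` (or character
#'   vector) of two aligned sequences of equal length divisible by 3.
#' @return named numeric vector of 61 codon frequencies in [senseCodons()]
#'   order.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ATGAAA", b = "ATGAAG"))
#' codonFrequenciesF3x4(aln)["ATG"]
#' @export
codonFrequenciesF3x4 <- function(alignment) {
  codons <- .alignmentCodons(alignment)
  cc <- c(codons[, 1L], codons[, 2L])
  cc <- cc[!is.na(cc)]
  keep <- grepl("^[ACGT]{3}$", cc)
  cc <- cc[keep]
  if (length(cc) == 0L)
    stop("alignment contains no ungapped, unambiguous codons")
  nuc <- c("A", "C", "G", "T")
  f <- vapply(1:3, function(p) {
    tab <- table(factor(substr(cc, p, p), levels = nuc))
    as.numeric(tab) / length(cc)
  }, numeric(4L))
  rownames(f) <- nuc
  sense <- .codonStrings()
  pi <- f[substr(sense, 1L, 1L), 1L] *
        f[substr(sense, 2L, 2L), 2L] *
        f[substr(sense, 3L, 3L), 3L]
  pi <- pi / sum(pi)  # strip stop-codon mass
  stats::setNames(pi, sense)
}

.checkPi <- function(pi) {
  if (length(pi) != 61L) stop("pi must have 61 entries (sense codons)")
  if (any(pi < 0)) stop("pi entries must be non-negative")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (is.null(names(pi))) names(pi) <- .codonStrings()
  pi
}

## shared builder: off-diagonal multiplier per substitution class, times Pi_j
.buildQ <- function(mult, pi, r) {
  cls <- codonSubstitutionClasses()
  m <- matrix(0, 61L, 61L, dimnames = dimnames(cls))
  for (k in names(mult))
    m[cls == k] <- mult[[k]]
  q <- m * rep(pi, each = 61L)  # column j scaled by Pi_j
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  methods::new("CodonRateMatrix", q = q, pi = unname(pi), r = r)
}

#' GY94 rate matrix at a given RSA value
#'
#' Builds the Goldman-Yang generator with target-codon-frequency factors:
#' synonymous transversions occur at the baseline rate \eqn{\Pi_j},
#' transitions are scaled by `kappa`, nonsynonymous changes by `omega`, and
#' codon pairs differing at more than one position have rate zero.
#'
#' @param omega nonsynonymous/synonymous rate ratio, > 0.
#' @param kappa transition/transversion rate ratio, > 0.
#' @param pi codon frequencies (length 61, [senseCodons()] order).
#' @param r RSA value (bin mid-point) the matrix is built at; bookkeeping
#'   only.
#' @return a [CodonRateMatrix-class] object.
#' @examples
#' q <- gy94RateMatrix(0.1, 3, rep(1 / 61, 61))
#' rateMatrix(q)["TTA", "CTA"]  # kappa * pi: synonymous transition
#' @export
gy94RateMatrix <- function(omega, kappa, pi, r = NA_real_) {
  if (!is.finite(omega) || omega <= 0) stop("omega must be > 0")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  pi <- .checkPi(pi)
  .buildQ(list(syn_tv = 1, syn_ts = kappa,
               nonsyn_tv = omega, nonsyn_ts = kappa * omega), pi, r)
}

#' MG94 rate matrix at a given RSA value
#'
#' Builds the Muse-Gaut-style generator in which the synonymous rate `alpha`
#' and the nonsynonymous rate `beta` are separate parameters: synonymous
#' changes occur at rate \eqn{\alpha \Pi_j}, nonsynonymous at
#' \eqn{\beta \Pi_j}, transitions additionally scaled by `kappa`. The
#' normative definition is the correspondence `alpha = t`, `beta = t * omega`:
#' with those values the unit-time transition matrix of this generator equals
#' `transitionMatrix(gy94RateMatrix(omega, kappa, pi), t)`. In particular,
#' `alpha == beta` reduces to GY94 with `omega = 1`.
#'
#' @param alpha synonymous rate, > 0.
#' @param beta nonsynonymous rate, > 0.
#' @param kappa transition/transversion rate ratio, > 0.
#' @param pi codon frequencies (length 61).
#' @param r RSA value the matrix is built at; bookkeeping only.
#' @return a [CodonRateMatrix-class] object.
#' @export
mg94RateMatrix <- function(alpha, beta, kappa, pi, r = NA_real_) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  pi <- .checkPi(pi)
  .buildQ(list(syn_tv = alpha, syn_ts = alpha * kappa,
               nonsyn_tv = beta, nonsyn_ts = beta * kappa), pi, r)
}

#' Extract the generator matrix
#'
#' @param q a [CodonRateMatrix-class] object.
#' @return the 61 x 61 numeric generator.
#' @export
rateMatrix <- function(q) q@q

#' Stationary frequencies of a rate matrix
#'
#' @param q a [CodonRateMatrix-class] object.
#' @return named numeric vector of 61 frequencies.
#' @export
stationaryFrequencies <- function(q) stats::setNames(q@pi, .codonStrings())

setMethod("show", "CodonRateMatrix", function(object) {
  cat("CodonRateMatrix: 61 x 61 generator",
      if (!is.na(object@r)) paste0("at r = ", format(object@r)) else "",
      "\n  total rate -sum(pi * diag(Q)) =",
      format(-sum(object@pi * diag(object@q))), "\n")
})

## Eigendecomposition of the symmetrized generator, reused across times t.
## S = D Q D^-1 with D = diag(sqrt(pi)) is symmetric because Q is reversible
## with respect to pi. Zero-frequency codons are isolated absorbing states.
.qEigen <- function(q, pi) {
  ok <- pi > 0
  d <- sqrt(pi[ok])
  s <- q[ok, ok, drop = FALSE] * (d / rep(d, each = sum(ok)))
  s <- (s + t(s)) / 2  # kill round-off asymmetry
  e <- eigen(s, symmetric = TRUE)
  list(ok = ok, d = d, values = e$values, vectors = e$vectors)
}

.pFromEigen <- function(ed, t) {
  n <- length(ed$d)
  w <- ed$vectors * rep(exp(t * ed$values), each = n)
  ps <- tcrossprod(w, ed$vectors)
  p <- ps * (rep(ed$d, each = n) / ed$d)  # D^-1 [.] D undoes the symmetrization
  if (all(ed$ok)) {
    full <- p
  } else {
    full <- diag(61L)
    full[ed$ok, ed$ok] <- p
  }
  full[full < 0] <- 0  # clamp round-off negatives
  dimnames(full) <- list(.codonStrings(), .codonStrings())
  full
}

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "CodonRateMatrix", function(q, t) {
  if (!is.finite(t) || t < 0) stop("t must be a non-negative number")
  .pFromEigen(.qEigen(q@q, q@pi), t)
})
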