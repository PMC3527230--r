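#' Number of RSA bins
#'
#' @param x an [RsaBinning-class], [ModelSpec-class] or [BinnedPairData-class]
#'   object.
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bin mid-points \eqn{r_k}
#'
#' @param x an [RsaBinning-class] object.
#' @return numeric vector of mid-points.
#' @export
setGeneric("binMidpoints", function(x) standardGeneric("binMidpoints"))

#' Bin edges
#'
#' @param x an [RsaBinning-class] object.
#' @return numeric vector of `nBins(x) + 1` edges.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' Free-parameter count of a model specification
#'
#' Counts the degrees of freedom of a model parameterization: 1 for each
#' constant form, 2 (intercept and slope) for each linear form, and one value
#' per RSA bin for each per-bin form. Codon frequencies are treated as fixed
#' empirical quantities and are not counted.
#'
#' @param spec a [ModelSpec-class] or [GroupedCodonSpec-class] object.
#' @return integer degrees of freedom.
#' @examples
#' modelDf(modelSpec("GY94", omega = "linear", t = "linear",
#'                   kappa = "per-bin", nBins = 20))  # 24
#' @export
setGeneric("modelDf", function(spec) standardGeneric("modelDf"))

#' Finite-time transition probability matrix
#'
#' Computes \eqn{P = \exp(t Q)} for a codon rate matrix. Because Q is
#' reversible with respect to its stationary frequencies, the exponential is
#' evaluated through the symmetric similarity transform
#' \eqn{S = \Pi^{1/2} Q \Pi^{-1/2}} and an eigendecomposition of S.
#'
#' @param q a [CodonRateMatrix-class] object.
#' @param t non-negative evolutionary time (branch length, arbitrary units).
#' @return a 61 x 61 row-stochastic matrix in sense-codon order.
#' @examples
#' pi <- rep(1 / 61, 61)
#' q <- gy94RateMatrix(omega = 0.2, kappa = 2, pi = pi)
#' p <- transitionMatrix(q, t = 0.5)
#' range(rowSums(p))  # 1
#' @export
setGeneric("transitionMatrix", function(q, t) standardGeneric("transitionMatrix"))

#' Codon pair counts per bin
#'
#' @param x a [BinnedPairData-class] object.
#' @return list of per-bin count matrices.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Number of codon sites used in the likelihood
#'
#' @param x a [BinnedPairData-class] or [CodonFit-class] object.
#' @return integer.
#' @export
setGeneric("sitesUsed", function(x) standardGeneric("sitesUsed"))

#' Fitted parameter estimates
#'
#' @param x a [CodonFit-class] or [GroupedCodonFit-class] object.
#' @return named list of fitted values (see [CodonFit-class]).
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
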