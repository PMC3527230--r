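.PARAM_FORMS <- c("constant", "linear", "per-bin")
.GY94_PARAMS <- c("omega", "t", "kappa")
.MG94_PARAMS <- c("alpha", "beta", "kappa")

#' RsaBinning: an even discretization of relative solvent accessibility
#'
#' Represents `n` evenly spaced bins on \[0, 1\]. Every RSA value within a bin
#' is represented by the bin mid-point \eqn{r_k}, so a rate matrix that
#' depends continuously on RSA is approximated by `n` discrete matrices
#' \eqn{Q_k = Q(r_k)}.
#'
#' @slot n integer, number of bins (>= 2).
#' @slot edges numeric of length `n + 1`, strictly increasing from 0 to 1.
#' @slot midpoints numeric of length `n`, bin mid-points \eqn{r_k}.
#'
#' @seealso [rsaBinning()], [assignBins()]
#' @export
setClass("RsaBinning",
  representation(n = "integer", edges = "numeric", midpoints = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
      msg <- c(msg, "n must be a single integer >= 2")
    else {
      if (length(object@edges) != object@n + 1L)
        msg <- c(msg, "edges must have length n + 1")
      if (any(diff(object@edges) <= 0))
        msg <- c(msg, "edges must be strictly increasing")
      if (!isTRUE(all.equal(object@edges[1L], 0)) ||
          !isTRUE(all.equal(object@edges[length(object@edges)], 1)))
        msg <- c(msg, "edges must span [0, 1]")
      if (length(object@midpoints) != object@n ||
          any(object@midpoints <= 0) || any(object@midpoints >= 1))
        msg <- c(msg, "midpoints must lie strictly inside (0, 1)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ModelSpec: a parameterization of the RSA-dependent codon model
#'
#' Names the model family and, for each family parameter, the functional form
#' of its RSA dependency. GY94 is parameterized by the nonsynonymous/synonymous
#' rate ratio `omega`, the branch length `t`, and the transition/transversion
#' ratio `kappa`; MG94 by the synonymous rate `alpha`, the nonsynonymous rate
#' `beta`, and `kappa`. Each parameter's form is one of `"constant"` (one
#' RSA-independent value), `"linear"` (intercept + slope in RSA), or
#' `"per-bin"` (one free value per RSA bin).
#'
#' @slot family `"GY94"` or `"MG94"`.
#' @slot forms named character vector of forms, named by the family's
#'   parameters.
#' @slot nBins integer, number of RSA bins the per-bin forms refer to.
#'
#' @seealso [modelSpec()], [enumerateModelSpecs()], [modelDf()]
#' @export
setClass("ModelSpec",
  representation(family = "character", forms = "character", nBins = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@family) != 1L || !object@family %in% c("GY94", "MG94"))
      msg <- c(msg, "family must be \"GY94\" or \"MG94\"")
    want <- if (identical(object@family, "MG94")) .MG94_PARAMS else .GY94_PARAMS
    if (!identical(names(object@forms), want))
      msg <- c(msg, paste0("forms must be named ",
                           paste(want, collapse = ", ")))
    if (!all(object@forms %in% .PARAM_FORMS))
      msg <- c(msg, "each form must be constant, linear or per-bin")
    if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 2L)
      msg <- c(msg, "nBins must be a single integer >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' CodonRateMatrix: an infinitesimal generator over the 61 sense codons
#'
#' The 61 x 61 generator Q of the codon substitution Markov process, together
#' with the stationary codon frequencies it is reversible against and the RSA
#' value (bin mid-point) it was built at. Off-diagonal entries are zero for
#' codon pairs differing at more than one nucleotide position; rows sum to
#' zero.
#'
#' @slot q 61 x 61 numeric matrix in lexicographic sense-codon order.
#' @slot pi numeric of length 61, stationary codon frequencies (sum 1).
#' @slot r numeric, the RSA value the matrix was built at (`NA` if not tied
#'   to a bin).
#'
#' @seealso [gy94RateMatrix()], [mg94RateMatrix()], [transitionMatrix()]
#' @export
setClass("CodonRateMatrix",
  representation(q = "matrix", pi = "numeric", r = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@q), c(61L, 61L)))
      msg <- c(msg, "q must be 61 x 61")
    if (length(object@pi) != 61L || any(object@pi < 0))
      msg <- c(msg, "pi must be 61 non-negative frequencies")
    else if (abs(sum(object@pi) - 1) > 1e-8)
      msg <- c(msg, "pi must sum to 1")
    off <- object@q; diag(off) <- 0
    if (any(off < -1e-12))
      msg <- c(msg, "off-diagonal rates must be non-negative")
    if (any(abs(rowSums(object@q)) > 1e-8))
      msg <- c(msg, "rows of q must sum to zero")
    if (is.null(msg)) TRUE else msg
  })

#' BinnedPairData: per-bin sufficient statistics of a pairwise alignment
#'
#' The likelihood of a pairwise codon alignment under the RSA-dependent model
#' depends on the data only through, for each RSA bin, the counts of ordered
#' sense-codon pairs (sequence-1 codon, sequence-2 codon) observed at sites
#' assigned to that bin. Sites with gaps or ambiguous nucleotides in either
#' sequence are excluded and counted in `nExcluded`.
#'
#' @slot nBins integer, number of RSA bins.
#' @slot counts list of length `nBins`; element k is a 3-column integer matrix
#'   (`i`, `j`, `count`) of codon-index pairs observed in bin k.
#' @slot nSitesUsed integer, total number of scored sites.
#' @slot nExcluded integer, number of sites dropped (gap/ambiguity/no RSA).
#'
#' @seealso [binPairCounts()], [codonLogLik()], [fitCodonModel()]
#' @export
setClass("BinnedPairData",
  representation(nBins = "integer", counts = "list",
                 nSitesUsed = "integer", nExcluded = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != object@nBins)
      msg <- c(msg, "counts must have one entry per bin")
    tot <- 0L
    for (m in object@counts) {
      if (!is.matrix(m) || ncol(m) != 3L)
        return("each counts entry must be a 3-column matrix (i, j, count)")
      if (nrow(m) > 0L) {
        if (any(m[, 3L] < 0) || any(m[, 1:2] < 1L) || any(m[, 1:2] > 61L))
          msg <- c(msg, "counts out of range")
        tot <- tot + sum(m[, 3L])
      }
    }
    if (length(object@nSitesUsed) == 1L && tot != object@nSitesUsed)
      msg <- c(msg, "nSitesUsed must equal the total count")
    if (is.null(msg)) TRUE else msg
  })

#' CodonFit: a fitted RSA-dependent codon model
#'
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot estimates named list of fitted parameter values; one numeric value
#'   for a constant form, `c(intercept, slope)` for a linear form, and one
#'   value per bin (NA for unoccupied bins) for a per-bin form.
#' @slot logLik maximized log-likelihood.
#' @slot df number of free parameters (codon frequencies excluded).
#' @slot aic Akaike information criterion, `2 * df - 2 * logLik`.
#' @slot converged logical, whether the best optimizer start converged.
#' @slot nSitesUsed number of codon sites entering the likelihood.
#' @slot pi codon frequencies the model was conditioned on.
#' @slot binning the [RsaBinning-class] used.
#'
#' @seealso [fitCodonModel()], [rankModels()], [lrTest()], [rateProfile()]
#' @export
setClass("CodonFit",
  representation(spec = "ModelSpec", estimates = "list", logLik = "numeric",
                 df = "integer", aic = "numeric", converged = "logical",
                 nSitesUsed = "integer", pi = "numeric",
                 binning = "RsaBinning"),
  validity = function(object) {
    if (abs(object@aic - (2 * object@df - 2 * object@logLik)) > 1e-6)
      "aic must equal 2 * df - 2 * logLik" else TRUE
  })

#' GroupedCodonSpec: a joint model over several gene groups with tied
#' parameters
#'
#' Describes a joint GY94 fit across groups of genes (e.g. large-core vs
#' small-core proteins, or high- vs low-expression genes): one shared
#' \eqn{\kappa(r)} and one shared \eqn{t(r)} across all groups, and a linear
#' \eqn{\omega(r) = \omega_0 + \omega_1 r} per group whose intercept and slope
#' may each be tied across groups. Ties are expressed as a mapping from group
#' label to tie class: groups sharing a class share the parameter.
#'
#' @slot tForm form of the shared branch length (`"constant"`, `"linear"`,
#'   `"per-bin"`).
#' @slot kappaForm form of the shared transition/transversion ratio.
#' @slot interceptTies named character; names are group labels, values are
#'   tie-class labels for \eqn{\omega_0}.
#' @slot slopeTies named character; tie-class labels for \eqn{\omega_1}.
#' @slot nBins integer, number of RSA bins.
#'
#' @seealso [groupedCodonSpec()], [fitGroupedModel()]
#' @export
setClass("GroupedCodonSpec",
  representation(tForm = "character", kappaForm = "character",
                 interceptTies = "character", slopeTies = "character",
                 nBins = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@tForm %in% .PARAM_FORMS || !object@kappaForm %in% .PARAM_FORMS)
      msg <- c(msg, "tForm and kappaForm must be constant, linear or per-bin")
    if (is.null(names(object@interceptTies)) ||
        is.null(names(object@slopeTies)) ||
        !identical(sort(names(object@interceptTies)),
                   sort(names(object@slopeTies))))
      msg <- c(msg, "interceptTies and slopeTies must be named by the same groups")
    if (length(object@interceptTies) < 2L)
      msg <- c(msg, "need at least two groups")
    if (length(object@nBins) != 1L || object@nBins < 2L)
      msg <- c(msg, "nBins must be >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' GroupedCodonFit: a fitted joint model over gene groups
#'
#' @slot spec the [GroupedCodonSpec-class] that was fitted.
#' @slot omegaIntercepts named numeric, fitted \eqn{\omega_0} per tie class.
#' @slot omegaSlopes named numeric, fitted \eqn{\omega_1} per tie class.
#' @slot shared named list with the fitted shared `t` and `kappa` values.
#' @slot logLik joint maximized log-likelihood over all groups.
#' @slot df total free-parameter count.
#' @slot aic `2 * df - 2 * logLik`.
#' @slot converged logical.
#' @slot pi codon frequencies used.
#' @slot binning the [RsaBinning-class] used.
#'
#' @seealso [fitGroupedModel()]
#' @export
setClass("GroupedCodonFit",
  representation(spec = "GroupedCodonSpec", omegaIntercepts = "numeric",
                 omegaSlopes = "numeric", shared = "list", logLik = "numeric",
                 df = "integer", aic = "numeric", converged = "logical",
                 pi = "numeric", binning = "RsaBinning"))
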