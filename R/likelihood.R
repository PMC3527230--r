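## Pairwise binned likelihood. Under reversibility the two-sequence likelihood
## with an unobserved root reduces (pulley principle) to a stationary root at
## one tip: a site in bin k with codons (i, j) contributes
## log(pi_i * P_k[i, j]) with P_k = exp[t(r_k) Q(r_k)]. Sites are independent,
## so the data enter only through per-bin counts of ordered codon pairs.

.OMEGA_START <- 0.2
.KAPPA_START <- 2.0
.T_START <- 0.3
.PARAM_LOWER <- 1e-6
.PARAM_UPPER <- c(omega = 100, t = 50, kappa = 500, alpha = 50, beta = 50)
.SLOPE_BOUND <- 100

#' Tabulate per-bin codon pair counts from an alignment
#'
#' Converts a pairwise codon alignment plus per-site RSA values into the
#' sufficient statistics of the binned likelihood: for each RSA bin, counts of
#' ordered sense-codon pairs. Sites without an RSA value, or whose codon in
#' either sequence contains a gap or non-ACGT character, are excluded and
#' tallied in `nExcluded`.
#'
#' @param alignment a `DNAStringSet` (or character vector) of two aligned
#'   sequences, length divisible by 3.
#' @param siteRsa data.frame with columns `site` (1-based codon position) and
#'   `rsa` (in \[0, 1\]).
#' @param binning an [RsaBinning-class] object.
#' @return a [BinnedPairData-class] object.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ATGAAATTA", b = "ATGAAGCTA"))
#' rsa <- data.frame(site = 1:3, rsa = c(0.02, 0.40, 0.95))
#' binPairCounts(aln, rsa, rsaBinning(5))
#' @export
binPairCounts <- function(alignment, siteRsa, binning) {
  codons <- .alignmentCodons(alignment)
  if (max(siteRsa$site) > nrow(codons))
    stop("site index ", max(siteRsa$site), " beyond alignment length (",
         nrow(codons), " codons)")
  sense <- .codonStrings()
  i <- match(codons[siteRsa$site, 1L], sense)
  j <- match(codons[siteRsa$site, 2L], sense)
  ok <- !is.na(i) & !is.na(j)
  bins <- assignBins(siteRsa$rsa, binning)
  n <- nBins(binning)
  counts <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- ok & bins == k
    if (!any(sel)) {
      counts[[k]] <- matrix(integer(0), 0L, 3L,
                            dimnames = list(NULL, c("i", "j", "count")))
    } else {
      tab <- table(i = i[sel], j = j[sel])
      idx <- which(tab > 0, arr.ind = TRUE)
      counts[[k]] <- cbind(i = as.integer(rownames(tab))[idx[, 1L]],
                           j = as.integer(colnames(tab))[idx[, 2L]],
                           count = as.integer(tab[idx]))
    }
  }
  methods::new("BinnedPairData", nBins = n, counts = counts,
               nSitesUsed = sum(ok), nExcluded = sum(!ok))
}

#' @describeIn binPairCounts number of bins of the count table.
#' @param x a [BinnedPairData-class] object.
#' @export
setMethod("nBins", "BinnedPairData", function(x) x@nBins)

#' @rdname binPairCounts
#' @export
setMethod("binCounts", "BinnedPairData", function(x) x@counts)

#' @rdname binPairCounts
#' @export
setMethod("sitesUsed", "BinnedPairData", function(x) x@nSitesUsed)

setMethod("show", "BinnedPairData", function(object) {
  occ <- sum(vapply(object@counts, nrow, 0L) > 0L)
  cat("BinnedPairData:", object@nSitesUsed, "sites in", occ, "of",
      object@nBins, "bins (", object@nExcluded, "excluded )\n")
})

.occupiedBins <- function(data) which(vapply(data@counts, nrow, 0L) > 0L)

## Evaluate a parameter's functional form at the bin mid-points.
## values: constant -> 1 value; linear -> c(intercept, slope);
## per-bin -> nBins values (NA allowed at unoccupied bins).
.evalForm <- function(form, values, midpoints) {
  switch(form,
    constant = rep(values[[1L]], length(midpoints)),
    linear = values[[1L]] + values[[2L]] * midpoints,
    `per-bin` = values,
    stop("unknown form: ", form))
}

.evalParams <- function(spec, params, midpoints) {
  out <- lapply(names(spec@forms), function(p)
    .evalForm(spec@forms[[p]], params[[p]], midpoints))
  names(out) <- names(spec@forms)
  out
}

## Per-bin transition matrices. GY94 shares the eigendecomposition across
## bins with equal (omega, kappa), so constant-omega/kappa models cost one
## eigendecomposition per evaluation regardless of the bin count.
.binTransitionMatrices <- function(family, ev, pi, bins, midpoints) {
  ps <- vector("list", length(bins))
  if (family == "GY94") {
    key <- paste(ev$omega[bins], ev$kappa[bins])
    for (u in unique(key)) {
      sel <- which(key == u)
      b1 <- bins[sel[1L]]
      q <- gy94RateMatrix(ev$omega[b1], ev$kappa[b1], pi, r = midpoints[b1])
      ed <- .qEigen(q@q, q@pi)
      for (s in sel) ps[[s]] <- .pFromEigen(ed, ev$t[bins[s]])
    }
  } else {
    key <- paste(ev$alpha[bins], ev$beta[bins], ev$kappa[bins])
    for (u in unique(key)) {
      sel <- which(key == u)
      b1 <- bins[sel[1L]]
      q <- mg94RateMatrix(ev$alpha[b1], ev$beta[b1], ev$kappa[b1], pi,
                          r = midpoints[b1])
      p <- .pFromEigen(.qEigen(q@q, q@pi), 1)
      for (s in sel) ps[[s]] <- p
    }
  }
  ps
}

#' Log-likelihood of binned pair data under a model specification
#'
#' Evaluates \eqn{\ell = \sum_k \sum_{i,j} c_k(i,j) \log(\pi_i P_k[i,j])}
#' with \eqn{P_k = \exp[t(r_k) Q(r_k)]} for GY94 and the unit-time transition
#' matrix of the (alpha, beta, kappa) generator for MG94. Every evaluated
#' parameter must be strictly positive at each occupied bin mid-point.
#'
#' @param spec a [ModelSpec-class].
#' @param params named list of parameter values matching the spec's forms
#'   (see [CodonFit-class] for the layout).
#' @param data a [BinnedPairData-class].
#' @param pi codon frequencies (length 61).
#' @param binning the [RsaBinning-class]; defaults to an even binning with
#'   `nBins(data)` bins.
#' @return the log-likelihood (a single number).
#' @export
codonLogLik <- function(spec, params, data, pi,
                        binning = rsaBinning(nBins(data))) {
  stopifnot(nBins(data) == spec@nBins, nBins(binning) == spec@nBins)
  pi <- .checkPi(pi)
  mids <- binMidpoints(binning)
  bins <- .occupiedBins(data)
  ev <- .evalParams(spec, params, mids)
  for (p in names(ev)) {
    v <- ev[[p]][bins]
    if (any(!is.finite(v)) || any(v <= 0))
      stop("parameter ", p, " is not strictly positive at every occupied ",
           "bin mid-point")
  }
  ps <- .binTransitionMatrices(spec@family, ev, pi, bins, mids)
  ll <- 0
  for (s in seq_along(bins)) {
    cm <- data@counts[[bins[s]]]
    ll <- ll + sum(cm[, 3L] *
                     log(pi[cm[, 1L]] * ps[[s]][cm[, c(1L, 2L), drop = FALSE]]))
  }
  ll
}

## ---- optimizer plumbing ----------------------------------------------------

## Describe the free-parameter vector for a spec: slices, bounds, starts.
.paramLayout <- function(spec, occupied) {
  starts <- c(omega = .OMEGA_START, t = .T_START, kappa = .KAPPA_START,
              alpha = .T_START, beta = .T_START * .OMEGA_START)
  layout <- list(); lower <- c(); upper <- c(); start <- c()
  pos <- 0L
  for (p in names(spec@forms)) {
    form <- spec@forms[[p]]
    base <- starts[[p]]; up <- .PARAM_UPPER[[p]]
    if (form == "constant") {
      idx <- pos + 1L
      lower <- c(lower, .PARAM_LOWER); upper <- c(upper, up)
      start <- c(start, base)
    } else if (form == "linear") {
      idx <- pos + 1:2
      lower <- c(lower, .PARAM_LOWER, -.SLOPE_BOUND)
      upper <- c(upper, up, .SLOPE_BOUND)
      start <- c(start, base, 0)
    } else {
      idx <- pos + seq_along(occupied)
      lower <- c(lower, rep(.PARAM_LOWER, length(occupied)))
      upper <- c(upper, rep(up, length(occupied)))
      start <- c(start, rep(base, length(occupied)))
    }
    pos <- pos + length(idx)
    layout[[p]] <- list(form = form, idx = idx)
  }
  list(layout = layout, lower = lower, upper = upper, start = start,
       occupied = occupied, npar = pos)
}

.unpackParams <- function(spec, lay, par) {
  out <- list()
  for (p in names(lay$layout)) {
    sl <- lay$layout[[p]]
    if (sl$form == "per-bin") {
      v <- rep(NA_real_, spec@nBins)
      v[lay$occupied] <- par[sl$idx]
      out[[p]] <- v
    } else {
      out[[p]] <- par[sl$idx]
    }
  }
  out
}

.negLogLik <- function(par, spec, lay, data, pi, mids, bins) {
  params <- .unpackParams(spec, lay, par)
  ev <- .evalParams(spec, params, mids)
  viol <- 0
  for (p in names(ev))
    viol <- viol + sum(pmax(0, .PARAM_LOWER - ev[[p]][bins]))
  if (viol > 0)
    return(1e9 * (1 + viol))  # smooth pull-back into the feasible region
  ps <- .binTransitionMatrices(spec@family, ev, pi, bins, mids)
  ll <- 0
  for (s in seq_along(bins)) {
    cm <- data@counts[[bins[s]]]
    pvals <- pi[cm[, 1L]] * ps[[s]][cm[, c(1L, 2L), drop = FALSE]]
    ll <- ll + sum(cm[, 3L] * log(pmax(pvals, 1e-300)))
  }
  -ll
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit an RSA-dependent codon model by maximum likelihood
#'
#' Maximizes the binned pairwise log-likelihood over the free parameters of a
#' [ModelSpec-class] with bounded quasi-Newton optimization (L-BFGS-B) and
#' multiple seeded restarts; the best start is kept. Per-bin parameters are
#' fitted only in occupied bins (unoccupied bins get `NA`), although the
#' degrees of freedom of the spec count all `nBins` values. Starting values
#' are omega = 0.2, kappa = 2, t = 0.3 (slopes 0), jittered by up to +/- 50%
#' in restarts.
#'
#' @param spec a [ModelSpec-class].
#' @param data a [BinnedPairData-class].
#' @param pi codon frequencies (length 61), e.g. from
#'   [codonFrequenciesF3x4()].
#' @param binning the [RsaBinning-class] (defaults to even bins matching the
#'   data).
#' @param control list of optimizer settings: `nStarts` (default 5), `seed`
#'   (default 1, drives the restart jitter), `maxit` (default 500), `factr`
#'   (L-BFGS-B convergence factor, default 1e7), and `start` (named list of
#'   parameter values used as the first, unjittered start — e.g. a simpler
#'   model's estimates when fitting a nested pair).
#' @return a [CodonFit-class] object.
#' @examples
#' \donttest{
#' binning <- rsaBinning(4)
#' sim <- simulateCodonPair(2000, modelSpec("GY94", nBins = 4),
#'                          list(omega = 0.2, t = 0.5, kappa = 2),
#'                          binning = binning, seed = 7)
#' data <- binPairCounts(sim$alignment, sim$siteRsa, binning)
#' fitCodonModel(modelSpec("GY94", nBins = 4), data,
#'               codonFrequenciesF3x4(sim$alignment), binning)
#' }
#' @export
fitCodonModel <- function(spec, data, pi, binning = rsaBinning(spec@nBins),
                          control = list()) {
  stopifnot(methods::is(spec, "ModelSpec"), methods::is(data, "BinnedPairData"))
  if (data@nSitesUsed == 0L) stop("no usable sites in the data")
  pi <- .checkPi(pi)
  nStarts <- control$nStarts %||% 5L
  seed <- control$seed %||% 1L
  maxit <- control$maxit %||% 500L
  factr <- control$factr %||% 1e7
  mids <- binMidpoints(binning)
  bins <- .occupiedBins(data)
  lay <- .paramLayout(spec, bins)
  if (!is.null(control$start)) {
    for (p in names(control$start)) {
      sl <- lay$layout[[p]]
      if (is.null(sl)) next
      v <- control$start[[p]]
      if (sl$form == "per-bin") v <- v[bins]
      v <- v[is.finite(v)]
      if (sl$form == "linear" && length(v) == 1L) v <- c(v, 0)
      v <- rep_len(v, length(sl$idx))
      lay$start[sl$idx] <- pmin(pmax(v, lay$lower[sl$idx]),
                                lay$upper[sl$idx])
    }
  }

  startMatrix <- .withSeed(seed, {
    m <- matrix(rep(lay$start, nStarts), ncol = nStarts)
    if (nStarts > 1L) {
      for (s in 2:nStarts) {
        jit <- stats::runif(lay$npar, 0.5, 1.5)
        m[, s] <- ifelse(lay$start > 0, lay$start * jit,
                         stats::runif(lay$npar, -0.25, 0.25))
      }
    }
    m
  })

  best <- NULL
  for (s in seq_len(nStarts)) {
    opt <- try(stats::optim(startMatrix[, s], .negLogLik, method = "L-BFGS-B",
                            lower = lay$lower, upper = lay$upper,
                            control = list(maxit = maxit, factr = factr),
                            spec = spec, lay = lay, data = data, pi = pi,
                            mids = mids, bins = bins), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all ", nStarts, " optimizer starts failed for spec ",
         paste(spec@forms, collapse = "/"))
  df <- modelDf(spec)
  lnL <- -best$value
  methods::new("CodonFit", spec = spec,
               estimates = .unpackParams(spec, lay, best$par),
               logLik = lnL, df = df, aic = 2 * df - 2 * lnL,
               converged = best$convergence == 0L,
               nSitesUsed = data@nSitesUsed, pi = unname(pi),
               binning = binning)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fitCodonModel
#' @param x a [CodonFit-class] object.
#' @export
setMethod("estimates", "CodonFit", function(x) x@estimates)

#' @rdname fitCodonModel
#' @export
setMethod("sitesUsed", "CodonFit", function(x) x@nSitesUsed)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "CodonFit", function(object, ...) {
  structure(object@logLik, df = object@df, class = "logLik")
})

setMethod("show", "CodonFit", function(object) {
  cat("CodonFit [", object@spec@family, "] ",
      paste(names(object@spec@forms), object@spec@forms, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  lnL =", format(object@logLik, nsmall = 2),
      " df =", object@df, " AIC =", format(object@aic, nsmall = 2),
      if (!object@converged) " (NOT converged)" else "", "\n")
  for (p in names(object@estimates)) {
    v <- object@estimates[[p]]
    if (length(v) <= 2L)
      cat("  ", p, ": ", paste(signif(v, 4), collapse = ", "), "\n", sep = "")
    else
      cat("  ", p, ": per-bin, range ",
          paste(signif(range(v, na.rm = TRUE), 4), collapse = " .. "),
          "\n", sep = "")
  }
})
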