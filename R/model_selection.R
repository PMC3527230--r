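## Enumeration and comparison of the 27 GY94 parameterizations (each of
## omega, t, kappa constant, linear, or per-bin), AIC ranking, likelihood
## ratio tests for nested pairs, and joint fits across gene groups with
## parameters tied between groups.

#' Create a model specification
#'
#' @param family `"GY94"` (parameters `omega`, `t`, `kappa`) or `"MG94"`
#'   (parameters `alpha`, `beta`, `kappa`).
#' @param omega,t,kappa,alpha,beta functional form of each parameter's RSA
#'   dependency: `"constant"`, `"linear"`, or `"per-bin"`.
#' @param nBins number of RSA bins (default 20).
#' @return a [ModelSpec-class] object.
#' @examples
#' modelSpec("GY94", omega = "linear", t = "linear", kappa = "per-bin")
#' modelSpec("MG94", alpha = "linear", beta = "linear", kappa = "per-bin")
#' @export
modelSpec <- function(family = c("GY94", "MG94"),
                      omega = "constant", t = "constant", kappa = "constant",
                      alpha = "constant", beta = "constant", nBins = 20L) {
  family <- match.arg(family)
  forms <- if (family == "GY94") c(omega = omega, t = t, kappa = kappa)
           else c(alpha = alpha, beta = beta, kappa = kappa)
  methods::new("ModelSpec", family = family, forms = forms,
               nBins = as.integer(nBins))
}

#' @describeIn modelSpec number of bins the spec refers to.
#' @param x a [ModelSpec-class] object.
#' @export
setMethod("nBins", "ModelSpec", function(x) x@nBins)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec [", object@family, "] ",
      paste(names(object@forms), object@forms, sep = "=", collapse = ", "),
      " (", object@nBins, " bins)\n", sep = "")
})

.formDf <- function(form, nBins)
  switch(form, constant = 1L, linear = 2L, `per-bin` = as.integer(nBins))

#' @rdname modelDf
#' @export
setMethod("modelDf", "ModelSpec", function(spec) {
  sum(vapply(spec@forms, .formDf, 0L, nBins = spec@nBins))
})

#' @rdname modelDf
#' @export
setMethod("modelDf", "GroupedCodonSpec", function(spec) {
  .formDf(spec@tForm, spec@nBins) + .formDf(spec@kappaForm, spec@nBins) +
    length(unique(spec@interceptTies)) + length(unique(spec@slopeTies))
})

#' Akaike information criterion
#'
#' `AIC = 2 * df - 2 * lnL`; lower is better. Plain AIC, no small-sample
#' correction.
#'
#' @param lnL log-likelihood.
#' @param df number of free parameters (>= 1).
#' @return the AIC value.
#' @examples
#' aicScore(-839713.86, 24)  # 1679475.72
#' @export
aicScore <- function(lnL, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * df - 2 * lnL
}

#' Enumerate all 27 parameterizations of a model family
#'
#' The Cartesian product of the three functional forms (constant, linear,
#' per-bin) over the family's three parameters gives 3^3 = 27 model
#' specifications; exactly 8 of them contain no constant form.
#'
#' @param family `"GY94"` (the default) or `"MG94"`.
#' @param nBins number of RSA bins.
#' @return list of 27 [ModelSpec-class] objects.
#' @export
enumerateModelSpecs <- function(family = "GY94", nBins = 20L) {
  grid <- expand.grid(p1 = .PARAM_FORMS, p2 = .PARAM_FORMS, p3 = .PARAM_FORMS,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(k) {
    if (family == "GY94")
      modelSpec("GY94", omega = grid$p1[k], t = grid$p2[k],
                kappa = grid$p3[k], nBins = nBins)
    else
      modelSpec("MG94", alpha = grid$p1[k], beta = grid$p2[k],
                kappa = grid$p3[k], nBins = nBins)
  })
}

.specLabel <- function(spec) paste(spec@forms, collapse = "/")

## Sign of the fitted RSA trend of a parameter: slope sign for linear forms,
## sign of the least-squares trend over bins for per-bin forms, 0 for
## constants and for slopes indistinguishable from zero.
.slopeSign <- function(form, values, midpoints, tol = 1e-4) {
  s <- switch(form,
    constant = 0,
    linear = values[[2L]],
    `per-bin` = {
      ok <- !is.na(values)
      if (sum(ok) < 2L) 0
      else stats::coef(stats::lm(values[ok] ~ midpoints[ok]))[[2L]]
    })
  if (abs(s) <= tol) "0" else if (s > 0) "+" else "-"
}

#' Rank fitted models by AIC
#'
#' Sorts a list of fits by ascending AIC (ties broken by smaller df, then by
#' model label) and reports the ranking with the per-model change in AIC from
#' the best model and the sign of the fitted RSA trend of each parameter.
#'
#' @param fits list of [CodonFit-class] objects.
#' @return data.frame with one row per model: the three parameter forms,
#'   `lnL`, `df`, `AIC`, `deltaAIC`, and trend signs; the reordered fits are
#'   attached as attribute `"fits"`.
#' @export
rankModels <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit")
  rows <- lapply(fits, function(f) {
    mids <- binMidpoints(f@binning)
    signs <- vapply(names(f@spec@forms), function(p)
      .slopeSign(f@spec@forms[[p]], f@estimates[[p]], mids), "")
    d <- data.frame(t(f@spec@forms), lnL = f@logLik, df = f@df, AIC = f@aic,
                    stringsAsFactors = FALSE)
    for (p in names(signs)) d[[paste0(p, "Slope")]] <- signs[[p]]
    d$label <- .specLabel(f@spec)
    d
  })
  tab <- do.call(rbind, rows)
  o <- order(tab$AIC, tab$df, tab$label)
  tab <- tab[o, , drop = FALSE]
  tab$deltaAIC <- tab$AIC - tab$AIC[1L]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[o]
  tab
}

.FORM_ORDER <- c(constant = 1L, linear = 2L, `per-bin` = 3L)

#' Likelihood ratio test of nested model fits
#'
#' Computes the statistic \eqn{2(\ell_{full} - \ell_{nested})} and the
#' asymptotic chi-square p-value on `df(full) - df(nested)` degrees of
#' freedom. When both arguments are single-model [CodonFit-class] objects of
#' the same family, nesting is verified structurally (each parameter's form
#' must be at most as flexible in the nested model, with constant nested in
#' linear nested in per-bin); grouped fits are checked on df only.
#'
#' @param nested the restricted fit.
#' @param full the more general fit.
#' @param tol slack allowed for `lnL(nested) <= lnL(full)` before erroring.
#' @return an object of class `"htest"` with the statistic, df and p-value.
#' @export
lrTest <- function(nested, full, tol = 1e-3) {
  lnN <- nested@logLik; dfN <- nested@df
  lnF <- full@logLik; dfF <- full@df
  if (methods::is(nested, "CodonFit") && methods::is(full, "CodonFit")) {
    if (!identical(nested@spec@family, full@spec@family))
      stop("fits are from different model families; not nested")
    oN <- .FORM_ORDER[nested@spec@forms]
    oF <- .FORM_ORDER[full@spec@forms]
    if (any(oN > oF))
      stop("models are not nested: ", .specLabel(nested@spec),
           " is not a restriction of ", .specLabel(full@spec))
  }
  if (dfF <= dfN) stop("full model must have more free parameters")
  if (lnN > lnF + tol)
    stop("nested fit has higher log-likelihood than the full fit (",
         format(lnN - lnF), "); refit with more starts")
  stat <- max(0, 2 * (lnF - lnN))
  dfDiff <- dfF - dfN
  structure(list(statistic = c(`2 ln LR` = stat),
                 parameter = c(df = dfDiff),
                 p.value = stats::pchisq(stat, dfDiff, lower.tail = FALSE),
                 method = "Likelihood ratio test of nested codon models",
                 data.name = paste(dfN, "df vs", dfF, "df fit")),
            class = "htest")
}

#' Create a grouped model specification
#'
#' Describes a joint GY94 model over several groups of genes: one shared
#' \eqn{t(r)} and \eqn{\kappa(r)} across groups, and a linear
#' \eqn{\omega(r) = \omega_0 + \omega_1 r} per group. Intercepts and slopes
#' are tied across groups via tie classes: groups given the same class label
#' share the parameter. The default gives every group its own intercept and
#' slope.
#'
#' @param groups character vector of group labels.
#' @param t,kappa forms of the shared parameters.
#' @param interceptTies,slopeTies named character vectors mapping each group
#'   to a tie class; defaults to one class per group (all free).
#' @param nBins number of RSA bins.
#' @return a [GroupedCodonSpec-class] object.
#' @examples
#' ## shared kappa/t, separate omega lines, then the intercept-equality
#' ## restriction used to test whether buried-residue rates differ:
#' groupedCodonSpec(c("largeCore", "smallCore"), t = "linear",
#'                  kappa = "per-bin")
#' groupedCodonSpec(c("largeCore", "smallCore"), t = "linear",
#'                  kappa = "per-bin",
#'                  interceptTies = c(largeCore = "all", smallCore = "all"))
#' @export
groupedCodonSpec <- function(groups, t = "linear", kappa = "linear",
                             interceptTies = NULL, slopeTies = NULL,
                             nBins = 20L) {
  groups <- as.character(groups)
  if (is.null(interceptTies))
    interceptTies <- stats::setNames(groups, groups)
  if (is.null(slopeTies))
    slopeTies <- stats::setNames(groups, groups)
  methods::new("GroupedCodonSpec", tForm = t, kappaForm = kappa,
               interceptTies = interceptTies[groups],
               slopeTies = slopeTies[groups], nBins = as.integer(nBins))
}

setMethod("show", "GroupedCodonSpec", function(object) {
  cat("GroupedCodonSpec over", length(object@interceptTies), "groups: t =",
      object@tForm, ", kappa =", object@kappaForm, "\n")
  cat("  omega intercept classes:",
      paste(unique(object@interceptTies), collapse = ", "), "\n")
  cat("  omega slope classes:",
      paste(unique(object@slopeTies), collapse = ", "), "\n")
})

#' Fit a joint model across gene groups with tied parameters
#'
#' Maximizes the joint likelihood (the sum of the binned log-likelihoods over
#' all groups) of a [GroupedCodonSpec-class]: shared \eqn{t(r)} and
#' \eqn{\kappa(r)}, and per-group linear \eqn{\omega(r)} whose intercepts and
#' slopes may be tied across groups. This supports the three designs used for
#' core-size and expression analyses: free lines per group, a common-intercept
#' restriction, and factorial designs where the slope is tied to one factor.
#'
#' @param groups named list of [BinnedPairData-class] objects, one per group;
#'   names must match the spec's group labels.
#' @param spec a [GroupedCodonSpec-class].
#' @param pi codon frequencies shared by all groups.
#' @param binning the [RsaBinning-class].
#' @param control optimizer settings as in [fitCodonModel()].
#' @return a [GroupedCodonFit-class] object.
#' @export
fitGroupedModel <- function(groups, spec, pi,
                            binning = rsaBinning(spec@nBins),
                            control = list()) {
  labels <- names(spec@interceptTies)
  if (!all(labels %in% names(groups)))
    stop("spec references group(s) absent from the data: ",
         paste(setdiff(labels, names(groups)), collapse = ", "))
  groups <- groups[labels]
  pi <- .checkPi(pi)
  nStarts <- control$nStarts %||% 5L
  seed <- control$seed %||% 1L
  maxit <- control$maxit %||% 500L
  mids <- binMidpoints(binning)
  occ <- lapply(groups, .occupiedBins)
  occAll <- sort(unique(unlist(occ)))

  iCls <- unique(spec@interceptTies)
  sCls <- unique(spec@slopeTies)
  nT <- .formDf(spec@tForm, spec@nBins)
  nT <- if (spec@tForm == "per-bin") length(occAll) else nT
  nK <- if (spec@kappaForm == "per-bin") length(occAll)
        else .formDf(spec@kappaForm, spec@nBins)
  idxT <- seq_len(nT)
  idxK <- nT + seq_len(nK)
  idxI <- nT + nK + seq_along(iCls)
  idxS <- nT + nK + length(iCls) + seq_along(sCls)
  npar <- nT + nK + length(iCls) + length(sCls)

  formBounds <- function(form, n, up, base) {
    if (form == "linear")
      list(lo = c(.PARAM_LOWER, -.SLOPE_BOUND), up = c(up, .SLOPE_BOUND),
           st = c(base, 0))
    else
      list(lo = rep(.PARAM_LOWER, n), up = rep(up, n), st = rep(base, n))
  }
  bT <- formBounds(spec@tForm, nT, .PARAM_UPPER[["t"]], .T_START)
  bK <- formBounds(spec@kappaForm, nK, .PARAM_UPPER[["kappa"]], .KAPPA_START)
  lower <- c(bT$lo, bK$lo, rep(.PARAM_LOWER, length(iCls)),
             rep(-.SLOPE_BOUND, length(sCls)))
  upper <- c(bT$up, bK$up, rep(.PARAM_UPPER[["omega"]], length(iCls)),
             rep(.SLOPE_BOUND, length(sCls)))
  start0 <- c(bT$st, bK$st, rep(.OMEGA_START, length(iCls)),
              rep(0, length(sCls)))

  evalShared <- function(form, vals) {
    if (form == "per-bin") {
      v <- rep(NA_real_, spec@nBins); v[occAll] <- vals; v
    } else .evalForm(form, vals, mids)
  }

  negll <- function(par) {
    tv <- evalShared(spec@tForm, par[idxT])
    kv <- evalShared(spec@kappaForm, par[idxK])
    i0 <- stats::setNames(par[idxI], iCls)
    s1 <- stats::setNames(par[idxS], sCls)
    viol <- 0
    for (g in labels) {
      om <- i0[[spec@interceptTies[[g]]]] + s1[[spec@slopeTies[[g]]]] * mids
      viol <- viol + sum(pmax(0, .PARAM_LOWER - om[occ[[g]]]))
    }
    viol <- viol + sum(pmax(0, .PARAM_LOWER - tv[occAll])) +
      sum(pmax(0, .PARAM_LOWER - kv[occAll]))
    if (viol > 0) return(1e9 * (1 + viol))
    ll <- 0
    for (g in labels) {
      om <- i0[[spec@interceptTies[[g]]]] + s1[[spec@slopeTies[[g]]]] * mids
      ev <- list(omega = om, t = tv, kappa = kv)
      ps <- .binTransitionMatrices("GY94", ev, pi, occ[[g]], mids)
      cnt <- groups[[g]]@counts
      for (s in seq_along(occ[[g]])) {
        cm <- cnt[[occ[[g]][s]]]
        pvals <- pi[cm[, 1L]] * ps[[s]][cm[, c(1L, 2L), drop = FALSE]]
        ll <- ll + sum(cm[, 3L] * log(pmax(pvals, 1e-300)))
      }
    }
    -ll
  }

  startMatrix <- .withSeed(seed, {
    m <- matrix(rep(start0, nStarts), ncol = nStarts)
    if (nStarts > 1L)
      for (s in 2:nStarts)
        m[, s] <- ifelse(start0 > 0, start0 * stats::runif(npar, 0.5, 1.5),
                         stats::runif(npar, -0.25, 0.25))
    m
  })
  best <- NULL
  for (s in seq_len(nStarts)) {
    opt <- try(stats::optim(startMatrix[, s], negll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = maxit)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for the grouped fit")

  df <- modelDf(spec)
  lnL <- -best$value
  sharedOut <- list(t = if (spec@tForm == "per-bin")
                          evalShared(spec@tForm, best$par[idxT])
                        else best$par[idxT],
                    kappa = if (spec@kappaForm == "per-bin")
                              evalShared(spec@kappaForm, best$par[idxK])
                            else best$par[idxK])
  methods::new("GroupedCodonFit", spec = spec,
               omegaIntercepts = stats::setNames(best$par[idxI], iCls),
               omegaSlopes = stats::setNames(best$par[idxS], sCls),
               shared = sharedOut, logLik = lnL, df = df,
               aic = 2 * df - 2 * lnL, converged = best$convergence == 0L,
               pi = unname(pi), binning = binning)
}

#' @rdname fitGroupedModel
#' @param x a [GroupedCodonFit-class] object.
#' @export
setMethod("estimates", "GroupedCodonFit", function(x)
  list(omegaIntercepts = x@omegaIntercepts, omegaSlopes = x@omegaSlopes,
       t = x@shared$t, kappa = x@shared$kappa))

#' @export
setMethod("logLik", "GroupedCodonFit", function(object, ...) {
  structure(object@logLik, df = object@df, class = "logLik")
})

setMethod("show", "GroupedCodonFit", function(object) {
  cat("GroupedCodonFit over", length(object@spec@interceptTies), "groups\n")
  cat("  lnL =", format(object@logLik, nsmall = 2), " df =", object@df,
      " AIC =", format(object@aic, nsmall = 2), "\n")
  cat("  omega0:", paste(names(object@omegaIntercepts),
                         signif(object@omegaIntercepts, 3),
                         sep = "=", collapse = ", "), "\n")
  cat("  omega1:", paste(names(object@omegaSlopes),
                         signif(object@omegaSlopes, 3),
                         sep = "=", collapse = ", "), "\n")
})
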