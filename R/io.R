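## Readers/writers for the package's exchange formats and the pipeline entry
## point behind the command-line script. Codon site indices are 1-based in
## all files; conversions are confined to this module.

## Split a 2-sequence alignment into an (n_codons x 2) matrix of uppercase
## codon strings. Accepts a DNAStringSet or a character vector of length 2.
.alignmentCodons <- function(alignment) {
  s <- toupper(as.character(alignment))
  if (length(s) != 2L)
    stop("expected exactly 2 aligned sequences, got ", length(s))
  w <- nchar(s)
  if (w[1L] != w[2L])
    stop("aligned sequences differ in length (", w[1L], " vs ", w[2L], ")")
  if (w[1L] %% 3L != 0L)
    stop("alignment length ", w[1L], " is not divisible by 3")
  nc <- w[1L] %/% 3L
  startsAt <- 3L * (seq_len(nc) - 1L) + 1L
  cbind(substring(s[1L], startsAt, startsAt + 2L),
        substring(s[2L], startsAt, startsAt + 2L))
}

#' Read a pairwise codon alignment from FASTA
#'
#' Reads a FASTA file that must contain exactly two aligned sequences of
#' equal length divisible by 3. Case is normalized to upper case and RNA `U`
#' is converted to `T`. Gaps (`-`) and IUPAC ambiguity codes are allowed;
#' sites carrying them are excluded later, at counting time.
#'
#' @param path path to the FASTA file.
#' @return a `DNAStringSet` of length 2.
#' @export
readPairAlignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) != 2L)
    stop("FASTA must contain exactly 2 records, found ", length(raw))
  s <- chartr("u", "T", chartr("U", "T", toupper(as.character(raw))))
  w <- nchar(s)
  if (w[1L] != w[2L])
    stop("aligned sequences differ in length (", w[1L], " vs ", w[2L], ")")
  if (w[1L] %% 3L != 0L)
    stop("alignment length ", w[1L], " is not divisible by 3")
  Biostrings::DNAStringSet(stats::setNames(s, names(raw)))
}

.fitToList <- function(fit) {
  list(family = fit@spec@family,
       forms = as.list(fit@spec@forms),
       nBins = fit@spec@nBins,
       estimates = fit@estimates,
       lnL = fit@logLik, df = fit@df, aic = fit@aic,
       converged = fit@converged, nSitesUsed = fit@nSitesUsed)
}

#' Write a fit report as JSON
#'
#' Serializes a [CodonFit-class] (spec, estimates, lnL, df, AIC, sites used)
#' together with the resolved run configuration, so that every report records
#' how it was produced.
#'
#' @param fit a [CodonFit-class] object.
#' @param path output path.
#' @param config optional list echoed into the report.
#' @return invisibly, `path`.
#' @export
writeFitJson <- function(fit, path, config = NULL) {
  out <- .fitToList(fit)
  if (!is.null(config)) out$config <- config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a pipeline command
#'
#' Programmatic equivalent of the command-line interface: dispatches on
#' `config$command` and writes the corresponding report files into
#' `config$outDir`. Supported commands:
#'
#' * `fit`: fit one model (`fasta`, `rsa`, `forms`, `nBins`) and write
#'   `fit.json`.
#' * `rank`: fit all 27 GY94 parameterizations and write a ranking TSV
#'   (`ranking.tsv`) with forms, lnL, df, AIC and fitted trend signs.
#' * `rates`: fit one model and write the per-bin dN/dS profile
#'   (`rates.tsv`).
#' * `simulate`: generate an alignment + site-RSA table under a stated model
#'   (`alignment.fasta`, `sites.tsv`).
#' * `rsa`: convert a DSSP output file to a site-RSA TSV (`sites.tsv`),
#'   taking the residue number as codon site index.
#' * `grouped-fit`: joint fit over labeled groups with tied parameters
#'   (`grouped_fit.json`).
#'
#' Every JSON report embeds the resolved configuration including the seed.
#'
#' @param config a named list; see Details and the `inst/cli/rsaevol.R`
#'   script for the fields of each command.
#' @return invisibly, a list of written file paths.
#' @export
runPipeline <- function(config) {
  cmd <- config$command %||% stop("config$command is required")
  outDir <- config$outDir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed %||% 1L
  nb <- as.integer(config$nBins %||% 20L)
  binning <- rsaBinning(nb)
  control <- list(seed = seed, nStarts = config$nStarts %||% 5L)
  written <- character(0)

  loadData <- function() {
    aln <- readPairAlignment(config$fasta)
    siteRsa <- readSiteRsa(config$rsa)
    data <- binPairCounts(aln, siteRsa, binning)
    if (length(.occupiedBins(data)) == 0L)
      stop("no occupied RSA bins; nothing to fit")
    message("using ", data@nSitesUsed, " sites in ",
            length(.occupiedBins(data)), " occupied bins (",
            data@nExcluded, " excluded)")
    list(data = data, pi = codonFrequenciesF3x4(aln))
  }

  if (cmd == "fit" || cmd == "rates") {
    d <- loadData()
    forms <- config$forms %||% list(omega = "linear", t = "linear",
                                    kappa = "linear")
    family <- config$family %||% "GY94"
    spec <- if (family == "GY94")
      modelSpec("GY94", omega = forms$omega, t = forms$t, kappa = forms$kappa,
                nBins = nb)
    else
      modelSpec("MG94", alpha = forms$alpha, beta = forms$beta,
                kappa = forms$kappa, nBins = nb)
    fit <- fitCodonModel(spec, d$data, d$pi, binning, control)
    if (cmd == "fit") {
      path <- file.path(outDir, "fit.json")
      writeFitJson(fit, path, config)
      written <- path
    } else {
      prof <- rateProfile(fit)
      path <- file.path(outDir, "rates.tsv")
      utils::write.table(prof, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- path
    }
  } else if (cmd == "rank") {
    d <- loadData()
    specs <- enumerateModelSpecs("GY94", nBins = nb)
    ## fit the all-constant model first and seed every other spec from it
    baseFit <- fitCodonModel(modelSpec("GY94", nBins = nb), d$data, d$pi,
                             binning, control)
    ctlWarm <- control
    ctlWarm$start <- estimates(baseFit)
    fits <- lapply(specs, function(sp)
      fitCodonModel(sp, d$data, d$pi, binning, ctlWarm))
    tab <- rankModels(fits)
    path <- file.path(outDir, "ranking.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- path
  } else if (cmd == "simulate") {
    family <- config$family %||% "GY94"
    forms <- config$forms %||% list(omega = "constant", t = "constant",
                                    kappa = "constant")
    spec <- if (family == "GY94")
      modelSpec("GY94", omega = forms$omega, t = forms$t, kappa = forms$kappa,
                nBins = nb)
    else
      modelSpec("MG94", alpha = forms$alpha, beta = forms$beta,
                kappa = forms$kappa, nBins = nb)
    sim <- simulateCodonPair(config$nSites %||% 1000L, spec, config$params,
                             pi = config$pi %||% rep(1 / 61, 61),
                             binning = binning,
                             rsaDist = config$rsaDist %||%
                               list(kind = "uniform"),
                             seed = seed)
    fa <- file.path(outDir, "alignment.fasta")
    Biostrings::writeXStringSet(sim$alignment, fa)
    ts <- file.path(outDir, "sites.tsv")
    writeSiteRsa(sim$siteRsa, ts)
    written <- c(fa, ts)
  } else if (cmd == "rsa") {
    d <- readDssp(config$dssp)
    if (!is.null(config$chain)) d <- d[d$chain == config$chain, ]
    siteRsa <- data.frame(site = d$resnum,
                          rsa = asaToRsa(d$asa, d$aa))
    path <- file.path(outDir, "sites.tsv")
    writeSiteRsa(siteRsa, path)
    written <- path
  } else if (cmd == "grouped-fit") {
    groups <- lapply(config$groups, function(g) {
      aln <- readPairAlignment(g$fasta)
      binPairCounts(aln, readSiteRsa(g$rsa), binning)
    })
    alnAll <- lapply(config$groups, function(g) readPairAlignment(g$fasta))
    ## pool both sequences of every group for the shared F3x4 frequencies
    pooled <- Biostrings::DNAStringSet(c(
      paste(vapply(alnAll, function(a) as.character(a)[1L], ""),
            collapse = ""),
      paste(vapply(alnAll, function(a) as.character(a)[2L], ""),
            collapse = "")))
    pi <- codonFrequenciesF3x4(pooled)
    spec <- groupedCodonSpec(names(groups),
                             t = config$tForm %||% "linear",
                             kappa = config$kappaForm %||% "linear",
                             interceptTies = config$interceptTies,
                             slopeTies = config$slopeTies, nBins = nb)
    fit <- fitGroupedModel(groups, spec, pi, binning, control)
    out <- list(groups = names(groups),
                omegaIntercepts = as.list(fit@omegaIntercepts),
                omegaSlopes = as.list(fit@omegaSlopes),
                shared = fit@shared, lnL = fit@logLik, df = fit@df,
                aic = fit@aic, converged = fit@converged, config = config)
    path <- file.path(outDir, "grouped_fit.json")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- path
  } else {
    stop("unknown command: ", cmd)
  }
  invisible(as.list(written))
}
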