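## Conversion of absolute solvent-accessible surface area (ASA) to relative
## solvent accessibility (RSA) and discretization of RSA into evenly spaced
## bins represented by their mid-points.

#' Maximum per-residue solvent accessibility in an extended Gly-X-Gly peptide
#'
#' The default normalization constants for converting DSSP-style absolute
#' accessibility (ASA, in square Angstroms) to relative solvent accessibility:
#' the theoretical maximum ASA of residue X in an extended Gly-X-Gly
#' tripeptide, from Miller, Janin, Lesk & Chothia (1987, J Mol Biol 196:641).
#' Any alternative published table with the same structure (a positive value
#' for each of the 20 amino-acid letters) can be passed wherever this default
#' is accepted.
#'
#' @return named numeric vector of 20 maxima (Angstrom^2), named by
#'   one-letter amino-acid code.
#' @examples
#' maxAsaTable()[["W"]]  # tryptophan, the largest residue
#' @export
maxAsaTable <- function() {
  c(A = 113, R = 241, N = 158, D = 151, C = 140, Q = 189, E = 183, G = 85,
    H = 194, I = 182, L = 180, K = 211, M = 204, F = 218, P = 143, S = 122,
    T = 146, W = 259, Y = 229, V = 160)
}

#' Convert absolute to relative solvent accessibility
#'
#' RSA is ASA divided by the residue's maximum accessibility in an extended
#' Gly-X-Gly peptide. Values above 1 (which DSSP can produce for distorted
#' residues) are clamped to 1.
#'
#' @param asa numeric vector of absolute accessibilities (Angstrom^2, >= 0).
#' @param aa character vector of one-letter amino-acid codes (recycled).
#' @param table named numeric vector of per-residue maxima; defaults to
#'   [maxAsaTable()].
#' @return numeric vector of RSA values in \[0, 1\].
#' @examples
#' asaToRsa(0, "W")                   # 0: fully buried
#' asaToRsa(maxAsaTable()[["A"]], "A")  # 1: fully exposed
#' @export
asaToRsa <- function(asa, aa, table = maxAsaTable()) {
  if (any(asa < 0)) stop("asa must be non-negative")
  aa <- rep_len(toupper(as.character(aa)), length(asa))
  mx <- table[aa]
  if (anyNA(mx))
    stop("unknown residue letter(s): ",
         paste(unique(aa[is.na(mx)]), collapse = ", "))
  pmin(asa / unname(mx), 1.0)
}

#' Construct an even RSA binning
#'
#' Divides \[0, 1\] into `n` equal-width bins. Each RSA value is later
#' represented by the mid-point \eqn{r_k} of the bin it falls into.
#'
#' @param n integer bin count, at least 2. The default of 20 bins
#'   approximates a smooth RSA dependency well while keeping per-bin forms
#'   fittable.
#' @return an [RsaBinning-class] object.
#' @examples
#' binMidpoints(rsaBinning(4))  # 0.125 0.375 0.625 0.875
#' @export
rsaBinning <- function(n = 20L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("n must be a single integer >= 2")
  edges <- seq(0, 1, length.out = n + 1L)
  methods::new("RsaBinning", n = n, edges = edges,
               midpoints = (edges[-1L] + edges[-(n + 1L)]) / 2)
}

#' @describeIn rsaBinning number of bins.
#' @param x an [RsaBinning-class] object.
#' @export
setMethod("nBins", "RsaBinning", function(x) x@n)

#' @rdname rsaBinning
#' @export
setMethod("binMidpoints", "RsaBinning", function(x) x@midpoints)

#' @rdname rsaBinning
#' @export
setMethod("binEdges", "RsaBinning", function(x) x@edges)

setMethod("show", "RsaBinning", function(object) {
  cat("RsaBinning:", object@n, "even bins on [0, 1], midpoints",
      format(object@midpoints[1L]), "...",
      format(object@midpoints[object@n]), "\n")
})

#' Assign RSA values to bins
#'
#' Bin intervals are half-open, `[edge_k, edge_{k+1})`, with the final bin
#' closed on the right so that RSA = 1 maps to bin `n`.
#'
#' @param rsa numeric vector of RSA values in \[0, 1\] (clamp with
#'   [asaToRsa()] first if needed).
#' @param binning an [RsaBinning-class] object.
#' @return integer vector of 1-based bin indices.
#' @examples
#' assignBins(c(0, 0.05, 1), rsaBinning(20))  # 1 2 20
#' @export
assignBins <- function(rsa, binning) {
  if (any(is.na(rsa)) || any(rsa < 0) || any(rsa > 1))
    stop("rsa values must lie in [0, 1]; clamp or filter first")
  k <- findInterval(rsa, binEdges(binning), rightmost.closed = TRUE)
  as.integer(k)
}

#' Read per-residue accessibility from a DSSP output file
#'
#' Parses the fixed-column residue table of a DSSP output file and returns
#' the chain, residue number, amino acid and absolute accessibility (the ACC
#' column) of every resolved residue. Chain-break records (`!` in the AA
#' column) are skipped; residue lines that cannot be parsed are skipped with
#' a message reporting their count.
#'
#' @param path path to a DSSP-format output file.
#' @return data.frame with columns `chain`, `resnum`, `aa`, `asa`.
#' @export
readDssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty DSSP file: ", path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L)
    stop("malformed DSSP file (no '  #  RESIDUE' header line): ", path)
  body <- lines[seq.int(hdr + 1L, length.out = length(lines) - hdr)]
  if (length(body) == 0L) stop("DSSP file has no residue records: ", path)
  aa <- substr(body, 14L, 14L)
  keep <- aa != "!"  # chain breaks
  body <- body[keep]; aa <- aa[keep]
  resnum <- suppressWarnings(as.integer(substr(body, 6L, 10L)))
  asa <- suppressWarnings(as.numeric(substr(body, 35L, 38L)))
  chain <- substr(body, 12L, 12L)
  ## lowercase letters are DSSP's SS-bonded cysteines
  aa <- ifelse(aa %in% letters, "C", aa)
  bad <- is.na(resnum) | is.na(asa) | !(aa %in% names(maxAsaTable()))
  if (any(bad))
    message("readDssp: skipped ", sum(bad), " unparseable residue line(s)")
  data.frame(chain = chain[!bad], resnum = resnum[!bad], aa = aa[!bad],
             asa = asa[!bad], stringsAsFactors = FALSE)
}

#' Read a site-RSA table
#'
#' Reads the canonical site-RSA exchange format: a TSV with a `site` column
#' (1-based codon position in the alignment) and either an `rsa` column
#' (values in \[0, 1\]) or `asa` + `aa` columns, in which case ASA is
#' normalized to RSA via [asaToRsa()].
#'
#' @param path path to the TSV file.
#' @param table max-ASA table used if normalization is needed.
#' @return data.frame with columns `site` and `rsa`.
#' @export
readSiteRsa <- function(path, table = maxAsaTable()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"site" %in% names(d)) stop("site-RSA table needs a 'site' column")
  if ("rsa" %in% names(d)) {
    rsa <- pmin(pmax(as.numeric(d$rsa), 0), 1)
  } else if (all(c("asa", "aa") %in% names(d))) {
    rsa <- asaToRsa(as.numeric(d$asa), d$aa, table)
  } else {
    stop("site-RSA table needs an 'rsa' column or 'asa' + 'aa' columns")
  }
  data.frame(site = as.integer(d$site), rsa = rsa)
}

#' Write a site-RSA table
#'
#' @param siteRsa data.frame with columns `site` and `rsa`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSiteRsa <- function(siteRsa, path) {
  utils::write.table(siteRsa[, c("site", "rsa")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
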