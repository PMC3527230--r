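## Codon state space of the standard genetic code and the classification of
## single-nucleotide codon changes into the rate categories of the model:
## synonymous vs nonsynonymous crossed with transition vs transversion.

.cache <- new.env(parent = emptyenv())

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' The 61 sense codons of the standard genetic code
#'
#' Returns the fixed codon alphabet the whole package operates on: the 61
#' sense codons of the standard genetic code (stop codons TAA, TAG, TGA
#' excluded) in lexicographic order over A < C < G < T. All rate and
#' transition matrices use this order.
#'
#' @return named character vector of length 61; values are the trinucleotide
#'   codons, names are the encoded amino-acid letters.
#' @examples
#' codons <- senseCodons()
#' length(codons)        # 61
#' codons[codons == "ATG"]  # M
#' @export
senseCodons <- function() {
  if (is.null(.cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    sense <- gc[gc != "*"]
    sense <- sense[order(names(sense))]  # lexicographic over A < C < G < T
    codons <- names(sense)
    .cache$codons <- stats::setNames(codons, unname(sense))
    .cache$aaOf <- stats::setNames(unname(sense), codons)
  }
  stats::setNames(.cache$codons, names(.cache$codons))
}

.codonStrings <- function() unname(senseCodons())

.aaOfCodon <- function(codon) {
  senseCodons()
  aa <- .cache$aaOf[codon]
  if (anyNA(aa))
    stop("not a sense codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Classify an ordered codon pair
#'
#' Classifies a substitution between two sense codons into the categories
#' that drive the rate matrix: `identical`, `multi` (more than one nucleotide
#' position differs; instantaneous rate zero), or, for single-nucleotide
#' changes, synonymous/nonsynonymous crossed with transition (A-G or C-T)
#' versus transversion. The classification is symmetric in its arguments.
#'
#' @param i,j character vectors of sense codons (recycled to common length).
#' @return character vector with values in `identical`, `multi`, `syn_ts`,
#'   `syn_tv`, `nonsyn_ts`, `nonsyn_tv`.
#' @examples
#' classifyCodonPair("TTA", "CTA")  # syn_ts: T-C transition, both Leu
#' classifyCodonPair("GAA", "GAT")  # nonsyn_tv: Glu -> Asp
#' classifyCodonPair("AAA", "ACC")  # multi
#' @export
classifyCodonPair <- function(i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(as.character(i), n)
  j <- rep_len(as.character(j), n)
  aaI <- .aaOfCodon(i)
  aaJ <- .aaOfCodon(j)
  out <- character(n)
  for (s in seq_len(n)) {
    ci <- strsplit(i[s], "", fixed = TRUE)[[1L]]
    cj <- strsplit(j[s], "", fixed = TRUE)[[1L]]
    d <- which(ci != cj)
    if (length(d) == 0L) {
      out[s] <- "identical"
    } else if (length(d) > 1L) {
      out[s] <- "multi"
    } else {
      ts <- .TRANSITIONS[ci[d]] == cj[d]
      syn <- aaI[s] == aaJ[s]
      out[s] <- paste0(if (syn) "syn" else "nonsyn", if (ts) "_ts" else "_tv")
    }
  }
  out
}

#' Substitution-class matrix over all ordered sense-codon pairs
#'
#' Precomputed 61 x 61 character matrix of [classifyCodonPair()] values, in
#' the fixed codon order of [senseCodons()]. This matrix defines which rate
#' multiplier each off-diagonal generator entry receives.
#'
#' @return 61 x 61 character matrix with codon dimnames.
#' @examples
#' cls <- codonSubstitutionClasses()
#' cls["TTA", "CTA"]  # syn_ts
#' @export
codonSubstitutionClasses <- function() {
  if (is.null(.cache$classMatrix)) {
    codons <- .codonStrings()
    n <- length(codons)
    ## vectorized over the 3 codon positions
    pos <- lapply(1:3, function(p) substr(codons, p, p))
    cls <- matrix("multi", n, n, dimnames = list(codons, codons))
    ndiff <- matrix(0L, n, n)
    for (p in 1:3)
      ndiff <- ndiff + outer(pos[[p]], pos[[p]], "!=")
    aa <- .aaOfCodon(codons)
    syn <- outer(aa, aa, "==")
    isTs <- function(a, b) .TRANSITIONS[a] == b
    ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
      only <- ndiff == 1L & outer(pos[[p]], pos[[p]], "!=")
      ts[only] <- outer(pos[[p]], pos[[p]], isTs)[only]
    }
    cls[ndiff == 0L] <- "identical"
    one <- ndiff == 1L
    cls[one & syn & ts] <- "syn_ts"
    cls[one & syn & !ts] <- "syn_tv"
    cls[one & !syn & ts] <- "nonsyn_ts"
    cls[one & !syn & !ts] <- "nonsyn_tv"
    .cache$classMatrix <- cls
  }
  .cache$classMatrix
}
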