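## S4 containers for the core objects: the paralogous repeat pair, a
## digital-PCR plate observation, and the two kinds of interval estimate
## (recombination rate, population allele frequency).

#' LCRPair: a pair of coordinate-matched paralogous low-copy repeats
#'
#' Holds the two LCR sequences flanking an NAHR-prone locus as a
#' \code{DNAStringSet} of length two.  The sequences are assumed
#' pre-aligned (coordinate-matched over the assayed region); no alignment
#' is performed by this package.
#'
#' @slot seqs A \code{\link[Biostrings]{DNAStringSet}} of length 2, named
#'   \code{"LCR1"} (proximal/centromeric) and \code{"LCR2"}
#'   (distal/telomeric).
#' @slot separation Distance in bp between the two repeats on the
#'   chromosome (2e5 for the DPY19L2 locus); metadata only.
#'
#' @examples
#' lp <- LCRPair("ACGTACGT", "ACGTACGA")
#' pairwiseIdentity(lp)
#' @export
setClass("LCRPair",
  representation(seqs = "DNAStringSet", separation = "numeric"),
  prototype(separation = NA_real_)
)

setValidity("LCRPair", function(object) {
  msg <- character()
  if (length(object@seqs) != 2L)
    msg <- c(msg, "seqs must contain exactly two sequences (LCR1, LCR2)")
  if (length(object@seqs) == 2L &&
      !identical(names(object@seqs), c("LCR1", "LCR2")))
    msg <- c(msg, "seqs must be named 'LCR1' and 'LCR2'")
  if (length(object@separation) != 1L)
    msg <- c(msg, "separation must be a single number")
  if (length(msg)) msg else TRUE
})

#' Construct an LCRPair
#'
#' @param lcr1,lcr2 Character strings or \code{DNAString}s; IUPAC
#'   nucleotide codes only.
#' @param separation Genomic distance between the repeats in bp.
#' @return An \code{\linkS4class{LCRPair}}.
#' @export
LCRPair <- function(lcr1, lcr2, separation = 2e5) {
  seqs <- Biostrings::DNAStringSet(c(LCR1 = as.character(lcr1),
                                     LCR2 = as.character(lcr2)))
  new("LCRPair", seqs = seqs, separation = as.numeric(separation))
}

#' PlateResult: one limiting-dilution digital-PCR plate
#'
#' A plate observation: total wells, positive wells, and the total number
#' of input template copies \code{N} (copies of the assayed chromosome
#' across the whole plate).  Copies per well \code{W = N / wellsTotal} need
#' not be an integer (e.g. 50 ng / 3 pg = 16666.7 copies).
#'
#' @slot wellsTotal Number of wells (96 for a standard plate).
#' @slot wellsPositive Number of wells with a recombinant-specific
#'   amplification.
#' @slot copiesTotal Total haploid-genome copies N distributed over the
#'   plate.
#' @export
setClass("PlateResult",
  representation(wellsTotal = "integer", wellsPositive = "integer",
                 copiesTotal = "numeric")
)

setValidity("PlateResult", function(object) {
  msg <- character()
  if (object@wellsTotal < 1L) msg <- c(msg, "wellsTotal must be >= 1")
  if (object@wellsPositive < 0L || object@wellsPositive > object@wellsTotal)
    msg <- c(msg, "wellsPositive must be in [0, wellsTotal]")
  if (!is.finite(object@copiesTotal) || object@copiesTotal <= 0)
    msg <- c(msg, "copiesTotal must be a positive finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a PlateResult
#'
#' @param wellsTotal Number of wells on the plate.
#' @param wellsPositive Number of positive wells.
#' @param copiesTotal Total template copies N across the plate.
#' @return A \code{\linkS4class{PlateResult}}.
#' @examples
#' PlateResult(96, 26, 1.6e6)  # donor A deletion assay
#' @export
PlateResult <- function(wellsTotal, wellsPositive, copiesTotal) {
  new("PlateResult", wellsTotal = as.integer(wellsTotal),
      wellsPositive = as.integer(wellsPositive),
      copiesTotal = as.numeric(copiesTotal))
}

#' RateEstimate: recombinant count and per-genome rate with CI
#'
#' Result of the hypergeometric tabulation: the inferred integer number of
#' recombinant molecules R in the plate input, the de novo rate
#' lambda = R / N (events per haploid genome), and, once
#' \code{\link{rateCI}} has been applied, exact binomial confidence bounds
#' on lambda.
#'
#' @slot recombinants Integer R.
#' @slot copiesTotal N used for the estimate.
#' @slot rate lambda = R / N.
#' @slot ciLow,ciHigh Confidence bounds on lambda (NA until computed).
#' @slot level Confidence level of the bounds.
#' @export
setClass("RateEstimate",
  representation(recombinants = "integer", copiesTotal = "numeric",
                 rate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 level = "numeric"),
  prototype(ciLow = NA_real_, ciHigh = NA_real_, level = NA_real_)
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (object@recombinants < 0L) msg <- c(msg, "recombinants must be >= 0")
  if (!isTRUE(all.equal(object@rate,
                        object@recombinants / object@copiesTotal)))
    msg <- c(msg, "rate must equal recombinants / copiesTotal")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@rate + 1e-15 &&
        object@rate <= object@ciHigh + 1e-15))
    msg <- c(msg, "must have ciLow <= rate <= ciHigh")
  if (length(msg)) msg else TRUE
})

RateEstimate <- function(recombinants, copiesTotal,
                         ciLow = NA_real_, ciHigh = NA_real_,
                         level = NA_real_) {
  new("RateEstimate", recombinants = as.integer(recombinants),
      copiesTotal = as.numeric(copiesTotal),
      rate = recombinants / copiesTotal,
      ciLow = ciLow, ciHigh = ciHigh, level = level)
}

#' AlleleFrequencyEstimate: carrier-derived population allele frequency
#'
#' Frequency of a variant allele estimated from heterozygous carrier
#' counts: q = carriers / (2 * individuals), with exact binomial
#' confidence bounds on that proportion.
#'
#' @slot carriers Number of (heterozygous) carriers observed.
#' @slot individuals Number of individuals screened.
#' @slot q Allele frequency.
#' @slot ciLow,ciHigh Exact binomial bounds on q.
#' @slot level Confidence level.
#' @export
setClass("AlleleFrequencyEstimate",
  representation(carriers = "integer", individuals = "integer",
                 q = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 level = "numeric")
)

setValidity("AlleleFrequencyEstimate", function(object) {
  msg <- character()
  if (object@carriers < 0L || object@carriers > object@individuals)
    msg <- c(msg, "carriers must be in [0, individuals]")
  ok <- 0 <= object@ciLow && object@ciLow <= object@q + 1e-15 &&
    object@q <= object@ciHigh + 1e-15 && object@ciHigh <= 1
  if (!ok) msg <- c(msg, "need 0 <= ciLow <= q <= ciHigh <= 1")
  if (length(msg)) msg else TRUE
})

## ---- accessors -------------------------------------------------------

#' @describeIn LCRPair Sequence of the proximal repeat.
#' @param x An object of the documented class.
#' @export
lcr1Seq <- function(x) x@seqs[["LCR1"]]

#' @describeIn LCRPair Sequence of the distal repeat.
#' @export
lcr2Seq <- function(x) x@seqs[["LCR2"]]

#' @describeIn LCRPair Fraction of identical positions between the two
#'   (coordinate-matched, equal-length) repeat sequences.
#' @export
pairwiseIdentity <- function(x) {
  a <- as.character(lcr1Seq(x)); b <- as.character(lcr2Seq(x))
  if (nchar(a) != nchar(b))
    stop("sequences must be coordinate-matched (equal length) ",
         "to compute positional identity")
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Wells, copies and rate accessors
#'
#' Small accessor helpers for \code{\linkS4class{PlateResult}} and
#' \code{\linkS4class{RateEstimate}} objects.
#'
#' @param x A \code{PlateResult} or \code{RateEstimate}.
#' @name plate-accessors
NULL

#' @rdname plate-accessors
#' @export
wellsTotal <- function(x) x@wellsTotal

#' @rdname plate-accessors
#' @export
wellsPositive <- function(x) x@wellsPositive

#' @rdname plate-accessors
#' @export
copiesTotal <- function(x) x@copiesTotal

#' @rdname plate-accessors
#' @export
copiesPerWell <- function(x) x@copiesTotal / x@wellsTotal

#' @rdname plate-accessors
#' @export
recombinants <- function(x) x@recombinants

#' @rdname plate-accessors
#' @export
rateValue <- function(x) x@rate

#' @rdname plate-accessors
#' @export
rateCIBounds <- function(x) c(low = x@ciLow, high = x@ciHigh)

#' @describeIn AlleleFrequencyEstimate Point estimate q.
#' @param x An \code{AlleleFrequencyEstimate}.
#' @export
alleleFreq <- function(x) x@q

#' @describeIn AlleleFrequencyEstimate Confidence bounds on q.
#' @export
alleleFreqCI <- function(x) c(low = x@ciLow, high = x@ciHigh)

## ---- show methods ----------------------------------------------------

setMethod("show", "LCRPair", function(object) {
  cat("LCRPair: LCR1", Biostrings::width(object@seqs)[1], "bp | LCR2",
      Biostrings::width(object@seqs)[2], "bp")
  w <- Biostrings::width(object@seqs)
  if (w[1] == w[2])
    cat(sprintf(" | identity %.1f%%", 100 * pairwiseIdentity(object)))
  if (!is.na(object@separation))
    cat(" | separation", object@separation, "bp")
  cat("\n")
})

setMethod("show", "PlateResult", function(object) {
  cat(sprintf("PlateResult: %d/%d wells positive, N = %.3g copies (W = %.1f/well)\n",
              object@wellsPositive, object@wellsTotal, object@copiesTotal,
              copiesPerWell(object)))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: R = %d of N = %.3g, lambda = %.2g",
              object@recombinants, object@copiesTotal, object@rate))
  if (!is.na(object@ciLow))
    cat(sprintf(" (%d%% CI: %.2g; %.2g)", round(100 * object@level),
                object@ciLow, object@ciHigh))
  cat("\n")
})

setMethod("show", "AlleleFrequencyEstimate", function(object) {
  cat(sprintf(
    "AlleleFrequencyEstimate: %d carriers / %d individuals, q = %.2g (%d%% CI: %.2g; %.2g)\n",
    object@carriers, object@individuals, object@q,
    round(100 * object@level), object@ciLow, object@ciHigh))
})
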