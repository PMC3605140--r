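## Degenerate PRDM9 motif analysis.  The 13-mer CCNCCNTNNCCNC marks a
## large fraction of human recombination hotspots; matches are sought on
## both strands (the reverse-strand pattern is the formal degenerate
## reverse complement, GNGGNNANGGNGG).  The recognition signal extends to
## a 39-mer context whose identity to an external consensus is scored
## per position.

#' The degenerate PRDM9 recognition 13-mer
#'
#' @return The IUPAC pattern string \code{"CCNCCNTNNCCNC"}.
#' @export
prdm9Motif <- function() "CCNCCNTNNCCNC"

#' Scan a sequence for a degenerate motif on both strands
#'
#' Finds every match of the IUPAC \code{pattern} on the forward strand
#' and every match of its degenerate reverse complement (a reverse-strand
#' site), with overlaps allowed.  Matching uses IUPAC compatibility via
#' \code{Biostrings::matchPattern(fixed = FALSE)}.  Each hit carries its
#' 39-mer context (13 bp of flank either side) when fully inside the
#' sequence.
#'
#' @param seq Character string, \code{DNAString}, or
#'   \code{\linkS4class{LCRPair}} sequence; A/C/G/T/N alphabet.
#' @param pattern Degenerate IUPAC pattern (default
#'   \code{\link{prdm9Motif}()}).
#' @return A data.frame with one row per hit: \code{position} (1-based
#'   start on the forward strand), \code{strand} ("+"/"-"),
#'   \code{matched_seq}, \code{context39} (NA when truncated at a
#'   sequence end).
#' @examples
#' scanMotif("AAACCACCATAACCACAAA")
#' @export
scanMotif <- function(seq, pattern = prdm9Motif()) {
  subj <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  pat <- Biostrings::DNAString(pattern)
  rcpat <- Biostrings::reverseComplement(pat)
  hitsOn <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
    if (length(m) == 0)
      return(data.frame(position = integer(), strand = character(),
                        matched_seq = character(), stringsAsFactors = FALSE))
    data.frame(position = Biostrings::start(m), strand = strand,
               matched_seq = as.character(m), stringsAsFactors = FALSE)
  }
  out <- rbind(hitsOn(pat, "+"), hitsOn(rcpat, "-"))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  k <- length(pat)
  flank <- (39 - k) / 2
  s <- as.character(subj)
  out$context39 <- vapply(out$position, function(pos) {
    a <- pos - flank; b <- pos + k - 1 + flank
    if (a < 1 || b > nchar(s)) NA_character_ else substr(s, a, b)
  }, "")
  out
}

#' Identity of a 39-mer context to an extended consensus
#'
#' Counts positions identical between a hit's 39-mer context and a
#' supplied consensus 39-mer (the extended recognition sequence is an
#' external input; it is not derivable from a single locus).  An optional
#' logical mask restricts the count to designated (e.g. highly conserved)
#' positions.  The integer percentage truncates toward zero, so 21/39 is
#' reported as 53%.
#'
#' @param context39 The 39-base context string (see
#'   \code{\link{scanMotif}}); NA or wrong length is flagged undefined.
#' @param consensus39 Consensus string of the same length.
#' @param mask Optional logical vector (length 39) of positions to score.
#' @return A list with \code{count}, \code{n} (positions scored),
#'   \code{fraction} and \code{percent} (truncated integer percent); all
#'   NA with \code{defined = FALSE} for truncated contexts.
#' @export
extendedIdentity <- function(context39, consensus39, mask = NULL) {
  if (is.na(context39) || nchar(context39) != nchar(consensus39))
    return(list(count = NA_integer_, n = NA_integer_,
                fraction = NA_real_, percent = NA_integer_,
                defined = FALSE))
  a <- strsplit(toupper(context39), "")[[1]]
  b <- strsplit(toupper(consensus39), "")[[1]]
  eq <- a == b
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(eq))
    eq <- eq[mask]
  }
  n <- length(eq)
  cnt <- sum(eq)
  list(count = cnt, n = n, fraction = cnt / n,
       percent = as.integer(100 * cnt / n), defined = TRUE)
}

#' Hotspot centre from breakpoint calls
#'
#' The hotspot centre is the median of the breakpoint-interval midpoints
#' of the resolved recombined alleles.  When motif hits are supplied,
#' the distance from each hit (midpoint of the matched 13-mer) to the
#' centre is also returned.
#'
#' @param calls Breakpoint-call data.frame with a \code{midpoint} column
#'   in bp (see \code{\link{callBreakpoint}}).
#' @param hits Optional motif-hit data.frame (see
#'   \code{\link{scanMotif}}).
#' @param motifLength Motif length for midpoint computation (default 13).
#' @return A list with \code{centre} and, when hits are given,
#'   \code{distances} (one per hit, bp).
#' @export
hotspotCenter <- function(calls, hits = NULL, motifLength = 13) {
  mid <- calls$midpoint[!is.na(calls$midpoint)]
  if (length(mid) == 0) stop("no resolved calls with coordinates")
  centre <- stats::median(mid)
  out <- list(centre = centre)
  if (!is.null(hits) && nrow(hits) > 0)
    out$distances <- abs(hits$position + (motifLength - 1) / 2 - centre)
  out
}

#' Probability of a chance motif near the hotspot centre
#'
#' With m motif sites placed uniformly in a sequence of length L, the
#' probability that at least one falls within d bp of a fixed centre
#' (a window of 2d positions) is 1 - (1 - m/L)^(2d).  For the reference
#' locus, m = 5, L = 28000, d = 35 gives 0.012.
#'
#' @param m Number of motif sites (>= 0).
#' @param L Sequence length in bp.
#' @param d Half-window in bp (2d <= L).
#' @return The probability.
#' @examples
#' chanceProximityProb(5, 28000, 35)
#' @export
chanceProximityProb <- function(m, L, d) {
  if (m < 0 || L <= 0 || d < 0) stop("need m >= 0, L > 0, d >= 0")
  if (m / L > 1) stop("m/L must not exceed 1")
  if (2 * d > L) stop("window 2d must not exceed L")
  1 - (1 - m / L)^(2 * d)
}

#' Write motif hits as a BED-like TSV
#'
#' 1-based inclusive coordinates: \code{seq_id}, \code{start},
#' \code{end}, \code{strand}, \code{matched_seq},
#' \code{extended_identity}.
#'
#' @param hits Motif-hit data.frame from \code{\link{scanMotif}}.
#' @param path Output path.
#' @param seqId Sequence identifier for the first column.
#' @param consensus39 Optional consensus for the identity column.
#' @export
writeMotifHits <- function(hits, path, seqId = "LCR1", consensus39 = NULL) {
  k <- nchar(hits$matched_seq[1])
  ident <- if (is.null(consensus39)) NA_integer_ else
    vapply(hits$context39,
           function(ctx) extendedIdentity(ctx, consensus39)$count, 0L)
  d <- data.frame(seq_id = seqId, start = hits$position,
                  end = hits$position + k - 1L, strand = hits$strand,
                  matched_seq = hits$matched_seq,
                  extended_identity = ident, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
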