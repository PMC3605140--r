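## Marker classification for the paralogous repeat pair.  Candidate sites
## are positions where the reference sequences of LCR1 and LCR2 differ;
## resequencing both repeats in a control panel separates true
## LCR-specific markers (homozygous and invariant within each repeat,
## differing between them) from shared SNPs that segregate within the
## repeats and carry no copy-of-origin information.

.KLASS <- c("LCR_SPECIFIC", "SHARED_SNP", "UNCLASSIFIABLE")

.checkCandidates <- function(candidates) {
  need <- c("marker_id", "position", "lcr1_allele", "lcr2_allele")
  if (!all(need %in% names(candidates)))
    stop("candidates must have columns: ", paste(need, collapse = ", "))
  o <- order(candidates$position)
  if (is.unsorted(candidates$marker_id[o], strictly = TRUE))
    stop("marker_id must be strictly increasing with position")
  if (any(candidates$lcr1_allele == candidates$lcr2_allele))
    stop("every candidate must have differing LCR1/LCR2 reference alleles")
  invisible(candidates)
}

# split "C" / "C/T" call strings into allele character vectors; NA or ""
# is a missing call
.parseCall <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  sort(unique(strsplit(x, "/", fixed = TRUE)[[1]]))
}

#' Classify candidate sites into LCR-specific markers and shared SNPs
#'
#' A candidate site is \code{LCR_SPECIFIC} iff, across the whole control
#' panel, every LCR1 call is homozygous for one allele, every LCR2 call is
#' homozygous for a single different allele.  Any heterozygous control
#' call within either repeat, or any sharing of the fixed allele between
#' the repeats, demotes the site to \code{SHARED_SNP}.  Sites with no
#' informative calls in one or both repeats are flagged
#' \code{UNCLASSIFIABLE} rather than dropped.  Missing calls in some (not
#' all) individuals are ignored.
#'
#' @param candidates A data.frame of candidate sites with columns
#'   \code{marker_id}, \code{position}, \code{lcr1_allele},
#'   \code{lcr2_allele} (reference alleles, which must differ).
#' @param panel Control panel data.frame with one row per
#'   (individual, repeat, site): columns \code{individual}, \code{lcr}
#'   (1 or 2), \code{marker_id}, \code{alleles} ("C" homozygous, "C/T"
#'   heterozygous, NA/"" missing).
#' @return The candidate table, order preserved, with a \code{klass}
#'   column added.
#' @examples
#' sim <- simulateLCRPair(simConfig(seed = 1))
#' cls <- classifySites(sim$markers, sim$panel)
#' table(cls$klass)
#' @export
classifySites <- function(candidates, panel) {
  .checkCandidates(candidates)
  if (nrow(panel) == 0) stop("panel must be non-empty")
  need <- c("individual", "lcr", "marker_id", "alleles")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))

  classifyOne <- function(id) {
    calls1 <- panel$alleles[panel$marker_id == id & panel$lcr == 1]
    calls2 <- panel$alleles[panel$marker_id == id & panel$lcr == 2]
    a1 <- lapply(calls1, .parseCall)
    a2 <- lapply(calls2, .parseCall)
    a1 <- a1[lengths(a1) > 0]
    a2 <- a2[lengths(a2) > 0]
    if (length(a1) == 0 || length(a2) == 0) return("UNCLASSIFIABLE")
    allHom <- function(a) all(lengths(a) == 1L)
    if (!allHom(a1) || !allHom(a2)) return("SHARED_SNP")
    u1 <- unique(unlist(a1)); u2 <- unique(unlist(a2))
    if (length(u1) == 1L && length(u2) == 1L && u1 != u2)
      "LCR_SPECIFIC" else "SHARED_SNP"
  }
  out <- candidates
  out$klass <- vapply(candidates$marker_id, classifyOne, "")
  out
}

#' Read and write marker tables
#'
#' Marker tables are TSVs with columns \code{marker_id}, \code{position},
#' \code{lcr1_allele}, \code{lcr2_allele} and (after classification)
#' \code{klass}.
#'
#' @param path File path.
#' @param markers A marker data.frame.
#' @return \code{readMarkerTable}: the marker data.frame.
#' @name marker-io
NULL

#' @rdname marker-io
#' @export
readMarkerTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(lcr1_allele = "character",
                                           lcr2_allele = "character"))
  .checkCandidates(d)
  if ("klass" %in% names(d) && !all(d$klass %in% .KLASS))
    stop("klass must be one of: ", paste(.KLASS, collapse = ", "))
  d
}

#' @rdname marker-io
#' @export
writeMarkerTable <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a control-panel TSV
#'
#' One row per (individual, repeat copy, site); columns
#' \code{individual}, \code{lcr} in \{1, 2\}, \code{marker_id},
#' \code{alleles} (e.g. "C" or "C/T").
#'
#' @param path File path.
#' @return The panel data.frame.
#' @export
readControlPanel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(alleles = "character"))
  if (!all(d$lcr %in% c(1L, 2L))) stop("lcr column must be 1 or 2")
  d
}

#' Read an LCR pair from a FASTA file
#'
#' Expects a multi-record FASTA whose first two records are the proximal
#' and distal repeat (records named LCR1/LCR2 are picked up by name).
#'
#' @param path FASTA file path.
#' @param separation Genomic separation in bp (metadata).
#' @return An \code{\linkS4class{LCRPair}}.
#' @export
readLCRPair <- function(path, separation = 2e5) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 2) stop("FASTA must contain at least two records")
  nm <- names(ss)
  i1 <- if ("LCR1" %in% nm) match("LCR1", nm) else 1L
  i2 <- if ("LCR2" %in% nm) match("LCR2", nm) else 2L
  LCRPair(ss[[i1]], ss[[i2]], separation = separation)
}

#' Write an LCR pair to FASTA
#'
#' @param pair An \code{\linkS4class{LCRPair}}.
#' @param path Output FASTA path.
#' @export
writeLCRPair <- function(pair, path) {
  Biostrings::writeXStringSet(pair@seqs, path)
  invisible(path)
}
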