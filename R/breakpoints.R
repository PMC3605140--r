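## Breakpoint-interval calling for recombined (deleted/duplicated)
## alleles.  A recombined amplicon carries proximal-repeat alleles up to
## the crossover and distal-repeat alleles after it; only LCR-specific
## markers are informative, and the call is the maximal interval between
## the last proximal-type and first distal-type marker.  Deleted
## amplicons read LCR1 -> LCR2; duplicated amplicons are the reciprocal
## junction and read LCR2 -> LCR1.

.BINS <- c("BP1", "BP2", "BP3", "BP4", "BP5")

#' Default breakpoint bin map
#'
#' Named breakpoint bins as open intervals between LCR-specific marker
#' ids: BP1 = (17, 18), BP2 = (18, 24), BP3 = (25, 28) as mapped at the
#' DPY19L2 hotspot, plus two flanking bins BP4 = (16, 17) and
#' BP5 = (28, 29) seen only in sperm.  The map is configuration: pass a
#' modified copy to the callers to re-bin.
#'
#' @return A data.frame with columns \code{bin}, \code{left},
#'   \code{right}.
#' @export
defaultBinMap <- function() {
  data.frame(bin = c("BP1", "BP2", "BP3", "BP4", "BP5"),
             left = c(17L, 18L, 25L, 16L, 28L),
             right = c(18L, 24L, 28L, 17L, 29L),
             stringsAsFactors = FALSE)
}

# map an interval (left,right marker ids) to a bin name:
# exact match first, else the unique bin contained in the interval
# (intervals widened over missing calls), else UNRESOLVED
.binForInterval <- function(left, right, binMap) {
  hit <- binMap$bin[binMap$left == left & binMap$right == right]
  if (length(hit) == 1L) return(hit)
  inside <- binMap$bin[binMap$left >= left & binMap$right <= right]
  if (length(inside) == 1L) return(inside)
  "UNRESOLVED"
}

# per-marker origin states for one haplotype/genotype:
# list of integer vectors: 1 = proximal-repeat allele, 2 = distal,
# integer(0) = missing; length-2 c(1,2) = heterozygous
.markerStates <- function(calls, specific, kind) {
  prox <- if (kind == "DELETION") specific$lcr1_allele else specific$lcr2_allele
  dist <- if (kind == "DELETION") specific$lcr2_allele else specific$lcr1_allele
  lapply(seq_len(nrow(specific)), function(i) {
    id <- as.character(specific$marker_id[i])
    a <- .parseCall(if (id %in% names(calls)) calls[[id]] else NA_character_)
    if (length(a) == 0) return(integer())
    st <- ifelse(a == prox[i], 1L, ifelse(a == dist[i], 2L, NA_integer_))
    if (any(is.na(st)))
      stop("unknown allele '", a[is.na(st)][1], "' at marker ", id)
    sort(unique(st))
  })
}

.callRow <- function(leftIdx, rightIdx, specific, bin, note = "") {
  leftM <- if (is.na(leftIdx)) NA_integer_ else specific$marker_id[leftIdx]
  rightM <- if (is.na(rightIdx)) NA_integer_ else specific$marker_id[rightIdx]
  width <- if (is.na(leftIdx) || is.na(rightIdx)) NA_real_ else
    specific$position[rightIdx] - specific$position[leftIdx]
  mid <- if (is.na(width)) NA_real_ else
    (specific$position[rightIdx] + specific$position[leftIdx]) / 2
  data.frame(left_marker = leftM, right_marker = rightM, bin = bin,
             max_region_bp = width, left_pos =
               if (is.na(leftIdx)) NA_real_ else specific$position[leftIdx],
             right_pos =
               if (is.na(rightIdx)) NA_real_ else specific$position[rightIdx],
             midpoint = mid, note = note, stringsAsFactors = FALSE)
}

#' Call the maximal breakpoint interval of a recombined allele
#'
#' Maps each LCR-specific marker call to its repeat of origin and returns
#' the maximal crossover interval: (last proximal-type marker, first
#' distal-type marker).  Shared SNPs never affect the interval.  Missing
#' marker calls widen the interval to the nearest called markers.  A
#' genotype matching a single repeat across all markers has its
#' breakpoint outside the assayed window (\code{bin = "OUTSIDE"}); a
#' non-monotone pattern (proximal allele reappearing after the switch) is
#' \code{"UNRESOLVED"} with a diagnostic note.
#'
#' @param calls Named character vector or one-row list of per-marker
#'   calls; names are marker ids, values "C" (homozygous) or "C/T"
#'   (heterozygous -- rejected here, see
#'   \code{\link{decomposeHeterozygote}}); NA/"" missing.
#' @param markers Classified marker table (see
#'   \code{\link{classifySites}}); only \code{LCR_SPECIFIC} rows are
#'   used.
#' @param kind \code{"DELETION"} (amplicon read LCR1 -> LCR2) or
#'   \code{"DUPLICATION"} (reciprocal, LCR2 -> LCR1).
#' @param binMap Bin configuration, see \code{\link{defaultBinMap}}.
#' @return A one-row data.frame: \code{left_marker},
#'   \code{right_marker}, \code{bin}, \code{max_region_bp},
#'   \code{left_pos}, \code{right_pos}, \code{midpoint}, \code{note}.
#' @export
callBreakpoint <- function(calls, markers, kind = c("DELETION", "DUPLICATION"),
                           binMap = defaultBinMap()) {
  kind <- match.arg(kind)
  specific <- markers[markers$klass == "LCR_SPECIFIC", , drop = FALSE]
  specific <- specific[order(specific$position), , drop = FALSE]
  if (nrow(specific) == 0) stop("no LCR_SPECIFIC markers available")
  st <- .markerStates(calls, specific, kind)
  if (any(lengths(st) == 2L))
    stop("genotype is heterozygous at marker ",
         specific$marker_id[which(lengths(st) == 2L)[1]],
         "; use decomposeHeterozygote()")
  v <- vapply(st, function(s) if (length(s)) s else NA_integer_, 0L)
  i1 <- which(v == 1L); i2 <- which(v == 2L)
  if (length(i1) == 0 && length(i2) == 0)
    return(.callRow(NA, NA, specific, "UNRESOLVED", "no informative calls"))
  if (length(i2) == 0 || length(i1) == 0)
    return(.callRow(NA, NA, specific, "OUTSIDE",
                    "genotype matches a single repeat over all markers"))
  if (max(i1) > min(i2))
    return(.callRow(NA, NA, specific, "UNRESOLVED",
                    "non-monotone marker pattern (possible double crossover or genotyping error)"))
  .callRow(max(i1), min(i2), specific,
           .binForInterval(specific$marker_id[max(i1)],
                           specific$marker_id[min(i2)], binMap))
}

#' Decompose a compound-heterozygous recombined genotype
#'
#' A sample carrying two different recombined alleles is heterozygous at
#' the LCR-specific markers lying between the two crossover points, and
#' those markers must form one contiguous run.  The unique monotone
#' haplotype pair then switches at the start and after the end of the
#' run, yielding two breakpoint calls.
#'
#' @inheritParams callBreakpoint
#' @return A two-row data.frame of breakpoint calls (rows named
#'   \code{hapA}, \code{hapB}); on inconsistency, two UNRESOLVED rows
#'   with a diagnostic note.
#' @export
decomposeHeterozygote <- function(calls, markers,
                                  kind = c("DELETION", "DUPLICATION"),
                                  binMap = defaultBinMap()) {
  kind <- match.arg(kind)
  specific <- markers[markers$klass == "LCR_SPECIFIC", , drop = FALSE]
  specific <- specific[order(specific$position), , drop = FALSE]
  st <- .markerStates(calls, specific, kind)
  het <- which(lengths(st) == 2L)
  if (length(het) == 0)
    stop("genotype has no heterozygous LCR-specific marker; ",
         "use callBreakpoint()")
  unresolved <- function(msg) {
    out <- rbind(.callRow(NA, NA, specific, "UNRESOLVED", msg),
                 .callRow(NA, NA, specific, "UNRESOLVED", msg))
    rownames(out) <- c("hapA", "hapB")
    out
  }
  # heterozygous markers must be contiguous among *called* markers
  called <- which(lengths(st) > 0)
  hetRank <- match(het, called)
  if (any(diff(hetRank) != 1L))
    return(unresolved("heterozygous markers are non-contiguous: no consistent monotone haplotype pair"))
  v <- vapply(st, function(s) if (length(s) == 1L) s else NA_integer_, 0L)
  before <- called[called < min(het)]
  after <- called[called > max(het)]
  if (any(v[before] != 1L, na.rm = TRUE) || any(v[after] != 2L, na.rm = TRUE))
    return(unresolved("homozygous calls inconsistent with a single heterozygous switch region"))
  # hapA switches at the first het marker, hapB after the last
  hapA <- if (length(before) == 0)
    .callRow(NA, NA, specific, "OUTSIDE",
             "switch at or before the first informative marker")
  else
    .callRow(max(before), min(het), specific,
             .binForInterval(specific$marker_id[max(before)],
                             specific$marker_id[min(het)], binMap))
  hapB <- if (length(after) == 0)
    .callRow(NA, NA, specific, "OUTSIDE",
             "switch at or after the last informative marker")
  else
    .callRow(max(het), min(after), specific,
             .binForInterval(specific$marker_id[max(het)],
                             specific$marker_id[min(after)], binMap))
  out <- rbind(hapA, hapB)
  rownames(out) <- c("hapA", "hapB")
  out
}

#' Count distinct haplotypes per breakpoint bin
#'
#' Two recombined alleles represent the same founder event only if they
#' share both the breakpoint bin and the allele vector at the shared SNP
#' sites; the number of distinct (bin, SNP-vector) pairs is a lower bound
#' on the number of independent recombination events in the cohort.
#'
#' @param calls A data.frame with columns \code{bin} and
#'   \code{snp_vector} (a string encoding the ordered SNP alleles, e.g.
#'   "ACGT..."); one row per allele.  All bins must be resolved.
#' @return A list with \code{perBin} (named integer vector) and
#'   \code{total}.
#' @export
countHaplotypes <- function(calls) {
  if (nrow(calls) == 0) return(list(perBin = integer(), total = 0L))
  if (any(calls$bin %in% c("UNRESOLVED", "OUTSIDE")))
    stop("all calls must have a resolved breakpoint bin")
  sp <- split(calls$snp_vector, calls$bin)
  perBin <- vapply(sp, function(v) length(unique(v)), 0L)
  list(perBin = perBin, total = sum(perBin))
}

#' Tabulate breakpoint-bin distributions
#'
#' Counts and percentages (1 decimal) of breakpoint bins per
#' allele-kind x source group, plus a pooled tabulation over all groups.
#'
#' @param calls A data.frame with columns \code{bin}, \code{allele_kind},
#'   \code{source}; one row per resolved allele.
#' @param bins Bin levels to tabulate (default the five named bins
#'   present in the data, in standard order).
#' @return A list with \code{byGroup} and \code{pooled} data.frames
#'   (columns \code{allele_kind}, \code{source}, \code{bin},
#'   \code{count}, \code{pct}).
#' @export
tabulateDistribution <- function(calls, bins = NULL) {
  if (is.null(bins)) bins <- intersect(.BINS, unique(calls$bin))
  tabOne <- function(d) {
    n <- vapply(bins, function(b) sum(d$bin == b), 0L)
    data.frame(bin = bins, count = n,
               pct = round(100 * n / max(sum(n), 1L), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  grp <- interaction(calls$allele_kind, calls$source, drop = TRUE)
  byGroup <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- calls[grp == g, , drop = FALSE]
    cbind(allele_kind = d$allele_kind[1], source = d$source[1], tabOne(d))
  }))
  list(byGroup = byGroup, pooled = tabOne(calls))
}

#' Genotype table IO and per-sample calling
#'
#' Genotype TSVs have columns \code{sample_id}, \code{allele_kind},
#' \code{source}, then one column per marker named \code{m<marker_id>}
#' holding "C" or "C/T".  \code{callBreakpoints} runs
#' \code{\link{callBreakpoint}} (or the heterozygote decomposition) on
#' every row and returns one row per resolved allele.
#'
#' @param path TSV path.
#' @param genotypes A genotype data.frame as read by
#'   \code{readGenotypeTable}.
#' @param markers Classified marker table.
#' @param binMap Bin configuration.
#' @return \code{callBreakpoints}: data.frame of breakpoint calls with
#'   \code{sample_id}, \code{allele_kind}, \code{source} prepended.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
readGenotypeTable <- function(path) {
  # allele calls like "T" must never be parsed as logicals
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "allele_kind", "source")
  if (!all(need %in% names(d)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname genotype-io
#' @export
callBreakpoints <- function(genotypes, markers, binMap = defaultBinMap()) {
  mcols <- grep("^m[0-9]+$", names(genotypes), value = TRUE)
  out <- lapply(seq_len(nrow(genotypes)), function(i) {
    calls <- as.character(genotypes[i, mcols])
    names(calls) <- sub("^m", "", mcols)
    kind <- genotypes$allele_kind[i]
    het <- any(grepl("/", calls[!is.na(calls)], fixed = TRUE))
    # only LCR-specific het calls force decomposition
    if (het) {
      spc <- as.character(
        markers$marker_id[markers$klass == "LCR_SPECIFIC"])
      het <- any(grepl("/", calls[names(calls) %in% spc], fixed = TRUE))
    }
    cl <- if (het) decomposeHeterozygote(calls, markers, kind, binMap)
          else callBreakpoint(calls, markers, kind, binMap)
    cbind(sample_id = genotypes$sample_id[i], allele_kind = kind,
          source = genotypes$source[i], cl, row.names = NULL)
  })
  do.call(rbind, out)
}

#' @rdname genotype-io
#' @param calls A breakpoint-call data.frame.
#' @export
writeBreakpointReport <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
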