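## Limiting-dilution digital PCR with the exact hypergeometric zero-well
## model.  Each well receives W copies drawn without replacement from the
## N input copies, of which R are recombinant; the probability that a
## given well contains no recombinant is
##     P0(R) = C(N - R, W) / C(N, W) = prod_{i=0}^{R-1} (N - W - i)/(N - i)
## and R is recovered by tabulation against the observed negative-well
## fraction.  No Poisson or binomial approximation is used.

#' Template copies from DNA mass
#'
#' Converts a per-well DNA mass into haploid-genome copy numbers, assuming
#' one haploid genome weighs \code{pgPerHaploid} picograms (3 pg for
#' human).  50 ng per well gives 16667 copies per well and ~1.6e6 copies
#' per 96-well plate.
#'
#' @param massPerWellNg DNA mass per well in nanograms.
#' @param pgPerHaploid Picograms of DNA per haploid genome (default 3).
#' @param wellsPerPlate Wells per plate (default 96).
#' @return A list with \code{perWell} (rounded to the nearest copy) and
#'   \code{perPlate}.
#' @examples
#' copiesFromMass(50)   # deletion assay: ~1.6e6 copies per plate
#' copiesFromMass(100)  # duplication assay: ~3.2e6
#' @export
copiesFromMass <- function(massPerWellNg, pgPerHaploid = 3,
                           wellsPerPlate = 96) {
  if (!is.finite(massPerWellNg) || massPerWellNg <= 0)
    stop("massPerWellNg must be positive")
  if (pgPerHaploid <= 0 || wellsPerPlate < 1)
    stop("pgPerHaploid and wellsPerPlate must be positive")
  perWell <- round(massPerWellNg * 1000 / pgPerHaploid)
  list(perWell = perWell, perPlate = perWell * wellsPerPlate)
}

#' Hypergeometric probability that a well contains no recombinant
#'
#' For a well of \code{W} copies drawn without replacement from \code{N}
#' total copies containing \code{R} recombinants, returns
#' \eqn{C(N-R, W) / C(N, W)}, evaluated stably in log space as
#' \eqn{\sum_{i=0}^{R-1} \log(1 - W/(N-i))}.  \code{W} may be fractional
#' (mass-derived copy numbers); \code{R} must be a non-negative integer.
#' Vectorised over \code{R}.
#'
#' @param R Integer recombinant count(s), >= 0.
#' @param plate A \code{\linkS4class{PlateResult}} supplying N and W, or
#'   \code{NULL} if \code{N} and \code{W} are given directly.
#' @param N,W Total copies and copies per well (overridden by
#'   \code{plate}).
#' @return Probability vector, one value per element of \code{R};
#'   1 when R = 0 and 0 when R > N - W.
#' @examples
#' pZero(30, N = 1.6e6, W = 1.6e6 / 96)
#' @export
pZero <- function(R, plate = NULL, N = NULL, W = NULL) {
  if (!is.null(plate)) {
    N <- copiesTotal(plate)
    W <- copiesPerWell(plate)
  }
  if (is.null(N) || is.null(W)) stop("supply a plate or both N and W")
  if (any(R < 0)) stop("R must be non-negative")
  if (any(R != round(R))) stop("R must be integer-valued")
  rmax <- max(R)
  # log terms for i = 0 .. rmax-1; cumulative sum gives log P0 for all R
  if (rmax >= 1) {
    i <- 0:(rmax - 1)
    term <- rep(-Inf, rmax)  # fewer than W non-recombinants left to draw
    ok <- (N - i) > W
    term[ok] <- log1p(-W / (N - i[ok]))
    logp <- c(0, cumsum(term))
  } else {
    logp <- 0
  }
  out <- exp(logp[R + 1])
  out[R > N - W] <- 0
  out
}

#' Estimate the recombinant count of a plate by tabulation
#'
#' Finds the integer R whose hypergeometric zero-well probability is
#' closest to the observed fraction of negative wells, and returns the
#' corresponding rate estimate lambda = R / N (events per haploid
#' genome).  Ties are broken toward the smaller R.  Confidence bounds are
#' left unfilled; see \code{\link{rateCI}}.
#'
#' @param plate A \code{\linkS4class{PlateResult}}.
#' @param searchFactor Upper bound of the tabulation, as a multiple of the
#'   number of wells (default 10; the zero-well probability is far below
#'   any achievable negative fraction beyond that).
#' @return A \code{\linkS4class{RateEstimate}} (CI slots NA).
#' @examples
#' estimateRecombinants(PlateResult(96, 26, 1.6e6))  # R = 30
#' @export
estimateRecombinants <- function(plate, searchFactor = 10) {
  wt <- wellsTotal(plate)
  wp <- wellsPositive(plate)
  if (wp >= wt)
    stop("saturated plate (no negative wells): rate not estimable ",
         "by the zero-well model")
  negFrac <- (wt - wp) / wt
  rGrid <- 0:ceiling(searchFactor * wt)
  p0 <- pZero(rGrid, plate)
  R <- rGrid[which.min(abs(p0 - negFrac))]  # which.min: smallest R on ties
  RateEstimate(R, copiesTotal(plate))
}

#' Exact binomial confidence interval on a recombination rate
#'
#' Attaches a two-sided exact binomial (Clopper-Pearson) confidence
#' interval to a rate estimate, modelling the R recombinants among the N
#' input copies as a binomial draw (\code{stats::binom.test}).
#'
#' @param est A \code{\linkS4class{RateEstimate}}, or an integer R.
#' @param N Total copies; defaults to the estimate's own N.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return The estimate with \code{ciLow}/\code{ciHigh}/\code{level}
#'   filled in.
#' @examples
#' rateCI(estimateRecombinants(PlateResult(96, 26, 1.6e6)))
#' @export
rateCI <- function(est, N = NULL, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("level must be a single number in (0, 1)")
  if (is(est, "RateEstimate")) {
    R <- recombinants(est)
    if (is.null(N)) N <- copiesTotal(est)
  } else {
    R <- as.integer(est)
    if (is.null(N)) stop("N required when est is a bare count")
  }
  ci <- stats::binom.test(R, round(N), conf.level = level)$conf.int
  RateEstimate(R, N, ciLow = ci[1], ciHigh = ci[2], level = level)
}

#' Pool digital-PCR plates sharing one assay
#'
#' Sums wells, positive wells and input copies across plates run with the
#' same per-well copy number, so that the recombinant count can be
#' re-tabulated on the pooled negative-well fraction.  Re-tabulation on
#' the pooled plate is not in general the sum of per-plate tabulations
#' (for the duplication assay of the reference locus it yields 74 where
#' the per-donor counts sum to 73).
#'
#' @param plates A list of \code{\linkS4class{PlateResult}} objects.
#' @param tol Relative tolerance for equality of copies-per-well.
#' @return A pooled \code{\linkS4class{PlateResult}}.
#' @export
poolPlates <- function(plates, tol = 1e-6) {
  if (is(plates, "PlateResult")) plates <- list(plates)
  stopifnot(length(plates) >= 1)
  w <- vapply(plates, copiesPerWell, 0.0)
  if (diff(range(w)) > tol * mean(w))
    stop("cannot pool plates with different copies-per-well (W)")
  PlateResult(sum(vapply(plates, wellsTotal, 0L)),
              sum(vapply(plates, wellsPositive, 0L)),
              sum(vapply(plates, copiesTotal, 0.0)))
}

#' Compare two recombination rates
#'
#' Rate ratio lambda_a / lambda_b with a two-sided conditional exact
#' binomial test: conditional on the total count R_a + R_b, R_a is
#' binomial with expected proportion N_a / (N_a + N_b) under equal rates.
#'
#' @param a,b \code{\linkS4class{RateEstimate}} objects (each carrying its
#'   own N).
#' @return A list with \code{ratio} (NA when lambda_b = 0), \code{pValue},
#'   and the two rates.
#' @examples
#' del <- rateCI(estimateRecombinants(PlateResult(288, 74, 4.8e6)))
#' dup <- rateCI(estimateRecombinants(PlateResult(288, 65, 9.6e6)))
#' compareRates(del, dup)  # ~2.3-fold enrichment of deletions
#' @export
compareRates <- function(a, b) {
  ra <- recombinants(a); rb <- recombinants(b)
  na <- copiesTotal(a); nb <- copiesTotal(b)
  ratio <- if (rateValue(b) == 0) NA_real_ else rateValue(a) / rateValue(b)
  pValue <- if (ra + rb == 0) 1 else
    stats::binom.test(ra, ra + rb, p = na / (na + nb))$p.value
  list(ratio = ratio, pValue = pValue,
       rateA = rateValue(a), rateB = rateValue(b))
}

#' Read a plate summary table
#'
#' Reads a TSV with columns \code{plate_id}, \code{assay} (deletion or
#' duplication), \code{wells_total}, \code{wells_positive},
#' \code{mass_per_well_ng}, and builds one \code{PlateResult} per row
#' using \code{\link{copiesFromMass}}.
#'
#' @param path TSV file path.
#' @param pgPerHaploid Picograms per haploid genome (default 3).
#' @return A data.frame with the input columns plus \code{copies_total},
#'   and the \code{PlateResult} objects in attribute \code{"plates"}.
#' @export
readPlateSummary <- function(path, pgPerHaploid = 3) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "assay", "wells_total", "wells_positive",
            "mass_per_well_ng")
  if (!all(need %in% names(d)))
    stop("plate summary must have columns: ", paste(need, collapse = ", "))
  plates <- lapply(seq_len(nrow(d)), function(i) {
    cp <- copiesFromMass(d$mass_per_well_ng[i], pgPerHaploid,
                         d$wells_total[i])
    PlateResult(d$wells_total[i], d$wells_positive[i], cp$perPlate)
  })
  d$copies_total <- vapply(plates, copiesTotal, 0.0)
  attr(d, "plates") <- plates
  d
}
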