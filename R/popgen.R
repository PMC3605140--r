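## Population genetics: carrier-based allele frequencies and the General
## Selection Model (GSM) for a rare deleterious allele.
##
## Genotype fitnesses at the reference locus: homozygous wild-type 1;
## homozygous deleted 0.5 (men fully infertile, women unaffected; sexes
## averaged); heterozygote W, with heterozygous women assumed unaffected
## so W = (1 + w_male)/2 and w_male = 2W - 1.  For a rare allele the GSM
## recurrence simplifies to
##     dq = -q [ W (q - p) + p - q/2 ],   p = 1 - q,
## which at W = 1 reduces to dq = -q^2/2.

#' Population allele frequency from carrier counts
#'
#' Estimates a variant allele frequency from the number of heterozygous
#' carriers found among screened individuals: q = carriers / (2 *
#' individuals) (one variant allele per carrier), with an exact binomial
#' (Clopper-Pearson) confidence interval on that proportion.
#'
#' @param carriers Number of carriers observed.
#' @param individuals Number of individuals screened.
#' @param level Confidence level (default 0.95).
#' @return An \code{\linkS4class{AlleleFrequencyEstimate}}.
#' @examples
#' alleleFrequency(30, 8574)   # deleted allele:    q ~ 1.7e-3
#' alleleFrequency(100, 8574)  # duplicated allele: q ~ 5.8e-3
#' @export
alleleFrequency <- function(carriers, individuals, level = 0.95) {
  if (individuals < 1) stop("individuals must be >= 1")
  if (carriers < 0 || carriers > individuals)
    stop("carriers must be in [0, individuals]")
  n <- 2L * as.integer(individuals)
  bt <- stats::binom.test(as.integer(carriers), n, conf.level = level)
  new("AlleleFrequencyEstimate", carriers = as.integer(carriers),
      individuals = as.integer(individuals), q = carriers / n,
      ciLow = bt$conf.int[1], ciHigh = bt$conf.int[2], level = level)
}

#' Per-generation allele-frequency change under the General Selection Model
#'
#' Computes dq = -q [ W (q - p) + p - q/2 ] with p = 1 - q: the
#' per-generation change in the frequency of a rare allele whose
#' homozygote has fitness 0.5 (lethal-equivalent in one sex) and whose
#' heterozygote has fitness W.  At W = 1 this is exactly -q^2 / 2.
#'
#' @param q Allele frequency in (0, 1) (vectorised); q = 0 returns 0.
#' @param W Heterozygote relative fitness (sex-averaged), default 1.
#' @return dq (negative under purifying selection).
#' @examples
#' deltaQ(30 / 17148)  # ~ -1.5e-6 per generation
#' @export
deltaQ <- function(q, W = 1) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  p <- 1 - q
  -q * (W * (q - p) + p - q / 2)
}

#' Heterozygote fitness balancing a de novo production rate
#'
#' Inverts the GSM recurrence: given the allele frequency q and a target
#' per-generation change (typically minus the measured de novo NAHR
#' rate), solves
#'     W = ( -dq/q - p + q/2 ) / (q - p)
#' and converts the sex-averaged heterozygote fitness W into a male
#' heterozygote relative fitness 2W - 1 (heterozygous women assumed
#' unaffected).
#'
#' @param q Allele frequency in (0, 1), q != 1/2.
#' @param deltaQTarget Target dq (negative for a net loss).
#' @return A list with \code{W} and \code{maleHetFitness} (= 2W - 1).
#' @examples
#' solveHetFitness(30 / 17148, -1.8e-5)  # W ~ 0.99, male fitness ~ 98%
#' @export
solveHetFitness <- function(q, deltaQTarget) {
  if (any(q <= 0 | q >= 1)) stop("q must lie in (0, 1)")
  if (any(abs(q - 0.5) < 1e-12))
    stop("W is undefined at q = 1/2 (division by q - p)")
  p <- 1 - q
  W <- (-deltaQTarget / q - p + q / 2) / (q - p)
  list(W = W, maleHetFitness = 2 * W - 1)
}

#' Equilibrium frequency under mutation-selection balance (W = 1)
#'
#' With no heterozygote effect, selection removes q^2/2 per generation and
#' recurrent NAHR adds mu, so the equilibrium solves q^2/2 = mu:
#' q* = sqrt(2 mu).
#'
#' @param mu Per-generation de novo production rate of the allele.
#' @return Equilibrium allele frequency.
#' @export
equilibriumFrequency <- function(mu) {
  if (any(mu < 0)) stop("mu must be non-negative")
  sqrt(2 * mu)
}

#' Selection-recombination balance check
#'
#' Compares the GSM-predicted per-generation selective loss of the allele,
#' |dq| evaluated at the estimated frequency and at its confidence bounds
#' (endpoint transformation of the monotone map), with the measured de
#' novo production rate and its confidence interval, and reports whether
#' the two intervals overlap.  Non-overlap indicates that, at face value,
#' selection at the assumed fitnesses does not balance the de novo influx.
#'
#' @param freq An \code{\linkS4class{AlleleFrequencyEstimate}}.
#' @param deNovo A \code{\linkS4class{RateEstimate}} with CI filled.
#' @param W Heterozygote fitness used in the GSM (default 1).
#' @return A list with \code{selectionLoss} (point, low, high),
#'   \code{deNovoRate} (point, low, high), \code{overlap} (logical) and
#'   \code{W}.
#' @examples
#' f <- alleleFrequency(30, 8574)
#' r <- rateCI(estimateRecombinants(PlateResult(288, 74, 4.8e6)))
#' equilibriumCheck(f, r)
#' @export
equilibriumCheck <- function(freq, deNovo, W = 1) {
  qs <- c(alleleFreq(freq), alleleFreqCI(freq))
  loss <- sort(abs(deltaQ(qs, W)))  # |dq| monotone in q for rare alleles
  sel <- c(point = abs(deltaQ(alleleFreq(freq), W)),
           low = unname(loss[1]), high = unname(loss[3]))
  den <- c(point = rateValue(deNovo), rateCIBounds(deNovo))
  if (any(is.na(den[2:3])))
    stop("deNovo estimate must carry a confidence interval (see rateCI)")
  overlap <- sel["low"] <= den["high"] && den["low"] <= sel["high"]
  list(selectionLoss = sel, deNovoRate = den,
       overlap = unname(overlap), W = W)
}
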