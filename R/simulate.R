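## Seeded synthetic-data generator.  Emulates every input the pipeline
## consumes: a ~28 kb paralogous repeat pair at ~98% identity with
## LCR-specific markers, shared SNPs and planted PRDM9 13-mers; control
## resequencing panels; recombined-allele cohorts with founder
## structure; limiting-dilution plates partitioned without replacement;
## and the deterministic population-frequency recurrence.

.DNA <- c("A", "C", "G", "T")

# deterministic candidate-site layout used at the default site counts:
# 34 sites over a ~2.1 kb amplified window, 14 of them shared SNPs
# (including 19-23, 26, 27, making BP2 = (18,24) and BP3 = (25,28)
# adjacent-specific-marker intervals), with offsets calibrated so that
# pos(28) - pos(17) = 1153 bp
.canonicalSnpIds <- c(2L, 5L, 8L, 13L, 14L, 19L, 20L, 21L, 22L, 23L,
                      26L, 27L, 31L, 34L)
.canonicalOffsets <- c(40L * (1:16), 700L, 810L, 850L, 900L, 950L,
                       1000L, 1060L, 1150L, 1300L, 1500L, 1700L, 1853L,
                       1900L, 1930L, 1960L, 1990L, 2020L, 2050L)
.canonicalCentreOffset <- 1044L  # hotspot centre, inside BP2

#' Simulation configuration
#'
#' Bundles every generator parameter with its study-condition default:
#' a 28 kb repeat pair at 98% identity; 20 LCR-specific markers + 14
#' shared SNPs; a 1153 bp maximal hotspot; breakpoint-bin weights
#' proportional to the observed sperm deletion counts (2/56/10/2/4);
#' true de novo rates 1.8e-5 (deletion) and 7.7e-6 (duplication) per
#' haploid genome; founder counts 3/2/2 for BP1-BP3; 96-well plates at
#' 50 ng (deletion) or 100 ng (duplication) per well, 3 pg per haploid
#' genome; a 20-individual control panel; and a 5000-generation
#' deterministic trajectory with mutation pressure equal to the de novo
#' rates.
#'
#' @param seed Mandatory integer seed; every generator draws from it.
#' @param lcrLength,identity Repeat length (bp) and target pairwise
#'   identity.
#' @param nSpecific,nSnps Candidate-site composition.
#' @param hotspotWidth Calibrated maximal-region width, bp (markers
#'   17-28).
#' @param breakpointWeights Named per-bin sampling weights (sum to 1).
#' @param trueRateDel,trueRateDup True per-haploid-genome event rates.
#' @param foundersPerBin Named founder-haplotype counts per bin.
#' @param wellsPerPlate,massDelNg,massDupNg,pgPerHaploid Plate geometry.
#' @param nControls Control-panel size.
#' @param popGenerations,muDel,muDup,hetW,q0Del,q0Dup Trajectory
#'   parameters.
#' @return A list of validated parameters (class \code{"simConfig"}).
#' @export
simConfig <- function(seed,
                      lcrLength = 28000L, identity = 0.98,
                      nSpecific = 20L, nSnps = 14L,
                      hotspotWidth = 1153L,
                      breakpointWeights = c(BP1 = 2, BP2 = 56, BP3 = 10,
                                            BP4 = 2, BP5 = 4) / 74,
                      trueRateDel = 1.8e-5, trueRateDup = 7.7e-6,
                      foundersPerBin = c(BP1 = 3L, BP2 = 2L, BP3 = 2L,
                                         BP4 = 1L, BP5 = 1L),
                      wellsPerPlate = 96L, massDelNg = 50,
                      massDupNg = 100, pgPerHaploid = 3,
                      nControls = 20L,
                      popGenerations = 5000L,
                      muDel = 1.8e-5, muDup = 7.7e-6, hetW = 1,
                      q0Del = 0, q0Dup = 0) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (abs(sum(breakpointWeights) - 1) > 1e-9)
    stop("breakpointWeights must sum to 1")
  if (any(c(trueRateDel, trueRateDup, muDel, muDup) < 0) ||
      any(c(trueRateDel, trueRateDup) > 1))
    stop("rates must lie in [0, 1]")
  if (identity < 0 || identity > 1) stop("identity must lie in [0, 1]")
  if (hotspotWidth > lcrLength) stop("hotspotWidth must not exceed lcrLength")
  cfg <- list(seed = as.integer(seed), lcrLength = as.integer(lcrLength),
              identity = identity, nSpecific = as.integer(nSpecific),
              nSnps = as.integer(nSnps),
              hotspotWidth = as.integer(hotspotWidth),
              breakpointWeights = breakpointWeights,
              trueRateDel = trueRateDel, trueRateDup = trueRateDup,
              foundersPerBin = foundersPerBin,
              wellsPerPlate = as.integer(wellsPerPlate),
              massDelNg = massDelNg, massDupNg = massDupNg,
              pgPerHaploid = pgPerHaploid, nControls = as.integer(nControls),
              popGenerations = as.integer(popGenerations),
              muDel = muDel, muDup = muDup, hetW = hetW,
              q0Del = q0Del, q0Dup = q0Dup)
  class(cfg) <- "simConfig"
  cfg
}

# derive a reproducible sub-seed so the independent generators do not
# share a stream; kept within 32-bit integer range
.subSeed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 48271 + offset) %% 2147483647)
}

# instantiate a degenerate IUPAC pattern: N positions drawn uniformly
.instantiateMotif <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  ch[ch == "N"] <- sample(.DNA, sum(ch == "N"), replace = TRUE)
  paste(ch, collapse = "")
}

`.sub<-` <- function(x, at, value) {
  # in-place substring assignment on a character scalar split vector
  x[at:(at + nchar(value) - 1)] <- strsplit(value, "")[[1]]
  x
}

#' Generate a synthetic LCR pair with markers, panel and planted motifs
#'
#' Builds two coordinate-matched repeat sequences at the configured
#' identity, plants five 13-mer recognition sites in each copy (one at
#' the hotspot centre plus four decoys, mixed strands) and scrubs any
#' chance matches so a scan returns exactly the planted sites; lays out
#' the candidate variant sites (truth-labelled LCR-specific markers vs
#' shared SNPs) and generates a control resequencing panel in which every
#' SNP site carries at least one call violating LCR-specificity (so
#' noise-free classification recovers the truth labels exactly).
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A list: \code{pair} (\code{\linkS4class{LCRPair}}),
#'   \code{markers} (truth-labelled candidate table with \code{klass}),
#'   \code{panel} (control-panel data.frame), \code{motifSites}
#'   (planted positions/strands), \code{centre} (hotspot centre, bp),
#'   \code{binMap}.
#' @export
simulateLCRPair <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(.subSeed(cfg, 1L))
  L <- cfg$lcrLength
  centre <- L %/% 2L

  s1 <- sample(.DNA, L, replace = TRUE)

  ## candidate-site layout
  nCand <- cfg$nSpecific + cfg$nSnps
  if (cfg$nSpecific == 20L && cfg$nSnps == 14L) {
    scale <- cfg$hotspotWidth / 1153
    offsets <- as.integer(round(.canonicalOffsets * scale))
    snpIds <- .canonicalSnpIds
    ampStart <- centre - as.integer(round(.canonicalCentreOffset * scale))
  } else if (nCand > 0) {
    span <- min(2100L, L - 2L)
    offsets <- sort(sample.int(span, nCand))
    snpIds <- sort(sample.int(nCand, cfg$nSnps))
    ampStart <- centre - span %/% 2L
  } else {
    offsets <- integer(); snpIds <- integer(); ampStart <- centre
  }
  positions <- ampStart + offsets
  if (nCand > 0 && (min(positions) < 1L || max(positions) > L))
    stop("candidate sites fall outside the sequence; increase lcrLength")

  ## plant motif instances (identical in both copies)
  pat <- prdm9Motif()
  k <- nchar(pat)
  motifStarts <- c(centre - (k %/% 2L),
                   as.integer(round(L * c(0.12, 0.32, 0.68, 0.88))))
  motifStrands <- c("+", "-", "+", "-", "+")
  protected <- unique(c(positions,
                        unlist(lapply(motifStarts,
                                      function(p) p:(p + k - 1L)))))
  for (i in seq_along(motifStarts)) {
    inst <- .instantiateMotif(pat)
    if (motifStrands[i] == "-")
      inst <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(inst)))
    .sub(s1, motifStarts[i]) <- inst
  }

  ## diverge the second copy: candidate sites always differ, plus enough
  ## background substitutions to reach the target identity
  s2 <- s1
  nDiff <- max(round((1 - cfg$identity) * L), nCand)
  pool <- setdiff(seq_len(L), protected)
  extra <- sample(pool, max(nDiff - nCand, 0L))
  for (p in c(positions, extra))
    s2[p] <- sample(setdiff(.DNA, s2[p]), 1L)

  ## scrub chance motif matches so exactly the 5 planted sites remain
  plantedSet <- motifStarts
  for (iter in 1:50) {
    dirty <- FALSE
    for (sq in c("s1", "s2")) {
      v <- get(sq)
      hits <- scanMotif(paste(v, collapse = ""), pat)
      stray <- hits$position[!(hits$position %in% plantedSet)]
      for (h in stray) {
        # break the match at a non-degenerate pattern position that is
        # neither a candidate site nor inside a planted motif
        fixedPos <- h + which(strsplit(pat, "")[[1]] != "N") - 1L
        fixedPos <- setdiff(fixedPos, protected)
        if (length(fixedPos) == 0) next
        p <- fixedPos[1]
        repl <- sample(setdiff(.DNA, c(s1[p], s2[p])), 1L)
        s1[p] <- repl  # same base in both copies: identity preserved
        s2[p] <- repl
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }

  seq1 <- paste(s1, collapse = "")
  seq2 <- paste(s2, collapse = "")

  ## truth-labelled candidate table
  if (nCand > 0) {
    klass <- ifelse(seq_len(nCand) %in% snpIds, "SHARED_SNP", "LCR_SPECIFIC")
    markers <- data.frame(marker_id = seq_len(nCand), position = positions,
                          lcr1_allele = s1[positions],
                          lcr2_allele = s2[positions],
                          klass = klass, stringsAsFactors = FALSE)
  } else {
    markers <- data.frame(marker_id = integer(), position = integer(),
                          lcr1_allele = character(),
                          lcr2_allele = character(), klass = character(),
                          stringsAsFactors = FALSE)
  }

  panel <- .simulatePanel(cfg, markers)

  list(pair = LCRPair(seq1, seq2),
       markers = markers, panel = panel,
       motifSites = data.frame(position = motifStarts,
                               strand = motifStrands,
                               site = letters[seq_along(motifStarts)],
                               stringsAsFactors = FALSE),
       centre = centre, binMap = defaultBinMap())
}

# control panel: specific sites fixed and homozygous per repeat; SNP
# sites segregate both alleles within each repeat, with one guaranteed
# heterozygous call so zero-noise classification is exact
.simulatePanel <- function(cfg, markers) {
  if (nrow(markers) == 0 || cfg$nControls == 0)
    return(data.frame(individual = character(), lcr = integer(),
                      marker_id = integer(), alleles = character(),
                      stringsAsFactors = FALSE))
  ids <- sprintf("ctrl%02d", seq_len(cfg$nControls))
  rows <- vector("list", nrow(markers) * 2L)
  ri <- 0L
  for (i in seq_len(nrow(markers))) {
    a <- markers$lcr1_allele[i]; b <- markers$lcr2_allele[i]
    for (lcr in 1:2) {
      if (markers$klass[i] == "LCR_SPECIFIC") {
        calls <- rep(if (lcr == 1) a else b, cfg$nControls)
      } else {
        g <- sample(0:2, cfg$nControls, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
        calls <- c(a, paste(sort(c(a, b)), collapse = "/"), b)[g + 1L]
        if (lcr == 1) calls[1] <- paste(sort(c(a, b)), collapse = "/")
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(individual = ids, lcr = lcr,
                               marker_id = markers$marker_id[i],
                               alleles = calls, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a cohort of recombined alleles with founder structure
#'
#' Draws breakpoint bins from the configured weights (or exact per-bin
#' counts), places each crossover uniformly inside its bin interval,
#' assigns founder SNP haplotypes round-robin within each bin (so every
#' founder is represented when the bin holds at least that many alleles)
#' and derives the per-marker allele of each recombined amplicon:
#' proximal-repeat alleles before the crossover, distal-repeat after,
#' founder alleles at the shared SNPs.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param sim Output of \code{\link{simulateLCRPair}}.
#' @param nAlleles Number of alleles to draw (ignored when
#'   \code{binCounts} is given).
#' @param kind \code{"DELETION"} or \code{"DUPLICATION"}.
#' @param source \code{"SOMATIC"} or \code{"SPERM"}.
#' @param binCounts Optional named vector of exact per-bin allele counts.
#' @param foundersPerBin Named founder counts (default from \code{cfg}).
#' @param streamOffset Integer offset decoupling this draw from other
#'   generators under the same seed.
#' @return A data.frame, one row per allele: \code{allele_id},
#'   \code{bin_true}, \code{founder}, \code{breakpoint_pos},
#'   \code{snp_vector}, \code{allele_kind}, \code{source}, and one
#'   \code{m<id>} call column per marker.
#' @export
simulateCohort <- function(cfg, sim, nAlleles,
                           kind = c("DELETION", "DUPLICATION"),
                           source = c("SPERM", "SOMATIC"),
                           binCounts = NULL, foundersPerBin = NULL,
                           streamOffset = 2L) {
  kind <- match.arg(kind); source <- match.arg(source)
  set.seed(.subSeed(cfg, streamOffset))
  markers <- sim$markers
  binMap <- sim$binMap
  if (is.null(foundersPerBin)) foundersPerBin <- cfg$foundersPerBin
  bins <- if (!is.null(binCounts)) {
    rep(names(binCounts), binCounts)
  } else if (nAlleles > 0) {
    sample(names(cfg$breakpointWeights), nAlleles, replace = TRUE,
           prob = cfg$breakpointWeights)
  } else character()

  snp <- markers[markers$klass == "SHARED_SNP", , drop = FALSE]
  spc <- markers[markers$klass == "LCR_SPECIFIC", , drop = FALSE]
  ## distinct founder haplotypes per bin over the SNP sites
  founderHaps <- lapply(sort(unique(bins)), function(b) {
    kf <- max(1L, foundersPerBin[[b]])
    if (nrow(snp) == 0) return(rep("", kf))  # no SNPs: haplotypes degenerate
    haps <- character(0)
    while (length(haps) < kf)  # resample collisions to keep them distinct
      haps <- unique(c(haps, vapply(seq_len(kf - length(haps)), function(j)
        paste(ifelse(stats::runif(nrow(snp)) < 0.5,
                     snp$lcr1_allele, snp$lcr2_allele), collapse = ""),
        "")))
    haps
  })
  names(founderHaps) <- sort(unique(bins))

  if (length(bins) == 0) {
    d <- data.frame(allele_id = character(), bin_true = character(),
                    founder = character(), breakpoint_pos = numeric(),
                    snp_vector = character(), allele_kind = character(),
                    source = character(), stringsAsFactors = FALSE)
    d[paste0("m", markers$marker_id)] <- list(character())
    return(d)
  }
  ## vectorised draw: crossover positions and round-robin founders
  lp <- markers$position[match(binMap$left[match(bins, binMap$bin)],
                               markers$marker_id)]
  rp <- markers$position[match(binMap$right[match(bins, binMap$bin)],
                               markers$marker_id)]
  bp <- stats::runif(length(bins), lp, rp)
  fIdx <- stats::ave(seq_along(bins), bins, FUN = function(i)
    (seq_along(i) - 1L) %% length(founderHaps[[bins[i[1]]]]) + 1L)
  hap <- vapply(seq_along(bins),
                function(i) founderHaps[[bins[i]]][fIdx[i]], "")

  prox <- if (kind == "DELETION") markers$lcr1_allele else markers$lcr2_allele
  dist <- if (kind == "DELETION") markers$lcr2_allele else markers$lcr1_allele
  out <- data.frame(allele_id = sprintf("al%05d", seq_along(bins)),
                    bin_true = bins,
                    founder = sprintf("%s_f%d", bins, fIdx),
                    breakpoint_pos = bp, snp_vector = hap,
                    allele_kind = kind, source = source,
                    stringsAsFactors = FALSE)
  snpRank <- match(markers$marker_id, snp$marker_id)  # NA for specific
  for (j in seq_len(nrow(markers))) {
    col <- paste0("m", markers$marker_id[j])
    out[[col]] <- if (markers$klass[j] == "LCR_SPECIFIC")
      ifelse(markers$position[j] < bp, prox[j], dist[j])
    else
      substr(hap, snpRank[j], snpRank[j])
  }
  out
}

#' Assemble diploid genotype rows from simulated alleles
#'
#' Combines pairs of simulated alleles into per-sample genotype rows as
#' observed after amplification: at each marker the union of the two
#' allele calls, written "C" when identical and "C/T" when they differ.
#' For haploid (sperm) data pass each allele as its own pair.
#'
#' @param alleles Output of \code{\link{simulateCohort}}.
#' @param pairs Two-column integer matrix of allele row indices; each row
#'   is one sample.
#' @param sampleIds Optional sample names.
#' @return A genotype data.frame suitable for
#'   \code{\link{callBreakpoints}}.
#' @export
assembleGenotypes <- function(alleles, pairs,
                              sampleIds = sprintf("s%03d", seq_len(nrow(pairs)))) {
  pairs <- as.matrix(pairs)
  mcols <- grep("^m[0-9]+$", names(alleles), value = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- alleles[pairs[i, 1], ]; b <- alleles[pairs[i, 2], ]
    calls <- vapply(mcols, function(m) {
      u <- sort(unique(c(a[[m]], b[[m]])))
      paste(u, collapse = "/")
    }, "")
    row <- data.frame(sample_id = sampleIds[i],
                      allele_kind = a$allele_kind, source = a$source,
                      stringsAsFactors = FALSE)
    row[mcols] <- as.list(calls)
    row
  })
  do.call(rbind, rows)
}

#' Simulate a limiting-dilution digital-PCR plate
#'
#' Draws the true recombinant count binomially from the input copies at
#' the configured rate, then allocates recombinants to wells without
#' replacement (each of the N copy "slots" belongs to exactly one well:
#' a multivariate hypergeometric partition).  A well is positive iff it
#' holds at least one recombinant.  The truth is retained for recovery
#' tests.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param assay \code{"deletion"} or \code{"duplication"} (sets mass per
#'   well and true rate).
#' @param replicate Replicate index (decorrelates the stream).
#' @return A list with \code{plate} (\code{\linkS4class{PlateResult}}),
#'   \code{rTrue}, and \code{trueRate}.
#' @export
simulatePlate <- function(cfg, assay = c("deletion", "duplication"),
                          replicate = 1L) {
  assay <- match.arg(assay)
  set.seed(.subSeed(cfg, 1000L + 2L * replicate +
                      (assay == "duplication")))
  mass <- if (assay == "deletion") cfg$massDelNg else cfg$massDupNg
  rate <- if (assay == "deletion") cfg$trueRateDel else cfg$trueRateDup
  cp <- copiesFromMass(mass, cfg$pgPerHaploid, cfg$wellsPerPlate)
  N <- cp$perPlate; W <- cp$perWell
  rTrue <- stats::rbinom(1L, N, rate)
  posWells <- if (rTrue > 0) {
    slots <- sample.int(N, rTrue)       # without replacement
    length(unique((slots - 1L) %/% W))
  } else 0L
  list(plate = PlateResult(cfg$wellsPerPlate, posWells, N),
       rTrue = rTrue, trueRate = rate)
}

#' Deterministic allele-frequency trajectory
#'
#' Iterates the infinite-population recurrence: the deleted allele loses
#' \code{deltaQ(q, W)} to selection and gains \code{muDel} by recurrent
#' NAHR each generation; the duplicated allele, not under selection,
#' gains \code{muDup} linearly.  Frequencies leaving [0, 1] are clipped
#' with a warning.  Under W = 1 the deleted allele converges to the
#' mutation-selection equilibrium q* = sqrt(2 mu).
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A data.frame: \code{generation}, \code{q_del}, \code{q_dup}.
#' @export
populationTrajectory <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  n <- cfg$popGenerations
  qd <- numeric(n + 1L); qu <- numeric(n + 1L)
  qd[1] <- cfg$q0Del; qu[1] <- cfg$q0Dup
  clipped <- FALSE
  for (t in seq_len(n)) {
    qd[t + 1] <- qd[t] + deltaQ(qd[t], cfg$hetW) + cfg$muDel
    qu[t + 1] <- qu[t] + cfg$muDup
    if (qd[t + 1] < 0 || qd[t + 1] > 1 || qu[t + 1] > 1) clipped <- TRUE
    qd[t + 1] <- min(max(qd[t + 1], 0), 1)
    qu[t + 1] <- min(qu[t + 1], 1)
  }
  if (clipped) warning("frequency left [0, 1] and was clipped")
  data.frame(generation = 0:n, q_del = qd, q_dup = qu)
}
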